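#' Simulation configuration
#'
#' Defaults mirror the cohort this pipeline was designed around: two
#' treatment-naive biopsies per tumour, 1-9 clones per treatment-naive
#' tumour (up to 11 once post-treatment samples are added), a cohort-mean
#' shared-mutation fraction of ~0.63, tumour purities 0.38-0.94, ~60x
#' depth, survival censored at 60 months with ~35-month median, and a
#' hazard ratio of 4 for patients carrying the APOBEC signature in their
#' private mutations. Mutations per clone default to a desk-scale 50-250.
#'
#' @param n_tumours number of tumours in the cohort.
#' @param samples_per_tumour_pre treatment-naive biopsies per tumour.
#' @param include_post simulate post-treatment samples as well.
#' @param n_post_samples post-treatment samples per tumour (when included).
#' @param clones_range inclusive range of treatment-naive clone counts.
#' @param post_extra_clones range of additional post-only clones.
#' @param mutations_per_clone inclusive range of mutations per clone.
#' @param shared_fraction target cohort shared-mutation fraction.
#' @param platinum_fraction_post fraction of post-only clone mutations that
#'   are planted platinum-style C>A-in-CpC events.
#' @param depth_mean mean sequencing depth (Poisson).
#' @param purity_range per-sample tumour purity range.
#' @param apobec_private_prob probability a tumour carries planted APOBEC
#'   (SBS2/13, with co-occurring SBS3) in its subclonal mutations.
#' @param hr_signature_present disease-specific-survival hazard ratio for
#'   signature-positive patients.
#' @param median_dss_months baseline median survival.
#' @param censor_month administrative censoring horizon.
#' @param genome_length fixture genome length (bases).
#' @param cpc_target target CpC dinucleotide frequency of the genome.
#' @param min_alt_reads alt-read threshold for a mutation to be "called" in
#'   a sample.
#' @param call_fn_rate per-sample probability that a detectable mutation is
#'   nevertheless missed by the caller (imperfect sensitivity; real call
#'   sets never agree perfectly even for fully clonal tumours).
#' @param seed integer seed; all cohort randomness derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_tumours = 29,
                       samples_per_tumour_pre = 2,
                       include_post = FALSE,
                       n_post_samples = 2,
                       clones_range = c(1, 9),
                       post_extra_clones = c(1, 3),
                       mutations_per_clone = c(50, 250),
                       shared_fraction = 0.628,
                       platinum_fraction_post = 0.3,
                       depth_mean = 60,
                       purity_range = c(0.38, 0.94),
                       apobec_private_prob = 0.4,
                       hr_signature_present = 4,
                       median_dss_months = 35,
                       censor_month = 60,
                       genome_length = 5e5,
                       cpc_target = 0.05,
                       min_alt_reads = 3,
                       call_fn_rate = 0.06,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$shared_fraction >= 0, cfg$shared_fraction <= 1,
            cfg$platinum_fraction_post >= 0, cfg$platinum_fraction_post < 1,
            diff(cfg$clones_range) >= 0, diff(cfg$mutations_per_clone) >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a reproducible fixture genome
#'
#' Single random contig with a tunable CpC dinucleotide frequency,
#' generated by a first-order Markov chain on {C, not-C}: with stationary
#' C frequency ~0.2, `P(C|C)` is set so that the CpC frequency matches
#' `cpc_target`. Deterministic given `seed`.
#'
#' @param length contig length in bases.
#' @param seed integer seed.
#' @param cpc_target target CpC dinucleotide frequency.
#' @param path optional FASTA output path.
#' @return named character vector (contig `"chr1"`); written to `path` as
#'   FASTA when given.
#' @export
make_fixture_genome <- function(length, seed, cpc_target = 0.05, path = NULL) {
  stopifnot(length >= 2, cpc_target > 0, cpc_target < 0.2)
  set.seed(seed)
  pi_c <- 0.2
  a <- cpc_target / pi_c            # P(C | prev C)
  b <- pi_c * (1 - a) / (1 - pi_c)  # P(C | prev not-C)
  u <- runif(length)
  is_c <- logical(length)
  is_c[1] <- runif(1) < pi_c
  for (i in 2:length) {
    is_c[i] <- u[i] < (if (is_c[i - 1]) a else b)
  }
  bases <- sample(c("A", "G", "T"), length, replace = TRUE,
                  prob = c(0.375, 0.25, 0.375))
  bases[is_c] <- "C"
  genome <- c(chr1 = paste(bases, collapse = ""))
  if (!is.null(path)) write_genome(genome, path)
  genome
}

# Index of genome positions by pyrimidine-strand trinucleotide context.
# Returns an environment with `groups` (context string -> integer positions)
# and `bases` for fast lookups.
context_index <- function(genome) {
  stopifnot(length(genome) == 1)
  b <- strsplit(genome[[1]], "")[[1]]
  L <- length(b)
  p <- 2:(L - 1)
  centre <- b[p]
  is_pyr <- centre %in% c("C", "T")
  ctx <- character(length(p))
  fwd <- paste0(b[p - 1], centre, b[p + 1])
  comp <- REVCOMP
  rev3 <- paste0(comp[b[p + 1]], comp[centre], comp[b[p - 1]])
  ctx[is_pyr] <- fwd[is_pyr]
  ctx[!is_pyr] <- rev3[!is_pyr]
  list(groups = split(p, ctx), bases = b, contig = names(genome)[1])
}

channel_context <- function(channel_label) {
  paste0(substr(channel_label, 1, 1), substr(channel_label, 3, 3),
         substr(channel_label, 7, 7))
}

#' Draw mutations from a signature mixture
#'
#' Channels are drawn multinomially from the mixture's 96-channel
#' probability vector; genomic positions are then drawn uniformly (without
#' replacement) among the genome sites whose pyrimidine-strand context
#' matches each channel. Records on the purine strand are emitted with
#' genome-consistent ref/alt and reference-strand context.
#'
#' @param mixture named signature weights (summing to 1) or a bare
#'   96-channel probability vector.
#' @param n number of mutations.
#' @param genome single-contig genome (see [make_fixture_genome()]).
#' @param seed integer seed.
#' @param matrix `signature_matrix` resolving signature names (default
#'   [sbs_reference()]); ignored when `mixture` is already a 96-vector.
#' @param index optional precomputed context index (internal reuse).
#' @param used optional logical vector marking positions already taken.
#' @return tibble: `chrom`, `pos`, `ref`, `alt`, `context`, `channel`.
#' @export
sample_mutations_from_signature <- function(mixture, n, genome, seed,
                                            matrix = sbs_reference(),
                                            index = NULL, used = NULL) {
  set.seed(seed)
  if (n == 0) {
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          context = character(0), channel = integer(0)))
  }
  if (length(mixture) == 96 && is.null(names(mixture))) {
    probs <- mixture / sum(mixture)
  } else {
    miss <- setdiff(names(mixture), colnames(matrix))
    if (length(miss) > 0) stop("unknown signature(s): ",
                               paste(miss, collapse = ", "))
    w <- mixture / sum(mixture)
    probs <- as.numeric(unclass(matrix)[, names(w), drop = FALSE] %*% w)
  }
  if (is.null(index)) index <- context_index(genome)
  # positions are always drawn without replacement, also across channels
  # sharing a context; the used vector is returned only when supplied
  return_used <- !is.null(used)
  if (is.null(used)) used <- logical(nchar(genome[[1]]))
  track_used <- TRUE
  labs <- sbs96_labels()
  counts <- as.integer(rmultinom(1, n, probs))
  out <- vector("list", 96)
  for (ch in which(counts > 0)) {
    ctx <- channel_context(labs[ch])
    pool <- index$groups[[ctx]]
    if (track_used) pool <- pool[!used[pool]]
    if (length(pool) < counts[ch]) {
      stop("fixture genome has too few unused sites for context ", ctx)
    }
    pos <- if (length(pool) == 1) pool else sample(pool, counts[ch])
    if (track_used) used[pos] <- TRUE
    pyr_ref <- substr(labs[ch], 3, 3)
    pyr_alt <- substr(labs[ch], 5, 5)
    base <- index$bases[pos]
    on_pyr <- base == pyr_ref
    ref <- ifelse(on_pyr, pyr_ref, unname(REVCOMP[pyr_ref]))
    alt <- ifelse(on_pyr, pyr_alt, unname(REVCOMP[pyr_alt]))
    ctx_fwd <- paste0(index$bases[pos - 1], base, index$bases[pos + 1])
    out[[ch]] <- tibble::tibble(
      chrom = index$contig, pos = as.integer(pos), ref = ref, alt = alt,
      context = ctx_fwd, channel = as.integer(ch)
    )
  }
  res <- dplyr::bind_rows(out)
  if (return_used) attr(res, "used") <- used
  res
}

#' Plant platinum-style mutations into a record set
#'
#' Adds C>A substitutions preferentially at CpC-context cytosines (and,
#' symmetrically, G>T at GpG guanines) so that the planted events make up
#' `fraction` of the returned set — the genomic footprint of platinum
#' chemotherapy.
#'
#' @param records mutation tibble (typically a post-only clone's mutations).
#' @param fraction target fraction of platinum events in the result.
#' @param genome single-contig genome.
#' @param seed integer seed.
#' @param index,used optional context index / used-position tracking.
#' @param cpc_bias probability a planted event lands in CpC (vs any C)
#'   context.
#' @return augmented tibble; added rows carry `planted_platinum = TRUE`.
#' @export
plant_platinum <- function(records, fraction, genome, seed,
                           index = NULL, used = NULL, cpc_bias = 0.9) {
  if (fraction == 0 || nrow(records) == 0) return(records)
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  if (is.null(index)) index <- context_index(genome)
  n_add <- max(1L, round(fraction * nrow(records) / (1 - fraction)))
  labs <- sbs96_labels()
  ca_channels <- which(grepl("\\[C>A\\]", labs))
  cpc_channels <- ca_channels[substr(labs[ca_channels], 1, 1) == "C"]
  probs <- numeric(96)
  probs[cpc_channels] <- cpc_bias / length(cpc_channels)
  probs[setdiff(ca_channels, cpc_channels)] <-
    (1 - cpc_bias) / length(setdiff(ca_channels, cpc_channels))
  extra <- sample_mutations_from_signature(
    probs, n_add, genome, seed = seed + 1, index = index, used = used
  )
  used_out <- attr(extra, "used")
  template <- records[sample.int(nrow(records), n_add, replace = TRUE), ,
                      drop = FALSE]
  for (col in c("chrom", "pos", "ref", "alt", "context", "channel")) {
    template[[col]] <- extra[[col]]
  }
  template$planted_platinum <- TRUE
  if (!"planted_platinum" %in% names(records)) {
    records$planted_platinum <- FALSE
  }
  out <- dplyr::bind_rows(records, template)
  if (!is.null(used_out)) attr(out, "used") <- used_out
  out
}

#' Simulate disease-specific survival under proportional hazards
#'
#' Exponential event times with the hazard multiplied by `hr` for
#' signature-present patients; administrative censoring at `censor_month`.
#'
#' @param presence_flags logical vector (one per patient).
#' @param hr hazard ratio for flagged patients.
#' @param seed integer seed.
#' @param median_months baseline median survival.
#' @param censor_month censoring horizon.
#' @return tibble: `dss_months`, `event`.
#' @export
simulate_survival <- function(presence_flags, hr, seed,
                              median_months = 35, censor_month = 60) {
  set.seed(seed)
  n <- length(presence_flags)
  rate <- log(2) / median_months * ifelse(presence_flags, hr, 1)
  t <- rexp(n, rate)
  tibble::tibble(
    dss_months = pmin(t, censor_month),
    event = as.integer(t <= censor_month)
  )
}
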