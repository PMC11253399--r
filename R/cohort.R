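#' Plant a clone structure for one tumour and emit read counts
#'
#' Draws a clone tree with per-sample prevalences obeying the sum rule
#' (children of a parent never exceed it in any sample), assigns mutations
#' to clones from per-clone signature mixtures, and emits binomial read
#' counts at the configured depth given purity and CCF. Shared/private
#' structure arises from clone-by-sample presence; the founder-clone
#' mutation count is calibrated so the expected shared fraction matches
#' `config$shared_fraction`. When `config$include_post` is set, post-only
#' clones are added and their mutations are seeded with platinum-style
#' C>A-in-CpC events via [plant_platinum()].
#'
#' @param config a [sim_config()].
#' @param genome single-contig genome.
#' @param tumour_id tumour identifier.
#' @param seed integer seed for this tumour.
#' @param index optional precomputed context index.
#' @return list with `records` (called mutations, one row per key per
#'   carrying sample), `pileup` (all key x sample cells), `sample_info`,
#'   and `truth` (clone table + per-tumour flags + `assignment` key->clone).
#' @export
plant_clone_structure <- function(config, genome, tumour_id = "TUM01",
                                  seed = 1, index = NULL) {
  set.seed(seed)
  if (is.null(index)) index <- context_index(genome)
  n_pre <- config$samples_per_tumour_pre
  pre_samples <- paste0(tumour_id, "_T", seq_len(n_pre))
  post_samples <- if (config$include_post) {
    paste0(tumour_id, "_P", seq_len(config$n_post_samples))
  } else character(0)
  samples <- c(pre_samples, post_samples)
  timepoint <- setNames(
    c(rep("pre", n_pre), rep("post", length(post_samples))), samples
  )
  purity <- setNames(
    runif(length(samples), config$purity_range[1], config$purity_range[2]),
    samples
  )

  # clone counts concentrate around the range midpoint (the cohort-average
  # clone number) rather than spreading uniformly; near-clonal tumours are
  # correspondingly rare, as observed in multi-region cohorts
  rint <- function(lo, hi) as.integer(lo + rbinom(1, hi - lo, 0.5))
  K_pre_target <- rint(config$clones_range[1], config$clones_range[2])
  K_extra_target <- if (config$include_post) {
    rint(config$post_extra_clones[1], config$post_extra_clones[2])
  } else 0L

  # Grow the clone set sequentially under the sum rule (children of one
  # parent never exceed it in any sample). Candidate clones must be
  # *detectable*: prevalence >= 0.12 in every sample they occupy, >= 0.25
  # in at least one, and an L-infinity separation >= 0.1 from every
  # existing clone's prevalence profile. Candidates whose parent budget
  # cannot support this are dropped, so the planted truth only contains
  # clones the read data can support.
  prev <- matrix(0, 1, length(samples), dimnames = list("C1", samples))
  prev[1, ] <- 1
  parent <- NA_integer_
  post_only <- FALSE
  for (cand in seq_len(K_pre_target + K_extra_target - 1)) {
    is_post <- cand > K_pre_target - 1
    ok <- FALSE
    for (attempt in 1:12) {
      K_now <- nrow(prev)
      par <- if (is_post) 1L else sample.int(K_now, 1)
      if (is_post) {
        in_s <- samples %in% post_samples
      } else {
        both <- runif(1) < 0.35
        in_pre <- if (both || n_pre == 1) pre_samples else sample(pre_samples, 1)
        survives_post <- config$include_post && runif(1) < 0.5
        in_s <- samples %in% c(in_pre, if (survives_post) post_samples)
      }
      phi <- numeric(length(samples))
      for (s in which(in_s)) {
        kids <- which(parent == par)
        budget <- prev[par, s] - sum(prev[kids, s])
        phi[s] <- if (budget >= 0.12) runif(1, 0.12, min(budget, 0.95)) else 0
      }
      occupied <- in_s & phi > 0
      if (!any(occupied) || max(phi) < 0.25) next
      sep <- apply(prev, 1, function(row) max(abs(row - phi)))
      if (min(sep) < 0.1) next
      ok <- TRUE
      break
    }
    if (!ok) next
    prev <- rbind(prev, phi)
    parent <- c(parent, par)
    post_only <- c(post_only, is_post)
  }
  K <- nrow(prev)
  clone_ids <- paste0("C", seq_len(K))
  rownames(prev) <- clone_ids
  present <- prev > 0
  K_pre <- sum(!post_only)

  # mutation counts; founder size calibrated to the shared-fraction target.
  # Calibration works on *expected called* counts: a clone's mutation is
  # detected in a sample with probability P(Binom(depth, vaf) >= min_alt),
  # so low-prevalence clones contribute fewer private calls than they hold
  # mutations.
  rng <- config$mutations_per_clone
  n_mut <- round(runif(K, rng[1], rng[2]))
  if (K > 1) {
    det <- function(phi, s) {
      vaf <- phi * purity[s] / (purity[s] * 2 + (1 - purity[s]) * 2)
      (1 - config$call_fn_rate) *
        (1 - stats::pbinom(config$min_alt_reads - 1, config$depth_mean, vaf))
    }
    s1 <- pre_samples[1]; s2 <- pre_samples[min(2, n_pre)]
    d1 <- vapply(2:K, function(k) det(prev[k, s1], s1), numeric(1))
    d2 <- vapply(2:K, function(k) det(prev[k, s2], s2), numeric(1))
    sh_k <- n_mut[2:K] * d1 * d2
    pr_k <- n_mut[2:K] * (d1 * (1 - d2) + d2 * (1 - d1))
    sh_k[post_only[2:K]] <- 0; pr_k[post_only[2:K]] <- 0
    # per-tumour targets are dispersed around the cohort mean, mirroring
    # the wide tumour-to-tumour spread real cohorts show
    t_sh <- min(0.95, max(0.05, runif(1, config$shared_fraction - 0.2,
                                      config$shared_fraction + 0.2)))
    # the founder also leaks calls into "private" through missed calls:
    # q_s / q_p are its both-/one-sample call probabilities at CCF 1
    f1 <- det(1, s1); f2 <- det(1, s2)
    q_s <- f1 * f2
    q_p <- f1 * (1 - f2) + f2 * (1 - f1)
    denom <- q_s * (1 - t_sh) - t_sh * q_p
    need <- t_sh * sum(sh_k + pr_k) - sum(sh_k)
    if (sum(sh_k + pr_k) > 0 && denom > 0 && need >= 0) {
      # grow the founder; its count is calibration-driven and only needs a
      # floor to stay a real clone
      n_mut[1] <- max(10, round(need / denom))
    } else if (sum(sh_k + pr_k) > 0) {
      # target below the structural floor: shrink the both-detected
      # subclones instead of growing the founder
      n_mut[1] <- 10
      both_det <- d1 * d2 >= 0.5 & !post_only[2:K]
      Sb <- sum(sh_k[both_det]); Pb <- sum(pr_k[both_det])
      Sp <- sum(sh_k[!both_det]); Pp <- sum(pr_k[!both_det])
      gden <- Sb * (1 - t_sh) - t_sh * Pb
      if (gden > 0) {
        gam <- (t_sh * (10 * (q_s + q_p) + Sp + Pp) - 10 * q_s - Sp) / gden
        gam <- min(1, max(0.04, gam))
        idx <- which(both_det) + 1
        n_mut[idx] <- pmax(10, round(gam * n_mut[idx]))
      }
    }
  }

  apobec <- runif(1) < config$apobec_private_prob && K_pre > 1
  base_mix <- c(SBS17a = 0.22, SBS17b = 0.18, SBS1 = 0.15,
                SBS5 = 0.30, SBS18 = 0.15)
  apobec_mix <- c(SBS2 = 0.30, SBS13 = 0.25, SBS3 = 0.15,
                  SBS5 = 0.20, SBS1 = 0.10)
  private_pre <- !apply(present[, pre_samples, drop = FALSE], 1, all) &
    !post_only
  clone_apobec <- apobec & private_pre

  used <- logical(nchar(genome[[1]]))
  muts <- vector("list", K)
  for (k in seq_len(K)) {
    mix <- if (clone_apobec[k]) apobec_mix else base_mix
    mk <- sample_mutations_from_signature(
      mix, n_mut[k], genome, seed = seed + 1000 + k, index = index,
      used = used
    )
    used <- attr(mk, "used")
    attr(mk, "used") <- NULL
    if (post_only[k] && config$platinum_fraction_post > 0) {
      mk <- plant_platinum(mk, config$platinum_fraction_post, genome,
                           seed = seed + 2000 + k, index = index, used = used)
      used <- attr(mk, "used") %||% used
      attr(mk, "used") <- NULL
    }
    mk$clone <- clone_ids[k]
    muts[[k]] <- mk
  }
  muts <- dplyr::bind_rows(muts)
  n_mut <- as.integer(table(factor(muts$clone, levels = clone_ids)))
  muts$key <- mutation_key(muts)

  # read counts per sample: Binomial(depth, ccf * purity * m / denom)
  cells <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    phi <- prev[muts$clone, s]
    depth <- rpois(nrow(muts), config$depth_mean)
    vaf <- phi * purity[s] * 1 / (purity[s] * 2 + (1 - purity[s]) * 2)
    alt <- rbinom(nrow(muts), depth, vaf)
    cells[[si]] <- tibble::tibble(
      key = muts$key, sample_id = s, alt_count = alt, depth = depth,
      chrom = muts$chrom, pos = muts$pos, ref = muts$ref, alt = muts$alt,
      context = muts$context, channel = muts$channel, clone = muts$clone
    )
  }
  cells <- dplyr::bind_rows(cells)
  called <- cells[cells$alt_count >= config$min_alt_reads &
                    runif(nrow(cells)) >= config$call_fn_rate, , drop = FALSE]
  region_of <- setNames(sub(paste0("^", tumour_id, "_"), "", samples), samples)
  records <- new_mutation_tbl(tibble::tibble(
    tumour_id = tumour_id,
    sample_id = called$sample_id,
    timepoint = unname(timepoint[called$sample_id]),
    region_label = unname(region_of[called$sample_id]),
    chrom = called$chrom, pos = called$pos,
    ref = called$ref, alt = called$alt,
    alt_count = called$alt_count, depth = called$depth,
    context = called$context, channel = called$channel,
    cn_total = 2L, cn_major = 1L
  ))
  pileup <- cells[c("key", "sample_id", "alt_count", "depth")]
  sample_info <- tibble::tibble(
    sample_id = samples, tumour_id = tumour_id,
    timepoint = unname(timepoint),
    region_label = unname(region_of),
    purity = unname(purity)
  )
  truth <- list(
    tumour_id = tumour_id,
    K_pre = K_pre, K_total = K,
    clones = tibble::tibble(
      clone = clone_ids, parent = ifelse(is.na(parent), NA_character_,
                                         clone_ids[parent]),
      n_mut = n_mut, post_only = post_only, apobec = clone_apobec,
      prevalence = lapply(seq_len(K), function(k) prev[k, ])
    ),
    prevalence = prev,
    assignment = setNames(muts$clone, muts$key),
    apobec_private = apobec,
    platinum = config$include_post && config$platinum_fraction_post > 0 &&
      any(post_only)
  )
  list(records = records, pileup = pileup, sample_info = sample_info,
       truth = truth)
}

#' Simulate a full cohort
#'
#' Generates a fixture genome and, per tumour, a planted clone structure
#' with read counts, plus the clinical and neoantigen-affinity tables the
#' pipeline consumes. Survival is linked to the planted APOBEC-in-private
#' flag through `config$hr_signature_present`. Fully deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an `oac_cohort`: list with `mutations`, `pileup`, `sample_info`,
#'   `clinical`, `affinity`, `truth` (per-tumour list), `genome`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  genome <- make_fixture_genome(config$genome_length, seed = config$seed,
                                cpc_target = config$cpc_target)
  index <- context_index(genome)
  ids <- sprintf("TUM%02d", seq_len(config$n_tumours))
  sims <- lapply(seq_along(ids), function(i) {
    plant_clone_structure(config, genome, tumour_id = ids[i],
                          seed = config$seed + 17 * i, index = index)
  })
  mutations <- dplyr::bind_rows(lapply(sims, `[[`, "records"))
  pileup <- dplyr::bind_rows(lapply(seq_along(sims), function(i) {
    p <- sims[[i]]$pileup
    p$tumour_id <- ids[i]
    p
  }))
  sample_info <- dplyr::bind_rows(lapply(sims, `[[`, "sample_info"))
  truth <- setNames(lapply(sims, `[[`, "truth"), ids)

  apobec_flags <- vapply(truth, `[[`, logical(1), "apobec_private")
  set.seed(config$seed + 7)
  surv <- simulate_survival(apobec_flags, config$hr_signature_present,
                            seed = config$seed + 11,
                            median_months = config$median_dss_months,
                            censor_month = config$censor_month)
  set.seed(config$seed + 13)
  stage_levels <- c("IB", "IIB", "III", "IVA")
  clinical <- tibble::tibble(
    patient_id = ids,
    age_years = round(runif(length(ids), 38, 71)),
    stage_ctnm = factor(
      sample(stage_levels, length(ids), replace = TRUE,
             prob = c(0.034, 0.207, 0.724, 0.034)),
      levels = stage_levels, ordered = TRUE
    ),
    treatment_arm = sample(c("CF", "DCF", "DCF_RT"), length(ids),
                           replace = TRUE, prob = c(0.5, 0.3, 0.2)),
    dss_months = surv$dss_months,
    event = surv$event
  )

  set.seed(config$seed + 19)
  affinity <- dplyr::bind_rows(lapply(ids, function(id) {
    keys <- unique(names(truth[[id]]$assignment))
    take <- sample(keys, min(150, length(keys)))
    n_ep <- sample(1:3, length(take), replace = TRUE)
    key_rep <- rep(take, n_ep)
    n <- length(key_rep)
    parts <- strsplit(key_rep, "[:>]")
    tibble::tibble(
      tumour_id = id,
      chrom = vapply(parts, `[[`, character(1), 1),
      pos = as.integer(vapply(parts, `[[`, character(1), 2)),
      ref = vapply(parts, `[[`, character(1), 3),
      alt = vapply(parts, `[[`, character(1), 4),
      hla_allele = sample(c("HLA-A*02:01", "HLA-B*07:02", "HLA-C*07:01"),
                          n, replace = TRUE),
      peptide_mt = strrep("A", 9), peptide_wt = strrep("A", 9),
      ic50_mt = exp(rnorm(n, log(300), 1)),
      ic50_wt = exp(rnorm(n, log(500), 1))
    )
  }))
  affinity$key <- mutation_key(affinity)

  structure(
    list(mutations = mutations, pileup = pileup, sample_info = sample_info,
         clinical = clinical, affinity = affinity, truth = truth,
         genome = genome, config = config),
    class = "oac_cohort"
  )
}

#' @export
print.oac_cohort <- function(x, ...) {
  cat("<oac_cohort> ", x$config$n_tumours, " tumours, ",
      nrow(x$sample_info), " samples, ",
      nrow(x$mutations), " called mutation rows\n", sep = "")
  invisible(x)
}
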