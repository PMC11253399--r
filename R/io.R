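#' Read a reference genome from FASTA
#'
#' The genome is held in memory as a named character vector (one element per
#' contig), which is convenient for the small fixture genomes this package
#' works with. Contig names are taken up to the first whitespace.
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return named character vector of uppercase contig sequences.
#' @export
read_genome <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, width = 70L
  )
  invisible(path)
}

# Match a chromosome name to the genome's contig naming ("chr1" vs "1").
normalise_chrom <- function(chrom, genome) {
  contigs <- names(genome)
  vapply(as.character(chrom), function(ch) {
    if (ch %in% contigs) return(ch)
    alt <- if (startsWith(ch, "chr")) sub("^chr", "", ch) else paste0("chr", ch)
    if (alt %in% contigs) return(alt)
    stop("chromosome '", ch, "' not found in genome contigs")
  }, character(1), USE.NAMES = FALSE)
}

#' Fetch reference-strand sequence context around a position
#'
#' @param genome named character vector from [read_genome()].
#' @param chrom contig name (a missing/extra "chr" prefix is tolerated).
#' @param pos 1-based position of the centre base.
#' @param flank number of bases either side; the result has length
#'   `2 * flank + 1`.
#' @return uppercase reference-strand sequence centred on `pos`.
#' @export
#' @examples
#' g <- c(ctg = "ACGTACGT")
#' fetch_context(g, "ctg", 4, 2) # "CGTAC"
fetch_context <- function(genome, chrom, pos, flank) {
  stopifnot(length(chrom) == 1, length(pos) == 1, flank >= 0)
  chrom <- normalise_chrom(chrom, genome)
  contig <- genome[[chrom]]
  if (pos - flank < 1 || pos + flank > nchar(contig)) {
    stop("context window [", pos - flank, ",", pos + flank,
         "] exceeds contig '", chrom, "' (length ", nchar(contig), ")")
  }
  substr(contig, pos - flank, pos + flank)
}

#' Annotate mutation records with trinucleotide context and SBS-96 channel
#'
#' Records whose context window leaves the contig, or whose stated reference
#' allele disagrees with the genome, are dropped with a message.
#'
#' @param records mutation tibble (see [read_mutation_table()]).
#' @param genome named character vector from [read_genome()].
#' @return the tibble with `context` and `channel` columns filled.
#' @export
annotate_context <- function(records, genome) {
  if (nrow(records) == 0) {
    records$context <- character(0)
    records$channel <- integer(0)
    return(records)
  }
  chrom <- normalise_chrom(records$chrom, genome)
  n <- nrow(records)
  ctx <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    contig <- genome[[chrom[i]]]
    p <- records$pos[i]
    if (p - 1 >= 1 && p + 1 <= nchar(contig)) {
      ctx[i] <- substr(contig, p - 1, p + 1)
    }
  }
  ok <- !is.na(ctx) & substr(ctx, 2, 2) == toupper(records$ref)
  n_edge <- sum(is.na(ctx))
  n_mismatch <- sum(!is.na(ctx) & substr(ctx, 2, 2) != toupper(records$ref))
  if (n_edge > 0) message(n_edge, " record(s) dropped: context window leaves contig")
  if (n_mismatch > 0) message(n_mismatch, " record(s) dropped: ref allele disagrees with genome")
  out <- records[ok, , drop = FALSE]
  out$context <- ctx[ok]
  out$channel <- as.integer(sbs96_channel(out$ref, out$alt, out$context))
  out
}

mutation_columns <- c(
  "tumour_id", "sample_id", "timepoint", "region_label", "chrom", "pos",
  "ref", "alt", "alt_count", "depth", "context", "channel",
  "cn_total", "cn_major"
)

new_mutation_tbl <- function(df) {
  for (col in setdiff(mutation_columns, names(df))) {
    df[[col]] <- switch(col,
      context = NA_character_,
      channel = NA_integer_,
      cn_total = NA_integer_, cn_major = NA_integer_,
      region_label = NA_character_,
      NA
    )
  }
  df <- tibble::as_tibble(df)[mutation_columns]
  df$pos <- as.integer(df$pos)
  df$alt_count <- as.integer(df$alt_count)
  df$depth <- as.integer(df$depth)
  stopifnot(all(df$pos >= 1), all(df$alt_count >= 0),
            all(df$alt_count <= df$depth))
  if (any(toupper(df$ref) == toupper(df$alt))) stop("ref == alt in input")
  df
}

#' Compose the sample-independent identity key of a mutation
#'
#' @param df tibble with `chrom`, `pos`, `ref`, `alt` columns.
#' @return character vector `chrom:pos:ref>alt`.
#' @export
mutation_key <- function(df) {
  paste0(df$chrom, ":", df$pos, ":", df$ref, ">", df$alt)
}

#' Read somatic SNV calls from MAF, VCF or internal TSV
#'
#' Only single-base substitutions enter the pipeline; indels, multi-allelic
#' rows and non-ACGT alleles are skipped and reported via a message and the
#' `"skipped"` attribute of the result. Coordinates are 1-based throughout.
#'
#' @param path input file.
#' @param format one of `"maf"`, `"vcf"`, `"tsv"` (the package's own TSV).
#' @param sample_metadata tibble with columns `sample_id`, `tumour_id`,
#'   `timepoint` (`"pre"`/`"post"`) and optionally `region_label`, keyed by
#'   the sample identifiers appearing in the file. Not needed for `"tsv"`.
#' @return mutation tibble with one row per SNV call per sample; attribute
#'   `skipped` holds the number of non-SNV rows dropped.
#' @export
read_mutation_table <- function(path, format = c("maf", "vcf", "tsv"),
                                sample_metadata = NULL) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  switch(format,
    maf = read_maf(path, sample_metadata),
    vcf = read_vcf(path, sample_metadata),
    tsv = read_internal_tsv(path)
  )
}

lookup_sample <- function(sample_ids, sample_metadata) {
  stopifnot(!is.null(sample_metadata))
  miss <- setdiff(unique(sample_ids), sample_metadata$sample_id)
  if (length(miss) > 0) {
    stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  }
  idx <- match(sample_ids, sample_metadata$sample_id)
  out <- sample_metadata[idx, , drop = FALSE]
  if (!"region_label" %in% names(out)) out$region_label <- out$sample_id
  out
}

is_snv <- function(ref, alt) {
  grepl("^[ACGT]$", ref) & grepl("^[ACGT]$", alt) & ref != alt
}

read_maf <- function(path, sample_metadata) {
  maf <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  needed <- c("Chromosome", "Start_Position", "Reference_Allele",
              "Tumor_Seq_Allele2", "t_alt_count", "t_depth",
              "Tumor_Sample_Barcode")
  miss <- setdiff(needed, names(maf))
  if (length(miss) > 0) stop("MAF missing mandatory column(s): ",
                             paste(miss, collapse = ", "))
  if (nrow(maf) == 0) {
    out <- new_mutation_tbl(tibble::tibble(
      tumour_id = character(0), sample_id = character(0),
      timepoint = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0),
      alt_count = integer(0), depth = integer(0)
    ))
    attr(out, "skipped") <- 0L
    return(out)
  }
  ref <- toupper(maf$Reference_Allele)
  alt <- toupper(maf$Tumor_Seq_Allele2)
  keep <- is_snv(ref, alt)
  n_skip <- sum(!keep)
  if (n_skip > 0) message(n_skip, " non-SNV MAF row(s) skipped")
  meta <- lookup_sample(maf$Tumor_Sample_Barcode[keep], sample_metadata)
  out <- new_mutation_tbl(tibble::tibble(
    tumour_id = meta$tumour_id,
    sample_id = meta$sample_id,
    timepoint = meta$timepoint,
    region_label = meta$region_label,
    chrom = as.character(maf$Chromosome[keep]),
    pos = maf$Start_Position[keep],
    ref = ref[keep], alt = alt[keep],
    alt_count = maf$t_alt_count[keep],
    depth = maf$t_depth[keep]
  ))
  attr(out, "skipped") <- n_skip
  out
}

read_vcf <- function(path, sample_metadata) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  smp <- colnames(v@gt)[-1]
  if (length(smp) != 1) stop("expected a single tumour sample column in VCF")
  keep <- is_snv(toupper(fix$REF), toupper(fix$ALT)) & !grepl(",", fix$ALT)
  n_skip <- sum(!keep)
  if (n_skip > 0) message(n_skip, " non-SNV/multi-allelic VCF row(s) skipped")
  ad <- vcfR::extract.gt(v, element = "AD")[keep, 1]
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[keep, 1]))
  alt_count <- suppressWarnings(
    as.integer(vapply(strsplit(ad, ","), function(x) x[2], character(1)))
  )
  meta <- lookup_sample(rep(smp, sum(keep)), sample_metadata)
  out <- new_mutation_tbl(tibble::tibble(
    tumour_id = meta$tumour_id, sample_id = meta$sample_id,
    timepoint = meta$timepoint, region_label = meta$region_label,
    chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    ref = toupper(fix$REF[keep]), alt = toupper(fix$ALT[keep]),
    alt_count = alt_count, depth = dp
  ))
  attr(out, "skipped") <- n_skip
  out
}

read_internal_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          chrom = readr::col_character(),
                          context = readr::col_character(),
                          region_label = readr::col_character()
                        ))
  miss <- setdiff(mutation_columns, names(df))
  if (length(miss) > 0) stop("internal TSV missing column(s): ",
                             paste(miss, collapse = ", "))
  out <- new_mutation_tbl(df)
  attr(out, "skipped") <- 0L
  out
}

#' Write mutation records to the package's canonical TSV
#'
#' @param records mutation tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, path) {
  readr::write_tsv(records[mutation_columns], path, progress = FALSE)
  invisible(path)
}

#' Read a COSMIC-format SBS signature matrix
#'
#' Expects a tab-separated file whose first column holds the 96 channel
#' labels (`A[C>A]A`, ...) and one column per signature. Rows are
#' canonicalised to the [sbs96_labels()] order; columns within 1e-3 of unit
#' sum are renormalised, anything further off is an error.
#'
#' @param path path to the TSV.
#' @return a `signature_matrix`: numeric 96 x S matrix with channel rownames,
#'   each column summing to 1.
#' @export
read_signature_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_signature_matrix(
    as.matrix(df[-1]),
    channels = as.character(df[[1]])
  )
}

#' Validate and canonicalise a signature matrix
#'
#' @param probs numeric 96 x S matrix of channel probabilities.
#' @param channels channel labels for the rows (defaults to existing rownames).
#' @return canonical `signature_matrix`.
#' @export
as_signature_matrix <- function(probs, channels = rownames(probs)) {
  labs <- sbs96_labels()
  if (is.null(channels)) stop("channel labels required")
  miss <- setdiff(labs, channels)
  if (length(miss) > 0) stop("missing channel row(s): ",
                             paste(head(miss, 3), collapse = ", "))
  probs <- as.matrix(probs)
  rownames(probs) <- channels
  probs <- probs[labs, , drop = FALSE]
  if (any(probs < 0)) stop("signature probabilities must be non-negative")
  cs <- colSums(probs)
  off <- abs(cs - 1) > 1e-3
  if (any(off)) stop("signature column(s) do not sum to 1: ",
                     paste(colnames(probs)[off], collapse = ", "))
  probs <- sweep(probs, 2, cs, "/")
  class(probs) <- c("signature_matrix", class(probs))
  probs
}

#' Read the clinical table
#'
#' Disease-specific survival is censored at `censor_month` on read: longer
#' times are truncated and their event flag suppressed, so downstream
#' survival code never sees uncensored times.
#'
#' @param path TSV with columns `patient_id`, `stage_ctnm`, `dss_months`,
#'   `event` and optionally `age_years`, `stage_yptnm`, `treatment_arm`,
#'   `tumour_length_pre_cm`, `tumour_size_post_cm`, `regression_pct`.
#' @param censor_month administrative censoring horizon (months).
#' @return clinical tibble.
#' @export
read_clinical_table <- function(path, censor_month = 60) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("patient_id", "stage_ctnm", "dss_months", "event"),
                  names(df))
  if (length(miss) > 0) stop("clinical table missing column(s): ",
                             paste(miss, collapse = ", "))
  censor_clinical(tibble::as_tibble(df), censor_month)
}

censor_clinical <- function(df, censor_month = 60) {
  if (nrow(df) == 0) return(df)
  if (any(df$dss_months < 0)) stop("negative survival time")
  stopifnot(all(df$event %in% c(0, 1)))
  over <- df$dss_months > censor_month
  df$event[over] <- 0
  df$dss_months[over] <- censor_month
  df
}

#' Read the neoantigen affinity table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `hla_allele`,
#'   `peptide_mt`, `peptide_wt`, `ic50_mt`, `ic50_wt` (nM).
#' @return affinity tibble with a `key` column added.
#' @export
read_affinity_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(chrom = readr::col_character()))
  miss <- setdiff(c("chrom", "pos", "ref", "alt", "hla_allele",
                    "peptide_mt", "peptide_wt", "ic50_mt", "ic50_wt"),
                  names(df))
  if (length(miss) > 0) stop("affinity table missing column(s): ",
                             paste(miss, collapse = ", "))
  if (nrow(df) > 0 && any(df$ic50_mt <= 0 | df$ic50_wt <= 0)) {
    stop("IC50 values must be positive")
  }
  df <- tibble::as_tibble(df)
  df$key <- mutation_key(df)
  df
}
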