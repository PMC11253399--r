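#' Filter putative neoantigens by binding affinity
#'
#' Epitopes whose mutant-peptide IC50 is at most `threshold` nM (inclusive)
#' are considered putative HLA binders; idempotent by construction.
#'
#' @param records affinity tibble from [read_affinity_table()].
#' @param threshold IC50 cutoff in nM (default 500).
#' @return the retained subset.
#' @export
filter_binders <- function(records, threshold = 500) {
  records[records$ic50_mt <= threshold, , drop = FALSE]
}

#' Differential agretopicity index
#'
#' `DAI = IC50(wild-type) - IC50(mutant)`: positive values mean the mutant
#' peptide binds its HLA allele more strongly than the corresponding
#' wild-type peptide, a proxy for immunogenicity.
#'
#' @param records affinity tibble.
#' @return the tibble with a `dai` column (nM).
#' @export
compute_dai <- function(records) {
  records$dai <- records$ic50_wt - records$ic50_mt
  records
}

#' DAI summaries per mutation population or clone
#'
#' Joins each (peptide, HLA) record to its mutation's group via the key and
#' reports per-group distribution summaries. Statistics are per record by
#' default; `per_mutation_best = TRUE` first reduces each mutation to its
#' best binder (lowest mutant IC50).
#'
#' @param records affinity tibble with `dai` (see [compute_dai()]).
#' @param group_by named character vector: mutation key -> group label
#'   (population label or clone id; `NA` keys are dropped).
#' @param per_mutation_best reduce to the best-binding epitope per mutation
#'   before summarising.
#' @return tibble: `group`, `n`, `median_dai`, `q1_dai`, `q3_dai`. Groups
#'   with no records are absent.
#' @export
dai_by_population <- function(records, group_by, per_mutation_best = FALSE) {
  stopifnot("dai" %in% names(records))
  records$group <- unname(group_by[records$key])
  records <- records[!is.na(records$group), , drop = FALSE]
  if (per_mutation_best && nrow(records) > 0) {
    records <- records |>
      dplyr::group_by(.data$key) |>
      dplyr::slice_min(.data$ic50_mt, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  records |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_dai = median(.data$dai),
      q1_dai = unname(quantile(.data$dai, 0.25)),
      q3_dai = unname(quantile(.data$dai, 0.75)),
      .groups = "drop"
    )
}
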