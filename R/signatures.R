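#' Build an SBS-96 catalogue from mutation records
#'
#' @param records mutation tibble; if the `channel` column is unset a
#'   `genome` must be supplied so contexts can be resolved.
#' @param genome optional named character vector from [read_genome()].
#' @return integer vector of length 96 (named by channel label) with
#'   attribute `n_mutations`.
#' @export
build_catalog <- function(records, genome = NULL) {
  if (nrow(records) > 0 && any(is.na(records$channel))) {
    if (is.null(genome)) stop("records lack channels and no genome given")
    records <- annotate_context(records, genome)
  }
  counts <- integer(96)
  if (nrow(records) > 0) {
    tab <- tabulate(records$channel, nbins = 96)
    counts <- as.integer(tab)
  }
  names(counts) <- sbs96_labels()
  attr(counts, "n_mutations") <- sum(counts)
  counts
}

#' Estimate signature exposures by simplex-constrained least squares
#'
#' Finds the non-negative, unit-sum weight vector `w` minimising
#' `|| catalog/n - P w ||^2` where `P` is the signature matrix — the
#' quadratic-programming formulation of signature refitting. The fit is
#' deterministic.
#'
#' @param catalog channel count vector from [build_catalog()] (or any
#'   non-negative 96-vector).
#' @param matrix a `signature_matrix`.
#' @return an `exposure_fit`: named numeric weights on the probability
#'   simplex, with attributes `sse` (residual sum of squares against the
#'   normalised catalogue) and `n_mutations`.
#' @export
fit_exposures <- function(catalog, matrix) {
  stopifnot(inherits(matrix, "signature_matrix"))
  n <- sum(catalog)
  if (n <= 0) stop("zero catalogue: no mutations to fit")
  g <- as.numeric(catalog)[match(rownames(matrix), names(catalog))]
  if (anyNA(g)) g <- as.numeric(catalog)
  g <- g / sum(g)
  P <- unclass(matrix)
  S <- ncol(P)
  if (S == 1) {
    w <- setNames(1, colnames(P))
  } else {
    D <- crossprod(P) + diag(1e-10, S)
    d <- crossprod(P, g)
    A <- cbind(rep(1, S), diag(S))
    sol <- quadprog::solve.QP(D, d, A, c(1, rep(0, S)), meq = 1)
    w <- pmax(sol$solution, 0)
    w <- setNames(w / sum(w), colnames(P))
  }
  resid <- g - P %*% w
  structure(w, sse = sum(resid^2), n_mutations = n,
            class = c("exposure_fit", "numeric"))
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("<exposure_fit> ", attr(x, "n_mutations"), " mutations",
      if (isTRUE(attr(x, "low_confidence"))) " (low confidence)", "\n", sep = "")
  print(round(unclass(x)[order(-unclass(x))], 4))
  invisible(x)
}

#' Cohort-level signature screen
#'
#' Retains the signatures reaching at least `min_prop` exposure in at least
#' one sample of the cohort, fitted against the full candidate matrix.
#'
#' @param per_sample_exposures list of `exposure_fit` objects (one per
#'   sample) or a samples x signatures numeric matrix.
#' @param min_prop retention threshold (default 0.10).
#' @return character vector of retained signature ids, in input order.
#' @export
select_cohort_signatures <- function(per_sample_exposures, min_prop = 0.10) {
  if (is.list(per_sample_exposures)) {
    if (length(per_sample_exposures) == 0) stop("no sample exposures given")
    m <- do.call(rbind, lapply(per_sample_exposures, unclass))
  } else {
    m <- as.matrix(per_sample_exposures)
  }
  if (nrow(m) == 0) stop("no sample exposures given")
  keep <- apply(m, 2, function(w) any(w >= min_prop))
  colnames(m)[keep]
}

#' Refit exposures with iterative pruning of minor signatures
#'
#' Fits exposures, removes signatures below `min_prop`, refits on the
#' survivors, and repeats to a fixed point, so mutations assigned to pruned
#' signatures are reattributed to the remaining ones. The largest-weight
#' signature is never dropped, guaranteeing a non-empty result; every
#' retained weight is >= `min_prop` (or the result is a single signature at
#' weight 1). Set `iterate = FALSE` for a single prune-and-refit pass.
#'
#' @param catalog channel count vector.
#' @param matrix_subset `signature_matrix` restricted to the candidate set.
#' @param min_prop pruning threshold (default 0.05).
#' @param iterate iterate pruning to a fixed point (default) or stop after
#'   one pass.
#' @return an `exposure_fit` over the surviving signatures.
#' @export
refit_with_pruning <- function(catalog, matrix_subset, min_prop = 0.05,
                               iterate = TRUE) {
  stopifnot(inherits(matrix_subset, "signature_matrix"))
  active <- colnames(matrix_subset)
  repeat {
    sub <- matrix_subset[, active, drop = FALSE]
    class(sub) <- class(matrix_subset)
    fit <- fit_exposures(catalog, sub)
    low <- unclass(fit) < min_prop
    if (all(low)) low[which.max(unclass(fit))] <- FALSE
    if (!any(low) || length(active) == 1) return(fit)
    active <- active[!low]
    if (!iterate) {
      sub <- matrix_subset[, active, drop = FALSE]
      class(sub) <- class(matrix_subset)
      return(fit_exposures(catalog, sub))
    }
  }
}

#' Combine exposures into reporting groups
#'
#' Group weight is the sum of the member signatures' weights; signatures not
#' covered by any group pass through unchanged, so total exposure is
#' conserved.
#'
#' @param exposure `exposure_fit` or named numeric vector.
#' @param groups named list of signature id sets, e.g. [signature_groups()].
#' @return named numeric vector of grouped weights.
#' @export
group_exposures <- function(exposure, groups = signature_groups()) {
  w <- unclass(exposure)
  out <- numeric(0)
  used <- character(0)
  for (g in names(groups)) {
    members <- intersect(groups[[g]], names(w))
    out[g] <- sum(w[members])
    used <- c(used, members)
  }
  rest <- w[setdiff(names(w), used)]
  c(out, rest)
}

#' Is a signature group present in a fitted population?
#'
#' A group is "present" when it survived the pruning refit, i.e. its
#' combined weight is positive in the pruned exposure vector.
#'
#' @param exposure pruned `exposure_fit` (from [refit_with_pruning()]).
#' @param group character vector of member signature ids.
#' @return logical.
#' @export
signature_presence <- function(exposure, group) {
  sum(unclass(exposure)[intersect(group, names(exposure))]) > 0
}

#' Signature profile of one mutation population
#'
#' Convenience composition for per-population reporting: builds the SBS-96
#' catalogue, restricts the reference to the cohort signature set
#' (optionally augmented with the platinum signatures SBS31/SBS35, which are
#' added only for pre-/post-treatment comparisons), and refits with
#' pruning. Populations smaller than `min_mutations` are still fitted but
#' flagged low-confidence.
#'
#' @param records mutation tibble for the population.
#' @param matrix full candidate `signature_matrix` (must contain the cohort
#'   set, and SBS31/SBS35 when `include_platinum = TRUE`).
#' @param cohort_signatures ids retained by [select_cohort_signatures()].
#' @param include_platinum add SBS31/SBS35 to the candidate set.
#' @param genome optional genome if records lack channels.
#' @param min_prop pruning threshold.
#' @param min_mutations below this population size the fit is flagged
#'   low-confidence (default 50).
#' @return pruned `exposure_fit` with attribute `low_confidence`.
#' @export
population_signature_profile <- function(records, matrix,
                                         cohort_signatures = oac_signature_set(),
                                         include_platinum = FALSE,
                                         genome = NULL,
                                         min_prop = 0.05,
                                         min_mutations = 50) {
  wanted <- cohort_signatures
  if (include_platinum) wanted <- union(wanted, c("SBS31", "SBS35"))
  miss <- setdiff(wanted, colnames(matrix))
  if (length(miss) > 0) stop("signature(s) absent from matrix: ",
                             paste(miss, collapse = ", "))
  cat96 <- build_catalog(records, genome)
  sub <- matrix[, wanted, drop = FALSE]
  class(sub) <- class(matrix)
  fit <- refit_with_pruning(cat96, sub, min_prop = min_prop)
  attr(fit, "low_confidence") <- attr(cat96, "n_mutations") < min_mutations
  fit
}

#' @export
tidy.exposure_fit <- function(x, ...) {
  tibble::tibble(
    signature = names(x),
    weight = as.numeric(unclass(x))
  ) |> dplyr::arrange(dplyr::desc(.data$weight))
}

#' @export
glance.exposure_fit <- function(x, ...) {
  tibble::tibble(
    n_signatures = length(x),
    n_mutations = attr(x, "n_mutations"),
    sse = attr(x, "sse"),
    low_confidence = isTRUE(attr(x, "low_confidence"))
  )
}
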