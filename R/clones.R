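#' Assemble the multi-sample read-count matrix for one tumour
#'
#' Collates alt/depth counts for every mutation key in the union of a
#' tumour's call sets across all its samples. Cells where the mutation was
#' not called are filled from the pileup table (possibly with zero alt
#' reads); (key, sample) cells absent from the pileup default to alt 0 /
#' depth 0 and are flagged in the `missing` matrix.
#'
#' @param records mutation tibble for one tumour (all samples).
#' @param pileup tibble with columns `key`, `sample_id`, `alt_count`,
#'   `depth` covering uncalled cells.
#' @param purity named numeric vector of per-sample tumour purities in
#'   (0, 1].
#' @return a `count_matrix`: list with `keys`, `samples`, integer matrices
#'   `alt`, `depth`, `cn_total`, `cn_major`, logical `missing`, and `purity`.
#' @export
build_count_matrix <- function(records, pileup = NULL, purity) {
  stopifnot(nrow(records) > 0)
  records$key <- mutation_key(records)
  # one key must carry one (ref, alt) pair; a chrom:pos seen with differing
  # alleles across samples is a collation error
  allele_tab <- unique(records[c("chrom", "pos", "ref", "alt")])
  if (anyDuplicated(allele_tab[c("chrom", "pos")]) > 0) {
    stop("inconsistent ref/alt across samples for the same position")
  }
  keys <- sort(unique(records$key))
  samples <- sort(unique(records$sample_id))
  stopifnot(all(samples %in% names(purity)),
            all(purity[samples] > 0), all(purity[samples] <= 1))
  n <- length(keys); S <- length(samples)
  mk <- function(x = 0L) matrix(x, n, S, dimnames = list(keys, samples))
  alt <- mk(); depth <- mk(); filled <- mk(FALSE)
  cn_total <- mk(2L); cn_major <- mk(1L)
  ri <- match(records$key, keys); ci <- match(records$sample_id, samples)
  alt[cbind(ri, ci)] <- records$alt_count
  depth[cbind(ri, ci)] <- records$depth
  filled[cbind(ri, ci)] <- TRUE
  if (!is.null(records$cn_total)) {
    has_cn <- !is.na(records$cn_total)
    cn_total[cbind(ri, ci)[has_cn, , drop = FALSE]] <- records$cn_total[has_cn]
  }
  if (!is.null(records$cn_major)) {
    has_cn <- !is.na(records$cn_major)
    cn_major[cbind(ri, ci)[has_cn, , drop = FALSE]] <- records$cn_major[has_cn]
  }
  if (!is.null(pileup)) {
    p <- pileup[pileup$key %in% keys & pileup$sample_id %in% samples, ,
                drop = FALSE]
    pri <- match(p$key, keys); pci <- match(p$sample_id, samples)
    use <- !filled[cbind(pri, pci)]
    alt[cbind(pri, pci)[use, , drop = FALSE]] <- p$alt_count[use]
    depth[cbind(pri, pci)[use, , drop = FALSE]] <- p$depth[use]
    filled[cbind(pri, pci)[use, , drop = FALSE]] <- TRUE
  }
  miss <- !filled
  if (any(miss)) message(sum(miss), " (key, sample) cell(s) missing from pileup; set to 0/0")
  structure(
    list(keys = keys, samples = samples, alt = alt, depth = depth,
         cn_total = cn_total, cn_major = cn_major, missing = miss,
         purity = purity[samples]),
    class = "count_matrix"
  )
}

#' Cancer cell fraction from read counts, purity and copy number
#'
#' Standard multiplicity-based point estimator: with VAF `v = alt/depth` and
#' total local copy number `ct`, the mutation multiplicity is
#' `m = clamp(round(v * (p*ct + (1-p)*2) / p), 1, cn_major)` and
#' `ccf = clamp(v * (p*ct + (1-p)*2) / (p*m), 0, 1)`. Vectorised; `depth = 0`
#' yields `NA`.
#'
#' @param alt,depth read counts.
#' @param purity tumour purity in (0, 1].
#' @param cn_total,cn_major local total and major-allele copy number.
#' @return numeric CCF in `[0, 1]` (or `NA`).
#' @export
#' @examples
#' ccf(25, 50, 1, 2, 1)    # clonal heterozygous diploid -> 1
#' ccf(25, 100, 0.5, 2, 1) # vaf 0.25 at purity 0.5 -> 1
ccf <- function(alt, depth, purity, cn_total, cn_major) {
  v <- ifelse(depth > 0, alt / depth, NA_real_)
  denom <- purity * cn_total + (1 - purity) * 2
  m <- pmin(pmax(round(v * denom / purity), 1), pmax(cn_major, 1))
  pmin(pmax(v * denom / (purity * m), 0), 1)
}

# per-cell linear factor c such that E[vaf] = c * ccf
ccf_factor <- function(cmat) {
  p <- matrix(cmat$purity, nrow = length(cmat$keys),
              ncol = length(cmat$samples), byrow = TRUE)
  denom <- p * cmat$cn_total + (1 - p) * 2
  v <- ifelse(cmat$depth > 0, cmat$alt / cmat$depth, 0)
  m <- pmin(pmax(round(v * denom / p), 1), pmax(cmat$cn_major, 1))
  p * m / denom
}

#' Decompose a tumour into clones by binomial-mixture clustering
#'
#' Fits a finite mixture over per-sample CCF centroids by
#' expectation-maximisation on binomial read-count likelihoods: each clone
#' `k` has a CCF `phi[k, s]` per sample and a mutation from clone `k`
#' produces alt reads `Binomial(depth, c * phi[k, s])`, where `c` maps CCF
#' to expected VAF through purity, copy number and multiplicity. Model size
#' is chosen by BIC over `K = 1..max_clusters` (the scan stops after
#' `patience` consecutive sizes without improvement); for each `K` the best
#' of `restarts` seeded initialisations is kept. Deterministic given `seed`.
#'
#' @param cmat `count_matrix` from [build_count_matrix()].
#' @param max_clusters largest clone number considered (default 40).
#' @param restarts random restarts per model size (default 100).
#' @param seed integer seed; restart `r` uses `seed + r - 1`.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param patience consecutive non-improving model sizes before the K scan
#'   stops.
#' @return a `clone_model`: list with `K`, `prevalence` (K x samples CCF
#'   matrix, clones ordered by mean prevalence and named `C1..CK`),
#'   `assignment` (named character: key -> clone id), `clone_fraction`,
#'   `loglik`, `bic`, `samples`, `purity`, and `tree` (unset until
#'   [infer_tree()]).
#' @export
cluster_mutations <- function(cmat, max_clusters = 40, restarts = 100,
                              seed = 1, max_iter = 200, tol = 1e-6,
                              patience = 3) {
  stopifnot(inherits(cmat, "count_matrix"))
  n <- length(cmat$keys)
  if (n == 0) stop("empty count matrix")
  cc <- ccf_factor(cmat)
  obs <- cmat$depth > 0
  kmax <- min(max_clusters, n)
  best <- NULL
  prev_best <- NULL
  since_improve <- 0
  for (K in seq_len(kmax)) {
    bk <- NULL
    for (r in seq_len(restarts)) {
      # first restart grows the best (K-1)-clone solution by splitting its
      # worst-fitting clone; the rest are random initialisations
      init <- if (r == 1 && !is.null(prev_best)) {
        split_init(prev_best, seed + K)
      } else NULL
      fit <- em_once(cmat, cc, obs, K, seed = seed + (K - 1) * restarts + r - 1,
                     max_iter = max_iter, tol = tol, phi_init = init)
      if (is.null(bk) || fit$loglik > bk$loglik) bk <- fit
    }
    npar <- (K - 1) + K * length(cmat$samples)
    bk$bic <- -2 * bk$loglik + npar * log(n)
    prev_best <- bk
    if (is.null(best) || bk$bic < best$bic) {
      best <- bk
      since_improve <- 0
    } else {
      since_improve <- since_improve + 1
      if (since_improve >= patience) break
    }
  }
  finalise_clone_model(best, cmat)
}

# duplicate the clone with the worst responsibility-weighted fit and
# perturb both copies
split_init <- function(fit, seed) {
  set.seed(seed)
  r <- fit$resp
  loss <- -colSums(r * pmax(log(r), -30))  # clones with diffuse membership
  k_split <- which.max(loss)
  phi <- rbind(fit$phi, fit$phi[k_split, ] + runif(ncol(fit$phi), -0.15, 0.15))
  pmin(pmax(phi, 0), 1)
}

em_once <- function(cmat, cc, obs, K, seed, max_iter, tol, phi_init = NULL) {
  set.seed(seed)
  n <- length(cmat$keys); S <- length(cmat$samples)
  A <- cmat$alt; D <- cmat$depth; DmA <- D - A
  A[!obs] <- 0; DmA[!obs] <- 0  # masked cells contribute nothing
  # binomial coefficient: constant in phi, added back for the reported
  # log-likelihood
  const_ll <- sum(lchoose(D[obs], cmat$alt[obs]))
  vaf <- ifelse(obs, cmat$alt / pmax(D, 1), 0)
  ccf_hat <- pmin(pmax(ifelse(obs, vaf / cc, 0), 0), 1)
  phi <- if (!is.null(phi_init)) {
    matrix(phi_init, K, S)
  } else {
    # random init: centroids at randomly chosen mutations' CCF profiles
    matrix(pmin(pmax(ccf_hat[sample.int(n, K), , drop = FALSE] +
                       runif(K * S, -0.02, 0.02), 0), 1), K, S)
  }
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  trace <- numeric(0)
  clamp_p <- function(p) pmin(pmax(p, 1e-9), 1 - 1e-9)
  for (iter in seq_len(max_iter)) {
    # E-step: log f(mutation i | clone k) over samples, vectorised per sample
    logl <- matrix(log(pi_k), n, K, byrow = TRUE)
    for (s in seq_len(S)) {
      P <- clamp_p(outer(cc[, s], phi[, s]))
      logl <- logl + A[, s] * log(P) + DmA[, s] * log1p(-P)
    }
    mx <- logl[cbind(seq_len(n), max.col(logl, ties.method = "first"))]
    w <- exp(logl - mx)
    denom <- rowSums(w)
    ll <- sum(mx + log(denom)) + const_ll
    trace <- c(trace, ll)
    r <- w / denom
    # M-step
    pi_k <- pmax(colMeans(r), 1e-12)
    pi_k <- pi_k / sum(pi_k)
    for (s in seq_len(S)) {
      a_s <- A[, s]; dma_s <- DmA[, s]; c_s <- cc[, s]
      # keep c*phi inside (0, 1) through the search interval, not per-eval
      # clamping
      ub <- min(1, (1 - 1e-9) / max(c_s))
      for (k in seq_len(K)) {
        wk <- r[, k]
        f <- function(phv) {
          p <- c_s * phv
          sum(wk * (a_s * log(p) + dma_s * log1p(-p)))
        }
        phi[k, s] <- optimize(f, c(1e-9, ub), maximum = TRUE,
                              tol = 1e-5)$maximum
      }
    }
    if (is.finite(ll_old) && ll - ll_old < tol * max(1, abs(ll))) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(K = K, phi = phi, pi = pi_k, resp = r, loglik = ll_old,
       ll_trace = trace)
}

finalise_clone_model <- function(fit, cmat) {
  K <- fit$K
  assign_idx <- max.col(fit$resp, ties.method = "first")
  ord <- order(-rowMeans(fit$phi))
  ids <- paste0("C", seq_len(K))
  relabel <- integer(K); relabel[ord] <- seq_len(K)
  prevalence <- fit$phi[ord, , drop = FALSE]
  dimnames(prevalence) <- list(ids, cmat$samples)
  assignment <- setNames(ids[relabel[assign_idx]], cmat$keys)
  frac <- table(factor(assignment, levels = ids))
  clone_fraction <- setNames(as.numeric(frac) / length(assignment), ids)
  structure(
    list(K = K, prevalence = prevalence, assignment = assignment,
         clone_fraction = clone_fraction, loglik = fit$loglik,
         bic = fit$bic, samples = cmat$samples, purity = cmat$purity,
         tree = NULL, pruned = character(0)),
    class = "clone_model"
  )
}

#' @export
print.clone_model <- function(x, ...) {
  cat("<clone_model> K =", x$K, "clones over",
      length(x$samples), "sample(s)\n")
  print(round(x$prevalence, 3))
  invisible(x)
}

#' Exclude minor clones
#'
#' Clones holding fewer than `min_fraction` of the tumour's mutations are
#' excluded from further analyses; their mutations become unassigned (`NA`).
#' `clone_fraction` is renormalised over the survivors for reporting while
#' the original fractions are retained in `clone_fraction_all`.
#'
#' @param model `clone_model`.
#' @param min_fraction exclusion threshold (default 0.01).
#' @return pruned `clone_model`.
#' @export
prune_clones <- function(model, min_fraction = 0.01) {
  keep <- model$clone_fraction >= min_fraction
  if (all(keep)) {
    model$clone_fraction_all <- model$clone_fraction
    return(model)
  }
  dropped <- names(model$clone_fraction)[!keep]
  model$clone_fraction_all <- model$clone_fraction
  model$pruned <- dropped
  model$assignment[model$assignment %in% dropped] <- NA_character_
  model$prevalence <- model$prevalence[keep, , drop = FALSE]
  surv <- model$clone_fraction[keep]
  model$clone_fraction <- surv / sum(surv)
  model$K <- sum(keep)
  model
}

#' Mutation sets per surviving clone
#'
#' Only mutations unique to a clone are used for per-clone signature and
#' neoantigen analyses, which this partition provides by construction.
#'
#' @param model `clone_model` (typically after [prune_clones()]).
#' @return named list: clone id -> character vector of mutation keys.
#' @export
clone_mutations <- function(model) {
  a <- model$assignment[!is.na(model$assignment)]
  split(names(a), factor(a, levels = rownames(model$prevalence)))
}

#' Average clonal prevalence per timepoint
#'
#' Arithmetic mean of each clone's per-sample prevalence within the
#' available samples of each timepoint; the result is the fishplot-ready
#' pre/post tumour profile.
#'
#' @param model `clone_model`.
#' @param sample_timepoints named character vector: sample id -> `"pre"` /
#'   `"post"`.
#' @return tibble: `clone`, `timepoint`, `prevalence`.
#' @export
timepoint_prevalence <- function(model, sample_timepoints) {
  stopifnot(all(model$samples %in% names(sample_timepoints)))
  tp <- sample_timepoints[model$samples]
  purrr::map_dfr(unique(tp), function(t) {
    cols <- model$samples[tp == t]
    tibble::tibble(
      clone = rownames(model$prevalence),
      timepoint = t,
      prevalence = unname(rowMeans(model$prevalence[, cols, drop = FALSE]))
    )
  })
}

#' Automated clonal-tree construction
#'
#' Greedy heuristic standing in for manual review of clonal structures:
#' clones are sorted by mean prevalence (descending) and each is attached to
#' the already-placed ancestor with the smallest mean prevalence that
#' satisfies, in every sample, the containment rule (child prevalence <=
#' parent prevalence + `tol`) and the sum rule (prevalences of the parent's
#' children must not exceed the parent's by more than `tol`). Clones with no
#' admissible ancestor become children of the founder and the model is
#' flagged as a forest when the founder does not dominate every sample.
#'
#' @param model `clone_model`.
#' @param tol per-sample tolerance on both rules (default 0.05).
#' @return the model with `tree` set (named character: clone -> parent id,
#'   `NA` for the founder) and attribute-like flag `forest`.
#' @export
infer_tree <- function(model, tol = 0.05) {
  ids <- rownames(model$prevalence)
  K <- length(ids)
  prev <- model$prevalence
  mean_prev <- rowMeans(prev)
  ord <- order(-mean_prev, ids)
  parent <- setNames(rep(NA_character_, K), ids)
  placed <- character(0)
  children <- list()
  root <- ids[ord[1]]
  for (i in ord) {
    id <- ids[i]
    if (id == root) { placed <- c(placed, id); next }
    cand <- Filter(function(p) {
      contain <- all(prev[id, ] <= prev[p, ] + tol)
      kids <- children[[p]] %||% character(0)
      load <- colSums(prev[c(kids, id), , drop = FALSE])
      sum_ok <- all(load <= prev[p, ] + tol)
      contain && sum_ok
    }, placed)
    if (length(cand) == 0) {
      parent[id] <- root
      children[[root]] <- c(children[[root]], id)
    } else {
      # smallest admissible ancestor; ties by larger mean prevalence, then id
      cand <- unlist(cand)
      o <- order(mean_prev[cand], cand)
      pick <- cand[o[1]]
      parent[id] <- pick
      children[[pick]] <- c(children[[pick]], id)
    }
    placed <- c(placed, id)
  }
  model$tree <- parent
  model$forest <- any(prev[root, ] + tol < apply(prev, 2, max))
  model
}

#' @export
tidy.clone_model <- function(x, ...) {
  prev <- x$prevalence
  out <- tibble::as_tibble(prev, rownames = "clone") |>
    tidyr::pivot_longer(-"clone", names_to = "sample_id",
                        values_to = "prevalence")
  out$clone_fraction <- x$clone_fraction[out$clone]
  if (!is.null(x$tree)) out$parent <- unname(x$tree[out$clone])
  out
}

#' @export
glance.clone_model <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    n_mutations = length(x$assignment),
    n_unassigned = sum(is.na(x$assignment)),
    n_pruned_clones = length(x$pruned),
    loglik = x$loglik,
    bic = x$bic
  )
}
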