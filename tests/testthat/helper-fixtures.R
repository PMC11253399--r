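# Shared fixtures, built once per test run and memoised.

local_fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = local_fixture_cache)) {
    assign(name, force(expr), envir = local_fixture_cache)
  }
  get(name, envir = local_fixture_cache)
}

fix_genome <- function() memo("genome", make_fixture_genome(2e5, seed = 11))

fix_sigs <- function() memo("sigs", sbs_reference())

sig_subset <- function(mat, cols) {
  out <- mat[, cols, drop = FALSE]
  class(out) <- class(mat)
  out
}

# simplex grid search oracle for exposure fitting (independent of quadprog)
grid_search_exposures <- function(catalog, matrix, step = 1e-2) {
  g <- as.numeric(catalog) / sum(catalog)
  P <- unclass(matrix)
  S <- ncol(P)
  stopifnot(S <= 3)
  grid <- seq(0, 1, by = step)
  best <- NULL; best_sse <- Inf
  if (S == 1) return(setNames(1, colnames(P)))
  if (S == 2) {
    for (w1 in grid) {
      w <- c(w1, 1 - w1)
      sse <- sum((g - P %*% w)^2)
      if (sse < best_sse) { best_sse <- sse; best <- w }
    }
  } else {
    for (w1 in grid) for (w2 in grid[grid <= 1 - w1 + 1e-12]) {
      w <- c(w1, w2, 1 - w1 - w2)
      sse <- sum((g - P %*% w)^2)
      if (sse < best_sse) { best_sse <- sse; best <- w }
    }
  }
  setNames(best, colnames(P))
}

# mutation tibble builder for hand fixtures
mk_records <- function(df, tumour_id = "T01", timepoint = "pre") {
  defaults <- tibble::tibble(
    tumour_id = tumour_id, sample_id = "S1", timepoint = timepoint,
    region_label = NA_character_, chrom = "chr1", pos = 100L,
    ref = "C", alt = "A", alt_count = 10L, depth = 30L,
    context = NA_character_, channel = NA_integer_,
    cn_total = 2L, cn_major = 1L
  )
  out <- defaults[rep(1, nrow(df)), ]
  for (nm in names(df)) out[[nm]] <- df[[nm]]
  out
}

# 3 well-separated clones (centres differ >= 0.3 per sample), 100 mutations
# each, depth ~60, explicit truth
three_clone_fixture <- function(seed = 5) {
  set.seed(seed)
  prev_truth <- matrix(c(1, 1, 0.6, 0.55, 0.25, 0.2), 3, 2, byrow = TRUE,
                       dimnames = list(c("K1", "K2", "K3"), c("S1", "S2")))
  purity <- c(S1 = 0.8, S2 = 0.8)
  n_per <- 100
  clone <- rep(rownames(prev_truth), each = n_per)
  n <- length(clone)
  rows <- list()
  for (s in c("S1", "S2")) {
    depth <- rpois(n, 60)
    vaf <- prev_truth[clone, s] * purity[s] / 2
    rows[[s]] <- mk_records(tibble::tibble(
      pos = seq_len(n) * 10L, sample_id = s,
      alt_count = rbinom(n, depth, vaf), depth = as.integer(depth)
    ))
  }
  rec <- dplyr::bind_rows(rows)
  cmat <- build_count_matrix(rec, purity = purity)
  truth <- setNames(clone, mutation_key(rows[[1]]))
  list(cmat = cmat, prevalence = prev_truth, assignment = truth)
}

# a mid-sized spatial cohort reused across pipeline/acceptance tests
fix_cohort <- function() memo("cohort", {
  suppressMessages(simulate_cohort(sim_config(
    n_tumours = 12, seed = 303, genome_length = 3e5,
    mutations_per_clone = c(60, 200)
  )))
})
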