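two_sample_matrix <- function(alt1, dep1, alt2, dep2, purity = c(S1 = 1, S2 = 1)) {
  n <- length(alt1)
  rec <- dplyr::bind_rows(
    mk_records(tibble::tibble(pos = seq_len(n) * 10L, sample_id = "S1",
                              alt_count = as.integer(alt1),
                              depth = as.integer(dep1))),
    mk_records(tibble::tibble(pos = seq_len(n) * 10L, sample_id = "S2",
                              alt_count = as.integer(alt2),
                              depth = as.integer(dep2)))
  )
  build_count_matrix(rec, purity = purity)
}

test_that("count matrices collate calls and fill uncalled cells from pileup", {
  rec <- dplyr::bind_rows(
    mk_records(tibble::tibble(pos = c(10L, 20L), sample_id = "S1",
                              alt_count = c(12L, 9L), depth = c(40L, 35L))),
    mk_records(tibble::tibble(pos = 10L, sample_id = "S2",
                              alt_count = 11L, depth = 38L))
  )
  pu <- tibble::tibble(key = "chr1:20:C>A", sample_id = "S2",
                       alt_count = 0L, depth = 40L)
  cm <- build_count_matrix(rec, pileup = pu, purity = c(S1 = 0.8, S2 = 0.7))
  expect_equal(cm$alt["chr1:10:C>A", "S1"], 12L)
  expect_equal(cm$alt["chr1:20:C>A", "S2"], 0L)    # zero-fill from pileup
  expect_equal(cm$depth["chr1:20:C>A", "S2"], 40L)
  expect_false(any(cm$missing))

  # without the pileup the uncalled cell is flagged missing
  cm2 <- suppressMessages(build_count_matrix(rec, purity = c(S1 = 0.8, S2 = 0.7)))
  expect_true(cm2$missing["chr1:20:C>A", "S2"])
  expect_equal(cm2$depth["chr1:20:C>A", "S2"], 0L)

  # brute-force assembly oracle over the union of keys and samples
  keys <- sort(unique(mutation_key(rec)))
  for (k in keys) for (s in c("S1", "S2")) {
    row <- rec[mutation_key(rec) == k & rec$sample_id == s, ]
    expected <- if (nrow(row) == 1) c(row$alt_count, row$depth) else {
      pr <- pu[pu$key == k & pu$sample_id == s, ]
      if (nrow(pr) == 1) c(pr$alt_count, pr$depth) else c(0L, 0L)
    }
    expect_equal(c(cm$alt[k, s], cm$depth[k, s]), expected)
  }

  # the same position with different alleles across samples is an error
  bad <- rec
  bad$alt[3] <- "G"
  expect_error(build_count_matrix(bad, purity = c(S1 = 0.8, S2 = 0.7)),
               "inconsistent ref/alt")
})

test_that("the CCF estimator matches its closed form", {
  expect_equal(ccf(25, 50, 1, 2, 1), 1)        # clonal het diploid
  expect_equal(ccf(25, 100, 0.5, 2, 1), 1)     # vaf 0.25 at purity 0.5
  expect_equal(ccf(0, 60, 0.8, 2, 1), 0)
  expect_true(is.na(ccf(0, 0, 0.8, 2, 1)))
  # subclonal: vaf 0.1, purity 1, cn 2, multiplicity 1 -> ccf 0.2
  expect_equal(ccf(10, 100, 1, 2, 1), 0.2)
  # multiplicity 2 rescues a high-vaf amplified site
  expect_equal(ccf(50, 100, 1, 2, 2), 1)
})

test_that("a uniform clonal tumour collapses to one clone", {
  set.seed(1)
  n <- 60
  cm <- two_sample_matrix(rbinom(n, 60, 0.5), rep(60, n),
                          rbinom(n, 60, 0.5), rep(60, n))
  mod <- cluster_mutations(cm, max_clusters = 5, restarts = 4, seed = 2)
  expect_equal(mod$K, 1L)
  expect_true(all(abs(mod$prevalence - 1) < 0.05))
})

test_that("three well-separated clones are recovered accurately", {
  fx <- three_clone_fixture(seed = 5)
  mod <- cluster_mutations(fx$cmat, max_clusters = 6, restarts = 10, seed = 5)
  expect_equal(mod$K, 3L)
  # match fitted clones to planted clones by nearest prevalence profile
  perm <- apply(mod$prevalence, 1, function(row) {
    which.min(colSums((t(fx$prevalence) - row)^2))
  })
  expect_equal(sort(unname(perm)), 1:3)
  for (k in seq_len(3)) {
    expect_lt(max(abs(mod$prevalence[k, ] - fx$prevalence[perm[k], ])), 0.05)
  }
  acc <- mean(rownames(fx$prevalence)[perm][
    match(mod$assignment, rownames(mod$prevalence))] ==
      fx$assignment[names(mod$assignment)])
  expect_gte(acc, 0.95)
})

test_that("model size never exceeds the mutation count", {
  cm <- two_sample_matrix(c(30, 28, 15, 3, 29), rep(60, 5),
                          c(31, 27, 14, 2, 30), rep(60, 5))
  mod <- cluster_mutations(cm, max_clusters = 40, restarts = 3, seed = 3)
  expect_lte(mod$K, 5L)
})

test_that("EM log-likelihood is non-decreasing within numerical tolerance", {
  set.seed(9)
  n <- 80
  cm <- two_sample_matrix(c(rbinom(n / 2, 60, 0.5), rbinom(n / 2, 60, 0.15)),
                          rep(60, n),
                          c(rbinom(n / 2, 60, 0.5), rbinom(n / 2, 60, 0.1)),
                          rep(60, n))
  fit <- oacevo:::em_once(cm, oacevo:::ccf_factor(cm), cm$depth > 0, K = 2,
                          seed = 4, max_iter = 100, tol = 1e-10)
  tr <- fit$ll_trace
  expect_gte(length(tr), 2)
  expect_true(all(diff(tr) > -1e-6 * pmax(1, abs(tr[-length(tr)]))))
})

test_that("clone relabelling leaves fractions and tree shape unchanged", {
  cfg <- sim_config(n_tumours = 1, seed = 55, genome_length = 2e5,
                    clones_range = c(3, 3), mutations_per_clone = c(80, 80))
  co <- suppressMessages(simulate_cohort(cfg))
  si <- co$sample_info
  cm <- build_count_matrix(co$mutations, co$pileup,
                           setNames(si$purity, si$sample_id))
  m1 <- cluster_mutations(cm, max_clusters = 5, restarts = 6, seed = 5)
  m2 <- cluster_mutations(cm, max_clusters = 5, restarts = 6, seed = 99)
  expect_equal(m1$K, m2$K)
  expect_equal(sort(round(m1$clone_fraction, 2)),
               sort(round(m2$clone_fraction, 2)), ignore_attr = TRUE)
  t1 <- infer_tree(m1); t2 <- infer_tree(m2)
  expect_equal(sort(table(t1$tree, useNA = "ifany")),
               sort(table(t2$tree, useNA = "ifany")), ignore_attr = TRUE)
})

test_that("clones under 1% of mutations are excluded and flagged", {
  mk_model <- function(fracs) {
    K <- length(fracs)
    ids <- paste0("C", seq_len(K))
    n <- round(fracs * 1000)
    assignment <- setNames(rep(ids, n), paste0("k", seq_len(sum(n))))
    structure(list(
      K = K,
      prevalence = matrix(rev(sort(runif(K))), K, 1,
                          dimnames = list(ids, "S1")),
      assignment = assignment,
      clone_fraction = setNames(as.numeric(n) / sum(n), ids),
      loglik = 0, bic = 0, samples = "S1", purity = c(S1 = 1),
      tree = NULL, pruned = character(0)
    ), class = "clone_model")
  }
  m <- mk_model(c(0.6, 0.395, 0.005))
  pr <- prune_clones(m)
  expect_equal(pr$K, 2L)
  expect_equal(pr$pruned, "C3")
  expect_true(all(is.na(pr$assignment[names(m$assignment)[
    m$assignment == "C3"]])))
  expect_equal(sum(pr$clone_fraction), 1)
  expect_equal(pr$clone_fraction_all, m$clone_fraction)

  m2 <- mk_model(c(0.5, 0.3, 0.2))
  expect_equal(prune_clones(m2)$K, 3L)
  # brute-force filter oracle
  expect_equal(names(prune_clones(m)$clone_fraction),
               names(m$clone_fraction)[m$clone_fraction >= 0.01])
})

test_that("clone mutation sets partition the assigned keys", {
  cfg <- sim_config(n_tumours = 1, seed = 77, genome_length = 2e5,
                    clones_range = c(2, 2), mutations_per_clone = c(60, 60))
  co <- suppressMessages(simulate_cohort(cfg))
  si <- co$sample_info
  cm <- build_count_matrix(co$mutations, co$pileup,
                           setNames(si$purity, si$sample_id))
  mod <- prune_clones(cluster_mutations(cm, max_clusters = 4, restarts = 4,
                                        seed = 1))
  sets <- clone_mutations(mod)
  all_keys <- unlist(sets, use.names = FALSE)
  expect_equal(anyDuplicated(all_keys), 0L)
  expect_setequal(all_keys,
                  names(mod$assignment)[!is.na(mod$assignment)])
  expect_equal(sets, split(names(mod$assignment)[!is.na(mod$assignment)],
                           factor(mod$assignment[!is.na(mod$assignment)],
                                  levels = rownames(mod$prevalence))))
})

test_that("timepoint prevalences are arithmetic means within timepoints", {
  prev <- matrix(c(1, 1, 1, 1, 0.2, 0.4, 0.6, 0.8), 2, 4, byrow = TRUE,
                 dimnames = list(c("C1", "C2"), c("T1", "T2", "P1", "P2")))
  model <- structure(list(prevalence = prev, samples = colnames(prev)),
                     class = "clone_model")
  tp <- c(T1 = "pre", T2 = "pre", P1 = "post", P2 = "post")
  out <- timepoint_prevalence(model, tp)
  expect_equal(out$prevalence[out$clone == "C2" & out$timepoint == "pre"], 0.3)
  expect_equal(out$prevalence[out$clone == "C2" & out$timepoint == "post"], 0.7)
  # single sample per timepoint is the identity
  one <- timepoint_prevalence(
    structure(list(prevalence = prev[, c(1, 3)], samples = c("T1", "P1")),
              class = "clone_model"),
    tp
  )
  expect_equal(one$prevalence[one$clone == "C2"], c(0.2, 0.6))
})

test_that("tree construction recovers chains and keeps exclusive clones apart", {
  mk <- function(prev) {
    structure(list(
      prevalence = prev, samples = colnames(prev),
      clone_fraction = setNames(rep(1 / nrow(prev), nrow(prev)),
                                rownames(prev)),
      assignment = setNames(character(0), character(0)), K = nrow(prev),
      pruned = character(0)
    ), class = "clone_model")
  }
  # single clone
  single <- infer_tree(mk(matrix(1, 1, 2, dimnames = list("C1", c("a", "b")))))
  expect_true(is.na(single$tree[["C1"]]))

  # linear chain 1.0 -> 0.6 -> 0.2 in both samples
  chain <- infer_tree(mk(matrix(c(1, 1, 0.6, 0.6, 0.2, 0.2), 3, 2,
                                byrow = TRUE,
                                dimnames = list(c("C1", "C2", "C3"),
                                                c("a", "b")))))
  expect_equal(unname(chain$tree[c("C2", "C3")]), c("C1", "C2"))

  # mutually exclusive subclones both attach to the founder
  excl <- infer_tree(mk(matrix(c(1, 1, 0.7, 0, 0, 0.7), 3, 2, byrow = TRUE,
                               dimnames = list(c("C1", "C2", "C3"),
                                               c("a", "b")))))
  expect_equal(unname(excl$tree[c("C2", "C3")]), c("C1", "C1"))
  # the sum rule forbids two large co-occurring clones as siblings of the
  # founder, so the later one nests inside the earlier
  sib <- infer_tree(mk(matrix(c(1, 1, 0.6, 0.6, 0.55, 0.55), 3, 2,
                              byrow = TRUE,
                              dimnames = list(c("C1", "C2", "C3"),
                                              c("a", "b")))))
  expect_equal(unname(sib$tree[["C3"]]), "C2")
})
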