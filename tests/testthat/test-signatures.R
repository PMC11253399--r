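test_that("catalogue building counts channels and matches a per-record oracle", {
  empty <- build_catalog(mk_records(tibble::tibble(pos = integer(0)))[0, ])
  expect_equal(sum(empty), 0L)
  expect_equal(attr(empty, "n_mutations"), 0L)

  rec <- mk_records(tibble::tibble(pos = rep(100L, 10)))
  rec$context <- "ACA"; rec$channel <- rep(1L, 10)
  cat10 <- build_catalog(rec)
  expect_equal(unname(cat10[["A[C>A]A"]]), 10L)

  g <- fix_genome()
  mu <- sample_mutations_from_signature(c(SBS2 = 0.5, SBS17b = 0.5), 300, g,
                                        seed = 8, matrix = fix_sigs())
  cat96 <- build_catalog(dplyr::mutate(mk_records(mu[, c("pos", "ref", "alt")]),
                                       context = mu$context,
                                       channel = mu$channel))
  oracle <- integer(96)
  for (i in seq_len(nrow(mu))) {
    ch <- sbs96_channel(mu$ref[i], mu$alt[i], mu$context[i])
    oracle[ch] <- oracle[ch] + 1L
  }
  expect_equal(unname(as.integer(cat96)), oracle)
})

test_that("exposure fitting solves the simplex least-squares problem", {
  m <- fix_sigs()
  m2 <- sig_subset(m, c("SBS2", "SBS17b"))
  # catalogue proportional to one column -> weight 1 on it
  f1 <- fit_exposures(m[, "SBS2"] * 1000, m2)
  expect_equal(unclass(f1), c(SBS2 = 1, SBS17b = 0), tolerance = 1e-8,
               ignore_attr = TRUE)
  # noiseless 0.7 / 0.3 mixture recovered
  mix <- 0.7 * m[, "SBS2"] + 0.3 * m[, "SBS17b"]
  f2 <- fit_exposures(mix, m2)
  expect_equal(unclass(f2), c(SBS2 = 0.7, SBS17b = 0.3), tolerance = 1e-6,
               ignore_attr = TRUE)
  # grid-search oracle agrees within the grid resolution
  oracle <- grid_search_exposures(mix, m2, step = 1e-3)
  expect_equal(unclass(f2), oracle, tolerance = 2e-3, ignore_attr = TRUE)
  # single-signature matrix -> weight 1 regardless of the catalogue
  f3 <- fit_exposures(m[, "SBS1"] * 50, sig_subset(m, "SBS5"))
  expect_equal(as.numeric(f3), 1)
  expect_error(fit_exposures(numeric(96), m2), "zero catalogue")
})

test_that("fits agree with a dense grid search on 3-signature problems", {
  m <- fix_sigs()
  set.seed(31)
  for (rep in 1:4) {
    cols <- sample(colnames(m), 3)
    m3 <- sig_subset(m, cols)
    w <- as.numeric(rmultinom(1, 20, rep(1, 3))) / 20
    cat96 <- as.numeric(unclass(m3) %*% w) + runif(96, 0, 1e-4)
    fit <- fit_exposures(cat96, m3)
    oracle <- grid_search_exposures(cat96, m3, step = 1e-2)
    expect_lt(max(abs(unclass(fit) - oracle)), 1.5e-2)
  }
})

test_that("exposures stay on the probability simplex at every stage", {
  m <- fix_sigs()
  set.seed(7)
  for (rep in 1:5) {
    cat96 <- rmultinom(1, 500, runif(96))[, 1]
    fit <- fit_exposures(cat96, m)
    expect_true(all(unclass(fit) >= 0))
    expect_equal(sum(fit), 1, tolerance = 1e-8)
    pruned <- refit_with_pruning(cat96, m)
    expect_true(all(unclass(pruned) >= 0))
    expect_equal(sum(pruned), 1, tolerance = 1e-8)
  }
})

test_that("cohort screen keeps signatures above 10% in any sample", {
  e1 <- structure(c(A = 0.95, B = 0.05), class = c("exposure_fit", "numeric"))
  expect_equal(select_cohort_signatures(list(e1)), "A")
  e2 <- structure(c(A = 0.05, B = 0.95), class = c("exposure_fit", "numeric"))
  expect_equal(select_cohort_signatures(list(e1, e2)), c("A", "B"))
  # cohort fixture equals a brute-force scan
  set.seed(12)
  mat <- matrix(runif(40), 8, 5, dimnames = list(NULL, LETTERS[1:5]))
  mat <- mat / rowSums(mat)
  oracle <- colnames(mat)[apply(mat >= 0.10, 2, any)]
  expect_equal(select_cohort_signatures(mat), oracle)
  expect_error(select_cohort_signatures(list()), "no sample")
})

test_that("pruning refit reaches a fixed point with all weights >= 5%", {
  m <- fix_sigs()
  # dominant signature with trace contamination: prunes to a single signature
  cat96 <- 0.94 * m[, "SBS2"] + 0.03 * m[, "SBS1"] + 0.03 * m[, "SBS5"]
  fit <- refit_with_pruning(cat96, sig_subset(m, c("SBS2", "SBS1", "SBS5")))
  expect_equal(unclass(fit), c(SBS2 = 1), tolerance = 1e-6,
               ignore_attr = TRUE)

  # already above threshold: output is the plain fit (fixed point at once)
  cat2 <- 0.6 * m[, "SBS2"] + 0.4 * m[, "SBS17b"]
  m2 <- sig_subset(m, c("SBS2", "SBS17b"))
  expect_equal(unclass(refit_with_pruning(cat2, m2)),
               unclass(fit_exposures(cat2, m2)), ignore_attr = TRUE)

  # exhaustive subset oracle on 4 candidates: the pruned fit equals a
  # re-run of the plain fit on its own support, and every retained weight
  # clears the threshold
  cols <- c("SBS2", "SBS13", "SBS17a", "SBS40")
  set.seed(4)
  cat4 <- as.numeric(unclass(sig_subset(m, cols)) %*% c(0.55, 0.30, 0.11, 0.04))
  pr <- refit_with_pruning(cat4, sig_subset(m, cols))
  expect_true(all(unclass(pr) >= 0.05) || length(pr) == 1)
  rerun <- fit_exposures(cat4, sig_subset(m, names(pr)))
  expect_equal(unclass(pr), unclass(rerun), tolerance = 1e-10,
               ignore_attr = TRUE)
  # one more prune-and-fit round changes nothing
  again <- refit_with_pruning(cat4, sig_subset(m, names(pr)))
  expect_equal(unclass(again), unclass(pr), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("signature mixtures are recovered with mean absolute error <= 0.03", {
  g <- fix_genome()
  m <- fix_sigs()
  truth <- c(SBS17a = 0.20, SBS17b = 0.20, SBS1 = 0.10, SBS5 = 0.20,
             SBS2 = 0.10, SBS13 = 0.10, SBS18 = 0.10)
  mu <- sample_mutations_from_signature(truth, 5000, g, seed = 77, matrix = m)
  cat96 <- integer(96); tab <- table(mu$channel)
  cat96[as.integer(names(tab))] <- as.integer(tab)
  cand <- sig_subset(m, oac_signature_set())
  fit <- fit_exposures(cat96, cand)
  full <- setNames(numeric(ncol(cand)), colnames(cand))
  full[names(truth)] <- truth
  expect_lt(mean(abs(unclass(fit) - full)), 0.03)
})

test_that("grouping is additive and conserves total exposure", {
  w <- structure(c(SBS2 = 0.1, SBS13 = 0.15, SBS1 = 0.5, SBS20 = 0.25),
                 class = c("exposure_fit", "numeric"))
  grp <- group_exposures(w)
  expect_equal(unname(grp["APOBEC"]), 0.25)
  expect_equal(unname(grp["MMR/MSI"]), 0.25)
  expect_equal(sum(grp), sum(w))
  none <- group_exposures(structure(c(SBS1 = 1),
                                    class = c("exposure_fit", "numeric")))
  expect_equal(unname(none["APOBEC"]), 0)
})

test_that("presence dichotomisation reflects survival of the pruning step", {
  w <- structure(c(SBS2 = 0.06, SBS1 = 0.94),
                 class = c("exposure_fit", "numeric"))
  expect_true(signature_presence(w, signature_groups()$APOBEC))
  w0 <- structure(c(SBS1 = 1), class = c("exposure_fit", "numeric"))
  expect_false(signature_presence(w0, signature_groups()$APOBEC))
})

test_that("population profiles gate the platinum pair and flag small inputs", {
  g <- fix_genome()
  m <- fix_sigs()
  mu <- sample_mutations_from_signature(c(SBS35 = 1), 400, g, seed = 15,
                                        matrix = m)
  rec <- mk_records(mu[, c("pos", "ref", "alt")])
  rec$context <- mu$context; rec$channel <- mu$channel
  with_pt <- population_signature_profile(rec, m, include_platinum = TRUE)
  without <- population_signature_profile(rec, m, include_platinum = FALSE)
  expect_true("SBS35" %in% names(with_pt))
  expect_false(any(c("SBS31", "SBS35") %in% names(without)))
  # a population drawn from SBS35 is recovered when the pair is included
  expect_gte(unclass(with_pt)[["SBS35"]], 0.8)
  expect_false(isTRUE(attr(with_pt, "low_confidence")))

  small <- population_signature_profile(rec[1:10, ], m)
  expect_true(attr(small, "low_confidence"))
})
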