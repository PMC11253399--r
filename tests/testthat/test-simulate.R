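test_that("fixture genomes are reproducible with the stated length and CpC density", {
  g1 <- make_fixture_genome(5000, seed = 9)
  g2 <- make_fixture_genome(5000, seed = 9)
  expect_identical(g1, g2)
  expect_equal(nchar(g1[[1]]), 5000L)
  expect_false(identical(g1, make_fixture_genome(5000, seed = 10)))

  # FASTA round trip is byte-stable
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  make_fixture_genome(2000, seed = 4, path = f1)
  make_fixture_genome(2000, seed = 4, path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(read_genome(f1), make_fixture_genome(2000, seed = 4))

  # CpC dinucleotide frequency hits the target at length 1e6
  big <- make_fixture_genome(1e6, seed = 13, cpc_target = 0.05)
  b <- strsplit(big[[1]], "")[[1]]
  cpc <- mean(b[-length(b)] == "C" & b[-1] == "C")
  expect_lt(abs(cpc - 0.05), 0.01)
})

test_that("signature-drawn mutations reproduce the mixture's channel law", {
  g <- fix_genome()
  m <- fix_sigs()
  expect_equal(nrow(sample_mutations_from_signature(c(SBS5 = 1), 0, g, 1)), 0L)

  mix <- c(SBS1 = 0.3, SBS5 = 0.4, SBS18 = 0.3)
  big_g <- memo("genome_1m", make_fixture_genome(1e6, seed = 29))
  mu <- sample_mutations_from_signature(mix, 50000, big_g, seed = 30,
                                        matrix = m)
  expect_equal(nrow(mu), 50000L)
  expect_equal(anyDuplicated(mu$pos), 0L)
  emp <- tabulate(mu$channel, 96) / 50000
  probs <- as.numeric(unclass(m)[, names(mix)] %*% mix)
  expect_lt(max(abs(emp - probs)), 0.005)
  # genome consistency: the reference allele is the genome base
  idx <- sample(50000, 200)
  expect_equal(substr(rep(big_g[[1]], 200), mu$pos[idx], mu$pos[idx]),
               mu$ref[idx])

  # single-signature round trip through the fitter
  mu1 <- sample_mutations_from_signature(c(SBS17b = 1), 3000, g, seed = 31,
                                         matrix = m)
  cat96 <- tabulate(mu1$channel, 96)
  fit <- fit_exposures(cat96, sig_subset(m, oac_signature_set()))
  expect_gte(unclass(fit)[["SBS17b"]], 0.97)
})

test_that("platinum planting controls the planted fraction and enrichment", {
  g <- fix_genome()
  mu <- sample_mutations_from_signature(c(SBS5 = 1), 500, g, seed = 40,
                                        matrix = fix_sigs())
  expect_identical(plant_platinum(mu, 0, g, seed = 41), mu)
  aug <- plant_platinum(mu, 0.3, g, seed = 41)
  expect_equal(mean(aug$planted_platinum), 0.3, tolerance = 0.01)
  rec <- mk_records(aug[, c("pos", "ref", "alt")])
  expect_gt(platinum_enrichment(rec, g)$odds_ratio, 1.5)
})

test_that("planted clone structures honour presence, sum rule and determinism", {
  g <- fix_genome()
  cfg1 <- sim_config(n_tumours = 1, clones_range = c(1, 1),
                     mutations_per_clone = c(80, 80), seed = 5,
                     call_fn_rate = 0)  # structural check without caller noise
  one <- plant_clone_structure(cfg1, g, seed = 5)
  # a single clone at prevalence 1 is called in (shared across) both regions
  idx <- index_by_key(one$records)
  lab <- classify_spatial(idx, one$sample_info$sample_id[1],
                          one$sample_info$sample_id[2])
  expect_gte(mean(lab$label == "shared"), 0.95)

  cfg <- sim_config(n_tumours = 1, clones_range = c(4, 6),
                    mutations_per_clone = c(50, 120), seed = 6,
                    include_post = TRUE)
  a <- plant_clone_structure(cfg, g, seed = 8)
  b <- plant_clone_structure(cfg, g, seed = 8)
  expect_identical(a, b)
  # sum rule: children of each parent never exceed it in any sample
  tr <- a$truth
  prev <- tr$prevalence
  for (k in seq_len(nrow(prev))) {
    kids <- which(tr$clones$parent == tr$clones$clone[k])
    if (length(kids) > 0) {
      expect_true(all(colSums(prev[kids, , drop = FALSE]) <= prev[k, ] + 1e-9))
    }
  }
})

test_that("cohorts reproduce the shared-fraction target and are deterministic", {
  co <- fix_cohort()  # 12 tumours, seeded
  sp <- suppressMessages(run_spatial(co, pipeline_config()))
  expect_lt(abs(mean(sp$proportions$prop_shared) -
                  co$config$shared_fraction), 0.1)
  co2 <- suppressMessages(simulate_cohort(co$config))
  expect_identical(co$mutations, co2$mutations)
  expect_identical(co$clinical, co2$clinical)
})

test_that("survival simulation respects the hazard ratio and censoring", {
  s0 <- simulate_survival(rep(FALSE, 400), hr = 3, seed = 50)
  expect_true(all(s0$dss_months <= 60))
  expect_equal(median(s0$dss_months[s0$event == 1] |> round()) < 60, TRUE)
  # all-censored configuration: horizon shorter than any survival time
  s1 <- simulate_survival(rep(FALSE, 50), hr = 1, seed = 51,
                          median_months = 1e6, censor_month = 60)
  expect_equal(sum(s1$event), 0L)
  # hr = 1: the log-rank test rejects at about the nominal rate (covered by
  # the calibration test); here check flagged patients die faster
  s2 <- simulate_survival(rep(c(TRUE, FALSE), each = 300), hr = 4, seed = 52)
  expect_lt(median(s2$dss_months[1:300]), median(s2$dss_months[301:600]))
})
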