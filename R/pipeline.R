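#' Pipeline configuration
#'
#' Central home for every analysis threshold: the 10% cohort signature
#' screen, the 5% per-population pruning, the 1% clone-size filter, the
#' clustering budget (up to 40 clusters, 100 restarts), the 41-base platinum
#' window, the 500 nM IC50 binder cutoff and the 60-month censoring horizon.
#'
#' @param cohort_sig_min cohort screen retention threshold.
#' @param population_prune per-population pruning threshold.
#' @param clone_min_fraction minimum fraction of a tumour's mutations a
#'   clone must hold.
#' @param max_clusters,restarts clustering budget.
#' @param platinum_window odd window width (bases).
#' @param ic50_threshold binder cutoff (nM).
#' @param censor_month survival censoring horizon (months).
#' @param min_population_mutations below this a population's signature fit
#'   is flagged low-confidence.
#' @param signature_set cohort candidate signature ids.
#' @param signature_matrix full candidate `signature_matrix` (must include
#'   the set above plus SBS31/SBS35).
#' @param seed integer seed for the clustering restarts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_sig_min = 0.10,
                            population_prune = 0.05,
                            clone_min_fraction = 0.01,
                            max_clusters = 40,
                            restarts = 100,
                            platinum_window = 41,
                            ic50_threshold = 500,
                            censor_month = 60,
                            min_population_mutations = 50,
                            signature_set = oac_signature_set(),
                            signature_matrix = sbs_reference(),
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$cohort_sig_min > 0, cfg$cohort_sig_min <= 1,
            cfg$population_prune > 0, cfg$population_prune <= 1,
            cfg$clone_min_fraction > 0, cfg$clone_min_fraction <= 1,
            cfg$platinum_window %% 2 == 1)
  class(cfg) <- "pipeline_config"
  cfg
}

# 10% cohort screen: fit every sample's full catalogue against the
# candidate set (without the platinum pair) and retain signatures reaching
# the threshold in at least one sample.
cohort_signature_screen <- function(mutations, config) {
  mat <- config$signature_matrix
  cand <- intersect(config$signature_set, colnames(mat))
  sub <- mat[, cand, drop = FALSE]
  class(sub) <- class(mat)
  fits <- mutations |>
    dplyr::group_split(.data$sample_id) |>
    purrr::map(function(df) fit_exposures(build_catalog(df), sub))
  select_cohort_signatures(fits, min_prop = config$cohort_sig_min)
}

#' Spatial (treatment-naive) analysis
#'
#' For every tumour with two or more treatment-naive biopsies: classify
#' mutations shared/private, summarise proportions, run the cohort 10%
#' signature screen, refit per-population exposures with 5% pruning,
#' dichotomise APOBEC (SBS2/13) and BRCA-like (SBS3) presence, test
#' shared-vs-private enrichment (Fisher + FDR), and associate
#' presence-in-private with disease-specific survival (log-rank and
#' stage-adjusted Cox) when a clinical table is available.
#'
#' @param cohort an `oac_cohort` (or a compatible list with `mutations`,
#'   `sample_info`, optional `clinical`).
#' @param config a [pipeline_config()].
#' @param spatial_pairs optional named list tumour_id -> character(2) sample
#'   pair, for tumours with more than two treatment-naive biopsies.
#' @return list: `proportions`, `paired_test`, `exposures`, `presence`,
#'   `enrichment_tests`, `survival` (per tested group), `cohort_signatures`.
#' @export
run_spatial <- function(cohort, config = pipeline_config(),
                        spatial_pairs = NULL) {
  pre <- cohort$mutations[cohort$mutations$timepoint == "pre", , drop = FALSE]
  message("spatial: ", nrow(pre), " pre-treatment mutation rows across ",
          length(unique(pre$tumour_id)), " tumours")
  cohort_sigs <- cohort_signature_screen(pre, config)
  message("cohort screen retained ", length(cohort_sigs), " signature(s)")
  mat <- config$signature_matrix

  tumours <- unique(pre$tumour_id)
  props <- list(); expo <- list(); presence <- list()
  for (tid in tumours) {
    rec <- pre[pre$tumour_id == tid, , drop = FALSE]
    smps <- unique(rec$sample_id)
    pair <- spatial_pairs[[tid]] %||% sort(smps)[1:2]
    if (length(smps) < 2 || anyNA(pair)) next
    rec <- rec[rec$sample_id %in% pair, , drop = FALSE]
    idx <- index_by_key(rec)
    labels <- classify_spatial(idx, pair[1], pair[2])
    props[[tid]] <- population_proportions(labels, tumour_id = tid)
    rec$key <- mutation_key(rec)
    for (pop in c("shared", "private")) {
      keys <- labels$key[labels$label == pop]
      if (length(keys) == 0) next
      prec <- rec[!duplicated(rec$key) & rec$key %in% keys, , drop = FALSE]
      fit <- population_signature_profile(
        prec, mat, cohort_signatures = cohort_sigs,
        include_platinum = FALSE, min_prop = config$population_prune,
        min_mutations = config$min_population_mutations
      )
      expo[[paste(tid, pop)]] <- tidy(fit) |>
        dplyr::mutate(tumour_id = tid, population = pop,
                      low_confidence = isTRUE(attr(fit, "low_confidence")),
                      .before = 1)
      for (grp in c("APOBEC", "BRCA")) {
        members <- if (grp == "APOBEC") signature_groups()$APOBEC else "SBS3"
        presence[[paste(tid, pop, grp)]] <- tibble::tibble(
          tumour_id = tid, population = pop, group = grp,
          present = signature_presence(fit, members)
        )
      }
    }
  }
  proportions <- dplyr::bind_rows(props)
  exposures <- dplyr::bind_rows(expo)
  presence <- dplyr::bind_rows(presence)

  paired_test <- if (nrow(proportions) >= 3) {
    paired_t(proportions$prop_shared, proportions$prop_private)
  } else NULL

  enrichment <- presence |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(df, key) {
      tab <- with(df, table(factor(population, c("shared", "private")),
                            factor(present, c(TRUE, FALSE))))
      fisher_exact(as.matrix(tab))
    }) |>
    dplyr::ungroup()
  if (nrow(enrichment) > 0) enrichment$q.value <- fdr_adjust(enrichment$p.value)

  surv_out <- list()
  if (!is.null(cohort$clinical)) {
    clin <- censor_clinical(cohort$clinical, config$censor_month)
    for (grp in unique(presence$group)) {
      pp <- presence[presence$population == "private" &
                       presence$group == grp, , drop = FALSE]
      flags <- setNames(pp$present, pp$tumour_id)[clin$patient_id]
      ok <- !is.na(flags)
      if (sum(ok) < 4 || length(unique(flags[ok])) < 2) next
      km <- km_logrank(clin$dss_months[ok], clin$event[ok],
                       ifelse(flags[ok], "present", "absent"))
      cox <- cox_adjusted(clin$dss_months[ok], clin$event[ok], flags[ok],
                          stage = clin$stage_ctnm[ok])
      surv_out[[grp]] <- list(km = km, cox = cox)
    }
  }

  list(proportions = proportions, paired_test = paired_test,
       exposures = exposures, presence = presence,
       enrichment_tests = enrichment, survival = surv_out,
       cohort_signatures = cohort_sigs)
}

#' Temporal (pre vs post treatment) analysis
#'
#' For tumours with post-treatment samples: classify mutations
#' shared/unique-pre/unique-post across all samples, refit per-population
#' signature exposures with the platinum pair SBS31/SBS35 added to the
#' candidate set (they are included only in this pre/post analysis), score
#' platinum enrichment per population, and compare unique-post vs
#' unique-pre odds ratios (paired t) and mutation counts.
#'
#' @param cohort an `oac_cohort` (needs `genome` for platinum windows).
#' @param config a [pipeline_config()].
#' @return list: `counts`, `exposures`, `platinum`, `or_test`,
#'   `count_test`; `NULL` (with a message) when no post-treatment samples
#'   exist.
#' @export
run_temporal <- function(cohort, config = pipeline_config()) {
  muts <- cohort$mutations
  post_tumours <- unique(muts$tumour_id[muts$timepoint == "post"])
  if (length(post_tumours) == 0) {
    message("no post-treatment samples; temporal analysis skipped")
    return(invisible(NULL))
  }
  message("temporal: ", length(post_tumours), " tumour(s) with post-treatment samples")
  cohort_sigs <- cohort_signature_screen(
    muts[muts$tumour_id %in% post_tumours, , drop = FALSE], config
  )
  mat <- config$signature_matrix
  counts <- list(); expo <- list(); plat <- list()
  for (tid in post_tumours) {
    rec <- muts[muts$tumour_id == tid, , drop = FALSE]
    pre_s <- unique(rec$sample_id[rec$timepoint == "pre"])
    post_s <- unique(rec$sample_id[rec$timepoint == "post"])
    idx <- index_by_key(rec)
    labels <- classify_temporal(idx, pre_s, post_s)
    counts[[tid]] <- population_proportions(labels, tumour_id = tid)
    rec$key <- mutation_key(rec)
    for (pop in c("shared", "unique_pre", "unique_post")) {
      keys <- labels$key[labels$label == pop]
      if (length(keys) == 0) next
      prec <- rec[!duplicated(rec$key) & rec$key %in% keys, , drop = FALSE]
      fit <- population_signature_profile(
        prec, mat, cohort_signatures = cohort_sigs,
        include_platinum = TRUE, min_prop = config$population_prune,
        min_mutations = config$min_population_mutations
      )
      expo[[paste(tid, pop)]] <- tidy(fit) |>
        dplyr::mutate(tumour_id = tid, population = pop, .before = 1)
      if (pop != "shared") {
        pres <- platinum_enrichment(prec, cohort$genome,
                                    window = config$platinum_window)
        pres$tumour_id <- tid; pres$population <- pop
        plat[[paste(tid, pop)]] <- pres
      }
    }
  }
  platinum <- dplyr::bind_rows(plat)
  or_test <- NULL; count_test <- NULL
  wide <- platinum |>
    dplyr::select("tumour_id", "population", "odds_ratio") |>
    tidyr::pivot_wider(names_from = "population", values_from = "odds_ratio")
  if (all(c("unique_pre", "unique_post") %in% names(wide))) {
    cc <- wide[complete.cases(wide), , drop = FALSE]
    if (nrow(cc) >= 3) or_test <- paired_t(cc$unique_post, cc$unique_pre)
  }
  counts <- dplyr::bind_rows(counts)
  if (nrow(counts) >= 3) {
    count_test <- paired_t(counts$n_unique_post, counts$n_unique_pre)
  }
  list(counts = counts, exposures = dplyr::bind_rows(expo),
       platinum = platinum, or_test = or_test, count_test = count_test,
       cohort_signatures = cohort_sigs)
}

#' Clonal decomposition analysis
#'
#' Per tumour: collate the multi-sample count matrix from calls plus
#' pileup, cluster mutations into clones (binomial-mixture EM, BIC model
#' selection), exclude clones under the 1% mutation-fraction filter, build
#' the clone tree, average prevalences per timepoint (fishplot table), and
#' attribute per-clone signature exposures, platinum enrichment and DAI
#' summaries using only each clone's own mutations.
#'
#' @param cohort an `oac_cohort`.
#' @param config a [pipeline_config()].
#' @param tumours optional subset of tumour ids.
#' @return list: `models` (named list of `clone_model`), `clone_table`,
#'   `fishplot`, `exposures`, `platinum`, `dai`, `clone_counts`.
#' @export
run_clonal <- function(cohort, config = pipeline_config(), tumours = NULL) {
  muts <- cohort$mutations
  tumours <- tumours %||% unique(muts$tumour_id)
  cohort_sigs <- cohort_signature_screen(muts, config)
  mat <- config$signature_matrix
  models <- list(); clone_tbl <- list(); fish <- list()
  expo <- list(); plat <- list(); dai_out <- list()
  aff <- cohort$affinity
  if (!is.null(aff)) {
    aff <- compute_dai(filter_binders(aff, config$ic50_threshold))
  }
  for (tid in tumours) {
    rec <- muts[muts$tumour_id == tid, , drop = FALSE]
    if (nrow(rec) == 0) next
    si <- cohort$sample_info[cohort$sample_info$tumour_id == tid, ,
                             drop = FALSE]
    purity <- setNames(si$purity, si$sample_id)
    pp <- cohort$pileup
    if (!is.null(pp) && "tumour_id" %in% names(pp)) {
      pp <- pp[pp$tumour_id == tid, , drop = FALSE]
    }
    cm <- build_count_matrix(rec, pileup = pp, purity = purity)
    model <- cluster_mutations(cm, max_clusters = config$max_clusters,
                               restarts = config$restarts,
                               seed = config$seed)
    model <- prune_clones(model, min_fraction = config$clone_min_fraction)
    if (length(model$pruned) > 0) {
      message(tid, ": ", length(model$pruned),
              " clone(s) under the ", config$clone_min_fraction * 100,
              "% filter excluded")
    }
    model <- infer_tree(model)
    models[[tid]] <- model
    ct <- tidy(model); ct$tumour_id <- tid
    clone_tbl[[tid]] <- ct
    tp <- setNames(si$timepoint, si$sample_id)
    ft <- timepoint_prevalence(model, tp); ft$tumour_id <- tid
    fish[[tid]] <- ft

    rec$key <- mutation_key(rec)
    uniq <- rec[!duplicated(rec$key), , drop = FALSE]
    for (cl in names(clone_mutations(model))) {
      keys <- clone_mutations(model)[[cl]]
      if (length(keys) == 0) next
      crec <- uniq[uniq$key %in% keys, , drop = FALSE]
      fit <- population_signature_profile(
        crec, mat, cohort_signatures = cohort_sigs,
        include_platinum = any(rec$timepoint == "post"),
        min_prop = config$population_prune,
        min_mutations = config$min_population_mutations
      )
      expo[[paste(tid, cl)]] <- tidy(fit) |>
        dplyr::mutate(tumour_id = tid, clone = cl,
                      low_confidence = isTRUE(attr(fit, "low_confidence")),
                      .before = 1)
      pres <- platinum_enrichment(crec, cohort$genome,
                                  window = config$platinum_window)
      pres$tumour_id <- tid; pres$clone <- cl
      plat[[paste(tid, cl)]] <- pres
    }
    if (!is.null(aff)) {
      dd <- dai_by_population(aff[aff$tumour_id == tid, , drop = FALSE],
                              model$assignment)
      if (nrow(dd) > 0) { dd$tumour_id <- tid; dai_out[[tid]] <- dd }
    }
  }
  clone_counts <- tibble::tibble(
    tumour_id = names(models),
    K = vapply(models, `[[`, integer(1), "K")
  )
  list(models = models, clone_table = dplyr::bind_rows(clone_tbl),
       fishplot = dplyr::bind_rows(fish),
       exposures = dplyr::bind_rows(expo),
       platinum = dplyr::bind_rows(plat),
       dai = dplyr::bind_rows(dai_out),
       clone_counts = clone_counts)
}

#' Run the full pipeline
#'
#' Spatial, temporal and clonal analyses plus a reproducibility manifest
#' (config hash, seed, package version, filtering counts).
#'
#' @param cohort an `oac_cohort`.
#' @param config a [pipeline_config()].
#' @return list: `spatial`, `temporal`, `clonal`, `manifest`.
#' @export
run_all <- function(cohort, config = pipeline_config()) {
  spatial <- run_spatial(cohort, config)
  temporal <- run_temporal(cohort, config)
  clonal <- run_clonal(cohort, config)
  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)[setdiff(names(unclass(config)),
                                                      "signature_matrix")]),
    package_version = as.character(utils::packageVersion("oacevo")),
    n_mutation_rows = nrow(cohort$mutations),
    n_samples = nrow(cohort$sample_info),
    n_tumours = length(unique(cohort$sample_info$tumour_id))
  )
  list(spatial = spatial, temporal = temporal, clonal = clonal,
       manifest = manifest)
}
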