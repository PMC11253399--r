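#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group with the two-group log-rank
#' chi-square (1 df), via the survival package. Times are expected to be
#' censored upstream (see [read_clinical_table()]).
#'
#' @param times follow-up in months.
#' @param events 1 = death from disease, 0 = censored.
#' @param group factor-like group labels; every level must be non-empty.
#' @return a `survfit_summary`: list with `curves` (tibble: group, time,
#'   n_risk, n_event, survival), `logrank_stat`, `logrank_p`, `n`,
#'   `n_groups`.
#' @export
km_logrank <- function(times, events, group) {
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(group) < 2) {
    stop("need >= 2 non-empty groups")
  }
  df <- data.frame(time = times, event = events, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata_grp <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  curves <- tibble::tibble(
    group = strata_grp, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, survival = fit$surv
  )
  if (sum(events) == 0) {
    stat <- 0; p <- 1  # no deaths: nothing to compare
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    stat <- unname(sd$chisq)
    p <- pchisq(stat, df = nlevels(group) - 1, lower.tail = FALSE)
  }
  structure(
    list(curves = curves, logrank_stat = stat, logrank_p = p,
         n = length(times), n_groups = nlevels(group)),
    class = "survfit_summary"
  )
}

#' Stage-adjusted Cox proportional-hazards model
#'
#' Partial-likelihood fit (Breslow tie handling by default, as configured)
#' with the exposure flag and ordinal-encoded clinical stage as covariates.
#' Complete separation (monotone likelihood) is flagged rather than
#' reported as a finite hazard ratio.
#'
#' @param times,events as in [km_logrank()].
#' @param exposure_flag logical/0-1 covariate of interest (e.g. signature
#'   presence).
#' @param stage ordinal stage covariate (numeric, or an ordered factor which
#'   is encoded as consecutive integers).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return a `coxfit_summary`: list with `hr`, `ci_low`, `ci_high`, `p`,
#'   `log_hr`, `se`, `n`, `n_events`, `flagged` (TRUE when inestimable).
#' @export
cox_adjusted <- function(times, events, exposure_flag, stage = NULL,
                         ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  x <- as.numeric(exposure_flag)
  if (length(unique(x)) < 2) {
    return(structure(list(hr = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_,
                          log_hr = NA_real_, se = NA_real_,
                          n = length(times), n_events = sum(events),
                          flagged = TRUE),
                     class = "coxfit_summary"))
  }
  df <- data.frame(time = times, event = events, exposure = x)
  fml <- survival::Surv(time, event) ~ exposure
  if (!is.null(stage)) {
    df$stage <- if (is.factor(stage)) as.numeric(stage) else as.numeric(stage)
    fml <- survival::Surv(time, event) ~ exposure + stage
  }
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      f <- suppressWarnings(survival::coxph(fml, data = df, ties = ties))
      attr(f, "warned") <- conditionMessage(w)
      f
    }
  )
  co <- summary(fit)$coefficients
  b <- co["exposure", "coef"]; se <- co["exposure", "se(coef)"]
  flagged <- !is.finite(b) || !is.finite(se) || abs(b) > 15 ||
    grepl("infinite", attr(fit, "warned") %||% "", fixed = TRUE)
  structure(
    list(hr = exp(b), ci_low = exp(b - 1.96 * se),
         ci_high = exp(b + 1.96 * se),
         p = co["exposure", "Pr(>|z|)"], log_hr = b, se = se,
         n = nrow(df), n_events = sum(df$event), flagged = flagged),
    class = "coxfit_summary"
  )
}

#' @export
tidy.survfit_summary <- function(x, ...) x$curves

#' @export
glance.survfit_summary <- function(x, ...) {
  tibble::tibble(logrank_stat = x$logrank_stat, logrank_p = x$logrank_p,
                 n = x$n, n_groups = x$n_groups)
}

#' @export
tidy.coxfit_summary <- function(x, ...) {
  tibble::tibble(term = "exposure", estimate = x$log_hr, std.error = x$se,
                 hr = x$hr, conf.low = x$ci_low, conf.high = x$ci_high,
                 p.value = x$p, flagged = x$flagged)
}

#' @export
glance.coxfit_summary <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, flagged = x$flagged)
}

#' Paired t-test
#'
#' @param x,y paired measurements.
#' @return tibble: `statistic`, `p.value`, `estimate` (mean difference).
#' @export
paired_t <- function(x, y) {
  if (all(x == y)) {
    return(tibble::tibble(statistic = 0, p.value = 1, estimate = 0))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic),
                 p.value = tt$p.value,
                 estimate = unname(tt$estimate))
}

#' Fisher's exact test on a 2x2 table
#'
#' @param table 2x2 integer matrix.
#' @return tibble: `odds_ratio` (conditional MLE), `p.value`.
#' @export
fisher_exact <- function(table) {
  ft <- fisher.test(table)
  tibble::tibble(odds_ratio = unname(ft$estimate), p.value = ft$p.value)
}

#' Kruskal-Wallis rank-sum test
#'
#' @param values numeric outcomes.
#' @param groups group labels.
#' @return tibble: `statistic`, `p.value`.
#' @export
kruskal_wallis <- function(values, groups) {
  kt <- kruskal.test(values, as.factor(groups))
  tibble::tibble(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p numeric vector of p-values.
#' @return q-values in input order (monotone step-up, bounded by 1).
#' @export
fdr_adjust <- function(p) {
  p.adjust(p, method = "fdr")
}
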