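#' Index mutations of one tumour by identity key
#'
#' @param records mutation tibble for a single tumour.
#' @return tibble with one row per distinct mutation key: `key` and
#'   `carriers`, a list-column of the sample ids the mutation was called in.
#' @export
index_by_key <- function(records) {
  if (length(unique(records$tumour_id)) > 1) {
    stop("records span multiple tumours: ",
         paste(unique(records$tumour_id), collapse = ", "))
  }
  records |>
    dplyr::mutate(key = mutation_key(records)) |>
    dplyr::distinct(.data$key, .data$sample_id) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(carriers = list(sort(unique(.data$sample_id))),
                     .groups = "drop")
}

#' Classify mutations of a two-region treatment-naive tumour
#'
#' Mutations called in both treatment-naive samples are `shared`; mutations
#' called in only one are `private` to that sample.
#'
#' @param index key index from [index_by_key()].
#' @param sample_pre_1,sample_pre_2 the two treatment-naive sample ids. For
#'   tumours with more than two biopsies, pass the chosen pair explicitly
#'   (e.g. the two most similar in cellularity).
#' @return tibble: `key`, `label` (`"shared"`/`"private"`), `carrier`
#'   (the private sample id, `NA` for shared).
#' @export
classify_spatial <- function(index, sample_pre_1, sample_pre_2) {
  stopifnot(sample_pre_1 != sample_pre_2)
  pair <- c(sample_pre_1, sample_pre_2)
  hit <- purrr::map(index$carriers, ~ intersect(.x, pair))
  n_hit <- lengths(hit)
  if (any(n_hit == 0)) {
    stop(sum(n_hit == 0), " key(s) carried by neither named sample")
  }
  tibble::tibble(
    key = index$key,
    label = ifelse(n_hit == 2, "shared", "private"),
    carrier = ifelse(n_hit == 2, NA_character_,
                     purrr::map_chr(hit, ~ .x[1] %||% NA_character_))
  )
}

#' Classify mutations across pre- and post-treatment samples
#'
#' `shared` mutations are called in *all* available pre- and post-treatment
#' samples. Mutations called in at least one treatment-naive but no
#' post-treatment sample are `unique_pre`; called in at least one
#' post-treatment but no treatment-naive sample, `unique_post`. Mutations
#' present in some-but-not-all samples spanning both timepoints have no
#' label in the source scheme and are reported as `partial`; downstream
#' unique-pre/unique-post analyses exclude them.
#'
#' @param index key index from [index_by_key()].
#' @param pre_samples,post_samples non-empty character vectors of sample ids.
#' @return tibble: `key`, `label`, `n_pre`, `n_post` carrier counts.
#' @export
classify_temporal <- function(index, pre_samples, post_samples) {
  if (length(pre_samples) == 0 || length(post_samples) == 0) {
    stop("both pre_samples and post_samples must be non-empty")
  }
  all_samples <- c(pre_samples, post_samples)
  n_pre <- purrr::map_int(index$carriers, ~ length(intersect(.x, pre_samples)))
  n_post <- purrr::map_int(index$carriers, ~ length(intersect(.x, post_samples)))
  n_all <- n_pre + n_post
  label <- dplyr::case_when(
    n_all == length(all_samples) ~ "shared",
    n_pre >= 1 & n_post == 0 ~ "unique_pre",
    n_post >= 1 & n_pre == 0 ~ "unique_post",
    TRUE ~ "partial"
  )
  tibble::tibble(key = index$key, label = label, n_pre = n_pre, n_post = n_post)
}

#' Summarise population proportions for one tumour
#'
#' @param labels classification tibble from [classify_spatial()] or
#'   [classify_temporal()].
#' @param tumour_id optional tumour id to stamp on the summary row.
#' @return one-row tibble of counts and proportions over distinct keys,
#'   plus `private_by_sample`, a list-column of per-carrier private counts
#'   (spatial classifications only).
#' @export
population_proportions <- function(labels, tumour_id = NA_character_) {
  if (nrow(labels) == 0) stop("empty label table")
  n <- nrow(labels)
  counts <- table(labels$label)
  props <- as.numeric(counts) / n
  names(props) <- names(counts)
  by_sample <- if ("carrier" %in% names(labels)) {
    tab <- table(labels$carrier[labels$label == "private"])
    list(tibble::tibble(sample_id = names(tab), n_private = as.integer(tab)))
  } else {
    list(NULL)
  }
  tibble::tibble(
    tumour_id = tumour_id,
    n_keys = n,
    n_shared = as.integer(counts["shared"] %||% 0L),
    prop_shared = unname(props["shared"] %||% 0),
    n_private = as.integer(counts["private"] %||% 0L),
    prop_private = unname(props["private"] %||% 0),
    n_unique_pre = as.integer(counts["unique_pre"] %||% 0L),
    n_unique_post = as.integer(counts["unique_post"] %||% 0L),
    n_partial = as.integer(counts["partial"] %||% 0L),
    private_by_sample = by_sample
  )
}

`%||%` <- function(x, y) {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) y else x
}
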