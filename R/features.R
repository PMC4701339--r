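#' Extract the sample-entropy feature vector for every subject
#'
#' For each of the eight GRF channels the pipeline is: normalize by body
#' weight, standardize to zero mean and unit variance, then compute
#' sample entropy with parameters `m` and `r`.  When a channel has
#' several trials (a `trial` column in the recordings), per-trial
#' entropies are averaged (`trial_mode = "average"`); the synthetic
#' generator emits one continuous series per channel.
#'
#' @param cohort A `fall_cohort` (see [generate_cohort()] /
#'   [read_cohort()]), or a list with tibbles `metadata` (`subject_id`,
#'   `group`, `weight_kg`) and `recordings` (`subject_id`, `activity`,
#'   `foot`, `axis`, and a `series` list-column or long `t_index`/`force`
#'   columns).
#' @param m,r Sample-entropy parameters (defaults 2 and 0.25).
#' @param weight_normalize Divide by body weight before standardizing.
#'   Standardization makes entropy invariant to this step; it is exposed
#'   as a regression guard.
#' @param trial_mode `"single"` (error if a channel has several trials)
#'   or `"average"` (entropy averaged across trials).
#' @return A tibble with `subject_id`, `group`, and the 8 entropy columns
#'   in canonical channel order.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_fallers = 2, n_nonfallers = 2,
#'                                       seed = 1, series_length = 600))
#' extract_features(cohort)
#' }
#' @export
extract_features <- function(cohort, m = 2, r = 0.25, weight_normalize = TRUE,
                             trial_mode = c("single", "average")) {
  trial_mode <- match.arg(trial_mode)
  if (!is.list(cohort) || is.null(cohort$metadata) || is.null(cohort$recordings)) {
    stop_param("`cohort` must contain `metadata` and `recordings` tables")
  }
  metadata <- tibble::as_tibble(cohort$metadata)
  recordings <- tibble::as_tibble(cohort$recordings)

  if (!"series" %in% names(recordings)) {
    if (!all(c("t_index", "force") %in% names(recordings))) {
      stop_param("`recordings` must have a `series` list-column or `t_index`/`force` columns")
    }
    grp_cols <- intersect(c("subject_id", "activity", "foot", "axis", "trial"),
                          names(recordings))
    recordings <- recordings |>
      dplyr::arrange(dplyr::across(dplyr::all_of(c(grp_cols, "t_index")))) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
      dplyr::summarise(series = list(.data$force), .groups = "drop")
  }
  if (!"feature" %in% names(recordings)) {
    recordings <- dplyr::left_join(recordings, grf_channels(),
                                   by = c("activity", "foot", "axis"))
  }
  if (anyNA(recordings$feature)) {
    stop_param("some recordings have an activity/foot/axis combination outside the 8-channel layout")
  }

  channels <- grf_channels()$feature
  rows <- vector("list", nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    sid <- metadata$subject_id[i]
    sub <- recordings[recordings$subject_id == sid, ]
    vals <- setNames(numeric(length(channels)), channels)
    for (ch in channels) {
      trials <- sub$series[sub$feature == ch]
      if (length(trials) == 0L) {
        stop_param(sprintf("subject %s is missing channel %s", sid, ch))
      }
      if (length(trials) > 1L && trial_mode == "single") {
        stop_param(sprintf(
          "subject %s has %d trials for channel %s; use trial_mode = \"average\"",
          sid, length(trials), ch))
      }
      ent <- vapply(trials, function(x) {
        if (weight_normalize) x <- normalize_by_weight(x, metadata$weight_kg[i])
        sample_entropy(standardize_series(x), m = m, r = r)
      }, numeric(1))
      if (anyNA(ent)) {
        stop_param(sprintf(
          "sample entropy is undefined for subject %s, channel %s (no matching template pairs)",
          sid, ch))
      }
      vals[ch] <- mean(ent)
    }
    rows[[i]] <- tibble::as_tibble_row(c(
      list(subject_id = sid, group = metadata$group[i]), as.list(vals)))
  }
  dplyr::bind_rows(rows)
}
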