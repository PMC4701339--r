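#' The eight GRF channels
#'
#' Channel layout of the analysis: three walking ground-reaction-force
#' axes per foot (medial-lateral ML, anterior-posterior AP,
#' superior-inferior SI) and one vertical (V) sit-to-stand channel per
#' foot, in the canonical feature order.
#'
#' @return A tibble with columns `feature`, `activity`, `foot`, `axis`.
#' @export
grf_channels <- function() {
  tibble::tibble(
    feature  = c("L_ML_F", "L_AP_F", "L_SI_F", "R_ML_F",
                 "R_AP_F", "R_SI_F", "L_V_F", "R_V_F"),
    activity = c(rep("walking", 6), rep("sts", 2)),
    foot     = c("left", "left", "left", "right", "right", "right",
                 "left", "right"),
    axis     = c("ML", "AP", "SI", "ML", "AP", "SI", "V", "V")
  )
}

#' Default per-channel entropy targets
#'
#' Group-wise sample-entropy means and SDs used to calibrate the
#' synthetic cohort: fallers show lower entropy than non-fallers on every
#' channel, most markedly on the sit-to-stand vertical forces.
#'
#' @return A tibble with columns `feature`, `group`, `mean`, `sd`.
#' @export
default_entropy_targets <- function() {
  ch <- grf_channels()$feature
  faller_mean    <- c(0.5586, 0.4496, 0.2574, 0.5700, 0.4661, 0.2996, 0.0852, 0.1003)
  faller_sd      <- c(0.1389, 0.0915, 0.1655, 0.1172, 0.0986, 0.1485, 0.0297, 0.0402)
  nonfaller_mean <- c(0.6246, 0.4835, 0.2819, 0.5826, 0.5116, 0.3187, 0.1110, 0.1339)
  nonfaller_sd   <- c(0.1858, 0.0421, 0.0690, 0.1963, 0.0574, 0.1144, 0.0313, 0.0340)
  dplyr::bind_rows(
    tibble::tibble(feature = ch, group = "faller",
                   mean = faller_mean, sd = faller_sd),
    tibble::tibble(feature = ch, group = "nonfaller",
                   mean = nonfaller_mean, sd = nonfaller_sd)
  )
}

#' Specify a synthetic GRF cohort
#'
#' @param n_fallers,n_nonfallers Group sizes (>= 1 each); defaults match
#'   the 23/15 split of the study cohort the generator emulates.
#' @param seed Master integer seed; every per-subject and per-channel
#'   random stream is derived deterministically from it.
#' @param series_length Samples per channel (> 100, so SampEn at `m = 2`
#'   has enough template pairs).
#' @param targets Per-channel entropy targets as returned by
#'   [default_entropy_targets()]: one row per `feature` x `group` with
#'   strictly positive target means.
#' @param variability Dimensionless scale on inter-subject entropy spread
#'   (1 reproduces the target SDs).
#' @param period,noise_amp MIX-process parameters, see [mix_params()].
#' @param weight_range Body-weight range (kg) subjects are drawn from.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_fallers = 23, n_nonfallers = 15, seed = 1,
                        series_length = 1000,
                        targets = default_entropy_targets(),
                        variability = 1, period = 200, noise_amp = 1,
                        weight_range = c(40, 90)) {
  n_fallers <- check_count(n_fallers, "n_fallers", min = 1L)
  n_nonfallers <- check_count(n_nonfallers, "n_nonfallers", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  series_length <- check_count(series_length, "series_length", min = 101L)
  variability <- check_number(variability, "variability")
  if (variability <= 0) stop_param("`variability` must be > 0")
  targets <- tibble::as_tibble(targets)
  need <- c("feature", "group", "mean", "sd")
  if (!all(need %in% names(targets))) {
    stop_param("`targets` must have columns feature, group, mean, sd")
  }
  ch <- grf_channels()$feature
  for (grp in c("faller", "nonfaller")) {
    got <- targets$feature[targets$group == grp]
    if (!setequal(got, ch)) {
      stop_param(sprintf("`targets` must cover all 8 channels for group '%s'", grp))
    }
  }
  if (any(!is.finite(targets$mean)) || any(targets$mean <= 0)) {
    stop_param("entropy target means must be strictly positive")
  }
  if (any(!is.finite(targets$sd)) || any(targets$sd < 0)) {
    stop_param("entropy target SDs must be non-negative")
  }
  structure(list(
    n_fallers = n_fallers, n_nonfallers = n_nonfallers, seed = seed,
    series_length = series_length, targets = targets,
    variability = variability, period = period, noise_amp = noise_amp,
    weight_range = as.numeric(weight_range)
  ), class = "cohort_spec")
}

#' Generate a synthetic two-group GRF cohort
#'
#' Builds an entropy-response curve for the MIX family once, then draws a
#' per-subject, per-channel target entropy around the group target
#' (shared latent factors induce moderate positive correlation within the
#' channel pairs `L_SI_F`/`R_ML_F` and `L_V_F`/`R_V_F`), inverts the
#' curve to an irregularity `p`, and generates the force series.  The
#' subject-level draw SD is shrunk by the single-realization entropy
#' noise so the realized spread approximates the target SD.
#'
#' Output is fully reproducible: an identical `cohort_spec` (including
#' seed) yields bit-identical tables.
#'
#' @param spec A [cohort_spec()].
#' @param curve_reps Realizations per grid point of the calibration
#'   curve.
#' @return A `fall_cohort` object: list with `metadata` (tibble
#'   `subject_id`, `group`, `weight_kg`), `recordings` (tibble
#'   `subject_id`, `activity`, `foot`, `axis`, `feature`, and the series
#'   as a list-column), and the `spec`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_fallers = 3, n_nonfallers = 3,
#'                                       seed = 7, series_length = 600))
#' cohort$metadata
#' }
#' @export
generate_cohort <- function(spec = cohort_spec(), curve_reps = 20) {
  if (!inherits(spec, "cohort_spec")) stop_param("`spec` must be a cohort_spec")

  curve <- mix_entropy_curve(
    length = spec$series_length, period = spec$period,
    noise_amp = spec$noise_amp, n_reps = curve_reps,
    seed = derive_seed(spec$seed, 0L, 0L)
  )
  # strictly increasing support for inversion
  keep <- !duplicated(curve$mean_entropy)
  inv_x <- curve$mean_entropy[keep]
  inv_p <- curve$p[keep]
  e_min <- min(inv_x); e_max <- max(inv_x)

  bad <- spec$targets$mean < e_min | spec$targets$mean > e_max
  if (any(bad)) {
    stop_calibration(sprintf(
      "entropy targets for %s are outside the achievable interval [%.4f, %.4f] at length %d",
      paste(spec$targets$feature[bad], collapse = ", "),
      e_min, e_max, spec$series_length))
  }

  channels <- grf_channels()
  # correlated channel blocks sharing a subject-level latent factor
  blocks <- list(c("L_SI_F", "R_ML_F"), c("L_V_F", "R_V_F"))
  rho <- 0.5
  target_of <- function(grp) {
    tg <- spec$targets[spec$targets$group == grp, ]
    tg[match(channels$feature, tg$feature), ]
  }
  # single-realization entropy SD along the curve, interpolated at a target
  noise_sd_at <- function(e) {
    approx(inv_x, curve$sd_entropy[keep], xout = e, rule = 2)$y
  }

  groups <- c(rep("faller", spec$n_fallers), rep("nonfaller", spec$n_nonfallers))
  ids <- c(sprintf("F%03d", seq_len(spec$n_fallers)),
           sprintf("N%03d", seq_len(spec$n_nonfallers)))

  # per-subject weight and latent irregularity draws
  draws <- lapply(seq_along(ids), function(s) {
    with_seed(derive_seed(spec$seed, s, 0L), {
      w <- runif(1, spec$weight_range[1], spec$weight_range[2])
      z_block <- rnorm(length(blocks))
      eps <- rnorm(nrow(channels))
      latent <- eps
      for (b in seq_along(blocks)) {
        in_b <- channels$feature %in% blocks[[b]]
        latent[in_b] <- sqrt(rho) * z_block[b] + sqrt(1 - rho) * eps[in_b]
      }
      list(w = w, latent = latent)
    })
  })
  # moment-match the latent factors within each group x channel (zero mean,
  # unit SD across subjects) so realized group means sit on the targets
  # rather than drifting with the finite-sample noise of the draws
  latent_mat <- do.call(rbind, lapply(draws, `[[`, "latent"))
  for (grp in unique(groups)) {
    rows <- which(groups == grp)
    if (length(rows) >= 2L) {
      for (ci in seq_len(ncol(latent_mat))) {
        v <- latent_mat[rows, ci]
        s_v <- sd(v)
        if (s_v > 0) latent_mat[rows, ci] <- (v - mean(v)) / s_v
      }
    }
  }

  meta <- vector("list", length(ids))
  recs <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    tg <- target_of(groups[s])
    noise_sd <- noise_sd_at(tg$mean)
    sd_eff <- spec$variability *
      sqrt(pmax(tg$sd^2 - noise_sd^2, (0.3 * tg$sd)^2))
    e_target <- pmin(pmax(tg$mean + sd_eff * latent_mat[s, ], e_min), e_max)
    p_sub <- approx(inv_x, inv_p, xout = e_target, rule = 2)$y

    series <- vector("list", nrow(channels))
    for (ci in seq_len(nrow(channels))) {
      pars <- mix_params(p_sub[ci], period = spec$period,
                         noise_amp = spec$noise_amp)
      sig <- generate_mix_series(pars, spec$series_length,
                                 derive_seed(spec$seed, s, ci))
      # scale to newtons: load-bearing axes carry ~1 body weight,
      # shear axes a small fraction; entropy is scale-invariant.
      vertical <- channels$axis[ci] %in% c("SI", "V")
      base_load <- if (vertical) 1.0 else 0.05
      amp <- if (vertical) 0.15 else 0.05
      series[[ci]] <- draws[[s]]$w * 9.81 * (base_load + amp * sig)
    }
    meta[[s]] <- tibble::tibble(subject_id = ids[s], group = groups[s],
                                weight_kg = draws[[s]]$w)
    recs[[s]] <- tibble::tibble(
      subject_id = ids[s],
      activity = channels$activity, foot = channels$foot,
      axis = channels$axis, feature = channels$feature,
      series = series
    )
  }

  structure(list(
    metadata = dplyr::bind_rows(meta),
    recordings = dplyr::bind_rows(recs),
    spec = spec,
    entropy_curve = curve
  ), class = "fall_cohort")
}

#' @export
print.fall_cohort <- function(x, ...) {
  n <- table(factor(x$metadata$group, levels = c("faller", "nonfaller")))
  cat(sprintf("<fall_cohort> %d subjects (%d fallers, %d non-fallers), %d recordings of %d samples\n",
              nrow(x$metadata), n[["faller"]], n[["nonfaller"]],
              nrow(x$recordings), x$spec$series_length))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes `metadata.tsv` (`subject_id`, `group`, `weight_kg`) and either
#' a single long-format `recordings.tsv` (`subject_id`, `activity`,
#' `foot`, `axis`, `t_index`, `force`) or one
#' `<subject>_<activity>_<foot>_<axis>.csv` per recording with columns
#' (`t_index`, `force`), or both.
#'
#' @param cohort A `fall_cohort`.
#' @param dir Output directory (created if missing).
#' @param format `"long"`, `"per_recording"`, or `"both"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("long", "per_recording", "both")) {
  format <- match.arg(format)
  if (!inherits(cohort, "fall_cohort")) stop_param("`cohort` must be a fall_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  long <- tidyr::unnest(
    dplyr::mutate(cohort$recordings,
                  series = purrr::map(.data$series,
                                      ~ tibble::tibble(t_index = seq_along(.x), force = .x))),
    "series")
  if (format %in% c("long", "both")) {
    readr::write_tsv(
      dplyr::select(long, "subject_id", "activity", "foot", "axis",
                    "t_index", "force"),
      file.path(dir, "recordings.tsv"))
  }
  if (format %in% c("per_recording", "both")) {
    purrr::pwalk(cohort$recordings, function(subject_id, activity, foot, axis,
                                             feature, series) {
      readr::write_csv(
        tibble::tibble(t_index = seq_along(series), force = series),
        file.path(dir, sprintf("%s_%s_%s_%s.csv", subject_id, activity, foot, axis)))
    })
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `metadata.tsv` and `recordings.tsv`.
#' @return A `fall_cohort` (without a generating spec).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  rec_path <- file.path(dir, "recordings.tsv")
  if (!file.exists(meta_path) || !file.exists(rec_path)) {
    stop_param(sprintf("`%s` must contain metadata.tsv and recordings.tsv", dir))
  }
  metadata <- readr::read_tsv(meta_path, show_col_types = FALSE)
  long <- readr::read_tsv(rec_path, show_col_types = FALSE)
  recordings <- long |>
    dplyr::arrange(.data$subject_id, .data$activity, .data$foot, .data$axis,
                   .data$t_index) |>
    dplyr::group_by(.data$subject_id, .data$activity, .data$foot, .data$axis) |>
    dplyr::summarise(series = list(.data$force), .groups = "drop") |>
    dplyr::left_join(grf_channels(), by = c("activity", "foot", "axis")) |>
    dplyr::select("subject_id", "activity", "foot", "axis", "feature", "series")
  structure(list(metadata = metadata, recordings = recordings, spec = NULL),
            class = "fall_cohort")
}
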