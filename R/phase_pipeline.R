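# ---------------------------------------------------------------------------
# Proof-of-principle time-lapse analysis pipeline: artifact-frame
# detection, histogram normalization, difference-image statistics,
# phase-boundary estimation, and region-growing confluence tracking.
# ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' @param frame_interval Minutes between frames (default 5).
#' @param median_window Odd median-filter window for the statistic and area
#'   signals (default 3: artifact frames are excluded before filtering, so
#'   the filter only has to suppress single-frame noise, and a short window
#'   does not displace the sharp adhesion spike).
#' @param prominence Extremum prominence threshold as a *fraction of each
#'   filtered signal's value range* (default 0.1); the four histogram
#'   statistics live on very different scales, so a relative threshold
#'   serves all of them.
#' @param artifact_z Robust z-score threshold for artifact-frame flagging
#'   (default 6).
#' @param spot_seed `(row, col)` seed of the unoccupied spot, 0-based.
#' @param grow_tolerance Region-growing intensity tolerance (default 35).
#' @param stay_tolerance Slack (in pixels of area) for the "reaches and
#'   stays at its minimum" rule (default 15).
#' @return A `phase_config` list.
#' @export
phase_config <- function(frame_interval = 5, median_window = 3L,
                         prominence = 0.1, artifact_z = 6,
                         spot_seed = NULL, grow_tolerance = 35,
                         stay_tolerance = 15) {
  if (frame_interval <= 0) stop_parameter("frame_interval must be positive")
  if (median_window %% 2L == 0L || median_window < 1L)
    stop_parameter("median_window must be odd")
  if (prominence < 0) stop_parameter("prominence must be non-negative")
  if (artifact_z <= 0) stop_parameter("artifact_z must be positive")
  if (grow_tolerance < 0 || stay_tolerance < 0)
    stop_parameter("tolerances must be non-negative")
  structure(list(frame_interval = frame_interval,
                 median_window = as.integer(median_window),
                 prominence = prominence, artifact_z = artifact_z,
                 spot_seed = spot_seed, grow_tolerance = grow_tolerance,
                 stay_tolerance = stay_tolerance),
            class = "phase_config")
}

#' Minutes elapsed at a frame index
#'
#' Frame 0 is recorded at t = 0; frame `i` at `i * frame_interval` minutes.
#'
#' @param frame 0-based frame index (vectorized).
#' @param frame_interval Minutes between frames.
#' @return Elapsed minutes.
#' @export
frame_minutes <- function(frame, frame_interval = 5) frame * frame_interval

#' Detect frames with the horizontal intensity-split recording artifact
#'
#' Flags frame `i` when its mean grey value deviates from the running
#' median (9-frame window) by more than `artifact_z` times the MAD of the
#' residuals.  The MAD is computed over all frames and floored at half a
#' grey level: long quiescent stretches (and degenerate constant stacks)
#' otherwise drive the MAD below the quantization scale and turn ordinary
#' proliferation drift into false positives.
#'
#' @param frames List of grey `image_item`s (>= 5).
#' @param artifact_z Positive robust z threshold.
#' @return Sorted 0-based indices of flagged frames.
#' @export
detect_artifact_frames <- function(frames, artifact_z = 6) {
  if (length(frames) < 5L)
    stop_parameter("artifact detection requires at least 5 frames")
  mg <- vapply(frames, function(f) mean_grey(item_payload(f)), 0)
  trend <- stats::runmed(mg, k = min(9L, 2L * (length(mg) %/% 2L) - 1L),
                         endrule = "median")
  resid <- mg - trend
  scale <- max(stats::mad(resid), 0.5)
  sort(which(abs(resid) > artifact_z * scale) - 1L)
}

#' Histogram statistics of consecutive difference images
#'
#' Applies histogram normalization to every frame (eliminating illumination
#' differences), forms the absolute difference images
#' `J_j = |I_{j+1} - I_j|`, and returns the energy, entropy, skewness and
#' kurtosis of each difference image's histogram as four signals of length
#' `N - 1`.
#'
#' @param frames List of >= 2 grey `image_item`s of equal shape.
#' @param frame_interval Optional minutes/frame recorded on the signals.
#' @return Named list of four `signal_item`s: `energy`, `entropy`,
#'   `skewness`, `kurtosis`.
#' @export
compute_phase_signals <- function(frames, frame_interval = NULL) {
  if (length(frames) < 2L)
    stop_parameter("needs at least 2 frames")
  frames <- lapply(frames, item_payload)
  norm <- lapply(frames, normalize_histogram)
  n <- length(norm)
  stats4 <- vapply(seq_len(n - 1L), function(j) {
    d <- abs_difference(norm[[j + 1L]], norm[[j]])
    unlist(histogram_statistics(d))
  }, numeric(4))
  mk <- function(row, nm, unit) signal_item(stats4[row, ], unit = unit,
                                            name = nm,
                                            sample_interval = frame_interval)
  list(energy = mk(1L, "energy", NULL),
       entropy = mk(2L, "entropy", "bit"),
       skewness = mk(3L, "skewness", NULL),
       kurtosis = mk(4L, "kurtosis", NULL))
}

# First prominent maximum and following first prominent minimum of one
# filtered signal; NULL when the pattern is absent.
signal_boundaries <- function(values, prominence_frac) {
  rng <- diff(range(values))
  if (rng == 0) return(NULL)
  ex <- find_extrema(values, min_prominence = prominence_frac * rng)
  if (length(ex$maxima) == 0L) return(NULL)
  b1 <- ex$maxima[1]
  mins_after <- ex$minima[ex$minima > b1]
  if (length(mins_after) == 0L) return(NULL)
  list(b1 = b1, b2 = mins_after[1])
}

#' Estimate the phase I/II and II/III boundaries from the four signals
#'
#' Each signal is median-filtered; entropy is negated first (it mirrors the
#' other three).  Per signal, the phase I/II boundary is the first
#' prominent maximum and the phase II/III boundary the first prominent
#' minimum after it.  Signals without a qualifying extremum pair are
#' dropped; estimates from the remaining signals are combined as plain
#' mean and standard error.
#'
#' @param signals List of four equal-length `signal_item`s named `energy`,
#'   `entropy`, `skewness`, `kurtosis` (from [compute_phase_signals()]).
#' @param config A [phase_config()].
#' @param index_map Optional vector mapping signal index `j` (1-based) to
#'   an original 0-based frame index (used after artifact-frame exclusion);
#'   defaults to `j - 1`.
#' @return List with `boundary_I_II` and `boundary_II_III`, each a
#'   `list(mean, se)` in (possibly mapped) frame units, plus `per_signal`.
#' @export
estimate_boundaries <- function(signals, config = phase_config(),
                                index_map = NULL) {
  stopifnot(length(signals) >= 2L)
  lens <- vapply(signals, length, 1L)
  if (length(unique(lens)) != 1L)
    stop_parameter("signals must have equal length")
  if (is.null(index_map)) index_map <- seq_len(lens[1]) - 1L
  per_signal <- list()
  for (nm in names(signals)) {
    v <- as_signal_values(signals[[nm]])
    if (identical(nm, "entropy")) v <- -v
    v <- median_filter(v, config$median_window)
    b <- signal_boundaries(v, config$prominence)
    if (!is.null(b))
      per_signal[[nm]] <- c(b1 = index_map[b$b1 + 1L],
                            b2 = index_map[b$b2 + 1L])
  }
  if (length(per_signal) < 2L)
    stop_detection(sprintf(
      "only %d of %d signals show the rise-fall boundary pattern",
      length(per_signal), length(signals)))
  b1s <- vapply(per_signal, `[[`, 0, "b1")
  b2s <- vapply(per_signal, `[[`, 0, "b2")
  # consensus gate: a statistic occasionally locks onto a spurious
  # extremum pair far from the other signals; estimates more than 5 frames
  # from the cross-signal median are excluded from the average
  ok <- abs(b1s - stats::median(b1s)) <= 5 & abs(b2s - stats::median(b2s)) <= 5
  if (sum(ok) >= 2L) {
    per_signal <- per_signal[ok]
    b1s <- b1s[ok]; b2s <- b2s[ok]
  }
  list(boundary_I_II = mean_and_se(b1s),
       boundary_II_III = mean_and_se(b2s),
       per_signal = per_signal)
}

#' Frame at which a signal reaches and stays at its minimum
#'
#' With `m = min(areas)`, returns the smallest index `i` such that
#' `areas[j] <= m + stay_tolerance` for every `j >= i`.
#'
#' @param areas Numeric vector or `signal_item` (e.g. unoccupied-spot areas).
#' @param stay_tolerance Non-negative slack above the minimum.
#' @return 0-based index.
#' @export
monolayer_frame <- function(areas, stay_tolerance = 0) {
  v <- as_signal_values(areas)
  if (length(v) < 1L) stop_parameter("needs at least one value")
  if (stay_tolerance < 0) stop_parameter("stay_tolerance must be non-negative")
  ok <- rev(cumprod(rev(v <= min(v) + stay_tolerance))) > 0
  which(ok)[1] - 1L
}

#' Full time-lapse proliferation analysis
#'
#' Orchestrates the pipeline: detect and exclude artifact frames; compute
#' the difference-image statistic signals; estimate the phase I/II and
#' II/III boundaries; measure the unoccupied-spot area on the *original*
#' frames by region growing at `config$spot_seed`; median-filter the area
#' signal; locate the monolayer frame; and assemble the report with
#' `t1 = boundary_I_II * dt`, `t2 = (boundary_II_III - boundary_I_II) * dt`,
#' `t123 = monolayer_frame * dt` and `t23 = t123 - t1`.
#'
#' All frame indices in the report refer to the original (0-based) frame
#' numbering, also after artifact exclusion; a boundary located at
#' difference image `J_j` is assigned the earlier frame index `j`.
#'
#' @param frames List of >= 5 grey `image_item`s (or `data_item`s).
#' @param config A [phase_config()]; `spot_seed` is required.
#' @return A `phase_report` with fields `artifact_frames`,
#'   `boundary_I_II`, `boundary_II_III` (each `list(mean, se)`),
#'   `monolayer_frame`, `t1`, `t2`, `t123`, `t23` (minutes), `signals`
#'   and `area_signal`.
#' @export
analyze_timelapse <- function(frames, config = phase_config()) {
  if (length(frames) < 5L)
    stop_parameter("analysis requires at least 5 frames")
  if (is.null(config$spot_seed))
    stop_parameter("config$spot_seed (row, col) is required")
  frames <- lapply(frames, item_payload)

  artifacts <- tryCatch(
    detect_artifact_frames(frames, config$artifact_z),
    stackops_error = function(e) stop_stackops(class(e)[1],
      paste0("artifact detection: ", conditionMessage(e))))
  keep <- setdiff(seq_along(frames) - 1L, artifacts)  # 0-based originals
  kept_frames <- frames[keep + 1L]

  signals <- tryCatch(
    compute_phase_signals(kept_frames, config$frame_interval),
    stackops_error = function(e) stop_stackops(class(e)[1],
      paste0("difference signals: ", conditionMessage(e))))

  # difference j of the kept stack straddles original frames keep[j],
  # keep[j+1]; the earlier index is used
  boundaries <- tryCatch(
    estimate_boundaries(signals, config, index_map = keep),
    stackops_error = function(e) stop_stackops(class(e)[1],
      paste0("boundary estimation: ", conditionMessage(e))))

  areas <- tryCatch(
    vapply(kept_frames, function(f)
      region_grow(f, config$spot_seed, config$grow_tolerance)$area, 0),
    stackops_error = function(e) stop_stackops(class(e)[1],
      paste0("region growing: ", conditionMessage(e))))
  area_filtered <- median_filter(areas, config$median_window)
  mono_kept <- monolayer_frame(area_filtered, config$stay_tolerance)
  mono <- keep[mono_kept + 1L]

  dt <- config$frame_interval
  b1 <- boundaries$boundary_I_II; b2 <- boundaries$boundary_II_III
  t1 <- list(minutes = b1$mean * dt, se = b1$se * dt)
  t123 <- mono * dt
  report <- structure(list(
    artifact_frames = artifacts,
    boundary_I_II = b1,
    boundary_II_III = b2,
    monolayer_frame = mono,
    t1 = t1,
    t2 = list(minutes = (b2$mean - b1$mean) * dt,
              se = sqrt(b1$se^2 + b2$se^2) * dt),
    t123 = t123,
    t23 = t123 - t1$minutes,
    signals = signals,
    area_signal = signal_item(areas, unit = "px", name = "spot area",
                              sample_interval = dt),
    frame_indices = keep,
    config = config), class = "phase_report")
  report
}

#' @export
print.phase_report <- function(x, ...) {
  cat("Time-lapse proliferation analysis\n")
  cat(sprintf("  artifact frames excluded : %s\n",
              if (length(x$artifact_frames) == 0L) "none"
              else paste(x$artifact_frames, collapse = ", ")))
  cat(sprintf("  phase I/II boundary      : frame %.1f +/- %.1f (t1 = %.0f +/- %.0f min)\n",
              x$boundary_I_II$mean, x$boundary_I_II$se, x$t1$minutes, x$t1$se))
  cat(sprintf("  phase II/III boundary    : frame %.1f +/- %.1f\n",
              x$boundary_II_III$mean, x$boundary_II_III$se))
  cat(sprintf("  phase II length          : t2 = %.0f +/- %.0f min\n",
              x$t2$minutes, x$t2$se))
  cat(sprintf("  monolayer frame          : %d (t123 = %.0f min)\n",
              x$monolayer_frame, x$t123))
  cat(sprintf("  adhesion to monolayer    : t23 = %.0f min\n", x$t23))
  invisible(x)
}
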