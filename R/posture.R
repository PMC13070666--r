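#' Centre of pressure of one frame
#'
#' Pressure-weighted centroid of the loaded cells, in fractional 0-based
#' sensel coordinates. Cells at or below `floor_mmHg` are excluded so that
#' sensor noise on unloaded cells does not drag the centroid; the floor is
#' distinct from (and lower than) the contact-area threshold.
#'
#' @param frame An `n_rows x n_cols` pressure matrix in mmHg.
#' @param floor_mmHg Exclusion floor in mmHg (default 5).
#' @return Named numeric `c(cop_row =, cop_col =)`.
#' @export
compute_cop <- function(frame, floor_mmHg = 5) {
  keep <- frame > floor_mmHg
  if (!any(keep)) abort("no load: all cells at or below the COP floor")
  w <- ifelse(keep, frame, 0)
  tot <- sum(w)
  rows <- seq_len(nrow(frame)) - 1
  cols <- seq_len(ncol(frame)) - 1
  c(cop_row = sum(rowSums(w) * rows) / tot,
    cop_col = sum(colSums(w) * cols) / tot)
}

#' Contact area of one frame
#'
#' Area of all sensels whose pressure exceeds the threshold, in cm^2
#' (`count * pitch_cm^2`).
#'
#' @param frame Pressure matrix in mmHg.
#' @param geometry A [mat_geometry()] (supplies the pitch).
#' @param threshold_mmHg Contact threshold in mmHg (default 20).
#' @return Area in cm^2.
#' @export
compute_contact_area <- function(frame, geometry, threshold_mmHg = 20) {
  stopifnot(threshold_mmHg >= 0)
  sum(frame > threshold_mmHg) * sensel_area_cm2(geometry)
}

#' Per-frame COP and contact-area trace
#'
#' @param seq A [pressure_sequence()].
#' @param cop_floor_mmHg COP exclusion floor (default 5 mmHg).
#' @param contact_threshold_mmHg Contact-area threshold (default 20 mmHg).
#' @return A tibble with columns `t_s`, `cop_row`, `cop_col`,
#'   `contact_area_cm2`, one row per frame.
#' @export
cop_trace <- function(seq, cop_floor_mmHg = 5, contact_threshold_mmHg = 20) {
  g <- seq$geometry
  n <- n_frames(seq)
  rows <- rep(seq_len(g$n_rows) - 1, times = g$n_cols)
  cols <- rep(seq_len(g$n_cols) - 1, each = g$n_rows)
  cop_row <- cop_col <- area <- numeric(n)
  chunk <- 4000L   # bound peak memory on long recordings
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    v <- matrix(seq$frames[, , lo:hi], nrow = g$n_rows * g$n_cols)
    w <- v * (v > cop_floor_mmHg)
    tot <- colSums(w)
    if (any(tot <= 0)) {
      abort(sprintf("no load: frame %d has no cell above the COP floor",
                    lo + which(tot <= 0)[1] - 2L))
    }
    cop_row[lo:hi] <- colSums(w * rows) / tot
    cop_col[lo:hi] <- colSums(w * cols) / tot
    area[lo:hi] <- colSums(v > contact_threshold_mmHg) * sensel_area_cm2(g)
  }
  tibble::tibble(t_s = seq$timestamps, cop_row = cop_row, cop_col = cop_col,
                 contact_area_cm2 = area)
}

moving_average <- function(x, w) {
  # centred moving average with truncated (partial) windows at the edges;
  # direct convolution (not cumsum differences) so that runs of identical
  # values smooth to exactly identical values and their derivative is an
  # exact zero
  if (w <= 1) return(x)
  n <- length(x)
  half <- w %/% 2
  out <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  for (i in which(is.na(out))) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

central_diff <- function(x, dt = 1) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

robust_z <- function(x, scale_floor = 0) {
  m <- median(x)
  s <- mad(x)
  # a mostly-idle channel (derivative zero except at sparse events) has
  # MAD 0 but is not constant: fall back to the SD so events still score;
  # a channel whose variation sits at or below the numerical floor is
  # treated as constant and contributes nothing
  if (s == 0) s <- sd(x)
  if (is.na(s) || s <= scale_floor) return(rep(0, length(x)))
  (x - m) / s
}

#' Combined movement signal
#'
#' The detector's input: each of the three channels (COP row, COP column,
#' contact area) is smoothed with a centred moving average, differentiated
#' by central differences, robust z-scored (median/MAD over the whole
#' recording; a zero-MAD but non-constant channel falls back to the SD as
#' its scale, and a truly constant channel contributes 0), and the three
#' z-scored derivatives are combined per frame as their Euclidean norm. Large-scale
#' postural changes appear as pulses in this non-negative signal.
#'
#' @param seq A [pressure_sequence()].
#' @param smooth_window_s Moving-average window in seconds (default 11).
#' @param cop_floor_mmHg,contact_threshold_mmHg Passed to [cop_trace()].
#' @param prefilter_window_s Optional extra low-pass (moving-average window
#'   in seconds) applied to each channel before the standard pipeline; set
#'   it to the cycling period of an alternating support surface to suppress
#'   its periodic load redistribution. `NULL` (default) applies none.
#' @return An object of class `cpm_movement_signal`: a list with `data`
#'   (tibble `t_s`, `signal`) and the parameters used.
#' @export
movement_signal <- function(seq, smooth_window_s = 11,
                            cop_floor_mmHg = 5, contact_threshold_mmHg = 20,
                            prefilter_window_s = NULL) {
  n <- n_frames(seq)
  if (n < 3) abort("movement signal needs at least 3 frames")
  rate <- seq$geometry$sample_rate_hz
  w <- max(1L, round(smooth_window_s * rate))
  if (n < 2 * w) {
    abort(sprintf(
      "recording too short to analyse: %d frames < 2 x smoothing window (%d frames)",
      n, w))
  }
  tr <- cop_trace(seq, cop_floor_mmHg, contact_threshold_mmHg)
  dt <- 1 / rate
  z <- vapply(
    list(tr$cop_row, tr$cop_col, tr$contact_area_cm2),
    function(x) {
      if (!is.null(prefilter_window_s)) {
        x <- moving_average(x, max(1L, round(prefilter_window_s * rate)))
      }
      sm <- moving_average(x, w)
      # floor well above double rounding dust, far below any real movement
      robust_z(central_diff(sm, dt), scale_floor = 1e-9 * max(abs(sm), 1))
    },
    numeric(n)
  )
  structure(
    list(
      data = tibble::tibble(t_s = tr$t_s, signal = sqrt(rowSums(z^2))),
      params = list(smooth_window_s = smooth_window_s,
                    cop_floor_mmHg = cop_floor_mmHg,
                    contact_threshold_mmHg = contact_threshold_mmHg,
                    prefilter_window_s = prefilter_window_s,
                    sample_rate_hz = rate)
    ),
    class = "cpm_movement_signal"
  )
}

#' Detect postural changes
#'
#' Thresholds the combined movement signal at `median + k_mad * MAD`,
#' merges each contiguous supra-threshold run into one candidate event at
#' the run's peak (ties broken toward the earlier frame), and accepts
#' candidates greedily in descending amplitude (then ascending time)
#' subject to a minimum separation. A run shorter than `min_event_width_s`
#' is rejected as a spike: a genuine postural change, smeared by the
#' smoothing window, stays above threshold for several seconds. Events at
#' the very first or last frame are discarded: change times must lie
#' strictly inside the recording.
#'
#' @param sig A `cpm_movement_signal` from [movement_signal()].
#' @param k_mad Threshold multiplier (default 6).
#' @param min_separation_s Minimum time between accepted events (default 60 s).
#' @param min_event_width_s Minimum supra-threshold run length for a
#'   candidate event (default 3 s; debouncing).
#' @return Sorted numeric vector of change times in seconds (possibly
#'   empty: a single static posture).
#' @export
detect_posture_changes <- function(sig, k_mad = 6, min_separation_s = 60,
                                   min_event_width_s = 3) {
  s <- sig$data$signal
  t_s <- sig$data$t_s
  thr <- median(s) + k_mad * mad(s)
  above <- s > thr
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_run <- max(1L, round(min_event_width_s * sig$params$sample_rate_hz))
  runs <- which(r$values & r$lengths >= min_run)
  if (length(runs) == 0) return(numeric(0))
  cand_idx <- vapply(runs, function(i) {
    span <- starts[i]:ends[i]
    span[which.max(s[span])]
  }, integer(1))
  interior <- cand_idx > 1L & cand_idx < length(s)
  cand_idx <- cand_idx[interior]
  if (length(cand_idx) == 0) return(numeric(0))
  ord <- order(-s[cand_idx], t_s[cand_idx])
  accepted <- numeric(0)
  for (i in cand_idx[ord]) {
    if (all(abs(t_s[i] - accepted) >= min_separation_s)) {
      accepted <- c(accepted, t_s[i])
    }
  }
  sort(accepted)
}

#' Segment a recording into static postures
#'
#' Partitions the monitoring period `[0, T)` at the detected change times
#' into half-open segments `[0, c1), [c1, c2), ..., [ck, T)`. Segment
#' durations sum to `T` exactly.
#'
#' @param seq A [pressure_sequence()] (supplies `T = n_frames / rate`).
#' @param change_times_s Sorted change times strictly inside `(0, T)`.
#' @return An object of class `cpm_segmentation`: list with
#'   `change_times_s`, `segments` (tibble `segment`, `start_s`, `end_s`,
#'   `duration_s`) and `monitoring_s`.
#' @export
segment_postures <- function(seq, change_times_s = numeric(0)) {
  T_s <- if (inherits(seq, "pressure_sequence")) duration_s(seq) else as.numeric(seq)
  ct <- as.numeric(change_times_s)
  if (is.unsorted(ct, strictly = TRUE)) {
    abort("change times must be strictly increasing (no duplicates)")
  }
  if (any(ct <= 0 | ct >= T_s)) {
    abort("change times must lie strictly inside (0, T)")
  }
  bounds <- c(0, ct, T_s)
  segments <- tibble::tibble(
    segment = seq_len(length(bounds) - 1L),
    start_s = bounds[-length(bounds)],
    end_s = bounds[-1]
  )
  segments$duration_s <- segments$end_s - segments$start_s
  structure(
    list(change_times_s = ct, segments = segments, monitoring_s = T_s),
    class = "cpm_segmentation"
  )
}

#' @export
print.cpm_segmentation <- function(x, ...) {
  cat(sprintf("<cpm_segmentation> %d static posture(s) over %.2f h (%d change(s))\n",
              nrow(x$segments), x$monitoring_s / 3600, length(x$change_times_s)))
  print(x$segments, ...)
  invisible(x)
}

#' Movement features of a segmentation
#'
#' Summary mobility descriptors: posture count, monitoring hours, postural
#' changes per hour, intervals between consecutive changes, and the
#' fraction of the monitoring period spent in a static posture longer than
#' 2 h. By default the hourly frequency is the *posture count* divided by
#' monitoring hours (`frequency_basis = "postures"`), the definition that
#' reproduces the published per-patient extremes; set
#' `frequency_basis = "transitions"` to divide the change count instead.
#'
#' @param segres A `cpm_segmentation`.
#' @param frequency_basis `"postures"` (default) or `"transitions"`.
#' @param static_threshold_h Duration above which a posture counts as
#'   prolonged static time (default 2 h).
#' @return A one-row tibble: `n_postures`, `n_changes`, `monitoring_hours`,
#'   `frequency_per_hour`, `pct_time_static_gt_2h` (a fraction in \[0, 1\]),
#'   and `intervals_s` (list-column of gaps between change times).
#' @export
movement_features <- function(segres, frequency_basis = c("postures", "transitions"),
                              static_threshold_h = 2) {
  frequency_basis <- match.arg(frequency_basis)
  segs <- segres$segments
  hours <- segres$monitoring_s / 3600
  n_post <- nrow(segs)
  n_chg <- length(segres$change_times_s)
  numer <- if (frequency_basis == "postures") n_post else n_chg
  tibble::tibble(
    n_postures = n_post,
    n_changes = n_chg,
    monitoring_hours = hours,
    frequency_per_hour = numer / hours,
    pct_time_static_gt_2h =
      sum(segs$duration_s[segs$duration_s > static_threshold_h * 3600]) /
        segres$monitoring_s,
    intervals_s = list(diff(segres$change_times_s))
  )
}

#' Five-number summary with interpolated quartiles
#'
#' Median, quartiles (linear interpolation at positions `1 + (n - 1) q` on
#' the sorted values, i.e. R's default type-7 quantiles), IQR and range.
#'
#' @param values Non-empty numeric vector.
#' @return One-row tibble: `n`, `median`, `q1`, `q3`, `iqr`, `min`, `max`.
#' @export
summarize_lengths <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(is.na(values))) {
    abort("summarize_lengths needs a non-empty numeric vector without NAs")
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  tibble::tibble(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
                 iqr = q[3] - q[1], min = min(values), max = max(values))
}
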