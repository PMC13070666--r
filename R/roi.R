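#' Region-of-interest specification
#'
#' The buttock ROI is a fixed-size window of sensels anchored at the
#' per-posture COP. The default 30 x 20 window (30 sensels along the long
#' body axis, 20 across the width) spans 47.7 cm x 31.8 cm at 15.9 mm
#' pitch and covers the sacral/buttock area where most pressure injuries
#' occur. The window must contain at least 10 cells because the peak
#' pressure index averages the 10 highest pressures.
#'
#' @param len_sensels Extent along the long axis (columns), default 30.
#' @param wid_sensels Extent across the width (rows), default 20.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(len_sensels = 30L, wid_sensels = 20L) {
  len_sensels <- as.integer(len_sensels)
  wid_sensels <- as.integer(wid_sensels)
  if (len_sensels * wid_sensels < 10) {
    abort("ROI must contain at least 10 cells (PPI averages the top 10)")
  }
  structure(list(len_sensels = len_sensels, wid_sensels = wid_sensels),
            class = "roi_spec")
}

#' Physical extent of an ROI
#'
#' @param spec A [roi_spec()].
#' @param geometry A [mat_geometry()].
#' @return Named numeric `c(long_cm =, across_cm =)`.
#' @export
roi_extent_cm <- function(spec, geometry) {
  c(long_cm = spec$len_sensels * pitch_cm(geometry),
    across_cm = spec$wid_sensels * pitch_cm(geometry))
}

# window of extent e centred at c spans c - floor(e/2) ... c + ceil(e/2) - 1
place_axis <- function(centre, extent, n) {
  start <- centre - extent %/% 2
  clipped <- FALSE
  if (start < 0) { start <- 0L; clipped <- TRUE }
  if (start + extent > n) { start <- n - extent; clipped <- TRUE }
  if (start < 0) abort("ROI larger than the mat grid")
  list(start = as.integer(start), clipped = clipped)
}

place_roi_window <- function(centre_row, centre_col, spec, geometry) {
  r <- place_axis(centre_row, spec$wid_sensels, geometry$n_rows)
  c <- place_axis(centre_col, spec$len_sensels, geometry$n_cols)
  structure(
    list(row0 = r$start, col0 = c$start,
         n_rows = spec$wid_sensels, n_cols = spec$len_sensels,
         clipped = r$clipped || c$clipped),
    class = "roi_placement"
  )
}

#' Anchor the buttock ROI for one posture segment
#'
#' Centres the window on the segment's median COP (per axis, rounded to the
#' nearest sensel), then shifts it minimally to fit inside the grid
#' (setting `clipped`). One placement per segment, fixed for all its
#' frames, so the gradient and index signatures are computed over a stable
#' patch of the mat.
#'
#' @param seq A [pressure_sequence()].
#' @param segment One row of a `cpm_segmentation`'s `segments` tibble (or
#'   any list with `start_s` and `end_s`).
#' @param spec A [roi_spec()].
#' @param cop_floor_mmHg COP exclusion floor.
#' @return An object of class `roi_placement`: `row0`, `col0` (0-based
#'   top-left sensel), `n_rows`, `n_cols`, `clipped`.
#' @export
locate_roi <- function(seq, segment, spec = roi_spec(), cop_floor_mmHg = 5) {
  idx <- which(seq$timestamps >= segment$start_s & seq$timestamps < segment$end_s)
  if (length(idx) == 0) abort("segment contains no frames")
  cops <- vapply(idx, function(i) compute_cop(get_frame(seq, i), cop_floor_mmHg),
                 numeric(2))
  centre_row <- floor(median(cops[1, ]) + 0.5)   # round half up, deterministically
  centre_col <- floor(median(cops[2, ]) + 0.5)
  place_roi_window(centre_row, centre_col, spec, seq$geometry)
}

roi_values <- function(frame, placement) {
  frame[placement$row0 + seq_len(placement$n_rows),
        placement$col0 + seq_len(placement$n_cols), drop = FALSE]
}

#' Per-frame pressure signatures within the ROI
#'
#' `peak_frame()` is the maximum pressure in the window; `ppi_frame()` the
#' peak pressure index, i.e. the mean of the 10 highest pressures;
#' `ppg_frame()` the peak pressure gradient: the largest absolute pressure
#' difference between *diagonally* adjacent sensels (both diagonal
#' orientations), divided by their centre-to-centre distance
#' `sqrt(2) * pitch_cm`, in mmHg/cm.
#'
#' @param frame Pressure matrix in mmHg.
#' @param placement An `roi_placement` (from [locate_roi()]).
#' @param geometry A [mat_geometry()] (needed for the gradient's cm
#'   spacing).
#' @return A scalar: mmHg for peak and PPI, mmHg/cm for PPG.
#' @export
peak_frame <- function(frame, placement) {
  max(roi_values(frame, placement))
}

#' @rdname peak_frame
#' @param k Number of top pressures averaged by the index (default 10).
#' @export
ppi_frame <- function(frame, placement, k = 10L) {
  v <- roi_values(frame, placement)
  if (length(v) < k) abort(sprintf("ROI has %d cells; PPI needs %d", length(v), k))
  mean(sort(as.vector(v), decreasing = TRUE)[seq_len(k)])
}

#' @rdname peak_frame
#' @export
ppg_frame <- function(frame, placement, geometry) {
  w <- roi_values(frame, placement)
  nr <- nrow(w); nc <- ncol(w)
  if (nr < 2 || nc < 2) return(0)
  d1 <- abs(w[-nr, -nc] - w[-1, -1])   # down-right diagonal
  d2 <- abs(w[-1, -nc] - w[-nr, -1])   # up-right diagonal
  max(d1, d2) / (sqrt(2) * pitch_cm(geometry))
}

#' Per-posture signature descriptors
#'
#' Computes the per-frame PPG/PPI/peak series over a posture segment's
#' frames (ROI fixed at the given placement) and reduces each to its mean
#' and sample SD (n - 1 denominator), plus the posture duration in hours.
#'
#' @param seq A [pressure_sequence()].
#' @param segment One row of a segmentation's `segments` tibble.
#' @param placement An `roi_placement` for this segment.
#' @param spec A [roi_spec()] (supplies the PPI cell count).
#' @return One-row tibble: `duration_h`, `ppg_mean`, `ppg_sd`, `ppi_mean`,
#'   `ppi_sd`, `peak_mean`, `roi_row0`, `roi_col0`, `clipped`.
#' @export
posture_signature <- function(seq, segment, placement, spec = roi_spec()) {
  idx <- which(seq$timestamps >= segment$start_s & seq$timestamps < segment$end_s)
  if (length(idx) < 2) abort("posture signature needs at least 2 frames (sample SD)")
  g <- seq$geometry
  series <- vapply(idx, function(i) {
    f <- get_frame(seq, i)
    c(ppg_frame(f, placement, g), ppi_frame(f, placement), peak_frame(f, placement))
  }, numeric(3))
  tibble::tibble(
    duration_h = (segment$end_s - segment$start_s) / 3600,
    ppg_mean = mean(series[1, ]), ppg_sd = sd(series[1, ]),
    ppi_mean = mean(series[2, ]), ppi_sd = sd(series[2, ]),
    peak_mean = mean(series[3, ]),
    roi_row0 = placement$row0, roi_col0 = placement$col0,
    clipped = placement$clipped
  )
}

#' Signatures for every posture of a segmentation
#'
#' Anchors the ROI per segment ([locate_roi()]) and computes
#' [posture_signature()] for each, returning one tidy row per posture.
#'
#' @param seq A [pressure_sequence()].
#' @param segres A `cpm_segmentation`.
#' @param spec A [roi_spec()].
#' @param cop_floor_mmHg COP exclusion floor.
#' @return A tibble with `segment`, `start_s`, `end_s` and the
#'   [posture_signature()] columns.
#' @export
posture_signatures <- function(seq, segres, spec = roi_spec(),
                               cop_floor_mmHg = 5) {
  purrr::map_dfr(seq_len(nrow(segres$segments)), function(i) {
    seg <- segres$segments[i, ]
    placement <- locate_roi(seq, seg, spec, cop_floor_mmHg)
    dplyr::bind_cols(
      seg[, c("segment", "start_s", "end_s")],
      posture_signature(seq, seg, placement, spec)
    )
  })
}
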