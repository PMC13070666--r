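#' Tidy a segmentation into its posture table
#'
#' @param x A `cpm_segmentation`.
#' @param ... Unused.
#' @return The segments tibble (`segment`, `start_s`, `end_s`,
#'   `duration_s`).
#' @exportS3Method generics::tidy
tidy.cpm_segmentation <- function(x, ...) x$segments

#' @rdname tidy.cpm_segmentation
#' @return `glance()` returns the one-row [movement_features()] tibble
#'   (without the list-column of intervals).
#' @exportS3Method generics::glance
glance.cpm_segmentation <- function(x, ...) {
  f <- movement_features(x)
  f$intervals_s <- NULL
  f
}

#' Tidy a full session analysis
#'
#' @param x A `cpm_analysis`.
#' @param what Which table: per-posture `"signatures"` (default),
#'   `"segments"`, or `"exposure"`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.cpm_analysis <- function(x, what = c("signatures", "segments", "exposure"),
                              ...) {
  switch(match.arg(what),
    signatures = x$signatures,
    segments = x$segmentation$segments,
    exposure = x$exposure
  )
}

#' @rdname tidy.cpm_analysis
#' @return `glance()` returns one row of movement features plus the
#'   high-or-worse exposure fraction for each signature type.
#' @exportS3Method generics::glance
glance.cpm_analysis <- function(x, ...) {
  f <- x$features
  f$intervals_s <- NULL
  hi <- x$exposure |>
    dplyr::filter(.data$category >= "high") |>
    dplyr::group_by(.data$signature_type) |>
    dplyr::summarise(frac = sum(.data$fraction), .groups = "drop")
  f$frac_high_plus_ppg <- hi$frac[hi$signature_type == "ppg"]
  f$frac_high_plus_ppi <- hi$frac[hi$signature_type == "ppi"]
  f
}
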