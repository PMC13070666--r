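#' Sigmoid pressure-time injury thresholds
#'
#' Three ordered boundary curves in the (exposure duration, pressure) plane
#' separate low / moderate / high / very-high exposure. Each curve starts
#' near a signature-specific "starting pressure" at short exposures and
#' decays logistically to a long-time plateau:
#' `B_k(t) = F_k + (S_k - F_k) / (1 + exp(alpha (t - t0)))`,
#' with `S_k` the starting pressure, `F_k = floor_fraction * S_k` the
#' asymptote. Default starting pressures are 25/35/45 mmHg/cm for the peak
#' pressure gradient and 70/90/110 mmHg for the peak pressure index; the
#' decay shape (floor fraction 0.4, steepness 2 per hour, inflection at
#' 2 h) is a configurable package default, chosen so that tolerable
#' pressure roughly halves between brief and sustained (several-hour)
#' loading.
#'
#' @param signature_type `"ppg"` or `"ppi"`.
#' @param p_start Strictly increasing triple of starting pressures;
#'   defaults depend on `signature_type`.
#' @param floor_fraction Long-time asymptote as a fraction of the starting
#'   pressure, in `[0, 1)`.
#' @param alpha_per_h Logistic steepness in 1/h.
#' @param t0_h Inflection time in hours.
#' @return An object of class `sigmoid_thresholds`.
#' @export
sigmoid_thresholds <- function(signature_type = c("ppg", "ppi"),
                               p_start = NULL, floor_fraction = 0.4,
                               alpha_per_h = 2, t0_h = 2) {
  signature_type <- match.arg(signature_type)
  if (is.null(p_start)) {
    p_start <- switch(signature_type, ppg = c(25, 35, 45), ppi = c(70, 90, 110))
  }
  stopifnot(length(p_start) == 3, all(diff(p_start) > 0),
            floor_fraction >= 0, floor_fraction < 1,
            alpha_per_h > 0, t0_h >= 0)
  structure(
    list(signature_type = signature_type, p_start = p_start,
         floor_fraction = floor_fraction, alpha_per_h = alpha_per_h,
         t0_h = t0_h),
    class = "sigmoid_thresholds"
  )
}

#' @export
print.sigmoid_thresholds <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_thresholds> %s: start %s, floor %.0f%%, alpha %g /h, t0 %g h\n",
    x$signature_type, paste(x$p_start, collapse = "/"),
    100 * x$floor_fraction, x$alpha_per_h, x$t0_h))
  invisible(x)
}

#' Exposure category levels
#' @return The four ordered levels, low < moderate < high < very_high.
#' @export
exposure_levels <- function() c("low", "moderate", "high", "very_high")

#' Boundary curve value
#'
#' @param t_h Exposure duration(s) in hours (vectorized).
#' @param k Curve index 1..3 (1 separates low from moderate).
#' @param thr A [sigmoid_thresholds()].
#' @return Boundary pressure(s) at `t_h`, strictly decreasing in `t_h`.
#' @export
exposure_boundary <- function(t_h, k, thr) {
  stopifnot(k %in% 1:3, all(t_h >= 0))
  S <- thr$p_start[k]
  F_ <- thr$floor_fraction * S
  F_ + (S - F_) / (1 + exp(thr$alpha_per_h * (t_h - thr$t0_h)))
}

#' Time at which a magnitude crosses a boundary curve
#'
#' Inverse of [exposure_boundary()] in `t`: the exposure duration after
#' which a constant signature magnitude exceeds curve `k`. Returns 0 when
#' the magnitude already exceeds the curve at t = 0, and `NA` when the
#' magnitude never exceeds it (at or below the plateau).
#'
#' @param magnitude Signature magnitude (vectorized).
#' @inheritParams exposure_boundary
#' @return Crossing time(s) in hours, 0, or `NA`.
#' @export
crossing_time <- function(magnitude, k, thr) {
  n <- max(length(magnitude), length(k))
  magnitude <- rep_len(magnitude, n)
  k <- rep_len(as.integer(k), n)
  S <- thr$p_start[k]
  F_ <- thr$floor_fraction * S
  b0 <- exposure_boundary(0, k, thr)
  out <- rep(NA_real_, n)
  out[magnitude >= b0] <- 0
  mid <- magnitude > F_ & magnitude < b0
  out[mid] <- thr$t0_h +
    log((S[mid] - F_[mid]) / (magnitude[mid] - F_[mid]) - 1) / thr$alpha_per_h
  out
}

#' Categorise one posture's pressure-time exposure
#'
#' A posture plotted at its (duration, mean signature magnitude) point is
#' assigned the category equal to the number of boundary curves it lies
#' above: 0 curves exceeded = low, 1 = moderate, 2 = high, 3 = very_high.
#' Vectorized over postures.
#'
#' @param duration_h Posture duration(s) in hours, > 0.
#' @param magnitude Mean signature magnitude(s), >= 0.
#' @param thr A [sigmoid_thresholds()].
#' @return Ordered factor with levels low < moderate < high < very_high.
#' @export
categorize_exposure <- function(duration_h, magnitude, thr) {
  stopifnot(all(duration_h > 0), all(magnitude >= 0))
  n_above <- Reduce(`+`, lapply(
    1:3, function(k) as.integer(magnitude > exposure_boundary(duration_h, k, thr))
  ))
  factor(exposure_levels()[n_above + 1], levels = exposure_levels(),
         ordered = TRUE)
}

#' Time-in-category exposure summary
#'
#' Accrues monitoring time to the four exposure categories for both
#' signature types and normalises by the total monitoring period, so the
#' fractions sum to 1.
#'
#' In `"posture"` mode (default, mirroring one marker per posture against
#' the curves) each posture's whole duration accrues to the category of its
#' (duration, mean magnitude) point. In `"resolved"` mode each posture's
#' own timeline `[0, duration)` is split at the crossing times of its mean
#' magnitude with the three curves, and every sub-interval accrues to the
#' category holding there — a posture can then start low and drift into
#' higher categories as the boundaries decay.
#'
#' @param signatures A tibble of per-posture signatures
#'   ([posture_signatures()] output): needs `duration_h`, `ppg_mean`,
#'   `ppi_mean`.
#' @param thr_ppg,thr_ppi [sigmoid_thresholds()] for each signature type.
#' @param mode `"posture"` or `"resolved"`.
#' @return A tibble with one row per signature type x category:
#'   `signature_type`, `category` (ordered factor), `hours`, `fraction`;
#'   fractions sum to 1 within each signature type.
#' @export
exposure_summary <- function(signatures,
                             thr_ppg = sigmoid_thresholds("ppg"),
                             thr_ppi = sigmoid_thresholds("ppi"),
                             mode = c("posture", "resolved")) {
  mode <- match.arg(mode)
  if (nrow(signatures) == 0) abort("exposure summary needs at least one posture")
  total_h <- sum(signatures$duration_h)
  one <- function(magnitude, thr) {
    hours <- numeric(4)
    if (mode == "posture") {
      cat <- categorize_exposure(signatures$duration_h, magnitude, thr)
      for (i in 1:4) hours[i] <- sum(signatures$duration_h[as.integer(cat) == i])
    } else {
      for (p in seq_len(nrow(signatures))) {
        d <- signatures$duration_h[p]
        tc <- crossing_time(rep(magnitude[p], 3), 1:3, thr)
        # B1 < B2 < B3, so crossings come in increasing order; NA = never
        tc[is.na(tc)] <- Inf
        cuts <- pmin(pmax(sort(tc), 0), d)
        edges <- c(0, cuts, d)
        hours <- hours + diff(edges)
      }
    }
    tibble::tibble(
      category = factor(exposure_levels(), levels = exposure_levels(),
                        ordered = TRUE),
      hours = hours,
      fraction = hours / total_h
    )
  }
  dplyr::bind_rows(
    dplyr::mutate(one(signatures$ppg_mean, thr_ppg), signature_type = "ppg",
                  .before = 1),
    dplyr::mutate(one(signatures$ppi_mean, thr_ppi), signature_type = "ppi",
                  .before = 1)
  )
}
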