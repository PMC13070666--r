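#' Analyse one monitoring session end to end
#'
#' Runs the full pipeline on a recording: COP/contact-area trace, combined
#' derivative movement signal, postural-change detection, static-posture
#' segmentation, movement features, per-posture buttock-ROI signatures, and
#' pressure-time exposure summaries for both signature types.
#'
#' @param seq A [pressure_sequence()].
#' @param smooth_window_s Moving-average window for the movement signal.
#' @param k_mad Detection threshold multiplier (median + k * MAD).
#' @param min_separation_s Minimum separation between detected changes.
#' @param min_event_width_s Minimum supra-threshold run length (debouncing).
#' @param roi [roi_spec()] for the buttock window.
#' @param thr_ppg,thr_ppi [sigmoid_thresholds()] for the two signatures.
#' @param exposure_mode `"posture"` or `"resolved"` (see
#'   [exposure_summary()]).
#' @param cop_floor_mmHg,contact_threshold_mmHg Channel thresholds.
#' @param frequency_basis Passed to [movement_features()].
#' @return An object of class `cpm_analysis`: a list with `trace`,
#'   `signal`, `segmentation`, `features`, `signatures`, `exposure`, and
#'   `params` (every parameter value used, for provenance).
#' @export
analyze_session <- function(seq,
                            smooth_window_s = 11, k_mad = 6,
                            min_separation_s = 60, min_event_width_s = 3,
                            roi = roi_spec(),
                            thr_ppg = sigmoid_thresholds("ppg"),
                            thr_ppi = sigmoid_thresholds("ppi"),
                            exposure_mode = c("posture", "resolved"),
                            cop_floor_mmHg = 5, contact_threshold_mmHg = 20,
                            frequency_basis = c("postures", "transitions")) {
  exposure_mode <- match.arg(exposure_mode)
  frequency_basis <- match.arg(frequency_basis)
  sig <- movement_signal(seq, smooth_window_s, cop_floor_mmHg,
                         contact_threshold_mmHg)
  changes <- detect_posture_changes(sig, k_mad, min_separation_s,
                                    min_event_width_s)
  segres <- segment_postures(seq, changes)
  feats <- movement_features(segres, frequency_basis)
  sigs <- posture_signatures(seq, segres, roi, cop_floor_mmHg)
  expo <- exposure_summary(sigs, thr_ppg, thr_ppi, exposure_mode)
  structure(
    list(
      trace = sig, signal = sig$data, segmentation = segres,
      features = feats, signatures = sigs, exposure = expo,
      params = list(
        smooth_window_s = smooth_window_s, k_mad = k_mad,
        min_separation_s = min_separation_s,
        min_event_width_s = min_event_width_s,
        roi_len_sensels = roi$len_sensels, roi_wid_sensels = roi$wid_sensels,
        thr_ppg = unclass(thr_ppg), thr_ppi = unclass(thr_ppi),
        exposure_mode = exposure_mode,
        cop_floor_mmHg = cop_floor_mmHg,
        contact_threshold_mmHg = contact_threshold_mmHg,
        frequency_basis = frequency_basis
      )
    ),
    class = "cpm_analysis"
  )
}

#' @export
print.cpm_analysis <- function(x, ...) {
  f <- x$features
  cat(sprintf(
    "<cpm_analysis> %.2f h monitored, %d posture(s), %.2f postures/h, %.0f%% time static > 2 h\n",
    f$monitoring_hours, f$n_postures, f$frequency_per_hour,
    100 * f$pct_time_static_gt_2h))
  invisible(x)
}

#' Write analysis outputs to a directory
#'
#' Emits the standard file set for one analysed session: `change_times.csv`
#' (`change_time_s`), `segments.csv` (`start_s,end_s,duration_s`),
#' `features.json`, `signatures.csv` (per-posture ROI signatures),
#' `exposure_ppg.csv` / `exposure_ppi.csv`
#' (`category,fraction_of_period,hours`), and `params.json` logging every
#' parameter value used.
#'
#' @param analysis A `cpm_analysis` from [analyze_session()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    tibble::tibble(change_time_s = analysis$segmentation$change_times_s),
    file.path(dir, "change_times.csv"))
  readr::write_csv(
    analysis$segmentation$segments[, c("start_s", "end_s", "duration_s")],
    file.path(dir, "segments.csv"))
  feats <- analysis$features
  feats$intervals_s <- NULL
  jsonlite::write_json(as.list(feats), file.path(dir, "features.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(analysis$signatures, file.path(dir, "signatures.csv"))
  for (st in c("ppg", "ppi")) {
    analysis$exposure |>
      dplyr::filter(.data$signature_type == st) |>
      dplyr::transmute(category = as.character(.data$category),
                       fraction_of_period = .data$fraction,
                       hours = .data$hours) |>
      readr::write_csv(file.path(dir, paste0("exposure_", st, ".csv")))
  }
  jsonlite::write_json(analysis$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
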