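.fixture_md5 <- c(
  table1 = "b3695a1249cbba3693a19bd04cb52fdb",
  table2 = "5bef0f3e80f22d8baf7bc463cddea1bf"
)

#' Load the packaged cohort fixtures
#'
#' The package ships the published 17-patient community cohort tables as
#' plain-text fixtures: `table1` (demographics, frailty, pressure-injury
#' category and support surface pre/post intervention) and `table2`
#' (per-patient monitoring length in hours and static-posture count, one
#' row per patient x phase). Files are checksummed at build time; any edit
#' fails loudly.
#'
#' @param name `"table1"` or `"table2"`.
#' @return A tibble (17 rows for table1; 34 rows, 17 per phase, for
#'   table2).
#' @export
load_fixture <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("promise_", name, ".csv"),
                      package = "presmat", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (sum != .fixture_md5[[name]]) {
    abort(sprintf("fixture integrity error: %s has md5 %s, expected %s",
                  basename(path), sum, .fixture_md5[[name]]))
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (name == "table1") {
    stopifnot(nrow(df) == 17, all(df$bmi > 0), all(df$frailty %in% 1:9))
  } else {
    stopifnot(nrow(df) == 34, all(df$monitoring_hours > 0),
              all(df$n_postures >= 1),
              all(df$phase %in% c("pre", "post")))
  }
  df
}

#' Tabulate pressure-injury categories
#'
#' Frequency table of the cohort's pressure-injury status in one phase.
#'
#' @param table1 The demographics tibble ([load_fixture("table1")] or any
#'   data frame with `pu_cat_pre` / `pu_cat_post` columns).
#' @param phase `"pre"` or `"post"`.
#' @return A tibble `pu_category`, `n`, sorted by decreasing count.
#' @export
tabulate_pu <- function(table1, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  col <- paste0("pu_cat_", phase)
  table1 |>
    dplyr::count(pu_category = .data[[col]], sort = TRUE)
}

#' Cohort BMI summary
#'
#' @param table1 Demographics tibble with a `bmi` column (kg/m^2).
#' @return One-row tibble: `mean`, `mean_rounded` (nearest integer, the
#'   report display convention), `min`, `max`.
#' @export
bmi_summary <- function(table1) {
  tibble::tibble(
    mean = mean(table1$bmi),
    mean_rounded = round(mean(table1$bmi)),
    min = min(table1$bmi),
    max = max(table1$bmi)
  )
}

#' Per-phase movement-feature report
#'
#' Summarises monitoring length, posture count and hourly posture frequency
#' per phase: median, interpolated quartiles/IQR ([summarize_lengths()]'s
#' convention) and range. The per-patient frequency is
#' `n_postures / monitoring_hours` rounded to 2 decimal places before the
#' extremes are taken, matching the printed precision of the source tables.
#'
#' @param table2 Tidy movement tibble (`patient_no`, `phase`,
#'   `monitoring_hours`, `n_postures`), e.g. [load_fixture("table2")] or
#'   features computed from recordings.
#' @return A tibble with one row per phase x metric
#'   (`monitoring_hours`, `n_postures`, `frequency_per_hour`) and columns
#'   `n`, `median`, `q1`, `q3`, `iqr`, `min`, `max`.
#' @export
movement_report <- function(table2) {
  table2 |>
    dplyr::mutate(frequency_per_hour = round(.data$n_postures / .data$monitoring_hours, 2)) |>
    tidyr::pivot_longer(c("monitoring_hours", "n_postures", "frequency_per_hour"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$phase, .data$metric) |>
    dplyr::reframe(summarize_lengths(.data$value)) |>
    dplyr::arrange(dplyr::desc(.data$phase), .data$metric)
}

#' Pre/post comparison report
#'
#' Joins per-patient results from the two phases and reports side-by-side
#' values and deltas (post minus pre) for every shared numeric column, plus
#' a pooled mean row per measure. Patients present in only one phase are
#' kept, with `NA` gaps flagged.
#'
#' @param pre,post Tibbles of per-patient results (one row per patient)
#'   sharing `id_col` and at least one numeric column.
#' @param id_col Name of the patient identifier column (default
#'   `"patient_no"`).
#' @return A tibble in long form: `patient_no` (or `"pooled_mean"`),
#'   `measure`, `pre`, `post`, `delta`, `complete`.
#' @export
compare_pre_post <- function(pre, post, id_col = "patient_no") {
  num_cols <- intersect(
    names(pre)[vapply(pre, is.numeric, logical(1))],
    names(post)[vapply(post, is.numeric, logical(1))]
  )
  num_cols <- setdiff(num_cols, id_col)
  if (length(num_cols) == 0) abort("no shared numeric columns to compare")
  long <- function(df, phase) {
    df |>
      dplyr::select(dplyr::all_of(c(id_col, num_cols))) |>
      tidyr::pivot_longer(dplyr::all_of(num_cols), names_to = "measure",
                          values_to = phase) |>
      dplyr::mutate(!!id_col := as.character(.data[[id_col]]))
  }
  out <- dplyr::full_join(long(pre, "pre"), long(post, "post"),
                          by = c(id_col, "measure")) |>
    dplyr::mutate(delta = .data$post - .data$pre,
                  complete = !is.na(.data$pre) & !is.na(.data$post))
  pooled <- out |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(pre = mean(.data$pre, na.rm = TRUE),
                     post = mean(.data$post, na.rm = TRUE),
                     delta = .data$post - .data$pre,
                     complete = all(.data$complete), .groups = "drop") |>
    dplyr::mutate(!!id_col := "pooled_mean")
  dplyr::bind_rows(out, pooled) |>
    dplyr::relocate(dplyr::all_of(id_col), "measure")
}
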