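test_that("boundary curves have the stated anchors, ordering and monotonicity", {
  thr <- sigmoid_thresholds("ppi")
  expect_equal(thr$p_start, c(70, 90, 110))
  expect_equal(sigmoid_thresholds("ppg")$p_start, c(25, 35, 45))

  # inflection midpoint and long-time plateau
  expect_equal(exposure_boundary(2, 3, thr), (110 + 44) / 2)  # 77.0 mmHg
  expect_equal(exposure_boundary(1e6, 3, thr), 44)
  expect_equal(exposure_boundary(1e6, 1, thr), 28)

  # ordering B1 < B2 < B3 over a dense grid; strict decrease over the range
  # where the decay is numerically resolvable (it saturates at the plateau)
  tt <- seq(0, 24, by = 0.05)
  b <- vapply(1:3, function(k) exposure_boundary(tt, k, thr), numeric(length(tt)))
  expect_true(all(b[, 1] < b[, 2]) && all(b[, 2] < b[, 3]))
  expect_true(all(diff(b[, 1]) <= 0) && all(diff(b[, 3]) <= 0))
  short <- tt <= 8
  expect_true(all(diff(b[short, 1]) < 0) && all(diff(b[short, 3]) < 0))

  expect_error(sigmoid_thresholds("ppi", p_start = c(90, 70, 110)))
})

test_that("categorisation counts exceeded curves and is monotone", {
  thr <- sigmoid_thresholds("ppi")
  expect_equal(as.character(categorize_exposure(5, 0, thr)), "low")
  expect_equal(as.character(categorize_exposure(0.01, 200, thr)), "very_high")

  # monotone in magnitude at fixed duration and in duration at fixed magnitude
  mags <- seq(0, 150, by = 1)
  cat_m <- categorize_exposure(rep(3, length(mags)), mags, thr)
  expect_true(all(diff(as.integer(cat_m)) >= 0))
  durs <- seq(0.1, 24, by = 0.1)
  cat_d <- categorize_exposure(durs, rep(80, length(durs)), thr)
  expect_true(all(diff(as.integer(cat_d)) >= 0))
})

test_that("crossing_time inverts the boundary", {
  thr <- sigmoid_thresholds("ppg")
  for (k in 1:3) {
    S <- thr$p_start[k]; F_ <- 0.4 * S
    expect_equal(crossing_time((S + F_) / 2, k, thr), thr$t0_h)
    expect_true(is.na(crossing_time(F_, k, thr)))
    expect_equal(crossing_time(exposure_boundary(0, k, thr) + 1, k, thr), 0)
    withr::local_seed(k)
    m <- runif(100, F_ + 1e-6, exposure_boundary(0, k, thr) - 1e-6)
    t_star <- crossing_time(m, k, thr)
    expect_equal(exposure_boundary(t_star, k, thr), m, tolerance = 1e-9)
  }
})

test_that("posture-mode summary accrues whole postures and conserves time", {
  thr_ppg <- sigmoid_thresholds("ppg")
  thr_ppi <- sigmoid_thresholds("ppi")
  sigs <- tibble::tibble(duration_h = c(2, 2),
                         ppg_mean = c(1, 200), ppi_mean = c(1, 500))
  es <- exposure_summary(sigs, thr_ppg, thr_ppi, mode = "posture")
  for (st in c("ppg", "ppi")) {
    e <- dplyr::filter(es, signature_type == st)
    expect_equal(e$fraction[e$category == "low"], 0.5)
    expect_equal(e$fraction[e$category == "very_high"], 0.5)
    expect_equal(sum(e$fraction), 1)
  }

  # magnitude below all curves throughout -> low fraction 1
  lone <- tibble::tibble(duration_h = 7, ppg_mean = 0.1, ppi_mean = 0.1)
  e1 <- exposure_summary(lone, mode = "posture")
  expect_equal(e1$fraction[e1$category == "low"], c(1, 1))
  expect_error(exposure_summary(lone[0, ]), "at least one")
})

test_that("resolved mode matches a dense per-second categorisation scan", {
  thr_ppg <- sigmoid_thresholds("ppg")
  thr_ppi <- sigmoid_thresholds("ppi")
  withr::local_seed(9)
  sigs <- tibble::tibble(
    duration_h = runif(6, 0.5, 8),
    ppg_mean = runif(6, 5, 60),
    ppi_mean = runif(6, 30, 140)
  )
  # include the worked case: one 6-h posture at PPI 77
  sigs <- dplyr::bind_rows(sigs, tibble::tibble(duration_h = 6, ppg_mean = 10,
                                                ppi_mean = 77))
  es <- exposure_summary(sigs, thr_ppg, thr_ppi, mode = "resolved")

  dense_scan <- function(magnitudes, thr) {
    hours <- numeric(4)
    for (p in seq_len(nrow(sigs))) {
      tt <- seq(0, sigs$duration_h[p], by = 1 / 3600)   # 1-s steps
      tt <- tt[-length(tt)]
      cat <- categorize_exposure(tt + 1e-12, rep(magnitudes[p], length(tt)), thr)
      for (i in 1:4) hours[i] <- hours[i] + sum(as.integer(cat) == i) / 3600
    }
    hours / sum(sigs$duration_h)
  }
  for (st in c("ppg", "ppi")) {
    thr <- if (st == "ppg") thr_ppg else thr_ppi
    mags <- if (st == "ppg") sigs$ppg_mean else sigs$ppi_mean
    got <- dplyr::filter(es, signature_type == st)$fraction
    expect_equal(got, dense_scan(mags, thr), tolerance = 1e-3)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})
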