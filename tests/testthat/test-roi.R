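test_that("ROI geometry and placement conventions", {
  g <- geometry_profile()
  spec <- roi_spec()
  expect_equal(unname(roi_extent_cm(spec, g)), c(47.7, 31.8))
  expect_gte(spec$len_sensels * spec$wid_sensels, 10)
  expect_error(roi_spec(3, 3), "at least 10")

  # centred placement: extent e spans centre - floor(e/2) ... centre + ceil(e/2) - 1
  s <- constant_sequence(20, v = 50, geometry = g)
  s$frames[24, 59, ] <- 500   # drag COP to (23.x, 58.x) is not needed; use direct window
  pl <- presmat:::place_roi_window(24, 59, spec, g)
  expect_equal(pl$row0, 24 - 10)
  expect_equal(pl$col0, 59 - 15)
  expect_false(pl$clipped)

  # COP 3 sensels from the edge: shifted flush, flagged clipped
  pl2 <- presmat:::place_roi_window(3, 59, spec, g)
  expect_true(pl2$clipped)
  expect_equal(pl2$row0, 0)
  expect_error(presmat:::place_roi_window(10, 10, roi_spec(200, 20), g),
               "larger than the mat")
})

test_that("locate_roi centres on the segment's median COP and captures the
           simulated buttock site", {
  for (seed in 1:20) {
    cfg <- recovery_config(seed, durations = c(90, 60, 60, 60, 60))
    sim <- simulate_session(cfg)
    seg <- list(start_s = 0, end_s = 90)
    pl <- locate_roi(sim$sequence, seg)
    truth <- sim$truth$postures[1, ]
    expect_true(truth$buttock_row >= pl$row0 &&
                truth$buttock_row < pl$row0 + pl$n_rows)
    expect_true(truth$buttock_col >= pl$col0 &&
                truth$buttock_col < pl$col0 + pl$n_cols)
  }
})

test_that("PPI and PPG match brute-force oracles on random ROIs", {
  withr::local_seed(1)
  g <- mat_geometry(40, 40, 15.9)
  for (i in 1:1000) {
    nr <- sample(2:20, 1)
    nc <- sample(2:30, 1)
    if (nr * nc < 10) next
    m <- matrix(runif(nr * nc, 0, 200), nr, nc)
    frame <- matrix(0, 40, 40)
    frame[1:nr, 1:nc] <- m
    pl <- structure(list(row0 = 0L, col0 = 0L, n_rows = nr, n_cols = nc,
                         clipped = FALSE), class = "roi_placement")
    expect_identical(ppi_frame(frame, pl), oracle_ppi(m))
    expect_identical(ppg_frame(frame, pl, g), oracle_ppg(m, 1.59))
    expect_identical(peak_frame(frame, pl), max(m))
  }
})

test_that("PPG hand values: stripes give 44.47 mmHg/cm, checkerboards zero", {
  g <- mat_geometry(10, 10, 15.9)
  pl <- structure(list(row0 = 0L, col0 = 0L, n_rows = 10, n_cols = 10,
                       clipped = FALSE), class = "roi_placement")
  stripes <- matrix(rep(c(0, 100), each = 10, length.out = 100), 10, 10)
  expect_equal(ppg_frame(stripes, pl, g), 100 / (sqrt(2) * 1.59),
               tolerance = 1e-12)
  expect_equal(round(ppg_frame(stripes, pl, g), 2), 44.47)

  cells <- outer(1:10, 1:10, function(r, c) 100 * ((r + c) %% 2))
  expect_equal(ppg_frame(cells, pl, g), 0)   # diagonal neighbours share parity
  expect_equal(ppg_frame(matrix(50, 10, 10), pl, g), 0)
})

test_that("signatures obey ordering and scale equivariance", {
  withr::local_seed(2)
  g <- mat_geometry(30, 40, 15.9)
  pl <- structure(list(row0 = 4L, col0 = 6L, n_rows = 20, n_cols = 30,
                       clipped = FALSE), class = "roi_placement")
  for (i in 1:50) {
    f <- matrix(rexp(30 * 40, 1 / 40), 30, 40)
    roi_mean <- mean(f[5:24, 7:36])
    peak <- peak_frame(f, pl); ppi <- ppi_frame(f, pl)
    expect_gte(peak, ppi)
    expect_gte(ppi, roi_mean)
    c_ <- runif(1, 0.1, 5)
    expect_equal(peak_frame(f * c_, pl), c_ * peak)
    expect_equal(ppi_frame(f * c_, pl), c_ * ppi, tolerance = 1e-12)
    expect_equal(ppg_frame(f * c_, pl, g), c_ * ppg_frame(f, pl, g),
                 tolerance = 1e-12)
  }
})

test_that("posture signatures reduce per-frame series to mean and sample SD", {
  g <- mat_geometry(10, 12, 15.9)
  # two frames engineered to PPI 80 and 100: ten cells at v, rest 0
  f <- function(v) { m <- matrix(0, 10, 12); m[1, 1:10] <- v; m }
  s <- pressure_sequence(array(c(f(80), f(100)), dim = c(10, 12, 2)),
                         geometry = g)
  pl <- structure(list(row0 = 0L, col0 = 0L, n_rows = 10, n_cols = 12,
                       clipped = FALSE), class = "roi_placement")
  sig <- posture_signature(s, list(start_s = 0, end_s = 2), pl,
                           roi_spec(12, 10))
  expect_equal(sig$ppi_mean, 90)
  expect_equal(sig$ppi_sd, sd(c(80, 100)))  # 14.142...
  expect_equal(sig$duration_h, 2 / 3600)

  # constant frames: sd 0, mean = single-frame value
  s2 <- constant_sequence(5, v = 50, geometry = g)
  sig2 <- posture_signature(s2, list(start_s = 0, end_s = 5), pl, roi_spec(12, 10))
  expect_equal(sig2$ppi_sd, 0)
  expect_equal(sig2$ppi_mean, 50)
  expect_equal(sig2$ppg_mean, 0)

  expect_error(posture_signature(s2, list(start_s = 0, end_s = 1), pl),
               "at least 2 frames")
})
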