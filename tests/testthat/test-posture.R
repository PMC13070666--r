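test_that("COP is the pressure-weighted centroid above the floor", {
  # uniform positive frame: geometric centre
  f <- matrix(30, 21, 41)
  expect_equal(unname(compute_cop(f)), c(10, 20))

  # single loaded cell (10, 20) 0-based
  f <- matrix(0, 48, 118)
  f[11, 21] <- 50
  expect_equal(unname(compute_cop(f)), c(10, 20))

  # hand-computed weighted mean: cells (0,0)=30, (0,2)=60, floor 5
  f <- matrix(0, 1, 3)
  f[1, 1] <- 30; f[1, 3] <- 60
  expect_equal(unname(compute_cop(f, floor_mmHg = 5)),
               c(0, (0 * 30 + 2 * 60) / 90))

  expect_error(compute_cop(matrix(1, 4, 4), floor_mmHg = 5), "no load")
})

test_that("COP is translation-equivariant on noise-free templates", {
  g <- geometry_profile()
  # interior placements: a centred blob whose tails stay on the mat
  tpl <- posture_template("custom", loading_site(24, 60, 4, 5, 100, buttock = TRUE))
  cop0 <- compute_cop(render_template(tpl, g))
  for (shift in list(c(3, 0), c(0, 7), c(-4, 12))) {
    cop1 <- compute_cop(render_template(tpl, g, offset = shift))
    expect_equal(unname(cop1 - cop0), shift, tolerance = 1e-6)
  }
  # the full-body supine template spans nearly the whole mat: small shifts
  tpl2 <- default_template("supine")
  cop0 <- compute_cop(render_template(tpl2, g))
  cop1 <- compute_cop(render_template(tpl2, g, offset = c(2, 5)))
  expect_equal(unname(cop1 - cop0), c(2, 5), tolerance = 1e-6)
})

test_that("contact area counts cells above threshold times cell area", {
  g <- mat_geometry(10, 10, 15.9)
  expect_equal(compute_contact_area(matrix(10, 10, 10), g), 0)
  f <- matrix(0, 10, 10)
  f[1, 1:5] <- 50
  expect_equal(compute_contact_area(f, g), 5 * 1.59^2)  # 12.6405 cm2
  # monotone in pressure
  expect_gte(compute_contact_area(f * 2, g), compute_contact_area(f, g))
})

test_that("movement signal is zero for a static posture and pulses at a jump", {
  s <- constant_sequence(100, v = 50, geometry = tiny_geometry(4, 4))
  sig <- movement_signal(s)
  expect_true(all(sig$data$signal == 0))

  s2 <- jump_sequence(n = 200, dc = 10)
  sig2 <- movement_signal(s2)
  peak_t <- sig2$data$t_s[which.max(sig2$data$signal)]
  expect_lte(abs(peak_t - 100), 11 / 2 + 1)  # within half the smoothing window

  expect_true(all(sig2$data$signal >= 0))
  expect_gt(max(sig2$data$signal), 6 * mad(sig2$data$signal) + median(sig2$data$signal))
})

test_that("short recordings are rejected rather than silently segmented", {
  s <- constant_sequence(15, geometry = tiny_geometry())
  expect_error(movement_signal(s, smooth_window_s = 11), "too short")
})

test_that("detector merges close events and reports run peaks", {
  s <- constant_sequence(400, v = 50, geometry = tiny_geometry(4, 4))
  sig <- movement_signal(s)
  expect_length(detect_posture_changes(sig), 0)

  # two true jumps 30 s apart with min_separation 60 -> one event
  g <- geometry_profile()
  tpl <- posture_template("custom", loading_site(24, 50, 4, 5, 100, buttock = TRUE))
  arr <- array(0, dim = c(g$n_rows, g$n_cols, 400))
  arr[, , 1:200] <- render_template(tpl, g)
  arr[, , 201:230] <- render_template(tpl, g, offset = c(0, 8))
  arr[, , 231:400] <- render_template(tpl, g, offset = c(0, 16))
  s2 <- pressure_sequence(arr, geometry = g)
  ev <- detect_posture_changes(movement_signal(s2), min_separation_s = 60)
  expect_length(ev, 1)
  ev2 <- detect_posture_changes(movement_signal(s2), min_separation_s = 20)
  expect_length(ev2, 2)
})

test_that("segmentation partitions [0, T) exactly", {
  # no changes, 16 h: one 16-h segment
  seg <- segment_postures(57600, numeric(0))
  expect_equal(nrow(seg$segments), 1)
  expect_equal(seg$segments$duration_s, 57600)

  seg2 <- segment_postures(10800, c(3600, 7200))
  expect_equal(seg2$segments$duration_s, c(3600, 3600, 3600))
  expect_equal(sum(seg2$segments$duration_s), 10800)

  # property: k change times -> k + 1 segments, durations sum to T exactly
  withr::local_seed(42)
  for (i in 1:25) {
    T_s <- runif(1, 1000, 100000)
    k <- sample(0:12, 1)
    ct <- sort(runif(k, 1, T_s - 1))
    sg <- segment_postures(T_s, ct)
    expect_equal(nrow(sg$segments), k + 1)
    expect_equal(sum(sg$segments$duration_s), T_s)
    # consecutive bounds coincide exactly: the partition has no gaps/overlaps
    expect_identical(sg$segments$start_s[-1], sg$segments$end_s[-(k + 1)])
    expect_identical(sg$segments$start_s[1], 0)
    expect_identical(sg$segments$end_s[k + 1], T_s)
  }

  expect_error(segment_postures(100, c(50, 50)), "strictly increasing")
  expect_error(segment_postures(100, 150), "inside")
})

test_that("movement features reproduce the published frequency extremes", {
  # 17 postures over 14.5 h -> 1.17 /h at 2 d.p.
  seg <- segment_postures(14.5 * 3600, seq(3600, by = 2700, length.out = 16))
  f <- movement_features(seg)
  expect_equal(round(f$frequency_per_hour, 2), 1.17)
  expect_equal(f$n_postures, 17)

  # 1 posture over 16 h -> 0.06 /h
  f2 <- movement_features(segment_postures(16 * 3600, numeric(0)))
  expect_equal(round(f2$frequency_per_hour, 2), 0.06)
  expect_equal(f2$pct_time_static_gt_2h, 1)

  # transitions basis differs by one posture
  f3 <- movement_features(seg, frequency_basis = "transitions")
  expect_equal(f3$frequency_per_hour, 16 / 14.5)

  # single 3-h posture in a 3-h recording: all time static > 2 h
  f4 <- movement_features(segment_postures(3 * 3600, numeric(0)))
  expect_equal(f4$pct_time_static_gt_2h, 1.0)
  # two 1.5-h postures: none
  f5 <- movement_features(segment_postures(3 * 3600, 1.5 * 3600))
  expect_equal(f5$pct_time_static_gt_2h, 0)
})

test_that("quartile convention reproduces the published table summaries", {
  t2 <- load_fixture("table2")
  pre <- dplyr::filter(t2, phase == "pre")
  post <- dplyr::filter(t2, phase == "post")
  expect_equal(summarize_lengths(pre$monitoring_hours)$median, 19)
  s_post <- summarize_lengths(post$monitoring_hours)
  expect_equal(s_post$median, 22.5)
  expect_equal(s_post$iqr, 8.7)
  expect_equal(summarize_lengths(pre$n_postures)$iqr, 4)
  expect_equal(summarize_lengths(post$n_postures)$iqr, 10)
  expect_error(summarize_lengths(numeric(0)))
})

test_that("detection under alternating-surface cycling, with and without prefilter", {
  # averaging a sinusoid over its own period removes it almost entirely
  x <- sin(2 * pi * (0:599) / 60)
  expect_lt(max(abs(presmat:::moving_average(x, 60)[31:570])), 0.05)

  # a genuine turn is still recovered on a cycling surface: the MAD-relative
  # threshold adapts to the periodic background
  sched <- tibble::tibble(template = c("supine", "lateral_left"),
                          duration_s = c(300, 300), offset_col = c(0, 6))
  cfg <- sim_config(sched, geometry_profile(), noise_sd_mmHg = 2,
                    jitter_sd_sensels = 0.2, transition_s = 10,
                    alternating_cycle = list(period_s = 60, depth_fraction = 0.15),
                    seed = 4)
  s <- simulate_session(cfg)$sequence
  ev <- detect_posture_changes(movement_signal(s))
  expect_length(ev, 1)
  expect_lte(abs(ev - 300), 11 / 2 + 10)

  # the optional low-pass runs and is recorded in the parameters
  filt <- movement_signal(s, prefilter_window_s = 60)
  expect_equal(filt$params$prefilter_window_s, 60)
  expect_length(detect_posture_changes(filt), 1)
})
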