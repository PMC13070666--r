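#' Body-loading sites and posture templates
#'
#' A posture template is a set of Gaussian loading sites on the mat grid —
#' one blob per body region in contact with the surface (head, scapulae,
#' sacrum/buttocks, heels, ...). Exactly one site is flagged as the
#' buttock/pelvic site; downstream recovery tests check that the
#' COP-anchored region of interest captures it. Rendered pressure at sensel
#' (r, c) is the sum over sites of
#' `amplitude * exp(-((r - cr)^2 / (2 sr^2) + (c - cc)^2 / (2 sc^2)))`.
#'
#' @param centre_row,centre_col Site centre in (fractional) sensel
#'   coordinates, 0-based.
#' @param spread_row,spread_col Gaussian SDs in sensels.
#' @param amplitude Peak pressure of the site in mmHg.
#' @param buttock Logical; flags the pelvic site.
#' @return `loading_site()` returns a one-row tibble; `posture_template()`
#'   an object of class `posture_template`.
#' @export
loading_site <- function(centre_row, centre_col, spread_row, spread_col,
                         amplitude, buttock = FALSE) {
  stopifnot(amplitude >= 0, spread_row > 0, spread_col > 0)
  tibble::tibble(centre_row = centre_row, centre_col = centre_col,
                 spread_row = spread_row, spread_col = spread_col,
                 amplitude = amplitude, buttock = buttock)
}

#' @rdname loading_site
#' @param name Template name: one of `"supine"`, `"lateral_left"`,
#'   `"lateral_right"`, `"high_sitting"`, `"custom"`.
#' @param sites A tibble of loading sites ([loading_site()] rows).
#' @export
posture_template <- function(name, sites) {
  name <- match.arg(name, c("supine", "lateral_left", "lateral_right",
                            "high_sitting", "custom"))
  if (nrow(sites) < 1) abort("posture template needs at least one loading site")
  if (sum(sites$buttock) != 1) {
    abort("exactly one site must be flagged as the buttock/pelvic site")
  }
  structure(list(name = name, sites = sites), class = "posture_template")
}

#' Default posture templates
#'
#' Fixed, documented body-loading constants for a lying adult on the default
#' 48 x 118 grid (head toward low column indices). Amplitudes are typical
#' interface-pressure magnitudes on a standard mattress: the pelvic load
#' dominates (80 mmHg) over heels (45), scapulae (40) and head (35). They
#' are rendering constants, not estimates fitted to any subject. Lateral
#' templates shift all sites across the width and concentrate the pelvic
#' load (higher peak, tighter spread) over the trochanter; high sitting
#' moves weight toward the pelvis.
#'
#' @param name Template name.
#' @return A [posture_template()].
#' @export
default_template <- function(name = c("supine", "lateral_left",
                                      "lateral_right", "high_sitting")) {
  name <- match.arg(name)
  base <- function(row_shift = 0, pelvic_amp = 80, pelvic_spread = c(4, 5)) {
    dplyr::bind_rows(
      loading_site(23.5 + row_shift, 12, 3.0, 3.0, 35),              # head
      loading_site(18.5 + row_shift, 30, 3.5, 4.5, 40),              # left scapula
      loading_site(28.5 + row_shift, 30, 3.5, 4.5, 40),              # right scapula
      loading_site(23.5 + row_shift, 60, pelvic_spread[1], pelvic_spread[2],
                   pelvic_amp, buttock = TRUE),                      # sacrum/buttocks
      loading_site(20.5 + row_shift, 103, 1.8, 2.2, 45),             # left heel
      loading_site(26.5 + row_shift, 103, 1.8, 2.2, 45)              # right heel
    )
  }
  sites <- switch(name,
    supine = base(),
    lateral_left = base(row_shift = -6, pelvic_amp = 95, pelvic_spread = c(3, 4)),
    lateral_right = base(row_shift = 6, pelvic_amp = 95, pelvic_spread = c(3, 4)),
    high_sitting = {
      s <- base(pelvic_amp = 100, pelvic_spread = c(4.5, 5))
      s$amplitude[s$centre_col == 30] <- 25   # scapulae partly unloaded
      s
    }
  )
  posture_template(name, sites)
}

#' Render a posture template to a single pressure frame
#'
#' Deterministic sum of the template's Gaussian loading sites evaluated at
#' sensel centres, clipped at zero.
#'
#' @param tpl A [posture_template()].
#' @param geometry A [mat_geometry()].
#' @param offset Length-2 numeric `(rows, cols)` displacement added to every
#'   site centre.
#' @return An `n_rows x n_cols` pressure matrix in mmHg.
#' @export
render_template <- function(tpl, geometry, offset = c(0, 0)) {
  if (!inherits(tpl, "posture_template")) abort("tpl must be a posture_template")
  r <- seq_len(geometry$n_rows) - 1
  c <- seq_len(geometry$n_cols) - 1
  frame <- matrix(0, geometry$n_rows, geometry$n_cols)
  for (i in seq_len(nrow(tpl$sites))) {
    s <- tpl$sites[i, ]
    gr <- exp(-(r - (s$centre_row + offset[1]))^2 / (2 * s$spread_row^2))
    gc <- exp(-(c - (s$centre_col + offset[2]))^2 / (2 * s$spread_col^2))
    frame <- frame + s$amplitude * outer(gr, gc)
  }
  pmax(frame, 0)
}

#' Simulation configuration
#'
#' @param schedule A tibble/data frame with one row per posture: columns
#'   `template` (list-column of [posture_template()] objects or character
#'   names resolved via [default_template()]), `duration_s`, and optionally
#'   `offset_row`, `offset_col` (whole-body displacement per posture,
#'   default 0).
#' @param geometry A [mat_geometry()].
#' @param noise_sd_mmHg SD of additive Gaussian sensor noise; the noisy
#'   frame is clipped at 0 (truncated noise), which biases very low
#'   pressures slightly upward.
#' @param jitter_sd_sensels Stationary SD (in sensels) of the within-posture
#'   micro-movement applied to all site centres: a mean-reverting AR(1)
#'   wander around the posture position with a ~60 s relaxation time, so the
#'   body jiggles but does not drift without bound during long postures.
#' @param transition_s Duration of the linear cross-fade between postures.
#' @param alternating_cycle Optional `list(period_s =, depth_fraction =)`
#'   for dynamic-mattress modulation: columns of even parity are multiplied
#'   by `1 + depth * sin(2 pi t / period)` and odd columns by the opposite
#'   sign, emulating alternating air-cell stripes.
#' @param seed Integer RNG seed; identical configs with identical seeds give
#'   identical sessions.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(schedule, geometry = geometry_profile("foresite_pt"),
                       noise_sd_mmHg = 2, jitter_sd_sensels = 0.2,
                       transition_s = 10, alternating_cycle = NULL,
                       seed = 1L) {
  schedule <- tibble::as_tibble(schedule)
  if (nrow(schedule) == 0) abort("schedule must be non-empty")
  if (!"offset_row" %in% names(schedule)) schedule$offset_row <- 0
  if (!"offset_col" %in% names(schedule)) schedule$offset_col <- 0
  if (is.character(schedule$template)) {
    schedule$template <- lapply(schedule$template, default_template)
  }
  stopifnot(noise_sd_mmHg >= 0, jitter_sd_sensels >= 0, transition_s >= 0,
            all(schedule$duration_s >= 60))
  if (!is.null(alternating_cycle)) {
    stopifnot(alternating_cycle$period_s > 0,
              alternating_cycle$depth_fraction >= 0,
              alternating_cycle$depth_fraction < 1)
  }
  structure(
    list(schedule = schedule, geometry = geometry,
         noise_sd_mmHg = noise_sd_mmHg, jitter_sd_sensels = jitter_sd_sensels,
         transition_s = transition_s, alternating_cycle = alternating_cycle,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a pressure-mat monitoring session
#'
#' Renders the scheduled postures frame by frame at the mat's sampling rate,
#' adds a within-posture centre-of-pressure random walk, truncated Gaussian
#' sensor noise and (optionally) alternating-mattress modulation, and
#' cross-fades linearly between consecutive postures over `transition_s`
#' seconds. Transition samples belong to the *following* posture
#' (half-open convention), matching how the ground-truth change times are
#' recorded.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `sequence` (a [pressure_sequence()]) and
#'   `truth` (class `cpm_ground_truth`): `change_times_s` plus a `postures`
#'   tibble with the template name, true buttock-site centre, interval, and
#'   the noise-free buttock-ROI signature values of each posture's clean
#'   template frame.
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- cfg$geometry
  rate <- g$sample_rate_hz
  n_per <- round(cfg$schedule$duration_s * rate)
  n_tot <- sum(n_per)
  if (n_tot < 2) abort("schedule too short: fewer than 2 frames in total")
  k <- nrow(cfg$schedule)
  change_idx <- cumsum(n_per)[-k]            # first frame index (1-based) of each new posture is change_idx+1
  change_times <- change_idx / rate          # in seconds, = cumulative duration

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  frames <- array(0, dim = c(g$n_rows, g$n_cols, n_tot))
  posture_of <- rep(seq_len(k), n_per)
  base_offsets <- cbind(cfg$schedule$offset_row, cfg$schedule$offset_col)

  # clean static frame per posture (no jitter), reused where possible
  clean <- lapply(seq_len(k), function(i)
    render_template(cfg$schedule$template[[i]], g, base_offsets[i, ]))

  jitter <- cfg$jitter_sd_sensels > 0
  for (i in seq_len(k)) {
    idx <- which(posture_of == i)
    if (jitter) {
      # mean-reverting micro-movement: AR(1) around the posture position with
      # ~60 s relaxation; jitter_sd_sensels is its stationary SD, so the
      # wander stays bounded however long the posture lasts
      phi <- exp(-1 / (60 * rate))
      innov_sd <- cfg$jitter_sd_sensels * sqrt(1 - phi^2)
      walk_r <- as.numeric(stats::filter(rnorm(length(idx), 0, innov_sd),
                                         phi, method = "recursive"))
      walk_c <- as.numeric(stats::filter(rnorm(length(idx), 0, innov_sd),
                                         phi, method = "recursive"))
      for (j in seq_along(idx)) {
        frames[, , idx[j]] <- render_template(
          cfg$schedule$template[[i]], g,
          base_offsets[i, ] + c(walk_r[j], walk_c[j]))
      }
    } else {
      frames[, , idx] <- clean[[i]]
    }
  }

  # linear cross-fade into each new posture over transition_s
  n_trans <- round(cfg$transition_s * rate)
  if (n_trans > 0 && k > 1) {
    for (ci in seq_along(change_idx)) {
      first_new <- change_idx[ci] + 1L
      last_prev <- frames[, , change_idx[ci]]
      span <- seq(first_new, min(first_new + n_trans - 1L, n_tot))
      w <- seq_along(span) / (n_trans + 1)   # 0 < w < 1: blend toward the new posture
      for (j in seq_along(span)) {
        frames[, , span[j]] <- (1 - w[j]) * last_prev + w[j] * frames[, , span[j]]
      }
    }
  }

  t_s <- (seq_len(n_tot) - 1) / rate
  if (!is.null(cfg$alternating_cycle)) {
    depth <- cfg$alternating_cycle$depth_fraction
    per <- cfg$alternating_cycle$period_s
    mod_t <- depth * sin(2 * pi * t_s / per)
    parity <- rep(c(1, -1), length.out = g$n_cols)   # +1 on even (0-based) cols
    modfac <- 1 + outer(parity, mod_t)               # n_cols x n_tot
    for (f in seq_len(n_tot)) {
      frames[, , f] <- frames[, , f] * rep(modfac[, f], each = g$n_rows)
    }
  }

  if (cfg$noise_sd_mmHg > 0) {
    cells <- g$n_rows * g$n_cols
    chunk <- 4000L   # bound peak memory on long sessions
    for (lo in seq(1L, n_tot, by = chunk)) {
      hi <- min(lo + chunk - 1L, n_tot)
      frames[, , lo:hi] <- pmax(
        frames[, , lo:hi] + rnorm(cells * (hi - lo + 1L), 0, cfg$noise_sd_mmHg),
        0)
    }
  }

  seq <- pressure_sequence(frames, geometry = g, timestamps = t_s,
                           meta = list(notes = "synthetic session"))

  starts <- c(0, change_times)
  ends <- c(change_times, n_tot / rate)
  postures <- purrr::map_dfr(seq_len(k), function(i) {
    tpl <- cfg$schedule$template[[i]]
    bsite <- tpl$sites[tpl$sites$buttock, ]
    centre <- c(bsite$centre_row + base_offsets[i, 1],
                bsite$centre_col + base_offsets[i, 2])
    sig <- clean_frame_signature(clean[[i]], centre, g)
    tibble::tibble(
      posture = i, template = tpl$name,
      start_s = starts[i], end_s = ends[i],
      buttock_row = centre[1], buttock_col = centre[2],
      ppg_clean = sig$ppg, ppi_clean = sig$ppi, peak_clean = sig$peak
    )
  })
  truth <- structure(
    list(change_times_s = change_times, postures = postures),
    class = "cpm_ground_truth"
  )
  list(sequence = seq, truth = truth)
}

# noise-free oracle: signatures of a clean frame with the default ROI centred
# on the true buttock-site centre
clean_frame_signature <- function(frame, centre, geometry, spec = roi_spec()) {
  placement <- place_roi_window(round(centre[1]), round(centre[2]), spec, geometry)
  list(
    ppg = ppg_frame(frame, placement, geometry),
    ppi = ppi_frame(frame, placement),
    peak = peak_frame(frame, placement)
  )
}

#' Write a ground-truth log
#'
#' Serializes a simulation's ground truth (true change times, per-posture
#' template, buttock centre and clean signatures) as JSON next to the
#' recording, for recovery testing.
#'
#' @param truth A `cpm_ground_truth` from [simulate_session()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(change_times_s = truth$change_times_s, postures = truth$postures),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
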