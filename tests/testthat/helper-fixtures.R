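# shared builders for small in-memory fixtures

tiny_geometry <- function(nr = 2, nc = 2, pitch = 10, rate = 1) {
  mat_geometry(nr, nc, pitch, rate)
}

# a constant-frame sequence (value v everywhere)
constant_sequence <- function(n_frames = 10, v = 30, geometry = tiny_geometry()) {
  arr <- array(v, dim = c(geometry$n_rows, geometry$n_cols, n_frames))
  pressure_sequence(arr, geometry = geometry)
}

# noise-free two-posture sequence: a single Gaussian blob jumping by
# (dr, dc) sensels at the midpoint; no transition
jump_sequence <- function(n = 200, dr = 0, dc = 10,
                          geometry = geometry_profile()) {
  tpl <- posture_template("custom", loading_site(24, 50, 4, 5, 100, buttock = TRUE))
  f1 <- render_template(tpl, geometry)
  f2 <- render_template(tpl, geometry, offset = c(dr, dc))
  arr <- array(0, dim = c(geometry$n_rows, geometry$n_cols, n))
  arr[, , 1:(n / 2)] <- f1
  arr[, , (n / 2 + 1):n] <- f2
  pressure_sequence(arr, geometry = geometry)
}

# standard 5-posture recovery schedule with lateral shifts >= 6 sensels
recovery_config <- function(seed, noise_sd = 2, jitter = 0.2,
                            durations = c(420, 360, 480, 300, 360)) {
  sched <- tibble::tibble(
    template = c("supine", "lateral_left", "supine", "lateral_right", "supine"),
    duration_s = durations,
    offset_row = c(0, -2, 6, 2, -4),
    offset_col = c(0, 4, -6, 8, 0)
  )
  sim_config(sched, geometry_profile(), noise_sd_mmHg = noise_sd,
             jitter_sd_sensels = jitter, transition_s = 10, seed = seed)
}

# brute-force oracles, kept deliberately naive and separate from the package
oracle_ppi <- function(m, k = 10) mean(rev(sort(as.vector(m)))[1:k])

oracle_ppg <- function(m, pitch_cm) {
  best <- 0
  nr <- nrow(m); nc <- ncol(m)
  for (r in 1:nr) for (c in 1:nc) {
    for (d in list(c(1, 1), c(1, -1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        best <- max(best, abs(m[r, c] - m[r2, c2]))
      }
    }
  }
  best / (sqrt(2) * pitch_cm)
}

oracle_cop <- function(m, floor = 5) {
  s <- 0; sr <- 0; sc <- 0
  for (r in 1:nrow(m)) for (c in 1:ncol(m)) {
    if (m[r, c] > floor) {
      s <- s + m[r, c]
      sr <- sr + m[r, c] * (r - 1)
      sc <- sc + m[r, c] * (c - 1)
    }
  }
  c(sr / s, sc / s)
}
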