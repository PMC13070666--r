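#' Construct a pressure sequence
#'
#' A `pressure_sequence` is the raw signal everything else consumes: a
#' time-ordered stack of 2-D pressure frames on a fixed mat geometry, with
#' session metadata. Frames are stored as a 3-D array indexed
#' `[row, col, frame]`; timestamps are seconds since the first frame (first
#' frame at t = 0) and must be uniformly spaced at `1 / sample_rate_hz`
#' within a jitter tolerance.
#'
#' @param frames 3-D numeric array `n_rows x n_cols x n_frames` of pressures
#'   in mmHg, or a list of equally sized matrices.
#' @param geometry A [mat_geometry()]. Defaults to the grid implied by
#'   `frames` at the bed-mat pitch.
#' @param timestamps Optional numeric vector of frame times in seconds;
#'   defaults to `0, 1/rate, 2/rate, ...`.
#' @param meta Session metadata: a list with elements `patient_id`, `phase`
#'   (`"pre"` or `"post"`), `support_surface`, `notes` (all optional).
#' @param validate If `TRUE` (default) the invariants are checked and the
#'   first violation raised as an error.
#'
#' @return An object of class `pressure_sequence`.
#' @seealso [validate_sequence()], [read_sequence()], [write_sequence()]
#' @export
pressure_sequence <- function(frames, geometry = NULL, timestamps = NULL,
                              meta = list(), validate = TRUE) {
  if (is.list(frames) && !is.array(frames)) {
    if (length(frames) == 0) abort("a pressure sequence needs at least 2 frames")
    dims <- vapply(frames, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
      abort(sprintf("ragged frame stack: frame %d has different dimensions", bad - 1L))
    }
    frames <- array(unlist(frames), dim = c(dims[1, 1], dims[2, 1], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (is.null(geometry)) {
    geometry <- mat_geometry(dim(frames)[1], dim(frames)[2])
  }
  n <- dim(frames)[3]
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1) / geometry$sample_rate_hz
  meta <- utils::modifyList(
    list(patient_id = NA_character_, phase = NA_character_,
         support_surface = NA_character_, notes = NA_character_),
    meta
  )
  seq <- structure(
    list(geometry = geometry, frames = frames,
         timestamps = as.numeric(timestamps), meta = meta),
    class = "pressure_sequence"
  )
  if (validate) {
    v <- validate_sequence(seq)
    if (nrow(v) > 0) {
      abort(sprintf("invalid pressure sequence: %s", v$message[1]))
    }
  }
  seq
}

#' Number of frames, duration and frame extraction
#'
#' `n_frames()` counts frames; `duration_s()` is the monitoring period
#' `n_frames / sample_rate` in seconds (each frame covers one sampling
#' interval); `get_frame()` extracts one frame as a matrix.
#'
#' @param seq A [pressure_sequence()].
#' @param i Frame index (1-based).
#' @return A count, a duration in seconds, or an `n_rows x n_cols` matrix.
#' @export
n_frames <- function(seq) dim(seq$frames)[3]

#' @rdname n_frames
#' @export
duration_s <- function(seq) n_frames(seq) / seq$geometry$sample_rate_hz

#' @rdname n_frames
#' @export
get_frame <- function(seq, i) seq$frames[, , i]

#' @export
print.pressure_sequence <- function(x, ...) {
  cat(sprintf(
    "<pressure_sequence> %d frames (%.1f min) on %d x %d grid @ %g Hz\n",
    n_frames(x), duration_s(x) / 60,
    x$geometry$n_rows, x$geometry$n_cols, x$geometry$sample_rate_hz
  ))
  if (!is.na(x$meta$patient_id)) {
    cat(sprintf("  patient %s, phase %s, surface %s\n",
                x$meta$patient_id, x$meta$phase, x$meta$support_surface))
  }
  invisible(x)
}

#' Check pressure-sequence invariants
#'
#' Reports every violated invariant instead of stopping at the first:
#' non-finite or negative pressures, fewer than 2 frames, non-increasing
#' timestamps, and sampling jitter (frame spacing departing from
#' `1 / sample_rate_hz` by more than `jitter_tol` of the nominal interval).
#'
#' @param seq A [pressure_sequence()].
#' @param jitter_tol Allowed relative deviation of each inter-frame interval
#'   from the nominal sampling interval (default 0.1, i.e. +/-10%).
#' @return A tibble with columns `invariant`, `frame` (0-based index of the
#'   offending frame, NA when not frame-specific) and `message`; zero rows
#'   when the sequence is valid.
#' @export
validate_sequence <- function(seq, jitter_tol = 0.1) {
  out <- list()
  add <- function(invariant, frame, message) {
    out[[length(out) + 1]] <<- tibble::tibble(
      invariant = invariant, frame = frame, message = message)
  }
  n <- dim(seq$frames)[3]
  if (n < 2) {
    add("min length", NA_integer_, sprintf("sequence has %d frame(s); at least 2 required", n))
  }
  if (length(seq$timestamps) != n) {
    add("timestamps length", NA_integer_,
        "timestamp vector length does not match frame count")
  }
  bad_finite <- which(apply(!is.finite(seq$frames), 3, any))
  for (i in bad_finite) {
    add("non-finite pressure", i - 1L,
        sprintf("frame %d contains non-finite pressure values", i - 1L))
  }
  neg <- which(apply(seq$frames < 0, 3, any, na.rm = TRUE))
  neg <- setdiff(neg, bad_finite)
  for (i in neg) {
    add("negative pressure", i - 1L,
        sprintf("frame %d contains negative pressures", i - 1L))
  }
  if (length(seq$timestamps) == n && n >= 2) {
    dt <- diff(seq$timestamps)
    nominal <- 1 / seq$geometry$sample_rate_hz
    if (any(dt <= 0)) {
      i <- which(dt <= 0)[1]
      add("monotone timestamps", i, sprintf(
        "timestamps not strictly increasing at frame %d", i))
    } else {
      jit <- which(abs(dt - nominal) > jitter_tol * nominal)
      for (i in jit) {
        add("sampling jitter", i, sprintf(
          "interval before frame %d is %.3g s (nominal %.3g s, tolerance %.0f%%)",
          i, dt[i], nominal, 100 * jitter_tol))
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(invariant = character(), frame = integer(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".meta.json")

#' Write a pressure sequence to disk
#'
#' Emits a long-format frame-stack CSV with header
#' `t_s,row,col,pressure_mmHg` (frames contiguous, row-major within each
#' timestamp, 0-based sensel indices) plus a JSON metadata sidecar
#' (`<stem>.meta.json`) carrying the geometry, session metadata and
#' duration. Pressures and timestamps are serialized with full precision so
#' that [read_sequence()] reproduces the sequence exactly.
#'
#' @param seq A valid [pressure_sequence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  v <- validate_sequence(seq)
  if (nrow(v) > 0) abort(sprintf("refusing to write invalid sequence: %s", v$message[1]))
  g <- seq$geometry
  n <- n_frames(seq)
  # row-major within each frame: row varies slowest
  rows <- rep(rep(0:(g$n_rows - 1L), each = g$n_cols), times = n)
  cols <- rep(rep(0:(g$n_cols - 1L), times = g$n_rows), times = n)
  t_s <- rep(seq$timestamps, each = g$n_rows * g$n_cols)
  p <- as.vector(aperm(seq$frames, c(2, 1, 3)))  # col fastest, then row, then frame
  readr::write_csv(
    tibble::tibble(t_s = t_s, row = rows, col = cols, pressure_mmHg = p),
    path
  )
  sidecar <- list(
    geometry = list(n_rows = g$n_rows, n_cols = g$n_cols,
                    pitch_mm = g$pitch_mm, sample_rate_hz = g$sample_rate_hz),
    meta = seq$meta[c("patient_id", "phase", "support_surface")],
    duration_s = duration_s(seq)
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a pressure sequence from disk
#'
#' Reads the frame-stack CSV format written by [write_sequence()] together
#' with its JSON metadata sidecar. The sidecar supplies the geometry and
#' session metadata; `geometry_override` takes precedence when given (and is
#' required if the sidecar is missing).
#'
#' @param path CSV path.
#' @param geometry_override Optional [mat_geometry()] overriding the sidecar.
#' @return A validated [pressure_sequence()].
#' @export
read_sequence <- function(path, geometry_override = NULL) {
  sc_path <- sidecar_path(path)
  meta <- list()
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    geometry <- mat_geometry(sc$geometry$n_rows, sc$geometry$n_cols,
                             sc$geometry$pitch_mm, sc$geometry$sample_rate_hz)
    meta <- lapply(sc$meta, function(x) if (is.null(x)) NA_character_ else x)
  } else if (is.null(geometry_override)) {
    abort(sprintf("missing metadata sidecar '%s' and no geometry_override given", sc_path))
  } else {
    geometry <- geometry_override
  }
  if (!is.null(geometry_override)) geometry <- geometry_override

  df <- readr::read_csv(path, col_types = readr::cols(
    t_s = readr::col_double(), row = readr::col_integer(),
    col = readr::col_integer(), pressure_mmHg = readr::col_double()
  ))
  ts <- unique(df$t_s)
  cells <- geometry$n_rows * geometry$n_cols
  counts <- table(factor(df$t_s, levels = ts))
  if (any(counts != cells)) {
    bad <- which(counts != cells)[1] - 1L
    abort(sprintf(
      "validation error: frame %d has %d cells but geometry implies %d",
      bad, as.integer(counts[bad + 1L]), cells))
  }
  if (any(df$pressure_mmHg < 0, na.rm = TRUE)) {
    bad <- match(TRUE, tapply(df$pressure_mmHg < 0, factor(df$t_s, levels = ts), any)) - 1L
    abort(sprintf("validation error: frame %d contains negative pressures", bad))
  }
  # frames are contiguous and row-major; order defensively anyway
  ord <- order(match(df$t_s, ts), df$row, df$col)
  arr <- array(df$pressure_mmHg[ord], dim = c(geometry$n_cols, geometry$n_rows, length(ts)))
  arr <- aperm(arr, c(2, 1, 3))
  pressure_sequence(arr, geometry = geometry, timestamps = ts, meta = meta)
}
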