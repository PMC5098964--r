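#' Pressure-plate geometry
#'
#' Describes a regular rectangular grid of pressure sensors. The defaults
#' reproduce the large walkway platform used for adult elephants: 44 sensor
#' columns across a 0.605 m width, 160 sensor rows along a 2.122 m length
#' (7040 sensors), sampled at 100 Hz. Sensor pitch is derived from the outer
#' dimensions, so `pitch_x_m * n_cols == width_m` exactly.
#'
#' Axis convention used throughout the package: `x` is the mediolateral axis
#' (across plate width, along sensor columns), `y` the cranio-caudal axis
#' (along the direction of travel, along sensor rows). Physical coordinates
#' refer to sensor-cell centres: column `j` (1-based) is at
#' `x = (j - 0.5) * pitch_x_m`.
#'
#' @param n_cols,n_rows Sensor counts across the width and along the length.
#' @param width_m,length_m Outer plate dimensions in metres.
#' @param freq_hz Sampling frequency in Hz.
#' @return An object of class `plate_spec`.
#' @export
#' @examples
#' plate_spec() # the default elephant walkway platform
plate_spec <- function(n_cols = 44L, n_rows = 160L, width_m = 0.605,
                       length_m = 2.122, freq_hz = 100) {
  n_cols <- as.integer(n_cols)
  n_rows <- as.integer(n_rows)
  if (is.na(n_cols) || n_cols < 1L || is.na(n_rows) || n_rows < 1L) {
    stop("`n_cols` and `n_rows` must be positive integers", call. = FALSE)
  }
  if (!is.numeric(width_m) || width_m <= 0 || !is.numeric(length_m) || length_m <= 0) {
    stop("`width_m` and `length_m` must be positive", call. = FALSE)
  }
  if (!is.numeric(freq_hz) || freq_hz <= 0) {
    stop("`freq_hz` must be positive", call. = FALSE)
  }
  structure(
    list(
      n_cols = n_cols, n_rows = n_rows,
      width_m = width_m, length_m = length_m,
      freq_hz = freq_hz,
      pitch_x_m = width_m / n_cols,
      pitch_y_m = length_m / n_rows
    ),
    class = "plate_spec"
  )
}

#' @export
print.plate_spec <- function(x, ...) {
  cat(sprintf(
    "<plate_spec> %d x %d sensors (%.3f x %.3f m), %g Hz, pitch %.4f x %.4f m\n",
    x$n_cols, x$n_rows, x$width_m, x$length_m, x$freq_hz,
    x$pitch_x_m, x$pitch_y_m
  ))
  invisible(x)
}

#' Physical coordinates of sensor-cell centres
#'
#' @param col,row 1-based column / row indices (may be fractional).
#' @param spec A [plate_spec()].
#' @return Coordinates in metres.
#' @export
cell_x <- function(col, spec) (col - 0.5) * spec$pitch_x_m

#' @rdname cell_x
#' @export
cell_y <- function(row, spec) (row - 0.5) * spec$pitch_y_m

#' A time-ordered stack of pressure frames
#'
#' The raw `p(x, y, t)` field of one walkway trial: pressures in kPa on a
#' fixed sensor grid at a fixed sampling frequency.
#'
#' @param frames Numeric array of dimension `(n_rows, n_cols, n_frames)`, or a
#'   single `n_rows x n_cols` matrix. All values must be non-negative kPa.
#' @param spec A [plate_spec()].
#' @param t0 Start time of the first frame in seconds.
#' @param meta Optional [trial_meta()].
#' @return An object of class `pressure_record`.
#' @export
pressure_record <- function(frames, spec = plate_spec(), t0 = 0, meta = NULL) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a (n_rows, n_cols, n_frames) array", call. = FALSE)
  }
  d <- dim(frames)
  if (d[1] != spec$n_rows || d[2] != spec$n_cols) {
    stop(sprintf(
      "frame shape %d x %d does not match plate spec %d x %d",
      d[1], d[2], spec$n_rows, spec$n_cols
    ), call. = FALSE)
  }
  if (d[3] < 1L) stop("record must contain at least one frame", call. = FALSE)
  neg <- which(frames < 0)
  if (length(neg)) {
    bad_frame <- (neg[1] - 1L) %/% (d[1] * d[2])
    stop(sprintf("negative pressure in frame %d", bad_frame), call. = FALSE)
  }
  if (!is.null(meta) && !inherits(meta, "trial_meta")) {
    stop("`meta` must be a trial_meta or NULL", call. = FALSE)
  }
  structure(
    list(spec = spec, frames = frames, t0 = t0, meta = meta),
    class = "pressure_record"
  )
}

#' Number of frames in a pressure record
#' @param record A [pressure_record()].
#' @export
n_frames <- function(record) dim(record$frames)[3]

#' @export
print.pressure_record <- function(x, ...) {
  cat(sprintf(
    "<pressure_record> %d frames of %d x %d cells (%.2f s at %g Hz), total load %.1f kPa\n",
    n_frames(x), x$spec$n_rows, x$spec$n_cols,
    n_frames(x) / x$spec$freq_hz, x$spec$freq_hz, sum(x$frames)
  ))
  invisible(x)
}

#' Trial-level subject metadata
#'
#' @param subject_id Subject label.
#' @param body_mass_kg Estimated body mass in kg.
#' @param shoulder_height_m,hip_height_m Heights in metres (hip height may be
#'   absent; it is the limb length used for Froude numbers).
#' @param velocity_ms Mean walking speed in m/s.
#' @param side_hint Optional walking-direction flag (free-form label).
#' @return An object of class `trial_meta`.
#' @export
trial_meta <- function(subject_id, body_mass_kg = NA_real_,
                       shoulder_height_m = NA_real_, hip_height_m = NA_real_,
                       velocity_ms = NA_real_, side_hint = NA_character_) {
  num <- c(
    body_mass_kg = body_mass_kg, shoulder_height_m = shoulder_height_m,
    hip_height_m = hip_height_m, velocity_ms = velocity_ms
  )
  bad <- !is.na(num) & num < 0
  if (any(bad)) {
    stop(sprintf("negative value for %s", paste(names(num)[bad], collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      body_mass_kg = as.numeric(body_mass_kg),
      shoulder_height_m = as.numeric(shoulder_height_m),
      hip_height_m = as.numeric(hip_height_m),
      velocity_ms = as.numeric(velocity_ms),
      side_hint = as.character(side_hint)
    ),
    class = "trial_meta"
  )
}
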