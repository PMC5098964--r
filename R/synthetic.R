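#' Parametric elephant foot-pressure model
#'
#' The plantar pressure field of one foot is modelled as a truncated Gaussian
#' mixture: five sharp "digit" components arranged on the cranial arc of an
#' elliptical outline (nail tips of digits i-v, medial to lateral) plus one
#' broad, lower-amplitude central/caudal "pad" component (the fat-pad /
#' slipper region). The mixture is truncated to zero outside the outline.
#' Default amplitudes put the largest peaks on the lateral digits (iii-v),
#' the qualitative pattern seen in walking elephants, and realized peak
#' pressures in the low-hundreds of kPa range; fore feet default to 7% higher
#' amplitudes than hind feet, matching the forelimbs' larger share of body
#' weight.
#'
#' The foot frame has `+y` cranial (direction of travel at heading 0) and
#' `+x` lateral; lateral maps to the animal's left (+x on the plate) for left
#' feet and is mirrored for right feet.
#'
#' @param foot_type `"fore"` or `"hind"`.
#' @param side `"left"` or `"right"`.
#' @param semi_x_m,semi_y_m Ellipse semi-axes of the foot outline (m).
#' @param digit_amplitudes Five peak amplitudes in kPa for digits i-v
#'   (medial to lateral). Default: lateral-biased, fore scaled by 1.07.
#' @param pad_amplitude Pad component amplitude in kPa.
#' @param digit_sigma_m,pad_sigma_m Gaussian widths (m).
#' @param digit_radius_frac Radial position of digit centres as a fraction of
#'   the outline semi-axes.
#' @return An object of class `foot_model`.
#' @export
foot_model <- function(foot_type = c("fore", "hind"), side = c("left", "right"),
                       semi_x_m = 0.11, semi_y_m = 0.13,
                       digit_amplitudes = NULL, pad_amplitude = NULL,
                       digit_sigma_m = 0.018, pad_sigma_m = 0.05,
                       digit_radius_frac = 0.8) {
  foot_type <- match.arg(foot_type)
  side <- match.arg(side)
  if (is.null(digit_amplitudes)) {
    digit_amplitudes <- c(250, 300, 460, 430, 390)
    if (foot_type == "fore") digit_amplitudes <- digit_amplitudes * 1.07
  }
  if (is.null(pad_amplitude)) {
    pad_amplitude <- if (foot_type == "fore") 200 else 190
  }
  if (length(digit_amplitudes) != 5L) {
    stop("`digit_amplitudes` must have length 5 (digits i-v)", call. = FALSE)
  }
  if (any(digit_amplitudes < 0) || pad_amplitude < 0) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  if (semi_x_m <= 0 || semi_y_m <= 0 || digit_sigma_m <= 0 || pad_sigma_m <= 0) {
    stop("sizes and sigmas must be positive", call. = FALSE)
  }
  # digits i-v on the cranial arc, medial (160 deg) to lateral (20 deg)
  ang <- seq(160, 20, length.out = 5) * pi / 180
  centres <- cbind(
    x = digit_radius_frac * semi_x_m * cos(ang),
    y = digit_radius_frac * semi_y_m * sin(ang)
  )
  structure(
    list(
      foot_type = foot_type, side = side,
      semi_x_m = semi_x_m, semi_y_m = semi_y_m,
      digit_centres = centres,
      digit_amplitudes = digit_amplitudes,
      pad_amplitude = pad_amplitude,
      pad_centre = c(x = 0, y = -0.25 * semi_y_m),
      digit_sigma_m = digit_sigma_m, pad_sigma_m = pad_sigma_m
    ),
    class = "foot_model"
  )
}

#' Default four-foot model set
#'
#' @param size_scale Multiplier on the outline semi-axes (subject size).
#' @param amp_scale Multiplier on all amplitudes (subject loading).
#' @return Named list `FL`, `FR`, `HL`, `HR` of [foot_model()] objects.
#' @export
default_foot_models <- function(size_scale = 1, amp_scale = 1) {
  mk <- function(ft, sd) {
    m <- foot_model(ft, sd,
                    semi_x_m = 0.11 * size_scale, semi_y_m = 0.13 * size_scale)
    m$digit_amplitudes <- m$digit_amplitudes * amp_scale
    m$pad_amplitude <- m$pad_amplitude * amp_scale
    m
  }
  list(
    FL = mk("fore", "left"), FR = mk("fore", "right"),
    HL = mk("hind", "left"), HR = mk("hind", "right")
  )
}

#' Gait plan for the synthetic generator
#'
#' Defines when and where each foot strikes the plate, the stance duration,
#' the time-varying mixture weights that shape the centre-of-pressure path,
#' and the sensor noise level. Total plate force follows a raised-cosine
#' stance envelope (single-peaked loading). Mixture weights ramp from the
#' caudal pad to the cranial digits over stance, producing the caudal-to-
#' cranial COP path. `lateral_gain` drives the mediolateral shape: early in
#' stance the lateral digits are over-weighted and the pad component bears
#' load lateral of its resting position, re-centring by mid-stance, so the
#' COP deviates laterally at impact and drifts medially towards mid-stance
#' (set `lateral_gain = 0` for a mediolaterally symmetric field).
#'
#' @param steps Data frame with columns `foot` (FL/FR/HL/HR), `x_m`, `y_m`
#'   (placement of the foot centre on the plate), `onset_s`, `heading_deg`.
#'   Default: four well-separated footfalls, left feet on the high-x column,
#'   each hind foot landing just cranial to the ipsilateral forefoot print
#'   after the forefoot has lifted.
#' @param stance_s Stance duration per footstep in seconds.
#' @param speed_ms Nominal walking speed (metadata only).
#' @param noise_sd_kpa Additive i.i.d. Gaussian sensor noise, clipped at 0.
#'   The default (1 kPa) keeps the 5 kPa activation threshold at five noise
#'   standard deviations, consistent with a working threshold that cleanly
#'   separates contact from baseline.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @param pad_frames Empty frames prepended/appended to each record so that
#'   interior steps are temporally complete.
#' @param lateral_gain Strength of the early-stance lateral over-weighting.
#' @param digit_ramp,pad_ramp Start/end mixture weights for the digit and pad
#'   components over stance fraction 0 -> 1.
#' @return An object of class `gait_plan`.
#' @export
gait_plan <- function(steps = NULL, stance_s = 1.2, speed_ms = 1.2,
                      noise_sd_kpa = 1, seed = 1L, pad_frames = 5L,
                      lateral_gain = 0.6, digit_ramp = c(0.25, 1),
                      pad_ramp = c(1.15, 0.25)) {
  if (is.null(steps)) steps <- default_step_sequence()
  steps <- as.data.frame(steps)
  req <- c("foot", "x_m", "y_m", "onset_s")
  if (!all(req %in% names(steps))) {
    stop("`steps` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (is.null(steps$heading_deg)) steps$heading_deg <- 0
  if (stance_s <= 0) stop("`stance_s` must be positive", call. = FALSE)
  if (noise_sd_kpa < 0) stop("`noise_sd_kpa` must be non-negative", call. = FALSE)
  for (ft in unique(steps$foot)) {
    on <- steps$onset_s[steps$foot == ft]
    if (any(diff(sort(on)) <= 0) || anyDuplicated(on)) {
      stop("onset times must be strictly increasing per foot", call. = FALSE)
    }
  }
  structure(
    list(
      steps = steps, stance_s = stance_s, speed_ms = speed_ms,
      noise_sd_kpa = noise_sd_kpa, seed = as.integer(seed),
      pad_frames = as.integer(pad_frames), lateral_gain = lateral_gain,
      digit_ramp = digit_ramp, pad_ramp = pad_ramp
    ),
    class = "gait_plan"
  )
}

#' @rdname gait_plan
#' @export
default_step_sequence <- function() {
  data.frame(
    foot = c("FL", "FR", "HL", "HR"),
    x_m = c(0.45, 0.16, 0.45, 0.16),
    y_m = c(0.55, 1.35, 0.64, 1.44),
    onset_s = c(0, 0.7, 1.45, 2.15),
    heading_deg = 0
  )
}

# Raised-cosine stance loading envelope on stance fraction tau in (0, 1).
stance_envelope <- function(tau) 0.5 * (1 - cos(2 * pi * tau))

# Time-varying mixture weights; lat in [-1, 1] medial -> lateral.
digit_weight <- function(tau, plan, lat) {
  base <- plan$digit_ramp[1] + (plan$digit_ramp[2] - plan$digit_ramp[1]) * tau
  base * (1 + plan$lateral_gain * (1 - tau) * lat)
}
pad_weight <- function(tau, plan) {
  plan$pad_ramp[1] + (plan$pad_ramp[2] - plan$pad_ramp[1]) * tau
}

# Evaluate the continuous generating field at foot-frame points (xf, yf) for
# scalar stance fraction tau. Returns kPa.
foot_field <- function(model, plan, xf, yf, tau) {
  inside <- (xf / model$semi_x_m)^2 + (yf / model$semi_y_m)^2 <= 1
  v <- numeric(length(xf))
  if (!any(inside)) return(v)
  xi <- xf[inside]; yi <- yf[inside]
  env <- stance_envelope(tau)
  lat <- seq(-1, 1, length.out = 5)
  acc <- numeric(length(xi))
  s2d <- 2 * model$digit_sigma_m^2
  for (k in 1:5) {
    d2 <- (xi - model$digit_centres[k, 1])^2 + (yi - model$digit_centres[k, 2])^2
    acc <- acc + digit_weight(tau, plan, lat[k]) * model$digit_amplitudes[k] *
      exp(-d2 / s2d)
  }
  # the pad bears load laterally at impact and re-centres by mid-stance,
  # producing the lateral deviation of the COP at foot-strike
  pad_x <- model$pad_centre[1] +
    plan$lateral_gain * 0.5 * model$semi_x_m * max(0, 1 - 2 * tau)
  d2 <- (xi - pad_x)^2 + (yi - model$pad_centre[2])^2
  acc <- acc + pad_weight(tau, plan) * model$pad_amplitude *
    exp(-d2 / (2 * model$pad_sigma_m^2))
  v[inside] <- env * acc
  v
}

# Plate-frame point -> foot-frame, for a placement (x_m, y_m, heading_deg).
# Left feet keep +x lateral; right feet mirror x.
plate_to_foot <- function(model, placement, x, y) {
  dx <- x - placement$x_m
  dy <- y - placement$y_m
  th <- -placement$heading_deg * pi / 180
  xr <- cos(th) * dx - sin(th) * dy
  yr <- sin(th) * dx + cos(th) * dy
  s <- if (model$side == "left") 1 else -1
  list(xf = s * xr, yf = yr)
}

foot_to_plate <- function(model, placement, xf, yf) {
  s <- if (model$side == "left") 1 else -1
  xr <- s * xf
  th <- placement$heading_deg * pi / 180
  dx <- cos(th) * xr - sin(th) * yf
  dy <- sin(th) * xr + cos(th) * yf
  list(x = placement$x_m + dx, y = placement$y_m + dy)
}

# 3x3 Gaussian kernel weights (sigma in pixels), normalized over the window.
kernel3_weights <- function(sigma_px = 1) {
  o <- -1:1
  w <- outer(exp(-o^2 / (2 * sigma_px^2)), exp(-o^2 / (2 * sigma_px^2)))
  w / sum(w)
}

#' Generate one synthetic footstep with analytic ground truth
#'
#' Samples the continuous generating field (see [foot_model()]) at sensor-cell
#' centres over one stance, noise-free. Ground truth is computed from the
#' continuous field independently of the record grid: per-frame COP as the
#' pressure-weighted centroid of the field (restricted to the activation
#' isocontour) by dense numerical integration on an oversampled grid, plus
#' the seven anatomical ROI loci (digit centres from the model; pad centroid
#' and caudal heel point from the oversampled peak field) with their regional
#' peak pressures as measured by the sigma = 1 px Gaussian 3x3 extraction
#' kernel.
#'
#' @param model A [foot_model()].
#' @param plan A [gait_plan()] (stance duration, weights; noise is *not*
#'   added here - single footsteps are returned noise-free, noise is a
#'   trial-level property).
#' @param placement List or one-row data frame with `x_m`, `y_m`,
#'   `heading_deg`.
#' @param spec A [plate_spec()].
#' @param clip Allow the outline to extend beyond the plate edge (the field is
#'   clipped; the step is flagged spatially incomplete). When `FALSE`, an
#'   off-plate placement is a geometry error.
#' @param truth_oversample Linear oversampling factor of the ground-truth
#'   integration grid relative to the sensor pitch.
#' @param mask_threshold_kpa Activation isocontour used for the ground-truth
#'   voxel mask and COP restriction (matches the segmentation default).
#' @return List with elements `record` (a [pressure_record()]) and `truth`
#'   (mask voxels, per-frame COP, ROI loci/peaks, completeness flags).
#' @export
generate_footstep <- function(model, plan, placement, spec = plate_spec(),
                              clip = FALSE, truth_oversample = 3L,
                              mask_threshold_kpa = 5) {
  placement <- as.list(placement)
  if (is.null(placement$heading_deg)) placement$heading_deg <- 0
  n_fr <- round(plan$stance_s * spec$freq_hz)
  if (n_fr < 5) stop("stance must cover at least 5 frames", call. = FALSE)
  reach <- max(model$semi_x_m, model$semi_y_m)
  if (placement$x_m < 0 || placement$x_m > spec$width_m ||
      placement$y_m < 0 || placement$y_m > spec$length_m) {
    stop("placement outside plate", call. = FALSE)
  }
  off_edge <- placement$x_m - reach < 0 || placement$x_m + reach > spec$width_m ||
    placement$y_m - reach < 0 || placement$y_m + reach > spec$length_m
  if (off_edge && !clip) {
    stop("foot outline extends beyond the plate; use clip = TRUE to allow",
         call. = FALSE)
  }

  cols <- max(1L, floor((placement$x_m - reach) / spec$pitch_x_m)):
    min(spec$n_cols, ceiling((placement$x_m + reach) / spec$pitch_x_m) + 1L)
  rows <- max(1L, floor((placement$y_m - reach) / spec$pitch_y_m)):
    min(spec$n_rows, ceiling((placement$y_m + reach) / spec$pitch_y_m) + 1L)
  grid <- expand.grid(row = rows, col = cols)
  ff <- plate_to_foot(model, placement, cell_x(grid$col, spec), cell_y(grid$row, spec))

  # oversampled foot-frame grid for ground-truth integration
  os <- as.integer(truth_oversample)
  fp <- min(spec$pitch_x_m, spec$pitch_y_m) / os
  # symmetric about the foot centre so truncation cannot bias the centroid
  fx <- seq(-model$semi_x_m, model$semi_x_m,
            length.out = 2L * ceiling(model$semi_x_m / fp) + 1L)
  fy <- seq(-model$semi_y_m, model$semi_y_m,
            length.out = 2L * ceiling(model$semi_y_m / fp) + 1L)
  fg <- expand.grid(xf = fx, yf = fy)

  pad <- plan$pad_frames
  frames <- array(0, dim = c(spec$n_rows, spec$n_cols, n_fr + 2L * pad))
  cop <- matrix(NA_real_, n_fr, 2)
  peak_fine <- numeric(nrow(fg))
  active_any <- rep(FALSE, n_fr)
  for (k in seq_len(n_fr)) {
    tau <- (k - 0.5) / n_fr
    v <- foot_field(model, plan, ff$xf, ff$yf, tau)
    if (any(v > 0)) {
      frames[cbind(grid$row, grid$col, k + pad)] <- v
      active_any[k] <- TRUE
    }
    vf <- foot_field(model, plan, fg$xf, fg$yf, tau)
    peak_fine <- pmax(peak_fine, vf)
    sel <- vf >= mask_threshold_kpa
    if (any(sel)) {
      w <- vf[sel]
      cf <- c(sum(w * fg$xf[sel]), sum(w * fg$yf[sel])) / sum(w)
      cp <- foot_to_plate(model, placement, cf[1], cf[2])
      cop[k, ] <- c(cp$x, cp$y)
    }
  }

  # ground-truth voxel mask at the activation threshold (record grid)
  midx <- which(frames >= mask_threshold_kpa)
  d <- dim(frames)
  mask <- data.frame(
    t = ((midx - 1L) %/% (d[1] * d[2])) + 1L,
    row = ((midx - 1L) %% d[1]) + 1L,
    col = (((midx - 1L) %/% d[1]) %% d[2]) + 1L
  )

  # ROI loci in the foot frame: digit centres from the model, pad / heel from
  # the oversampled peak field.
  fsel <- peak_fine >= mask_threshold_kpa
  if (!any(fsel)) stop("generated field never reaches the activation threshold",
                       call. = FALSE)
  pad_locus <- c(mean(fg$xf[fsel]), mean(fg$yf[fsel]))
  mid <- fsel & abs(fg$xf - pad_locus[1]) <= fp
  heel_locus <- c(pad_locus[1], min(fg$yf[mid]))
  loci_f <- rbind(model$digit_centres, roi6 = pad_locus, roi7 = heel_locus)
  loci_p <- foot_to_plate(model, placement, loci_f[, 1], loci_f[, 2])
  pix <- data.frame(
    row = pmin(pmax(round(loci_p$y / spec$pitch_y_m + 0.5), 2L), spec$n_rows - 1L),
    col = pmin(pmax(round(loci_p$x / spec$pitch_x_m + 0.5), 2L), spec$n_cols - 1L)
  )
  # snap each digitized pixel onto the sampled supra-threshold mask (an
  # isocontour locus can round to a cell whose sampled value is just below it)
  peak_img <- apply(frames, c(1, 2), max)
  for (i in seq_len(nrow(pix))) {
    if (peak_img[pix$row[i], pix$col[i]] >= mask_threshold_kpa) next
    win_r <- pmin(pmax(pix$row[i] + (-1:1), 1L), spec$n_rows)
    win_c <- pmin(pmax(pix$col[i] + (-1:1), 1L), spec$n_cols)
    sub <- peak_img[win_r, win_c]
    if (any(sub >= mask_threshold_kpa)) {
      k <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      pix$row[i] <- win_r[k[1]]
      pix$col[i] <- win_c[k[2]]
    }
  }
  # regional peak at each locus = 3x3 sigma-1 kernel applied to the
  # max-over-stance continuous field at the cell centres around the pixel
  w3 <- kernel3_weights(1)
  peaks <- vapply(seq_len(7L), function(i) {
    orow <- rep(pix$row[i] + (-1:1), times = 3)
    ocol <- rep(pix$col[i] + (-1:1), each = 3)
    pf <- plate_to_foot(model, placement, cell_x(ocol, spec), cell_y(orow, spec))
    pk <- numeric(9L)
    for (k in seq_len(n_fr)) {
      pk <- pmax(pk, foot_field(model, plan, pf$xf, pf$yf, (k - 0.5) / n_fr))
    }
    sum(as.vector(w3) * pk)
  }, numeric(1))

  foot_label <- paste0(
    if (model$foot_type == "fore") "F" else "H",
    if (model$side == "left") "L" else "R"
  )
  complete_spatial <- !off_edge &&
    !any(mask$row %in% c(1L, spec$n_rows) | mask$col %in% c(1L, spec$n_cols))
  truth <- list(
    foot_label = foot_label,
    mask = mask,
    cop = data.frame(
      frame = which(!is.na(cop[, 1])) + pad,
      x_m = cop[!is.na(cop[, 1]), 1], y_m = cop[!is.na(cop[, 1]), 2]
    ),
    roi = data.frame(
      roi = 1:7,
      locus_x_m = loci_p$x, locus_y_m = loci_p$y,
      row = pix$row, col = pix$col,
      peak_kpa = peaks
    ),
    complete_spatial = complete_spatial,
    complete_temporal = TRUE,
    threshold_kpa = mask_threshold_kpa
  )
  record <- pressure_record(frames, spec,
                            t0 = placement$onset_s %||% 0 - pad / spec$freq_hz)
  list(record = record, truth = truth)
}

#' Generate a full synthetic walkway trial
#'
#' Superimposes one footstep per row of `plan$steps` (frame-wise sum of the
#' individual noise-free footstep records), then adds a single trial-level
#' realization of i.i.d. Gaussian sensor noise, clipped at zero. Ground truth
#' carries per-step voxel masks, foot identities, COP paths, ROI peaks and
#' completeness flags; a step whose mask touches the plate boundary is
#' flagged spatially incomplete, and clipped (half-off-plate) placements are
#' permitted.
#'
#' @inheritParams generate_footstep
#' @param models Named list of [foot_model()] objects keyed by the foot labels
#'   used in `plan$steps` (see [default_foot_models()]).
#' @return List with `record` (noisy trial) and `truth` (list with per-step
#'   truths on the trial timeline, the noise level and seed).
#' @export
generate_trial <- function(models, plan, spec = plate_spec(),
                           truth_oversample = 3L, mask_threshold_kpa = 5) {
  steps <- plan$steps
  pad <- plan$pad_frames
  n_fr <- round(plan$stance_s * spec$freq_hz)
  onset_frame <- round(steps$onset_s * spec$freq_hz)
  onset_frame <- onset_frame - min(onset_frame)
  n_total <- max(onset_frame) + n_fr + 2L * pad
  frames <- array(0, dim = c(spec$n_rows, spec$n_cols, n_total))
  step_truths <- vector("list", nrow(steps))
  single_plan <- plan
  single_plan$pad_frames <- 0L
  for (i in seq_len(nrow(steps))) {
    lab <- steps$foot[i]
    if (is.null(models[[lab]])) stop("no foot model for label ", lab, call. = FALSE)
    fs <- generate_footstep(
      models[[lab]], single_plan,
      list(x_m = steps$x_m[i], y_m = steps$y_m[i],
           heading_deg = steps$heading_deg[i]),
      spec = spec, clip = TRUE, truth_oversample = truth_oversample,
      mask_threshold_kpa = mask_threshold_kpa
    )
    off <- pad + onset_frame[i]
    frames[, , off + seq_len(n_fr)] <- frames[, , off + seq_len(n_fr)] +
      fs$record$frames
    tr <- fs$truth
    tr$mask$t <- tr$mask$t + off
    tr$cop$frame <- tr$cop$frame + off
    step_truths[[i]] <- tr
  }
  if (plan$noise_sd_kpa > 0) {
    set.seed(plan$seed)
    frames <- pmax(frames + stats::rnorm(length(frames), 0, plan$noise_sd_kpa), 0)
  }
  list(
    record = pressure_record(frames, spec, t0 = 0),
    truth = list(
      steps = step_truths, noise_sd_kpa = plan$noise_sd_kpa,
      seed = plan$seed, threshold_kpa = mask_threshold_kpa
    )
  )
}
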