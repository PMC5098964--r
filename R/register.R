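#' Rigid 2D transform
#'
#' Translation (in sensor cells; `dx` along columns / mediolateral, `dy`
#' along rows / cranio-caudal) plus rotation about a centre point. When
#' `centre` is `NULL` the rotation centre defaults to the active-pixel
#' centroid of whichever image the transform is applied to, which decouples
#' rotation from translation in the registration search. An optional
#' `reflect` flag mirrors the image about the vertical (constant-x) axis
#' through the centre before rotating; it stays off for within-foot
#' registration.
#'
#' @param dx_cells,dy_cells Translation in cells.
#' @param theta_deg Rotation in degrees (counter-clockwise in (x, y)).
#' @param centre Optional rotation centre `c(col, row)` in cell units.
#' @param reflect Mirror about the vertical axis through the centre.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx_cells = 0, dy_cells = 0, theta_deg = 0,
                            centre = NULL, reflect = FALSE) {
  structure(
    list(dx_cells = dx_cells, dy_cells = dy_cells, theta_deg = theta_deg,
         centre = centre, reflect = isTRUE(reflect)),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dx %.2f dy %.2f cells, theta %.2f deg%s\n",
              x$dx_cells, x$dy_cells, x$theta_deg,
              if (x$reflect) ", reflected" else ""))
  invisible(x)
}

# Forward-map points (col, row) under a transform with a resolved centre.
transform_points <- function(pts, tf, centre) {
  x <- pts[, 1] - centre[1]
  y <- pts[, 2] - centre[2]
  if (tf$reflect) x <- -x
  th <- tf$theta_deg * pi / 180
  cbind(
    cos(th) * x - sin(th) * y + centre[1] + tf$dx_cells,
    sin(th) * x + cos(th) * y + centre[2] + tf$dy_cells
  )
}

active_centroid <- function(values) {
  act <- which(values > 0, arr.ind = TRUE)
  if (!nrow(act)) stop("image has no active pixels", call. = FALSE)
  c(mean(act[, 2]), mean(act[, 1])) # (col, row)
}

#' Peak-pressure image of a footstep
#'
#' Each pixel holds the maximum pressure attained at that sensor cell over
#' the step's stance; never-active cells hold 0. This is the unit of ROI
#' analysis and registration.
#'
#' @param step A [footstep_series()].
#' @return An object of class `peak_pressure_image` (fields `values`
#'   matrix, `spec`, `foot_label`).
#' @export
peak_pressure_image <- function(step) {
  stopifnot(inherits(step, "footstep_series"))
  spec <- step$spec
  v <- step$voxels
  dt <- data.table::data.table(row = v$row, col = v$col, p = v$p)
  mx <- dt[, list(p = max(p)), by = c("row", "col")]
  m <- matrix(0, spec$n_rows, spec$n_cols)
  m[cbind(mx$row, mx$col)] <- mx$p
  structure(
    list(values = m, spec = spec, foot_label = step$foot_label),
    class = "peak_pressure_image"
  )
}

#' @export
print.peak_pressure_image <- function(x, ...) {
  cat(sprintf("<peak_pressure_image> %s: %d active px, max %.1f kPa\n",
              x$foot_label, sum(x$values > 0), max(x$values)))
  invisible(x)
}

#' Select the registration template
#'
#' The template is the first (in acquisition order) peak-pressure image whose
#' footstep is both spatially and temporally complete; its mask is the
#' isocontour at `iso_threshold_kpa`.
#'
#' @param images List of [peak_pressure_image()] in acquisition order.
#' @param flags Data frame or list of logical pairs with elements
#'   `complete_spatial`, `complete_temporal`, one per image.
#' @param iso_threshold_kpa Template isocontour threshold (kPa).
#' @param min_active Minimum number of active template pixels.
#' @return An object of class `template_image`; also records the chosen index
#'   as field `source_index`.
#' @export
select_template <- function(images, flags, iso_threshold_kpa = 5,
                            min_active = 20L) {
  if (is.data.frame(flags)) {
    flags <- lapply(seq_len(nrow(flags)), function(i) flags[i, ])
  }
  stopifnot(length(images) == length(flags))
  for (i in seq_along(images)) {
    f <- flags[[i]]
    if (isTRUE(as.logical(f[["complete_spatial"]])) &&
        isTRUE(as.logical(f[["complete_temporal"]]))) {
      img <- images[[i]]
      mask <- img$values >= iso_threshold_kpa
      if (sum(mask) < min_active) {
        stop("template candidate has fewer than ", min_active,
             " active pixels at the isocontour", call. = FALSE)
      }
      return(structure(
        list(values = img$values, spec = img$spec,
             foot_label = img$foot_label,
             iso_threshold_kpa = iso_threshold_kpa, mask = mask,
             source_index = i),
        class = c("template_image", "peak_pressure_image")
      ))
    }
  }
  stop("no spatio-temporally complete image available for a template",
       call. = FALSE)
}

# Bilinear (or nearest) sample of matrix `m` at fractional (row, col); zero
# outside the grid.
sample_image <- function(m, rr, cc, interp = "bilinear") {
  nr <- nrow(m); nc <- ncol(m)
  out <- numeric(length(rr))
  if (interp == "nearest") {
    ri <- round(rr); ci <- round(cc)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  val(r0, c0) * (1 - fr) * (1 - fc) +
    val(r0 + 1L, c0) * fr * (1 - fc) +
    val(r0, c0 + 1L) * (1 - fr) * fc +
    val(r0 + 1L, c0 + 1L) * fr * fc
}

#' Apply a rigid transform to a peak-pressure image
#'
#' The output is resampled on the same sensor grid by inverse mapping with
#' bilinear interpolation (nearest-neighbour available for mass-conservation
#' checks); samples falling outside the grid are zero. Integer translations
#' are exact.
#'
#' @param image A [peak_pressure_image()] (or plain matrix).
#' @param tf A [rigid_transform()].
#' @param interp `"bilinear"` or `"nearest"`.
#' @return Transformed image of the same class.
#' @export
apply_transform <- function(image, tf, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  is_img <- inherits(image, "peak_pressure_image")
  m <- if (is_img) image$values else image
  centre <- tf$centre
  if (is.null(centre)) centre <- active_centroid(m)
  out <- transform_matrix(m, tf, centre, interp)
  if (is_img) {
    res <- image
    res$values <- out
    res
  } else {
    out
  }
}

transform_matrix <- function(m, tf, centre, interp = "bilinear") {
  nr <- nrow(m); nc <- ncol(m)
  # inverse map output pixel centres back into the source image
  gc <- rep(seq_len(nc), each = nr)
  gr <- rep(seq_len(nr), times = nc)
  x <- gc - centre[1] - tf$dx_cells
  y <- gr - centre[2] - tf$dy_cells
  th <- -tf$theta_deg * pi / 180
  xs <- cos(th) * x - sin(th) * y
  ys <- sin(th) * x + cos(th) * y
  if (tf$reflect) xs <- -xs
  matrix(sample_image(m, ys + centre[2], xs + centre[1], interp), nr, nc)
}

mse_union_support <- function(a, b) {
  sup <- (a > 0) | (b > 0)
  if (!any(sup)) return(Inf)
  mean((a[sup] - b[sup])^2)
}

#' Register a source footprint to a template
#'
#' Finds the rigid transform minimizing the mean squared pressure difference
#' over the union of the two active supports. The search is a coarse grid
#' (translation within `trans_range` cells in steps of 1; rotation within
#' `rot_range` degrees in steps of `rot_step`) followed by Nelder-Mead
#' refinement. The bounded rotation range deliberately avoids the
#' symmetry-flip failure mode of unconstrained automatic registration on
#' near-symmetric footprints; a manual transform can always be applied with
#' [apply_transform()] instead.
#'
#' @param source,template [peak_pressure_image()] / [select_template()]
#'   output from the same foot.
#' @param trans_range Translation search half-range in cells.
#' @param rot_range,rot_step Rotation search half-range and coarse step
#'   (degrees).
#' @param refine Run local refinement after the coarse grid.
#' @return A [rigid_transform()] whose `centre` is fixed at the source
#'   active-pixel centroid (so the same transform can be re-applied to the
#'   step's frame series).
#' @export
register_to_template <- function(source, template, trans_range = 10L,
                                 rot_range = 20, rot_step = 2, refine = TRUE) {
  src <- if (inherits(source, "peak_pressure_image")) source$values else source
  tpl <- if (inherits(template, "peak_pressure_image")) template$values else template
  if (!is.null(source$foot_label) && !is.null(template$foot_label) &&
      !identical(source$foot_label, template$foot_label) &&
      source$foot_label != "unknown" && template$foot_label != "unknown") {
    stop("source and template are from different feet", call. = FALSE)
  }
  centre_full <- active_centroid(src)

  # crop to the union of active bounding boxes plus search margin
  act <- which(src > 0 | tpl > 0, arr.ind = TRUE)
  mar <- trans_range + 4L
  r1 <- max(1L, min(act[, 1]) - mar); r2 <- min(nrow(src), max(act[, 1]) + mar)
  c1 <- max(1L, min(act[, 2]) - mar); c2 <- min(ncol(src), max(act[, 2]) + mar)
  s <- src[r1:r2, c1:c2]
  tp <- tpl[r1:r2, c1:c2]
  centre <- c(centre_full[1] - c1 + 1, centre_full[2] - r1 + 1)

  shifts <- -trans_range:trans_range
  thetas <- seq(-rot_range, rot_range, by = rot_step)
  if (!0 %in% thetas) thetas <- sort(c(thetas, 0))
  nr <- nrow(s); nc <- ncol(s)
  best <- list(mse = Inf, dx = 0, dy = 0, theta = 0)
  for (th in thetas) {
    rot <- if (th == 0) s else
      transform_matrix(s, rigid_transform(0, 0, th), centre)
    for (dy in shifts) {
      rs_to <- max(1, 1 + dy):min(nr, nr + dy)
      rs_from <- rs_to - dy
      for (dx in shifts) {
        cs_to <- max(1, 1 + dx):min(nc, nc + dx)
        cs_from <- cs_to - dx
        sh <- matrix(0, nr, nc)
        sh[rs_to, cs_to] <- rot[rs_from, cs_from]
        mse <- mse_union_support(sh, tp)
        if (mse < best$mse) best <- list(mse = mse, dx = dx, dy = dy, theta = th)
      }
    }
  }
  if (!is.finite(best$mse)) {
    stop("registration failed: no overlapping support in the search range",
         call. = FALSE)
  }
  if (refine) {
    obj <- function(par) {
      tf <- rigid_transform(par[1], par[2], par[3])
      mse_union_support(transform_matrix(s, tf, centre), tp)
    }
    opt <- stats::optim(c(best$dx, best$dy, best$theta), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    if (opt$value <= best$mse) {
      best <- list(mse = opt$value, dx = opt$par[1], dy = opt$par[2],
                   theta = opt$par[3])
    }
  }
  tf <- rigid_transform(best$dx, best$dy, best$theta, centre = centre_full)
  attr(tf, "mse") <- best$mse
  tf
}

#' Re-apply a footprint transform to the pressure time series
#'
#' Applies the transform obtained on the step's peak-pressure image to every
#' frame of the step, with the rotation centre fixed at the peak image's
#' active-pixel centroid, so that the peak image of the output equals the
#' transformed peak image of the input up to interpolation.
#'
#' @param step A [footstep_series()].
#' @param tf A [rigid_transform()] (ideally from [register_to_template()],
#'   with `centre` set).
#' @param interp Interpolation scheme, as in [apply_transform()].
#' @return The transformed [footstep_series()].
#' @export
apply_transform_to_series <- function(step, tf, interp = "bilinear") {
  stopifnot(inherits(step, "footstep_series"))
  spec <- step$spec
  centre <- tf$centre
  if (is.null(centre)) centre <- active_centroid(peak_pressure_image(step)$values)
  fr <- step_frames(step)
  tmin <- step$t_range[1]
  vox <- vector("list", dim(fr)[3])
  for (k in seq_len(dim(fr)[3])) {
    out <- transform_matrix(fr[, , k], tf, centre, interp)
    idx <- which(out > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      vox[[k]] <- data.frame(
        t = tmin + k - 1L, row = idx[, 1], col = idx[, 2], p = out[idx]
      )
    }
  }
  vox <- do.call(rbind, vox)
  footstep_series(vox, spec, step$n_frames_record,
                  foot_label = step$foot_label,
                  complete_spatial = step$complete_spatial,
                  complete_temporal = step$complete_temporal)
}
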