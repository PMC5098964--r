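#' The seven anatomical regions of interest
#'
#' ROIs 1-5 are the midpoints of the bottom surfaces of the nails of digits
#' i-v (medial to lateral), ROI 6 the middle of the foot sole (slipper) and
#' ROI 7 the caudal-most (heel) aspect of the sole, all as pixel coordinates
#' on the registered template grid. Each ROI carries four one-pixel
#' sensitivity neighbours (above, below, left, right).
#'
#' @param points Data frame with columns `roi` (1..7), `row`, `col`.
#' @param foot_label Foot the set belongs to.
#' @param template Optional [select_template()] output; when given, points
#'   are checked to lie inside the template's active mask.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(points, foot_label = "unknown", template = NULL) {
  points <- as.data.frame(points)
  stopifnot(all(c("roi", "row", "col") %in% names(points)))
  points <- points[order(points$roi), c("roi", "row", "col")]
  if (!identical(as.integer(points$roi), 1:7)) {
    stop("an roi_set needs exactly the seven ROIs 1..7", call. = FALSE)
  }
  if (!is.null(template)) {
    inside <- template$mask[cbind(points$row, points$col)]
    if (!all(inside)) {
      stop("ROI(s) ", paste(points$roi[!inside], collapse = ", "),
           " fall outside the template active mask", call. = FALSE)
    }
  }
  structure(list(points = points, foot_label = foot_label), class = "roi_set")
}

# position offsets (grid rows increase cranially)
roi_positions <- function() {
  data.frame(
    position = c("centre", "above", "below", "left", "right"),
    d_row = c(0L, 1L, -1L, 0L, 0L),
    d_col = c(0L, 0L, 0L, -1L, 1L),
    is_primary = c(TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Pixel-wise mean of registered peak-pressure images
#'
#' @param images Non-empty list of [peak_pressure_image()] on one template
#'   grid.
#' @return A [peak_pressure_image()] holding the arithmetic mean.
#' @export
mean_image <- function(images) {
  if (!length(images)) stop("no images to average", call. = FALSE)
  mats <- lapply(images, function(im) {
    if (inherits(im, "peak_pressure_image")) im$values else im
  })
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1)))) {
    stop("images are not on a common grid", call. = FALSE)
  }
  out <- Reduce(`+`, mats) / length(mats)
  first <- images[[1]]
  if (inherits(first, "peak_pressure_image")) {
    res <- first
    res$values <- out
    res
  } else {
    out
  }
}

#' Gaussian smoothing of a pressure image
#'
#' Separable discrete Gaussian convolution with reflective borders, used for
#' display interpolation between pressure grid points. It is *not* part of
#' ROI extraction, which applies its own kernel (see [extract_roi_peak()]).
#'
#' @param image A [peak_pressure_image()] or matrix.
#' @param sigma_px Kernel standard deviation in pixels; 0 is the identity.
#' @return Smoothed image of the same class.
#' @export
smooth_gaussian <- function(image, sigma_px) {
  if (sigma_px < 0) stop("`sigma_px` must be non-negative", call. = FALSE)
  is_img <- inherits(image, "peak_pressure_image")
  m <- if (is_img) image$values else image
  if (sigma_px > 0) {
    rad <- max(1L, ceiling(3 * sigma_px))
    k <- stats::dnorm(-rad:rad, sd = sigma_px)
    k <- k / sum(k)
    m <- conv_reflect(m, k, rad, along_rows = TRUE)
    m <- conv_reflect(m, k, rad, along_rows = FALSE)
  }
  if (is_img) {
    res <- image
    res$values <- m
    res
  } else {
    m
  }
}

conv_reflect <- function(m, k, rad, along_rows = TRUE) {
  n <- if (along_rows) nrow(m) else ncol(m)
  pad_idx <- c(rad:1, 1:n, n:(n - rad + 1L)) # scipy-style 'reflect'
  if (along_rows) {
    mp <- m[pad_idx, , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
    }
  } else {
    mp <- m[, pad_idx, drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[, (j - 1L) + seq_len(ncol(m)), drop = FALSE]
    }
  }
  out
}

#' Gaussian-kernel peak pressure at one ROI
#'
#' The regional peak pressure is the Gaussian-weighted average of the image
#' over a 3 x 3 pixel window centred on the ROI, with a kernel standard
#' deviation of one pixel and weights renormalized over the window. (A
#' "3-pixel area" with a sigma = 1 px kernel is read as the 3 x 3 window —
#' the only size compatible with the four one-pixel sensitivity neighbours;
#' both are configurable.)
#'
#' @param image A [peak_pressure_image()] or matrix.
#' @param point ROI pixel as `c(row, col)` or a one-row data frame.
#' @param sigma_px Kernel standard deviation (pixels).
#' @param window Odd window width in pixels.
#' @param roi_label Label used in border-error messages.
#' @return Peak pressure in kPa.
#' @export
extract_roi_peak <- function(image, point, sigma_px = 1, window = 3L,
                             roi_label = NULL) {
  m <- if (inherits(image, "peak_pressure_image")) image$values else image
  if (is.data.frame(point)) point <- c(point$row[1], point$col[1])
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be odd and positive", call. = FALSE)
  }
  h <- (window - 1L) %/% 2L
  rows <- point[1] + (-h:h)
  cols <- point[2] + (-h:h)
  if (min(rows) < 1L || max(rows) > nrow(m) || min(cols) < 1L || max(cols) > ncol(m)) {
    stop(sprintf("ROI %s window clipped by the image border",
                 roi_label %||% sprintf("(%d, %d)", point[1], point[2])),
         call. = FALSE)
  }
  o <- -h:h
  w <- outer(exp(-o^2 / (2 * sigma_px^2)), exp(-o^2 / (2 * sigma_px^2)))
  w <- w / sum(w)
  sum(w * m[rows, cols])
}

#' Placement-sensitivity table for one image
#'
#' For each of the seven ROIs, extracts the regional peak pressure at the
#' digitized point and at its four one-pixel neighbours (above, below, left,
#' right): 35 rows per image, with the digitized point flagged as primary.
#' Downstream summaries use the mean over the five positions per ROI.
#'
#' @param image A [peak_pressure_image()] or matrix.
#' @param rois An [roi_set()].
#' @inheritParams extract_roi_peak
#' @return A [tibble::tibble()] with columns `foot`, `roi`, `position`,
#'   `is_primary`, `row`, `col`, `peak_pressure_kpa`.
#' @export
sensitivity_table <- function(image, rois, sigma_px = 1, window = 3L) {
  pos <- roi_positions()
  rows <- lapply(seq_len(nrow(rois$points)), function(i) {
    pt <- rois$points[i, ]
    vals <- vapply(seq_len(nrow(pos)), function(j) {
      extract_roi_peak(
        image, c(pt$row + pos$d_row[j], pt$col + pos$d_col[j]),
        sigma_px = sigma_px, window = window,
        roi_label = sprintf("%d/%s", pt$roi, pos$position[j])
      )
    }, numeric(1))
    tibble::tibble(
      foot = rois$foot_label, roi = pt$roi, position = pos$position,
      is_primary = pos$is_primary,
      row = pt$row + pos$d_row, col = pt$col + pos$d_col,
      peak_pressure_kpa = vals
    )
  })
  dplyr::bind_rows(rows)
}

#' Digitize the seven ROIs on a template
#'
#' Manual mode stores supplied pixel coordinates verbatim (the standard
#' approach on real data, read from a `foot,roi,row,col` CSV). Automatic mode
#' exists to run the synthetic pipeline unattended: ROIs 1-5 are the five
#' cranial local maxima of the template ordered medial to lateral (using the
#' foot side to orient the medial axis), ROI 6 is the active-mask centroid
#' and ROI 7 the caudal-most active pixel on the mask midline.
#'
#' @param template A [select_template()] output.
#' @param mode `"auto"` or `"manual"`.
#' @param points Data frame `roi,row,col` (manual mode).
#' @return An [roi_set()].
#' @export
digitize_rois <- function(template, mode = c("auto", "manual"), points = NULL) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    if (is.null(points)) stop("manual mode needs `points`", call. = FALSE)
    return(roi_set(points, foot_label = template$foot_label, template = template))
  }
  v <- template$values
  mask <- template$mask
  cen <- c(row = mean(which(mask, arr.ind = TRUE)[, 1]),
           col = mean(which(mask, arr.ind = TRUE)[, 2]))
  # strict 8-neighbour local maxima inside the mask
  nr <- nrow(v); nc <- ncol(v)
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    nb[rs, cs] <- v[rs - dr, cs - dc]
    is_max <- is_max & (v > nb)
  }
  cand <- which(is_max & mask, arr.ind = TRUE)
  cand <- cand[cand[, 1] > cen["row"], , drop = FALSE] # cranial half
  if (nrow(cand) > 5L) {
    stop(sprintf(
      "auto digitization found %d cranial maxima (need 5); supply manual points",
      nrow(cand)
    ), call. = FALSE)
  }
  if (nrow(cand) < 5L) {
    # a digit peak can collapse into a shoulder of a stronger neighbour after
    # resampling; recover it by non-maximum suppression over cranial pixels
    min_sep <- 3
    pool <- which(mask, arr.ind = TRUE)
    pool <- pool[pool[, 1] > cen["row"], , drop = FALSE]
    pool <- pool[order(v[pool], decreasing = TRUE), , drop = FALSE]
    picked <- cand
    for (i in seq_len(nrow(pool))) {
      if (nrow(picked) >= 5L) break
      p <- pool[i, ]
      if (nrow(picked) == 0L ||
          all((picked[, 1] - p[1])^2 + (picked[, 2] - p[2])^2 >= min_sep^2)) {
        picked <- rbind(picked, p)
      }
    }
    cand <- picked
  }
  if (nrow(cand) != 5L) {
    stop(sprintf(
      "auto digitization found %d digit peaks (need 5); supply manual points",
      nrow(cand)
    ), call. = FALSE)
  }
  side <- substr(template$foot_label, 2L, 2L)
  ordc <- order(cand[, 2], decreasing = identical(side, "R"))
  digits <- cand[ordc, , drop = FALSE] # medial -> lateral

  mid <- which(mask, arr.ind = TRUE)
  mid <- mid[abs(mid[, 2] - cen["col"]) <= 1, , drop = FALSE]
  heel <- mid[which.min(mid[, 1]), ]
  cen_pix <- c(round(cen["row"]), round(cen["col"]))
  if (!mask[cen_pix[1], cen_pix[2]]) {
    # snap the sole centre onto the nearest mask pixel
    all_pix <- which(mask, arr.ind = TRUE)
    k <- which.min((all_pix[, 1] - cen["row"])^2 + (all_pix[, 2] - cen["col"])^2)
    cen_pix <- all_pix[k, ]
  }
  pts <- data.frame(
    roi = 1:7,
    row = c(digits[, 1], cen_pix[1], heel[1]),
    col = c(digits[, 2], cen_pix[2], heel[2])
  )
  roi_set(pts, foot_label = template$foot_label, template = template)
}

#' Read manual ROI definitions from CSV
#'
#' Expected columns: `foot,roi,row,col` (0-based or 1-based indices as
#' written; `one_based = FALSE` converts from the 0-based file convention).
#'
#' @param path CSV path.
#' @param one_based Whether indices in the file are already 1-based.
#' @return Named list of data frames keyed by foot label, each usable as the
#'   `points` argument of [digitize_rois()].
#' @export
read_roi_csv <- function(path, one_based = TRUE) {
  tb <- read_table(path, schema = c(
    foot = "character", roi = "integer", row = "integer", col = "integer"
  ))
  if (!one_based) {
    tb$row <- tb$row + 1L
    tb$col <- tb$col + 1L
  }
  lapply(split(tb, tb$foot), as.data.frame)
}
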