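#' Segmentation configuration
#'
#' Footsteps are isolated as connected clusters of supra-threshold pressure
#' voxels `(t, row, col)`, where two voxels are connected when their in-plane
#' Chebyshev distance is at most `spatial_gap_cells + 1` **and** their frame
#' distance is at most `temporal_gap_frames + 1`; i.e. gaps of up to
#' `spatial_gap_cells` empty cells and `temporal_gap_frames` empty frames are
#' bridged. Clusters smaller than `min_voxels` are discarded as sensor
#' artefacts.
#'
#' The 5 kPa activation threshold matches the template isocontour used for
#' registration. The gap defaults (2 cells = 2.7 cm, 10 frames = 0.1 s at
#' 100 Hz) are chosen so that an elephant footprint never splits across its
#' own internal pressure minima while successive footfalls never merge.
#'
#' @param p_threshold_kpa Activation threshold in kPa.
#' @param spatial_gap_cells Largest in-plane gap (cells) bridged.
#' @param temporal_gap_frames Largest temporal gap (frames) bridged.
#' @param min_voxels Minimum cluster size kept.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(p_threshold_kpa = 5, spatial_gap_cells = 2L,
                                temporal_gap_frames = 10L, min_voxels = 20L) {
  if (p_threshold_kpa <= 0 || spatial_gap_cells < 0 || temporal_gap_frames < 0 ||
      min_voxels < 1) {
    stop("segmentation parameters must be positive", call. = FALSE)
  }
  structure(
    list(
      p_threshold_kpa = p_threshold_kpa,
      spatial_gap_cells = as.integer(spatial_gap_cells),
      temporal_gap_frames = as.integer(temporal_gap_frames),
      min_voxels = as.integer(min_voxels)
    ),
    class = "segmentation_config"
  )
}

#' One isolated footstep
#'
#' @param voxels Data frame with columns `t`, `row`, `col`, `p` (1-based
#'   indices into the parent record, pressures in kPa).
#' @param spec The parent record's [plate_spec()].
#' @param n_frames_record Frame count of the parent record.
#' @param foot_label One of `"FL"`, `"FR"`, `"HL"`, `"HR"`, `"unknown"`.
#' @param complete_spatial,complete_temporal Completeness flags (may be `NA`
#'   until [assess_completeness()] has run).
#' @return An object of class `footstep_series`.
#' @export
footstep_series <- function(voxels, spec, n_frames_record,
                            foot_label = "unknown",
                            complete_spatial = NA, complete_temporal = NA) {
  stopifnot(all(c("t", "row", "col", "p") %in% names(voxels)))
  if (nrow(voxels) == 0L) stop("a footstep needs at least one voxel", call. = FALSE)
  voxels <- voxels[order(voxels$t, voxels$row, voxels$col), , drop = FALSE]
  rownames(voxels) <- NULL
  structure(
    list(
      voxels = voxels, spec = spec,
      n_frames_record = as.integer(n_frames_record),
      t_range = range(voxels$t),
      bbox = c(row_min = min(voxels$row), row_max = max(voxels$row),
               col_min = min(voxels$col), col_max = max(voxels$col)),
      foot_label = foot_label,
      complete_spatial = complete_spatial,
      complete_temporal = complete_temporal
    ),
    class = "footstep_series"
  )
}

#' @export
print.footstep_series <- function(x, ...) {
  cat(sprintf(
    "<footstep_series> %s: %d voxels, frames %d-%d, rows %d-%d, cols %d-%d\n",
    x$foot_label, nrow(x$voxels), x$t_range[1], x$t_range[2],
    x$bbox["row_min"], x$bbox["row_max"], x$bbox["col_min"], x$bbox["col_max"]
  ))
  invisible(x)
}

#' Reconstruct the dense frame stack of a footstep
#'
#' @param step A [footstep_series()].
#' @return Array `(n_rows, n_cols, n_frames)` on the step's own time window
#'   (frame 1 = `step$t_range[1]` of the parent record), zero outside the
#'   step's voxels.
#' @export
step_frames <- function(step, full_grid = TRUE) {
  spec <- step$spec
  tmin <- step$t_range[1]
  nt <- step$t_range[2] - tmin + 1L
  fr <- array(0, dim = c(spec$n_rows, spec$n_cols, nt))
  fr[cbind(step$voxels$row, step$voxels$col, step$voxels$t - tmin + 1L)] <-
    step$voxels$p
  fr
}

# --- connected-component machinery -----------------------------------------

# 8-connected components of a logical matrix, by iterative label propagation.
# Returns an integer matrix of labels (0 = background).
label_components_2d <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  big <- sum(mask) + 1L
  repeat {
    m <- matrix(big, nr, nc)
    m[mask] <- lab[mask]
    best <- m
    shift <- function(mm, dr, dc) {
      out <- matrix(big, nr, nc)
      r1 <- max(1, 1 + dr); r2 <- min(nr, nr + dr)
      c1 <- max(1, 1 + dc); c2 <- min(nc, nc + dc)
      if (r1 > r2 || c1 > c2) return(out)
      out[r1:r2, c1:c2] <- mm[(r1:r2) - dr, (c1:c2) - dc]
      out
    }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      best <- pmin(best, shift(m, dr, dc))
    }
    new_lab <- lab
    upd <- mask & best < lab
    if (!any(upd)) break
    new_lab[upd] <- best[upd]
    lab <- new_lab
  }
  lab
}

# TRUE iff min Chebyshev distance between two in-plane point sets is <= d.
cheb_within <- function(r1, c1, r2, c2, d) {
  if (min(r2) - max(r1) > d || min(r1) - max(r2) > d ||
      min(c2) - max(c1) > d || min(c1) - max(c2) > d) {
    return(FALSE)
  }
  # direct overlap fast path
  if (d >= 0 && anyDuplicated(c(r1 * 100000L + c1, r2 * 100000L + c2)) > 0) {
    return(TRUE)
  }
  n1 <- length(r1); n2 <- length(r2)
  if (as.double(n1) * n2 <= 4e6) {
    dr <- abs(outer(r1, r2, "-"))
    dc <- abs(outer(c1, c2, "-"))
    return(any(pmax(dr, dc) <= d))
  }
  # large sets: rasterize set 1 dilated by d into a cropped window
  rmin <- min(r1, r2) - d; cmin <- min(c1, c2) - d
  nr <- max(r1, r2) - rmin + 1L + d; nc <- max(c1, c2) - cmin + 1L + d
  m <- matrix(FALSE, nr, nc)
  for (dr in -d:d) for (dc in -d:d) {
    m[cbind(r1 - rmin + 1L + dr, c1 - cmin + 1L + dc)] <- TRUE
  }
  any(m[cbind(r2 - rmin + 1L, c2 - cmin + 1L)])
}

# minimal union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Isolate individual footsteps from a pressure record
#'
#' Thresholds the record at `config$p_threshold_kpa` and partitions the
#' supra-threshold voxels into connected clusters using the spatio-temporal
#' gap rule of [segmentation_config()]. Every supra-threshold voxel belongs
#' to exactly one returned step or to a discarded cluster smaller than
#' `min_voxels` (available in the `"discarded"` attribute of the result).
#'
#' @param record A [pressure_record()].
#' @param config A [segmentation_config()].
#' @return List of [footstep_series()] in order of onset frame, with
#'   attribute `"discarded"` (data frame of voxels in sub-minimum clusters).
#' @export
segment_steps <- function(record, config = segmentation_config()) {
  stopifnot(inherits(record, "pressure_record"))
  spec <- record$spec
  d_s <- config$spatial_gap_cells + 1L
  d_t <- config$temporal_gap_frames + 1L
  nfr <- n_frames(record)
  idx <- which(record$frames >= config$p_threshold_kpa)
  empty <- structure(list(), discarded = data.frame(
    t = integer(), row = integer(), col = integer(), p = numeric()
  ))
  if (!length(idx)) return(empty)
  dm <- dim(record$frames)
  vox <- data.frame(
    t = ((idx - 1L) %/% (dm[1] * dm[2])) + 1L,
    row = ((idx - 1L) %% dm[1]) + 1L,
    col = (((idx - 1L) %/% dm[1]) %% dm[2]) + 1L,
    p = record$frames[idx]
  )

  # stage 1: per-frame fine components (cropped 8-connectivity labeling)
  comps <- list()
  for (tt in sort(unique(vox$t))) {
    vt <- vox[vox$t == tt, , drop = FALSE]
    r0 <- min(vt$row); c0 <- min(vt$col)
    m <- matrix(FALSE, max(vt$row) - r0 + 1L, max(vt$col) - c0 + 1L)
    m[cbind(vt$row - r0 + 1L, vt$col - c0 + 1L)] <- TRUE
    lab <- label_components_2d(m)
    ids <- lab[cbind(vt$row - r0 + 1L, vt$col - c0 + 1L)]
    for (u in unique(ids)) {
      sel <- ids == u
      comps[[length(comps) + 1L]] <- list(
        t = tt, row = vt$row[sel], col = vt$col[sel], vox_idx = which(vox$t == tt)[sel]
      )
    }
  }
  nc_ <- length(comps)
  comp_t <- vapply(comps, `[[`, integer(1), "t")

  # stage 2: union components whose voxel sets contain an adjacent pair
  parent <- uf_new(nc_)
  ord <- order(comp_t)
  for (a in seq_len(nc_)) {
    i <- ord[a]
    for (b in seq_len(nc_)) {
      if (b <= a) next
      j <- ord[b]
      if (comp_t[j] - comp_t[i] > d_t) break
      ri <- uf_find(parent, i); rj <- uf_find(parent, j)
      if (ri == rj) next
      if (cheb_within(comps[[i]]$row, comps[[i]]$col,
                      comps[[j]]$row, comps[[j]]$col, d_s)) {
        parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(nc_), function(i) uf_find(parent, i), integer(1))

  steps <- list()
  discarded <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    vi <- unlist(lapply(comps[members], `[[`, "vox_idx"))
    cluster <- vox[vi, , drop = FALSE]
    if (nrow(cluster) >= config$min_voxels) {
      steps[[length(steps) + 1L]] <- footstep_series(cluster, spec, nfr)
    } else {
      discarded[[length(discarded) + 1L]] <- cluster
    }
  }
  if (length(steps)) {
    onset <- vapply(steps, function(s) s$t_range[1], numeric(1))
    steps <- steps[order(onset)]
  }
  attr(steps, "discarded") <- if (length(discarded)) {
    do.call(rbind, discarded)
  } else {
    data.frame(t = integer(), row = integer(), col = integer(), p = numeric())
  }
  steps
}

#' Assess spatio-temporal completeness of a footstep
#'
#' A step is spatially incomplete when any of its voxels lies on the
#' outermost sensor row or column (the print may continue off-plate), and
#' temporally incomplete when it is active in the first or last frame of the
#' record (contact may continue outside the recording window).
#'
#' @param step A [footstep_series()] obtained from `record`.
#' @param record The parent [pressure_record()].
#' @param config A [segmentation_config()] (unused by the border criterion
#'   but kept so alternative criteria can be configured).
#' @return Named logical vector `c(complete_spatial, complete_temporal)`.
#' @export
assess_completeness <- function(step, record, config = segmentation_config()) {
  spec <- record$spec
  v <- step$voxels
  if (any(v$t < 1L | v$t > n_frames(record) |
          v$row < 1L | v$row > spec$n_rows |
          v$col < 1L | v$col > spec$n_cols)) {
    stop("step voxels outside record bounds", call. = FALSE)
  }
  c(
    complete_spatial = !any(v$row %in% c(1L, spec$n_rows) |
                              v$col %in% c(1L, spec$n_cols)),
    complete_temporal = !any(v$t %in% c(1L, n_frames(record)))
  )
}

#' Assign foot identities to segmented steps
#'
#' Left/right is assigned from each step's mediolateral position relative to
#' the trackway centreline (the median `x` of all step centroids; the
#' convention is that the animal walks towards +y with its left feet on the
#' high-x side, which matches the synthetic generator and can be flipped by
#' mirroring the record). Fore/hind uses the footfall sequence: walking
#' elephants place the hind foot close to the print of the ipsilateral
#' forefoot, so within a spatial cluster of successive prints the earlier
#' print is the forefoot. Steps that cannot be resolved are labelled
#' `"unknown"` with a message.
#'
#' @param steps List of [footstep_series()].
#' @param meta Optional [trial_meta()] (reserved for direction hints).
#' @param pair_radius_m Centroid distance below which two prints on the same
#'   side are treated as a fore/hind pair.
#' @return The input list with `foot_label` fields filled in.
#' @export
classify_feet <- function(steps, meta = NULL, pair_radius_m = 0.15) {
  n <- length(steps)
  if (n == 0L) return(steps)
  spec <- steps[[1]]$spec
  cx <- vapply(steps, function(s) {
    sum(s$voxels$p * cell_x(s$voxels$col, spec)) / sum(s$voxels$p)
  }, numeric(1))
  cy <- vapply(steps, function(s) {
    sum(s$voxels$p * cell_y(s$voxels$row, spec)) / sum(s$voxels$p)
  }, numeric(1))
  onset <- vapply(steps, function(s) s$t_range[1], numeric(1))

  side <- rep(NA_character_, n)
  if (n >= 2L && diff(range(cx)) > spec$pitch_x_m) {
    centreline <- stats::median(cx)
    side <- ifelse(cx > centreline, "L",
                   ifelse(cx < centreline, "R", NA_character_))
  }

  role <- rep(NA_character_, n)
  ord <- order(onset)
  paired <- rep(FALSE, n)
  for (a in seq_len(n)) {
    i <- ord[a]
    if (paired[i]) next
    for (b in seq_len(n)) {
      if (b <= a) next
      j <- ord[b]
      if (paired[j]) next
      d <- sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2)
      same_side <- is.na(side[i]) || is.na(side[j]) || side[i] == side[j]
      if (d <= pair_radius_m && same_side) {
        role[i] <- "F"; role[j] <- "H"
        paired[i] <- paired[j] <- TRUE
        break
      }
    }
  }

  for (i in seq_len(n)) {
    if (!is.na(side[i]) && !is.na(role[i])) {
      steps[[i]]$foot_label <- paste0(role[i], side[i])
    } else {
      steps[[i]]$foot_label <- "unknown"
      reason <- if (is.na(side[i])) "no mediolateral centreline" else "no fore/hind pair"
      message(sprintf("step %d labelled unknown: %s", i, reason))
    }
  }
  steps
}
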