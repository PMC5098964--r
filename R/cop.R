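#' Centre-of-pressure trajectories
#'
#' A COP trajectory is the ordered sequence of pressure-weighted centroids of
#' the contact pressure field over the stance phase of one footstep, in
#' physical plate coordinates (metres; x mediolateral, y cranio-caudal).
#'
#' @name cop_trajectory_class
#' @keywords internal
NULL

new_cop_trajectory <- function(frame, frac, x, y, p_total) {
  structure(
    list(frame = frame, frac = frac, x = x, y = y, p_total = p_total,
         n_points = length(x)),
    class = "cop_trajectory"
  )
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cop_trajectory> %d points, x [%.3f, %.3f] m, y [%.3f, %.3f] m\n",
    x$n_points, min(x$x), max(x$x), min(x$y), max(x$y)
  ))
  invisible(x)
}

#' @export
as.data.frame.cop_trajectory <- function(x, ...) {
  data.frame(
    frame = if (is.null(x$frame)) NA_integer_ else x$frame,
    frac = if (is.null(x$frac)) NA_real_ else x$frac,
    x_m = x$x, y_m = x$y,
    p_total_kpa = if (is.null(x$p_total)) NA_real_ else x$p_total
  )
}

cop_points <- function(traj) {
  if (inherits(traj, "cop_trajectory")) cbind(traj$x, traj$y) else as.matrix(traj)
}

#' COP of a single pressure frame
#'
#' Pressure-weighted centroid of the cells at or above the threshold, in
#' physical coordinates; `NULL` when no cell passes (inactive frame).
#'
#' @param frame `n_rows x n_cols` pressure matrix (kPa).
#' @param spec A [plate_spec()].
#' @param threshold_kpa Activation threshold.
#' @return `c(x_m, y_m)` or `NULL`.
#' @export
cop_frame <- function(frame, spec, threshold_kpa = 5) {
  sel <- which(frame >= threshold_kpa, arr.ind = TRUE)
  if (!nrow(sel)) return(NULL)
  w <- frame[sel]
  c(
    x_m = sum(w * cell_x(sel[, 2], spec)) / sum(w),
    y_m = sum(w * cell_y(sel[, 1], spec)) / sum(w)
  )
}

#' COP trajectory of a footstep
#'
#' One point per active frame (frames with at least one cell at or above the
#' threshold), in time order; inactive frames are skipped. Stance fraction is
#' `(frame - first_active) / (last_active - first_active)`.
#'
#' @param step A [footstep_series()].
#' @param threshold_kpa Activation threshold (kPa).
#' @return A `cop_trajectory`.
#' @export
cop_trajectory <- function(step, threshold_kpa = 5) {
  stopifnot(inherits(step, "footstep_series"))
  spec <- step$spec
  v <- step$voxels[step$voxels$p >= threshold_kpa, , drop = FALSE]
  if (!nrow(v)) stop("step has no voxels above the threshold", call. = FALSE)
  dt <- data.table::data.table(
    t = v$t, w = v$p, wx = v$p * cell_x(v$col, spec), wy = v$p * cell_y(v$row, spec)
  )
  agg <- dt[, list(w = sum(w), x = sum(wx), y = sum(wy)), by = "t"]
  data.table::setorder(agg, t)
  if (nrow(agg) < 2L) {
    stop("need at least 2 active frames for a trajectory", call. = FALSE)
  }
  t0 <- agg$t[1]; t1 <- agg$t[nrow(agg)]
  new_cop_trajectory(
    frame = agg$t,
    frac = (agg$t - t0) / (t1 - t0),
    x = agg$x / agg$w, y = agg$y / agg$w,
    p_total = agg$w
  )
}

#' Resample a trajectory to uniform stance fractions
#'
#' Linear interpolation at fractions `k / (n_points - 1)`; endpoints are
#' preserved exactly. 101 points (stance percent) is the gait-analysis
#' convention and makes trajectories of unequal duration comparable.
#'
#' @param traj A `cop_trajectory`.
#' @param n_points Number of resampled points.
#' @return A `cop_trajectory` with `n_points` points.
#' @export
time_normalize <- function(traj, n_points = 101L) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (n_points < 2L) stop("`n_points` must be at least 2", call. = FALSE)
  fr <- traj$frac
  if (is.null(fr)) fr <- seq(0, 1, length.out = traj$n_points)
  at <- seq(0, 1, length.out = n_points)
  new_cop_trajectory(
    frame = NULL, frac = at,
    x = stats::approx(fr, traj$x, xout = at, rule = 2)$y,
    y = stats::approx(fr, traj$y, xout = at, rule = 2)$y,
    p_total = if (is.null(traj$p_total)) NULL else
      stats::approx(fr, traj$p_total, xout = at, rule = 2)$y
  )
}

#' Pointwise mean of time-normalized trajectories
#'
#' @param trajs List of `cop_trajectory`, all with the same number of points.
#' @return A `cop_trajectory`.
#' @export
mean_trajectory <- function(trajs) {
  if (!length(trajs)) stop("no trajectories to average", call. = FALSE)
  np <- vapply(trajs, function(t) t$n_points, integer(1))
  if (length(unique(np)) != 1L) {
    stop("trajectories have mixed lengths; time-normalize first", call. = FALSE)
  }
  new_cop_trajectory(
    frame = NULL, frac = trajs[[1]]$frac,
    x = rowMeans(vapply(trajs, `[[`, numeric(np[1]), "x")),
    y = rowMeans(vapply(trajs, `[[`, numeric(np[1]), "y")),
    p_total = NULL
  )
}

#' Translate a trajectory so its centroid is at the origin
#'
#' Plate coordinates are arbitrary per trial, so mean trajectories are
#' centred before untransformed comparison — the only frame all feet share.
#'
#' @param traj A `cop_trajectory`.
#' @return The centred trajectory.
#' @export
center_trajectory <- function(traj) {
  out <- traj
  out$x <- traj$x - mean(traj$x)
  out$y <- traj$y - mean(traj$y)
  out
}

#' Untransformed trajectory comparison
#'
#' Pearson correlation of the mediolateral coordinate sequences (`x_r`), of
#' the cranio-caudal sequences (`y_r`), and the root mean square error
#' (RMSE): the root mean squared Euclidean point distance with no
#' superimposition beyond centring.
#'
#' @param a,b `cop_trajectory` objects with equal point counts.
#' @param center Centre both trajectories first (default).
#' @return List with `x_r`, `y_r`, `rmse`; a zero-variance axis yields `NA`
#'   for that correlation.
#' @export
compare_untransformed <- function(a, b, center = TRUE) {
  if (a$n_points != b$n_points) {
    stop("trajectories must have equal point counts", call. = FALSE)
  }
  if (center) {
    a <- center_trajectory(a)
    b <- center_trajectory(b)
  }
  safe_cor <- function(u, v) {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) NA_real_ else stats::cor(u, v)
  }
  list(
    x_r = safe_cor(a$x, b$x),
    y_r = safe_cor(a$y, b$y),
    rmse = sqrt(mean((a$x - b$x)^2 + (a$y - b$y)^2))
  )
}

#' Ordinary Procrustes superimposition of one trajectory onto another
#'
#' Centres both configurations, then finds the orthogonal matrix (rotation,
#' or rotation + reflection when `reflect = TRUE`) and, when `scale = TRUE`,
#' the least-squares uniform scale applied to the *source*, minimizing the
#' sum of squared point distances to the fixed *target* (closed form via the
#' singular value decomposition of the cross-covariance). The RMSD is the
#' root mean squared residual point distance after superimposition, with the
#' number of points as denominator (a mean per-point distance).
#'
#' @param target,source `cop_trajectory` objects or `n x 2` matrices with
#'   equal point counts (>= 2).
#' @param scale Allow uniform scaling of the source.
#' @param reflect Allow reflection (determinant -1).
#' @return List of class `procrustes_opa` with the superimposed source
#'   coordinates (`aligned`), `rotation`, `scale`, `translation`,
#'   `reflected` (whether the optimum used a reflection), and `rmsd`.
#' @export
procrustes_opa <- function(target, source, scale = TRUE, reflect = TRUE) {
  X <- cop_points(target)
  Y <- cop_points(source)
  if (nrow(X) != nrow(Y) || nrow(X) < 2L) {
    stop("configurations must have equal point counts >= 2", call. = FALSE)
  }
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx)
  Yc <- sweep(Y, 2, my)
  ssy <- sum(Yc^2)
  if (ssy == 0 || sum(Xc^2) == 0) {
    stop("degenerate configuration (zero centroid size)", call. = FALSE)
  }
  A <- crossprod(Yc, Xc)
  sv <- svd(A)
  d <- sv$d
  U <- sv$u; V <- sv$v
  R <- U %*% t(V)
  if (!reflect && det(R) < 0) {
    U[, 2] <- -U[, 2]
    d[2] <- -d[2]
    R <- U %*% t(V)
  }
  s <- if (scale) sum(d) / ssy else 1
  fitted <- s * Yc %*% R
  resid <- Xc - fitted
  rmsd <- sqrt(mean(rowSums(resid^2)))
  structure(
    list(
      aligned = sweep(fitted, 2, mx, `+`),
      rotation = R, scale = s,
      translation = mx - my,
      reflected = det(R) < 0,
      rmsd = rmsd,
      scale_used = scale, reflect_used = reflect
    ),
    class = "procrustes_opa"
  )
}

#' @export
print.procrustes_opa <- function(x, ...) {
  cat(sprintf(
    "<procrustes_opa> rmsd %.4g, scale %.4g, theta %.2f deg%s\n",
    x$rmsd, x$scale, atan2(x$rotation[2, 1], x$rotation[1, 1]) * 180 / pi,
    if (x$reflected) ", reflected" else ""
  ))
  invisible(x)
}

#' Pairwise comparison table of mean COP trajectories
#'
#' One row per requested pair of labelled trajectories, mirroring published
#' pairwise comparison tables: axis-wise Pearson correlations and RMSE on
#' the untransformed (centred) data, and the RMSD after ordinary Procrustes
#' superimposition with the requested scale/reflect settings (the second
#' member of each pair is superimposed onto the first).
#'
#' @param mean_trajs Named list of `cop_trajectory` (e.g. `FL`, `FR`, `HL`,
#'   `HR`), all with the same point count.
#' @param pairs Character vector like `"FL-FR"`, or `NULL` for all unordered
#'   pairs in list order.
#' @param scale,reflect Passed to [procrustes_opa()].
#' @return A [tibble::tibble()] with columns `pair`, `x_r`, `y_r`, `rmse`,
#'   `rmsd`, `scale_used`, `reflect_used`.
#' @export
compare_feet <- function(mean_trajs, pairs = NULL, scale = TRUE, reflect = TRUE) {
  labs <- names(mean_trajs)
  if (is.null(pairs)) {
    if (length(labs) < 2L) stop("need at least two labelled trajectories", call. = FALSE)
    cmb <- utils::combn(labs, 2L)
    pairs <- paste(cmb[1, ], cmb[2, ], sep = "-")
  }
  rows <- lapply(pairs, function(p) {
    ab <- strsplit(p, "-", fixed = TRUE)[[1]]
    if (length(ab) != 2L || !all(ab %in% labs)) {
      stop("unknown pair label: ", p, call. = FALSE)
    }
    a <- mean_trajs[[ab[1]]]
    b <- mean_trajs[[ab[2]]]
    un <- compare_untransformed(a, b)
    pr <- procrustes_opa(a, b, scale = scale, reflect = reflect)
    tibble::tibble(
      pair = p, x_r = un$x_r, y_r = un$y_r, rmse = un$rmse, rmsd = pr$rmsd,
      scale_used = scale, reflect_used = reflect
    )
  })
  dplyr::bind_rows(rows)
}
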