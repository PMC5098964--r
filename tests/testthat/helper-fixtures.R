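# Shared fixtures: a scaled-down plate with the same sensor pitch as the
# default platform, compact foot models, and brute-force oracles.

small_spec <- function(n_cols = 24L, n_rows = 60L) {
  plate_spec(
    n_cols = n_cols, n_rows = n_rows,
    width_m = n_cols * 0.605 / 44, length_m = n_rows * 2.122 / 160,
    freq_hz = 100
  )
}

small_foot <- function(foot_type = "fore", side = "left", ...) {
  foot_model(foot_type, side, semi_x_m = 0.05, semi_y_m = 0.06,
             digit_sigma_m = 0.012, pad_sigma_m = 0.03, ...)
}

# larger, smoother foot for registration / ROI fidelity tests: digit peaks
# wider than one sensor pitch so resampling is well behaved
reg_foot <- function(foot_type = "fore", side = "left", ...) {
  foot_model(foot_type, side, semi_x_m = 0.095, semi_y_m = 0.105,
             digit_sigma_m = 0.016, pad_sigma_m = 0.04,
             digit_radius_frac = 0.85, ...)
}

small_models <- function() {
  list(
    FL = small_foot("fore", "left"), FR = small_foot("fore", "right"),
    HL = small_foot("hind", "left"), HR = small_foot("hind", "right")
  )
}

# four well-separated footfalls on the small plate (left feet high-x,
# hind lands near the ipsilateral fore print after it lifts)
small_steps <- function() {
  data.frame(
    foot = c("FL", "FR", "HL", "HR"),
    x_m = c(0.24, 0.09, 0.24, 0.09),
    y_m = c(0.18, 0.42, 0.25, 0.49),
    onset_s = c(0, 0.25, 0.55, 0.8),
    heading_deg = 0
  )
}

small_plan <- function(noise_sd_kpa = 0, seed = 1L, ...) {
  gait_plan(small_steps(), stance_s = 0.35, noise_sd_kpa = noise_sd_kpa,
            seed = seed, pad_frames = 3L, ...)
}

# a random sparse record for IO / segmentation tests
random_record <- function(seed, spec = small_spec(12L, 16L), nfr = 10L,
                          density = 0.08, max_kpa = 50) {
  set.seed(seed)
  fr <- array(0, dim = c(spec$n_rows, spec$n_cols, nfr))
  n <- length(fr)
  idx <- sample(n, round(density * n))
  fr[idx] <- round(stats::runif(length(idx), 1, max_kpa), 6)
  pressure_record(fr, spec)
}

# --- oracles ----------------------------------------------------------------

# Brute-force voxel clustering: union-find over all voxel pairs adjacent
# under the Chebyshev box rule.
oracle_clusters <- function(record, config) {
  thr <- config$p_threshold_kpa
  d_s <- config$spatial_gap_cells + 1L
  d_t <- config$temporal_gap_frames + 1L
  idx <- which(record$frames >= thr)
  if (!length(idx)) return(list())
  dm <- dim(record$frames)
  t <- ((idx - 1L) %/% (dm[1] * dm[2])) + 1L
  row <- ((idx - 1L) %% dm[1]) + 1L
  col <- (((idx - 1L) %/% dm[1]) %% dm[2]) + 1L
  n <- length(idx)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (abs(t[i] - t[j]) <= d_t &&
          abs(row[i] - row[j]) <= d_s && abs(col[i] - col[j]) <= d_s) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(r) {
    sel <- roots == r
    sort(paste(t[sel], row[sel], col[sel], sep = ":"))
  })
}

voxel_keys <- function(step) {
  sort(paste(step$voxels$t, step$voxels$row, step$voxels$col, sep = ":"))
}

# Independent OPA oracle: dense rotation grid + optimize() per reflection,
# closed-form least-squares scale given the rotation.
oracle_procrustes_rmsd <- function(X, Y, scale = TRUE, reflect = TRUE) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  refls <- if (reflect) list(diag(2), diag(c(1, -1))) else list(diag(2))
  best <- Inf
  for (refl in refls) {
    obj <- function(th) {
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      Yr <- Yc %*% refl %*% R
      s <- if (scale) sum(Xc * Yr) / sum(Yr^2) else 1
      sqrt(mean(rowSums((Xc - s * Yr)^2)))
    }
    grid <- seq(0, 2 * pi, length.out = 721)
    vals <- vapply(grid, obj, numeric(1))
    k <- which.min(vals)
    lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
    o <- stats::optimize(obj, c(lo, hi), tol = 1e-12)
    best <- min(best, o$objective)
  }
  best
}

rand_traj <- function(seed, n = 20L) {
  set.seed(seed)
  new_traj(cumsum(stats::rnorm(n, 0, 0.01)), seq(0, 0.3, length.out = n) +
             stats::rnorm(n, 0, 0.005))
}

# build a cop_trajectory directly from coordinates
new_traj <- function(x, y, frac = NULL) {
  if (is.null(frac)) frac <- seq(0, 1, length.out = length(x))
  tr <- pedopress:::new_cop_trajectory(frame = NULL, frac = frac, x = x, y = y,
                                       p_total = NULL)
  tr
}
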