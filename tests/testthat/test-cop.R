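# COP computation, time normalization, averaging, and trajectory comparison
# (Pearson / RMSE / Procrustes RMSD).

test_that("cop_frame is the pressure-weighted centroid above threshold", {
  spec <- plate_spec(n_cols = 4L, n_rows = 6L, width_m = 0.4, length_m = 0.6)
  f <- matrix(0, 6, 4)
  f[3, 2] <- 80
  expect_equal(cop_frame(f, spec), c(x_m = 0.15, y_m = 0.25))

  f2 <- matrix(0, 6, 4)
  f2[3, 2] <- 40; f2[3, 4] <- 40 # equal loads at x 0.15 and 0.35
  expect_equal(cop_frame(f2, spec)[["x_m"]], 0.25)

  expect_null(cop_frame(matrix(1, 6, 4), spec, threshold_kpa = 5))

  set.seed(6)
  fr <- matrix(runif(24, 0, 50), 6, 4)
  got <- cop_frame(fr, spec, threshold_kpa = 10)
  num <- c(0, 0); den <- 0 # direct loop oracle
  for (r in 1:6) for (c in 1:4) {
    if (fr[r, c] >= 10) {
      num <- num + fr[r, c] * c((c - 0.5) * 0.1, (r - 0.5) * 0.1)
      den <- den + fr[r, c]
    }
  }
  expect_equal(unname(got), num / den, tolerance = 1e-12)
})

test_that("trajectories follow active frames in order and reverse with time", {
  spec <- small_spec(8L, 10L)
  vox <- data.frame(
    t = rep(2:5, each = 2),
    row = c(2, 3, 3, 4, 4, 5, 5, 6),
    col = rep(c(3, 4), 4),
    p = 20
  )
  st <- footstep_series(vox, spec, 8L)
  tr <- cop_trajectory(st, 5)
  expect_equal(tr$n_points, 4L)
  expect_equal(tr$frac, c(0, 1, 2, 3) / 3)
  expect_true(all(diff(tr$y) > 0))

  rvox <- vox
  rvox$t <- max(vox$t) + min(vox$t) - vox$t # reverse time
  rtr <- cop_trajectory(footstep_series(rvox, spec, 8L), 5)
  expect_equal(rtr$x, rev(tr$x))
  expect_equal(rtr$y, rev(tr$y))

  expect_error(cop_trajectory(footstep_series(vox[1:2, ], spec, 8L), 5),
               "2 active frames")
})

test_that("time normalization interpolates linearly and preserves endpoints", {
  tr <- new_traj(c(0, 1), c(0, 2))
  tn <- time_normalize(tr, 3L)
  expect_equal(tn$x, c(0, 0.5, 1))
  expect_equal(tn$y, c(0, 1, 2))

  tr2 <- rand_traj(31, n = 101L)
  expect_equal(time_normalize(tr2, 101L)$x, tr2$x, tolerance = 1e-12)

  tr3 <- rand_traj(32, n = 17L)
  tn3 <- time_normalize(tr3, 50L)
  at <- seq(0, 1, length.out = 50)
  want <- approx(tr3$frac, tr3$x, xout = at)$y # direct interpolation oracle
  expect_equal(tn3$x, want, tolerance = 1e-12)
  expect_equal(tn3$x[c(1, 50)], tr3$x[c(1, 17)])
})

test_that("mean trajectories average pointwise and respect symmetry", {
  a <- rand_traj(41)
  expect_equal(mean_trajectory(list(a, a, a))$x, a$x)

  b <- a; b$x <- -a$x # mirror about the y axis
  m <- mean_trajectory(list(a, b))
  expect_equal(m$x, rep(0, a$n_points), tolerance = 1e-12)
  expect_equal(m$y, a$y)

  cc <- rand_traj(42)
  got <- mean_trajectory(list(a, cc))
  expect_equal(got$y, (a$y + cc$y) / 2, tolerance = 1e-12)

  expect_error(mean_trajectory(list(a, rand_traj(43, n = 7L))), "mixed lengths")
})

test_that("untransformed comparison matches the direct formulae", {
  a <- rand_traj(51)
  self <- compare_untransformed(a, a)
  expect_equal(self$x_r, 1)
  expect_equal(self$y_r, 1)
  expect_equal(self$rmse, 0)

  b <- a; b$x <- -b$x
  flip <- compare_untransformed(a, b)
  expect_equal(flip$x_r, -1)
  expect_equal(flip$y_r, 1)

  cc <- rand_traj(52)
  got <- compare_untransformed(a, cc)
  ax <- a$x - mean(a$x); cx <- cc$x - mean(cc$x)
  ay <- a$y - mean(a$y); cy <- cc$y - mean(cc$y)
  expect_equal(got$x_r, sum(ax * cx) / sqrt(sum(ax^2) * sum(cx^2)),
               tolerance = 1e-12)
  expect_equal(got$rmse, sqrt(mean((ax - cx)^2 + (ay - cy)^2)),
               tolerance = 1e-12)

  flat <- a; flat$x <- rep(0, a$n_points)
  expect_true(is.na(compare_untransformed(a, flat)$x_r))
})

test_that("OPA is exact on similarity-transformed copies and matches the grid oracle", {
  set.seed(61)
  X <- cbind(rnorm(10), rnorm(10))
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Y <- 1.7 * X %*% diag(c(1, -1)) %*% R + matrix(c(2, -3), 10, 2, byrow = TRUE)
  expect_lt(procrustes_opa(X, Y, scale = TRUE, reflect = TRUE)$rmsd, 1e-10)
  expect_lt(procrustes_opa(X, X)$rmsd, 1e-12)

  for (seed in 62:67) {
    set.seed(seed)
    n <- sample(5:20, 1)
    A <- cbind(rnorm(n), rnorm(n))
    B <- cbind(rnorm(n), rnorm(n))
    for (sc in c(TRUE, FALSE)) for (rf in c(TRUE, FALSE)) {
      got <- procrustes_opa(A, B, scale = sc, reflect = rf)$rmsd
      want <- oracle_procrustes_rmsd(A, B, scale = sc, reflect = rf)
      expect_equal(got, want, tolerance = 1e-4)
    }
  }
  expect_error(procrustes_opa(X, matrix(1, 10, 2)), "degenerate")
})

test_that("OPA agrees with an independent Procrustes implementation", {
  set.seed(71)
  X <- cbind(rnorm(12), rnorm(12))
  Y <- cbind(rnorm(12), rnorm(12))
  ours <- procrustes_opa(X, Y, scale = TRUE, reflect = TRUE)
  ref <- vegan::procrustes(X, Y, scale = TRUE, symmetric = FALSE)
  expect_equal(ours$rmsd^2 * 12, ref$ss, tolerance = 1e-10)
  expect_equal(abs(det(ours$rotation)), 1, tolerance = 1e-12)
})

test_that("RMSD is invariant to rigid motions and shrinks with more freedom", {
  set.seed(81)
  A <- cbind(rnorm(10), rnorm(10))
  B <- cbind(rnorm(10), rnorm(10))
  base <- procrustes_opa(A, B)$rmsd

  th <- -0.6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(procrustes_opa(A, B %*% R + 5)$rmsd, base, tolerance = 1e-10)
  expect_equal(procrustes_opa(A %*% R - 2, B)$rmsd, base, tolerance = 1e-10)
  expect_equal(procrustes_opa(A, 3.1 * B)$rmsd, base, tolerance = 1e-10)
  expect_equal(procrustes_opa(A, B %*% diag(c(-1, 1)))$rmsd, base,
               tolerance = 1e-10)

  for (seed in 82:85) {
    set.seed(seed)
    P <- cbind(rnorm(8), rnorm(8)); Q <- cbind(rnorm(8), rnorm(8))
    r_all <- procrustes_opa(P, Q, scale = TRUE, reflect = TRUE)$rmsd
    r_sc <- procrustes_opa(P, Q, scale = TRUE, reflect = FALSE)$rmsd
    r_no <- procrustes_opa(P, Q, scale = FALSE, reflect = FALSE)$rmsd
    expect_lte(r_all, r_sc + 1e-12)
    expect_lte(r_sc, r_no + 1e-12)
  }
})

test_that("pairwise foot comparison mirrors the published table layout", {
  trajs <- list(FL = rand_traj(91), FR = rand_traj(92), HL = rand_traj(93),
                HR = rand_traj(94))
  tab <- compare_feet(trajs)
  expect_identical(tab$pair, c("FL-FR", "FL-HL", "FL-HR", "FR-HL", "FR-HR",
                               "HL-HR"))
  expect_identical(names(tab)[1:5], c("pair", "x_r", "y_r", "rmse", "rmsd"))
  expect_true(all(tab$rmsd <= tab$rmse + 1e-12))

  same <- compare_feet(list(A = trajs$FL, B = trajs$FL), pairs = "A-B")
  expect_equal(unlist(same[1, c("x_r", "y_r", "rmse", "rmsd")]),
               c(x_r = 1, y_r = 1, rmse = 0, rmsd = 0), tolerance = 1e-10)

  # a left foot versus its exact mirror: reflection fixes it, rotation alone
  # cannot
  L <- rand_traj(95)
  M <- L; M$x <- -M$x
  refl <- compare_feet(list(L = L, M = M), pairs = "L-M", reflect = TRUE)
  norf <- compare_feet(list(L = L, M = M), pairs = "L-M", reflect = FALSE)
  expect_lt(refl$rmsd, 1e-10)
  expect_gt(norf$rmsd, refl$rmsd)

  expect_error(compare_feet(trajs, pairs = "FL-XX"), "unknown pair")
})

test_that("RMSD grows with noise and mean paths converge as 1/sqrt(n)", {
  truth <- rand_traj(101, n = 30L)
  noisy <- function(sd, seed) {
    set.seed(seed)
    tr <- truth
    tr$x <- tr$x + rnorm(30, 0, sd)
    tr$y <- tr$y + rnorm(30, 0, sd)
    tr
  }
  rmsd_at <- function(sd) {
    mean(vapply(1:6, function(s) {
      procrustes_opa(truth, noisy(sd, s))$rmsd
    }, numeric(1)))
  }
  r <- vapply(c(0.002, 0.01, 0.05), rmsd_at, numeric(1))
  expect_true(all(diff(r) > 0))

  mean_err <- function(n) {
    mean(vapply(1:8, function(s) {
      set.seed(s * 1000 + n)
      m <- mean_trajectory(lapply(1:n, function(i) noisy(0.02, s * 100 + i)))
      sqrt(mean((m$x - truth$x)^2 + (m$y - truth$y)^2))
    }, numeric(1)))
  }
  e2 <- mean_err(2L); e16 <- mean_err(16L)
  expect_lt(e16, e2 / 1.8) # close to the 1/sqrt(8) prediction
})
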