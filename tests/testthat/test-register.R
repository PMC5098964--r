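# Peak images, template selection, rigid transforms and the automated
# registration search.

make_synth_image <- function(seed = 1, x_m = 0.15, y_m = 0.3) {
  spec <- small_spec()
  fs <- generate_footstep(reg_foot(), small_plan(seed = seed),
                          list(x_m = x_m, y_m = y_m, heading_deg = 0), spec)
  st <- segment_steps(fs$record)[[1]]
  list(img = peak_pressure_image(st), step = st, truth = fs$truth, spec = spec)
}

test_that("peak image is the per-cell maximum over stance", {
  spec <- small_spec(6L, 8L)
  vox <- data.frame(
    t = c(1L, 2L, 2L), row = c(3L, 3L, 4L), col = c(2L, 2L, 5L),
    p = c(10, 30, 12)
  )
  st <- footstep_series(vox, spec, 4L)
  img <- peak_pressure_image(st)
  expect_equal(img$values[3, 2], 30)
  expect_equal(img$values[4, 5], 12)
  expect_equal(sum(img$values > 0), 2L)

  # one-frame step: image equals that frame
  st1 <- footstep_series(vox[1, ], spec, 4L)
  expect_equal(peak_pressure_image(st1)$values[3, 2], 10)
})

test_that("synthetic peak image peaks where the generating field peaks", {
  fx <- make_synth_image()
  got <- which(fx$img$values == max(fx$img$values), arr.ind = TRUE)
  # independent dense evaluation of the max-over-stance field at cell centres
  spec <- fx$spec
  plan <- small_plan()
  m <- reg_foot()
  grid <- expand.grid(row = 1:spec$n_rows, col = 1:spec$n_cols)
  ff <- pedopress:::plate_to_foot(m, list(x_m = 0.15, y_m = 0.3, heading_deg = 0),
                                  cell_x(grid$col, spec), cell_y(grid$row, spec))
  n_fr <- round(plan$stance_s * spec$freq_hz)
  pk <- numeric(nrow(grid))
  for (k in seq_len(n_fr)) {
    pk <- pmax(pk, pedopress:::foot_field(m, plan, ff$xf, ff$yf, (k - 0.5) / n_fr))
  }
  want <- grid[which.max(pk), ]
  expect_equal(unname(got[1, "row"]), want$row)
  expect_equal(unname(got[1, "col"]), want$col)
})

test_that("the template is the first spatio-temporally complete image", {
  fx <- make_synth_image()
  imgs <- list(fx$img, fx$img, fx$img)
  flags <- list(
    c(complete_spatial = FALSE, complete_temporal = TRUE),
    c(complete_spatial = TRUE, complete_temporal = TRUE),
    c(complete_spatial = TRUE, complete_temporal = TRUE)
  )
  tpl <- select_template(imgs, flags)
  expect_equal(tpl$source_index, 2L)
  expect_equal(tpl$iso_threshold_kpa, 5)
  expect_true(sum(tpl$mask) >= 20)

  all_bad <- list(
    c(complete_spatial = FALSE, complete_temporal = TRUE),
    c(complete_spatial = TRUE, complete_temporal = FALSE)
  )
  expect_error(select_template(imgs[1:2], all_bad), "complete")
})

test_that("rigid transforms behave exactly on identity, shifts and 90 degrees", {
  fx <- make_synth_image()
  img <- fx$img
  expect_equal(apply_transform(img, rigid_transform(0, 0, 0))$values,
               img$values, tolerance = 1e-12)

  sh <- apply_transform(img, rigid_transform(3, 0, 0))
  expect_equal(sh$values[, 4:ncol(sh$values)],
               img$values[, 1:(ncol(img$values) - 3)], tolerance = 1e-12)

  # 90-degree rotation of a square print about its centroid equals the exact
  # pixel permutation
  m <- matrix(0, 21, 21)
  m[9:13, 9:13] <- matrix(1:25, 5, 5)
  cen <- c(11, 11) # active centroid (col, row)
  rot <- apply_transform(m, rigid_transform(0, 0, 90, centre = cen))
  oracle <- matrix(0, 21, 21)
  for (r in 1:21) for (c in 1:21) {
    # inverse map of +90 deg: (x, y) -> (y, -x) about the centre
    cc <- (r - cen[2]) + cen[1]
    rr <- -(c - cen[1]) + cen[2]
    if (rr >= 1 && rr <= 21 && cc >= 1 && cc <= 21) oracle[r, c] <- m[rr, cc]
  }
  expect_equal(rot, oracle, tolerance = 1e-12)
})

test_that("interior transforms conserve pressure mass within 2%", {
  fx <- make_synth_image()
  tfd <- apply_transform(fx$img, rigid_transform(2.3, -1.7, 7))
  expect_lt(abs(sum(tfd$values) - sum(fx$img$values)) / sum(fx$img$values), 0.02)
})

test_that("registration recovers known transforms within half a cell / degree", {
  fx <- make_synth_image()
  img <- fx$img

  # pure translation
  src <- apply_transform(img, rigid_transform(4, -2, 0))
  tf <- register_to_template(src, img)
  expect_equal(tf$dx_cells, -4, tolerance = 0.5)
  expect_equal(tf$dy_cells, 2, tolerance = 0.5)
  expect_equal(tf$theta_deg, 0, tolerance = 0.5)

  # pure rotation
  src2 <- apply_transform(img, rigid_transform(0, 0, 10))
  tf2 <- register_to_template(src2, img)
  expect_equal(tf2$theta_deg, -10, tolerance = 0.5)

  # identity in == identity out
  tf0 <- register_to_template(img, img)
  expect_equal(abs(tf0$dx_cells) + abs(tf0$dy_cells) + abs(tf0$theta_deg), 0,
               tolerance = 0.2)
  expect_lt(attr(tf0, "mse"), 1e-10)

  # residual never worse than doing nothing
  src3 <- apply_transform(img, rigid_transform(3.4, 1.2, -6))
  tf3 <- register_to_template(src3, img)
  after <- apply_transform(src3, tf3)
  expect_lte(mean((after$values - img$values)^2),
             mean((src3$values - img$values)^2))
})

test_that("series transforms commute with the COP (centroid equivariance)", {
  fx <- make_synth_image()
  spec <- fx$spec
  tf <- rigid_transform(2.5, -1.5, 5,
                        centre = pedopress:::active_centroid(fx$img$values))
  moved <- apply_transform_to_series(fx$step, tf)
  a <- cop_trajectory(fx$step, 5)
  b <- cop_trajectory(moved, 5)
  # transform the original COP points (converted to cell units) forward
  pts <- cbind(a$x / spec$pitch_x_m + 0.5, a$y / spec$pitch_y_m + 0.5)
  fwd <- pedopress:::transform_points(pts, tf, tf$centre)
  common <- intersect(a$frame, b$frame)
  ia <- match(common, a$frame); ib <- match(common, b$frame)
  err <- sqrt(((fwd[ia, 1] - 0.5) * spec$pitch_x_m - b$x[ib])^2 +
                ((fwd[ia, 2] - 0.5) * spec$pitch_y_m - b$y[ib])^2)
  expect_lt(max(err), spec$pitch_x_m / 2)

  # integer shift: per-frame exact
  tfi <- rigid_transform(3, 2, 0, centre = tf$centre)
  mi <- apply_transform_to_series(fx$step, tfi)
  expect_equal(sort(unique(mi$voxels$col - 0)),
               sort(unique(fx$step$voxels$col + 3)))
  expect_equal(sum(mi$voxels$p), sum(fx$step$voxels$p), tolerance = 1e-9)

  # peak image of transformed series == transformed peak image
  pk1 <- peak_pressure_image(apply_transform_to_series(fx$step, tf))$values
  pk2 <- apply_transform(fx$img, tf)$values
  expect_lt(max(abs(pk1 - pk2)) / max(pk2), 0.05)
})
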