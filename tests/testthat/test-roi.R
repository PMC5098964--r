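# Mean images, display smoothing, Gaussian-kernel ROI extraction, the
# one-pixel sensitivity analysis, and ROI digitization.

test_that("mean_image is the pixel-wise arithmetic mean", {
  a <- matrix(0, 6, 6); b <- matrix(100, 6, 6)
  expect_equal(mean_image(list(a, b))[3, 3], 50)
  expect_equal(mean_image(list(a, a, a)), a)

  set.seed(3)
  stack <- lapply(1:4, function(i) matrix(runif(36, 0, 50), 6, 6))
  got <- mean_image(stack)
  want <- matrix(0, 6, 6)
  for (m in stack) want <- want + m / 4 # direct loop oracle
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(mean_image(list()), "no images")
  expect_error(mean_image(list(a, matrix(0, 5, 5))), "common grid")
})

test_that("smooth_gaussian preserves identity, DC level and matches direct convolution", {
  set.seed(4)
  m <- matrix(runif(15 * 12, 0, 100), 15, 12)
  expect_equal(smooth_gaussian(m, 0), m)
  expect_equal(smooth_gaussian(matrix(7, 9, 9), 2), matrix(7, 9, 9),
               tolerance = 1e-12)
  expect_error(smooth_gaussian(m, -1), "non-negative")

  # impulse response: centre weight equals the normalized kernel value at 0
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  sm <- smooth_gaussian(imp, 1)
  rad <- 3
  k <- dnorm(-rad:rad, sd = 1); k <- k / sum(k)
  expect_equal(sm[6, 6], k[rad + 1]^2, tolerance = 1e-12)

  # full direct 2D convolution oracle with reflected borders
  rad <- 3
  pad <- function(mm) {
    ridx <- c(rad:1, 1:nrow(mm), nrow(mm):(nrow(mm) - rad + 1))
    cidx <- c(rad:1, 1:ncol(mm), ncol(mm):(ncol(mm) - rad + 1))
    mm[ridx, cidx]
  }
  mp <- pad(m)
  want <- matrix(0, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    acc <- 0
    for (i in -rad:rad) for (j in -rad:rad) {
      acc <- acc + k[i + rad + 1] * k[j + rad + 1] * mp[r + rad + i, c + rad + j]
    }
    want[r, c] <- acc
  }
  expect_equal(smooth_gaussian(m, 1), want, tolerance = 1e-10)
})

test_that("extract_roi_peak is the normalized 3x3 sigma-1 kernel average", {
  expect_equal(extract_roi_peak(matrix(42, 7, 7), c(4, 4)), 42)

  # single hot pixel: value * normalized centre weight
  m <- matrix(0, 7, 7); m[4, 4] <- 200
  w00 <- 1 / (1 + 4 * exp(-0.5) + 4 * exp(-1))
  expect_equal(extract_roi_peak(m, c(4, 4)), 200 * w00, tolerance = 1e-12)

  # random image: direct weighted-sum oracle; linearity; bounds
  set.seed(5)
  r1 <- matrix(runif(64, 0, 300), 8, 8)
  r2 <- matrix(runif(64, 0, 300), 8, 8)
  w <- outer(exp(-(-1:1)^2 / 2), exp(-(-1:1)^2 / 2)); w <- w / sum(w)
  want <- sum(w * r1[3:5, 4:6])
  expect_equal(extract_roi_peak(r1, c(4, 5)), want, tolerance = 1e-12)
  expect_equal(extract_roi_peak(r1 + r2, c(4, 5)),
               extract_roi_peak(r1, c(4, 5)) + extract_roi_peak(r2, c(4, 5)),
               tolerance = 1e-12)
  expect_gte(extract_roi_peak(r1, c(4, 5)), min(r1[3:5, 4:6]))
  expect_lte(extract_roi_peak(r1, c(4, 5)), max(r1[3:5, 4:6]))

  expect_error(extract_roi_peak(r1, c(1, 4), roi_label = "7"), "ROI 7")
})

test_that("sensitivity tables have 35 rows and respond to gradients analytically", {
  pts <- data.frame(roi = 1:7, row = c(10, 11, 12, 11, 10, 8, 5),
                    col = c(4, 5, 7, 9, 10, 7, 7))
  rois <- roi_set(pts, foot_label = "FL")

  tab <- sensitivity_table(matrix(33, 16, 13), rois)
  expect_equal(nrow(tab), 35L)
  expect_equal(sum(tab$is_primary), 7L)
  expect_true(all(tab$peak_pressure_kpa == 33))

  # pure x-gradient: left/right move by the per-pixel gradient, up/down do not
  g <- 2.5
  grad <- matrix(rep(g * (1:13), each = 16), 16, 13)
  tb <- sensitivity_table(grad, rois)
  for (r in 1:7) {
    v <- tb[tb$roi == r, ]
    ctr <- v$peak_pressure_kpa[v$position == "centre"]
    expect_equal(v$peak_pressure_kpa[v$position == "right"], ctr + g,
                 tolerance = 1e-10)
    expect_equal(v$peak_pressure_kpa[v$position == "left"], ctr - g,
                 tolerance = 1e-10)
    expect_equal(v$peak_pressure_kpa[v$position == "above"], ctr,
                 tolerance = 1e-10)
    expect_equal(v$peak_pressure_kpa[v$position == "below"], ctr,
                 tolerance = 1e-10)
  }
})

test_that("extraction at the digitized loci recovers the generator's regional peaks", {
  spec <- small_spec()
  fs <- generate_footstep(reg_foot(), small_plan(),
                          list(x_m = 0.15, y_m = 0.3, heading_deg = 0), spec)
  st <- segment_steps(fs$record)[[1]]
  img <- peak_pressure_image(st)
  rt <- fs$truth$roi
  got <- vapply(1:7, function(i) {
    extract_roi_peak(img, c(rt$row[i], rt$col[i]))
  }, numeric(1))
  expect_true(all(abs(got - rt$peak_kpa) / rt$peak_kpa < 0.02))
})

test_that("ROI digitization: manual verbatim, auto within one cell of the truth", {
  spec <- small_spec()
  fs <- generate_footstep(reg_foot(), small_plan(),
                          list(x_m = 0.15, y_m = 0.3, heading_deg = 0), spec)
  st <- segment_steps(fs$record)[[1]]
  img <- peak_pressure_image(st)
  img$foot_label <- "FL"
  tpl <- select_template(list(img), list(c(complete_spatial = TRUE,
                                           complete_temporal = TRUE)))

  rt <- fs$truth$roi
  manual <- digitize_rois(tpl, "manual",
                          points = rt[, c("roi", "row", "col")])
  expect_equal(manual$points$row, rt$row)
  expect_equal(manual$points$col, rt$col)

  auto <- digitize_rois(tpl, "auto")
  expect_true(all(abs(auto$points$row - rt$row) <= 1))
  expect_true(all(abs(auto$points$col - rt$col) <= 1))

  # mirrored (right) foot: medial -> lateral ordering reverses with side
  fsR <- generate_footstep(reg_foot(side = "right"), small_plan(),
                           list(x_m = 0.15, y_m = 0.3, heading_deg = 0), spec)
  stR <- segment_steps(fsR$record)[[1]]
  imgR <- peak_pressure_image(stR)
  imgR$foot_label <- "FR"
  tplR <- select_template(list(imgR), list(c(complete_spatial = TRUE,
                                             complete_temporal = TRUE)))
  autoR <- digitize_rois(tplR, "auto")
  dirL <- sign(diff(auto$points$col[1:5]))
  dirR <- sign(diff(autoR$points$col[1:5]))
  expect_true(all(dirL == 1))  # left foot: digit i..v runs medial->lateral (+x)
  expect_true(all(dirR == -1)) # right foot mirrored
  expect_true(all(abs(autoR$points$col - fsR$truth$roi$col) <= 1))

  expect_error(roi_set(data.frame(roi = 1:6, row = 1, col = 1)), "seven")
})
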