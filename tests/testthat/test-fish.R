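test_that("max projection is the per-pixel maximum across slices", {
  st <- array(0, dim = c(4, 4, 3))
  st[, , 1] <- 1; st[2, 3, 2] <- 9; st[, , 3] <- 0.5
  img <- max_project(st)
  expect_equal(img[2, 3], 9)
  expect_equal(img[1, 1], 1)
  # single slice projects to itself
  expect_equal(max_project(array(st[, , 1], c(4, 4, 1))), st[, , 1],
               ignore_attr = TRUE)
})

test_that("puncta counting recovers a constructed sparse grid exactly", {
  # 12 puncta on a grid, spacing far above 3 x PSF sigma
  n <- 200
  img <- matrix(10, n, n)
  centers <- expand.grid(x = seq(30, 180, by = 50), y = seq(30, 130, by = 50))
  xs <- 1:n
  for (i in seq_len(nrow(centers))) {
    gx <- exp(-(xs - centers$x[i])^2 / (2 * 1.25^2))
    gy <- exp(-(xs - centers$y[i])^2 / (2 * 1.25^2))
    img <- img + 120 * outer(gy, gx)
  }
  res <- count_puncta(img)
  expect_equal(res$count, nrow(centers))
  # centroids land on the planted centers
  d <- vapply(seq_len(nrow(centers)), function(i)
    min(sqrt((res$centroids$x - centers$x[i])^2 +
               (res$centroids$y - centers$y[i])^2)), 0)
  expect_lt(max(d), 1)

  # two puncta closer than 2 sigma merge and count once
  img2 <- matrix(10, 60, 60)
  for (cx in c(30, 32)) {
    gx <- exp(-(xs[1:60] - cx)^2 / (2 * 1.25^2))
    gy <- exp(-(xs[1:60] - 30)^2 / (2 * 1.25^2))
    img2 <- img2 + 120 * outer(gy, gx)
  }
  expect_equal(count_puncta(img2)$count, 1L)

  # blank and constant images
  expect_warning(res0 <- count_puncta(matrix(5, 50, 50)), "constant")
  expect_equal(res0$count, 0L)
})

test_that("planted puncta are recovered within 5% at default densities", {
  err <- vapply(1:5, function(s) {
    st <- render_fish_stack(fish_image_spec(), seed = 300 + s)
    res <- count_puncta(max_project(st))
    (res$count - nrow(st$truth$puncta)) / nrow(st$truth$puncta)
  }, 0)
  expect_lt(max(abs(err)), 0.05)
})

test_that("lamina profile reproduces planted band means and is linear", {
  # piecewise-constant bands along x, 0.5 um/px
  n <- 400
  band_vals <- c(40, 10, 25, 15)
  img <- matrix(rep(rep(band_vals, each = n / 4), each = n), n, n)
  attr(img, "um_per_px") <- 0.5
  roi <- line_roi_spec(origin_px = c(10, 200), angle_deg = 0,
                       length_um = 180, step_um = 10, n_lines = 10,
                       spacing_um = 10)
  prof <- lamina_profile(img, roi)
  expect_equal(nrow(prof), 19L)
  # positions 10 um inside each 50-um band (away from edges) hit band means
  mid <- c(20, 70, 120, 170)  # um along the line, origin at x = 10 px = 5 um
  for (i in seq_along(mid)) {
    v <- prof$intensity[prof$position_um == mid[i]]
    expect_lt(abs(v - band_vals[i]) / band_vals[i], 0.02)
  }
  # linearity: scaling the image scales the profile
  img3 <- img * 3
  attr(img3, "um_per_px") <- 0.5
  expect_equal(lamina_profile(img3, roi)$intensity, prof$intensity * 3)
  # uniform image gives a constant profile
  u <- matrix(7, 100, 100); attr(u, "um_per_px") <- 1
  pu <- lamina_profile(u, line_roi_spec(c(20, 50), 0, 50, 10, 3, 5))
  expect_true(all(pu$intensity == 7))
  # 300-um line sampled every 10 um has 31 points
  big <- matrix(1, 500, 500); attr(big, "um_per_px") <- 1
  p300 <- lamina_profile(big, line_roi_spec(c(50, 250), 0, 300, 10, 1, 0))
  expect_equal(nrow(p300), 31L)
  # anchored positions put the landmark at the anchor
  roi_a <- line_roi_spec(c(50, 250), 0, 300, 10, 1, 0,
                         anchor_um = 150, landmark_um = 120)
  pa <- lamina_profile(big, roi_a)
  expect_equal(pa$position_um[13], 150)
  expect_error(lamina_profile(big, line_roi_spec(c(480, 250), 0, 300,
                                                 10, 1, 0)),
               "exits")
})

test_that("region ratio is calibrated across planted fractions", {
  for (f in c(0.25, 0.5, 0.75, 1.0)) {
    vals <- vapply(1:4, function(s) {
      st <- render_fish_stack(fish_actd_spec(fraction = f), seed = 600 + s)
      region_remaining_fraction(max_project(st))
    }, 0)
    expect_lt(abs(mean(vals) - 100 * f), 2)
  }
  # degenerate geometry
  img <- matrix(1, 100, 100); attr(img, "um_per_px") <- 1
  expect_error(region_remaining_fraction(
    img, region_spec(region_diam_um = 500, core_diam_um = 10)),
    "entire field")
})

test_that("rectangular ROI means are exact", {
  img <- matrix(0, 10, 10)
  img[, 6:10] <- 100
  expect_equal(roi_mean_intensity(img, c(1, 1, 10, 10)), 50)
  expect_equal(roi_mean_intensity(img, c(3, 3, 3, 3)), 0)
  img2 <- matrix(runif(100), 10, 10)
  expect_equal(roi_mean_intensity(img2, c(2, 4, 2, 4)), img2[4, 2])
  expect_error(roi_mean_intensity(img, c(5, 5, 11, 5)), "exceeds")
  expect_error(roi_mean_intensity(img, c(5, 5, 4, 5)), "empty")
})

test_that("TIFF round trip preserves the stack and its metadata", {
  skip_if_not_installed("tiff")
  st <- render_fish_stack(fish_image_spec(field_um = 25.6, um_per_px = 0.4,
                                          bands = NULL,
                                          uniform_density = 0.02),
                          seed = 1)
  f <- tempfile(fileext = ".tif")
  write_stack_tiff(st$stack, f)
  back <- read_stack_tiff(f)
  expect_equal(dim(back), dim(st$stack))
  expect_equal(attr(back, "um_per_px"), 0.4)
  expect_lt(max(abs(back - st$stack)) / max(st$stack), 1e-6)
})
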