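test_that("enrichment index matches designed channel intensities", {
  g <- matrix(200, 32, 32); r <- matrix(600, 32, 32)
  expect_equal(enrichment_index(g, r), 0.25)
  expect_equal(enrichment_index(g, g), 0.5)
  expect_equal(enrichment_index(g, r * 0), 1)
  # complement identity and common-gain invariance on any ROI
  roi <- matrix(FALSE, 32, 32); roi[5:20, 8:30] <- TRUE
  set.seed(2)
  g2 <- matrix(runif(32 * 32), 32); r2 <- matrix(runif(32 * 32), 32)
  expect_equal(enrichment_index(g2, r2, roi) + enrichment_index(r2, g2, roi), 1)
  expect_equal(enrichment_index(g2 * 7, r2 * 7, roi),
               enrichment_index(g2, r2, roi))
  expect_error(enrichment_index(g * 0, r * 0), "undefined index")
  expect_error(enrichment_index(g, matrix(1, 16, 16)), "shape")
})

test_that("box counting recovers analytic fractal dimensions", {
  fd <- function(img, ...) fractal_metrics(img, ...)$fd
  expect_equal(fd(fractal_fixture("filled_square", 729)), 2, tolerance = 0.025)
  expect_equal(fd(fractal_fixture("line", 729)), 1, tolerance = 0.05)
  expect_equal(fd(fractal_fixture("sierpinski", 729, depth = 5)),
               log(8) / log(3), tolerance = 0.025)
  expect_error(fractal_metrics(matrix(0, 64, 64)), "empty foreground")
  expect_error(fractal_metrics(matrix(1, 64, 64), scales = c(2, 4, 8)),
               "4 box-counting scales")
})

test_that("lacunarity of a uniform image is zero at dividing scales", {
  fm <- fractal_metrics(matrix(1, 256, 256), scales = c(2, 4, 8, 16, 32))
  expect_identical(fm$lacunarity, 0)
  expect_true(all(fm$per_scale$mass_var == 0))
})

test_that("fractal dimension is invariant to translation and rotation", {
  carpet <- fractal_fixture("sierpinski", 243, depth = 4)
  base <- fractal_metrics(carpet)$fd
  pad <- matrix(0, 343, 343)
  pad[51:293, 31:273] <- carpet
  expect_equal(fractal_metrics(pad)$fd, base, tolerance = 0.02)
  rot <- t(carpet[nrow(carpet):1, ])  # 90 degree rotation
  expect_equal(fractal_metrics(rot)$fd, base, tolerance = 0.02)
})

test_that("dense fixtures score higher fd and lower lacunarity than porous", {
  # dense woven matrix (scar-like) vs sparse porous lattice (healthy-like)
  set.seed(9)
  dense <- matrix(0, 243, 243)
  dense[matrix(runif(243 * 243), 243) < 0.75] <- 1
  porous <- fractal_fixture("sierpinski", 243, depth = 4)
  fd_d <- fractal_metrics(dense)
  fd_p <- fractal_metrics(porous)
  expect_gt(fd_d$fd, fd_p$fd)
  expect_lt(fd_d$lacunarity, fd_p$lacunarity)
})

test_that("CMYK conversion matches the closed formulas", {
  px <- function(r, g, b) {
    im <- array(c(r, g, b), c(1, 1, 3))
    as.vector(rgb_to_cmyk(im))
  }
  expect_equal(px(0, 0, 0), c(0, 0, 0, 1))        # black
  expect_equal(px(1, 1, 1), c(0, 0, 0, 0))        # white
  expect_equal(px(0, 0, 1), c(1, 1, 0, 0))        # pure blue
  expect_equal(px(0.5, 0.25, 0.75), c((1 - 0.5 - 0.25) / 0.75,
                                      (1 - 0.25 - 0.25) / 0.75,
                                      (1 - 0.75 - 0.25) / 0.75, 0.25))
  expect_error(rgb_to_cmyk(array(0, c(4, 4, 2))), "RGB")
})

test_that("nuclei counting recovers the planted count and size gate", {
  hf <- histology_fixture(n_nuclei = 12, nucleus_area = 80,
                          collagen_area = 0, seed = 4)
  expect_identical(count_nuclei(hf$image)$count, 12L)
  # blank section counts zero
  blank <- histology_fixture(n_nuclei = 0, collagen_area = 0, noise_sd = 0,
                             seed = 1)
  expect_identical(suppressMessages(count_nuclei(blank$image))$count, 0L)
  # a single oversized object is rejected by the 30-200 px^2 gate
  big <- histology_fixture(n_nuclei = 1, nucleus_area = 500,
                           collagen_area = 0, seed = 2)
  expect_identical(count_nuclei(big$image)$count, 0L)
})

test_that("collagen scar area is recovered from the cyan channel", {
  hf <- histology_fixture(n_nuclei = 0, collagen_area = 10000, seed = 5)
  sa <- scar_area(hf$image)
  expect_equal(sa$area_px2, 10000, tolerance = 0.02)
  expect_equal(sa$fraction, 10000 / (512 * 512), tolerance = 0.02)
  expect_equal(scar_area(hf$image, pixel_size = 2)$area_um2,
               sa$area_px2 * 4)
  # an all-white section has no collagen signal
  white <- array(1, c(128, 128, 3))
  expect_equal(suppressMessages(scar_area(white))$area_px2, 0)
  # red-only tissue has a dark cyan channel
  red <- array(rep(c(0.9, 0.1, 0.1), each = 128 * 128), c(128, 128, 3))
  expect_lt(suppressMessages(scar_area(red))$fraction, 0.01)
})

test_that("structure tensor recovers stripe orientations", {
  for (ang in c(0, 30, 120)) {
    of <- orientation_field(stripe_image(ang), grid_size = 64)
    delta <- (of$field$angle - ang + 90) %% 180 - 90
    expect_lt(max(abs(delta)), 2)
    expect_gt(min(of$field$coherence), 0.9)
  }
})

test_that("orientation is equivariant and noise is incoherent", {
  # rotating the texture by 40 degrees shifts every recovered angle by 40
  of30 <- orientation_field(stripe_image(30), grid_size = 64)
  of70 <- orientation_field(stripe_image(70), grid_size = 64)
  delta <- (of70$field$angle - of30$field$angle - 40 + 90) %% 180 - 90
  expect_lt(max(abs(delta)), 2)
  # isotropic noise: low mean coherence over seeds
  cohs <- vapply(1:3, function(s) {
    set.seed(s)
    noise <- matrix(runif(200 * 200), 200)
    mean(orientation_field(noise, grid_size = 50)$field$coherence)
  }, numeric(1))
  expect_lt(mean(cohs), 0.2)
  # a flat image is flagged unreliable everywhere
  flat <- orientation_field(matrix(1, 128, 128), grid_size = 64)
  expect_true(all(!flat$field$reliable))
  expect_true(all(flat$field$coherence == 0))
})

test_that("front trajectories are perpendicular to planar contours", {
  frames <- lapply(c(60, 110, 160), function(x0) {
    m <- matrix(0, 200, 256)
    m[, 1:x0] <- 1
    m
  })
  fmod <- front_trajectories(frames, smoothing = 6)
  expect_true(fmod$advancing)
  dirs <- vapply(fmod$trajectories, function(p) {
    if (nrow(p) < 5) return(NA_real_)
    v <- p[nrow(p), ] - p[1, ]
    atan2(v[2], v[1]) * 180 / pi
  }, numeric(1))
  dirs <- dirs[!is.na(dirs)]
  expect_gt(length(dirs), 5)
  # contours are vertical (tangent at 90 deg): orthogonality means
  # trajectories run along +x within 3 degrees
  expect_lt(max(abs(dirs)), 3)
})

test_that("a shrinking circular front yields centripetal trajectories", {
  mk_disc <- function(r) {
    xs <- matrix(rep(0:199, each = 200), 200)
    ys <- matrix(rep(0:199, 200), 200)
    ((xs - 99.5)^2 + (ys - 99.5)^2 <= r^2) * 1
  }
  frames <- lapply(c(80, 55, 30), mk_disc)
  fmod <- front_trajectories(frames, smoothing = 5)
  expect_false(fmod$advancing)
  for (p in fmod$trajectories) {
    if (nrow(p) < 5) next
    r0 <- sqrt(sum((p[1, ] - 99.5)^2))
    r1 <- sqrt(sum((p[nrow(p), ] - 99.5)^2))
    expect_lt(r1, r0)  # moves towards the centre
  }
})

test_that("a static front yields zero-length trajectories", {
  m <- matrix(0, 128, 128); m[, 1:60] <- 1
  fmod <- front_trajectories(list(m, m, m), smoothing = 5)
  expect_true(all(vapply(fmod$trajectories, nrow, integer(1)) == 1L))
})
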