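test_that("swarm_config enforces its invariants", {
  expect_error(swarm_config(n_cells = 0), "invalid config")
  expect_error(swarm_config(n_frames = 1), "invalid config")
  expect_error(swarm_config(dt = 0), "invalid config")
  expect_error(swarm_config(noise_weight = -1), "invalid config")
  expect_error(swarm_config(mode = "random", attraction_weight = 1),
               "invalid config")
  cfg <- swarm_config(mode = "random")
  expect_identical(cfg$attraction_weight, 0)
  expect_identical(cfg$alignment_weight, 0)
})

test_that("simulations are bit-reproducible given the seed", {
  cfg <- swarm_config(n_cells = 20, n_frames = 10, seed = 99)
  t1 <- simulate_tracks(cfg)
  t2 <- simulate_tracks(cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$z, t2$z)
  t3 <- simulate_tracks(swarm_config(n_cells = 20, n_frames = 10, seed = 100))
  expect_false(identical(t1$x, t3$x))
})

test_that("random-mode step length equals the configured speed exactly", {
  cfg <- swarm_config(mode = "random", n_cells = 1000, n_frames = 20,
                      speed = 2, arena_radius = 1e4, dim = 3, seed = 5)
  kin <- step_kinematics(simulate_tracks(cfg))
  expect_equal(mean(kin$steps$step_displacement), 2, tolerance = 0.01)
  # step length is fixed by construction except at boundary reflections
  expect_equal(median(kin$steps$step_displacement), 2, tolerance = 1e-12)
})

test_that("halving the speed halves the mean step speed", {
  v <- vapply(c(2, 1), function(s) {
    cfg <- swarm_config(mode = "random", n_cells = 200, n_frames = 20,
                        speed = s, arena_radius = 1e4, seed = 7)
    mean(step_kinematics(simulate_tracks(cfg))$steps$velocity)
  }, numeric(1))
  expect_equal(v[1] / v[2], 2, tolerance = 0.01)
})

test_that("swarm mode drifts centripetally over seeds", {
  for (seed in 1:5) {
    cfg <- swarm_config(mode = "swarm", n_cells = 200, n_frames = 40,
                        attraction_weight = 1, noise_weight = 0.1, seed = seed)
    trk <- simulate_tracks(cfg)
    r <- tapply(sqrt(trk$x^2 + trk$y^2 + trk$z^2), trk$frame, mean)
    expect_lt(r[[length(r)]], r[[1]])
  }
})

test_that("random-mode MSD grows linearly with slope speed^2", {
  cfg <- swarm_config(mode = "random", n_cells = 1000, n_frames = 41,
                      speed = 2, arena_radius = 1e4, dim = 3, seed = 21)
  trk <- simulate_tracks(cfg)
  pos <- array(c(trk$x, trk$y, trk$z), c(41, 1000, 3))
  lags <- c(1, 2, 4, 8, 16)
  msd <- vapply(lags, function(L) {
    d <- pos[seq_len(41 - L) + L, , ] - pos[seq_len(41 - L), , ]
    mean(apply(d^2, c(1, 2), sum))
  }, numeric(1))
  slope <- sum(msd * lags) / sum(lags^2)  # regression through the origin
  expect_equal(slope, 4, tolerance = 0.05)
})

test_that("chimera mode seeds two lineages in concentric regions", {
  cfg <- swarm_config(mode = "chimera", n_cells = 100, n_frames = 3,
                      arena_radius = 100, seed = 3)
  trk <- simulate_tracks(cfg)
  f0 <- trk[trk$frame == 0, ]
  r <- sqrt(f0$x^2 + f0$y^2 + f0$z^2)
  expect_true(all(r[f0$lineage == "inner"] <= 50))
  expect_true(all(r[f0$lineage == "outer"] >= 50))
  expect_setequal(unique(trk$lineage), c("inner", "outer"))
})

test_that("rendered movies place spots at cell positions", {
  df <- data.frame(track_id = "a", frame = 0:2, x = 10.2, y = 20.7, z = 0)
  tt <- track_table(df, dt = 15)
  mv <- render_movie(tt, render_config(image_shape = c(64, 64), spot_sigma = 2,
                                       offset = c(0, 0)))
  for (t in 1:3) {
    fr <- mv$pixels[t, 1, , ]
    pk <- which(fr == max(fr), arr.ind = TRUE)
    expect_identical(unname(pk[1, ]), c(22L, 11L))  # rounded (y, x) + 1
  }
  # static noiseless scene renders identical frames
  expect_identical(mv$pixels[1, 1, , ], mv$pixels[3, 1, , ])
})

test_that("channel sums are proportional to per-lineage cell counts", {
  df <- rbind(
    data.frame(track_id = sprintf("g%d", 1:9), frame = 0,
               x = seq(-60, 60, length.out = 9), y = -30, z = 0,
               lineage = "epf"),
    data.frame(track_id = sprintf("r%d", 1:3), frame = 0,
               x = c(-40, 0, 40), y = 30, z = 0, lineage = "enf"))
  tt <- track_table(df, dt = 15)
  mv <- render_movie(tt, render_config(image_shape = c(200, 200), spot_sigma = 2,
                                       channel_map = c(epf = 1, enf = 2)))
  s <- c(sum(mv$pixels[1, 1, , ]), sum(mv$pixels[1, 2, , ]))
  expect_equal(s[1] / s[2], 3, tolerance = 0.05)
})

test_that("renderer rejects tracks outside the canvas and empty input", {
  df <- data.frame(track_id = "a", frame = 0, x = 500, y = 0, z = 0)
  expect_error(render_movie(track_table(df, dt = 15),
                            render_config(image_shape = c(64, 64))),
               "fit inside")
  expect_error(render_movie(track_table(df[0, ], dt = 15)), "empty")
})

test_that("advected pairs carry their analytic ground truth", {
  rc <- render_config(image_shape = c(128, 128), seed = 2)
  # zero translation: identical images
  p0 <- advected_pair(flow_spec("translation", dx = 0, dy = 0), rc)
  expect_identical(p0$a, p0$b)
  # full-frame correlation peaks at the planted shift
  p <- advected_pair(flow_spec("translation", dx = 5, dy = -3), rc)
  s <- brute_xcorr_argmax(p$a, p$b, 8)
  expect_identical(unname(s), c(5, -3))
  # rigid-rotation ground truth equals the closed-form displacement field
  fl <- flow_spec("rotation", centre = c(63.5, 63.5), angle = 2)
  gt <- flow_displacement(fl, c(0, 63.5, 100), c(0, 63.5, 20))
  th <- 2 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  for (i in 1:3) {
    p0v <- c(c(0, 63.5, 100)[i], c(0, 63.5, 20)[i]) - c(63.5, 63.5)
    d <- R %*% p0v - p0v
    expect_equal(c(gt$u[i], gt$v[i]), as.vector(d), tolerance = 1e-12)
  }
  expect_error(advected_pair(flow_spec("translation", dx = 500, dy = 0), rc),
               "invalid flow")
})

test_that("fractal fixtures have the constructed foreground", {
  expect_equal(mean(fractal_fixture("filled_square", 81)), 1)
  expect_equal(sum(fractal_fixture("line", 729)), 729)
  for (d in 1:3) {
    expect_equal(mean(fractal_fixture("sierpinski", 729, depth = d)),
                 (8 / 9)^d)
  }
  expect_error(fractal_fixture("sierpinski", 100, depth = 5), "invalid config")
})

test_that("histology fixtures plant exact ground truth", {
  blank <- histology_fixture(n_nuclei = 0, collagen_area = 0, seed = 1)
  expect_equal(sum(blank$nuclei_mask), 0)
  expect_equal(sum(blank$collagen_mask), 0)
  hf <- histology_fixture(n_nuclei = 12, nucleus_area = 80,
                          collagen_area = 10000, seed = 4)
  expect_identical(nrow(hf$nuclei_centres), 12L)
  expect_identical(sum(hf$collagen_mask), 10000L)
  expect_false(any(hf$collagen_mask & hf$nuclei_mask))
})
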