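test_that("mutual-nearest-neighbour linking recovers clean tracks", {
  # single detection per frame -> one full-length track
  det <- data.frame(frame = 0:9, x = (0:9) * 0.5, y = 0, z = 0)
  tt <- link_detections(det, max_disp = 2)
  expect_identical(length(unique(tt$track_id)), 1L)
  expect_identical(nrow(tt), 10L)
  # well-separated simulated tracks are recovered exactly
  cfg <- swarm_config(mode = "random", n_cells = 20, n_frames = 15, speed = 1,
                      arena_radius = 400, dim = 3, seed = 8)
  truth <- simulate_tracks(cfg)
  det2 <- as.data.frame(truth[, c("frame", "x", "y", "z")])
  linked <- link_detections(det2, max_disp = 3)
  expect_identical(length(unique(linked$track_id)), 20L)
  # same partition of detections into tracks as the ground truth
  key <- function(tt) {
    unname(split(paste(round(tt$x, 6), round(tt$y, 6), tt$frame),
                 tt$track_id))
  }
  expect_setequal(vapply(key(linked), paste, collapse = ";", ""),
                  vapply(key(truth), paste, collapse = ";", ""))
})

test_that("a jump beyond max_disp splits the track", {
  det <- data.frame(frame = 0:9, x = c(rep(0, 5), rep(50, 5)), y = 0, z = 0)
  tt <- link_detections(det, max_disp = 5)
  expect_identical(length(unique(tt$track_id)), 2L)
  sizes <- table(tt$track_id)
  expect_setequal(as.integer(sizes), c(5L, 5L))
  expect_error(link_detections(det, max_disp = 0), "positive")
})

test_that("step kinematics reproduce hand-computed 3D distances", {
  df <- data.frame(track_id = "a", frame = 0:2,
                   x = c(0, 3, 3), y = c(0, 4, 4), z = 0)
  kin <- step_kinematics(track_table(df, dt = 15))
  expect_equal(kin$steps$step_displacement, c(5, 0))
  expect_equal(kin$steps$velocity, c(1 / 3, 0))
  # a track of length 1 contributes no rows
  df1 <- rbind(df, data.frame(track_id = "b", frame = 0, x = 1, y = 1, z = 1))
  expect_identical(nrow(step_kinematics(track_table(df1, dt = 15))$steps), 2L)
  # totals equal path length
  cfg <- swarm_config(mode = "random", n_cells = 5, n_frames = 20, speed = 2,
                      arena_radius = 1e3, seed = 4)
  trk <- simulate_tracks(cfg)
  kin2 <- step_kinematics(trk)
  tot <- tapply(kin2$steps$step_displacement, kin2$steps$track_id, sum)
  expect_equal(unname(tot), rep(2 * 19, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("uniform motion scores exactly zero similarity", {
  tt <- uniform_motion_tracks(50, 10, step = c(1, 1, 0), seed = 1)
  sim <- movement_similarity(tt)
  expect_identical(sim$global_score, 0)
  expect_true(all(sim$per_cell$score == 0))
})

test_that("antiparallel neighbours score 180 degrees", {
  df <- data.frame(track_id = c("c1", "c2", "c1", "c2"),
                   frame = c(0, 0, 1, 1),
                   x = c(0, 1, 2, -1), y = 0, z = 0)
  tt <- track_table(df, dt = 15)
  sim <- suppressMessages(movement_similarity(tt, min_cells = 2))
  expect_identical(sim$per_cell$score, c(180, 180))
  # zero-length movement vectors are skipped pairwise
  df$x[3] <- 0  # c1 does not move
  sim0 <- suppressMessages(movement_similarity(track_table(df, dt = 15),
                                               min_cells = 2))
  expect_identical(nrow(sim0$per_cell), 0L)
  expect_true(is.na(sim0$global_score))
})

test_that("isotropic random motion converges to 90 degrees", {
  gl <- vapply(1:3, function(s) {
    cfg <- swarm_config(mode = "random", n_cells = 500, n_frames = 10,
                        speed = 1, arena_radius = 500, dim = 3, seed = s)
    movement_similarity(simulate_tracks(cfg))$global_score
  }, numeric(1))
  expect_equal(mean(gl), 90, tolerance = 1 / 90)  # +- 1 degree
})

test_that("similarity is invariant to rigid motion and step rescaling", {
  cfg <- swarm_config(mode = "swarm", n_cells = 60, n_frames = 6, seed = 17)
  trk <- simulate_tracks(cfg)
  base <- movement_similarity(trk)$global_score
  # global rotation about z plus translation
  th <- 0.7
  rot <- trk
  rot$x <- cos(th) * trk$x - sin(th) * trk$y + 100
  rot$y <- sin(th) * trk$x + cos(th) * trk$y - 40
  expect_equal(movement_similarity(rot)$global_score, base, tolerance = 1e-6)
  # uniform rescaling of all coordinates rescales every movement vector
  sc <- trk
  sc$x <- trk$x * 3; sc$y <- trk$y * 3; sc$z <- trk$z * 3
  expect_equal(movement_similarity(sc)$global_score, base, tolerance = 1e-6)
})

test_that("swarming scores below random motion at matched speed", {
  for (s in 1:5) {
    sw <- movement_similarity(simulate_tracks(
      swarm_config(mode = "swarm", n_cells = 150, n_frames = 8,
                   alignment_weight = 1, seed = s)))$global_score
    rd <- movement_similarity(simulate_tracks(
      swarm_config(mode = "random", n_cells = 150, n_frames = 8,
                   seed = s)))$global_score
    expect_lt(sw, rd)
  }
})

test_that("small-instance scores match an all-pairs brute force", {
  set.seed(30)
  for (rep in 1:3) {
    n <- 8
    p0 <- matrix(runif(n * 3) * 40, n, 3)
    v <- matrix(rnorm(n * 3), n, 3)
    df <- rbind(
      data.frame(track_id = sprintf("c%d", 1:n), frame = 0,
                 x = p0[, 1], y = p0[, 2], z = p0[, 3]),
      data.frame(track_id = sprintf("c%d", 1:n), frame = 1,
                 x = p0[, 1] + v[, 1], y = p0[, 2] + v[, 2],
                 z = p0[, 3] + v[, 3]))
    sim <- movement_similarity(track_table(df, dt = 15), min_cells = 5)
    ref_edges <- scipy_delaunay_edges(p0)
    brute <- vapply(seq_len(n), function(i) {
      nb <- c(ref_edges[ref_edges[, 1] == i, 2],
              ref_edges[ref_edges[, 2] == i, 1])
      ang <- vapply(nb, function(j) {
        acos(min(1, max(-1, sum(v[i, ] * v[j, ]) /
                          sqrt(sum(v[i, ]^2) * sum(v[j, ]^2))))) * 180 / pi
      }, numeric(1))
      mean(ang)
    }, numeric(1))
    got <- sim$per_cell$score[match(sprintf("c%d", 1:n), sim$per_cell$track_id)]
    expect_equal(got, brute, tolerance = 1e-9)
  }
})

test_that("landmark displacement accumulates alternate-frame steps", {
  mk <- function(fun) {
    do.call(rbind, lapply(1:5, function(i) {
      data.frame(track_id = sprintf("L%d", i), frame = 0:10,
                 x = fun(i, 0:10), y = 0, z = 0)
    }))
  }
  # static landmarks: flat zero series
  st <- landmark_displacement(track_table(mk(function(i, f) i), dt = 15))
  expect_true(all(st$cumulative == 0))
  # uniform translation of 2 px per frame, stride 2 -> 4 px per sample
  mv <- landmark_displacement(track_table(mk(function(i, f) i + 2 * f),
                                          dt = 15))
  expect_true(all(mv$mean_displacement == 4))
  expect_equal(mv$cumulative, cumsum(rep(4, nrow(mv))))
  # wrong landmark count is an explicit input error
  four <- mk(function(i, f) i)
  four <- four[four$track_id != "L5", ]
  expect_error(landmark_displacement(track_table(four, dt = 15)), "exactly 5")
  # matches a brute-force recomputation on simulated swarm landmarks
  cfg <- swarm_config(mode = "swarm", n_cells = 5, n_frames = 11, seed = 2)
  trk <- simulate_tracks(cfg)
  ld <- landmark_displacement(trk, stride = 2)
  pos <- array(c(trk$x, trk$y, trk$z), c(11, 5, 3))
  ref <- vapply(seq(3, 11, 2), function(f) {
    mean(sqrt(rowSums((pos[f, , ] - pos[f - 2, , ])^2)))
  }, numeric(1))
  expect_equal(ld$mean_displacement, ref, tolerance = 1e-9)
})

test_that("time-coded export draws the trailing window with a fixed ramp", {
  df <- data.frame(track_id = "a", frame = 0:29, x = 0:29, y = 0, z = 0)
  tt <- track_table(df, dt = 15)
  segs <- time_coded_segments(tt, at_frame = 29, tail = 12)
  expect_identical(nrow(segs), 12L)
  expect_identical(segs$colour[nrow(segs)], "#FF0000")
  expect_identical(nrow(time_coded_segments(tt, tail = 1)), 1L)
  # two tracks: every track's last segment sits at the ramp endpoint
  df2 <- rbind(df, data.frame(track_id = "b", frame = 0:29, x = 0,
                              y = 0:29, z = 0))
  segs2 <- time_coded_segments(track_table(df2, dt = 15), tail = 3)
  last <- tapply(seq_len(nrow(segs2)), segs2$track_id,
                 function(i) segs2$colour[max(i)])
  expect_true(all(last == "#FF0000"))
})
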