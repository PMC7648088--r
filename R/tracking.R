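#' Link frame-by-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames:
#' a detection in frame `f` is linked to one in frame `f + 1` when each is
#' the other's nearest neighbour and their distance does not exceed
#' `max_disp`.  Unlinked detections start new tracks.  The procedure is
#' deterministic; there is no gap closing or merge/split handling.
#'
#' @param detections data frame with columns `frame`, `x`, `y` and optionally
#'   `z` and `intensity`.
#' @param max_disp maximum link length in pixels (> 0).
#' @param dt frame interval in minutes used to fill `t_min`.
#' @return a [track_table()].
#' @export
link_detections <- function(detections, max_disp, dt = 15) {
  if (max_disp <= 0) stop("max_disp must be positive")
  detections <- as.data.frame(detections)
  if (!("z" %in% names(detections))) detections$z <- 0
  if (nrow(detections) == 0) {
    return(track_table(tibble(track_id = character(), frame = integer(),
                              x = numeric(), y = numeric(), z = numeric()),
                       dt = dt))
  }
  frames <- sort(unique(detections$frame))
  per_frame <- lapply(frames, function(f) {
    as.matrix(detections[detections$frame == f, c("x", "y", "z")])
  })
  next_id <- 0L
  new_ids <- function(k) {
    ids <- next_id + seq_len(k)
    next_id <<- next_id + k
    ids
  }
  ids_prev <- new_ids(nrow(per_frame[[1]]))
  rows <- list(data.frame(track_id = ids_prev, frame = frames[1],
                          per_frame[[1]]))
  for (i in seq_along(frames)[-1]) {
    cur <- per_frame[[i]]
    prev <- per_frame[[i - 1]]
    ids_cur <- rep(NA_integer_, nrow(cur))
    if (frames[i] - frames[i - 1] == 1 && nrow(prev) > 0 && nrow(cur) > 0) {
      d2 <- outer(rowSums(prev^2), rowSums(cur^2), "+") - 2 * prev %*% t(cur)
      d2[d2 < 0] <- 0
      nn_fwd <- apply(d2, 1, which.min)
      nn_bwd <- apply(d2, 2, which.min)
      for (p in seq_len(nrow(prev))) {
        q <- nn_fwd[p]
        if (nn_bwd[q] == p && d2[p, q] <= max_disp^2) ids_cur[q] <- ids_prev[p]
      }
    }
    fresh <- is.na(ids_cur)
    if (any(fresh)) ids_cur[fresh] <- new_ids(sum(fresh))
    rows[[i]] <- data.frame(track_id = ids_cur, frame = frames[i], cur)
    ids_prev <- ids_cur
  }
  df <- do.call(rbind, rows)
  df$track_id <- sprintf("track%04d", df$track_id)
  track_table(df, dt = dt)
}

#' Per-step 3D displacement and velocity of tracks
#'
#' Computes the Euclidean 3D distance between positions of the same cell at
#' consecutive time points, the per-step velocity (`distance / dt`) and a
#' population velocity-versus-time curve smoothed with a centred moving
#' average.
#'
#' @param tracks a [track_table()].
#' @param dt frame interval in minutes (defaults to the table's attribute).
#' @param smooth_window centred moving-average window (time points) for the
#'   velocity curve.
#' @return list of class `kinematics` with `steps` (tibble: `track_id`,
#'   `frame` of the step end, `t_min`, `step_displacement` px, `velocity`
#'   px/min) and `velocity_curve` (tibble: `t_min`, `mean_velocity`,
#'   `smoothed`).
#' @export
step_kinematics <- function(tracks, dt = NULL, smooth_window = 5) {
  dt <- track_dt(tracks, dt)
  parts <- split(seq_len(nrow(tracks)), tracks$track_id)
  steps <- lapply(parts, function(idx) {
    if (length(idx) < 2) return(NULL)
    p <- as.matrix(tracks[idx, c("x", "y", "z")])
    dp <- diff(p)
    disp <- sqrt(rowSums(dp^2))
    gap <- diff(tracks$frame[idx])
    tibble(track_id = tracks$track_id[idx[1]],
           frame = tracks$frame[idx][-1],
           t_min = tracks$t_min[idx][-1],
           step_displacement = disp,
           velocity = disp / (gap * dt))
  })
  steps <- do.call(rbind, steps[!vapply(steps, is.null, logical(1))])
  if (is.null(steps)) {
    steps <- tibble(track_id = character(), frame = integer(),
                    t_min = numeric(), step_displacement = numeric(),
                    velocity = numeric())
  }
  curve <- NULL
  if (nrow(steps) > 0) {
    agg <- aggregate(velocity ~ t_min, data = steps, FUN = mean)
    agg <- agg[order(agg$t_min), ]
    sm <- if (nrow(agg) >= smooth_window) {
      as.numeric(stats::filter(agg$velocity,
                               rep(1 / smooth_window, smooth_window),
                               sides = 2))
    } else {
      agg$velocity
    }
    curve <- tibble(t_min = agg$t_min, mean_velocity = agg$velocity,
                    smoothed = sm)
  }
  structure(list(steps = as_tibble(steps), velocity_curve = curve, dt = dt),
            class = "kinematics")
}

#' Cumulative landmark displacement over time
#'
#' Displacement is measured on exactly five landmark tracks between alternate
#' frames (stride 2 by default); the per-interval mean over the five
#' landmarks is accumulated and reported versus time.
#'
#' @param landmarks a [track_table()] with exactly 5 tracks sharing frames.
#' @param stride frame stride between compared positions (default 2,
#'   i.e. alternate frames).
#' @param dt frame interval in minutes.
#' @return tibble with `frame`, `t_min`, `mean_displacement` (px per
#'   interval) and `cumulative` (px).
#' @export
landmark_displacement <- function(landmarks, stride = 2, dt = NULL) {
  dt <- track_dt(landmarks, dt)
  ids <- unique(landmarks$track_id)
  if (length(ids) != 5) {
    stop("landmark displacement requires exactly 5 landmark tracks, got ",
         length(ids))
  }
  frames <- sort(unique(landmarks$frame))
  common <- Reduce(intersect, lapply(split(landmarks$frame, landmarks$track_id),
                                     identity))
  frames <- frames[frames %in% common]
  sampled <- frames[seq(1, length(frames), by = stride)]
  if (length(sampled) < 2) stop("not enough frames for the given stride")
  pos <- lapply(sampled, function(f) {
    m <- landmarks[landmarks$frame == f, ]
    m <- m[match(ids, m$track_id), ]
    as.matrix(m[, c("x", "y", "z")])
  })
  disp <- vapply(seq_along(sampled)[-1], function(i) {
    mean(sqrt(rowSums((pos[[i]] - pos[[i - 1]])^2)))
  }, numeric(1))
  tibble(frame = sampled[-1], t_min = sampled[-1] * dt,
         mean_displacement = disp, cumulative = cumsum(disp))
}

#' Time-coded track segments for visual overlays
#'
#' Emits the trailing `tail` segments of every track at a reference frame,
#' coloured along a fixed purple-to-red ramp as a function of time over the
#' whole movie (the classic time-coded track rendering; the trailing-window
#' display keeps images uncluttered).
#'
#' @param tracks a [track_table()].
#' @param at_frame reference frame (default: last frame of the table).
#' @param tail number of trailing segments per track (default 12).
#' @return tibble of segments: `track_id`, `frame` (segment end), `x0`, `y0`,
#'   `x1`, `y1`, `frac` (time fraction) and `colour` (hex).
#' @export
time_coded_segments <- function(tracks, at_frame = NULL, tail = 12) {
  if (tail < 1) stop("tail must be >= 1")
  if (nrow(tracks) == 0) {
    return(tibble(track_id = character(), frame = integer(), x0 = numeric(),
                  y0 = numeric(), x1 = numeric(), y1 = numeric(),
                  frac = numeric(), colour = character()))
  }
  at_frame <- at_frame %||% max(tracks$frame)
  f0 <- min(tracks$frame)
  ramp <- colorRampPalette(c("#A020F0", "#0000FF", "#00FFFF", "#00FF00",
                             "#FFFF00", "#FF0000"))(256)
  span <- max(1, max(tracks$frame) - f0)
  parts <- split(seq_len(nrow(tracks)), tracks$track_id)
  segs <- lapply(parts, function(idx) {
    idx <- idx[tracks$frame[idx] <= at_frame]
    if (length(idx) < 2) return(NULL)
    idx <- idx[max(1, length(idx) - tail):length(idx)]
    n <- length(idx)
    fr <- tracks$frame[idx]
    frac <- (fr[-1] - f0) / span
    tibble(track_id = tracks$track_id[idx[1]], frame = fr[-1],
           x0 = tracks$x[idx[-n]], y0 = tracks$y[idx[-n]],
           x1 = tracks$x[idx[-1]], y1 = tracks$y[idx[-1]],
           frac = frac, colour = ramp[1 + floor(frac * 255)])
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0) {
    return(time_coded_segments(tracks[0, ], at_frame, tail))
  }
  do.call(rbind, segs)
}

#' Plot time-coded track overlays
#'
#' @param tracks a [track_table()].
#' @param at_frame,tail see [time_coded_segments()].
#' @param ... passed to [graphics::plot()].
#' @return the segment tibble, invisibly.
#' @export
plot_time_coded_tracks <- function(tracks, at_frame = NULL, tail = 12, ...) {
  segs <- time_coded_segments(tracks, at_frame, tail)
  graphics::plot(range(c(segs$x0, segs$x1)), range(c(segs$y0, segs$y1)),
                 type = "n", xlab = "x (px)", ylab = "y (px)",
                 ylim = rev(range(c(segs$y0, segs$y1))), asp = 1, ...)
  graphics::segments(segs$x0, segs$y0, segs$x1, segs$y1, col = segs$colour,
                     lwd = 2)
  invisible(segs)
}
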