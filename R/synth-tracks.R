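#' Configuration of the agent-based migration simulator
#'
#' The simulator is a minimal Vicsek-type model with an added centripetal
#' attraction term.  Each cell carries a unit heading; at every step the new
#' heading is proportional to
#' `attraction_weight * u_centre + alignment_weight * mean(neighbour headings)
#'  + noise_weight * eta`, where `u_centre` points towards the arena centre,
#' neighbour headings are averaged over cells within `neighbor_radius`
#' (including the cell itself) and `eta` is an isotropic unit vector.  The
#' position advances by exactly `speed` pixels along the normalised heading,
#' so the per-step displacement is `speed` by construction.  Cells reflect at
#' the arena boundary.
#'
#' Three modes encode the behavioural dichotomy between scar-forming fascia
#' fibroblasts and oral-mucosa fibroblasts: `"swarm"` (attraction + alignment
#' on), `"random"` (both forced to zero, pure isotropic random walk) and
#' `"chimera"` (two lineages seeded in concentric discs, mirroring the
#' 4-mm/2-mm explant-chimera geometry).
#'
#' @param n_cells number of cells (>= 1).
#' @param arena_radius arena radius in pixels; cells reflect at the boundary.
#' @param dim spatial dimension, 2 or 3.
#' @param n_frames number of frames (>= 2); 97 frames at `dt = 15` min
#'   correspond to a 24-h recording.
#' @param dt frame interval in minutes (acquisition default 15).
#' @param speed step length in pixels per frame.
#' @param attraction_weight,alignment_weight,noise_weight non-negative weights
#'   of the heading update; in `"random"` mode attraction and alignment must
#'   be zero (the default).
#' @param neighbor_radius alignment interaction radius in pixels.
#' @param mode `"swarm"`, `"random"` or `"chimera"`.
#' @param seed integer seed; simulations are bit-reproducible given the seed.
#' @return a `swarm_config` list.
#' @export
swarm_config <- function(n_cells = 200, arena_radius = 150, dim = 3,
                         n_frames = 97, dt = 15, speed = 2,
                         attraction_weight = NULL, alignment_weight = NULL,
                         noise_weight = 0.5, neighbor_radius = 30,
                         mode = c("swarm", "random", "chimera"), seed = 1) {
  mode <- match.arg(mode)
  attraction_weight <- attraction_weight %||% if (mode == "random") 0 else 1
  alignment_weight <- alignment_weight %||% if (mode == "random") 0 else 1
  if (n_cells < 1 || n_frames < 2) {
    stop("invalid config: n_cells >= 1 and n_frames >= 2 required")
  }
  if (dt <= 0) stop("invalid config: dt must be positive")
  if (!dim %in% c(2, 3)) stop("invalid config: dim must be 2 or 3")
  if (min(attraction_weight, alignment_weight, noise_weight) < 0) {
    stop("invalid config: weights must be non-negative")
  }
  if (mode == "random" && (attraction_weight != 0 || alignment_weight != 0)) {
    stop("invalid config: random mode requires attraction and alignment = 0")
  }
  if (arena_radius <= 0 || speed < 0 || neighbor_radius <= 0) {
    stop("invalid config: arena_radius/neighbor_radius must be positive, speed >= 0")
  }
  structure(list(
    n_cells = as.integer(n_cells), arena_radius = arena_radius,
    dim = as.integer(dim), n_frames = as.integer(n_frames), dt = dt,
    speed = speed, attraction_weight = attraction_weight,
    alignment_weight = alignment_weight, noise_weight = noise_weight,
    neighbor_radius = neighbor_radius, mode = mode, seed = as.integer(seed)
  ), class = "swarm_config")
}

# uniform sample in a d-ball of radius R (optionally an annulus [r0, R])
random_in_ball <- function(n, d, R, r0 = 0) {
  dirs <- runit(n, d)
  u <- stats::runif(n)
  rad <- (r0^d + u * (R^d - r0^d))^(1 / d)
  dirs * rad
}

#' Simulate cell migration tracks
#'
#' Runs the agent-based model described in [swarm_config()] and returns a
#' [track_table()].  In `"chimera"` mode the returned table carries a
#' `lineage` column (`"outer"` for cells seeded in the outer annulus,
#' `"inner"` for the inner disc).
#'
#' @param config a [swarm_config()].
#' @return a [track_table()] with `n_cells * n_frames` rows; frames are
#'   0-based and `t_min = frame * dt`.
#' @export
simulate_tracks <- function(config) {
  if (!inherits(config, "swarm_config")) config <- do.call(swarm_config, config)
  n <- config$n_cells; d <- config$dim; R <- config$arena_radius
  nf <- config$n_frames
  with_seed(config$seed, {
    if (config$mode == "chimera") {
      n_in <- n %/% 2
      n_out <- n - n_in
      pos <- rbind(random_in_ball(n_out, d, R, r0 = R / 2),
                   random_in_ball(n_in, d, R / 2))
      lineage <- rep(c("outer", "inner"), c(n_out, n_in))
    } else {
      pos <- random_in_ball(n, d, R)
      lineage <- NULL
    }
    heading <- runit(n, d)
    traj <- array(NA_real_, c(nf, n, d))
    traj[1, , ] <- pos
    need_align <- config$alignment_weight > 0
    for (f in 2:nf) {
      drift <- matrix(0, n, d)
      if (config$attraction_weight > 0) {
        uc <- row_unit(-pos)
        drift <- drift + config$attraction_weight * uc
      }
      if (need_align) {
        d2 <- as.matrix(stats::dist(pos))^2
        adj <- d2 <= config$neighbor_radius^2   # includes self (diagonal)
        mh <- row_unit(adj %*% heading)
        drift <- drift + config$alignment_weight * mh
      }
      drift <- drift + config$noise_weight * runit(n, d)
      h <- row_unit(drift)
      zero <- attr(h, "zero")
      if (any(zero)) h[zero, ] <- heading[zero, , drop = FALSE]
      pos <- pos + config$speed * h
      heading <- h
      # reflect at the arena boundary
      r <- sqrt(rowSums(pos^2))
      out <- r > R
      if (any(out)) {
        nrm <- pos[out, , drop = FALSE] / r[out]
        pos[out, ] <- nrm * (2 * R - r[out])
        hh <- heading[out, , drop = FALSE]
        heading[out, ] <- hh - 2 * rowSums(hh * nrm) * nrm
      }
      traj[f, , ] <- pos
    }
    df <- tibble(
      track_id = rep(sprintf("cell%04d", seq_len(n)), each = nf),
      frame = rep(0:(nf - 1), n),
      x = as.vector(aperm(traj[, , 1, drop = FALSE], c(1, 2, 3))),
      y = as.vector(aperm(traj[, , 2, drop = FALSE], c(1, 2, 3))),
      z = if (d == 3) as.vector(aperm(traj[, , 3, drop = FALSE], c(1, 2, 3))) else 0
    )
    if (!is.null(lineage)) df$lineage <- rep(lineage, each = nf)
    tt <- track_table(df, dt = config$dt)
    attr(tt, "mode") <- config$mode
    attr(tt, "arena_radius") <- R
    tt
  })
}
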