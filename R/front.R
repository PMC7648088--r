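#' Leading-front contours and trajectory prediction
#'
#' For each selected time point the (maximum-intensity projected) frame is
#' Gaussian-smoothed and the leading front extracted as an iso-intensity
#' contour.  A scalar front-passage surface assigns every pixel the time
#' index at which the front passes it (first-coverage time for an advancing
#' front, last-coverage time for a receding one); its gradient integral
#' curves are locally perpendicular to every front contour and predict the
#' trajectory of the migrating swarm.  Trajectories are seeded on the
#' earliest front and integrated by fixed-step gradient ascent; a static
#' front yields zero-length trajectories.
#'
#' @param frames an [image_stack()] or a list of greyscale matrices.
#' @param times time indices to use (default: all).
#' @param channel channel to analyse when `frames` is an image stack
#'   (conventionally the lineage-reporter channel).
#' @param smoothing Gaussian smoothing scale in pixels applied to each frame
#'   and to the passage surface (default 8; the reference analysis used a
#'   heavier plugin-specific smoothing whose exact meaning is not public,
#'   so the scale is exposed as a parameter).
#' @param level iso-contour level as a fraction of the global smoothed
#'   maximum (default 0.5).
#' @param n_seeds number of trajectory seeds along the earliest front.
#' @param step_px integration step in pixels.
#' @param max_steps integration cap per trajectory.
#' @return list of class `front_model`: `contours` (per time, list of
#'   0-based xy polylines), `surface` (front-passage matrix), `trajectories`
#'   (list of 0-based xy polylines) and `times`.
#' @export
front_trajectories <- function(frames, times = NULL, channel = 1,
                               smoothing = 8, level = 0.5, n_seeds = 25,
                               step_px = 1, max_steps = 2000) {
  mats <- if (inherits(frames, "image_stack")) {
    nt <- dim(frames$pixels)[1]
    lapply(seq_len(nt), function(t) stack_frame(frames, t, channel))
  } else {
    frames
  }
  times <- times %||% seq_along(mats)
  if (length(times) < 2) stop("at least 2 time points are required")
  sm <- lapply(mats[times], gaussian_blur, sigma = smoothing)
  iso <- level * max(unlist(lapply(sm, max)))

  contours <- lapply(sm, function(m) {
    cl <- contourLines(x = seq_len(ncol(m)) - 1, y = seq_len(nrow(m)) - 1,
                       z = t(m), levels = iso)
    lapply(cl, function(ci) cbind(x = ci$x, y = ci$y))
  })
  empty <- vapply(contours, function(cc) length(cc) == 0, logical(1))
  if (any(empty)) {
    warning("front not detectable at time index ",
            paste(times[empty], collapse = ", "), "; dropped")
    keep <- !empty
    sm <- sm[keep]; contours <- contours[keep]; times <- times[keep]
    if (length(times) < 2) stop("fewer than 2 usable time points")
  }

  masks <- lapply(sm, function(m) m >= iso)
  areas <- vapply(masks, sum, numeric(1))
  advancing <- areas[length(areas)] >= areas[1]
  occ <- Reduce(`+`, lapply(masks, function(m) m * 1))
  n_t <- length(masks)
  static <- all(occ %in% c(0, n_t))  # coverage never changes: front is static
  # front-passage time: first coverage when advancing, last coverage when
  # receding; pixels the front passed before/after the recording clamp to
  # the ends so that passage increases along the direction of front motion
  if (static) {
    passage <- matrix(0, nrow(occ), ncol(occ))
  } else if (advancing) {
    passage <- matrix(n_t + 1, nrow(occ), ncol(occ))  # beyond the final front
    for (i in rev(seq_len(n_t))) passage[masks[[i]]] <- i
  } else {
    passage <- matrix(0, nrow(occ), ncol(occ))        # lost before t0
    for (i in seq_len(n_t)) passage[masks[[i]]] <- i
    passage[occ == n_t] <- n_t + 1                    # core the front never left
  }
  surf <- gaussian_blur(passage, smoothing)

  gxm <- gradient_x(surf, 1)
  gym <- gradient_y(surf, 1)
  grad_floor <- 1e-4 * max(abs(c(gxm, gym)), 1e-12)

  # seeds along the earliest front contour
  first_contour <- do.call(rbind, contours[[1]])
  idx <- unique(round(seq(1, nrow(first_contour), length.out = n_seeds)))
  seeds <- first_contour[idx, , drop = FALSE]
  H <- nrow(surf); W <- ncol(surf)
  trajectories <- lapply(seq_len(nrow(seeds)), function(i) {
    p <- as.numeric(seeds[i, ])
    path <- matrix(p, 1, 2)
    for (s in seq_len(max_steps)) {
      gx <- bilinear(gxm, p[1] + 1, p[2] + 1)
      gy <- bilinear(gym, p[1] + 1, p[2] + 1)
      gn <- sqrt(gx^2 + gy^2)
      if (!is.finite(gn) || gn < grad_floor) break
      p <- p + step_px * c(gx, gy) / gn
      if (p[1] < 0 || p[1] > W - 1 || p[2] < 0 || p[2] > H - 1) break
      path <- rbind(path, p)
      if (bilinear(surf, p[1] + 1, p[2] + 1) >= n_t) break
    }
    colnames(path) <- c("x", "y")
    path
  })
  structure(list(contours = contours, surface = surf,
                 trajectories = trajectories, times = times,
                 advancing = advancing, iso = iso),
            class = "front_model")
}
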