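#' Multi-channel time-lapse image stack
#'
#' Thin container for raster movies: a numeric array with axes
#' `(time, channel, y, x)` or `(time, channel, z, y, x)`, all intensities
#' finite and non-negative, plus acquisition metadata.
#'
#' @param pixels numeric array with 4 (TCYX) or 5 (TCZYX) dimensions.
#' @param frame_interval frame interval in minutes (default 15).
#' @param pixel_size physical pixel size in micrometres per pixel (optional).
#' @return an `image_stack`.
#' @export
image_stack <- function(pixels, frame_interval = 15, pixel_size = NA_real_) {
  if (!length(dim(pixels)) %in% c(4, 5)) {
    stop("pixels must be a 4D (TCYX) or 5D (TCZYX) array")
  }
  if (any(dim(pixels) < 1)) stop("all axis lengths must be >= 1")
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("intensities must be finite and non-negative")
  }
  structure(list(pixels = pixels, frame_interval = frame_interval,
                 pixel_size = pixel_size,
                 axes = if (length(dim(pixels)) == 4) "TCYX" else "TCZYX"),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %s [%s], frame interval %s min\n", x$axes,
              paste(dim(x$pixels), collapse = " x "),
              format(x$frame_interval)))
  invisible(x)
}

# frame extractor (matrix y by x)
stack_frame <- function(stack, t = 1, channel = 1, z = NULL) {
  px <- stack$pixels
  if (length(dim(px)) == 5) {
    if (is.null(z)) {
      apply(px[t, channel, , , , drop = FALSE], c(4, 5), max)  # MIP over z
    } else px[t, channel, z, , ]
  } else px[t, channel, , ]
}

#' Configuration of the fluorescence movie renderer
#'
#' Each cell is drawn as an isotropic Gaussian spot in its lineage's channel.
#' Noise follows the standard fluorescence model: Poisson shot noise on
#' `signal * photon_scale` (skipped when `photon_scale = 0`) followed by
#' additive Gaussian read noise.
#'
#' @param image_shape `(height, width)` in pixels.
#' @param spot_sigma Gaussian spot standard deviation in pixels (> 0).
#' @param background constant background intensity.
#' @param photon_scale photons per intensity unit; 0 disables shot noise.
#' @param read_noise_sd Gaussian read noise standard deviation; 0 disables.
#' @param channel_map named integer vector mapping lineage labels to channel
#'   indices; `NULL` renders every cell into channel 1.
#' @param offset length-2 `(x, y)` offset added to track coordinates before
#'   rendering; `NULL` maps the coordinate origin to the image centre (the
#'   simulator's arena is centred on the origin).
#' @param seed integer seed for the noise.
#' @return a `render_config` list.
#' @export
render_config <- function(image_shape = c(256, 256), spot_sigma = 2,
                          background = 0, photon_scale = 0,
                          read_noise_sd = 0, channel_map = NULL,
                          offset = NULL, seed = 1) {
  if (spot_sigma <= 0) stop("spot_sigma must be positive")
  if (any(image_shape < 1)) stop("image_shape must be positive")
  structure(list(image_shape = as.integer(image_shape), spot_sigma = spot_sigma,
                 background = background, photon_scale = photon_scale,
                 read_noise_sd = read_noise_sd, channel_map = channel_map,
                 offset = offset, seed = as.integer(seed)),
            class = "render_config")
}

#' Render tracks into a synthetic fluorescence movie
#'
#' @param tracks a [track_table()]; the `lineage` column (if present) selects
#'   the output channel through `render$channel_map`.
#' @param render a [render_config()].
#' @return an [image_stack()] with one frame per track frame (TCYX).
#' @export
render_movie <- function(tracks, render = render_config()) {
  if (nrow(tracks) == 0) stop("empty track table")
  H <- render$image_shape[1]; W <- render$image_shape[2]
  off <- render$offset %||% c((W - 1) / 2, (H - 1) / 2)
  lin <- if ("lineage" %in% names(tracks)) tracks$lineage else rep("all", nrow(tracks))
  cmap <- render$channel_map
  if (is.null(cmap)) {
    cmap <- stats::setNames(seq_along(unique(lin)), unique(lin))
  }
  if (!all(lin %in% names(cmap))) stop("channel_map does not cover all lineages")
  n_c <- max(cmap)
  frames <- sort(unique(tracks$frame))
  n_t <- length(frames)
  xs <- tracks$x + off[1]
  ys <- tracks$y + off[2]
  if (any(xs < 0 | xs > W - 1 | ys < 0 | ys > H - 1)) {
    stop("tracks do not fit inside image_shape after the coordinate offset")
  }
  sig <- render$spot_sigma
  ext <- ceiling(4 * sig)
  px <- array(render$background, c(n_t, n_c, H, W))
  for (it in seq_len(n_t)) {
    sel <- which(tracks$frame == frames[it])
    for (ch in unique(cmap[lin[sel]])) {
      img <- matrix(0, H, W)
      for (i in sel[cmap[lin[sel]] == ch]) {
        cx <- xs[i]; cy <- ys[i]
        c0 <- max(0, floor(cx) - ext); c1 <- min(W - 1, ceiling(cx) + ext)
        r0 <- max(0, floor(cy) - ext); r1 <- min(H - 1, ceiling(cy) + ext)
        gx <- exp(-((c0:c1) - cx)^2 / (2 * sig^2))
        gy <- exp(-((r0:r1) - cy)^2 / (2 * sig^2))
        img[(r0:r1) + 1, (c0:c1) + 1] <- img[(r0:r1) + 1, (c0:c1) + 1] + gy %o% gx
      }
      px[it, ch, , ] <- px[it, ch, , ] + img
    }
  }
  with_seed(render$seed, {
    if (render$photon_scale > 0) {
      px[] <- stats::rpois(length(px), px * render$photon_scale) / render$photon_scale
    }
    if (render$read_noise_sd > 0) {
      px[] <- px + stats::rnorm(length(px), sd = render$read_noise_sd)
    }
  })
  px[px < 0] <- 0
  image_stack(px, frame_interval = attr(tracks, "dt") %||% 15)
}
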