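#' Specify a known flow field for PIV validation
#'
#' @param kind `"translation"`, `"rotation"` or `"radial"`.
#' @param dx,dy translation in pixels per frame (kind `"translation"`).
#' @param centre length-2 rotation/expansion centre in 0-based pixel
#'   coordinates (`"rotation"`/`"radial"`).
#' @param angle rotation angle in degrees per frame (`"rotation"`).
#' @param rate radial expansion rate per frame; negative contracts
#'   (`"radial"`).
#' @return a `flow_spec`.
#' @export
flow_spec <- function(kind = c("translation", "rotation", "radial"),
                      dx = NULL, dy = NULL, centre = NULL, angle = NULL,
                      rate = NULL) {
  kind <- match.arg(kind)
  if (kind == "translation" && (is.null(dx) || is.null(dy))) {
    stop("translation flow requires dx and dy")
  }
  if (kind == "rotation" && (is.null(centre) || is.null(angle))) {
    stop("rotation flow requires centre and angle")
  }
  if (kind == "radial" && (is.null(centre) || is.null(rate))) {
    stop("radial flow requires centre and rate")
  }
  structure(list(kind = kind, dx = dx, dy = dy, centre = centre,
                 angle = angle, rate = rate), class = "flow_spec")
}

#' Ground-truth displacement of a flow at given pixels
#'
#' @param flow a [flow_spec()].
#' @param x,y 0-based pixel coordinates.
#' @return list with components `u` and `v` (pixels per frame).
#' @export
flow_displacement <- function(flow, x, y) {
  switch(flow$kind,
    translation = list(u = rep(flow$dx, length(x)), v = rep(flow$dy, length(y))),
    rotation = {
      th <- flow$angle * pi / 180
      px <- x - flow$centre[1]; py <- y - flow$centre[2]
      list(u = cos(th) * px - sin(th) * py - px,
           v = sin(th) * px + cos(th) * py - py)
    },
    radial = list(u = flow$rate * (x - flow$centre[1]),
                  v = flow$rate * (y - flow$centre[2]))
  )
}

# inverse of the forward map q = p + d(p)
flow_inverse <- function(flow, x, y) {
  switch(flow$kind,
    translation = list(x = x - flow$dx, y = y - flow$dy),
    rotation = {
      th <- -flow$angle * pi / 180
      px <- x - flow$centre[1]; py <- y - flow$centre[2]
      list(x = cos(th) * px - sin(th) * py + flow$centre[1],
           y = sin(th) * px + cos(th) * py + flow$centre[2])
    },
    radial = list(x = (x - flow$centre[1]) / (1 + flow$rate) + flow$centre[1],
                  y = (y - flow$centre[2]) / (1 + flow$rate) + flow$centre[2])
  )
}

#' Generate a speckle image pair advected by a known flow
#'
#' Produces a random speckle texture and the same texture displaced by the
#' flow (bilinear sub-pixel interpolation), the standard synthetic oracle for
#' particle image velocimetry.  Ground truth at any pixel is available through
#' [flow_displacement()].
#'
#' @param flow a [flow_spec()].
#' @param render a [render_config()]; `image_shape` and `seed` are used, and
#'   `read_noise_sd` adds independent sensor noise to both images.
#' @param speckle_sigma smoothing scale of the speckle texture in pixels.
#' @return list with matrices `a` and `b` (rows = y, cols = x) and the flow.
#' @export
advected_pair <- function(flow, render = render_config(), speckle_sigma = 1.5) {
  H <- render$image_shape[1]; W <- render$image_shape[2]
  gx <- seq(0, W - 1); gy <- seq(0, H - 1)
  g <- expand.grid(x = gx, y = gy)
  d <- flow_displacement(flow, g$x, g$y)
  dmax <- sqrt(max(d$u^2 + d$v^2))
  if (dmax >= min(H, W)) stop("invalid flow: displacement exceeds image extent")
  pad <- ceiling(dmax) + 4
  with_seed(render$seed, {
    big <- matrix(stats::rnorm((H + 2 * pad) * (W + 2 * pad)), H + 2 * pad)
    big <- gaussian_blur(big, speckle_sigma)
    big <- (big - min(big)) / (max(big) - min(big))
    a <- big[pad + seq_len(H), pad + seq_len(W)]
    src <- flow_inverse(flow, g$x, g$y)
    b <- matrix(bilinear(big, src$x + pad + 1, src$y + pad + 1),
                H, W, byrow = TRUE)
    if (render$read_noise_sd > 0) {
      a <- a + stats::rnorm(length(a), sd = render$read_noise_sd)
      b <- b + stats::rnorm(length(b), sd = render$read_noise_sd)
    }
    list(a = a, b = b, flow = flow)
  })
}
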