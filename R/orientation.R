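#' Structure-tensor orientation vector field
#'
#' Local orientation from the smoothed structure tensor: image gradients are
#' taken with Gaussian-derivative filters (scale `grad_sigma`), the tensor
#' components `J_xx`, `J_xy`, `J_yy` are smoothed at `tensor_sigma`, and the
#' dominant structure orientation is `0.5 * atan2(2 J_xy, J_xx - J_yy) + 90`
#' degrees, mapped to `[0, 180)` (the +90 converts the dominant gradient
#' direction into the direction of the oriented structure).  Coherence is
#' `(lambda1 - lambda2) / (lambda1 + lambda2)` in `[0, 1]`; flat regions get
#' coherence 0 and an unreliable-angle flag.  Vectors are sampled on a grid
#' of pitch `grid_size` (150 px in the reference analyses) with unit-length
#' ("100 %") scale.
#'
#' @param img greyscale matrix (rows = y, columns = x, y pointing down).
#' @param grid_size sampling pitch in pixels (default 150).
#' @param grad_sigma gradient (derivative) scale in pixels.
#' @param tensor_sigma tensor smoothing scale in pixels.
#' @return list of class `orientation_field`: tibble `field` with 0-based
#'   `x`, `y`, `angle` (degrees in `[0,180)`), `coherence` and `reliable`;
#'   plus the dense `angle_map` and `coherence_map`.
#' @export
orientation_field <- function(img, grid_size = 150, grad_sigma = 1,
                              tensor_sigma = 4) {
  if (any(dim(img) < grid_size)) stop("image smaller than grid_size")
  gx <- gradient_x(img, grad_sigma)
  gy <- gradient_y(img, grad_sigma)
  jxx <- gaussian_blur(gx * gx, tensor_sigma)
  jxy <- gaussian_blur(gx * gy, tensor_sigma)
  jyy <- gaussian_blur(gy * gy, tensor_sigma)
  ang <- (0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi + 90) %% 180
  tr <- jxx + jyy
  dif <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
  coh <- matrix(0, nrow(img), ncol(img))
  nz <- tr > .Machine$double.eps
  coh[nz] <- dif[nz] / tr[nz]
  xs <- seq(ceiling(grid_size / 2), ncol(img), by = grid_size)
  ys <- seq(ceiling(grid_size / 2), nrow(img), by = grid_size)
  g <- expand.grid(y = ys, x = xs)
  fld <- tibble(x = g$x - 1, y = g$y - 1,
                angle = ang[cbind(g$y, g$x)],
                coherence = coh[cbind(g$y, g$x)],
                reliable = coh[cbind(g$y, g$x)] > 1e-3)
  fld$angle[!fld$reliable] <- NA_real_
  structure(list(field = fld, angle_map = ang, coherence_map = coh,
                 grid_size = grid_size),
            class = "orientation_field")
}

# Gaussian-derivative gradients (x = columns, y = rows/down)
gradient_x <- function(img, sigma) {
  sm <- gaussian_blur(img, sigma)
  (cbind(sm[, -1], sm[, ncol(sm)]) - cbind(sm[, 1], sm[, -ncol(sm)])) / 2
}

gradient_y <- function(img, sigma) {
  sm <- gaussian_blur(img, sigma)
  (rbind(sm[-1, ], sm[nrow(sm), ]) - rbind(sm[1, ], sm[-nrow(sm), ])) / 2
}
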