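#' Configuration of the iterative PIV cascade
#'
#' Defaults follow the standard iterative cross-correlation scheme used for
#' collective cell migration: a 64/32/16-pixel interrogation-window cascade
#' with normalized-median-test validation (noise 0.2, threshold 5).  The
#' window overlap, the number of passes per window size and the treatment of
#' flagged vectors are not fixed by that scheme; the defaults here (50 %
#' overlap, one pass per size, flagged vectors replaced by the neighbourhood
#' median) are assumptions and are configurable.
#'
#' @param window_sizes strictly decreasing interrogation window sides in
#'   pixels, each >= 8.
#' @param overlap_fraction window overlap within `[0, 1)`; 0.5 means windows
#'   advance by half a window.
#' @param subpixel sub-pixel peak estimator; `"gaussian3pt"` (3-point Gaussian
#'   fit per axis, parabolic fallback when a neighbour is non-positive).
#' @param mediantest_noise,mediantest_threshold normalized median test
#'   parameters.
#' @param replace_invalid replace flagged vectors by the neighbourhood median
#'   in the final field (intermediate passes always replace, for stability of
#'   the window-offset predictor).
#' @return a `piv_config`.
#' @export
piv_config <- function(window_sizes = c(64, 32, 16), overlap_fraction = 0.5,
                       subpixel = "gaussian3pt", mediantest_noise = 0.2,
                       mediantest_threshold = 5, replace_invalid = TRUE) {
  if (any(diff(window_sizes) >= 0) && length(window_sizes) > 1) {
    stop("window_sizes must be strictly decreasing")
  }
  if (any(window_sizes < 8)) stop("window sizes must be >= 8 px")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)")
  }
  subpixel <- match.arg(subpixel, "gaussian3pt")
  structure(list(window_sizes = as.integer(window_sizes),
                 overlap_fraction = overlap_fraction, subpixel = subpixel,
                 mediantest_noise = mediantest_noise,
                 mediantest_threshold = mediantest_threshold,
                 replace_invalid = isTRUE(replace_invalid)),
            class = "piv_config")
}

new_vector_field <- function(grid_x, grid_y, u, v, valid, peak_quality, window) {
  structure(list(grid_x = grid_x, grid_y = grid_y, u = u, v = v,
                 valid = valid, peak_quality = peak_quality, window = window),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field> %d x %d vectors (window %d px), %d invalid\n",
              length(x$grid_y), length(x$grid_x), x$window, sum(!x$valid)))
  invisible(x)
}

# zero-padded linear cross-correlation of two equal square windows:
# c(s) = sum_i A(i) * B(i + s), s in [-smax, smax] each axis.
# Returns list(corr = (2smax+1)^2 matrix indexed [sy, sx], shifts).
window_xcorr <- function(A, B, smax) {
  W <- nrow(A)
  P <- 2 * W
  Ap <- matrix(0, P, P); Bp <- matrix(0, P, P)
  Ap[1:W, 1:W] <- A - mean(A)
  Bp[1:W, 1:W] <- B - mean(B)
  cc <- Re(stats::fft(Conj(stats::fft(Ap)) * stats::fft(Bp), inverse = TRUE)) / P^2
  # index k (1-based) corresponds to shift s = k-1 for k <= P/2, k-1-P beyond
  ks <- c(P - smax + seq_len(smax), seq_len(smax + 1))  # s = -smax..smax
  corr <- cc[ks, ks]
  list(corr = corr, shifts = -smax:smax)
}

subpixel_offset <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0 && c0 >= cm && c0 >= cp) {
    den <- 2 * (log(cm) + log(cp) - 2 * log(c0))
    if (den < 0) return(max(-1, min(1, (log(cm) - log(cp)) / den)))
  }
  den <- 2 * (cm - 2 * c0 + cp)
  if (den == 0) return(0)
  max(-1, min(1, (cm - cp) / den))
}

#' Iterative cross-correlation particle image velocimetry
#'
#' Multi-pass PIV: each pass correlates zero-mean interrogation windows of
#' decreasing size (FFT-based, zero-padded linear correlation), locates the
#' correlation peak, refines it to sub-pixel accuracy by a 3-point Gaussian
#' fit per axis, and offsets the next pass's windows by the interpolated
#' previous field (window offsetting, no image deformation).  The normalized
#' median test is applied after every pass.  Windows lie fully inside the
#' frame; the final grid is at the smallest window size.
#'
#' @param frame_a,frame_b greyscale matrices of identical size (rows = y).
#' @param config a [piv_config()].
#' @return a `vector_field`: window-centre coordinates `grid_x`/`grid_y`
#'   (0-based pixel units), displacement matrices `u`/`v` (px per frame pair,
#'   indexed `[y, x]`), `valid` flags and the first-to-second peak-ratio
#'   diagnostic `peak_quality`.
#' @export
run_piv <- function(frame_a, frame_b, config = piv_config()) {
  if (!all(dim(frame_a) == dim(frame_b))) stop("frame shape mismatch")
  H <- nrow(frame_a); W <- ncol(frame_a)
  if (max(config$window_sizes) > min(H, W)) {
    stop("window larger than frame")
  }
  field <- NULL
  n_pass <- length(config$window_sizes)
  for (k in seq_len(n_pass)) {
    Wk <- config$window_sizes[k]
    stride <- max(1L, as.integer(round(Wk * (1 - config$overlap_fraction))))
    tlx <- seq(1L, W - Wk + 1L, stride)
    tly <- seq(1L, H - Wk + 1L, stride)
    cx <- tlx - 1 + (Wk - 1) / 2
    cy <- tly - 1 + (Wk - 1) / 2
    nx <- length(tlx); ny <- length(tly)
    u <- matrix(0, ny, nx); v <- matrix(0, ny, nx)
    pq <- matrix(0, ny, nx)
    # predictor from the previous (coarser) field, rounded to integers
    if (is.null(field)) {
      du0 <- dv0 <- matrix(0L, ny, nx)
    } else {
      gx <- (cx - field$grid_x[1]) / diff(field$grid_x[1:2]) + 1
      gy <- (cy - field$grid_y[1]) / diff(field$grid_y[1:2]) + 1
      g <- expand.grid(y = gy, x = gx)
      du0 <- matrix(as.integer(round(bilinear(field$u, g$x, g$y))), ny, nx)
      dv0 <- matrix(as.integer(round(bilinear(field$v, g$x, g$y))), ny, nx)
    }
    smax <- max(2L, Wk %/% 2L - 1L)
    clamped <- matrix(FALSE, ny, nx)
    for (iy in seq_len(ny)) {
      for (ix in seq_len(nx)) {
        ra <- tly[iy]:(tly[iy] + Wk - 1L)
        ca <- tlx[ix]:(tlx[ix] + Wk - 1L)
        # clamp the offset window for frame b inside the frame; a clamped
        # window loses matching texture across the frame border, so its
        # vector is flagged invalid below
        oy <- min(max(tly[iy] + dv0[iy, ix], 1L), H - Wk + 1L)
        ox <- min(max(tlx[ix] + du0[iy, ix], 1L), W - Wk + 1L)
        clamped[iy, ix] <- oy != tly[iy] + dv0[iy, ix] ||
          ox != tlx[ix] + du0[iy, ix]
        A <- frame_a[ra, ca]
        B <- frame_b[oy:(oy + Wk - 1L), ox:(ox + Wk - 1L)]
        if (stats::sd(A) == 0 || stats::sd(B) == 0) {
          u[iy, ix] <- ox - tlx[ix]
          v[iy, ix] <- oy - tly[iy]
          pq[iy, ix] <- 0
          next
        }
        xc <- window_xcorr(A, B, smax)
        pk <- which(xc$corr == max(xc$corr), arr.ind = TRUE)[1, ]
        sy <- xc$shifts[pk[1]]; sx <- xc$shifts[pk[2]]
        # sub-pixel refinement per axis (peak must be interior)
        ddx <- ddy <- 0
        if (pk[2] > 1 && pk[2] < ncol(xc$corr)) {
          ddx <- subpixel_offset(xc$corr[pk[1], pk[2] - 1],
                                 xc$corr[pk[1], pk[2]],
                                 xc$corr[pk[1], pk[2] + 1])
        }
        if (pk[1] > 1 && pk[1] < nrow(xc$corr)) {
          ddy <- subpixel_offset(xc$corr[pk[1] - 1, pk[2]],
                                 xc$corr[pk[1], pk[2]],
                                 xc$corr[pk[1] + 1, pk[2]])
        }
        u[iy, ix] <- (ox - tlx[ix]) + sx + ddx
        v[iy, ix] <- (oy - tly[iy]) + sy + ddy
        # first-to-second peak ratio (second peak outside the 3x3 core)
        excl <- xc$corr
        excl[max(1, pk[1] - 1):min(nrow(excl), pk[1] + 1),
             max(1, pk[2] - 1):min(ncol(excl), pk[2] + 1)] <- -Inf
        c2 <- max(excl)
        pq[iy, ix] <- if (is.finite(c2) && c2 > 0) max(xc$corr) / c2 else Inf
      }
    }
    field <- new_vector_field(cx, cy, u, v,
                              valid = matrix(TRUE, ny, nx),
                              peak_quality = pq, window = Wk)
    replace <- if (k < n_pass) TRUE else config$replace_invalid
    field <- normalized_median_test(field, noise = config$mediantest_noise,
                                    threshold = config$mediantest_threshold,
                                    replace_invalid = replace)
    field$valid <- field$valid & !clamped
  }
  field
}

#' Normalized median test for PIV vector validation
#'
#' For every vector, `m` is the component-wise median of its (up to) eight
#' grid neighbours and `r_m` the median of the neighbour residual magnitudes
#' `|neighbour - m|`.  The vector is flagged invalid when
#' `|v - m| / (r_m + noise) > threshold`.  Border vectors use the available
#' neighbours.
#'
#' @param field a `vector_field`.
#' @param noise noise floor in displacement units (default 0.2).
#' @param threshold residual threshold (default 5).
#' @param replace_invalid replace flagged vectors by `m`.
#' @return the field with updated `valid` flags (and vectors, if replaced).
#' @export
normalized_median_test <- function(field, noise = 0.2, threshold = 5,
                                   replace_invalid = FALSE) {
  u <- field$u; v <- field$v
  ny <- nrow(u); nx <- ncol(u)
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dy == 0 & shifts$dx == 0), ]
  nu <- array(NA_real_, c(ny, nx, nrow(shifts)))
  nv <- array(NA_real_, c(ny, nx, nrow(shifts)))
  for (s in seq_len(nrow(shifts))) {
    dy <- shifts$dy[s]; dx <- shifts$dx[s]
    ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
    oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
    nu[oky, okx, s] <- u[ys[oky], xs[okx]]
    nv[oky, okx, s] <- v[ys[oky], xs[okx]]
  }
  n_nb <- apply(!is.na(nu), c(1, 2), sum)
  if (any(n_nb < 3)) stop("grid too small for the normalized median test")
  mu <- apply(nu, c(1, 2), stats::median, na.rm = TRUE)
  mv <- apply(nv, c(1, 2), stats::median, na.rm = TRUE)
  resid_nb <- sqrt((nu - array(mu, dim(nu)))^2 + (nv - array(mv, dim(nv)))^2)
  rm <- apply(resid_nb, c(1, 2), stats::median, na.rm = TRUE)
  res <- sqrt((u - mu)^2 + (v - mv)^2) / (rm + noise)
  bad <- res > threshold
  field$valid <- field$valid & !bad
  if (replace_invalid && any(bad)) {
    field$u[bad] <- mu[bad]
    field$v[bad] <- mv[bad]
  }
  field
}

#' Summarise a PIV vector field as speed and direction
#'
#' @param field a `vector_field`.
#' @param dt time between the correlated frames, in minutes.
#' @return list with `magnitude` (px/min) and `direction` (degrees in
#'   `[0, 360)`) maps, `mean_speed` over valid vectors, the circular
#'   `mean_direction` (degrees, `NA` when undefined) and `direction_defined`.
#' @export
field_summary <- function(field, dt) {
  if (dt <= 0) stop("dt must be positive")
  mag <- sqrt(field$u^2 + field$v^2) / dt
  dir <- (atan2(field$v, field$u) * 180 / pi) %% 360
  ok <- field$valid
  if (!any(ok)) {
    warning("all vectors invalid: empty summary")
    return(list(magnitude = mag, direction = dir, mean_speed = NA_real_,
                mean_direction = NA_real_, direction_defined = FALSE))
  }
  mean_speed <- mean(mag[ok])
  zc <- mean(exp(1i * atan2(field$v[ok], field$u[ok])))
  defined <- Mod(zc) > 1e-6
  list(magnitude = mag, direction = dir, mean_speed = mean_speed,
       mean_direction = if (defined) (Arg(zc) * 180 / pi) %% 360 else NA_real_,
       direction_defined = defined)
}
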