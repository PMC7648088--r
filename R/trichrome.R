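#' Convert an RGB image to CMYK channels
#'
#' Naive device-independent conversion: `K = 1 - max(R, G, B)`,
#' `C = (1 - R - K) / (1 - K)` (analogously M and Y), with `C = M = Y = 0`
#' where `K = 1`.  In Masson's trichrome sections the K channel captures
#' iron-haematoxylin-stained nuclei and the C channel the aniline-blue
#' stained collagen.
#'
#' @param image H x W x 3 array with intensities in `[0, 1]`.
#' @return H x W x 4 array of C, M, Y, K channels in `[0, 1]`.
#' @export
rgb_to_cmyk <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("input must be an H x W x 3 RGB array")
  }
  hw <- dim(image)[1:2]
  R <- matrix(image[, , 1], hw[1], hw[2])
  G <- matrix(image[, , 2], hw[1], hw[2])
  B <- matrix(image[, , 3], hw[1], hw[2])
  K <- 1 - pmax(R, pmax(G, B))
  den <- 1 - K
  safe <- den > 0
  conv <- function(ch) {
    out <- matrix(0, hw[1], hw[2])
    out[safe] <- (1 - ch[safe] - K[safe]) / den[safe]
    out
  }
  out <- array(0, c(hw, 4))
  out[, , 1] <- conv(R); out[, , 2] <- conv(G); out[, , 3] <- conv(B)
  out[, , 4] <- K
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grey-scale morphological opening of
#' the image with a ball-shaped (non-flat) structuring element of the given
#' radius, computed on a shrunken copy for large radii (the classic
#' rolling-ball algorithm), and subtracts it.
#'
#' @param img numeric matrix.
#' @param radius ball radius in pixels (default 50).
#' @return background-subtracted matrix (clamped at 0).
#' @export
rolling_ball <- function(img, radius = 50) {
  shrink <- max(1L, ceiling(radius / 12))
  small <- if (shrink > 1) block_reduce(img, shrink, min) else img
  r <- radius / shrink
  se <- ball_kernel(r)
  bg_small <- ball_dilate(ball_erode(small, se), se)
  bg <- if (shrink > 1) resize_bilinear(bg_small, dim(img)) else bg_small
  out <- img - pmin(bg, img)
  out
}

ball_kernel <- function(r) {
  ir <- floor(r)
  off <- expand.grid(dy = -ir:ir, dx = -ir:ir)
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]
  off$h <- sqrt(r^2 - off$dx^2 - off$dy^2) - r   # heights <= 0
  off
}

shift_pad <- function(m, dy, dx, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) + dy; xs <- seq_len(nc) + dx
  oky <- ys >= 1 & ys <= nr; okx <- xs >= 1 & xs <= nc
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

ball_erode <- function(m, se) {
  out <- matrix(Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(se))) {
    out <- pmin(out, shift_pad(m, se$dy[i], se$dx[i], Inf) - se$h[i])
  }
  out
}

ball_dilate <- function(m, se) {
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(se))) {
    out <- pmax(out, shift_pad(m, -se$dy[i], -se$dx[i], -Inf) + se$h[i])
  }
  out
}

block_reduce <- function(m, k, fun) {
  nr <- ceiling(nrow(m) / k) * k
  nc <- ceiling(ncol(m) / k) * k
  mp <- matrix(NA_real_, nr, nc)
  mp[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  # replicate-pad the ragged edge
  if (nr > nrow(m)) mp[(nrow(m) + 1):nr, ] <- mp[rep(nrow(m), nr - nrow(m)), ]
  if (nc > ncol(m)) mp[, (ncol(m) + 1):nc] <- mp[, rep(ncol(m), nc - ncol(m))]
  gy <- rep(seq_len(nr / k), each = k)
  gx <- rep(seq_len(nc / k), each = k)
  apply_block <- function(mm) {
    a <- array(mm, c(k, nr / k, nc))
    a <- apply(a, c(2, 3), fun)
    a2 <- array(t(a), c(k, nc / k, nr / k))
    t(apply(a2, c(2, 3), fun))
  }
  apply_block(mp)
}

resize_bilinear <- function(m, out_dim) {
  nr <- out_dim[1]; nc <- out_dim[2]
  sy <- nrow(m) / nr; sx <- ncol(m) / nc
  ys <- (seq_len(nr) - 0.5) * sy + 0.5
  xs <- (seq_len(nc) - 0.5) * sx + 0.5
  g <- expand.grid(y = ys, x = xs)
  matrix(bilinear(m, g$x, g$y), nr, nc)
}

#' Contrast stretching with saturated tails
#'
#' Linearly rescales intensities to `[0, 1]`, saturating the stated
#' percentage of pixels split evenly between the two tails (the usual
#' "enhance contrast, normalised" operation).
#'
#' @param img numeric matrix.
#' @param saturated total percentage of saturated pixels (default 0.1).
#' @return rescaled matrix in `[0, 1]`.
#' @export
stretch_contrast <- function(img, saturated = 0.1) {
  qs <- stats::quantile(img, c(saturated / 200, 1 - saturated / 200),
                        names = FALSE)
  if (diff(qs) <= 0) return(img * 0)
  out <- pmin(1, pmax(0, (img - qs[1]) / (qs[2] - qs[1])))
  dim(out) <- dim(img)
  out
}

#' Unsharp masking
#'
#' `out = (in - w * Gaussian(in, r)) / (1 - w)` with the stated radius and
#' mask weight.
#'
#' @param img numeric matrix.
#' @param radius Gaussian sigma in pixels (default 2).
#' @param weight mask weight in `[0, 1)` (default 0.6).
#' @return sharpened matrix.
#' @export
unsharp_mask <- function(img, radius = 2, weight = 0.6) {
  (img - weight * gaussian_blur(img, radius)) / (1 - weight)
}

#' Minimum auto-threshold of a grey-level histogram
#'
#' Iteratively smooths the 256-bin histogram with a length-3 mean filter
#' until exactly two local maxima remain, then thresholds at the minimum
#' between them.  When bimodality is unreachable within `max_iter`
#' iterations, falls back to Otsu's threshold with a message.
#'
#' @param img numeric matrix with values in `[0, 1]`.
#' @param max_iter smoothing iteration cap (default 10000).
#' @return threshold on the `[0, 1]` intensity scale.
#' @export
threshold_minimum <- function(img, max_iter = 10000) {
  h <- tabulate(pmin(256L, 1L + as.integer(floor(img * 256))), nbins = 256)
  h <- as.numeric(h)
  if (sum(h > 0) <= 1) {
    message("degenerate single-level histogram: empty foreground")
    return(1)
  }
  count_maxima <- function(hh) {
    # local maxima on the smoothed histogram (plateau-safe)
    up <- c(TRUE, diff(hh) > 0)
    dn <- c(diff(hh) < 0, TRUE)
    sum(up & dn & hh > 0)
  }
  it <- 0
  hh <- h
  while (count_maxima(hh) != 2 && it < max_iter) {
    hh <- stats::filter(hh, rep(1 / 3, 3), sides = 2)
    hh[is.na(hh)] <- 0
    hh <- as.numeric(hh)
    it <- it + 1
  }
  if (count_maxima(hh) != 2) {
    message("histogram not bimodal after smoothing: falling back to Otsu")
    return(EBImage::otsu(EBImage::Image(t(img)), range = c(0, 1)))
  }
  n <- length(hh)
  up <- c(TRUE, diff(hh) > 0)
  dn <- c(diff(hh) < 0, TRUE)
  peaks <- which(up & dn & hh > 0)
  p1 <- peaks[1]; p2 <- peaks[length(peaks)]
  valley <- p1 + which.min(hh[p1:p2]) - 1
  (valley - 0.5) / 256
}

#' Count nuclei in a trichrome section
#'
#' Applies the standard counting chain to the CMYK black channel within the
#' region of interest: rolling-ball background subtraction (radius 50 px),
#' contrast stretching (0.1 % saturated, normalised), unsharp masking
#' (radius 2, weight 0.6), median filtering (radius 1) and Minimum
#' auto-thresholding; touching objects are split by a distance-transform
#' watershed and connected components with area inside `size_range` are
#' counted.
#'
#' @param image H x W x 3 RGB array in `[0, 1]`.
#' @param roi region of interest (see [as_roi_mask()]).
#' @param size_range `(min, max)` particle area gate in px^2 (default
#'   `c(30, 200)`).
#' @param rolling_radius rolling-ball radius in pixels (default 50).
#' @return list with `count`, the integer `labels` mask and the binary mask.
#' @export
count_nuclei <- function(image, roi = NULL, size_range = c(30, 200),
                         rolling_radius = 50) {
  k <- rgb_to_cmyk(image)[, , 4]
  mask <- as_roi_mask(roi, dim(k))
  k[!mask] <- 0
  k <- rolling_ball(k, rolling_radius)
  k <- stretch_contrast(k, 0.1)
  k <- unsharp_mask(k, 2, 0.6)
  k <- pmin(1, pmax(0, k))
  dim(k) <- dim(mask)
  k <- ebi_to_matrix(EBImage::medianFilter(EBImage::Image(t(k)), size = 1))
  thr <- threshold_minimum(k)
  binary <- (k > thr) & mask
  if (!any(binary)) {
    return(list(count = 0L, labels = matrix(0L, nrow(k), ncol(k)),
                binary = binary))
  }
  bw <- EBImage::Image(t(binary * 1))
  dm <- EBImage::distmap(bw)
  labels <- EBImage::watershed(dm, tolerance = 1)
  lab <- t(EBImage::imageData(labels))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= size_range[1] & sizes <= size_range[2])
  lab_keep <- matrix(0L, nrow(lab), ncol(lab))
  if (length(keep) > 0) {
    sel <- lab %in% keep
    lab_keep[sel] <- match(lab[sel], keep)
  }
  list(count = length(keep), labels = lab_keep, binary = binary)
}

ebi_to_matrix <- function(img) t(EBImage::imageData(img))

#' Collagen (scar) area from a trichrome section
#'
#' Thresholds the CMYK cyan channel (aniline-blue collagen) within the
#' region of interest using the Minimum auto-threshold (Otsu fallback) and
#' reports the foreground area.
#'
#' @param image H x W x 3 RGB array in `[0, 1]`.
#' @param roi region of interest (see [as_roi_mask()]).
#' @param pixel_size physical pixel size (micrometres per pixel) for the
#'   optional area conversion.
#' @return list with `area_px2`, `fraction` of the ROI and `area_um2`
#'   (`NA` without `pixel_size`), plus the binary mask.
#' @export
scar_area <- function(image, roi = NULL, pixel_size = NA_real_) {
  cyan <- rgb_to_cmyk(image)[, , 1]
  mask <- as_roi_mask(roi, dim(cyan))
  thr <- threshold_minimum(cyan * mask)
  binary <- (cyan > thr) & mask
  area <- sum(binary)
  list(area_px2 = area, fraction = area / sum(mask),
       area_um2 = if (is.na(pixel_size)) NA_real_ else area * pixel_size^2,
       binary = binary)
}
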