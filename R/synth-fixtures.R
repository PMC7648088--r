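#' Binary fixtures of known fractal dimension
#'
#' Test oracles for box-counting: a one-pixel horizontal line (dimension 1),
#' a filled square (dimension 2) and a Sierpinski carpet of the requested
#' depth (similarity dimension log 8 / log 3 = 1.8928; foreground fraction
#' `(8/9)^depth` by construction).
#'
#' @param kind `"line"`, `"filled_square"` or `"sierpinski"`.
#' @param size image side in pixels; for `"sierpinski"` it must be a multiple
#'   of `3^depth`.
#' @param depth recursion depth of the carpet.
#' @return binary matrix (`size` by `size`) of 0/1.
#' @export
fractal_fixture <- function(kind = c("line", "filled_square", "sierpinski"),
                            size = 729, depth = 5) {
  kind <- match.arg(kind)
  if (size < 1) stop("invalid config: size must be positive")
  if (kind == "line") {
    m <- matrix(0, size, size)
    m[ceiling(size / 2), ] <- 1
    return(m)
  }
  if (kind == "filled_square") {
    return(matrix(1, size, size))
  }
  if (depth < 0 || size < 3^depth || size %% 3^depth != 0) {
    stop("invalid config: sierpinski requires size to be a multiple of 3^depth")
  }
  m <- matrix(1, 1, 1)
  hole <- matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3, 3)
  for (i in seq_len(depth)) m <- kronecker(m, hole)
  k <- size %/% 3^depth
  if (k > 1) m <- kronecker(m, matrix(1, k, k))
  m
}

#' Synthetic trichrome-like histology fixture
#'
#' Builds an RGB image resembling a Masson's trichrome section: dark
#' haematoxylin-like nuclear disks and a blue aniline-like collagen region of
#' exactly the requested pixel area on a light background, with the planted
#' ground truth returned alongside.
#'
#' @param n_nuclei number of nuclear disks.
#' @param nucleus_area target disk area in px^2.
#' @param collagen_area exact collagen region area in px^2.
#' @param size `(height, width)` of the canvas.
#' @param noise_sd Gaussian colour noise (keeps histograms realistic).
#' @param seed integer seed for placement and noise.
#' @return list with `image` (H x W x 3 array in `[0,1]`), `nuclei_centres`
#'   (tibble of 0-based x, y), `nuclei_mask`, `collagen_mask` and the planted
#'   counts/areas.
#' @export
histology_fixture <- function(n_nuclei = 12, nucleus_area = 80,
                              collagen_area = 0, size = c(512, 512),
                              noise_sd = 0.01, seed = 1) {
  H <- size[1]; W <- size[2]
  bg <- c(0.92, 0.90, 0.88)
  nucleus_col <- c(0.16, 0.13, 0.15)
  collagen_col <- c(0.25, 0.35, 0.75)
  img <- array(rep(bg, each = H * W), c(H, W, 3))
  collagen_mask <- matrix(FALSE, H, W)
  nuclei_mask <- matrix(FALSE, H, W)
  with_seed(seed, {
    if (collagen_area > 0) {
      w <- max(1, floor(sqrt(collagen_area)))
      h <- collagen_area %/% w
      rem <- collagen_area %% w
      if ((h + 2) >= H - 2 || w >= W - 2) stop("placement error: collagen too large")
      r0 <- sample.int(H - h - 4, 1) + 1
      c0 <- sample.int(W - w - 4, 1) + 1
      collagen_mask[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
      if (rem > 0) collagen_mask[r0 + h, c0:(c0 + rem - 1)] <- TRUE
    }
    centres <- NULL
    if (n_nuclei > 0) {
      r_nuc <- sqrt(nucleus_area / pi)
      margin <- ceiling(r_nuc) + 2
      placed <- 0
      tries <- 0
      xs <- ys <- numeric(0)
      while (placed < n_nuclei) {
        tries <- tries + 1
        if (tries > 5000) stop("placement error: could not fit all nuclei")
        cx <- stats::runif(1, margin, W - 1 - margin)
        cy <- stats::runif(1, margin, H - 1 - margin)
        if (placed > 0 &&
            min((xs - cx)^2 + (ys - cy)^2) < (2.5 * r_nuc + 4)^2) next
        cc <- round(cx); rr <- round(cy)
        rwin <- (rr - margin):(rr + margin)
        cwin <- (cc - margin):(cc + margin)
        dmask <- outer((rwin - cy), (cwin - cx),
                       function(dy, dx) dy^2 + dx^2) <= r_nuc^2
        sub <- collagen_mask[rwin + 1, cwin + 1]
        if (any(dmask & sub)) next
        nuclei_mask[rwin + 1, cwin + 1] <- nuclei_mask[rwin + 1, cwin + 1] | dmask
        xs <- c(xs, cx); ys <- c(ys, cy)
        placed <- placed + 1
      }
      centres <- tibble(x = xs, y = ys)
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[collagen_mask] <- collagen_col[ch]
      plane[nuclei_mask] <- nucleus_col[ch]
      if (noise_sd > 0) plane <- plane + stats::rnorm(length(plane), sd = noise_sd)
      img[, , ch] <- pmin(1, pmax(0, plane))
    }
    list(image = img, nuclei_centres = centres, nuclei_mask = nuclei_mask,
         collagen_mask = collagen_mask, n_nuclei = n_nuclei,
         collagen_area = sum(collagen_mask))
  })
}
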