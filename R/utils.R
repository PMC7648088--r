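`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# n isotropic unit vectors in d dimensions (rows).
runit <- function(n, d) {
  m <- matrix(stats::rnorm(n * d), n, d)
  nm <- sqrt(rowSums(m^2))
  nm[nm == 0] <- 1
  m / nm
}

# Row-normalise a matrix; rows with zero norm are returned as zero rows and
# reported through the `zero` attribute.
row_unit <- function(m) {
  nm <- sqrt(rowSums(m^2))
  zero <- nm < .Machine$double.eps
  nm[zero] <- 1
  out <- m / nm
  attr(out, "zero") <- zero
  out
}

# Angle in degrees (0..180) between rows of two matrices of 3D vectors,
# via atan2(|a x b|, a.b): exact 0/180 for (anti)parallel vectors and
# well-conditioned near them, unlike the acos form.
vector_angle_deg <- function(a, b) {
  dot <- rowSums(a * b)
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  out <- atan2(sqrt(cx^2 + cy^2 + cz^2), dot) * 180 / pi
  out[rowSums(a^2) == 0 | rowSums(b^2) == 0] <- NA_real_
  out
}

# Bilinear interpolation of matrix `m` (rows = y, cols = x) at 1-based
# fractional coordinates; coordinates are clamped to the matrix extent.
bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1); x1 <- x0 + 1
  y0 <- pmin(floor(y), nr - 1); y1 <- y0 + 1
  if (nc == 1) { x0 <- x1 <- rep(1, length(x)) }
  if (nr == 1) { y0 <- y1 <- rep(1, length(y)) }
  fx <- x - x0; fy <- y - y0
  m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    m[cbind(y0, x1)] * fx * (1 - fy) +
    m[cbind(y1, x0)] * (1 - fx) * fy +
    m[cbind(y1, x1)] * fx * fy
}

# Separable Gaussian blur of a numeric matrix (reflective boundaries).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(mm) {
    # pad rows reflectively, convolve down columns
    idx <- c(pmin(r:1, nrow(mm)), seq_len(nrow(mm)),
             pmax(nrow(mm) - seq_len(r) + 1L, 1L))
    p <- mm[idx, , drop = FALSE]
    out <- matrix(0, nrow(mm), ncol(mm))
    for (i in seq_along(k)) {
      out <- out + k[i] * p[seq_len(nrow(mm)) + i - 1L, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

is_binary_image <- function(m) all(m %in% c(0, 1))

# md5 of a canonical (recursively key-sorted) JSON rendering of a list.
canonical_hash <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v)) {
      nm <- names(v)
      if (!is.null(nm) && any(nzchar(nm))) v <- v[order(nm)]
      lapply(v, sort_rec)
    } else v
  }
  js <- jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}
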