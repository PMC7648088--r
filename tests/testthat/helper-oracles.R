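# Independent oracles used across the suite.

# Brute-force spatial cross-correlation argmax over integer shifts
# |s| <= smax, with the same zero-mean / zero-padded definition as the
# package's FFT path (computed by direct summation).
brute_xcorr_argmax <- function(A, B, smax) {
  A0 <- A - mean(A)
  B0 <- B - mean(B)
  W <- nrow(A)
  best <- c(-Inf, NA, NA)
  for (sy in -smax:smax) {
    ia <- max(1, 1 - sy):min(W, W - sy)
    for (sx in -smax:smax) {
      ja <- max(1, 1 - sx):min(W, W - sx)
      cc <- sum(A0[ia, ja] * B0[ia + sy, ja + sx])
      if (cc > best[1]) best <- c(cc, sx, sy)
    }
  }
  c(sx = best[2], sy = best[3])
}

# Delaunay edge list via scipy.spatial (independent reference
# implementation available in the analysis environment).
scipy_delaunay_edges <- function(pts) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.table(pts, f, row.names = FALSE, col.names = FALSE, sep = ",")
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np\n",
    "from scipy.spatial import Delaunay\n",
    "p = np.loadtxt('", f, "', delimiter=',')\n",
    "tri = Delaunay(p)\n",
    "es = set()\n",
    "for s in tri.simplices:\n",
    "    for i in range(len(s)):\n",
    "        for j in range(i+1, len(s)):\n",
    "            es.add((min(s[i], s[j]) + 1, max(s[i], s[j]) + 1))\n",
    "for a, b in sorted(es): print(a, b)\n"))), stdout = TRUE)
  m <- do.call(rbind, lapply(strsplit(out, " "), as.integer))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

sort_edges <- function(e) {
  e <- t(apply(e, 1, sort))
  unname(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

# track table with every cell translated by the same vector each frame
uniform_motion_tracks <- function(n_cells = 50, n_frames = 10,
                                  step = c(1, 1, 0), seed = 1, dt = 15) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  pos <- withr_seed(matrix(runif(n_cells * 3) * 100, n_cells, 3))
  df <- do.call(rbind, lapply(seq_len(n_frames) - 1, function(f) {
    data.frame(track_id = sprintf("c%03d", seq_len(n_cells)), frame = f,
               x = pos[, 1] + f * step[1], y = pos[, 2] + f * step[2],
               z = pos[, 3] + f * step[3])
  }))
  track_table(df, dt = dt)
}

# stripe image at a given structure orientation (degrees, y-down convention)
stripe_image <- function(angle_deg, size = 256, period = 16) {
  th <- angle_deg * pi / 180
  xs <- matrix(rep(seq_len(size) - 1, each = size), size)
  ys <- matrix(rep(seq_len(size) - 1, size), size)
  sin(2 * pi * (ys * cos(th) - xs * sin(th)) / period)
}
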