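#' Read an image stack from TIFF or PNG
#'
#' Multi-page TIFFs are assembled into a `(T, C, [Z,] Y, X)` array.  A JSON
#' sidecar written by [write_image_stack()] (same path plus `.json`) is used
#' to recover axis sizes and metadata when present; otherwise pages are laid
#' out according to `axes` and the explicit axis sizes.  Single-page images
#' and RGB PNGs become `T = 1` stacks with channels preserved.
#'
#' @param path TIFF or PNG file.
#' @param axes axis order of the pages, `"TCYX"` or `"TCZYX"` (page order is
#'   T-major, then C, then Z).
#' @param n_channels,n_z axis sizes when no sidecar exists.
#' @param frame_interval,pixel_size metadata fallbacks.
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, axes = "TCYX", n_channels = 1, n_z = 1,
                             frame_interval = 15, pixel_size = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  intensity_scale <- 1
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    axes <- meta$axes
    n_channels <- meta$n_channels
    n_z <- meta$n_z %||% 1
    frame_interval <- meta$frame_interval
    pixel_size <- meta$pixel_size %||% NA_real_
    intensity_scale <- meta$intensity_scale %||% 1
  }
  if (!axes %in% c("TCYX", "TCZYX")) {
    stop("format error: unsupported axes string '", axes, "'")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2) {
      px <- array(img, c(1, 1, dim(img)))
    } else {
      px <- array(0, c(1, dim(img)[3], dim(img)[1], dim(img)[2]))
      for (ch in seq_len(dim(img)[3])) px[1, ch, , ] <- img[, , ch]
    }
    return(image_stack(px, frame_interval, pixel_size))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p  # greyscale pages expected
  })
  n_pages <- length(pages)
  per_t <- n_channels * n_z
  if (n_pages %% per_t != 0) {
    stop("format error: ", n_pages, " pages not divisible by C*Z = ", per_t)
  }
  n_t <- n_pages / per_t
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  if (axes == "TCYX") {
    px <- array(0, c(n_t, n_channels, H, W))
    i <- 1
    for (t in seq_len(n_t)) for (ch in seq_len(n_channels)) {
      px[t, ch, , ] <- pages[[i]]; i <- i + 1
    }
  } else {
    px <- array(0, c(n_t, n_channels, n_z, H, W))
    i <- 1
    for (t in seq_len(n_t)) for (ch in seq_len(n_channels)) for (z in seq_len(n_z)) {
      px[t, ch, z, , ] <- pages[[i]]; i <- i + 1
    }
  }
  if (intensity_scale != 1) px <- px * intensity_scale
  image_stack(px, frame_interval, pixel_size)
}

#' Write an image stack as a multi-page 32-bit TIFF
#'
#' Pages are written in T-major (then C, then Z) order as 32-bit samples.
#' Intensities are normalised by a power-of-two scale before writing; the
#' scale is recorded in the JSON sidecar (`<path>.json`) together with axis
#' sizes and metadata, so [read_image_stack()] restores the original
#' intensities to 1 part in 2^32 of the scale and a second write-read round
#' trip is bit-exact.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  px <- stack$pixels
  d <- dim(px)
  # power-of-two scale: normalised values are exact dyadics after the
  # writer's 32-bit quantisation, so a second round trip is the identity
  scale <- if (max(px) > 0) 2^ceiling(log2(max(px))) else 1
  # quantise to the reader's k / 2^32 grid and express each level as a value
  # the writer's trunc(x * (2^32 - 1)) conversion maps back to exactly k
  quantise <- function(m) {
    k <- pmin(round(m / scale * 2^32), 2^32 - 1)
    v <- pmin((k + 0.5) / (2^32 - 1), 1)
    dim(v) <- dim(m)
    v
  }
  pages <- list()
  if (length(d) == 4) {
    for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
      pages[[length(pages) + 1]] <- quantise(px[t, ch, , ])
    }
    meta <- list(axes = "TCYX", n_channels = d[2], n_z = 1)
  } else {
    for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
      pages[[length(pages) + 1]] <- quantise(px[t, ch, z, , ])
    }
    meta <- list(axes = "TCZYX", n_channels = d[2], n_z = d[3])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta$intensity_scale <- scale
  meta$frame_interval <- stack$frame_interval
  meta$pixel_size <- stack$pixel_size
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and write track tables as CSV
#'
#' The canonical interchange dialect has the header
#' `track_id,frame,t_min,x,y,z` with an optional trailing `lineage` column.
#' Reading enforces the track-table invariants (unique `(track_id, frame)`,
#' strictly increasing frames, finite coordinates) and names the offending
#' row on failure; writing uses 6 significant digits, so a write-read round
#' trip at that precision is the identity.
#'
#' @param path CSV file path.
#' @return [read_tracks()] returns a [track_table()].
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- c("track_id", "frame", "t_min", "x", "y", "z")
  ok <- identical(names(df), base) ||
    identical(names(df), c(base, "lineage"))
  if (!ok) {
    stop("format error: expected header track_id,frame,t_min,x,y,z[,lineage], got ",
         paste(names(df), collapse = ","))
  }
  key <- paste(df$track_id, df$frame)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("validation error: duplicate (track_id, frame) at row ", i)
  }
  track_table(df)
}

#' @param tracks a [track_table()].
#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  df <- as.data.frame(tracks)
  num <- c("t_min", "x", "y", "z")
  for (cn in num) df[[cn]] <- formatC(df[[cn]], format = "g", digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
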