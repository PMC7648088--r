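#' Construct and validate a track table
#'
#' A track table is the tidy substrate of all kinematic statistics: one row
#' per (cell, frame) with 3D pixel coordinates.  Columns are `track_id`,
#' `frame` (integer, 0-based), `t_min` (minutes, `frame * dt`), `x`, `y`, `z`
#' (pixels) and optionally `lineage`.
#'
#' @param df data frame with the columns above (`t_min` may be omitted when
#'   `dt` is given).
#' @param dt frame interval in minutes; recorded as an attribute and used to
#'   fill `t_min` when absent.
#' @return a `track_table` (a tibble subclass).
#' @export
track_table <- function(df, dt = NULL) {
  df <- as_tibble(df)
  need <- c("track_id", "frame", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("track table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!("t_min" %in% names(df))) {
    if (is.null(dt)) stop("either a t_min column or dt must be supplied")
    df$t_min <- df$frame * dt
  }
  keep <- intersect(c("track_id", "frame", "t_min", "x", "y", "z", "lineage"),
                    names(df))
  df <- df[keep]
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  validate_track_table(df)
  if (is.null(dt)) {
    dts <- unique(diff(sort(unique(df$t_min))))
    dt <- if (length(dts) > 0) min(dts) else NA_real_
  }
  structure(df, class = c("track_table", class(df)), dt = dt)
}

validate_track_table <- function(df) {
  key <- paste(df$track_id, df$frame)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("duplicate (track_id, frame) pair at row ", i, ": ", key[i])
  }
  for (cn in c("x", "y", "z", "t_min")) {
    if (!all(is.finite(df[[cn]]))) stop("non-finite values in column ", cn)
  }
  inc <- tapply(df$frame, df$track_id, function(f) all(diff(f) > 0))
  if (!all(unlist(inc))) stop("frames must be strictly increasing within a track")
  invisible(df)
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("<track_table> %d tracks, %d rows, frames %d..%d, dt = %s min\n",
              length(unique(x$track_id)), nrow(x),
              min(x$frame), max(x$frame), format(attr(x, "dt"))))
  NextMethod()
}

# dt accessor with override
track_dt <- function(tracks, dt = NULL) {
  dt <- dt %||% attr(tracks, "dt")
  if (is.null(dt) || !is.finite(dt) || dt <= 0) {
    stop("a positive frame interval dt (minutes) is required")
  }
  dt
}
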