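#' Delaunay-neighbour movement-similarity score
#'
#' For every evaluated frame interval, the movement vector of each cell is
#' the difference of its positions at consecutive time points.  Neighbours
#' are defined by a Delaunay triangulation of the 3D cell coordinates at the
#' interval's start frame (recomputed every frame; degenerate clouds fall
#' back to 2D, see [delaunay_edges()]).  A cell's score is the mean angle in
#' degrees (range 0-180) between its movement vector and each neighbour's;
#' the global score is the unweighted mean over all (cell, frame) scores.
#' Uniform migration scores 0; independent isotropic motion scores 90 in
#' expectation (the mean angle between isotropic 3D vectors), which are the
#' two endpoints of the conventional 0 (uniform) to 90 (random) display
#' scale.  Scores above 90 indicate anti-correlated motion; the display scale
#' is a colour-map clamp, not a property of the statistic.
#'
#' @param tracks a [track_table()].
#' @param frames start frames to evaluate (default: every frame with a
#'   successor frame `f + 1`).
#' @param min_cells minimum number of co-occurring cells per frame for a
#'   non-degenerate triangulation (default 5); frames below it are skipped
#'   with a message.
#' @return list of class `similarity_result`: `per_cell` (tibble `track_id`,
#'   `frame`, `score`, `n_neighbours`), `global_score` (degrees) and
#'   `neighbor_graph` (per-frame edge lists as track-id pairs).
#' @export
movement_similarity <- function(tracks, frames = NULL, min_cells = 5) {
  all_frames <- sort(unique(tracks$frame))
  starts <- frames %||% all_frames[(all_frames + 1) %in% all_frames]
  per_cell <- list()
  graphs <- list()
  for (f in starts) {
    a <- tracks[tracks$frame == f, ]
    b <- tracks[tracks$frame == f + 1, ]
    ids <- intersect(a$track_id, b$track_id)
    if (length(ids) < min_cells) {
      message("frame ", f, ": fewer than ", min_cells,
              " co-occurring cells, skipped")
      next
    }
    a <- a[match(ids, a$track_id), ]
    b <- b[match(ids, b$track_id), ]
    P <- as.matrix(a[, c("x", "y", "z")])
    V <- as.matrix(b[, c("x", "y", "z")]) - P
    edges <- delaunay_edges(P)
    graphs[[as.character(f)]] <- if (nrow(edges) > 0) {
      cbind(from = ids[edges[, 1]], to = ids[edges[, 2]])
    } else matrix(character(), 0, 2)
    vlen <- sqrt(rowSums(V^2))
    adj <- edge_adjacency(edges, length(ids))
    sc <- nn <- rep(NA_real_, length(ids))
    for (i in seq_along(ids)) {
      nb <- adj[[i]]
      if (is.null(nb) || vlen[i] == 0) next
      nb <- nb[vlen[nb] > 0]          # zero-length pairs are skipped
      if (length(nb) == 0) next
      ang <- vector_angle_deg(V[rep(i, length(nb)), , drop = FALSE],
                              V[nb, , drop = FALSE])
      sc[i] <- mean(ang)
      nn[i] <- length(nb)
    }
    keep <- !is.na(sc)
    if (any(keep)) {
      per_cell[[as.character(f)]] <- tibble(
        track_id = ids[keep], frame = f, score = sc[keep],
        n_neighbours = as.integer(nn[keep]))
    }
  }
  per_cell <- if (length(per_cell) > 0) do.call(rbind, per_cell) else
    tibble(track_id = character(), frame = integer(), score = numeric(),
           n_neighbours = integer())
  structure(list(per_cell = as_tibble(per_cell),
                 global_score = if (nrow(per_cell) > 0) mean(per_cell$score)
                                else NA_real_,
                 neighbor_graph = graphs),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "<similarity_result> global score %.2f deg over %d (cell, frame) scores\n",
    x$global_score, nrow(x$per_cell)))
  invisible(x)
}
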