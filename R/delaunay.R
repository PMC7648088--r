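#' Delaunay neighbour edges of a point cloud
#'
#' Returns the edge list of the Delaunay triangulation of 2D or 3D points,
#' used to define the neighbour graph of the movement-similarity score.
#' Degenerate 3D clouds (coplanar within tolerance, or fewer than 5 points)
#' fall back to a 2D triangulation on the two highest-variance axes; collinear
#' 2D clouds fall back to a nearest-neighbour chain along the dominant axis.
#' Both fallbacks emit a [message()] notice.
#'
#' @param points numeric matrix, one point per row, 2 or 3 columns.
#' @return integer matrix with two columns of 1-based point indices, one row
#'   per undirected Delaunay edge; attribute `dim_used` records whether the
#'   triangulation ran in 2 or 3 dimensions (1 for the collinear chain).
#' @export
delaunay_edges <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  d <- ncol(points)
  if (!d %in% c(2L, 3L)) stop("points must have 2 or 3 columns")
  if (n < 2) {
    out <- matrix(integer(), 0, 2)
    attr(out, "dim_used") <- d
    return(out)
  }
  if (n == 2) {
    out <- matrix(c(1L, 2L), 1, 2)
    attr(out, "dim_used") <- d
    return(out)
  }

  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  rank_eff <- sum(sv > max(sv[1], .Machine$double.eps) * 1e-8)

  if (d == 3 && (rank_eff <= 2 || n < 5)) {
    ax <- order(apply(points, 2, stats::var), decreasing = TRUE)[1:2]
    message("degenerate 3D point set: falling back to 2D Delaunay on axes ",
            paste(c("x", "y", "z")[sort(ax)], collapse = ", "))
    points <- points[, sort(ax), drop = FALSE]
    d <- 2L
    ctr <- sweep(points, 2, colMeans(points))
    sv <- svd(ctr, nu = 0, nv = 0)$d
    rank_eff <- sum(sv > max(sv[1], .Machine$double.eps) * 1e-8)
  }
  if (d == 2 && rank_eff <= 1) {
    message("collinear point set: using a chain along the dominant axis")
    ax <- which.max(apply(points, 2, stats::var))
    o <- order(points[, ax])
    out <- cbind(o[-n], o[-1])
    out <- t(apply(out, 1, sort))
    storage.mode(out) <- "integer"
    attr(out, "dim_used") <- 1L
    return(out)
  }
  out <- delaunay_edges_cpp(points[, seq_len(d), drop = FALSE], d)
  attr(out, "dim_used") <- d
  out
}

# adjacency list (per point, integer vector of neighbours) from an edge matrix
edge_adjacency <- function(edges, n) {
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}
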