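#' Region of interest as a logical mask
#'
#' Accepts a logical/0-1 matrix mask or a polygon (two-column matrix of
#' 0-based x, y vertices) which is rasterised by point-in-polygon testing of
#' pixel centres.
#'
#' @param roi mask matrix, polygon matrix, or `NULL` for the whole image.
#' @param dim target image dimensions `(rows, cols)`.
#' @return logical matrix of the image dimensions.
#' @export
as_roi_mask <- function(roi, dim) {
  if (is.null(roi)) return(matrix(TRUE, dim[1], dim[2]))
  if (is.matrix(roi) && ncol(roi) == 2 && !is.logical(roi) &&
      nrow(roi) >= 3 && !all(dim(roi) == dim)) {
    xs <- rep(seq_len(dim[2]) - 1, each = dim[1])
    ys <- rep(seq_len(dim[1]) - 1, dim[2])
    inside <- point_in_polygon(xs, ys, roi[, 1], roi[, 2])
    return(matrix(inside, dim[1], dim[2]))
  }
  m <- roi != 0
  if (!all(dim(m) == dim)) stop("ROI mask does not match image dimensions")
  if (!any(m)) stop("ROI is empty")
  m
}

# even-odd ray casting
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xi <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & (px < xi))
    j <- i
  }
  inside
}

#' Fluorescence enrichment index
#'
#' The fraction of lineage-reporter signal attributable to the first channel:
#' `MFI_G / (MFI_G + MFI_R)` over the region of interest, where MFI is the
#' mean fluorescence intensity.  With GFP-labelled scar-forming fibroblasts
#' and RFP-labelled lineage-negative fibroblasts this is the EPF enrichment
#' index.  Note the index is invariant to a common gain applied to both
#' channels but not to per-channel gain.
#'
#' @param img_g,img_r co-registered greyscale matrices of identical size.
#' @param roi region of interest (see [as_roi_mask()]); default whole image.
#' @return fraction in `[0, 1]`.
#' @export
enrichment_index <- function(img_g, img_r, roi = NULL) {
  if (!all(dim(img_g) == dim(img_r))) stop("channel images differ in shape")
  mask <- as_roi_mask(roi, dim(img_g))
  mg <- mean(img_g[mask])
  mr <- mean(img_r[mask])
  if (mg + mr <= 0) stop("undefined index: both channels are zero in the ROI")
  mg / (mg + mr)
}
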