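#' Rasterize a curve into a binary vessel mask
#'
#' Draws an ordered point list onto a logical raster as an 8-connected
#' polyline and thickens it to the requested width, emulating a segmented
#' vessel of roughly constant caliber. Coordinates are mapped as
#' `row = round(y) + margin`, `col = round(x) + margin` after shifting the
#' curve into the positive quadrant.
#'
#' @param points Tibble/matrix of curve points (`x`, `y`).
#' @param shape Optional `c(rows, cols)` canvas size. By default the canvas is
#'   sized to fit the curve plus a margin.
#' @param thickness Stroke width in pixels (odd values render symmetrically).
#' @param margin Border margin in pixels when `shape` is auto-sized.
#' @return A logical matrix (`TRUE` = vessel).
#' @export
rasterize_curve <- function(points, shape = NULL, thickness = 3, margin = NULL) {
  xy <- as_xy(points)
  if (thickness < 1) abort("thickness must be >= 1")
  rad <- (thickness - 1) / 2
  if (is.null(margin)) margin <- ceiling(rad) + 2
  # densify so consecutive rounded pixels are 8-adjacent
  seglen <- step_lengths(xy)
  dense <- purrr::map(seq_along(seglen), function(i) {
    n <- max(2L, ceiling(seglen[i] / 0.4) + 1L)
    cbind(seq(xy[i, 1], xy[i + 1, 1], length.out = n),
          seq(xy[i, 2], xy[i + 1, 2], length.out = n))
  })
  dense <- do.call(rbind, dense)
  if (is.null(shape)) {
    # auto-canvas: shift the curve into the positive quadrant plus a margin
    cols <- round(dense[, 1] - min(dense[, 1])) + margin + 1L
    rows <- round(dense[, 2] - min(dense[, 2])) + margin + 1L
    shape <- c(max(rows) + margin, max(cols) + margin)
  } else {
    # fixed canvas: coordinates are used as given (1-based after rounding)
    cols <- round(dense[, 1]) + 1L
    rows <- round(dense[, 2]) + 1L
    if (any(rows < 1 | cols < 1 | rows > shape[1] | cols > shape[2])) {
      abort("curve does not fit the requested canvas")
    }
  }
  mask <- matrix(FALSE, shape[1], shape[2])
  mask[cbind(rows, cols)] <- TRUE
  if (rad > 0) mask <- dilate_disc(mask, rad)
  mask
}

# Morphological dilation by a disc of radius `rad` (pixels), done by stamping
# the disc offset set at every foreground pixel.
dilate_disc <- function(mask, rad) {
  r <- ceiling(rad)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= rad^2 + 1e-9, , drop = FALSE]
  fg <- which(mask, arr.ind = TRUE)
  rows <- rep(fg[, 1], each = nrow(off)) + off$dr
  cols <- rep(fg[, 2], each = nrow(off)) + off$dc
  keep <- rows >= 1 & rows <= nrow(mask) & cols >= 1 & cols <= ncol(mask)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[cbind(rows[keep], cols[keep])] <- TRUE
  out
}

#' Read a binary vessel mask from a PNG or TIFF file
#'
#' Any pixel with a nonzero value in any channel is treated as vessel.
#'
#' @param path Image path (`.png`, `.tif`, `.tiff`).
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort(paste0("mask file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported mask format: .", ext))
  )
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), max)
  img > 0
}

#' Write a binary vessel mask to a PNG file
#'
#' @param mask Logical matrix.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
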