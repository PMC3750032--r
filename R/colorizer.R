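# Apply a color LUT to FA volumes and render slice mosaics for screening.

#' Colorize an FA volume
#'
#' Maps every finite, in-mask voxel through [interpolate_color()]; `NaN`
#' voxels and voxels outside the mask get the background color. The mapping
#' is purely voxelwise: no smoothing or resampling is applied, so the
#' rendered colors reflect the measured FA values directly. The background
#' defaults to exact black independently of the LUT's `DOMAIN_MIN` color;
#' with a non-black `DOMAIN_MIN`, tissue at FA ~ 0 therefore remains
#' distinguishable from non-brain.
#'
#' @param volume an [fa_volume()] (or bare 3D array).
#' @param lut a `color_lut`.
#' @param mask optional logical/0-1 volume of the same shape.
#' @param background RGB triple for NaN / out-of-mask voxels.
#' @return object of class `rgb_volume`: `data` is a 4D integer array
#'   `dim x 3`, plus the source `pixdim`.
#' @export
colorize <- function(volume, lut, mask = NULL, background = c(0L, 0L, 0L)) {
  if (inherits(volume, "fa_volume")) {
    x <- volume$data; pixdim <- volume$pixdim
  } else {
    if (length(dim(volume)) != 3L) stop("volume must be a 3D array")
    x <- volume; pixdim <- c(1, 1, 1)
  }
  d <- dim(x)
  if (!is.null(mask)) {
    mdim <- if (inherits(mask, "fa_volume")) dim(mask$data) else dim(mask)
    if (!identical(as.integer(mdim), as.integer(d)))
      stop("mask shape (", paste(mdim, collapse = "x"),
           ") does not match volume shape (", paste(d, collapse = "x"), ")")
    mvals <- if (inherits(mask, "fa_volume")) mask$data else mask
    inmask <- is.finite(as.vector(mvals)) & as.vector(mvals) != 0
  } else {
    inmask <- TRUE
  }
  v <- as.vector(x)
  use <- is.finite(v) & inmask
  n <- length(v)
  out <- matrix(rep(as.integer(background), each = n), nrow = n)
  if (any(use)) out[use, ] <- interpolate_color(lut, v[use])
  structure(list(data = array(out, dim = c(d, 3L)), pixdim = pixdim),
            class = "rgb_volume")
}

#' @export
print.rgb_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<rgb_volume> %d x %d x %d voxels x 3 channels\n",
              d[1], d[2], d[3]))
  invisible(x)
}

# one display slice of an rgb_volume as a [rows, cols, 3] array in [0, 1];
# nearest-voxel extraction only, no resampling
extract_slice <- function(rgb, plane, k, radiological = TRUE) {
  d <- dim(rgb$data)[1:3]
  ax <- switch(plane, axial = 3L, coronal = 2L, sagittal = 1L,
               stop("plane must be axial, coronal or sagittal"))
  if (k < 1L || k > d[ax])
    stop("slice index ", k, " out of range [1, ", d[ax], "] for ", plane,
         " plane")
  keep <- setdiff(1:3, ax)
  sl <- switch(plane,
               axial    = rgb$data[, , k, , drop = FALSE],
               coronal  = rgb$data[, k, , , drop = FALSE],
               sagittal = rgb$data[k, , , , drop = FALSE])
  sl <- array(sl, dim = c(d[keep], 3L))  # (width-axis, height-axis, 3)
  img <- aperm(sl, c(2L, 1L, 3L)) / 255
  img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]  # superior/anterior up
  if (radiological && plane != "sagittal")
    img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  img
}

#' Render a slice mosaic with a color bar
#'
#' Tiles the selected slices of a colorized volume into a grid and appends a
#' horizontal strip showing the LUT across the full FA domain. Output is a
#' deterministic PNG: identical inputs give byte-identical files. Display
#' is radiological by default (subject's left on the image right); no voxel
#' interpolation is performed.
#'
#' @param rgb an `rgb_volume` from [colorize()].
#' @param lut the `color_lut` used, for the color bar (`NULL` to omit).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param slices integer slice indices (1-based along the chosen axis).
#' @param path output PNG path.
#' @param ncol tiles per row; default `ceiling(sqrt(length(slices)))`.
#' @param bar_height color-bar strip height in pixels (default 16).
#' @param radiological flip left/right for radiological display convention.
#' @return `path`, invisibly.
#' @export
render_mosaic <- function(rgb, lut = NULL, plane = "axial", slices, path,
                          ncol = NULL, bar_height = 16L, radiological = TRUE) {
  stopifnot(inherits(rgb, "rgb_volume"), length(slices) >= 1L)
  tiles <- lapply(slices, function(k)
    extract_slice(rgb, plane, as.integer(k), radiological))
  th <- dim(tiles[[1]])[1]; tw <- dim(tiles[[1]])[2]
  n <- length(tiles)
  if (is.null(ncol)) ncol <- ceiling(sqrt(n))
  nrow <- ceiling(n / ncol)
  width <- ncol * tw
  bar_height <- if (is.null(lut)) 0L else as.integer(bar_height)
  img <- array(0, dim = c(nrow * th + bar_height, width, 3L))
  for (i in seq_len(n)) {
    r0 <- ((i - 1L) %/% ncol) * th
    c0 <- ((i - 1L) %% ncol) * tw
    img[r0 + seq_len(th), c0 + seq_len(tw), ] <- tiles[[i]]
  }
  if (bar_height > 0L) {
    bar <- interpolate_color(lut, (seq_len(width) - 1L) / (width - 1L)) / 255
    for (ch in 1:3)
      img[nrow * th + seq_len(bar_height), , ch] <-
        matrix(bar[, ch], nrow = bar_height, ncol = width, byrow = TRUE)
  }
  png::writePNG(img, path)
  invisible(path)
}
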