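#' Construct a 2D grayscale image
#'
#' Lightweight container for a single 2D grayscale image. Pixels are stored
#' as a numeric matrix in row-major image convention: rows index `y`
#' (increasing downward), columns index `x`.
#'
#' @param pixels Numeric matrix of intensities (arbitrary units).
#' @param ... Free-form metadata (e.g. `source`, `slice_id`) stored as a list.
#' @return An object of class `image2d` with elements `pixels`, `height`,
#'   `width`, `metadata`.
#' @export
image2d <- function(pixels, ...) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("image intensities must all be finite")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         metadata = list(...)),
    class = "image2d"
  )
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %d x %d (h x w), range [%g, %g]>\n",
              x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Load a 2D grayscale image from disk
#'
#' Reads NIfTI, PNG, TIFF or plain CSV numeric grids into an [image2d()].
#' PNG and TIFF intensities are rescaled to the 0..255 range (8-bit
#' convention) so that write-then-read round trips recover integer gray
#' levels. 3D NIfTI volumes require a 0-based `slice_id` selecting the
#' axial slice.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"csv"`, `"png"`, `"tiff"`, `"nifti"`.
#'   `"auto"` dispatches on the file extension.
#' @param slice_id 0-based slice index for 3D NIfTI volumes.
#' @param collapse_channels How to treat multichannel (RGB) input:
#'   `"error"` (default) or `"mean"`.
#' @return An [image2d()].
#' @export
load_image <- function(path, format = c("auto", "csv", "png", "tiff", "nifti"),
                       slice_id = NULL, collapse_channels = c("error", "mean")) {
  format <- match.arg(format)
  collapse_channels <- match.arg(collapse_channels)
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
    format <- switch(ext,
      csv = "csv", txt = "csv",
      png = "png",
      tif = "tiff", tiff = "tiff",
      nii = "nifti",
      stop("cannot infer image format from extension: ", path))
  }
  px <- switch(format,
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("package 'png' is required to read PNG images")
      arr <- png::readPNG(path)
      .collapse(arr, collapse_channels) * 255
    },
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' is required to read TIFF images")
      arr <- tiff::readTIFF(path)
      .collapse(arr, collapse_channels) * 255
    },
    nifti = {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("package 'RNifti' is required to read NIfTI images")
      vol <- RNifti::readNifti(path)
      a <- as.array(vol)
      if (length(dim(a)) == 3L) {
        if (is.null(slice_id))
          stop("3D NIfTI volume: a 0-based slice_id must be supplied")
        if (slice_id < 0L || slice_id >= dim(a)[3L])
          stop("slice_id out of range: ", slice_id)
        a <- a[, , slice_id + 1L]
      } else if (length(dim(a)) != 2L) {
        stop("only 2D or 3D NIfTI volumes are supported")
      }
      a
    })
  dimnames(px) <- NULL
  img <- image2d(px, source = path, format = format)
  if (!is.null(slice_id)) img$metadata$slice_id <- slice_id
  img
}

.collapse <- function(arr, mode) {
  if (length(dim(arr)) == 2L) return(arr)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] == 1L) return(arr[, , 1L])
    if (mode == "mean") return(apply(arr, c(1, 2), mean))
    stop("multichannel image: pass collapse_channels = \"mean\" to average channels")
  }
  stop("unsupported image array with ", length(dim(arr)), " dimensions")
}

#' Specify a rectangular ROI
#'
#' Coordinates are 0-based with `y` increasing downward; the rectangle is
#' half-open, covering columns `x0 .. x0+width-1` and rows
#' `y0 .. y0+height-1`.
#'
#' @param x0,y0 0-based top-left pixel.
#' @param width,height Extent in pixels (default 8 x 9, the standard patch
#'   used throughout this package).
#' @param rat_id,slice_id,side,group Optional sample metadata.
#' @return A one-row `data.frame` with class `roi_spec`.
#' @export
roi_spec <- function(x0, y0, width = 8L, height = 9L,
                     rat_id = NA, slice_id = NA, side = NA, group = NA) {
  if (width * height < 4) stop("ROI must contain at least 4 pixels")
  if (x0 < 0 || y0 < 0) stop("ROI coordinates must be non-negative")
  structure(
    data.frame(rat_id = rat_id, slice_id = slice_id, side = side,
               group = group, x0 = as.integer(x0), y0 = as.integer(y0),
               width = as.integer(width), height = as.integer(height),
               stringsAsFactors = FALSE),
    class = c("roi_spec", "data.frame")
  )
}

#' Read an ROI table from CSV
#'
#' Expects columns `rat_id, slice_id, side, group, x0, y0, width, height`.
#'
#' @param path CSV path.
#' @return A `data.frame` of ROI specifications.
#' @export
read_roi_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rat_id", "slice_id", "side", "group", "x0", "y0", "width", "height")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("ROI table is missing columns: ", paste(missing, collapse = ", "))
  tab
}

#' Extract the raw pixel patch for an ROI
#' @keywords internal
roi_patch <- function(image, roi) {
  stopifnot(inherits(image, "image2d"))
  x0 <- roi$x0; y0 <- roi$y0; w <- roi$width; h <- roi$height
  if (x0 < 0 || y0 < 0 || x0 + w > image$width || y0 + h > image$height)
    stop(sprintf("ROI [%d,%d %dx%d] lies outside the %dx%d image",
                 x0, y0, w, h, image$width, image$height))
  image$pixels[(y0 + 1L):(y0 + h), (x0 + 1L):(x0 + w), drop = FALSE]
}

#' Normalize and quantize an ROI to integer gray levels
#'
#' Implements the standard MR texture-analysis normalization: intensities
#' outside `mu +/- 3*SD` (computed over the ROI) are saturated to the
#' nearest bound (and counted), then the remaining range is mapped affinely
#' onto integer levels `1 .. 2^k_bits`. Saturation rather than removal
#' keeps the ROI geometry intact, which the co-occurrence and run-length
#' features require.
#'
#' @param image An [image2d()], or a numeric matrix treated as the patch
#'   itself when `roi` is `NULL`.
#' @param roi A one-row ROI specification ([roi_spec()] or a row of
#'   [read_roi_table()]); `NULL` to use the full image as the patch.
#' @param k_bits Bit depth; levels run 1..2^k_bits. Default 6 (64 levels),
#'   common practice for matrix-based texture features on small ROIs.
#' @param clip_mode `"mu3sd"` (default) or `"none"` (plain min-max).
#' @return An object of class `quantized_roi`: integer matrix `levels`,
#'   `ng`, `mu`, `sd`, `n_discarded`, `k_bits`, `clip_mode`.
#' @export
normalize_quantize <- function(image, roi = NULL, k_bits = 6L,
                               clip_mode = c("mu3sd", "none")) {
  clip_mode <- match.arg(clip_mode)
  if (k_bits < 1L || k_bits > 12L) stop("k_bits must be in 1..12")
  patch <- if (is.null(roi)) {
    if (inherits(image, "image2d")) image$pixels else as.matrix(image)
  } else {
    roi_patch(if (inherits(image, "image2d")) image else image2d(image), roi)
  }
  if (!all(is.finite(patch))) stop("ROI contains non-finite pixel values")
  ng <- 2L^k_bits
  mu <- mean(patch)
  sdv <- stats::sd(as.vector(patch))
  n_discarded <- 0L
  x <- patch
  if (clip_mode == "mu3sd" && sdv > 0) {
    lo_clip <- mu - 3 * sdv
    hi_clip <- mu + 3 * sdv
    out <- x < lo_clip | x > hi_clip
    n_discarded <- sum(out)
    x <- pmin(pmax(x, lo_clip), hi_clip)
  }
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    lev <- 1L + floor((x - lo) / (hi - lo) * (ng - 1) + 1e-9)
    lev <- pmin(pmax(lev, 1L), ng)
  } else {
    lev <- array(1L, dim = dim(x))
  }
  storage.mode(lev) <- "integer"
  structure(
    list(levels = lev, ng = ng, mu = mu, sd = sdv,
         n_discarded = as.integer(n_discarded),
         k_bits = as.integer(k_bits), clip_mode = clip_mode),
    class = "quantized_roi"
  )
}

#' Build a quantized ROI directly from a level matrix
#'
#' Mainly for tests and oracles: wraps an integer matrix already expressed
#' in gray levels `1..ng`.
#'
#' @param levels Integer matrix with values in `1..ng`.
#' @param ng Number of gray levels; defaults to `max(levels)`.
#' @return A `quantized_roi`.
#' @export
quantized_roi <- function(levels, ng = max(levels)) {
  levels <- as.matrix(levels)
  if (any(levels < 1L) || any(levels > ng))
    stop("levels must lie in 1..ng")
  if (any(levels != round(levels))) stop("levels must be integers")
  storage.mode(levels) <- "integer"
  structure(
    list(levels = levels, ng = as.integer(ng), mu = mean(levels),
         sd = stats::sd(as.vector(levels)), n_discarded = 0L,
         k_bits = as.integer(ceiling(log2(ng))), clip_mode = "none"),
    class = "quantized_roi"
  )
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi %d x %d, Ng=%d, mu=%.3f, sd=%.3f, discarded=%d>\n",
              nrow(x$levels), ncol(x$levels), x$ng, x$mu, x$sd, x$n_discarded))
  invisible(x)
}

#' Write a CSV numeric grid image
#'
#' Plain-text counterpart of [load_image()]'s `csv` format; used by the
#' pipeline stages so intermediate images stay lossless and inspectable.
#'
#' @param image An [image2d()] or numeric matrix.
#' @param path Output path.
#' @export
write_image_csv <- function(image, path) {
  px <- if (inherits(image, "image2d")) image$pixels else as.matrix(image)
  utils::write.table(px, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
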