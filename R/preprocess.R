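#' Read a raster image as a grayscale matrix
#'
#' Reads an 8- or 16-bit PNG or TIFF. Three-channel (RGB) inputs are reduced
#' to luminance with [to_grayscale()]; single-channel inputs are returned as
#' read. Values are kept on their native scale (a 16-bit value of 40000 stays
#' 40000; nothing is clipped or rescaled), and the source bit depth is
#' recorded as an attribute.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param weights Luminance weights passed to [to_grayscale()] for RGB input.
#' @return A numeric matrix (rows = image rows) with attributes `bit_depth`
#'   and `source`.
#' @examples
#' \dontrun{
#' img <- read_gray("field_01.png")
#' }
#' @export
read_gray <- function(path, weights = c(0.299, 0.587, 0.114)) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "bw_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- tryCatch(png::readPNG(path, info = TRUE), error = function(e) {
      abort(paste0("not a readable PNG: ", path), class = "bw_error")
    })
    bit_depth <- as.integer(attr(arr, "info")$bit.depth %||% 8L)
    scale <- 2^bit_depth - 1 # readPNG normalizes to [0,1]; undo it
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                    error = function(e) {
      abort(paste0("not a readable TIFF: ", path), class = "bw_error")
    })
    bit_depth <- as.integer(attr(arr, "bits.per.sample") %||% 8L)
    scale <- 1 # as.is = TRUE returns native integer values unscaled
  } else {
    abort(paste0("unsupported image format: .", ext), class = "bw_error")
  }
  if (length(arr) == 0) abort("zero-sized image", class = "bw_error")
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] == 4) arr <- arr[, , 1:3, drop = FALSE] # drop alpha
    if (dim(arr)[3] == 2) arr <- arr[, , 1, drop = TRUE]    # gray + alpha
  }
  if (length(dim(arr)) == 3) {
    g <- to_grayscale(arr * scale, weights = weights)
  } else {
    g <- as.matrix(arr) * scale
  }
  check_gray(g)
  structure(g, bit_depth = bit_depth, source = path)
}

#' Luminance conversion of an RGB array
#'
#' Collapses a 3-channel raster to a single channel with fixed luminance
#' weights (Rec. 601 by default, as in common imaging software). The choice
#' of weights is configurable because acquisition pipelines differ; the
#' output range is always within the input range.
#'
#' @param rgb A numeric array `rows x cols x 3`.
#' @param weights Length-3 non-negative weights summing to 1.
#' @return A numeric matrix.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' # not a valid pipeline image (too small), but the arithmetic is exact:
#' sum(px[1, 1, ] * c(0.299, 0.587, 0.114))
#' @export
to_grayscale <- function(rgb, weights = c(0.299, 0.587, 0.114)) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    abort("to_grayscale() expects a rows x cols x 3 array",
          class = "bw_error")
  }
  if (length(weights) != 3 || any(weights < 0)) {
    abort("weights must be 3 non-negative numbers", class = "bw_error")
  }
  weights <- weights / sum(weights)
  out <- rgb[, , 1] * weights[1] + rgb[, , 2] * weights[2] +
    rgb[, , 3] * weights[3]
  dim(out) <- dim(rgb)[1:2] # keep matrix shape even for 1 x 1 input
  out
}

#' 3x3 median filter
#'
#' Replaces every pixel by the median of its 3x3 neighbourhood, the standard
#' remedy for photon (shot) noise in photomicrographs. Borders use reflect
#' padding so no dark frame leaks into the downstream spectrum. Implemented
#' as a vectorized 9-element median selection network, so large fields filter
#' in milliseconds.
#'
#' @param img Numeric matrix, at least 16 x 16.
#' @return Matrix of the same dimensions.
#' @examples
#' x <- matrix(0, 32, 32)
#' x[16, 16] <- 255           # an isolated hot pixel
#' max(median3x3(x))          # 0: the impulse is removed
#' @export
median3x3 <- function(img) {
  check_gray(img)
  p <- pad_reflect(img, 1L)
  nr <- nrow(img)
  nc <- ncol(img)
  win <- vector("list", 9L)
  k <- 0L
  for (dc in 0:2) {
    for (dr in 0:2) {
      k <- k + 1L
      win[[k]] <- p[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
    }
  }
  # 19-exchange median-of-9 selection network (min into first slot, max into
  # second); the median lands in slot 5.
  net <- list(
    c(2, 3), c(5, 6), c(8, 9), c(1, 2), c(4, 5), c(7, 8),
    c(2, 3), c(5, 6), c(8, 9), c(1, 4), c(6, 9), c(5, 8),
    c(4, 7), c(2, 5), c(3, 6), c(5, 8), c(5, 3), c(7, 5), c(5, 3)
  )
  for (pr in net) {
    lo <- pmin(win[[pr[1]]], win[[pr[2]]])
    hi <- pmax(win[[pr[1]]], win[[pr[2]]])
    win[[pr[1]]] <- lo
    win[[pr[2]]] <- hi
  }
  out <- win[[5]]
  attributes(out) <- attributes(img)
  out
}

#' Rectangular region of interest
#'
#' Coordinates are 0-based with half-open extents, so `rect_roi(0, 0, h, w)`
#' on an `h x w` image is the identity crop. Used to separate papillary and
#' reticular dermal compartments for per-compartment indices.
#'
#' @param row0,col0 0-based top-left corner.
#' @param height,width Extent in pixels; both must be at least 16.
#' @param label Optional compartment label carried into result rows.
#' @return A list of class `bw_roi`.
#' @export
rect_roi <- function(row0, col0, height, width, label = NA_character_) {
  roi <- list(row0 = as.integer(row0), col0 = as.integer(col0),
              height = as.integer(height), width = as.integer(width),
              label = as.character(label))
  if (roi$row0 < 0 || roi$col0 < 0) {
    abort("ROI corner must be non-negative", class = "bw_error")
  }
  if (roi$height < 16L || roi$width < 16L) {
    abort("ROI must be at least 16 x 16", class = "bw_error")
  }
  structure(roi, class = "bw_roi")
}

#' Crop an image to a region of interest
#'
#' @param img Numeric matrix.
#' @param roi A [rect_roi()].
#' @return The exact sub-matrix; image attributes are inherited.
#' @export
crop_roi <- function(img, roi) {
  check_gray(img)
  stopifnot(inherits(roi, "bw_roi"))
  if (roi$row0 + roi$height > nrow(img) || roi$col0 + roi$width > ncol(img)) {
    abort("ROI extends past the image boundary", class = "bw_error")
  }
  out <- img[roi$row0 + seq_len(roi$height), roi$col0 + seq_len(roi$width),
             drop = FALSE]
  for (a in c("bit_depth", "source")) attr(out, a) <- attr(img, a)
  out
}

#' Read a ROI table
#'
#' Plain-text CSV with columns `image, compartment_label, row0, col0, height,
#' width` (0-based, half-open), one row per compartment rectangle.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_roi_csv <- function(path) {
  cols <- readr::cols(
    image = readr::col_character(),
    compartment_label = readr::col_character(),
    row0 = readr::col_integer(),
    col0 = readr::col_integer(),
    height = readr::col_integer(),
    width = readr::col_integer()
  )
  readr::read_csv(path, col_types = cols)
}

# Shared validation for matrices entering the pipeline.
check_gray <- function(img) {
  stop_not_matrix(img)
  if (nrow(img) < 16L || ncol(img) < 16L) {
    abort("images entering the pipeline must be at least 16 x 16",
          class = "bw_error")
  }
  invisible(img)
}

#' Write a grayscale matrix as a PNG
#'
#' Debug/phantom output helper: values are min-max scaled to `[0, 1]` unless
#' already within it.
#'
#' @param img Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  stop_not_matrix(img)
  v <- img
  if (min(v) < 0 || max(v) > 1) {
    rng <- range(v)
    v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  }
  png::writePNG(v, path)
  invisible(path)
}
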