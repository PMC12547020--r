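#' Image and mask input/output
#'
#' Images are represented as plain numeric matrices in row, column order
#' (`img[r, c]`), with optional `channel` and `pixel_size_um` attributes.
#' Label masks are integer matrices in which 0 is background and each
#' positive value labels one cell; labels need not be consecutive.
#'
#' @name image-io
NULL

new_fluor_image <- function(pixels, channel = NA_character_, pixel_size_um = NA_real_) {
  stopifnot(is.matrix(pixels))
  attr(pixels, "channel") <- channel
  attr(pixels, "pixel_size_um") <- pixel_size_um
  pixels
}

#' Read a single-plane grayscale image
#'
#' Reads 16-bit (or 8-bit) grayscale TIFF or PNG into an integer-valued
#' matrix, preserving pixel values bit-exactly. Multi-channel (RGB/RGBA)
#' input is rejected: the pipeline operates on single-channel fluorescence
#' frames.
#'
#' @param path file path to a `.tif`/`.tiff` or `.png` file
#' @param channel optional free-text channel tag stored as an attribute
#' @return numeric matrix of pixel intensities (counts in \[0, 65535\])
#' @export
read_image <- function(path, channel = NA_character_) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE, all = FALSE)
    if (length(dim(px)) == 3L) {
      if (dim(px)[3] == 1L) px <- px[, , 1L]
      else stop("multi-channel TIFF not supported (", dim(px)[3], " channels): ", path)
    }
  } else if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) {
      if (dim(px)[3] == 1L) px <- px[, , 1L]
      else stop("multi-channel PNG not supported (", dim(px)[3], " channels): ", path)
    }
    # png values are scaled to [0, 1]; undo the scaling at the stored bit depth
    bits <- if (max(px) > 0 && any(abs(px * 255 - round(px * 255)) > 1e-9)) 16L else 8L
    px <- round(px * (2^bits - 1))
  } else {
    stop("unsupported image format '", ext, "': ", path)
  }
  if (!is.matrix(px)) px <- as.matrix(px)
  storage.mode(px) <- "double"
  new_fluor_image(px, channel = channel)
}

#' Write a single-plane grayscale image
#'
#' Writes an integer-valued matrix as 16-bit grayscale TIFF or PNG. Values
#' must lie in \[0, 65535\]; `read_image(write_image(x))` is bit-exact.
#'
#' @param img numeric matrix with values in \[0, 65535\]
#' @param path output path, `.tif`/`.tiff` or `.png`
#' @return `path`, invisibly
#' @export
write_image <- function(img, path) {
  stopifnot(is.matrix(img))
  if (any(img < 0) || any(img > 65535)) stop("pixel values outside [0, 65535]")
  if (any(abs(img - round(img)) > 1e-9)) stop("pixel values must be integers for 16-bit storage")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (max(img) > 255) stop("PNG output supports 8-bit values only; use TIFF for 16-bit")
    png::writePNG(img / 255, path)
  } else {
    stop("unsupported image format '", ext, "': ", path)
  }
  invisible(path)
}

#' Read an integer label mask
#'
#' Reads a segmentation mask (0 = background, k > 0 = cell k) from PNG or
#' TIFF. Values must be integers; a fractional pixel anywhere is treated as
#' a format error since labels are identities, not intensities.
#'
#' @param path file path
#' @return integer matrix; attribute `n_cells` holds the count of distinct
#'   positive labels
#' @export
read_label_mask <- function(path) {
  px <- read_image(path)
  if (any(abs(px - round(px)) > 1e-9)) stop("label mask contains non-integer values: ", path)
  labels <- round(px)
  storage.mode(labels) <- "integer"
  n_cells <- length(setdiff(unique(as.vector(labels)), 0L))
  if (n_cells == 0L) warning("label mask contains no cells: ", path)
  attr(labels, "n_cells") <- n_cells
  labels
}

#' Write an integer label mask
#'
#' @param labels integer matrix of labels (0 background)
#' @param path output path; PNG for label values up to 255, TIFF otherwise
#' @return `path`, invisibly
#' @export
write_label_mask <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels >= 0))
  write_image(labels, path)
}

#' Check that an image and a label mask are a valid pair
#'
#' @param img image matrix
#' @param labels label matrix
#' @return invisibly TRUE; stops with a dimension error otherwise
#' @export
check_pair <- function(img, labels) {
  if (!identical(dim(img), dim(labels)))
    stop("image (", paste(dim(img), collapse = "x"), ") and mask (",
         paste(dim(labels), collapse = "x"), ") dimensions differ")
  invisible(TRUE)
}
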