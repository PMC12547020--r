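#' Binary and label-mask morphology
#'
#' The peripheral-intensity method is built from three morphological steps:
#' a 1-px diamond erosion of every cell label so adjacent masks no longer
#' touch, removal of connected components below a size threshold, and a 7-px
#' diamond erosion whose complement is the peripheral ring. The diamond
#' (L1-ball) structuring element of radius r is separable into r successive
#' radius-1 erosions, which is how `erode_diamond` is computed; out-of-bounds
#' pixels count as background.
#'
#' @name morphology
NULL

erode1 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  up    <- rbind(m[-1, , drop = FALSE], matrix(FALSE, 1L, p))
  down  <- rbind(matrix(FALSE, 1L, p), m[-n, , drop = FALSE])
  left  <- cbind(m[, -1, drop = FALSE], matrix(FALSE, n, 1L))
  right <- cbind(matrix(FALSE, n, 1L), m[, -p, drop = FALSE])
  m & up & down & left & right
}

#' Erode a binary mask with a diamond structuring element
#'
#' A pixel is retained iff every pixel within L1 (Manhattan) distance
#' `radius` lies inside the mask; pixels outside the image count as
#' background.
#'
#' @param mask logical (or 0/1) matrix
#' @param radius erosion radius in px (>= 1)
#' @return logical matrix of the same dimensions
#' @export
erode_diamond <- function(mask, radius) {
  stopifnot(is.matrix(mask), radius >= 1)
  m <- mask != 0
  for (i in seq_len(radius)) m <- erode1(m)
  m
}

#' Label connected components (8-connectivity)
#'
#' Components are labeled 1..K. `EBImage::bwlabel` provides the 4-connected
#' labeling; labels that touch diagonally are then merged so that the result
#' is 8-connected.
#'
#' @param bin logical (or 0/1) matrix
#' @return integer matrix of component labels, 0 = background
#' @export
label_components <- function(bin) {
  stopifnot(is.matrix(bin))
  lab <- EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(bin != 0), nrow(bin), ncol(bin))))
  storage.mode(lab) <- "integer"
  K <- max(lab)
  if (K <= 1L) return(lab)
  n <- nrow(lab); p <- ncol(lab)
  # diagonal neighbor label pairs (down-right and down-left offsets)
  a1 <- lab[-n, -p]; b1 <- lab[-1, -1]
  a2 <- lab[-n, -1]; b2 <- lab[-1, -p]
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2])))
  if (nrow(pairs) > 0L) {
    parent <- seq_len(K)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(K), find, integer(1))
    remap <- match(root, sort(unique(root)))
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

bounding_box <- function(idx, dims, pad = 0L) {
  rc <- arrayInd(idx, dims)
  r0 <- max(1L, min(rc[, 1]) - pad); r1 <- min(dims[1], max(rc[, 1]) + pad)
  c0 <- max(1L, min(rc[, 2]) - pad); c1 <- min(dims[2], max(rc[, 2]) + pad)
  c(r0, r1, c0, c1)
}

#' Separate, size-filter and relabel a cell mask
#'
#' Each label is eroded independently with a diamond of radius
#' `cfg$erosion_radius_separate` (so touching cells detach), connected
#' components (8-connectivity) smaller than `cfg$min_component_px` are
#' removed, and survivors are relabeled 1..K. The count of retained and
#' dropped components is attached as attributes `n_kept` / `n_dropped`.
#'
#' @param labels integer label matrix (0 = background)
#' @param cfg a [run_config()]
#' @return cleaned integer label matrix
#' @export
clean_labels <- function(labels, cfg = run_config()) {
  stopifnot(is.matrix(labels))
  dims <- dim(labels)
  out <- matrix(0L, dims[1], dims[2])
  k <- 0L; dropped <- 0L
  pad <- cfg$erosion_radius_separate
  for (lb in setdiff(sort(unique(as.vector(labels))), 0L)) {
    idx <- which(labels == lb)
    bb <- bounding_box(idx, dims, pad = pad)
    crop <- labels[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE] == lb
    er <- erode_diamond(crop, cfg$erosion_radius_separate)
    if (!any(er)) { dropped <- dropped + 1L; next }
    comp <- label_components(er)
    sizes <- tabulate(comp[comp > 0L])
    for (ci in seq_along(sizes)) {
      if (sizes[ci] >= cfg$min_component_px) {
        k <- k + 1L
        sub <- out[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
        sub[comp == ci] <- k
        out[bb[1]:bb[2], bb[3]:bb[4]] <- sub
      } else dropped <- dropped + 1L
    }
  }
  if (k == 0L) warning("clean_labels: no components survived the size filter")
  attr(out, "n_kept") <- k
  attr(out, "n_dropped") <- dropped
  out
}

#' Build peripheral ring masks
#'
#' For every cell in a cleaned label mask, the ring is the set difference
#' between the cell and its diamond erosion of radius
#' `cfg$erosion_radius_ring` -- the band of pixels within that L1 depth of
#' the cell edge. Cells that the ring erosion empties entirely are kept but
#' flagged `fully_peripheral` (their ring equals the whole cell); the
#' measurement pipeline drops flagged cells since they are smaller than the
#' cell size the method assumes.
#'
#' @param labels cleaned integer label matrix (see [clean_labels()])
#' @param cfg a [run_config()]
#' @return object of class `ring_set`: a list with one element per cell
#'   (`label`, `idx` linear pixel indices, `n_px`, `fully_peripheral`), with
#'   the mask dimensions in attribute `dim`
#' @export
make_rings <- function(labels, cfg = run_config()) {
  stopifnot(is.matrix(labels))
  dims <- dim(labels)
  rings <- list()
  for (lb in setdiff(sort(unique(as.vector(labels))), 0L)) {
    idx <- which(labels == lb)
    bb <- bounding_box(idx, dims, pad = 0L)
    crop <- labels[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE] == lb
    inner <- erode_diamond(crop, cfg$erosion_radius_ring)
    ring <- crop & !inner
    fully <- !any(inner)
    ridx <- which(ring)
    rc <- arrayInd(ridx, dim(ring))
    lin <- (bb[3] + rc[, 2] - 2L) * dims[1] + (bb[1] + rc[, 1] - 1L)
    rings[[length(rings) + 1L]] <- list(label = lb, idx = lin,
                                        n_px = length(lin),
                                        fully_peripheral = fully)
  }
  structure(rings, class = "ring_set", dim_image = dims)
}
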