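#' Measure mean intensity over peripheral rings
#'
#' One row per retained cell: the arithmetic mean of (signed) intensities
#' over that cell's ring pixels, the ring pixel count, and the cell's group.
#' Cells flagged `fully_peripheral` by [make_rings()] are excluded.
#'
#' @param img numeric matrix (typically the flat-field-subtracted image)
#' @param rings a `ring_set` from [make_rings()]
#' @param groups data frame with columns `cell_id` and `group` mapping each
#'   retained label to its experimental group; NULL assigns group NA
#' @return tibble with columns `cell_id`, `group`, `ring_px`,
#'   `mean_ring_intensity`
#' @export
measure_rings <- function(img, rings, groups = NULL) {
  stopifnot(inherits(rings, "ring_set"))
  if (!identical(dim(img), attr(rings, "dim_image")))
    stop("image dimensions do not match the mask that produced the rings")
  keep <- Filter(function(r) !r$fully_peripheral, rings)
  if (length(keep) < length(rings))
    warning(length(rings) - length(keep), " fully-peripheral cell(s) dropped")
  ids <- vapply(keep, `[[`, integer(1), "label")
  if (!is.null(groups)) {
    stopifnot(all(c("cell_id", "group") %in% names(groups)))
    miss <- setdiff(ids, groups$cell_id)
    if (length(miss) > 0)
      stop("cell ids missing from group map: ", paste(miss, collapse = ", "))
    grp <- groups$group[match(ids, groups$cell_id)]
  } else grp <- rep(NA_character_, length(ids))
  tibble::tibble(
    cell_id = ids,
    group = as.character(grp),
    ring_px = vapply(keep, `[[`, integer(1), "n_px"),
    mean_ring_intensity = vapply(keep, function(r) mean(img[r$idx]), numeric(1))
  )
}

#' Peripheral-membrane quantification pipeline
#'
#' Runs the full widefield quantification on one image/mask pair:
#' label separation erosion and size filtering ([clean_labels()]), ring
#' construction ([make_rings()]), pseudo-flat-field subtraction
#' ([flatfield_subtract()]), and ring measurement ([measure_rings()]).
#'
#' Cleaned labels are relabeled 1..K, so any `groups` mapping must refer to
#' cleaned ids; for the common case of one experimental group per image,
#' pass `group` as a single string instead.
#'
#' @param img raw intensity matrix
#' @param labels label mask matrix (same dimensions)
#' @param cfg a [run_config()]
#' @param group single group id applied to every cell in the image (or NULL)
#' @param flatfield logical; apply pseudo-flat-field subtraction (default TRUE)
#' @return tibble as in [measure_rings()]
#' @export
quantify_pm <- function(img, labels, cfg = run_config(), group = NULL,
                        flatfield = TRUE) {
  check_pair(img, labels)
  cleaned <- clean_labels(labels, cfg)
  rings <- make_rings(cleaned, cfg)
  meas_img <- if (flatfield) flatfield_subtract(img, cfg) else img
  groups <- NULL
  if (!is.null(group)) {
    ids <- vapply(rings, `[[`, integer(1), "label")
    groups <- data.frame(cell_id = ids, group = group)
  }
  measure_rings(meas_img, rings, groups)
}
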