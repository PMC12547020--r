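#' Vacuole line-scan phenotyping
#'
#' A line scan through the largest vacuolar body crosses the vacuole
#' membrane twice, so the vacuole-membrane marker channel (e.g.
#' Vph1-Tomato) shows two peaks. The marker peaks and their immediately
#' flanking positions define the vacuolar membrane; positions strictly
#' between the flanked peaks define the lumen. The receptor (cargo) channel
#' is averaged over both index sets and the lumen:membrane ratio assigns
#' the phenotype: > 1 means a cargo-full vacuole, < 1 a cargo-empty one
#' (ratio exactly 1 classifies as full, a deterministic tie rule).
#'
#' All indices here are 1-based R vector indices.
#'
#' @name vacuole
NULL

#' Sample an image along a line segment
#'
#' Bilinear interpolation at unit-pixel steps from `p0` to `p1`
#' (inclusive); the series has `ceiling(distance) + 1` samples.
#'
#' @param img numeric matrix
#' @param p0,p1 numeric length-2 vectors, (row, col), inside the image
#' @return numeric vector of interpolated intensities
#' @export
sample_line <- function(img, p0, p1) {
  stopifnot(is.matrix(img), length(p0) == 2, length(p1) == 2)
  nr <- nrow(img); nc <- ncol(img)
  if (any(c(p0, p1) < 1) || p0[1] > nr || p1[1] > nr || p0[2] > nc || p1[2] > nc)
    stop("line endpoints lie outside the image")
  len <- sqrt(sum((p1 - p0)^2))
  nstep <- ceiling(len)
  t <- if (nstep == 0) 0 else seq(0, 1, length.out = nstep + 1)
  r <- p0[1] + t * (p1[1] - p0[1])
  cc <- p0[2] + t * (p1[2] - p0[2])
  r0 <- pmin(floor(r), nr - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(cc), nc - 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- cc - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

peak_prominences <- function(x) {
  L <- length(x)
  peaks <- which(diff(sign(diff(x))) < 0) + 1L
  peaks <- peaks[x[peaks] > x[peaks - 1L] & x[peaks] > x[peaks + 1L]]
  prom <- vapply(peaks, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    hi <- which(left > h)
    lmin <- min(left[seq.int(if (length(hi)) max(hi) + 1L else 1L, i - 1L)])
    right <- x[seq.int(i + 1L, L)]
    hi <- which(right > h)
    rmin <- min(right[seq_len(if (length(hi)) min(hi) - 1L else length(right))])
    h - max(lmin, rmin)
  }, numeric(1))
  list(peaks = peaks, prominences = prom)
}

#' Locate the two vacuole-membrane peaks in a marker profile
#'
#' Finds strict local maxima, ranks them by topographic prominence, and
#' returns the admissible pair (index separation >= `min_sep`) with the
#' greatest prominences, ordered left < right. When fewer than two
#' qualifying maxima exist, returns `c(NA, NA)` with a `reason` attribute
#' so that callers can flag the cell unclassifiable.
#'
#' @param marker numeric vector (length >= 7) of marker intensities
#' @param min_sep minimum index separation between the two peaks (default 10)
#' @return integer vector `c(peak_left, peak_right)` (1-based), NA on failure
#' @export
find_vacuole_peaks <- function(marker, min_sep = 10) {
  stopifnot(length(marker) >= 7)
  no_peaks <- function(reason) structure(c(NA_integer_, NA_integer_), reason = reason)
  pp <- peak_prominences(marker)
  if (length(pp$peaks) < 2L)
    return(no_peaks("fewer than two local maxima"))
  best <- NULL; best_score <- c(-Inf, -Inf)
  n <- length(pp$peaks)
  for (a in seq_len(n - 1L)) for (b in seq.int(a + 1L, n)) {
    if (pp$peaks[b] - pp$peaks[a] < min_sep) next
    sc <- sort(c(pp$prominences[a], pp$prominences[b]), decreasing = TRUE)
    if (sc[1] > best_score[1] || (sc[1] == best_score[1] && sc[2] > best_score[2])) {
      best_score <- sc
      best <- c(pp$peaks[a], pp$peaks[b])
    }
  }
  if (is.null(best))
    return(no_peaks("no peak pair at the required separation"))
  best
}

#' Classify one vacuole line profile as cargo-full or cargo-empty
#'
#' @param marker numeric vector, vacuole-membrane marker intensities
#' @param cargo numeric vector (same length), receptor intensities
#' @param min_sep minimum peak separation passed to [find_vacuole_peaks()]
#' @return list with `peak_left`, `peak_right` (1-based indices),
#'   `mem_mean`, `lum_mean`, `ratio`, and `klass` in
#'   `{"full", "empty", "unclassifiable"}` (with a `reason` when
#'   unclassifiable)
#' @export
classify_vacuole <- function(marker, cargo, min_sep = 10) {
  stopifnot(length(marker) == length(cargo), length(marker) >= 7)
  unclass_result <- function(reason) {
    list(peak_left = NA_integer_, peak_right = NA_integer_,
         mem_mean = NA_real_, lum_mean = NA_real_, ratio = NA_real_,
         klass = "unclassifiable", reason = reason)
  }
  pk <- find_vacuole_peaks(marker, min_sep)
  if (anyNA(pk)) return(unclass_result(attr(pk, "reason")))
  pl <- pk[1]; pr <- pk[2]
  if (pl + 4L > pr) return(unclass_result("peaks too close for a lumen"))
  L <- length(cargo)
  mem_idx <- unique(pmax(1L, pmin(L, c(pl - 1L, pl, pl + 1L, pr - 1L, pr, pr + 1L))))
  lum_idx <- seq.int(pl + 2L, pr - 2L)
  mem_mean <- mean(cargo[mem_idx])
  lum_mean <- mean(cargo[lum_idx])
  if (mem_mean <= 0) return(unclass_result("non-positive membrane mean"))
  ratio <- lum_mean / mem_mean
  list(peak_left = pl, peak_right = pr, mem_mean = mem_mean,
       lum_mean = lum_mean, ratio = ratio,
       klass = if (ratio >= 1) "full" else "empty")
}

#' Classify a table of line profiles
#'
#' @param profiles long-format data frame with columns `cell_id`, `group`,
#'   `position`, `marker`, `cargo`; one block of rows per cell, ordered by
#'   position
#' @param min_sep minimum peak separation (px)
#' @return tibble with one row per cell: `cell_id`, `group`, `peak_left`,
#'   `peak_right`, `mem_mean`, `lum_mean`, `ratio`, `klass`
#' @export
classify_profiles <- function(profiles, min_sep = 10) {
  stopifnot(all(c("cell_id", "group", "position", "marker", "cargo") %in% names(profiles)))
  cells <- split(profiles, profiles$cell_id)
  rows <- lapply(cells, function(d) {
    d <- d[order(d$position), ]
    res <- classify_vacuole(d$marker, d$cargo, min_sep)
    tibble::tibble(cell_id = d$cell_id[1], group = d$group[1],
                   peak_left = res$peak_left, peak_right = res$peak_right,
                   mem_mean = res$mem_mean, lum_mean = res$lum_mean,
                   ratio = res$ratio, klass = res$klass)
  })
  out <- do.call(rbind, rows)
  n_un <- sum(out$klass == "unclassifiable")
  if (n_un > 0) message(n_un, " profile(s) unclassifiable and excluded from fractions")
  out
}

#' Per-group empty-vacuole fractions and fold change
#'
#' Fractions are computed over classified cells only (unclassifiable
#' profiles are excluded). The fold change is
#' `fraction(test) / fraction(reference)`; a reference fraction of zero
#' leaves the fold undefined (NA).
#'
#' @param phenotypes tibble from [classify_profiles()]
#' @param test,reference group names for the fold change (optional)
#' @return list with `fractions` (tibble: group, n_classified, n_empty,
#'   empty_fraction) and, when both group names are given, `fold_change`
#' @export
empty_fraction <- function(phenotypes, test = NULL, reference = NULL) {
  cl <- phenotypes[phenotypes$klass != "unclassifiable", ]
  if (nrow(cl) == 0) stop("no classified cells")
  sp <- split(cl, cl$group)
  fr <- tibble::tibble(
    group = names(sp),
    n_classified = vapply(sp, nrow, integer(1)),
    n_empty = vapply(sp, function(d) sum(d$klass == "empty"), integer(1))
  )
  fr$n_classified <- unname(fr$n_classified)
  fr$n_empty <- unname(fr$n_empty)
  fr$empty_fraction <- fr$n_empty / fr$n_classified
  out <- list(fractions = fr)
  if (!is.null(test) && !is.null(reference)) {
    if (!all(c(test, reference) %in% fr$group))
      stop("unknown group name(s): ",
           paste(setdiff(c(test, reference), fr$group), collapse = ", "))
    f_ref <- fr$empty_fraction[fr$group == reference]
    f_test <- fr$empty_fraction[fr$group == test]
    out$fold_change <- if (f_ref == 0) NA_real_ else f_test / f_ref
  }
  out
}
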