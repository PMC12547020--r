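#' Pipeline run configuration
#'
#' Collects the fixed numeric settings of the quantification pipeline in one
#' object: the morphological radii used to separate touching cells and to cut
#' the peripheral ring, the minimum component size retained after separation,
#' the Gaussian sigma of the pseudo-flat-field correction, the rolling-ball
#' radius used for confocal background subtraction, the Tukey alpha, the
#' bootstrap replicate count, and the master RNG seed from which all
#' stage-level seeds are derived.
#'
#' All radii and sigmas are in pixels; coordinates throughout the package are
#' 1-based (row, column) following R matrix convention.
#'
#' @param erosion_radius_separate Diamond erosion radius (px) applied per
#'   label so that adjacent cell masks no longer touch. Default 1.
#' @param erosion_radius_ring Diamond erosion radius (px) whose complement
#'   defines the peripheral ring. Default 7.
#' @param min_component_px Connected components smaller than this (after the
#'   separation erosion) are discarded. Default 5000.
#' @param flatfield_sigma Standard deviation (px) of the Gaussian blur
#'   subtracted as a pseudo-flat-field background estimate. Default 50.
#' @param rollingball_radius Radius (px) of the grayscale ball used for
#'   rolling-ball background subtraction. Default 50.
#' @param tukey_alpha Significance level for Tukey HSD comparisons. Default 0.05.
#' @param bootstrap_B Bootstrap replicate count for percentile intervals.
#'   Default 1000.
#' @param rng_seed Master seed (integer or NULL).
#' @return A list of class `run_config`.
#' @export
run_config <- function(erosion_radius_separate = 1L,
                       erosion_radius_ring = 7L,
                       min_component_px = 5000L,
                       flatfield_sigma = 50,
                       rollingball_radius = 50,
                       tukey_alpha = 0.05,
                       bootstrap_B = 1000L,
                       rng_seed = NULL) {
  stopifnot(erosion_radius_separate >= 1, erosion_radius_ring >= 1,
            min_component_px >= 0, flatfield_sigma > 0, rollingball_radius > 0,
            tukey_alpha > 0, tukey_alpha < 1, bootstrap_B >= 1)
  structure(list(
    erosion_radius_separate = as.integer(erosion_radius_separate),
    erosion_radius_ring = as.integer(erosion_radius_ring),
    min_component_px = as.integer(min_component_px),
    flatfield_sigma = flatfield_sigma,
    rollingball_radius = rollingball_radius,
    tukey_alpha = tukey_alpha,
    bootstrap_B = as.integer(bootstrap_B),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file may set any subset of the [run_config()] fields; unknown keys
#' are an error so that typos do not silently fall back to defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    stop("unsupported config format '", ext, "': ", path))
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Derive a stage-level seed from a master seed
#'
#' Deterministic linear-congruential mix kept below 2^31 so that every
#' pipeline stage gets an independent, reproducible stream.
#'
#' @param seed master seed (integer)
#' @param stage stage index (integer >= 0)
#' @return integer seed in [0, 2^31 - 2]
#' @export
derive_seed <- function(seed, stage = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((abs(seed) * 69069 + 12345 * (stage + 1)) %% 2147483647)
}
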