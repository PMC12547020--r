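#' Synthetic data with known ground truth
#'
#' Generators for every input the pipeline consumes: widefield-like fields
#' of non-overlapping yeast cells with bright peripheral membrane rings,
#' additive illumination gradients and counting noise; two-channel vacuole
#' line profiles with known full/empty phenotypes; Hill-shaped dose-response
#' plates; and binomially sampled mating colony counts. Effect presets carry
#' the relative changes under study (membrane abundance, Emax, EC50,
#' empty-vacuole probability, mating probability); absolute intensity scales
#' are arbitrary instrument units, so every recovery experiment is
#' ratio-based.
#'
#' @name synthetic-data
NULL

#' Built-in effect presets
#'
#' Each preset expresses one experimental condition as multipliers relative
#' to the control arm: `membrane_scale` scales peripheral membrane
#' intensity, `emax_scale`/`ec50_scale` scale the Hill parameters of the
#' transcriptional dose response, `empty_vacuole_prob` is the probability
#' that a cell's vacuole is cargo-empty, and `mating_prob` the per-cell
#' mating probability. Values encode the relative changes between arms
#' (e.g. a 60% membrane reduction is `membrane_scale = 0.40`); the
#' wild-type empty-vacuole fraction is fixed at 0.15 with the mutant at
#' 0.60, a 4-fold change.
#'
#' @return tibble with columns `name`, `membrane_scale`, `emax_scale`,
#'   `ec50_scale`, `empty_vacuole_prob`, `mating_prob`
#' @export
builtin_presets <- function() {
  tibble::tribble(
    ~name,                      ~membrane_scale, ~emax_scale, ~ec50_scale, ~empty_vacuole_prob, ~mating_prob,
    "control",                  1.00,            1.00,        1.00,        NA,                  NA,
    "stationary",               0.38,            1.00,        1.00,        NA,                  NA,
    "low_nitrogen",             0.34,            1.00,        1.00,        NA,                  NA,
    "rapamycin_ste2",           0.40,            1.00,        1.00,        NA,                  NA,
    "rapamycin_ste3",           0.78,            1.00,        1.00,        NA,                  NA,
    "rapamycin_pma1",           1.16,            1.00,        1.00,        NA,                  NA,
    "rapamycin_transcription",  1.00,            0.74,        1.00,        NA,                  NA,
    "ypk1_delta",               1.00,            5.33,        0.61,        NA,                  NA,
    "atg8_delta_transcription", 1.00,            1.30,        1.00,        NA,                  NA,
    "wt_vacuole",               1.00,            1.00,        1.00,        0.15,                NA,
    "atg8_vacuole",             1.00,            1.00,        1.00,        0.60,                NA,
    "mating_control",           1.00,            1.00,        1.00,        NA,                  0.78,
    "mating_rapamycin",         1.00,            1.00,        1.00,        NA,                  0.53
  )
}

get_preset <- function(preset) {
  if (is.character(preset)) {
    tab <- builtin_presets()
    if (!preset %in% tab$name) stop("unknown preset: ", preset)
    preset <- tab[tab$name == preset, ]
  }
  stopifnot(is.data.frame(preset), nrow(preset) == 1)
  preset
}

# Fixed rendering constants (arbitrary instrument units / px). Only ratios
# between arms are meaningful; these anchor the control arm.
.render_const <- list(
  membrane_intensity = 8000, cytoplasm_intensity = 1000,
  vacuole_intensity = 400, membrane_band_px = 4,
  axis_min = 45, axis_max = 60, clearance_px = 3,
  gradient_lo = 500, gradient_hi = 1500, read_noise_sd = 20
)

render_cell_crop <- function(a, b, vac_dr, vac_dc, vac_r, membrane_intensity) {
  k <- .render_const
  R <- ceiling(max(a, b))
  d <- -R:R
  dr <- matrix(d, 2 * R + 1, 2 * R + 1)
  dc <- t(dr)
  rho <- sqrt((dr / a)^2 + (dc / b)^2)
  cell <- rho <= 1
  dist <- sqrt(dr^2 + dc^2)
  depth <- ifelse(rho > 0, dist * (1 / rho - 1), Inf)
  membrane <- cell & depth <= k$membrane_band_px
  vac <- cell & ((dr - vac_dr)^2 + (dc - vac_dc)^2 <= vac_r^2)
  val <- matrix(0, 2 * R + 1, 2 * R + 1)
  val[cell] <- k$cytoplasm_intensity
  val[vac] <- k$vacuole_intensity
  val[membrane] <- membrane_intensity
  list(R = R, cell = cell, val = val)
}

place_cells <- function(n_cells, dim) {
  k <- .render_const
  rows <- numeric(0); cols <- numeric(0); ra <- numeric(0); rb <- numeric(0)
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (attempt in seq_len(5000)) {
      a <- stats::runif(1, k$axis_min, k$axis_max)
      b <- stats::runif(1, k$axis_min, k$axis_max)
      rmax <- max(a, b)
      r <- stats::runif(1, rmax + 2, dim - rmax - 1)
      cc <- stats::runif(1, rmax + 2, dim - rmax - 1)
      if (length(rows) == 0 ||
          all(sqrt((rows - r)^2 + (cols - cc)^2) >=
              pmax(ra, rb) + rmax + k$clearance_px)) {
        rows <- c(rows, r); cols <- c(cols, cc); ra <- c(ra, a); rb <- c(rb, b)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place ", n_cells, " non-overlapping cells in a ",
                      dim, "x", dim, " field (placed ", length(rows), ")")
  }
  data.frame(row = rows, col = cols, a = ra, b = rb)
}

#' Render one synthetic field of cells
#'
#' A `dim` x `dim` 16-bit field of axis-aligned elliptical cells (semi-axes
#' uniform on 45-60 px) with a 4-px peripheral membrane band at
#' `8000 * membrane_scale` AU, cytoplasm at 1000 AU, and one interior
#' vacuole disc at 400 AU. With `gradient = TRUE` an additive planar
#' illumination ramp (500 to 1500 AU across the field) is applied; with
#' `noise = TRUE`, Poisson counting noise plus Gaussian read noise
#' (sd 20 AU). Cells never overlap (>= 3 px clearance) and their
#' post-separation-erosion areas always exceed the pipeline's 5000-px size
#' filter by construction of the radii.
#'
#' @param preset preset name or one-row preset table (see
#'   [builtin_presets()])
#' @param n_cells number of cells to place (error if placement fails)
#' @param seed RNG seed for this field
#' @param noise,gradient logical switches
#' @param dim field edge length in px (default 1200)
#' @return list with `image` (numeric matrix, integer counts in
#'   \[0, 65535\]), `mask` (integer label matrix), and `truth` (tibble:
#'   cell_id, row, col, a, b, vac_dr, vac_dc, vac_r, membrane_intensity,
#'   cytoplasm_intensity, vacuole_intensity, group)
#' @export
render_field <- function(preset, n_cells, seed = NULL, noise = TRUE,
                         gradient = TRUE, dim = 1200) {
  preset <- get_preset(preset)
  k <- .render_const
  run <- function() {
    geom <- place_cells(n_cells, dim)
    geom$vac_r <- 0.4 * pmin(geom$a, geom$b)
    geom$vac_dr <- stats::runif(n_cells, -0.15, 0.15) * pmin(geom$a, geom$b)
    geom$vac_dc <- stats::runif(n_cells, -0.15, 0.15) * pmin(geom$a, geom$b)
    img <- matrix(0, dim, dim)
    mask <- matrix(0L, dim, dim)
    mem_int <- k$membrane_intensity * preset$membrane_scale
    for (i in seq_len(n_cells)) {
      cr <- render_cell_crop(geom$a[i], geom$b[i], geom$vac_dr[i],
                             geom$vac_dc[i], geom$vac_r[i], mem_int)
      r0 <- round(geom$row[i]) - cr$R; c0 <- round(geom$col[i]) - cr$R
      rr <- r0:(r0 + 2 * cr$R); cc <- c0:(c0 + 2 * cr$R)
      sub_i <- img[rr, cc]; sub_m <- mask[rr, cc]
      sub_i[cr$cell] <- cr$val[cr$cell]
      sub_m[cr$cell] <- i
      img[rr, cc] <- sub_i; mask[rr, cc] <- sub_m
    }
    if (gradient) {
      ramp <- k$gradient_lo + (k$gradient_hi - k$gradient_lo) *
        (seq_len(dim) - 1) / (dim - 1)
      img <- img + matrix(ramp, dim, dim, byrow = TRUE)
    }
    if (noise) {
      img <- matrix(stats::rpois(dim * dim, lambda = as.vector(img)), dim, dim) +
        matrix(stats::rnorm(dim * dim, 0, k$read_noise_sd), dim, dim)
    }
    img <- round(img)
    if (any(img > 65535)) {
      warning("intensity overflow clipped at 65535")
      img[img > 65535] <- 65535
    }
    img[img < 0] <- 0
    truth <- tibble::tibble(
      cell_id = seq_len(n_cells),
      row = round(geom$row), col = round(geom$col),
      a = geom$a, b = geom$b,
      vac_dr = geom$vac_dr, vac_dc = geom$vac_dc, vac_r = geom$vac_r,
      membrane_intensity = mem_int,
      cytoplasm_intensity = k$cytoplasm_intensity,
      vacuole_intensity = k$vacuole_intensity,
      group = preset$name
    )
    list(image = img, mask = mask, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Re-render the noiseless, gradient-free image implied by a field truth
#'
#' The deterministic expectation of the rendered signal, used as the
#' analytic oracle for ring-mean measurements.
#'
#' @param truth truth tibble from [render_field()]
#' @param dim field edge length in px
#' @return numeric matrix
#' @export
render_from_truth <- function(truth, dim = 1200) {
  img <- matrix(0, dim, dim)
  for (i in seq_len(nrow(truth))) {
    cr <- render_cell_crop(truth$a[i], truth$b[i], truth$vac_dr[i],
                           truth$vac_dc[i], truth$vac_r[i],
                           truth$membrane_intensity[i])
    rr <- (truth$row[i] - cr$R):(truth$row[i] + cr$R)
    cc <- (truth$col[i] - cr$R):(truth$col[i] + cr$R)
    sub <- img[rr, cc]
    sub[cr$cell] <- cr$val[cr$cell]
    img[rr, cc] <- sub
  }
  img
}

#' Render a multi-field cohort for one preset
#'
#' Fields are rendered with per-field seeds derived from `seed`, each with
#' at most `n_per_field` cells, until `n_cells` cells exist in total.
#'
#' @inheritParams render_field
#' @param n_per_field cells per field (default 30)
#' @return list of [render_field()] results
#' @export
render_cohort <- function(preset, n_cells, seed, n_per_field = 30,
                          noise = TRUE, gradient = TRUE, dim = 1200) {
  fields <- list()
  left <- n_cells
  i <- 0L
  while (left > 0) {
    i <- i + 1L
    n <- min(n_per_field, left)
    fields[[i]] <- render_field(preset, n, seed = derive_seed(seed, i),
                                noise = noise, gradient = gradient, dim = dim)
    left <- left - n
  }
  fields
}

#' Quantify a rendered cohort with the peripheral-membrane pipeline
#'
#' @param fields list from [render_cohort()]
#' @param cfg a [run_config()]
#' @param flatfield apply pseudo-flat-field subtraction (default TRUE)
#' @return tibble as in [measure_rings()], plus a `field` column; `cell_id`
#'   is made unique across fields
#' @export
quantify_cohort <- function(fields, cfg = run_config(), flatfield = TRUE) {
  out <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    m <- quantify_pm(f$image, f$mask, cfg, group = f$truth$group[1],
                     flatfield = flatfield)
    m$field <- i
    m$cell_id <- m$cell_id + 10000L * i
    m
  })
  do.call(rbind, out)
}

#' Generate two-channel vacuole line profiles with known phenotypes
#'
#' The marker channel is a 50-AU baseline with two Gaussian membrane peaks
#' (sd 2 px, amplitude 500 AU) near positions 25 and 75 (0-based, uniform
#' jitter of up to 5 px). The cargo channel sits at a shoulder level of
#' 300 AU over the membrane positions; the lumen plateau between them is 3x
#' the shoulder for a full vacuole and 0.3x for an empty one, drawn per cell
#' as Bernoulli(`empty_vacuole_prob`). Multiplicative Gaussian noise with sd
#' 5% of signal is applied to both channels when `noise = TRUE`.
#'
#' @param preset preset name or one-row preset table (must carry
#'   `empty_vacuole_prob`)
#' @param n_cells number of profiles
#' @param length profile length in samples (>= 31, default 101)
#' @param seed RNG seed
#' @param noise logical
#' @return list with `profiles` (long tibble: cell_id, group, position
#'   (0-based), marker, cargo) and `truth` (tibble: cell_id, phenotype,
#'   peak_left, peak_right as 0-based positions)
#' @export
gen_profiles <- function(preset, n_cells, length = 101, seed = NULL,
                         noise = TRUE) {
  preset <- get_preset(preset)
  stopifnot(length >= 31)
  p_empty <- preset$empty_vacuole_prob
  if (is.na(p_empty)) stop("preset '", preset$name, "' has no empty_vacuole_prob")
  shoulder <- 300; base <- 0.1 * shoulder
  run <- function() {
    rows <- vector("list", n_cells)
    truth <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      p1 <- round(0.25 * (length - 1)) + sample(-5:5, 1) + 1L  # 1-based
      p2 <- round(0.75 * (length - 1)) + sample(-5:5, 1) + 1L
      x <- seq_len(length)
      marker <- 50 + 500 * exp(-(x - p1)^2 / 8) + 500 * exp(-(x - p2)^2 / 8)
      empty <- stats::runif(1) < p_empty
      lumen_level <- if (empty) 0.3 * shoulder else 3 * shoulder
      cargo <- rep(base, length)
      cargo[c(p1 - 1L, p1, p1 + 1L, p2 - 1L, p2, p2 + 1L)] <- shoulder
      cargo[(p1 + 2L):(p2 - 2L)] <- lumen_level
      if (noise) {
        marker <- marker * (1 + stats::rnorm(length, 0, 0.05))
        cargo <- cargo * (1 + stats::rnorm(length, 0, 0.05))
      }
      rows[[i]] <- tibble::tibble(cell_id = i, group = preset$name,
                                  position = x - 1L, marker = marker,
                                  cargo = cargo)
      truth[[i]] <- tibble::tibble(cell_id = i,
                                   phenotype = if (empty) "empty" else "full",
                                   peak_left = p1 - 1L, peak_right = p2 - 1L)
    }
    list(profiles = do.call(rbind, rows), truth = do.call(rbind, truth))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a synthetic dose-response plate for one preset
#'
#' The true curve is the Hill model with control parameters b = 50 AU,
#' Emax = 1000 AU, EC50 = 1.0 uM, slope 1.2 (arbitrary control anchors;
#' only relative changes are meaningful), scaled by the preset's
#' `emax_scale` and `ec50_scale`, evaluated on the half-log dose ladder
#' 0, 0.003, 0.01, 0.03, ... 300 uM. Each well's response gets
#' multiplicative Gaussian noise of coefficient of variation `cv`; culture
#' densities are drawn uniform on (0.6, 0.8) and multiplied into the raw
#' fluorescence so that density normalization must undo them.
#'
#' @param preset preset name or one-row preset table
#' @param replicates biological replicates per dose (default 9)
#' @param cv coefficient of variation of well noise (default 0.10)
#' @param seed RNG seed
#' @return tibble with columns `group`, `replicate`, `dose_uM`,
#'   `fluorescence`, `a600`
#' @export
gen_dose_response <- function(preset, replicates = 9, cv = 0.10, seed = NULL) {
  preset <- get_preset(preset)
  stopifnot(cv >= 0, replicates >= 1)
  doses <- c(0, 0.003, 0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 100, 300)
  truth <- hill_model(doses, b = 50, emax = 1000 * preset$emax_scale,
                      ec50 = 1 * preset$ec50_scale, hill_n = 1.2)
  run <- function() {
    grid <- expand.grid(replicate = seq_len(replicates),
                        dose_i = seq_along(doses))
    n <- nrow(grid)
    value <- truth[grid$dose_i] * (1 + stats::rnorm(n, 0, cv))
    a600 <- stats::runif(n, 0.6, 0.8)
    tibble::tibble(group = preset$name,
                   replicate = paste0("rep", grid$replicate),
                   dose_uM = doses[grid$dose_i],
                   fluorescence = value * a600,
                   a600 = a600)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate synthetic quantitative-mating colony counts
#'
#' Per assay, the mating-competent colony count is Poisson with mean
#' `n_competent` and the diploid count is Binomial(competent,
#' `mating_prob`); dilution factors are equal, so the per-assay efficiency
#' estimates the preset's mating probability.
#'
#' @param preset preset name or one-row preset table (must carry
#'   `mating_prob`)
#' @param n_assays number of independent assays (default 5)
#' @param n_competent expected competent colony count per assay (default 500)
#' @param seed RNG seed
#' @return tibble with the [mating_efficiency()] input columns
#' @export
gen_mating_counts <- function(preset, n_assays = 5, n_competent = 500,
                              seed = NULL) {
  preset <- get_preset(preset)
  stopifnot(n_assays >= 1)
  p <- preset$mating_prob
  if (is.na(p)) stop("preset '", preset$name, "' has no mating_prob")
  run <- function() {
    competent <- pmax(stats::rpois(n_assays, n_competent), 1L)
    diploid <- stats::rbinom(n_assays, competent, p)
    tibble::tibble(assay_id = paste0("assay", seq_len(n_assays)),
                   treatment = preset$name,
                   competent_colonies = competent,
                   diploid_colonies = diploid,
                   dilution_competent = 1, dilution_diploid = 1)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
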