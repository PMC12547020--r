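#' Hill dose-response analysis
#'
#' Reporter fluorescence from pheromone-stimulated cultures is normalized to
#' culture density (A600), per-dose replicate means are fit to a
#' four-parameter Hill equation
#' \deqn{y(d) = b + E_{max} \frac{d^{n}}{EC_{50}^{n} + d^{n}}}
#' by bounded least squares (lower bounds at zero, no upper bounds), and
#' parameter differences between genotypes/treatments are called significant
#' when the 95% confidence intervals do not overlap.
#'
#' @name dose-response
NULL

#' Normalize reporter fluorescence to culture density
#'
#' Adds a `normalized` column (`fluorescence / density`) and computes the
#' per-dose replicate means used for fitting.
#'
#' @param table data frame with columns `group`, `replicate`, `dose_uM`,
#'   `fluorescence`, `a600`
#' @return list with `table` (input plus `normalized`) and `means`
#'   (tibble: group, dose_uM, mean_response, n_replicates)
#' @export
normalize_density <- function(table) {
  req <- c("group", "replicate", "dose_uM", "fluorescence", "a600")
  stopifnot(all(req %in% names(table)))
  bad <- which(table$a600 <= 0)
  if (length(bad) > 0)
    stop("non-positive culture density in rows: ", paste(bad, collapse = ", "))
  table$normalized <- table$fluorescence / table$a600
  agg <- stats::aggregate(normalized ~ group + dose_uM, data = table,
                          FUN = function(v) c(m = mean(v), n = length(v)))
  means <- tibble::tibble(group = agg$group, dose_uM = agg$dose_uM,
                          mean_response = unname(agg$normalized[, "m"]),
                          n_replicates = as.integer(agg$normalized[, "n"]))
  means <- means[order(means$group, means$dose_uM), ]
  list(table = table, means = means)
}

#' Hill equation
#'
#' `b + Emax * dose^n / (EC50^n + dose^n)`; returns `b` at dose 0. Monotone
#' nondecreasing in dose for all admissible (nonnegative) parameters.
#'
#' @param dose dose vector (uM, >= 0)
#' @param b baseline response (AU)
#' @param emax maximal response above baseline (AU)
#' @param ec50 half-maximal dose (uM)
#' @param hill_n Hill slope (dimensionless)
#' @return response vector (AU)
#' @export
hill_model <- function(dose, b, emax, ec50, hill_n) {
  stopifnot(all(dose >= 0))
  ifelse(dose == 0, b, b + emax * dose^hill_n / (ec50^hill_n + dose^hill_n))
}

#' Fit the Hill equation to one group's dose-response means
#'
#' Bounded Levenberg-Marquardt least squares over (b, Emax, EC50, n) with
#' lower bounds fixed at zero and no upper bounds. Start values: b = min
#' response, Emax = max - min, EC50 = dose nearest half-max, n = 1 (robust
#' for sigmoid data on a log dose ladder). 95% confidence intervals come
#' from the asymptotic (Jacobian-based) covariance with a t quantile at
#' `n_points - 4` degrees of freedom.
#'
#' The fit is flagged (`flag` field) when the optimizer fails to converge,
#' when the fitted EC50 lies more than 10x outside the tested dose range,
#' or when the Emax interval includes zero ("no response").
#'
#' @param means tibble for a single group with columns `dose_uM` and
#'   `mean_response` (see [normalize_density()])
#' @return object of class `hill_fit`: list with `estimate` (named vector),
#'   `ci95` (2x4 matrix lo/hi), `residual_sd`, `n_points`, `converged`,
#'   `flag`
#' @export
fit_hill <- function(means) {
  stopifnot(all(c("dose_uM", "mean_response") %in% names(means)))
  if (nrow(means) == 0) stop("empty dose-response table")
  d <- means$dose_uM; y <- means$mean_response
  if (length(unique(d)) < 4) stop("need at least 4 distinct doses to fit")
  if (diff(range(y)) == 0) {
    # perfectly flat response: baseline only, Emax pinned at zero
    ci <- rbind(lo = c(b = y[1], emax = 0, ec50 = NA, hill_n = NA),
                hi = c(b = y[1], emax = 0, ec50 = NA, hill_n = NA))
    return(structure(list(estimate = c(b = y[1], emax = 0, ec50 = NA_real_,
                                       hill_n = NA_real_),
                          ci95 = ci, residual_sd = 0, n_points = length(y),
                          converged = TRUE, flag = "no response"),
                     class = "hill_fit"))
  }
  b0 <- max(min(y), 0)
  e0 <- max(max(y) - min(y), 1e-6)
  half <- b0 + e0 / 2
  pos <- d > 0
  ec0 <- d[pos][which.min(abs(y[pos] - half))]
  fit <- try(minpack.lm::nlsLM(
    y ~ hill_model(d, b, emax, ec50, hill_n),
    start = list(b = b0, emax = e0, ec50 = ec0, hill_n = 1),
    lower = c(0, 0, 0, 0),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(estimate = c(b = NA, emax = NA, ec50 = NA, hill_n = NA),
                          ci95 = matrix(NA_real_, 2, 4,
                                        dimnames = list(c("lo", "hi"),
                                                        c("b", "emax", "ec50", "hill_n"))),
                          residual_sd = NA_real_, n_points = length(y),
                          converged = FALSE, flag = "no convergence"),
                     class = "hill_fit"))
  }
  est <- stats::coef(fit)
  names(est) <- c("b", "emax", "ec50", "hill_n")
  n_points <- length(y)
  df <- n_points - 4L
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NaN, 4))
  se[!is.finite(se)] <- Inf  # unidentifiable directions (e.g. flat response)
  tq <- stats::qt(0.975, df)
  ci <- rbind(lo = est - tq * se, hi = est + tq * se)
  colnames(ci) <- names(est)
  flag <- NA_character_
  dr <- range(d[pos])
  if (est["ec50"] > 10 * dr[2] || (est["ec50"] > 0 && est["ec50"] < dr[1] / 10))
    flag <- "EC50 outside tested dose range"
  if (ci["lo", "emax"] <= 0) flag <- "no response"
  structure(list(estimate = est, ci95 = ci,
                 residual_sd = sqrt(sum(stats::resid(fit)^2) / max(df, 1)),
                 n_points = n_points, converged = TRUE, flag = flag),
            class = "hill_fit")
}

#' Fit Hill curves for every group in a dose-response table
#'
#' @param table raw dose-response data frame (see [normalize_density()])
#' @return named list of `hill_fit` objects, one per group
#' @export
fit_hill_groups <- function(table) {
  means <- normalize_density(table)$means
  sp <- split(means, means$group)
  lapply(sp, fit_hill)
}

#' Compare a Hill parameter between two fits by CI overlap
#'
#' Two estimates are called significantly different iff their 95% confidence
#' intervals are disjoint. Flagged or unconverged fits give "indeterminate".
#'
#' @param fit_a,fit_b `hill_fit` objects
#' @param param one of "b", "emax", "ec50", "hill_n"
#' @return "significant", "not_significant", or "indeterminate"
#' @export
ci_overlap_significant <- function(fit_a, fit_b, param = c("emax", "ec50", "b", "hill_n")) {
  param <- match.arg(param)
  stopifnot(inherits(fit_a, "hill_fit"), inherits(fit_b, "hill_fit"))
  bad <- function(f) !isTRUE(f$converged) || !is.na(f$flag)
  if (bad(fit_a) || bad(fit_b)) return("indeterminate")
  a <- fit_a$ci95[, param]; b <- fit_b$ci95[, param]
  if (a["hi"] < b["lo"] || b["hi"] < a["lo"]) "significant" else "not_significant"
}
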