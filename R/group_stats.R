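#' Group-level statistics for per-cell measurements
#'
#' Per-cell intensities are expressed as percentages of the control-group
#' mean (optionally within strata such as time points), compared by Welch
#' t tests or one-way ANOVA with Tukey HSD, summarized with SEM and
#' percentile-bootstrap confidence intervals, and -- for the four-group
#' mutant/treatment design -- classified into rescue categories from the
#' mutant-treated group's two Tukey comparisons against the wild-type
#' groups.
#'
#' @name group-stats
NULL

#' Normalize measurements to the control-group mean
#'
#' `percent = 100 * value / mean(control values in the same stratum)`.
#' When `stratum` is given (e.g. a time point), each stratum is normalized
#' to its own control mean.
#'
#' @param measurements data frame with columns `group`,
#'   `mean_ring_intensity` (or any `value` column named by `value_col`),
#'   and optionally the stratum column
#' @param control_group id of the control (reference) group
#' @param stratum optional name of a stratum column
#' @param value_col measurement column name (default "mean_ring_intensity")
#' @param cfg a [run_config()]; supplies `bootstrap_B` and the seed for the
#'   bootstrap intervals
#' @return list with `cells` (input plus `percent`) and `summary` (tibble:
#'   group, n_cells, mean_percent, sem_percent, boot_lo, boot_hi)
#' @export
normalize_percent <- function(measurements, control_group, stratum = NULL,
                              value_col = "mean_ring_intensity",
                              cfg = run_config()) {
  stopifnot(value_col %in% names(measurements), "group" %in% names(measurements))
  if (!control_group %in% measurements$group)
    stop("control group '", control_group, "' not present")
  strat <- if (is.null(stratum)) rep("all", nrow(measurements))
           else as.character(measurements[[stratum]])
  vals <- measurements[[value_col]]
  percent <- rep(NA_real_, nrow(measurements))
  for (s in unique(strat)) {
    in_s <- strat == s
    ctrl <- vals[in_s & measurements$group == control_group]
    if (length(ctrl) == 0) stop("control group empty in stratum '", s, "'")
    m <- mean(ctrl)
    if (m <= 0) stop("control mean is not positive in stratum '", s, "'")
    percent[in_s] <- 100 * vals[in_s] / m
  }
  measurements$percent <- percent
  sp <- split(percent, measurements$group)
  seed <- if (is.null(cfg$rng_seed)) 1L else cfg$rng_seed
  summ <- tibble::tibble(
    group = names(sp),
    n_cells = unname(vapply(sp, length, integer(1))),
    mean_percent = unname(vapply(sp, mean, numeric(1))),
    sem_percent = unname(vapply(sp, function(v) stats::sd(v) / sqrt(length(v)),
                                numeric(1)))
  )
  cis <- mapply(function(v, i) {
    if (length(v) < 2) c(v, v)
    else bootstrap_ci(v, B = cfg$bootstrap_B, seed = derive_seed(seed, i))
  }, sp, seq_along(sp))
  summ$boot_lo <- unname(cis[1, ])
  summ$boot_hi <- unname(cis[2, ])
  list(cells = measurements, summary = summ)
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom.
#' For `tails = 1`, `direction` states the alternative for the first
#' sample's mean relative to the second ("less" or "greater").
#'
#' @param a,b numeric samples (n >= 2 each)
#' @param tails 1 or 2
#' @param direction alternative for one-tailed tests
#' @return list with `t`, `df`, `p`
#' @export
welch_t <- function(a, b, tails = 2, direction = c("less", "greater")) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  alternative <- if (tails == 2) "two.sided" else match.arg(direction)
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' The (2.5, 97.5) percentiles of `B` resampled means; deterministic for a
#' given seed.
#'
#' @param values numeric sample (n >= 2)
#' @param B bootstrap replicates (>= 1)
#' @param seed RNG seed (NULL leaves the RNG state alone)
#' @return numeric c(lo, hi)
#' @export
bootstrap_ci <- function(values, B = 1000, seed = NULL) {
  stopifnot(length(values) >= 2, B >= 1)
  draw <- function() {
    n <- length(values)
    res <- matrix(sample(values, n * B, replace = TRUE), nrow = n)
    unname(stats::quantile(colMeans(res), c(0.025, 0.975)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Classic Tukey honestly-significant-difference adjustment: studentized
#' range on the pooled within-group variance across all groups.
#'
#' @param values numeric response vector
#' @param group group factor/vector (each group n >= 2)
#' @param alpha significance level recorded in the result
#' @return list with `F`, `p_overall`, `pairwise` (tibble: group1, group2,
#'   diff, p_adj), and `alpha`
#' @export
anova_tukey <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (any(table(group) < 2)) stop("every group needs n >= 2")
  fit <- stats::aov(values ~ group)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  list(
    F = an[["F value"]][1],
    p_overall = an[["Pr(>F)"]][1],
    pairwise = tibble::tibble(
      group1 = vapply(nm, `[`, character(1), 1),
      group2 = vapply(nm, `[`, character(1), 2),
      diff = tk[, "diff"],
      p_adj = tk[, "p adj"]
    ),
    alpha = alpha
  )
}

tukey_p_between <- function(pairwise, g1, g2) {
  hit <- (pairwise$group1 == g1 & pairwise$group2 == g2) |
         (pairwise$group1 == g2 & pairwise$group2 == g1)
  if (!any(hit)) stop("no Tukey comparison between '", g1, "' and '", g2, "'")
  pairwise$p_adj[which(hit)[1]]
}

#' Assign a rescue category from Tukey comparisons
#'
#' In the four-group design (WT untreated, WT treated, mutant untreated,
#' mutant treated), the mutant-treated group's two Tukey p values against
#' the WT groups determine the category: different only from untreated WT
#' means the drug still acts (no rescue); different from both means an
#' intermediate phenotype (partial rescue); different only from treated WT
#' means the drug no longer acts (complete rescue); different from neither
#' is indeterminate.
#'
#' @param p_vs_wt_untreated,p_vs_wt_treated Tukey-adjusted p values for the
#'   mutant-treated group against the two WT reference groups
#' @param alpha significance level (default 0.05)
#' @return list with the two p values and `category`
#' @export
classify_rescue <- function(p_vs_wt_untreated, p_vs_wt_treated, alpha = 0.05) {
  sig_u <- p_vs_wt_untreated < alpha
  sig_t <- p_vs_wt_treated < alpha
  category <- if (sig_u && !sig_t) "no_rescue"
    else if (sig_u && sig_t) "partial_rescue"
    else if (!sig_u && sig_t) "complete_rescue"
    else "indeterminate"
  list(p_vs_wt_untreated = p_vs_wt_untreated,
       p_vs_wt_treated = p_vs_wt_treated,
       category = category)
}

#' Rescue classification for a four-group measurement table
#'
#' Normalizes per-cell values to the WT-untreated mean, runs the one-way
#' ANOVA + Tukey HSD over the four groups, and classifies the mutant from
#' its treated group's comparisons against the two WT groups.
#'
#' @param measurements per-cell table with `group` and the value column
#' @param wt_untreated,wt_treated,mut_untreated,mut_treated group ids
#' @param alpha significance level
#' @param normalized normalize to the WT-untreated mean first (default TRUE,
#'   matching percentage-scale reporting; set FALSE to test raw intensities)
#' @param value_col measurement column name
#' @param cfg a [run_config()]
#' @return list: `anova` (from [anova_tukey()]) plus the [classify_rescue()]
#'   fields
#' @export
rescue_classify <- function(measurements, wt_untreated, wt_treated,
                            mut_untreated, mut_treated, alpha = 0.05,
                            normalized = TRUE,
                            value_col = "mean_ring_intensity",
                            cfg = run_config()) {
  need <- c(wt_untreated, wt_treated, mut_untreated, mut_treated)
  miss <- setdiff(need, unique(measurements$group))
  if (length(miss) > 0) stop("missing group(s): ", paste(miss, collapse = ", "))
  measurements <- measurements[measurements$group %in% need, ]
  vals <- if (normalized)
    normalize_percent(measurements, wt_untreated, value_col = value_col,
                      cfg = cfg)$cells$percent
  else measurements[[value_col]]
  at <- anova_tukey(vals, measurements$group, alpha)
  p_u <- tukey_p_between(at$pairwise, mut_treated, wt_untreated)
  p_t <- tukey_p_between(at$pairwise, mut_treated, wt_treated)
  c(list(anova = at), classify_rescue(p_u, p_t, alpha))
}

#' Mating efficiency from colony counts
#'
#' `efficiency = 100 * (diploid_colonies * dilution_diploid) /
#' (competent_colonies * dilution_competent)`: the percentage of
#' mating-competent cells (lys- selection) that formed diploids
#' (lys- met- cys- selection), after correcting each count for its plating
#' dilution.
#'
#' @param counts data frame with columns `assay_id`, `treatment`,
#'   `competent_colonies`, `diploid_colonies`, `dilution_competent`,
#'   `dilution_diploid`
#' @return input tibble plus `efficiency_percent`
#' @export
mating_efficiency <- function(counts) {
  req <- c("assay_id", "treatment", "competent_colonies", "diploid_colonies",
           "dilution_competent", "dilution_diploid")
  stopifnot(all(req %in% names(counts)))
  comp <- counts$competent_colonies * counts$dilution_competent
  dip <- counts$diploid_colonies * counts$dilution_diploid
  if (any(comp <= 0)) stop("zero mating-competent colony estimate")
  if (any(dip > comp))
    stop("diploid estimate exceeds competent estimate in assay(s): ",
         paste(counts$assay_id[dip > comp], collapse = ", "))
  counts$efficiency_percent <- 100 * dip / comp
  tibble::as_tibble(counts)
}

#' Compare mating efficiency between treated and control arms
#'
#' One-tailed Welch t test of the alternative that the treated arm mates
#' less efficiently than the control arm.
#'
#' @param efficiencies tibble from [mating_efficiency()]
#' @param treated,control values of the `treatment` column
#' @return list with per-arm means and the [welch_t()] result
#' @export
compare_mating <- function(efficiencies, treated, control) {
  a <- efficiencies$efficiency_percent[efficiencies$treatment == treated]
  b <- efficiencies$efficiency_percent[efficiencies$treatment == control]
  if (length(a) == 0 || length(b) == 0) stop("unknown treatment group")
  list(mean_treated = mean(a), mean_control = mean(b),
       test = welch_t(a, b, tails = 1, direction = "less"))
}
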