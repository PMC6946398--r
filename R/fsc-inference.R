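#' Estimate the number of active FSCs from clone-size fractions
#'
#' If an ovariole is maintained by `l` equipotent stem cells and exactly
#' one is labelled, the labelled lineage is expected to cover `1/l` of the
#' follicle epithelium; the reciprocal of the mean labelled fraction across
#' mosaic ovarioles therefore estimates `l` (an average of ~50\% labelling
#' implies two active FSCs). Uncertainty is quantified by a percentile
#' bootstrap over ovarioles.
#'
#' @param fractions Numeric vector of per-ovariole labelled fractions, in
#'   (0, 1]. Use mosaic ovarioles with persistent clones only (see
#'   [classify_labeling()]); fully labelled and unlabelled ovarioles are
#'   excluded from the analysis by design.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level of the percentile interval.
#' @return An object of class `fsc_estimate` with fields `mean_fraction`,
#'   `sd_fraction`, `l_hat` (`1/mean`), `l_rounded` (nearest integer,
#'   clamped to >= 1), `ci` (bootstrap interval for `l_hat`),
#'   `implied_range` (from mean ± 2 SD, see [implied_fsc_range()]), `n`,
#'   `n_boot`, `conf`. Supports [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @examples
#' est <- estimate_fsc_number(rep(0.5, 20))
#' est$l_rounded
#' @export
estimate_fsc_number <- function(fractions, n_boot = 1e4, seed = 1L,
                                conf = 0.95) {
  if (length(fractions) == 0) stop("empty fraction list", call. = FALSE)
  if (any(!is.finite(fractions)) || any(fractions <= 0) ||
      any(fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  mean_fraction <- mean(fractions)
  sd_fraction <- if (length(fractions) > 1) stats::sd(fractions) else 0
  l_hat <- 1 / mean_fraction
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    1 / mean(sample(fractions, replace = TRUE))
  }, 0)
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  structure(list(
    mean_fraction = mean_fraction,
    sd_fraction = sd_fraction,
    l_hat = max(1, l_hat),
    l_rounded = max(1L, as.integer(round(l_hat))),
    ci = ci,
    implied_range = implied_fsc_range(mean_fraction, sd_fraction),
    n = length(fractions),
    n_boot = n_boot,
    conf = conf), class = "fsc_estimate")
}

#' @export
print.fsc_estimate <- function(x, ...) {
  cat(sprintf(
    "<fsc_estimate> mean labelled fraction %.3f (SD %.3f, n = %d)\n",
    x$mean_fraction, x$sd_fraction, x$n))
  cat(sprintf("  active FSCs: %.2f (rounds to %d); %d%% bootstrap CI [%.2f, %.2f]\n",
              x$l_hat, x$l_rounded, round(100 * x$conf), x$ci[1], x$ci[2]))
  cat(sprintf("  mean +/- 2 SD implies %.2f-%.2f FSCs\n",
              x$implied_range[1], x$implied_range[2]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname estimate_fsc_number
#' @param x An `fsc_estimate`.
#' @param ... Unused.
#' @method tidy fsc_estimate
#' @export
tidy.fsc_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("mean_fraction", "l_hat"),
    estimate = c(x$mean_fraction, x$l_hat),
    conf.low = c(NA, x$ci[1]),
    conf.high = c(NA, x$ci[2]))
}

#' @rdname estimate_fsc_number
#' @method glance fsc_estimate
#' @export
glance.fsc_estimate <- function(x, ...) {
  tibble::tibble(
    mean_fraction = x$mean_fraction, sd_fraction = x$sd_fraction,
    l_hat = x$l_hat, l_rounded = x$l_rounded,
    ci_low = x$ci[1], ci_high = x$ci[2],
    implied_low = x$implied_range[1], implied_high = x$implied_range[2],
    n = x$n, n_boot = x$n_boot)
}

#' FSC-number range implied by clone-size spread
#'
#' Converts the mean ± 2 SD envelope of the labelled fraction into a
#' range of stem-cell numbers: `low = 1 / (mean + 2 sd)` (clamped to
#' `>= 1`) and `high = 1 / max(mean - 2 sd, eps)`. At the observed 7-dphs
#' mean of 0.501 and SD of 0.141 this gives roughly 1.3 to 4.6, i.e.
#' approximately one to four active FSCs. Bounds are returned unrounded.
#'
#' @param mean_fraction Mean labelled fraction (in (0, 1]).
#' @param sd_fraction Standard deviation of the labelled fraction
#'   (`>= 0`).
#' @param eps Floor for `mean - 2 sd`; if the lower envelope falls at or
#'   below 0 the upper bound is capped at `1/eps` and flagged with
#'   attribute `capped = TRUE`.
#' @return Numeric `c(low, high)`.
#' @export
implied_fsc_range <- function(mean_fraction, sd_fraction, eps = 0.01) {
  if (!is.finite(mean_fraction) || mean_fraction <= 0) {
    stop("mean fraction must be positive", call. = FALSE)
  }
  if (sd_fraction < 0) stop("sd must be >= 0", call. = FALSE)
  hi_frac <- min(mean_fraction + 2 * sd_fraction, 1)
  lo_frac <- mean_fraction - 2 * sd_fraction
  capped <- lo_frac <= eps
  lo_frac <- max(lo_frac, eps)
  out <- c(low = max(1, 1 / hi_frac), high = 1 / lo_frac)
  attr(out, "capped") <- capped
  out
}

#' Invert the complement rule for the clone-induction probability
#'
#' If each of `l` stem cells is labelled independently with probability
#' `p`, the fraction of ovarioles carrying at least one FSC clone is
#' `1 - (1 - p)^l`. Given the observed fraction, this solves for `p`:
#' an observed 33.9\% of two-FSC ovarioles with clones implies a
#' per-FSC induction probability of about 0.187.
#'
#' @param frac_with_clones Fraction of ovarioles with at least one FSC
#'   clone, in \[0, 1).
#' @param l Number of active FSCs (`>= 1`).
#' @return Per-FSC induction probability `1 - (1 - frac)^(1/l)`.
#' @examples
#' estimate_induction_probability(0.339, 2)
#' @export
estimate_induction_probability <- function(frac_with_clones, l) {
  if (any(frac_with_clones < 0) || any(frac_with_clones >= 1)) {
    stop("frac_with_clones must lie in [0, 1)", call. = FALSE)
  }
  if (any(l < 1)) stop("l must be >= 1", call. = FALSE)
  1 - (1 - frac_with_clones)^(1 / l)
}

#' Pairwise comparison of clone sizes across conditions
#'
#' Welch two-sample t tests of labelled fractions for every pair of
#' conditions (e.g. heat-shock regimens or marking systems), with
#' Bonferroni-adjusted p values. Similar clone sizes across regimens and
#' marking systems support a condition-independent stem-cell number.
#'
#' @param data A data frame with one row per ovariole.
#' @param condition,fraction Column names (strings) holding the condition
#'   label and labelled fraction. Alternatively pass a named list of
#'   numeric vectors as `data`.
#' @return A tibble with one row per condition pair: `group1`, `group2`,
#'   `n1`, `n2`, `mean1`, `mean2`, `statistic`, `p.value`,
#'   `p.adjusted` (Bonferroni).
#' @export
compare_clone_sizes <- function(data, condition = "condition",
                                fraction = "fraction") {
  groups <- if (is.data.frame(data)) {
    split(data[[fraction]], data[[condition]])
  } else {
    data
  }
  if (length(groups) < 2) stop("need at least two conditions", call. = FALSE)
  small <- names(groups)[vapply(groups, length, 0L) < 2]
  if (length(small)) {
    stop("conditions with fewer than 2 observations: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  pairs <- utils::combn(names(groups), 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    ht <- stats::t.test(groups[[g1]], groups[[g2]])
    tibble::tibble(group1 = g1, group2 = g2,
                   n1 = length(groups[[g1]]), n2 = length(groups[[g2]]),
                   mean1 = mean(groups[[g1]]), mean2 = mean(groups[[g2]]),
                   statistic = unname(ht$statistic),
                   p.value = ht$p.value)
  }) |>
    dplyr::bind_rows()
  out$p.adjusted <- stats::p.adjust(out$p.value, "bonferroni")
  out
}

#' Mosaic clone-size fractions from a simulated cohort
#'
#' Convenience extractor chaining [classify_labeling()]: the labelled
#' fractions of mosaic ovarioles (persistent clone covering part, but not
#' all, of the scored region), the input for [estimate_fsc_number()].
#'
#' @param cohort A patch-record tibble.
#' @param dphs Optional dphs value(s) to restrict to.
#' @return A tibble `(ovariole, dphs, phenotype, fraction)`.
#' @export
mosaic_fractions <- function(cohort, dphs = NULL) {
  lab <- classify_labeling(cohort)
  if (!is.null(dphs)) lab <- dplyr::filter(lab, .data$dphs %in% !!dphs)
  lab |>
    dplyr::filter(.data$labeling == "mosaic") |>
    dplyr::select("ovariole", "dphs", "phenotype", "fraction")
}
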