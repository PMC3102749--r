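#' Fluctuation assay experiment
#'
#' Bundles per-culture mutant colony counts with the final viable cell
#' number per culture (N_t). Fewer than 14 cultures triggers a warning:
#' rate estimates from small fluctuation assays are unstable.
#'
#' @param counts Non-negative mutant colony counts, one per culture.
#' @param n_cells Final viable cells per culture (N_t, > 0).
#' @param strain Strain label.
#' @param assay Assay label, `"minusTy"` or `"plusTy912"`.
#' @return A list of class `fluctuation_experiment`.
#' @export
fluctuation_experiment <- function(counts, n_cells, strain = "strain",
                                   assay = c("plusTy912", "minusTy")) {
  assay <- match.arg(assay)
  if (length(counts) == 0L) stopf("`counts` must be non-empty")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stopf("`counts` must be finite and non-negative")
  }
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells <= 0) {
    stopf("`n_cells` must be a single positive number")
  }
  if (length(counts) < 14L) {
    warning(sprintf("only %d cultures; 14 or more are recommended",
                    length(counts)), call. = FALSE)
  }
  structure(list(counts = as.numeric(counts), n_cells = as.numeric(n_cells),
                 strain = strain, assay = assay),
            class = "fluctuation_experiment")
}

# Solve the Lea-Coulson median equation r/m - ln(m) = 1.24 for m.
# The left side is strictly decreasing in m, so the root is bracketed
# on [1e-6, 1e6] for any median of practical size.
lc_m_from_median <- function(r_median, lower = 1e-6, upper = 1e6,
                             tol = 1e-10) {
  if (r_median <= 0) stopf("median must be positive to solve for m")
  f <- function(m) r_median / m - log(m) - 1.24
  if (f(lower) < 0 || f(upper) > 0) {
    stopf("root not bracketed on [%g, %g] for median %g (f(lower)=%g, f(upper)=%g)",
          lower, upper, r_median, f(lower), f(upper))
  }
  stats::uniroot(f, c(lower, upper), tol = tol)$root
}

#' Lea-Coulson median estimator of the mutation rate
#'
#' Estimates the expected number of mutational events per culture, m, from
#' the sample median mutant count r by solving the Lea-Coulson median
#' equation r/m - ln(m) = 1.24 (bracketed root finding, tolerance 1e-10),
#' and reports the per-cell rate mu = m / N_t. When the median count is 0
#' the rate cannot be estimated and an upper bound is reported instead,
#' obtained by substituting r = `zero_median_sub` (default 0.5) and flagging
#' the estimate as censored; censored entries correspond to "<" rates in
#' published fluctuation tables.
#'
#' The 95% confidence interval is the exact order-statistic CI for the
#' median count (see [median_ci95()]) mapped through the same m(r)/N_t
#' transform; count bounds of 0 use the same substitution.
#'
#' @param exp A [fluctuation_experiment()].
#' @param zero_median_sub Median substitute used for censored (all-zero
#'   median) estimates.
#' @param conf_int Compute the rate-scale CI (requires >= 6 cultures).
#' @return A list of class `rate_estimate` with elements `m`, `median_count`,
#'   `rate`, `ci_low`, `ci_high`, `censored`, `n_cultures`, `n_cells`,
#'   `strain`, `assay`.
#' @examples
#' exp <- fluctuation_experiment(c(0, 1, 2, 3, 5, 5, 6, 8, 9, 12, 15, 20, 31, 60),
#'                               n_cells = 1e8)
#' estimate_rate_lc_median(exp)$rate
#' @export
estimate_rate_lc_median <- function(exp, zero_median_sub = 0.5,
                                    conf_int = TRUE) {
  stopifnot(inherits(exp, "fluctuation_experiment"))
  r <- stats::median(exp$counts)
  censored <- r == 0
  r_eff <- if (censored) zero_median_sub else r
  m <- lc_m_from_median(r_eff)
  rate <- m / exp$n_cells
  ci_low <- ci_high <- NA_real_
  if (conf_int && length(exp$counts) >= 6L) {
    ci <- median_ci95(exp$counts)
    to_rate <- function(b) {
      lc_m_from_median(if (b == 0) zero_median_sub else b) / exp$n_cells
    }
    ci_low <- to_rate(ci[1])
    ci_high <- to_rate(ci[2])
  }
  structure(list(m = m, median_count = r, rate = rate,
                 ci_low = ci_low, ci_high = ci_high, censored = censored,
                 n_cultures = length(exp$counts), n_cells = exp$n_cells,
                 strain = exp$strain, assay = exp$assay),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Rate estimate (%s, %s): %s%.3g per cell per generation\n",
              x$strain, x$assay, if (x$censored) "<" else "", x$rate))
  cat(sprintf("  m = %.4g, median count = %g, n = %d cultures\n",
              x$m, x$median_count, x$n_cultures))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% CI: [%.3g, %.3g]\n", x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Exact nonparametric 95% confidence interval for the median
#'
#' Returns the (k-th, (n+1-k)-th) order-statistic pair where k is the
#' largest integer whose two-sided exact binomial(n, 1/2) coverage,
#' 1 - 2 P(X <= k - 1), is at least 0.95. At least 6 values are required;
#' below that no order-statistic interval reaches 95% coverage.
#'
#' @param values Numeric sample.
#' @return Numeric length-2 vector `(low, high)` with attributes `k` and
#'   `coverage` (the exact coverage probability).
#' @examples
#' x <- rnorm(14)
#' ci <- median_ci95(x)     # 3rd and 12th order statistics
#' attr(ci, "coverage")     # 0.9871
#' @export
median_ci95 <- function(values) {
  n <- length(values)
  if (n < 6L) {
    stopf("need at least 6 values for a 95%% order-statistic CI (got %d)", n)
  }
  k <- 1L
  for (kk in seq_len(floor(n / 2))) {
    if (1 - 2 * stats::pbinom(kk - 1, n, 0.5) >= 0.95) k <- kk else break
  }
  s <- sort(values)
  out <- c(s[k], s[n + 1L - k])
  attr(out, "k") <- k
  attr(out, "coverage") <- 1 - 2 * stats::pbinom(k - 1, n, 0.5)
  out
}

#' Fold change between two rate estimates
#'
#' Computes `mutant$rate / wt$rate`. The printed fold mirrors the mixed
#' precision of published rate tables: folds of at least 10 are rounded to
#' integers, smaller folds to one significant figure. The raw unrounded
#' fold is always returned alongside. A censored mutant estimate yields a
#' "<" bounded fold; a censored wild-type estimate has no defined fold.
#'
#' @param mutant,wt [estimate_rate_lc_median()] results (`rate_estimate`),
#'   or bare rates; a bare numeric rate is treated as uncensored.
#' @return A list with `fold` (raw), `rounded` (numeric), and `label`
#'   (character, with a leading "<" for censored numerators).
#' @examples
#' fold_change(4.2e-6, 8.4e-8)$rounded  # 50
#' @export
fold_change <- function(mutant, wt) {
  as_est <- function(x) {
    if (inherits(x, "rate_estimate")) x else list(rate = as.numeric(x),
                                                  censored = FALSE)
  }
  mutant <- as_est(mutant); wt <- as_est(wt)
  if (isTRUE(wt$censored)) stopf("fold undefined: wild-type rate is censored")
  if (!is.finite(wt$rate) || wt$rate <= 0) stopf("wild-type rate must be > 0")
  f <- mutant$rate / wt$rate
  rounded <- if (f >= 10) round(f) else signif(f, 1)
  label <- paste0(if (isTRUE(mutant$censored)) "<" else "",
                  format(rounded, scientific = FALSE, trim = TRUE))
  list(fold = f, rounded = rounded, label = label,
       censored = isTRUE(mutant$censored))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()]: the exact distribution is
#' used for small untied samples (total n <= 20), otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param rates_a,rates_b Numeric samples (e.g. replicate rate estimates).
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(rates_a, rates_b) {
  if (length(rates_a) == 0L || length(rates_b) == 0L) {
    stopf("both samples must be non-empty")
  }
  exact <- length(rates_a) + length(rates_b) <= 20 &&
    !anyDuplicated(c(rates_a, rates_b))
  suppressWarnings(
    stats::wilcox.test(rates_a, rates_b, exact = exact,
                       alternative = "two.sided")$p.value
  )
}

#' Assign a mutation class from four rate estimates
#'
#' Classifies a mutant relative to wild type using 95% CI overlap in the
#' two assays. The Roman numeral comes from the +Ty912 assay: I when the
#' mutant CI lies wholly above the wild-type CI, III when wholly below,
#' II otherwise. The letter comes from the -Ty assay: A when wholly above,
#' B otherwise; a censored mutant -Ty estimate can only yield B.
#'
#' @param mut_plus,mut_minus,wt_plus,wt_minus `rate_estimate` objects with
#'   confidence intervals (the wild-type estimates must not be censored).
#' @return A list of class `mutation_class` with elements `label` (e.g.
#'   `"IA"`), `numeral`, `letter`.
#' @export
assign_mutation_class <- function(mut_plus, mut_minus, wt_plus, wt_minus) {
  ests <- list(mut_plus = mut_plus, mut_minus = mut_minus,
               wt_plus = wt_plus, wt_minus = wt_minus)
  for (nm in names(ests)) {
    e <- ests[[nm]]
    if (!inherits(e, "rate_estimate")) stopf("`%s` must be a rate_estimate", nm)
    if (is.na(e$ci_low) || is.na(e$ci_high)) {
      stopf("`%s` lacks a confidence interval", nm)
    }
  }
  if (isTRUE(wt_plus$censored) || isTRUE(wt_minus$censored)) {
    stopf("wild-type estimates must not be censored")
  }
  numeral <- if (mut_plus$ci_low > wt_plus$ci_high) "I"
    else if (mut_plus$ci_high < wt_plus$ci_low) "III"
    else "II"
  letter <- if (!isTRUE(mut_minus$censored) &&
                mut_minus$ci_low > wt_minus$ci_high) "A" else "B"
  structure(list(label = paste0(numeral, letter), numeral = numeral,
                 letter = letter),
            class = "mutation_class")
}

#' Read fluctuation-assay culture data from TSV
#'
#' Expected columns: `strain`, `assay`, `culture_id`, `mutant_count`,
#' `n_cells`. Returns one [fluctuation_experiment()] per strain/assay pair.
#'
#' @param path TSV path.
#' @return Named list of `fluctuation_experiment` objects
#'   (names `strain.assay`).
#' @export
read_fluctuation_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("strain", "assay", "culture_id", "mutant_count", "n_cells")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("fluctuation TSV %s lacks column(s): %s",
                          path, paste(miss, collapse = ", "))
  key <- interaction(tab$strain, tab$assay, drop = TRUE)
  lapply(split(tab, key), function(g) {
    fluctuation_experiment(g$mutant_count, g$n_cells[1], strain = g$strain[1],
                           assay = g$assay[1])
  })
}
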