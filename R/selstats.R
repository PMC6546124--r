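# Post-processing of branch-site selection tests (likelihood-ratio statistic,
# chi-squared tail probability, Holm-Bonferroni correction) and the
# stable-vs-unstable group comparison.

#' Likelihood-ratio test from null and alternative log-likelihoods
#'
#' Computes the statistic `2 * (lnL_alt - lnL_null)` and its upper-tail
#' chi-squared probability. A negative statistic (alternative fit below the
#' null, which happens when an optimizer stalls in a local optimum) is
#' clamped to 0 with a warning rather than treated as an error, so tables of
#' real optimizer output can be processed in bulk.
#'
#' @param lnL_null,lnL_alt Finite log-likelihoods (vectorized).
#' @param df Degrees of freedom of the test, `>= 1`.
#' @return List with components `stat` and `p_raw`.
#' @examples
#' lrt(-11225.209, -11219.170, df = 1)   # stat 12.078, p ~ 5.1e-4
#' @export
lrt <- function(lnL_null, lnL_alt, df = 1L) {
  if (any(!is.finite(lnL_null)) || any(!is.finite(lnL_alt)))
    stop("log-likelihoods must be finite", call. = FALSE)
  if (any(df < 1)) stop("df must be >= 1", call. = FALSE)
  stat <- 2 * (lnL_alt - lnL_null)
  neg <- stat < 0
  if (any(neg)) {
    warning(sum(neg), " test(s) with alternative lnL below the null; ",
            "statistic clamped to 0")
    stat[neg] <- 0
  }
  list(stat = stat, p_raw = chi2_sf(stat, df))
}

#' Chi-squared survival function
#'
#' Upper-tail probability `P(X >= x)` for a chi-squared random variable,
#' evaluated in the tail-stable parameterization so that values such as
#' 1e-12 keep full relative accuracy.
#'
#' @param x Nonnegative quantile(s).
#' @param df Degrees of freedom, `>= 1`.
#' @return Probability in `[0, 1]`.
#' @examples
#' chi2_sf(50.167, 1)   # ~1.4e-12
#' @export
chi2_sf <- function(x, df = 1L) {
  if (any(x < 0)) stop("x must be nonnegative", call. = FALSE)
  if (any(df < 1)) stop("df must be >= 1", call. = FALSE)
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Holm-Bonferroni step-down correction
#'
#' Adjusted p-values under Holm's step-down procedure: the i-th smallest raw
#' value is multiplied by `(m - i + 1)` and a running maximum enforces
#' monotonicity in the sorted order (so the largest raw value can be lifted
#' above `1 x p`), capped at 1. Results are returned in the input order.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Numeric vector of corrected p-values, same order as input.
#' @examples
#' holm_bonferroni(c(5.1e-4, 8.7e-3, 1.4e-12, 2.8e-3, 4.2e-5, 9.4e-3))
#' @export
holm_bonferroni <- function(p) {
  if (!length(p)) stop("need at least one p-value", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}

#' Process a table of selection tests
#'
#' Adds the likelihood-ratio statistic, raw chi-squared p-value and
#' Holm-Bonferroni corrected p-value to a table of per-hypothesis null and
#' alternative log-likelihoods. Optional branch-site model parameter columns
#' (`p0`, `p1`, `p2a`, `p2b`, `omega0`, `omega1`, `omega2`) are validated for
#' range but carried through untouched: this package post-processes codon
#' model fits, it never estimates them.
#'
#' @param tests Data frame with columns `label`, `lnL_null`, `lnL_alt` and
#'   optional `df` (default 1) plus metadata columns.
#' @return The input data frame with columns `stat`, `p_raw`, `p_holm`
#'   appended.
#' @export
process_lrt_table <- function(tests) {
  need <- c("label", "lnL_null", "lnL_alt")
  miss <- setdiff(need, names(tests))
  if (length(miss))
    stop("selection-test table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- if (is.null(tests$df)) 1L else tests$df
  for (col in c("p0", "p1", "p2a", "p2b")) {
    v <- tests[[col]]
    if (!is.null(v) && any(v < 0 | v > 1, na.rm = TRUE))
      stop("site-class proportion out of [0,1] in column ", col, call. = FALSE)
  }
  for (col in c("omega0", "omega1", "omega2")) {
    v <- tests[[col]]
    if (!is.null(v) && any(v <= 0, na.rm = TRUE))
      stop("omega must be positive in column ", col, call. = FALSE)
  }
  res <- lrt(tests$lnL_null, tests$lnL_alt, df)
  tests$stat <- res$stat
  tests$p_raw <- res$p_raw
  tests$p_holm <- holm_bonferroni(res$p_raw)
  tests
}

#' Read a selection-test TSV
#'
#' @param path TSV with header columns `label`, `lnL_null`, `lnL_alt`,
#'   optional `df` and metadata columns.
#' @return Data frame.
#' @export
read_lrt_table <- function(path) {
  read_tsv_checked(path, c("label", "lnL_null", "lnL_alt"))
}

#' Two-sample t-test
#'
#' Two-sided comparison of two groups of measurements, either with the
#' classical pooled-variance Student statistic (`df = nA + nB - 2`) or
#' Welch's unequal-variance form.
#'
#' @param a,b Numeric vectors, each of length `>= 2`.
#' @param flavor `"student_pooled"` (default) or `"welch"`.
#' @param labels Length-2 character vector naming the groups.
#' @param metric Name of the measured quantity, carried into the result.
#' @return A `group_comparison`: list with `metric`, `flavor`, `groups`,
#'   `n`, `means`, `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, flavor = c("student_pooled", "welch"),
                         labels = c("a", "b"), metric = "value") {
  flavor <- match.arg(flavor)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("values must be finite", call. = FALSE)
  if (flavor == "student_pooled" &&
      stats::var(a) + stats::var(b) == 0)
    stop("zero pooled variance: all values identical within groups",
         call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = (flavor == "student_pooled"),
                      alternative = "two.sided")
  structure(list(metric = metric, flavor = flavor, groups = labels,
                 n = c(length(a), length(b)),
                 means = unname(ht$estimate),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s by %s (%s t-test): n = %d/%d, means %.3f vs %.3f, t = %.3f, df = %.4g, P = %.2g\n",
              x$metric, paste(x$groups, collapse = " vs "),
              sub("_", " ", x$flavor), x$n[1], x$n[2],
              x$means[1], x$means[2], x$t, x$df, x$p))
  invisible(x)
}

#' Compare a branch-length metric between stable and unstable clades
#'
#' Joins per-clade branch statistics with stability calls, splits the chosen
#' metric by class and runs [two_sample_t()]. The observation unit is the
#' clade.
#'
#' @param stats Data frame from [clade_stats_table()].
#' @param calls Data frame from [classify_stability()].
#' @param metric One of `"cbl"`, `"normalized_cbl"`, `"cpd"`.
#' @param flavor t-test flavor, see [two_sample_t()].
#' @return A `group_comparison` with groups `stable`, `unstable`.
#' @export
compare_groups <- function(stats, calls,
                           metric = c("cbl", "normalized_cbl", "cpd"),
                           flavor = c("student_pooled", "welch")) {
  metric <- match.arg(metric)
  flavor <- match.arg(flavor)
  miss <- setdiff(stats$clade_id, calls$clade_id)
  if (length(miss))
    stop("no stability call for clade(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- merge(stats, calls[, c("clade_id", "status")], by = "clade_id")
  vals <- split(m[[metric]], m$status)
  for (grp in c("stable", "unstable"))
    if (length(vals[[grp]]) < 2L)
      stop("group '", grp, "' has fewer than 2 clades (",
           length(vals[[grp]]), ")", call. = FALSE)
  two_sample_t(vals$stable, vals$unstable, flavor = flavor,
               labels = c("stable", "unstable"), metric = metric)
}
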