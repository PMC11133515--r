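#' Two-sample tests and clinical indices for cohort tables
#'
#' Thin, convention-fixing wrappers around the standard tests used for
#' demographic/biochemical group comparisons: Student's t (equal-variance
#' by default, Welch on request), Wilcoxon rank-sum with normal
#' approximation and tie correction, and Pearson's chi-squared without
#' continuity correction. All p-values are two-sided.
#'
#' @name cohort_stats
NULL

#' @rdname cohort_stats
#' @param x,y numeric samples for the two groups (n >= 2 each for the t-test).
#' @param welch use Welch's unequal-variance t-test?
#' @return two-sided p-value.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero variance in both groups")
  }
  stats::t.test(x, y, var.equal = !welch)$p.value
}

#' @rdname cohort_stats
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
}

#' @rdname cohort_stats
#' @param tab a 2 x k contingency table (counts); empty categories are an
#'   error rather than silently dropped.
#' @export
chi_squared <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2) stop("expected a 2 x k table")
  if (any(colSums(tab) == 0)) stop("empty category in contingency table")
  stats::chisq.test(tab, correct = FALSE)$p.value
}

#' HOMA-IR insulin-resistance index
#'
#' `insulin [uU/mL] * glucose [mmol/L] / 22.5`.
#'
#' @param insulin fasting insulin, uU/mL (> 0).
#' @param glucose fasting glucose, mmol/L (> 0); use [glucose_to_mmol()]
#'   for mg/dL inputs.
#' @return the index.
#' @export
homa_ir <- function(insulin, glucose) {
  if (any(insulin <= 0) || any(glucose <= 0)) stop("inputs must be > 0")
  insulin * glucose / 22.5
}

#' Convert glucose mg/dL to mmol/L
#' @param mg_dl glucose in mg/dL.
#' @param factor conversion factor (standard 0.0555 mmol/L per mg/dL).
#' @return glucose in mmol/L.
#' @export
glucose_to_mmol <- function(mg_dl, factor = 0.0555) mg_dl * factor

#' Group-comparison table for cohort characteristics
#'
#' Builds one comparison row per declared variable: mean +/- SD with a
#' t-test for normal continuous variables, median (q1; q3) with a Wilcoxon
#' rank-sum test for skewed ones, frequency (%) with a chi-squared test for
#' categorical ones. The test per variable is declared by the analyst
#' (distributional choice is not automated).
#'
#' @param samples sample table with a `group` column (`case`/`control`).
#' @param variables named character vector: variable name -> test, one of
#'   `"t"`, `"wilcoxon"`, `"chi2"`.
#' @return data frame: `variable`, `summary_case`, `summary_control`,
#'   `test`, `p_value`.
#' @export
compare_groups <- function(samples, variables) {
  stopifnot(all(variables %in% c("t", "wilcoxon", "chi2")))
  is_case <- samples$group == "case"
  rows <- lapply(names(variables), function(v) {
    test <- variables[[v]]
    x <- samples[[v]]
    if (is.null(x)) stop("variable '", v, "' not in sample table")
    if (test == "chi2") {
      tab <- table(samples$group, x)
      p <- chi_squared(tab)
      fmt <- function(g) paste(sprintf("%s: %d (%.1f%%)", colnames(tab),
                                       tab[g, ], 100 * prop.table(tab[g, ])),
                               collapse = "; ")
      sc <- fmt("case"); sn <- fmt("control")
    } else if (test == "t") {
      p <- two_sample_t(x[is_case], x[!is_case])
      f <- function(z) sprintf("%.1f ± %.1f", mean(z), stats::sd(z))
      sc <- f(x[is_case]); sn <- f(x[!is_case])
    } else {
      p <- wilcoxon_rank_sum(x[is_case], x[!is_case])
      f <- function(z) sprintf("%.1f [%.1f;%.1f]", stats::median(z),
                               stats::quantile(z, 0.25),
                               stats::quantile(z, 0.75))
      sc <- f(x[is_case]); sn <- f(x[!is_case])
    }
    data.frame(variable = v, summary_case = sc, summary_control = sn,
               test = test, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
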