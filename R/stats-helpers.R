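#' Holm-Bonferroni multiple-comparison adjustment
#'
#' Step-down Holm adjustment of a vector of p-values (monotone, never below
#' the raw values). Thin wrapper around \code{stats::p.adjust} with input
#' validation.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' holmBonferroni(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holmBonferroni <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Two-sample Welch t-test
#'
#' Unequal-variance two-sample t-test comparing group means, as used for
#' between-condition comparisons of NPo and permeability summaries.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param var.equal Assume equal variances (classic Student test) instead of
#'   the Welch default.
#' @return List with \code{statistic} (t) and \code{p} (two-sided p-value).
#' @examples
#' twoSampleT(rnorm(10), rnorm(10, 1))
#' @export
twoSampleT <- function(a, b, var.equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per group")
  ht <- stats::t.test(a, b, var.equal = var.equal)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Mean and standard error across replicates
#'
#' @param x Numeric vector of replicate-level values.
#' @return List with \code{mean}, \code{sem} and \code{n}.
#' @export
meanSEM <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  list(mean = mean(x),
       sem = if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_,
       n = n)
}
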