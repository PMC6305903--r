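#' Effect size (standardized mean difference with pooled SD)
#'
#' `d = (mu_1 - mu_2) / sigma` with the pooled standard deviation
#' `sigma = sqrt(((n1 - 1) s1^2 + (n2 - 1) s2^2) / (n1 + n2 - 2))`
#' (Hedges' form; equivalent to Cohen's d for equal sample sizes). No
#' small-sample bias correction is applied. The 95% confidence interval
#' uses the standard large-sample variance approximation
#' `var(d) ~ (n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2 - 2))`.
#'
#' @param sample1,sample2 Numeric vectors, each of length >= 2.
#' @return An object of class `effect_size_result` with fields `d`, `ci95`
#'   (length-2 vector containing `d`), `n1`, `n2`, `pooled_sd`, and
#'   `infinite` flagging a zero pooled SD with unequal means (signed
#'   infinity sentinel).
#' @export
effect_size <- function(sample1, sample2) {
  s1 <- as.numeric(sample1); s2 <- as.numeric(sample2)
  n1 <- length(s1); n2 <- length(s2)
  if (n1 < 2L || n2 < 2L) stop("both samples must have at least 2 values")
  if (anyNA(s1) || anyNA(s2)) stop("samples must not contain NA")
  m1 <- mean(s1); m2 <- mean(s2)
  pooled <- sqrt(((n1 - 1) * stats::var(s1) + (n2 - 1) * stats::var(s2)) /
                 (n1 + n2 - 2))
  infinite <- FALSE
  if (pooled == 0) {
    if (m1 == m2) {
      d <- 0
    } else {
      d <- sign(m1 - m2) * Inf
      infinite <- TRUE
    }
    ci <- c(d, d)
  } else {
    d <- (m1 - m2) / pooled
    k1 <- as.numeric(n1); k2 <- as.numeric(n2)  # avoid integer overflow
    se <- sqrt((k1 + k2) / (k1 * k2) + d^2 / (2 * (k1 + k2 - 2)))
    ci <- d + c(-1, 1) * stats::qnorm(0.975) * se
  }
  structure(list(d = d, ci95 = ci, n1 = n1, n2 = n2, pooled_sd = pooled,
                 infinite = infinite),
            class = "effect_size_result")
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf("effect size d = %.4g [%.4g, %.4g] (n1 = %d, n2 = %d)\n",
              x$d, x$ci95[1], x$ci95[2], x$n1, x$n2))
  invisible(x)
}

#' Average effect size over multiple simulation runs
#'
#' For repeated independent runs (e.g. several network states) the per-run
#' effect sizes are combined as an unweighted mean with their standard
#' deviation.
#'
#' @param pairs List of two-element lists/vectors `(sample1, sample2)`.
#' @return A list with `mean_d`, `sd_d` (`NA` for a single pair), `n_pairs`
#'   and the per-pair `d` values.
#' @export
mean_effect_size <- function(pairs) {
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  d <- vapply(pairs, function(p) effect_size(p[[1L]], p[[2L]])$d, numeric(1))
  list(mean_d = mean(d),
       sd_d = if (length(d) > 1L) stats::sd(d) else NA_real_,
       n_pairs = length(d), d = d)
}

#' Two-sample hypothesis test
#'
#' Two-sided comparison of two sample distributions: Student's t-test for
#' equality of the means (to be applied only to approximately normal
#' measures), the Kolmogorov-Smirnov test (supremum distance of the two
#' empirical CDFs) or the Mann-Whitney U test (rank sums of the jointly
#' sorted samples) for equality of the distributions.
#'
#' @param sample1,sample2 Non-empty numeric vectors.
#' @param test `"t"`, `"ks"` or `"mwu"`.
#' @return An object of class `hypothesis_test_result` with fields `test`,
#'   `statistic` and `p_value`.
#' @export
two_sample_test <- function(sample1, sample2, test = c("ks", "mwu", "t")) {
  test <- match.arg(test)
  s1 <- as.numeric(sample1); s2 <- as.numeric(sample2)
  if (!length(s1) || !length(s2)) stop("samples must be non-empty")
  res <- switch(test,
    t = stats::t.test(s1, s2, var.equal = TRUE, alternative = "two.sided"),
    ks = suppressWarnings(stats::ks.test(s1, s2, alternative = "two.sided")),
    mwu = suppressWarnings(stats::wilcox.test(s1, s2,
                                              alternative = "two.sided")))
  structure(list(test = test, statistic = unname(res$statistic),
                 p_value = unname(res$p.value)),
            class = "hypothesis_test_result")
}

#' @export
print.hypothesis_test_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g\n",
              toupper(x$test), x$statistic, x$p_value))
  invisible(x)
}
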