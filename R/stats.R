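#' Significance stars for a p-value
#'
#' The reporting convention: `ns` for p >= 0.05, `*` for p <= 0.05, `**`
#' for p <= 0.01, `***` for p <= 0.001, the strongest applicable label
#' winning (so p = 0.05 exactly is `*`).
#'
#' @param p p-value in `[0, 1]`.
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p), p >= 0, p <= 1)
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*"
  else "ns"
}

#' F test followed by a Student's t test
#'
#' The two-group comparison convention: a two-sided F test of variance
#' equality decides the t-test variant — pooled-variance Student's t when
#' the F test does not reject (`f_p >= alpha`), Welch's t otherwise — and
#' the two-sided t p-value is mapped to significance stars with
#' [significance_stars()].
#'
#' @param a,b numeric samples with at least 2 finite values each.
#' @param alpha F-test level deciding the variant.
#' @return An object of class `TestResult`: list with `f_p`, `variant`
#'   (`"pooled"` or `"welch"`), `t_stat`, `t_p`, `stars`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `sd_a`, `sd_b`.
#' @export
f_then_t <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L || !all(is.finite(c(a, b)))) {
    sq_stop("SAMPLE_TOO_SMALL",
            "both samples need >= 2 finite values (have %d and %d)",
            length(a), length(b))
  }
  f_p <- stats::var.test(a, b)$p.value
  variant <- if (!is.na(f_p) && f_p < alpha) "welch" else "pooled"
  tt <- stats::t.test(a, b, var.equal = variant == "pooled")
  structure(list(f_p = f_p, variant = variant,
                 t_stat = unname(tt$statistic), t_p = tt$p.value,
                 stars = significance_stars(tt$p.value),
                 n_a = length(a), n_b = length(b),
                 mean_a = mean(a), mean_b = mean(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b)),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("TestResult: %s t test, t = %.3f, p = %.4g (%s); F-test p = %.4g\n",
              x$variant, x$t_stat, x$t_p, x$stars, x$f_p))
  cat(sprintf("  a: n = %d, mean = %.4g (sd %.3g); b: n = %d, mean = %.4g (sd %.3g)\n",
              x$n_a, x$mean_a, x$sd_a, x$n_b, x$mean_b, x$sd_b))
  invisible(x)
}
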