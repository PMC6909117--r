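#' Paired TOST equivalence test
#'
#' Two one-sided tests on paired differences d = a - b against the margins
#' -margin and +margin: equivalence is declared when both one-sided tests
#' reject, i.e. when the larger of the two one-sided p-values falls below
#' alpha. Student t reference distribution with n - 1 degrees of freedom.
#'
#' @param a,b Paired measurements (equal length >= 3).
#' @param margin Equivalence margin, same units as the data (> 0); 0.03 mmCu
#'   is the conventional margin for copper HVL method comparison.
#' @param alpha Significance level (default 0.05).
#' @return An object of class \code{tost_result}: \code{n}, \code{mean_diff},
#'   \code{sd_diff}, \code{margin}, \code{t_lower}, \code{t_upper},
#'   \code{p_lower}, \code{p_upper}, \code{p} = max of the two, and
#'   \code{equivalent} (p < alpha). When the differences have zero variance
#'   and the mean lies inside the margin, p is reported at the machine floor
#'   with \code{degenerate = TRUE}.
#' @export
tost_paired <- function(a, b, margin = 0.03, alpha = 0.05) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs")
  if (!is.numeric(margin) || margin <= 0) stop("margin must be positive")
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  degenerate <- FALSE
  if (sdd == 0) {
    if (abs(md) < margin) {
      degenerate <- TRUE
      t_lower <- Inf; t_upper <- Inf
      p_lower <- .Machine$double.xmin; p_upper <- .Machine$double.xmin
    } else {
      t_lower <- if (md <= -margin) -Inf else Inf
      t_upper <- if (md >= margin) -Inf else Inf
      p_lower <- if (md <= -margin) 1 else .Machine$double.xmin
      p_upper <- if (md >= margin) 1 else .Machine$double.xmin
    }
  } else {
    se <- sdd / sqrt(n)
    t_lower <- (md + margin) / se       # H0: mean <= -margin
    t_upper <- (margin - md) / se       # H0: mean >= +margin
    p_lower <- stats::pt(t_lower, df = n - 1, lower.tail = FALSE)
    p_upper <- stats::pt(t_upper, df = n - 1, lower.tail = FALSE)
  }
  p <- max(p_lower, p_upper)
  structure(
    list(n = n, mean_diff = md, sd_diff = sdd, margin = margin,
         alpha = alpha, t_lower = t_lower, t_upper = t_upper,
         p_lower = p_lower, p_upper = p_upper, p = p,
         equivalent = p < alpha, degenerate = degenerate),
    class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf("<tost_result> n = %d pairs | mean diff %+.4g +/- %.4g | margin +/-%g\n",
              x$n, x$mean_diff, x$sd_diff, x$margin),
      sprintf("  t_lower = %.3f (p = %.4g), t_upper = %.3f (p = %.4g)  =>  p = %.4g: %s at alpha = %g\n",
              x$t_lower, x$p_lower, x$t_upper, x$p_upper, x$p,
              if (x$equivalent) "EQUIVALENT" else "not equivalent", x$alpha))
  invisible(x)
}

#' Paired-difference summary for method comparison
#'
#' Summaries of d = a - b: signed mean, SD of the signed differences, min,
#' max, and the mean absolute difference. Note the two "mean difference"
#' readings: the signed mean is the one consistent with pairing a +/- SD
#' value, while the mean absolute difference is a distinct (larger) summary.
#'
#' @param a,b Paired measurements (equal length).
#' @param digits Optional rounding for display (e.g. 2 for mmCu reported to
#'   two decimals); NULL (default) returns full precision.
#' @return A list: \code{mean_signed}, \code{sd}, \code{min}, \code{max},
#'   \code{mean_abs}, \code{n}.
#' @export
difference_summary <- function(a, b, digits = NULL) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  d <- a - b
  out <- list(mean_signed = mean(d), sd = stats::sd(d),
              min = min(d), max = max(d), mean_abs = mean(abs(d)),
              n = length(d))
  if (!is.null(digits))
    out[c("mean_signed", "sd", "min", "max", "mean_abs")] <-
      lapply(out[c("mean_signed", "sd", "min", "max", "mean_abs")],
             round, digits = digits)
  out
}
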