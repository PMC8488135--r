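#' Paired t-test with Bonferroni-corrected significance threshold
#'
#' Classical paired t statistic on the differences `d = x - y` with `n - 1`
#' degrees of freedom and a two-tailed p-value, flagged against a
#' Bonferroni-corrected alpha. The default corrected threshold is
#' 0.05 / 3 (three echo analysis methods compared against the reference),
#' i.e. two-tailed P < 0.0167.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @param alpha corrected significance level (default `0.05 / 3`).
#' @return An object of class `paired_comparison`: `n`, `mean_diff`,
#'   `sd_diff`, `t`, `df`, `p`, `alpha`, `significant`.
#' @export
paired_t <- function(x, y, alpha = 0.05 / 3) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("paired t-test requires n >= 2")
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d < .Machine$double.eps * max(1, abs(mean(d))) * 100 || sd_d == 0)
    stop("statistic undefined: differences have zero variance")
  tval <- mean(d) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  structure(list(n = n, mean_diff = mean(d), sd_diff = sd_d,
                 t = tval, df = n - 1L, p = p, alpha = alpha,
                 significant = p < alpha),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired t: mean diff %.3f (SD %.3f), t(%d) = %.3f, p = %.4g%s\n",
              x$mean_diff, x$sd_diff, x$df, x$t, x$p,
              if (x$significant) sprintf(" (significant at %.4f)", x$alpha)
              else ""))
  invisible(x)
}

#' Intraclass correlation ICC(A,k): two-way model, absolute agreement,
#' average of k measurements
#'
#' Computes the McGraw-Wong ICC(A,k) from the two-way ANOVA mean squares of
#' an n x k table (rows = subjects, columns = methods/raters):
#' \deqn{ICC(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}}
#' This is the average-measure, absolute-agreement form appropriate when a
#' fixed set of methods each measures every subject and systematic offsets
#' between methods should count against agreement.
#'
#' @param ratings complete numeric n x k matrix or data.frame, n >= 2
#'   subjects, k >= 2 methods; missing cells are an error (no imputation).
#' @return An object of class `icc_result`: `icc`, `model` (descriptor),
#'   `n`, `k`, and the mean squares `ms_rows`, `ms_cols`, `ms_error`.
#' @export
icc_a_k <- function(ratings) {
  X <- as.matrix(ratings)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("ratings table has missing cells (no imputation)")
  n <- nrow(X); k <- ncol(X)
  if (n < 2L || k < 2L) stop("ICC requires n >= 2 subjects and k >= 2 methods")
  grand <- mean(X)
  row_m <- rowMeans(X); col_m <- colMeans(X)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((X - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)
  structure(list(icc = icc,
                 model = "two-way mixed effects, absolute agreement, average of k measurements",
                 n = n, k = k,
                 ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,%d) = %.4f (%s; n = %d)\n", x$k, x$icc, x$model, x$n))
  invisible(x)
}

#' Two-method Bland-Altman analysis
#'
#' Bias (mean difference) and 95% limits of agreement,
#' `bias +/- 1.96 * SD(d)` with the sample SD (denominator n - 1) of the
#' paired differences `d = x - y`: the values between which 95% of
#' differences between the two methods are expected to fall.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return An object of class `bland_altman`: `bias`, `sd_diff`, `loa`
#'   (lower, upper), `half_width`, `n`.
#' @export
bland_altman_two <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("Bland-Altman analysis requires n >= 3")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  hw <- 1.96 * s
  structure(list(bias = bias, sd_diff = s,
                 loa = c(lower = bias - hw, upper = bias + hw),
                 half_width = hw, n = n, k = 2L),
            class = "bland_altman")
}

#' Multi-method Bland-Altman analysis (method vs. subject mean)
#'
#' For k >= 3 methods measured on every subject, differences are taken
#' from each method to the mean of the measurements for that subject:
#' `d_ij = x_ij - mean_j(x_ij)`. The per-method bias is the mean of its
#' differences (the k biases sum to zero by construction), and a single
#' symmetric 95% limit-of-agreement half-width is `1.96 * SD` of all
#' `n * k` differences pooled after removing each method's bias (no
#' small-sample or row-mean-correlation correction), so with
#' i.i.d. N(0, sigma^2) measurement noise the half-width estimates
#' `1.96 * sigma * sqrt((k - 1) / k)`.
#'
#' @param methods complete numeric n x k matrix or data.frame, k >= 3.
#' @return An object of class `bland_altman_multi`: `bias` (named
#'   per-method vector), `half_width`, `sd_diff`, `n`, `k`.
#' @export
bland_altman_multi <- function(methods) {
  X <- as.matrix(methods)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("methods table has missing cells")
  n <- nrow(X); k <- ncol(X)
  if (k < 3L) stop("multi-method Bland-Altman requires k >= 3 (use bland_altman_two)")
  d <- X - rowMeans(X)
  bias <- colMeans(d)
  names(bias) <- colnames(X) %||% paste0("method", seq_len(k))
  resid <- sweep(d, 2L, bias)
  s <- stats::sd(as.vector(resid))
  structure(list(bias = bias, half_width = 1.96 * s, sd_diff = s,
                 n = n, k = k),
            class = "bland_altman_multi")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, 95%% LoA [%.3f, %.3f]\n",
              x$n, x$bias, x$loa[1L], x$loa[2L]))
  invisible(x)
}

#' @export
print.bland_altman_multi <- function(x, ...) {
  cat(sprintf("Multi-method Bland-Altman (n = %d, k = %d): symmetric LoA +/- %.3f\n",
              x$n, x$k, x$half_width))
  cat("  biases:", paste(sprintf("%s %.3f", names(x$bias), x$bias),
                         collapse = ", "), "\n")
  invisible(x)
}
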