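# Parametric follow-up statistics on interval-averaged measures: t tests,
# Cohen's d, adjusted partial eta squared, and JZS Bayes factors.

#' Average a curve over a time interval
#'
#' Per-subject mean over the samples of a subject x time matrix that fall
#' inside a window (both edges inclusive).
#'
#' @param curve numeric matrix subjects x time (a vector is treated as one
#'   subject).
#' @param times time axis in ms.
#' @param window interval in ms (length 2).
#' @return numeric vector of per-subject means.
#' @export
intervalAverage <- function(curve, times, window) {
  curve <- rbind(curve)
  if (ncol(curve) != length(times))
    stop("times must annotate the columns of curve")
  idx <- which(times >= window[1] & times <= window[2])
  if (length(idx) == 0L)
    stop("no samples inside the window [", window[1], ", ", window[2], "] ms")
  rowMeans(curve[, idx, drop = FALSE])
}

#' Adjusted partial eta squared from a t statistic
#'
#' Bias-adjusted variance-explained effect size for a single-df effect:
#' `F = t^2`, `eta_adj = (F - 1) / (F - 1 + (df_error + 1) / df_effect)`.
#' Returns 0 exactly at F = 1 and can be slightly negative for F < 1.
#'
#' @param t t statistic(s).
#' @param dfError error degrees of freedom (n - 1 for one-sample/paired
#'   designs).
#' @param dfEffect effect degrees of freedom (default 1).
#' @return adjusted partial eta squared (vectorised over `t`).
#' @export
#' @examples
#' adjustedPartialEtaSq(5.42, 27)  # ~0.50
adjustedPartialEtaSq <- function(t, dfError, dfEffect = 1) {
  stopifnot(dfError >= 1)
  F <- t^2
  (F - 1) / (F - 1 + (dfError + 1) / dfEffect)
}

#' JZS Bayes factor for one-sample and paired t designs
#'
#' Default Bayes factor with a Jeffreys prior on the variance and a
#' zero-centred Cauchy prior (scale `priorScale`, default 0.707) on the
#' standardised effect size. BF10 is the marginal likelihood of the data
#' under H1 divided by that under H0, computed from the t statistic by
#' integrating the Cauchy prior via its inverse-gamma mixture
#' representation; the integrand is evaluated in log space so that
#' `|t|` up to the largest values printed in practice (~60) stay finite.
#'
#' @param t t statistic.
#' @param n number of (paired) observations; degrees of freedom are `n - 1`.
#' @param priorScale Cauchy prior scale r (default `0.707`).
#' @param relTol relative tolerance of the quadrature (default 1e-8).
#' @return named numeric vector with elements `bf10` and `bf01`.
#' @export
#' @examples
#' jzsBayesFactor(0.47, 28)  # bf01 ~ 4.5
jzsBayesFactor <- function(t, n, priorScale = sqrt(2) / 2, relTol = 1e-8) {
  stopifnot(is.finite(t), n >= 2)
  nu <- n - 1
  r2 <- priorScale^2
  # log integrand over the mixing variance g of the Cauchy representation
  logf <- function(g) {
    -0.5 * log1p(n * g * r2) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n * g * r2) * nu)) -
      0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g)
  }
  # location of the integrand's mode for log-space rescaling
  opt <- stats::optimize(logf, c(1e-8, 1e4), maximum = TRUE)
  shift <- opt$objective
  intg <- stats::integrate(function(g) exp(logf(g) - shift), 0, Inf,
                           rel.tol = relTol)
  if (intg$message != "OK")
    stop("Bayes factor quadrature did not converge: ", intg$message)
  logNum <- log(intg$value) + shift
  logDen <- -(nu + 1) / 2 * log1p(t^2 / nu)
  bf10 <- exp(logNum - logDen)
  c(bf10 = bf10, bf01 = 1 / bf10)
}

#' t test with effect sizes and Bayes factor
#'
#' Two-sided one-sample t test of `x` against `mu`, or paired t test of
#' `x` against `y`, with Cohen's d (`d = t / sqrt(n)`), adjusted partial eta
#' squared, and the JZS Bayes factor.
#'
#' @param x numeric vector of per-subject values.
#' @param y optional paired partner values (same length).
#' @param mu reference value for the one-sample test (default 0); e.g. 0.5
#'   for decoding accuracy against chance.
#' @param priorScale Cauchy prior scale for the Bayes factor.
#' @return an [InferenceResult-class].
#' @export
#' @examples
#' set.seed(1)
#' inferenceTest(rnorm(28, 0.2), mu = 0)
inferenceTest <- function(x, y = NULL, mu = 0, priorScale = sqrt(2) / 2) {
  if (!is.null(y)) {
    stopifnot(length(x) == length(y))
    x <- x - y
    mu <- 0
  }
  n <- length(x)
  if (n < 2) stop("at least 2 observations are required")
  if (stats::sd(x) == 0)
    stop("degenerate t: zero variance in the (difference) values")
  tt <- stats::t.test(x, mu = mu)
  t <- unname(tt$statistic)
  bf <- jzsBayesFactor(t, n, priorScale)
  new("InferenceResult",
      t = t, df = unname(tt$parameter), p = tt$p.value,
      d = t / sqrt(n), etaAdj = adjustedPartialEtaSq(t, n - 1),
      bf10 = unname(bf["bf10"]), bf01 = unname(bf["bf01"]),
      priorScale = priorScale, n = n, estimate = mean(x) - mu)
}
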