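#' D'Agostino & Pearson omnibus normality test
#'
#' Combines the sample-size-corrected skewness Z (D'Agostino's transformed
#' \eqn{\sqrt{b_1}}) and kurtosis Z (Anscombe-Glynn's transformed \eqn{b_2})
#' into the omnibus statistic \eqn{K^2 = Z_{skew}^2 + Z_{kurt}^2}, referred to
#' a chi-square distribution with 2 degrees of freedom.  The test is used to
#' check that MMSE and square-root-transformed NFT scores are compatible with
#' normality before Pearson correlation screening.
#'
#' The kurtosis transformation is numerically unreliable for very small
#' samples, so n >= 8 is required.
#'
#' @param x numeric vector, length >= 8, not constant.
#' @return a list with elements `k2` (omnibus statistic), `z_skew`, `z_kurt`
#'   (component Z-scores), `skewness`, `kurtosis` (moment estimates
#'   \eqn{g_1} and \eqn{b_2}) and `p` (two-sided omnibus p-value).
#' @export
dagostino_pearson_test <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8)
    stop("the omnibus normality test is undefined for n < 8 (n = ", n,
         "); the kurtosis transformation is unstable at this size",
         call. = FALSE)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0)
    stop("input is constant; normality test undefined", call. = FALSE)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  g1 <- m3 / m2^1.5          # sqrt(b1), moment skewness
  b2 <- m4 / m2^2            # moment kurtosis (3 under normality)

  # D'Agostino (1970) transformed skewness
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * asinh(y / alpha)

  # Anscombe & Glynn (1983) transformed kurtosis
  e_b2 <- 3 * (n - 1) / (n + 1)
  v_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(v_b2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  num <- 1 - 2 / a
  den <- 1 + xk * sqrt(2 / (a - 4))
  ratio <- num / den
  z_kurt <- ((1 - 2 / (9 * a)) - sign(ratio) * abs(ratio)^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  list(
    k2 = k2, z_skew = z_skew, z_kurt = z_kurt,
    skewness = g1, kurtosis = b2,
    p = pchisq(k2, df = 2, lower.tail = FALSE)
  )
}
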