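first_order_names <- function() {
  c("mean", "sd", "variance", "skewness", "kurtosis", "energy", "entropy",
    "range")
}

#' First-order intensity features of a masked region
#'
#' All moments use the population form (denominator `N`): variance is
#' `sum((x - mu)^2) / N`, skewness `m3 / m2^(3/2)` and kurtosis `m4 / m2^2`
#' (Pearson, not excess).  `energy` is the sum of squared intensities and
#' `entropy` the Shannon entropy (bits) of a 64-bin histogram of the masked
#' values.  For a constant region the variance is 0 and skewness/kurtosis
#' are undefined (`NA`).
#'
#' @param volume numeric array.
#' @param mask logical array of the same shape, non-empty.
#' @return named numeric vector of length 8.
#' @export
first_order_features <- function(volume, mask) {
  if (!any(mask)) stop_invalid("mask is empty")
  x <- volume[mask]
  n <- length(x)
  mu <- mean(x)
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  ent <- if (diff(range(x)) == 0) 0 else {
    shannon_entropy(tabulate(
      pmin(64L, floor((x - min(x)) / diff(range(x)) * 64) + 1L), nbins = 64L))
  }
  c(mean = mu,
    sd = sqrt(m2),
    variance = m2,
    skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_,
    energy = sum(x^2),
    entropy = ent,
    range = diff(range(x)))
}
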