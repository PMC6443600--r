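## Gabor texture response features (2-D, per axial slice).

## cache of kernel FFTs keyed by (padded size, frequency, orientation)
.gabor_cache <- new.env(parent = emptyenv())

#' Build a complex 2-D Gabor kernel
#'
#' Gaussian-modulated complex sinusoid with `frequency` cycles/voxel along
#' `orientation` (radians), envelope sd `sigma = 0.56 / frequency` (about a
#' one-octave bandwidth) and spatial aspect ratio `gamma`.  The real
#' (cosine) part is DC-corrected against the Gaussian envelope so a
#' constant image yields zero response.
#'
#' @param frequency cycles per voxel, in `(0, 0.5]`.
#' @param orientation angle in radians.
#' @param gamma aspect ratio of the envelope (default 0.5).
#' @return list with `re` and `im` kernel matrices.
#' @export
gabor_kernel <- function(frequency, orientation, gamma = 0.5) {
  check_number(frequency, "frequency", lower = 0, upper = 0.5, strict_lower = TRUE)
  sigma <- 0.56 / frequency
  r <- ceiling(2.5 * sigma)
  xy <- seq(-r, r)
  X <- matrix(rep(xy, each = length(xy)), nrow = length(xy))  # column coord
  Y <- t(X)                                                   # row coord
  xr <- X * cos(orientation) + Y * sin(orientation)
  yr <- -X * sin(orientation) + Y * cos(orientation)
  env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  re <- env * cos(2 * pi * frequency * xr)
  im <- env * sin(2 * pi * frequency * xr)
  re <- re - env * sum(re) / sum(env)   # zero-DC correction
  list(re = re, im = im)
}

## index map for reflecting an out-of-range coordinate into [1, n]
## (repeated mirror reflection, period 2n - 2)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n - 2L)
  ifelse(j >= n, 2L * n - 2L - j, j) + 1L
}

## linear convolution (via FFT) of a reflect-padded slice with both kernel
## parts, returning the "same"-size complex response magnitude; reflection
## keeps the response free of artificial edges, so a constant image gives
## zero response even when the kernel is wider than the slice
gabor_response <- function(slice, frequency, orientation) {
  kern <- gabor_kernel(frequency, orientation)
  ks <- nrow(kern$re)
  if (ks > min(dim(slice)))
    warning("Gabor kernel larger than slice; reflect-padded convolution used")
  half <- (ks - 1L) %/% 2L
  pr <- reflect_index(seq(1L - half, nrow(slice) + half), nrow(slice))
  pc <- reflect_index(seq(1L - half, ncol(slice) + half), ncol(slice))
  padded <- slice[pr, pc, drop = FALSE]
  n1 <- nrow(padded) + ks - 1L
  n2 <- ncol(padded) + ks - 1L
  key <- sprintf("%d_%d_%g_%g", n1, n2, frequency, orientation)
  if (is.null(.gabor_cache[[key]])) {
    pad <- function(k) {
      m <- matrix(0, n1, n2); m[seq_len(ks), seq_len(ks)] <- k; m
    }
    .gabor_cache[[key]] <- stats::fft(pad(kern$re)) + 1i * stats::fft(pad(kern$im))
  }
  Kf <- .gabor_cache[[key]]
  S <- matrix(0, n1, n2)
  S[seq_len(nrow(padded)), seq_len(ncol(padded))] <- padded
  conv <- stats::fft(stats::fft(S) * Kf, inverse = TRUE) / (n1 * n2)
  # original pixel (i, j) sits at padded (i + half, j + half); the "same"
  # response of the full convolution adds another `half` offset
  Mod(conv[2L * half + seq_len(nrow(slice)),
           2L * half + seq_len(ncol(slice)), drop = FALSE])
}

#' Gabor response features of a masked slice
#'
#' Convolves the slice with a complex Gabor kernel, takes the response
#' magnitude inside the mask, and reports its population variance and the
#' Shannon entropy (bits) of its 64-bin histogram.
#'
#' @param slice numeric matrix.
#' @param mask logical matrix, same shape, non-empty.
#' @param frequency cycles per voxel in `(0, 0.5]`.
#' @param orientation angle in radians.
#' @return named numeric vector `c(variance, entropy)`.
#' @export
gabor_features <- function(slice, mask, frequency, orientation) {
  if (!any(mask)) stop_invalid("mask is empty")
  mag <- gabor_response(slice, frequency, orientation)[mask]
  v <- sum((mag - mean(mag))^2) / length(mag)
  # numerically constant response (e.g. constant input) has zero entropy
  ent <- if (diff(range(mag)) <= 1e-10 * max(abs(mag), 1)) 0 else
    shannon_entropy(tabulate(
      pmin(64L, floor((mag - min(mag)) / diff(range(mag)) * 64) + 1L),
      nbins = 64L))
  c(variance = v, entropy = ent)
}
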