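#' Texture parameters of a synthetic tumour phantom
#'
#' A phantom's texture is a stationary Gaussian random field with
#' squared-exponential covariance.  `correlation_length` (voxels) sets the
#' spatial scale of intensity patches, `noise_sd` the marginal standard
#' deviation of the field, `contrast` a dimensionless multiplier on the
#' fluctuation amplitude, and `mean_intensity` the HU-like plateau the
#' fluctuations ride on.  Larger `correlation_length` and `contrast` mimic
#' coarser, stronger intra-tumour heterogeneity.
#'
#' @param correlation_length positive length scale in voxels.
#' @param contrast non-negative dimensionless amplitude multiplier.
#' @param mean_intensity mean intensity inside the tumour (HU-like units).
#' @param noise_sd marginal standard deviation of the field (same units).
#' @return an object of class `texture_params`.
#' @export
texture_params <- function(correlation_length = 2, contrast = 1,
                           mean_intensity = 40, noise_sd = 10) {
  check_number(correlation_length, "correlation_length", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(contrast, "contrast", lower = 0)
  check_number(mean_intensity, "mean_intensity")
  structure(list(correlation_length = correlation_length, contrast = contrast,
                 mean_intensity = mean_intensity, noise_sd = noise_sd),
            class = "texture_params")
}

## 1-D Gaussian convolution matrix with reflecting boundary, kernel sd `s`.
## Convolving white noise with a Gaussian kernel of sd s yields a Gaussian
## process with squared-exponential covariance of length scale s * sqrt(2).
gauss_conv_matrix <- function(n, s) {
  if (s <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * s))
  k <- exp(-(seq(-r, r))^2 / (2 * s^2))
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- j + seq(-r, r)
    # reflect out-of-range indices back into [1, n]
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    for (t in seq_along(idx)) K[idx[t], j] <- K[idx[t], j] + k[t]
  }
  K
}

## apply a matrix along one axis of a 3-D array
apply_axis <- function(a, M, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- M %*% matrix(ap, nrow = dp[1])
  ap <- array(m, dim = dp)
  aperm(ap, order(perm))
}

#' Generate a synthetic tumour phantom
#'
#' Builds a 3-D scalar volume containing a stationary Gaussian random field
#' (squared-exponential covariance with length scale `params$correlation_length`
#' and marginal sd `params$noise_sd`, scaled by `params$contrast`) inside an
#' ellipsoidal binary mask, standing in for a segmented tumour ROI on CT.
#' The field is produced by Gaussian smoothing of white noise and re-scaled
#' to the requested marginal sd, so the zero-noise limit is a constant volume.
#'
#' @param params a [texture_params()] object.
#' @param shape integer voxel triple, each entry at least 8.
#' @param seed integer seed; the phantom is bit-reproducible for a fixed seed.
#' @param voxel_spacing mm per voxel, length-3 (default 2 mm isotropic).
#' @return an object of class `tumor_phantom` with fields `volume`, `mask`,
#'   `voxel_spacing`, `params`.
#' @export
generate_tumor_phantom <- function(params, shape = c(24, 24, 24), seed = 1,
                                   voxel_spacing = c(2, 2, 2)) {
  if (!inherits(params, "texture_params")) params <- do.call(texture_params, params)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 8L))
    stop_invalid("`shape` must be three integers, each >= 8")
  if (any(voxel_spacing <= 0)) stop_invalid("voxel spacing must be positive per axis")

  set.seed(as.integer(seed))
  vol <- array(rnorm(prod(shape)), dim = shape)
  s <- params$correlation_length / sqrt(2)  # kernel sd giving SE length scale
  for (ax in 1:3) vol <- apply_axis(vol, gauss_conv_matrix(shape[ax], s), ax)
  # normalise the smoothed field back to unit marginal sd, then scale
  f <- sd(as.vector(vol))
  if (f > 0) vol <- vol / f
  vol <- params$mean_intensity + params$contrast * params$noise_sd * vol

  ctr <- (shape + 1) / 2
  semi <- 0.42 * shape
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
  d2 <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2
  mask <- array(d2 <= 1, dim = shape)

  structure(list(volume = vol, mask = mask,
                 voxel_spacing = as.numeric(voxel_spacing), params = params),
            class = "tumor_phantom")
}

#' @export
print.tumor_phantom <- function(x, ...) {
  cat(sprintf("<tumor_phantom> %s voxels, %d in mask, spacing %s mm\n",
              paste(dim(x$volume), collapse = "x"), sum(x$mask),
              paste(x$voxel_spacing, collapse = "x")))
  invisible(x)
}

#' Write a phantom as a NIfTI volume/mask pair
#'
#' @param phantom a `tumor_phantom`.
#' @param volume_path,mask_path output `.nii` / `.nii.gz` paths.
#' @return invisibly, the two paths.  The affine carries the voxel spacing.
#' @export
write_phantom_nifti <- function(phantom, volume_path, mask_path) {
  img <- RNifti::asNifti(phantom$volume)
  RNifti::pixdim(img) <- phantom$voxel_spacing
  msk <- RNifti::asNifti(array(as.integer(phantom$mask), dim = dim(phantom$mask)))
  RNifti::pixdim(msk) <- phantom$voxel_spacing
  RNifti::writeNifti(img, volume_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(volume_path, mask_path))
}
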