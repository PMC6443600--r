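#' Gray-level quantization of a masked volume
#'
#' Equal-width binning of the masked intensity range into `G` levels
#' numbered 1..G.  A constant masked region maps wholly to level 1.
#' Values outside the mask are binned with the same rule but carry no
#' meaning downstream; only masked voxels enter any texture matrix.
#'
#' @param volume numeric array (2-D or 3-D).
#' @param mask logical array, same shape, with at least one `TRUE` voxel.
#' @param G number of gray levels, at least 2.
#' @return list of class `quantized_volume`: `grid` (integer array in
#'   `[1, G]`), `G`, `mask`.
#' @export
quantize <- function(volume, mask, G) {
  if (!all(dim(volume) == dim(mask))) stop_invalid("volume/mask shape mismatch")
  if (!any(mask)) stop_invalid("mask is empty")
  check_number(G, "G", lower = 2)
  v <- volume[mask]
  mn <- min(v); mx <- max(v)
  if (mx <= mn) {
    grid <- array(1L, dim = dim(volume))
  } else {
    grid <- floor((volume - mn) / (mx - mn) * G) + 1L
    grid[grid > G] <- as.integer(G)   # the masked maximum lands in level G
    grid[grid < 1L] <- 1L
    storage.mode(grid) <- "integer"
  }
  structure(list(grid = grid, G = as.integer(G), mask = mask),
            class = "quantized_volume")
}

## Canonical direction sets: offsets with components in {-1,0,1}, first
## non-zero component positive (so each undirected axis appears once).
glcm_directions_3d <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- apply(d, 1, function(v) {
    nz <- which(v != 0)
    length(nz) > 0 && v[nz[1]] > 0
  })
  unname(d[keep, , drop = FALSE])
}

glcm_directions_2d <- function() {
  rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
}

## Masked voxel positions as an N x k integer matrix (k = 2 or 3).
mask_positions <- function(mask) {
  which(mask, arr.ind = TRUE)
}

## Linear index of positions in an array of dims `dims`.
pos_to_linear <- function(pos, dims) {
  k <- length(dims)
  idx <- pos[, 1]
  mult <- 1
  if (k >= 2) { mult <- dims[1]; idx <- idx + (pos[, 2] - 1) * mult }
  if (k >= 3) { mult <- mult * dims[2]; idx <- idx + (pos[, 3] - 1) * mult }
  idx
}

## Index pairs (ia, ib) of in-mask voxel pairs separated by `offset`
## (already multiplied by the distance).  Used by GLCM accumulation.
offset_pairs <- function(mask, pos, offset) {
  dims <- dim(mask)
  k <- length(dims)
  q <- pos + matrix(rep(as.integer(offset), each = nrow(pos)), ncol = k)
  ok <- rep(TRUE, nrow(q))
  for (ax in seq_len(k)) ok <- ok & q[, ax] >= 1L & q[, ax] <= dims[ax]
  ia <- pos_to_linear(pos[ok, , drop = FALSE], dims)
  ib <- pos_to_linear(q[ok, , drop = FALSE], dims)
  inm <- mask[ib]
  list(ia = ia[inm], ib = ib[inm])
}
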