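## Gray-level co-occurrence features (Haralick family).
## The matrix P(i, j) is the relative frequency of in-mask voxel pairs at a
## fixed spatial offset having levels (i, j), accumulated symmetrically
## (each ordered pair counted in both orientations) and normalised to sum 1.

glcm_feature_names <- function() {
  c("autocorrelation", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_entropy",
    "difference_variance", "dissimilarity", "energy", "entropy",
    "inverse_difference", "inverse_difference_moment", "idmn", "idn",
    "inverse_variance", "max_probability", "sum_average", "sum_entropy")
}

## cached per-G index grids (row level i, column level j, |i-j|, i+j)
.glcm_cache <- new.env(parent = emptyenv())
glcm_grids <- function(G) {
  key <- as.character(G)
  if (is.null(.glcm_cache[[key]])) {
    i <- matrix(rep(seq_len(G), G), nrow = G)        # row index
    j <- t(i)                                        # column index
    .glcm_cache[[key]] <- list(i = i, j = j, absd = abs(i - j), s = i + j)
  }
  .glcm_cache[[key]]
}

#' Build a gray-level co-occurrence matrix
#'
#' @param q a [quantize()]d volume.
#' @param offset integer offset vector (direction times distance), length
#'   matching the array dimensionality.
#' @param symmetric accumulate each pair in both orientations (default).
#' @return list of class `glc_matrix`: `P` (GxG probability matrix summing
#'   to 1), `n_pairs` (ordered pair count), `mu_x`, `mu_y`; or `NULL` when
#'   no valid in-mask pair exists at the offset.
#' @export
glcm_matrix <- function(q, offset, symmetric = TRUE) {
  pos <- mask_positions(q$mask)
  pr <- offset_pairs(q$mask, pos, offset)
  if (length(pr$ia) == 0L) return(NULL)
  G <- q$G
  a <- q$grid[pr$ia]; b <- q$grid[pr$ib]
  counts <- tabulate(a + (b - 1L) * G, nbins = G * G)
  Pm <- matrix(counts, G, G)
  if (symmetric) Pm <- Pm + t(Pm)
  n_pairs <- sum(Pm)
  P <- Pm / n_pairs
  px <- rowSums(P); py <- colSums(P)
  lev <- seq_len(G)
  structure(list(P = P, n_pairs = n_pairs,
                 mu_x = sum(lev * px), mu_y = sum(lev * py)),
            class = "glc_matrix")
}

glcm_features_from_matrix <- function(m, G) {
  g <- glcm_grids(G)
  P <- m$P
  lev <- seq_len(G)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- m$mu_x; mu_y <- m$mu_y
  sx <- sqrt(sum((lev - mu_x)^2 * px))
  sy <- sqrt(sum((lev - mu_y)^2 * py))
  dev <- g$s - mu_x - mu_y

  # marginal distributions of |i-j| (k = 0..G-1) and i+j (k = 2..2G)
  pd <- tabulate_weighted(g$absd + 1L, P, G)              # index k+1
  ps <- tabulate_weighted(g$s - 1L, P, 2L * G - 1L)       # index (i+j)-1
  kd <- 0:(G - 1L)
  ks <- 2:(2L * G)
  mu_d <- sum(kd * pd)

  autoc <- sum(g$i * g$j * P)
  corr <- if (sx * sy > 0) (autoc - mu_x * mu_y) / (sx * sy) else 0
  offdiag <- g$absd > 0

  c(autocorrelation = autoc,
    cluster_prominence = sum(dev^4 * P),
    cluster_shade = sum(dev^3 * P),
    cluster_tendency = sum(dev^2 * P),
    contrast = sum(g$absd^2 * P),
    correlation = corr,
    difference_entropy = shannon_entropy(pd),
    difference_variance = sum((kd - mu_d)^2 * pd),
    dissimilarity = sum(g$absd * P),
    energy = sum(P^2),
    entropy = shannon_entropy(P),
    inverse_difference = sum(P / (1 + g$absd)),
    inverse_difference_moment = sum(P / (1 + g$absd^2)),
    idmn = sum(P / (1 + (g$absd / G)^2)),
    idn = sum(P / (1 + g$absd / G)),
    inverse_variance = sum(P[offdiag] / g$absd[offdiag]^2),
    max_probability = max(P),
    sum_average = sum(ks * ps),
    sum_entropy = shannon_entropy(ps))
}

## sum weights `w` into bins given by integer `bin` (both same-shape)
tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  s <- rowsum(as.vector(w), as.vector(bin))
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Co-occurrence features at one offset
#'
#' Computes the 19 Haralick-style features, including cluster shade
#' `sum_ij (i + j - mu_x - mu_y)^3 P(i, j)`, from the symmetric normalised
#' co-occurrence matrix at the given offset.  When no valid voxel pair
#' exists at the offset every feature is returned as `NA` (missing, not
#' zero).
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of length 19.
#' @export
glcm_features <- function(q, offset, symmetric = TRUE) {
  m <- glcm_matrix(q, offset, symmetric)
  nm <- glcm_feature_names()
  if (is.null(m)) return(setNames(rep(NA_real_, length(nm)), nm))
  glcm_features_from_matrix(m, q$G)
}

## direction-averaged features at a given distance (used by the bank)
glcm_features_avg <- function(q, directions, distance, pair_cache = NULL) {
  nm <- glcm_feature_names()
  acc <- matrix(NA_real_, nrow = nrow(directions), ncol = length(nm))
  G <- q$G
  for (r in seq_len(nrow(directions))) {
    pr <- if (!is.null(pair_cache)) pair_cache[[r]] else
      offset_pairs(q$mask, mask_positions(q$mask), directions[r, ] * distance)
    if (length(pr$ia) == 0L) next
    a <- q$grid[pr$ia]; b <- q$grid[pr$ib]
    counts <- tabulate(a + (b - 1L) * G, nbins = G * G)
    Pm <- matrix(counts, G, G)
    Pm <- Pm + t(Pm)
    P <- Pm / sum(Pm)
    lev <- seq_len(G)
    m <- list(P = P, mu_x = sum(lev * rowSums(P)), mu_y = sum(lev * colSums(P)))
    acc[r, ] <- glcm_features_from_matrix(m, G)
  }
  setNames(colMeans(acc, na.rm = TRUE), nm)
}
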