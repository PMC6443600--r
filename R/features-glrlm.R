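## Gray-level run-length features (Galloway family).
## A run is a maximal segment of consecutive in-mask voxels of one gray
## level along a direction; R(i, j) counts runs of level i and length j.

glrlm_feature_names <- function() {
  c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
    "srlge", "srhge", "lrlge", "lrhge")
}

## Enumerate runs along direction `d` (components in {-1,0,1}, first
## non-zero component +1).  Voxels on one line share the anchor
## `pos - t*d` where t is the coordinate along the first moving axis;
## sorting by (line key, t) makes run extraction a vectorised scan.
enumerate_runs <- function(q, d) {
  pos <- mask_positions(q$mask)
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 1)
  k <- ncol(pos)
  d <- as.integer(d[seq_len(k)])
  ax <- which(d != 0)[1]
  t <- pos[, ax]
  anchor <- pos - t %o% d
  dims <- dim(q$mask)
  span <- max(dims) * 3L
  key <- numeric(nrow(pos))
  for (c_ in seq_len(k)) key <- key * span + (anchor[, c_] + max(dims))
  lv <- q$grid[pos_to_linear(pos, dims)]
  o <- order(key, t)
  key <- key[o]; t <- t[o]; lv <- lv[o]
  n <- length(lv)
  if (n == 0L) return(list(level = integer(0), length = integer(0)))
  newrun <- c(TRUE, key[-1] != key[-n] | t[-1] != t[-n] + 1L | lv[-1] != lv[-n])
  starts <- which(newrun)
  len <- diff(c(starts, n + 1L))
  list(level = lv[starts], length = len)
}

glrlm_from_runs <- function(level, len, G, n_voxels) {
  nm <- glrlm_feature_names()
  N_r <- length(level)
  if (N_r == 0L) return(setNames(rep(NA_real_, length(nm)), nm))
  i2 <- as.numeric(level)^2
  j2 <- as.numeric(len)^2
  gl_counts <- tabulate(level, nbins = G)
  rl_counts <- tabulate(len, nbins = max(len))
  c(sre = sum(1 / j2) / N_r,
    lre = sum(j2) / N_r,
    gln = sum(gl_counts^2) / N_r,
    rln = sum(rl_counts^2) / N_r,
    rp = N_r / n_voxels,
    lgre = sum(1 / i2) / N_r,
    hgre = sum(i2) / N_r,
    srlge = sum(1 / (i2 * j2)) / N_r,
    srhge = sum(i2 / j2) / N_r,
    lrlge = sum(j2 / i2) / N_r,
    lrhge = sum(i2 * j2) / N_r)
}

#' Run-length features along one direction
#'
#' Computes the 11 Galloway-style run-length features, including low
#' gray-level run emphasis `LGRE = (1/N_r) sum_ij R(i, j) / i^2`, from the
#' run-length matrix accumulated along `direction` inside the mask.
#'
#' @param q a [quantize()]d volume.
#' @param direction integer unit offset (components in -1/0/1, first
#'   non-zero positive), length matching the array dimensionality.
#' @return named numeric vector of length 11.
#' @export
glrlm_features <- function(q, direction) {
  if (!any(q$mask)) stop_invalid("mask is empty")
  runs <- enumerate_runs(q, direction)
  glrlm_from_runs(runs$level, runs$length, q$G, sum(q$mask))
}

#' Run-length matrix along one direction
#'
#' @inheritParams glrlm_features
#' @return list of class `run_length_matrix`: `R` (G x L count matrix),
#'   `N_r` total run count.
#' @export
glrlm_matrix <- function(q, direction) {
  runs <- enumerate_runs(q, direction)
  L <- max(runs$length, 1L)
  R <- matrix(tabulate(runs$level + (runs$length - 1L) * q$G, nbins = q$G * L),
              q$G, L)
  structure(list(R = R, N_r = sum(R)), class = "run_length_matrix")
}

glrlm_features_avg <- function(q, directions) {
  vals <- t(vapply(seq_len(nrow(directions)),
                   function(r) glrlm_features(q, directions[r, ]),
                   numeric(length(glrlm_feature_names()))))
  setNames(colMeans(vals, na.rm = TRUE), glrlm_feature_names())
}
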