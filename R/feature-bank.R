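#' Configuration of the texture feature bank
#'
#' The default grid is sized so that a full extraction yields exactly
#' 356 three-dimensional and 236 two-dimensional features per patient:
#' \itemize{
#'   \item 3-D: 8 first-order + 19 co-occurrence features x 4 quantization
#'     levels (8, 16, 32, 64) x 4 distances (1-4 voxels), averaged over the
#'     13 canonical 3-D directions, + 11 run-length features x 4 levels
#'     (13-direction averaged) = 8 + 304 + 44 = 356.
#'   \item 2-D (per axial slice, unweighted mean over mask-intersecting
#'     slices): 8 first-order + 19 co-occurrence x 4 levels x 2 distances
#'     (4-direction averaged) + 11 run-length x 4 levels + Gabor
#'     variance/entropy at 4 frequencies x 4 orientations
#'     = 8 + 152 + 44 + 32 = 236.
#' }
#'
#' @param quantization_levels integer vector of gray-level counts (all >= 2).
#' @param glcm_distances_3d,glcm_distances_2d voxel distances (>= 1).
#' @param gabor_frequencies cycles/voxel in `(0, 0.5]`.
#' @param gabor_orientations angles in degrees.
#' @return object of class `feature_bank_config`.
#' @export
feature_bank_config <- function(quantization_levels = c(8, 16, 32, 64),
                                glcm_distances_3d = c(1, 2, 3, 4),
                                glcm_distances_2d = c(1, 2),
                                gabor_frequencies = c(0.05, 0.1, 0.2, 0.4),
                                gabor_orientations = c(0, 45, 90, 135)) {
  if (any(quantization_levels < 2)) stop_invalid("quantization levels must be >= 2")
  if (any(c(glcm_distances_3d, glcm_distances_2d) < 1)) stop_invalid("distances must be >= 1")
  if (any(gabor_frequencies <= 0 | gabor_frequencies > 0.5))
    stop_invalid("gabor frequencies must lie in (0, 0.5]")
  structure(list(quantization_levels = as.integer(quantization_levels),
                 glcm_distances_3d = as.integer(glcm_distances_3d),
                 glcm_distances_2d = as.integer(glcm_distances_2d),
                 gabor_frequencies = gabor_frequencies,
                 gabor_orientations = gabor_orientations),
            class = "feature_bank_config")
}

#' Feature manifest: id, family, dimensionality and parameters
#'
#' The id set is a pure function of the configuration and is identical for
#' every patient.
#'
#' @param config a [feature_bank_config()].
#' @return data.frame with columns `id`, `family`, `dim`, `levels`,
#'   `distance`, `frequency`, `orientation`, `feature`.
#' @export
feature_manifest <- function(config = feature_bank_config()) {
  rows <- list()
  add <- function(id, family, dim, feature, levels = NA, distance = NA,
                  frequency = NA, orientation = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, family = family, dim = dim, feature = feature,
      levels = levels, distance = distance, frequency = frequency,
      orientation = orientation, stringsAsFactors = FALSE)
  }
  for (f in first_order_names()) add(paste0("fo3d_", f), "first_order", "3D", f)
  for (G in config$quantization_levels)
    for (d in config$glcm_distances_3d)
      for (f in glcm_feature_names())
        add(sprintf("glcm3d_G%d_d%d_%s", G, d, f), "glcm", "3D", f, G, d)
  for (G in config$quantization_levels)
    for (f in glrlm_feature_names())
      add(sprintf("glrlm3d_G%d_%s", G, f), "glrlm", "3D", f, G)
  for (f in first_order_names()) add(paste0("fo2d_", f), "first_order", "2D", f)
  for (G in config$quantization_levels)
    for (d in config$glcm_distances_2d)
      for (f in glcm_feature_names())
        add(sprintf("glcm2d_G%d_d%d_%s", G, d, f), "glcm", "2D", f, G, d)
  for (G in config$quantization_levels)
    for (f in glrlm_feature_names())
      add(sprintf("glrlm2d_G%d_%s", G, f), "glrlm", "2D", f, G)
  for (fr in config$gabor_frequencies)
    for (o in config$gabor_orientations)
      for (f in c("variance", "entropy"))
        add(sprintf("gabor2d_f%g_o%g_%s", fr, o, f), "gabor", "2D", f,
            frequency = fr, orientation = o)
  do.call(rbind, rows)
}

#' Extract the full feature bank from one phantom
#'
#' 3-D features are computed on the whole masked volume with
#' direction-averaged co-occurrence and run-length statistics; 2-D features
#' are computed per axial slice (slices intersecting the mask, each slice
#' quantized on its own masked range) and aggregated by unweighted mean.
#' Any feature undefined on a slice (e.g. no voxel pair at an offset) is
#' skipped in the slice mean; a feature undefined everywhere is `NA`.
#'
#' @param phantom a [generate_tumor_phantom()] result, or any list with
#'   numeric `volume` and logical `mask` arrays of equal shape.
#' @param config a [feature_bank_config()].
#' @return named numeric vector; with the default configuration its length
#'   is 592 (356 3-D + 236 2-D).
#' @export
extract_feature_bank <- function(phantom, config = feature_bank_config()) {
  vol <- phantom$volume; mask <- phantom$mask
  if (is.null(vol) || is.null(mask) || !any(mask))
    stop_invalid("phantom must carry a volume and a non-empty mask")
  out <- numeric(0)

  ## ---- 3-D ----
  out <- c(out, setNames(first_order_features(vol, mask),
                         paste0("fo3d_", first_order_names())))
  dirs3 <- glcm_directions_3d()
  pos <- mask_positions(mask)
  pair_cache <- lapply(config$glcm_distances_3d, function(d)
    lapply(seq_len(nrow(dirs3)), function(r)
      offset_pairs(mask, pos, dirs3[r, ] * d)))
  qs <- lapply(config$quantization_levels, function(G) quantize(vol, mask, G))
  for (gi in seq_along(config$quantization_levels)) {
    G <- config$quantization_levels[gi]
    for (di in seq_along(config$glcm_distances_3d)) {
      d <- config$glcm_distances_3d[di]
      v <- glcm_features_avg(qs[[gi]], dirs3, d, pair_cache[[di]])
      names(v) <- sprintf("glcm3d_G%d_d%d_%s", G, d, glcm_feature_names())
      out <- c(out, v)
    }
  }
  for (gi in seq_along(config$quantization_levels)) {
    G <- config$quantization_levels[gi]
    v <- glrlm_features_avg(qs[[gi]], dirs3)
    names(v) <- sprintf("glrlm3d_G%d_%s", G, glrlm_feature_names())
    out <- c(out, v)
  }

  ## ---- 2-D (axial slices) ----
  zs <- which(apply(mask, 3, any))
  dirs2 <- glcm_directions_2d()
  nm_fo <- first_order_names(); nm_gl <- glcm_feature_names()
  nm_rl <- glrlm_feature_names()
  fo_acc <- matrix(NA_real_, length(zs), length(nm_fo))
  gl_acc <- array(NA_real_, c(length(zs), length(config$quantization_levels),
                              length(config$glcm_distances_2d), length(nm_gl)))
  rl_acc <- array(NA_real_, c(length(zs), length(config$quantization_levels),
                              length(nm_rl)))
  gb_acc <- array(NA_real_, c(length(zs), length(config$gabor_frequencies),
                              length(config$gabor_orientations), 2L))
  for (si in seq_along(zs)) {
    z <- zs[si]
    sl <- vol[, , z]; mk <- mask[, , z]
    fo_acc[si, ] <- first_order_features(sl, mk)
    pos2 <- mask_positions(mk)
    pc2 <- lapply(config$glcm_distances_2d, function(d)
      lapply(seq_len(nrow(dirs2)), function(r)
        offset_pairs(mk, pos2, dirs2[r, ] * d)))
    for (gi in seq_along(config$quantization_levels)) {
      q2 <- quantize(sl, mk, config$quantization_levels[gi])
      for (di in seq_along(config$glcm_distances_2d))
        gl_acc[si, gi, di, ] <- glcm_features_avg(q2, dirs2,
                                                  config$glcm_distances_2d[di],
                                                  pc2[[di]])
      rl_acc[si, gi, ] <- glrlm_features_avg(q2, dirs2)
    }
    for (fi in seq_along(config$gabor_frequencies))
      for (oi in seq_along(config$gabor_orientations))
        # low frequencies give kernels wider than small slices; linear
        # zero-padded convolution handles that, so the per-call warning
        # is routine here
        gb_acc[si, fi, oi, ] <- suppressWarnings(gabor_features(
          sl, mk, config$gabor_frequencies[fi],
          config$gabor_orientations[oi] * pi / 180))
  }
  slice_mean <- function(x) {
    m <- colMeans(x, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }
  out <- c(out, setNames(slice_mean(fo_acc), paste0("fo2d_", nm_fo)))
  for (gi in seq_along(config$quantization_levels)) {
    G <- config$quantization_levels[gi]
    for (di in seq_along(config$glcm_distances_2d)) {
      d <- config$glcm_distances_2d[di]
      v <- slice_mean(matrix(gl_acc[, gi, di, ], ncol = length(nm_gl)))
      out <- c(out, setNames(v, sprintf("glcm2d_G%d_d%d_%s", G, d, nm_gl)))
    }
  }
  for (gi in seq_along(config$quantization_levels)) {
    G <- config$quantization_levels[gi]
    v <- slice_mean(matrix(rl_acc[, gi, ], ncol = length(nm_rl)))
    out <- c(out, setNames(v, sprintf("glrlm2d_G%d_%s", G, nm_rl)))
  }
  for (fi in seq_along(config$gabor_frequencies))
    for (oi in seq_along(config$gabor_orientations)) {
      v <- slice_mean(matrix(gb_acc[, fi, oi, ], ncol = 2L))
      out <- c(out, setNames(v, sprintf("gabor2d_f%g_o%g_%s",
                                        config$gabor_frequencies[fi],
                                        config$gabor_orientations[oi],
                                        c("variance", "entropy"))))
    }
  out
}

#' Extract features for every phantom of a cohort
#'
#' @param x a `synthetic_cohort` with phantoms, or a named list of
#'   phantoms.
#' @param config a [feature_bank_config()].
#' @return numeric matrix, rows = patients (named), columns = feature ids.
#' @export
extract_cohort_features <- function(x, config = feature_bank_config()) {
  phantoms <- if (inherits(x, "synthetic_cohort")) x$phantoms else x
  if (is.null(phantoms)) stop_invalid("cohort carries no images")
  t(vapply(phantoms, extract_feature_bank, config = config,
           FUN.VALUE = numeric(nrow(feature_manifest(config)))))
}

#' Read a volume/mask NIfTI pair and extract its feature bank
#'
#' @param volume_path,mask_path NIfTI file paths.
#' @inheritParams extract_feature_bank
#' @return named numeric vector of features.
#' @export
extract_from_nifti <- function(volume_path, mask_path,
                               config = feature_bank_config()) {
  vol <- as.array(RNifti::readNifti(volume_path))
  msk <- as.array(RNifti::readNifti(mask_path)) > 0
  extract_feature_bank(list(volume = vol, mask = msk), config)
}

#' Write a feature matrix and its manifest
#'
#' @param features matrix from [extract_cohort_features()].
#' @param dir output directory.
#' @param config the generating [feature_bank_config()].
#' @return invisibly, the path of `features.csv`.
#' @export
write_features <- function(features, dir, config = feature_bank_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(id = rownames(features), features, check.names = FALSE)
  write.csv(df, file.path(dir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(feature_manifest(config),
                       file.path(dir, "feature_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "features.csv"))
}
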