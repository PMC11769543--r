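# Preprocessing recipe: dataset-level percentile clipping, isotropic
# resampling to 1.0 mm, z-score normalization from pooled statistics.

#' Dataset-level intensity statistics
#'
#' Pools the voxel values of all training volumes, takes the 0.5th and
#' 99.5th percentiles (linear interpolation between order statistics) as the
#' clipping window, and computes the mean and standard deviation of the
#' pooled values after clipping. These statistics are frozen at training time
#' and reused verbatim at inference.
#'
#' @param volumes A list of [ct_volume()] objects (or a single one).
#' @param lower,upper Percentile bounds as fractions (defaults 0.005/0.995).
#' @param per_image If `TRUE`, return a list of per-volume statistics instead
#'   of pooled ones (ablation mode; pooled is the default behaviour).
#' @return An object of class `intensity_stats` with fields `lower_clip`,
#'   `upper_clip`, `mean`, `std`, `n_voxels`.
#' @export
compute_intensity_stats <- function(volumes, lower = 0.005, upper = 0.995,
                                    per_image = FALSE) {
  if (inherits(volumes, "ct_volume")) volumes <- list(volumes)
  if (length(volumes) == 0L) stopf("need at least one volume")
  if (per_image)
    return(lapply(volumes, compute_intensity_stats, lower = lower,
                  upper = upper))
  values <- unlist(lapply(volumes, function(v) as.vector(v$data)),
                   use.names = FALSE)
  if (length(values) < 2L) stopf("pooled voxel count must be >= 2")
  q <- stats::quantile(values, c(lower, upper), names = FALSE, type = 7)
  clipped <- pmin(pmax(values, q[1]), q[2])
  structure(list(lower_clip = q[1], upper_clip = q[2],
                 mean = mean(clipped), std = stats::sd(clipped),
                 n_voxels = length(values)),
            class = "intensity_stats")
}

#' @export
print.intensity_stats <- function(x, ...) {
  cat(sprintf(
    "intensity_stats: clip [%.2f, %.2f], mean %.3f, sd %.3f (n=%d)\n",
    x$lower_clip, x$upper_clip, x$mean, x$std, x$n_voxels))
  invisible(x)
}

#' Clip and z-score normalize a volume
#'
#' Clips intensities to the statistics' window and maps them to zero mean
#' and unit variance: `(clip(v) - mean) / std`. Spacing is unchanged.
#'
#' @param vol A [ct_volume()].
#' @param stats An [compute_intensity_stats()] result with `std > 0`.
#' @return The normalized `ct_volume`.
#' @export
clip_and_normalize <- function(vol, stats) {
  stopifnot(inherits(vol, "ct_volume"), inherits(stats, "intensity_stats"))
  if (!is.finite(stats$std) || stats$std <= 0)
    stopf(paste("cannot normalize: the intensity standard deviation is 0",
                "(constant data); z-scoring is undefined"))
  dat <- (pmin(pmax(vol$data, stats$lower_clip), stats$upper_clip) -
            stats$mean) / stats$std
  ct_volume(dat, vol$spacing, vol$origin)
}

#' Resample a volume or mask to isotropic spacing
#'
#' Output extents are `round(extent * spacing / target)` per axis (half away
#' from zero, minimum 1). Images are interpolated trilinearly, label masks by
#' nearest neighbour so labels stay in {0,1,2}.
#'
#' @param x A `ct_volume` or `label_mask`.
#' @param target_spacing Target isotropic voxel size in mm (default 1.0).
#' @return The resampled object with spacing `(t, t, t)`.
#' @export
resample_isotropic <- function(x, target_spacing = 1.0) {
  stopifnot(is_grid(x))
  t <- as.numeric(target_spacing)
  if (!is.finite(t) || t <= 0) stopf("target_spacing must be > 0")
  in_dims <- grid_dim(x)
  out_dims <- pmax(1L, as.integer(round_half_away(in_dims * x$spacing / t)))
  if (identical(out_dims, in_dims) && max(abs(x$spacing - t)) < 1e-12) {
    out <- x
    out$spacing <- rep(t, 3L)
    return(out)
  }
  # output voxel i maps to input coordinate (i + 0.5) * t / spacing - 0.5
  scale <- t / x$spacing
  A <- cbind(diag(scale), 0.5 * scale - 0.5)
  is_mask <- inherits(x, "label_mask")
  res <- .resampleAffine3d(as.numeric(x$data), as.integer(in_dims), A,
                           as.integer(out_dims),
                           if (is_mask) 1L else 0L,
                           if (is_mask) 0 else min(x$data))
  arr <- array(res, out_dims)
  if (is_mask) label_mask(arr, rep(t, 3L), x$origin)
  else ct_volume(arr, rep(t, 3L), x$origin)
}

#' Preprocess a case for the segmentation pipeline
#'
#' Resamples image (and optional mask) to isotropic spacing, then clips and
#' normalizes the image with frozen dataset statistics.
#'
#' @param vol A [ct_volume()] in native spacing.
#' @param stats Frozen [compute_intensity_stats()].
#' @param mask Optional paired [label_mask()].
#' @param target_spacing Isotropic target in mm (default 1.0).
#' @return A list with `vol` (normalized) and `mask` (or `NULL`).
#' @export
preprocess_case <- function(vol, stats, mask = NULL, target_spacing = 1.0) {
  v <- clip_and_normalize(resample_isotropic(vol, target_spacing), stats)
  m <- if (!is.null(mask)) resample_isotropic(mask, target_spacing)
  list(vol = v, mask = m)
}

# Serialize / restore stats through plain-text configs.
stats_to_list <- function(stats) {
  lapply(unclass(stats), as.numeric)
}
stats_from_list <- function(x) {
  structure(list(lower_clip = x$lower_clip, upper_clip = x$upper_clip,
                 mean = x$mean, std = x$std,
                 n_voxels = as.integer(x$n_voxels %||% 0L)),
            class = "intensity_stats")
}
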