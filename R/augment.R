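# Training-time augmentation: random rotations, scaling, mirroring, axis
# transposition, gamma correction. The same sampled geometric transform is
# applied to image (linear interpolation) and mask (nearest neighbour);
# gamma applies to the image only.

#' Augmentation parameters
#'
#' The transform families follow common 3D segmentation practice: rotations
#' up to ±30° per axis, scaling in 0.85-1.25, mirroring on all axes,
#' transposition of the two in-plane axes, gamma in 0.7-1.5. Every
#' magnitude and probability is overridable.
#'
#' @param rotation_range Max absolute rotation per axis, degrees.
#' @param scale_range Multiplicative scale range (length 2, positive).
#' @param mirror_axes Axes eligible for mirroring (subset of 1:3).
#' @param transpose_enabled Allow swapping the two in-plane axes?
#' @param gamma_range Gamma exponent range (length 2, positive).
#' @param p_rotation,p_scale,p_mirror,p_transpose,p_gamma Per-transform
#'   application probabilities (mirroring is decided per axis).
#' @return An object of class `augment_params`.
#' @export
augment_params <- function(rotation_range = 30,
                           scale_range = c(0.85, 1.25),
                           mirror_axes = 1:3,
                           transpose_enabled = TRUE,
                           gamma_range = c(0.7, 1.5),
                           p_rotation = 0.3, p_scale = 0.3, p_mirror = 0.5,
                           p_transpose = 0.2, p_gamma = 0.3) {
  if (any(scale_range <= 0) || any(gamma_range <= 0))
    stopf("scale_range and gamma_range bounds must be strictly positive")
  ps <- c(p_rotation, p_scale, p_mirror, p_transpose, p_gamma)
  if (any(ps < 0 | ps > 1)) stopf("probabilities must lie in [0,1]")
  structure(list(rotation_range = rotation_range, scale_range = scale_range,
                 mirror_axes = as.integer(mirror_axes),
                 transpose_enabled = isTRUE(transpose_enabled),
                 gamma_range = gamma_range,
                 p_rotation = p_rotation, p_scale = p_scale,
                 p_mirror = p_mirror, p_transpose = p_transpose,
                 p_gamma = p_gamma),
            class = "augment_params")
}

rotation_matrix_3d <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Resample on the fixed grid through a centre-fixed rotation+scale (no
# canvas growth); out-of-canvas voxels are filled with the image background
# (its minimum value) / label 0.
apply_rot_scale <- function(arr, angles_deg, scale, mode, fill) {
  dims <- dim(arr)
  ctr <- (dims - 1) / 2
  Rinv <- t(rotation_matrix_3d(angles_deg))   # inverse of a rotation
  M <- Rinv / scale
  offset <- ctr - M %*% ctr
  A <- cbind(M, offset)
  array(.resampleAffine3d(as.numeric(arr), as.integer(dims), A,
                          as.integer(dims), mode, fill), dims)
}

flip_axis <- function(arr, axis) {
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- rev(seq_len(dim(arr)[axis]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Randomly augment a paired image and mask
#'
#' Samples one transform configuration and applies the identical geometry to
#' both inputs. Gamma correction maps intensities through
#' `v -> ((v - min)/(max - min))^gamma`, rescaled back to the original range.
#'
#' @param vol A [ct_volume()] (typically normalized).
#' @param mask The paired [label_mask()] on the same grid.
#' @param params An [augment_params()].
#' @param rng Optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @return A list with augmented `vol` and `mask`.
#' @export
random_augment <- function(vol, mask, params = augment_params(), rng = NULL) {
  stopifnot(inherits(vol, "ct_volume"), inherits(mask, "label_mask"),
            inherits(params, "augment_params"))
  check_same_grid(vol, mask)
  with_seed(rng, {
    img <- vol$data
    lab <- mask$data
    spacing_v <- vol$spacing
    do_rot <- stats::runif(1) < params$p_rotation
    do_scale <- stats::runif(1) < params$p_scale
    angles <- if (do_rot)
      stats::runif(3, -params$rotation_range, params$rotation_range)
    else c(0, 0, 0)
    scl <- if (do_scale)
      stats::runif(1, params$scale_range[1], params$scale_range[2]) else 1
    if (do_rot || do_scale) {
      img <- apply_rot_scale(img, angles, scl, 0L, min(img))
      lab <- apply_rot_scale(lab, angles, scl, 1L, 0)
    }
    for (ax in params$mirror_axes) {
      if (stats::runif(1) < params$p_mirror) {
        img <- flip_axis(img, ax)
        lab <- flip_axis(lab, ax)
      }
    }
    if (params$transpose_enabled && stats::runif(1) < params$p_transpose) {
      img <- aperm(img, c(2, 1, 3))
      lab <- aperm(lab, c(2, 1, 3))
      spacing_v <- spacing_v[c(2, 1, 3)]
    }
    if (stats::runif(1) < params$p_gamma) {
      gamma <- stats::runif(1, params$gamma_range[1], params$gamma_range[2])
      rng_lo <- min(img); rng_hi <- max(img)
      if (rng_hi > rng_lo) {
        img <- ((img - rng_lo) / (rng_hi - rng_lo))^gamma *
          (rng_hi - rng_lo) + rng_lo
      }
    }
    list(vol = ct_volume(img, spacing_v, vol$origin),
         mask = label_mask(round(lab), spacing_v, mask$origin))
  })
}
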