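# Parametric CT phantoms: a soft-tissue body ellipsoid, bright bilateral
# kidney ellipsoids, tumors of controlled unidirectional diameter and
# contrast, a high-density spine cylinder (a decoy for false positives),
# and additive Gaussian noise. Geometry is painted analytically at voxel
# centres, so the ground truth is exact.

#' Phantom specification
#'
#' Intensities are Hounsfield-like: air background -1000, soft tissue ~40,
#' kidney parenchyma ~120 (contrast-enhanced), spine ~700. Tumors take the
#' kidney intensity plus `intensity_offset`. Two presets are provided:
#' `"desk"` (64^3 grid at 1 mm, small tumors, suitable for CPU training) and
#' `"full"` (96^3 at 2 mm, room for the whole TNM size range).
#'
#' @param extent Grid extents (voxels), length 3.
#' @param spacing Voxel size in mm, length 3 (possibly anisotropic).
#' @param body_hu,kidney_hu,spine_hu Tissue intensities (HU).
#' @param background_hu Air background (HU).
#' @param noise_sd Additive Gaussian noise sd (HU).
#' @param tumors A list of tumor specs, each a list with `centre` (voxel
#'   coords, 1-based, may be fractional), `ud_cm` (target unidirectional
#'   diameter), `intensity_offset` (HU relative to kidney), `exophytic` flag.
#'   `centre = NULL` lets the generator place the tumor on a kidney.
#' @param kidney_centres,kidney_radii Kidney ellipsoid geometry (mm, in
#'   physical coordinates); defaults scale with the grid.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(extent = c(64L, 64L, 64L),
                         spacing = c(1, 1, 1),
                         body_hu = 40, kidney_hu = 120, spine_hu = 700,
                         background_hu = -1000, noise_sd = 10,
                         tumors = list(),
                         kidney_centres = NULL, kidney_radii = NULL) {
  extent <- as.integer(extent)
  fov <- extent * spacing
  ctr <- fov / 2
  if (is.null(kidney_centres)) {
    off <- 0.28 * fov[1]
    kidney_centres <- list(ctr - c(off, 0, 0), ctr + c(off, 0, 0))
  }
  if (is.null(kidney_radii)) {
    r <- c(0.13, 0.11, 0.18) * min(fov)
    kidney_radii <- list(r, r)
  }
  for (tm in tumors) {
    if (!is.null(tm$ud_cm) && (tm$ud_cm < 0.5 || tm$ud_cm > 10))
      stopf("tumor target UD must lie in [0.5, 10] cm, got %.2f", tm$ud_cm)
  }
  if (!(background_hu < body_hu && body_hu < kidney_hu &&
        kidney_hu < spine_hu))
    stopf("intensities must be ordered background < body < kidney < spine")
  structure(list(extent = extent, spacing = as.numeric(spacing),
                 body_hu = body_hu, kidney_hu = kidney_hu,
                 spine_hu = spine_hu, background_hu = background_hu,
                 noise_sd = noise_sd, tumors = tumors,
                 kidney_centres = kidney_centres,
                 kidney_radii = kidney_radii,
                 body_radii = 0.46 * fov,
                 spine_centre_xy = c(ctr[1], ctr[2] + 0.30 * fov[2]),
                 spine_radius = 0.06 * min(fov[1:2])),
            class = "phantom_spec")
}

ellipsoid_mask <- function(coords, centre, radii) {
  ((coords$x - centre[1]) / radii[1])^2 +
    ((coords$y - centre[2]) / radii[2])^2 +
    ((coords$z - centre[3]) / radii[3])^2 <= 1
}

phantom_coords <- function(extent, spacing) {
  cx <- (seq_len(extent[1]) - 0.5) * spacing[1]
  cy <- (seq_len(extent[2]) - 0.5) * spacing[2]
  cz <- (seq_len(extent[3]) - 0.5) * spacing[3]
  list(x = array(rep(cx, times = extent[2] * extent[3]), extent),
       y = array(rep(rep(cy, each = extent[1]), times = extent[3]), extent),
       z = array(rep(cz, each = extent[1] * extent[2]), extent))
}

# Snap a physical coordinate to the nearest voxel corner. Corner-centred
# spheres span an even number of voxel centres per axis (offsets +-0.5h,
# +-1.5h, ...), so a radius of r = k*h voxels paints exactly 2k centres and
# the measured unidirectional diameter hits its target within one voxel
# without the systematic +1 bias of voxel-centre snapping.
snap_to_voxel_corner <- function(p, spacing) {
  round(p / spacing) * spacing
}

#' Generate a CT phantom and its ground-truth mask
#'
#' Paints the spec's geometry (labels: kidney = 1, tumor = 2, tumor
#' overriding kidney), then adds Gaussian noise to the image. Tumors must
#' intersect or abut a kidney ellipsoid; a tumor that touches no kidney is
#' refused. Painted tumor components hit the requested unidirectional
#' diameter to within one voxel.
#'
#' @param spec A [phantom_spec()].
#' @param rng Optional integer seed.
#' @return A list with `vol` ([ct_volume()]) and `mask` ([label_mask()]).
#' @export
generate_phantom <- function(spec = phantom_spec(), rng = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(rng, {
    co <- phantom_coords(spec$extent, spec$spacing)
    img <- array(spec$background_hu, spec$extent)
    lab <- array(0L, spec$extent)
    fov <- spec$extent * spec$spacing
    body <- ellipsoid_mask(co, fov / 2, spec$body_radii)
    img[body] <- spec$body_hu
    sp_d2 <- (co$x - spec$spine_centre_xy[1])^2 +
      (co$y - spec$spine_centre_xy[2])^2
    spine <- body & (sp_d2 <= spec$spine_radius^2)
    img[spine] <- spec$spine_hu
    kid <- array(FALSE, spec$extent)
    for (k in seq_along(spec$kidney_centres)) {
      kid <- kid | ellipsoid_mask(co, spec$kidney_centres[[k]],
                                  spec$kidney_radii[[k]])
    }
    img[kid] <- spec$kidney_hu
    lab[kid] <- 1L
    for (tm in spec$tumors) {
      placed <- place_tumor(tm, spec, co, kid)
      img[placed$mask] <- spec$kidney_hu + (tm$intensity_offset %||% -50)
      lab[placed$mask] <- 2L
    }
    if (spec$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), sd = spec$noise_sd),
                         spec$extent)
    list(vol = ct_volume(img, spec$spacing),
         mask = label_mask(lab, spec$spacing))
  })
}

# Resolve a tumor's centre (sampling one if absent), paint its ellipsoid,
# and enforce the kidney-contact contract.
place_tumor <- function(tm, spec, co, kid) {
  r_cm <- (tm$ud_cm %||% 1.5) / 2
  r_mm <- r_cm * 10
  radii <- c(r_mm, r_mm, r_mm * (tm$z_ratio %||% 0.9))
  if (is.null(tm$centre_mm)) {
    k <- sample.int(length(spec$kidney_centres), 1L)
    kc <- spec$kidney_centres[[k]]
    kr <- spec$kidney_radii[[k]]
    if (isTRUE(tm$exophytic)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      centre <- kc + u * kr * 0.9
    } else if (r_mm >= min(kr)) {
      centre <- kc     # tumor as large as the kidney: centre it
    } else {
      u <- stats::runif(3, -0.5, 0.5)
      centre <- kc + u * pmax(kr - r_mm, 0)
    }
  } else {
    centre <- tm$centre_mm
  }
  centre <- snap_to_voxel_corner(centre, spec$spacing)
  centre <- pmin(pmax(centre, radii + spec$spacing),
                 spec$extent * spec$spacing - radii - spec$spacing)
  centre <- snap_to_voxel_corner(centre, spec$spacing)
  tmask <- ellipsoid_mask(co, centre, radii)
  if (!any(tmask)) stopf("tumor too small to paint at this spacing")
  touches <- any(tmask & kid)
  if (!touches) {
    # abutment: dilate the tumor by one voxel and re-test
    grown <- ellipsoid_mask(co, centre, radii + max(spec$spacing))
    touches <- any(grown & kid)
  }
  if (!touches)
    stopf("tumor at (%s) mm does not touch a kidney; refusing to generate",
          paste(format(centre, digits = 4), collapse = ", "))
  list(mask = tmask, centre = centre)
}

#' Generate a phantom cohort with a requested size mix
#'
#' Case counts per TNM category follow `size_mix` (largest-remainder
#' rounding). The `"easy"` difficulty uses high tumor contrast (-50 HU
#' against kidney) and noise sd 10; `"hard"` uses low contrast (|offset|
#' <= 20 HU) and noise sd 25. Preset `"desk"` generates 64^3 1 mm phantoms
#' whose tumors span 0.8-1.8 cm (all small); `"full"` generates 96^3 2 mm
#' phantoms spanning the whole 1-10 cm range.
#'
#' @param n Number of cases.
#' @param size_mix Fractions per category (small, medium, large); must sum
#'   to 1.
#' @param difficulty `"easy"` or `"hard"`.
#' @param seed Integer seed for the whole cohort.
#' @param preset `"full"` or `"desk"`.
#' @param out_dir If non-`NULL`, write NIfTI pairs and a manifest CSV there
#'   and return file paths; otherwise keep cases in memory.
#' @return A list with `cases` (list of `vol`/`mask` pairs or file paths)
#'   and `manifest` (data.frame: case_id, category, true_ud_cm, exophytic,
#'   seed).
#' @export
generate_cohort <- function(n, size_mix = c(small = 0.54, medium = 0.24,
                                            large = 0.22),
                            difficulty = c("easy", "hard"), seed = 1L,
                            preset = c("full", "desk"), out_dir = NULL) {
  difficulty <- match.arg(difficulty)
  preset <- match.arg(preset)
  if (n < 1L) stopf("n must be >= 1")
  if (abs(sum(size_mix) - 1) > 1e-8) stopf("size_mix fractions must sum to 1")
  counts <- largest_remainder_counts(n, size_mix)
  cats <- rep(names(counts), counts)
  noise <- if (difficulty == "easy") 10 else 25
  offset_range <- if (difficulty == "easy") c(-55, -45) else c(-20, 20)
  ud_range <- switch(preset,
                     desk = list(small = c(0.8, 1.8), medium = c(0.8, 1.8),
                                 large = c(0.8, 1.8)),
                     full = list(small = c(1.0, 3.9), medium = c(4.2, 6.9),
                                 large = c(7.2, 9.5)))
  grid <- switch(preset,
                 desk = list(extent = c(64L, 64L, 64L), spacing = c(1, 1, 1)),
                 full = list(extent = c(96L, 96L, 96L), spacing = c(2, 2, 2)))
  cases <- vector("list", n)
  man <- vector("list", n)
  with_seed(seed, {
    case_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
    cats <- sample(cats)   # shuffle category order across the cohort
    for (i in seq_len(n)) {
      with_seed(case_seeds[i], {
        ud <- stats::runif(1, ud_range[[cats[i]]][1], ud_range[[cats[i]]][2])
        exo <- stats::runif(1) < 0.25
        off <- stats::runif(1, offset_range[1], offset_range[2])
        if (difficulty == "hard" && abs(off) < 5) off <- sign(off + 1e-9) * 5
        spec <- phantom_spec(extent = grid$extent, spacing = grid$spacing,
                             noise_sd = noise,
                             tumors = list(list(ud_cm = ud,
                                                intensity_offset = off,
                                                exophytic = exo)))
        cases[[i]] <- generate_phantom(spec)
        man[[i]] <- data.frame(case_id = sprintf("case_%03d", i),
                                category = cats[i], true_ud_cm = ud,
                                exophytic = exo,
                                intensity_offset = off,
                                seed = case_seeds[i])
      })
    }
  })
  manifest <- do.call(rbind, man)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- lapply(seq_len(n), function(i) {
      vp <- file.path(out_dir, sprintf("case_%03d_image.nii.gz", i))
      mp <- file.path(out_dir, sprintf("case_%03d_mask.nii.gz", i))
      write_volume(cases[[i]]$vol, vp)
      write_volume(cases[[i]]$mask, mp)
      list(image = vp, mask = mp)
    })
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    return(list(cases = paths, manifest = manifest))
  }
  list(cases = cases, manifest = manifest)
}

largest_remainder_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}
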