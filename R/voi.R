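# Volumes of interest: per-kidney bounding boxes, 25% expansion, crop/paste.

#' Construct a VOI (axis-aligned half-open voxel box)
#'
#' @param start,stop Integer vectors (length 3) of 0-based half-open voxel
#'   indices, `start < stop` on every axis.
#' @param source_start,source_stop The pre-expansion box, if any.
#' @param expansion Expansion fraction applied to the source box.
#' @return An object of class `voi`.
#' @export
voi <- function(start, stop, source_start = start, source_stop = stop,
                expansion = 0) {
  start <- as.integer(start); stop <- as.integer(stop)
  if (any(start >= stop)) stopf("voi must satisfy start < stop on every axis")
  if (any(start < 0L)) stopf("voi start must be >= 0")
  structure(list(start = start, stop = stop,
                 source_start = as.integer(source_start),
                 source_stop = as.integer(source_stop),
                 expansion = expansion), class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("voi [%s) extent %s (expansion %.0f%%)\n",
              paste(sprintf("%d..%d", x$start, x$stop), collapse = ", "),
              paste(x$stop - x$start, collapse = "x"), 100 * x$expansion))
  invisible(x)
}

voi_extent <- function(v) v$stop - v$start

# Grow a half-open box to at least `min_extent` per axis, centred on the
# original box and shifted to stay inside the grid; axes whose grid is
# smaller than min_extent get the whole grid. Both the tumor-stage training
# crops and the pipeline's inference crops pass VOIs through this, so the
# network always sees patch-sized blocks of real context.
extend_box_to <- function(start, stop, min_extent, bounds) {
  start <- as.integer(start); stop <- as.integer(stop)
  for (ax in 1:3) {
    need <- min_extent[ax] - (stop[ax] - start[ax])
    if (need > 0L) {
      start[ax] <- start[ax] - need %/% 2L
      stop[ax] <- stop[ax] + (need - need %/% 2L)
      if (start[ax] < 0L) {
        stop[ax] <- stop[ax] - start[ax]
        start[ax] <- 0L
      }
      if (stop[ax] > bounds[ax]) {
        start[ax] <- max(0L, start[ax] - (stop[ax] - bounds[ax]))
        stop[ax] <- bounds[ax]
      }
    }
  }
  list(start = start, stop = stop)
}

# Expand a tight box: the expanded extent per axis is
# round(extent * (1 + expansion)) (half away from zero), margin split evenly
# across the two sides (extra voxel at the stop side), then clipped.
expand_box <- function(start, stop, expansion, bounds) {
  extent <- stop - start
  target <- as.integer(round_half_away(extent * (1 + expansion)))
  delta <- target - extent
  lo <- start - delta %/% 2L
  hi <- stop + (delta - delta %/% 2L)
  lo <- pmax(lo, 0L)
  hi <- pmin(hi, as.integer(bounds))
  list(start = lo, stop = hi)
}

#' Extract per-kidney VOIs from a stage-one mask
#'
#' 26-connected components of the binary kidney-region mask with at least
#' `min_component_voxels` voxels each yield one VOI; at most the two largest
#' components (left and right kidney) are kept. Each tight bounding box is
#' expanded by `expansion` per axis (half per side) and clipped to the grid.
#'
#' @param kidney_mask A binary [label_mask()] (values 0/1).
#' @param expansion Per-axis expansion fraction (default 0.25).
#' @param min_component_voxels Components below this size are ignored.
#' @return A list of [voi()] objects (possibly empty, meaning no kidney
#'   was found).
#' @export
extract_vois <- function(kidney_mask, expansion = 0.25,
                         min_component_voxels = 50L) {
  stopifnot(inherits(kidney_mask, "label_mask"))
  vals <- unique(as.vector(kidney_mask$data))
  if (!all(vals %in% c(0, 1))) stopf("kidney mask must be binary (0/1)")
  dims <- grid_dim(kidney_mask)
  labels <- .labelComponents26(as.integer(kidney_mask$data),
                               as.integer(dims))
  if (all(labels == 0L)) return(list())
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_component_voxels)
  if (length(keep) == 0L) return(list())
  keep <- keep[order(sizes[keep], decreasing = TRUE)][seq_len(min(2L, length(keep)))]
  keep <- sort(keep)  # deterministic output order: raster order of components
  lab_arr <- array(labels, dims)
  lapply(keep, function(lb) {
    idx <- which(lab_arr == lb, arr.ind = TRUE)
    start <- as.integer(apply(idx, 2L, min)) - 1L
    stop <- as.integer(apply(idx, 2L, max))
    box <- expand_box(start, stop, expansion, dims)
    voi(box$start, box$stop, source_start = start, source_stop = stop,
        expansion = expansion)
  })
}

#' Crop a volume or mask to a VOI
#'
#' @param x A `ct_volume` or `label_mask`.
#' @param v A [voi()] lying within the grid bounds.
#' @return The same kind of object with extents `stop - start`; the origin
#'   is advanced so physical coordinates are preserved.
#' @export
crop_volume <- function(x, v) {
  stopifnot(is_grid(x), inherits(v, "voi"))
  dims <- grid_dim(x)
  if (any(v$stop > dims)) stopf("voi exceeds grid bounds")
  sub <- x$data[v$start[1] + seq_len(v$stop[1] - v$start[1]),
                v$start[2] + seq_len(v$stop[2] - v$start[2]),
                v$start[3] + seq_len(v$stop[3] - v$start[3]), drop = FALSE]
  origin <- x$origin + v$start * x$spacing
  if (inherits(x, "label_mask")) label_mask(sub, x$spacing, origin)
  else ct_volume(sub, x$spacing, origin)
}

#' Paste a cropped patch back at its VOI location
#'
#' Inverse of [crop_volume()]: writes `patch` into `target` at the voxel
#' box of `v`, leaving all other voxels untouched.
#'
#' @param target A `ct_volume`/`label_mask` (or 3D array) on the full grid.
#' @param patch The cropped object (or array) with extents `stop - start`.
#' @param v The [voi()] used for cropping.
#' @return The modified `target`.
#' @export
paste_volume <- function(target, patch, v) {
  tdat <- if (is_grid(target)) target$data else target
  pdat <- if (is_grid(patch)) patch$data else patch
  if (!identical(as.integer(dim(pdat)), as.integer(voi_extent(v))))
    stopf("patch extent does not match voi extent")
  tdat[v$start[1] + seq_len(v$stop[1] - v$start[1]),
       v$start[2] + seq_len(v$stop[2] - v$start[2]),
       v$start[3] + seq_len(v$stop[3] - v$start[3])] <- pdat
  if (is_grid(target)) { target$data <- tdat; target } else tdat
}
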