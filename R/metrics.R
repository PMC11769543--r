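# Evaluation protocol: voxel metrics, object-wise IoU detection at 0.25,
# unidirectional-diameter size stratification, sensitivity and per-patient
# false-positive counts, and paired model comparison.

#' Voxel-wise confusion counts
#'
#' @param pred,gt Binary fields (3D arrays or vectors) on the same grid.
#' @return A list with integer `tp`, `fp`, `fn` (class `voxel_confusion`).
#' @export
voxel_confusion <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stopf("pred and gt must share a grid")
  p <- as.vector(pred) != 0
  g <- as.vector(gt) != 0
  structure(list(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g)),
            class = "voxel_confusion")
}

# Degenerate-case convention: with an empty ground truth and an empty
# prediction, Dice is 1 and VD/OSR/USR are 0 (perfect negative); with an
# empty ground truth but FP > 0, OSR/USR are undefined (NA).

#' Segmentation metrics from a voxel confusion
#'
#' `dice = 2TP/(2TP+FP+FN)`, `precision = TP/(TP+FP)`,
#' `vd = |FN-FP|/(2TP+FP+FN)` (volumetric distance),
#' `osr = FP/(TP+FN)` (over-segmentation ratio),
#' `usr = FN/(TP+FN)` (under-segmentation ratio).
#'
#' @param c A [voxel_confusion()].
#' @return The metric value.
#' @export
dice <- function(c) {
  d <- 2 * c$tp + c$fp + c$fn
  if (d == 0) 1 else 2 * c$tp / d
}

#' @rdname dice
#' @export
precision <- function(c) {
  d <- c$tp + c$fp
  if (d == 0) { if (c$fn == 0) 1 else 0 } else c$tp / d
}

#' @rdname dice
#' @export
vd <- function(c) {
  d <- 2 * c$tp + c$fp + c$fn
  if (d == 0) 0 else abs(c$fn - c$fp) / d
}

#' @rdname dice
#' @export
osr <- function(c) {
  d <- c$tp + c$fn
  if (d == 0) { if (c$fp == 0) 0 else NA_real_ } else c$fp / d
}

#' @rdname dice
#' @export
usr <- function(c) {
  d <- c$tp + c$fn
  if (d == 0) { if (c$fp == 0) 0 else NA_real_ } else c$fn / d
}

# ---- tumor instances ------------------------------------------------------

#' Size category from a unidirectional diameter
#'
#' TNM-style bins: small `<= 4` cm, medium `> 4` and `<= 7` cm, large
#' `> 7` cm; small tumors carry a subcategory `<=2`, `>2-<=3`, `>3-<=4` cm.
#'
#' @param diameter_cm Unidirectional diameter in cm.
#' @return Character category.
#' @export
size_category <- function(diameter_cm) {
  ifelse(diameter_cm <= 4, "small",
         ifelse(diameter_cm <= 7, "medium", "large"))
}

#' @rdname size_category
#' @export
size_subcategory <- function(diameter_cm) {
  ifelse(diameter_cm > 4, NA_character_,
         ifelse(diameter_cm <= 2, "<=2",
                ifelse(diameter_cm <= 3, ">2-<=3", ">3-<=4")))
}

#' Unidirectional diameter of a tumor instance
#'
#' RECIST-style: the maximum in-plane extent over axial (z) slices — the
#' largest pairwise voxel-centre distance within any single slice, floored
#' at one in-plane voxel for single-voxel instances, in cm.
#' `mode = "feret3d"` measures the maximum 3D voxel-centre distance instead.
#'
#' @param idx Integer matrix of voxel coordinates (rows; 1-based) or a
#'   `tumor_instance`.
#' @param spacing Per-axis voxel size in mm.
#' @param mode `"axial"` (default) or `"feret3d"`.
#' @return Diameter in cm.
#' @export
tumor_diameter <- function(idx, spacing, mode = c("axial", "feret3d")) {
  mode <- match.arg(mode)
  if (inherits(idx, "tumor_instance")) idx <- idx$voxel_indices
  if (is.null(dim(idx)) || nrow(idx) == 0L) stopf("empty tumor instance")
  if (mode == "feret3d") {
    pts <- sweep(idx, 2L, spacing, `*`)
    return(max(max_pairwise_dist(pts), mean(spacing)) / 10)
  }
  best <- 0
  for (z in unique(idx[, 3L])) {
    sl <- idx[idx[, 3L] == z, 1:2, drop = FALSE]
    pts <- sweep(sl, 2L, spacing[1:2], `*`)
    best <- max(best, max_pairwise_dist(pts))
  }
  max(best, mean(spacing[1:2])) / 10
}

# Largest pairwise distance among points (rows); reduces to the convex hull
# first when 2D and large enough for it to pay off.
max_pairwise_dist <- function(pts) {
  if (nrow(pts) == 1L) return(0)
  if (ncol(pts) == 2L && nrow(pts) > 8L) {
    h <- unique(pts[, 1:2, drop = FALSE])
    if (nrow(h) > 3L) {
      hull <- tryCatch(grDevices::chull(h[, 1L], h[, 2L]),
                       error = function(e) NULL)
      if (!is.null(hull) && length(hull) >= 2L)
        pts <- h[hull, , drop = FALSE]
      else pts <- h
    } else pts <- h
    if (nrow(pts) == 1L) return(0)
  }
  max(stats::dist(pts))
}

#' Connected tumor instances of a binary field
#'
#' 26-connected components; each is measured ([tumor_diameter()]) and
#' categorized; components below `min_voxels` are discarded as noise.
#'
#' @param mask Binary 3D array (or `label_mask`; tumor label 2 is taken).
#' @param spacing Per-axis voxel size in mm (taken from a `label_mask`).
#' @param min_voxels Minimum component size in voxels (default 5).
#' @param diameter_mode Passed to [tumor_diameter()].
#' @return A list of `tumor_instance` objects with fields `component_id`,
#'   `voxel_indices`, `n_voxels`, `diameter_cm`, `category`, `subcategory`.
#' @export
instance_components <- function(mask, spacing = NULL, min_voxels = 5L,
                                diameter_mode = "axial") {
  if (inherits(mask, "label_mask")) {
    spacing <- mask$spacing
    arr <- (mask$data == 2L) * 1L
    if (!any(arr) && any(mask$data == 1L) && !any(mask$data == 2L) &&
        all(mask$data %in% c(0L, 1L)))
      arr <- mask$data   # binary mask: treat 1 as the instance label
  } else {
    arr <- (mask != 0) * 1L
    dim(arr) <- dim(mask)
  }
  if (is.null(spacing)) stopf("spacing required for plain-array masks")
  dims <- dim(arr)
  labels <- .labelComponents26(as.integer(arr), as.integer(dims))
  if (all(labels == 0L)) return(list())
  lab_arr <- array(labels, dims)
  n <- max(labels)
  out <- list()
  for (lb in seq_len(n)) {
    idx <- which(lab_arr == lb, arr.ind = TRUE)
    if (nrow(idx) < min_voxels) next
    d_cm <- tumor_diameter(idx, spacing, mode = diameter_mode)
    out[[length(out) + 1L]] <- structure(
      list(component_id = lb, voxel_indices = idx, n_voxels = nrow(idx),
           diameter_cm = d_cm, category = size_category(d_cm),
           subcategory = size_subcategory(d_cm)),
      class = "tumor_instance")
  }
  out
}

# ---- detection ------------------------------------------------------------

instance_iou <- function(a, b, dims) {
  la <- (a[, 1L] - 1L) + dims[1L] * ((a[, 2L] - 1L) + dims[2L] * (a[, 3L] - 1L))
  lb <- (b[, 1L] - 1L) + dims[1L] * ((b[, 2L] - 1L) + dims[2L] * (b[, 3L] - 1L))
  inter <- length(intersect(la, lb))
  inter / (length(la) + length(lb) - inter)
}

#' Object-wise detection matching at an IoU threshold
#'
#' Computes pairwise 3D object IoU between ground-truth and predicted
#' instances and matches greedily, one-to-one, in descending IoU order
#' (ties broken by lower ground-truth then prediction index); pairs below
#' the threshold are not matched. Unmatched predictions are false positives.
#'
#' @param gt,pred Lists of `tumor_instance`s from the same grid.
#' @param dims Grid extents (needed to hash voxel indices).
#' @param iou_threshold Detection threshold (default 0.25).
#' @return A `detection_result`: `matches` (data.frame gt_id, pred_id, iou),
#'   `detected_gt_ids`, `unmatched_pred_ids`, `iou_threshold`.
#' @export
match_detections <- function(gt, pred, dims, iou_threshold = 0.25) {
  pairs <- expand.grid(gi = seq_along(gt), pi = seq_along(pred))
  if (nrow(pairs) > 0L) {
    pairs$iou <- mapply(function(gi, pi)
      instance_iou(gt[[gi]]$voxel_indices, pred[[pi]]$voxel_indices, dims),
      pairs$gi, pairs$pi)
    pairs <- pairs[pairs$iou >= iou_threshold, , drop = FALSE]
    pairs <- pairs[order(-pairs$iou, pairs$gi, pairs$pi), , drop = FALSE]
  } else {
    pairs$iou <- numeric(0)
  }
  used_g <- logical(length(gt)); used_p <- logical(length(pred))
  matches <- list()
  for (r in seq_len(nrow(pairs))) {
    gi <- pairs$gi[r]; pi <- pairs$pi[r]
    if (used_g[gi] || used_p[pi]) next
    used_g[gi] <- TRUE; used_p[pi] <- TRUE
    matches[[length(matches) + 1L]] <-
      data.frame(gt_id = gi, pred_id = pi, iou = pairs$iou[r])
  }
  matches <- if (length(matches)) do.call(rbind, matches)
  else data.frame(gt_id = integer(0), pred_id = integer(0), iou = numeric(0))
  structure(list(matches = matches,
                 detected_gt_ids = which(used_g),
                 unmatched_pred_ids = which(!used_p),
                 iou_threshold = iou_threshold),
            class = "detection_result")
}

# ---- cohort summaries -----------------------------------------------------

#' Evaluate one case: instances, detection, per-instance voxel metrics
#'
#' @param pred_mask,gt_mask `label_mask`s (tumor label 2) on the same grid.
#' @param iou_threshold Object-wise detection threshold.
#' @param min_voxels Minimum instance size.
#' @param diameter_mode Passed to [tumor_diameter()].
#' @return A list with `gt`, `pred` (instance lists), `detection`, and
#'   `case_confusion` (whole-field voxel confusion).
#' @export
evaluate_case <- function(pred_mask, gt_mask, iou_threshold = 0.25,
                          min_voxels = 5L, diameter_mode = "axial") {
  check_same_grid(pred_mask, gt_mask)
  gt <- instance_components(gt_mask, min_voxels = min_voxels,
                            diameter_mode = diameter_mode)
  pred <- instance_components(pred_mask, min_voxels = min_voxels,
                              diameter_mode = diameter_mode)
  det <- match_detections(gt, pred, grid_dim(gt_mask), iou_threshold)
  list(gt = gt, pred = pred, detection = det,
       case_confusion = voxel_confusion(pred_mask$data == 2L,
                                        gt_mask$data == 2L),
       dims = grid_dim(gt_mask))
}

instance_confusion <- function(gt_inst, pred_inst, dims) {
  la <- with(list(a = gt_inst$voxel_indices),
             (a[, 1L] - 1L) + dims[1L] * ((a[, 2L] - 1L) + dims[2L] * (a[, 3L] - 1L)))
  lb <- with(list(b = pred_inst$voxel_indices),
             (b[, 1L] - 1L) + dims[1L] * ((b[, 2L] - 1L) + dims[2L] * (b[, 3L] - 1L)))
  tp <- length(intersect(la, lb))
  structure(list(tp = tp, fp = length(lb) - tp, fn = length(la) - tp),
            class = "voxel_confusion")
}

#' Size-stratified evaluation report over a cohort
#'
#' Sensitivity per category is the fraction of ground-truth instances of
#' that size that were detected; FPC is the number of unmatched predicted
#' instances of that size (measured on the prediction's own diameter)
#' divided by the number of patients. Voxel metrics are computed per
#' matched instance pair and aggregated as mean and sd. With
#' `undetected_zero = TRUE`, undetected ground-truth tumors contribute a
#' Dice (and precision) of 0 instead of being left out.
#'
#' @param cases A list of [evaluate_case()] results (one per patient).
#' @param case_ids Optional case identifiers.
#' @param undetected_zero Include undetected GT tumors as zeros?
#' @return A list of class `evaluation_report` with `per_instance`,
#'   `per_case`, and `per_category` data.frames.
#' @export
summarize_evaluation <- function(cases, case_ids = NULL,
                                 undetected_zero = FALSE) {
  if (length(cases) == 0L) stopf("need at least one case")
  case_ids <- case_ids %||% sprintf("case_%03d", seq_along(cases))
  inst_rows <- list()
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    det <- cs$detection
    matched_g <- det$matches$gt_id
    for (gi in seq_along(cs$gt)) {
      g <- cs$gt[[gi]]
      row <- data.frame(case_id = case_ids[ci], kind = "gt",
                        category = g$category,
                        subcategory = g$subcategory %||% NA_character_,
                        diameter_cm = g$diameter_cm,
                        detected = gi %in% det$detected_gt_ids,
                        dice = NA_real_, precision = NA_real_, vd = NA_real_,
                        osr = NA_real_, usr = NA_real_,
                        stringsAsFactors = FALSE)
      if (row$detected) {
        pi <- det$matches$pred_id[match(gi, matched_g)]
        cf <- instance_confusion(g, cs$pred[[pi]], cs$dims)
        row$dice <- dice(cf); row$precision <- precision(cf)
        row$vd <- vd(cf); row$osr <- osr(cf); row$usr <- usr(cf)
      } else if (undetected_zero) {
        row$dice <- 0; row$precision <- 0; row$vd <- 1
        row$osr <- 0; row$usr <- 1
      }
      inst_rows[[length(inst_rows) + 1L]] <- row
    }
    for (pi in det$unmatched_pred_ids) {
      p <- cs$pred[[pi]]
      inst_rows[[length(inst_rows) + 1L]] <-
        data.frame(case_id = case_ids[ci], kind = "fp",
                   category = p$category,
                   subcategory = p$subcategory %||% NA_character_,
                   diameter_cm = p$diameter_cm, detected = NA,
                   dice = NA_real_, precision = NA_real_, vd = NA_real_,
                   osr = NA_real_, usr = NA_real_, stringsAsFactors = FALSE)
    }
  }
  per_instance <- if (length(inst_rows)) do.call(rbind, inst_rows)
  else data.frame()
  n_patients <- length(cases)
  cats <- c("small", "medium", "large")
  per_category <- do.call(rbind, lapply(cats, function(cat) {
    g <- per_instance[per_instance$kind == "gt" &
                        per_instance$category == cat, , drop = FALSE]
    f <- per_instance[per_instance$kind == "fp" &
                        per_instance$category == cat, , drop = FALSE]
    dvals <- g$dice[!is.na(g$dice)]
    data.frame(category = cat, n_gt = nrow(g),
               n_detected = sum(g$detected),
               sensitivity = if (nrow(g)) sum(g$detected) / nrow(g)
               else NA_real_,
               n_fp = nrow(f), fpc = nrow(f) / n_patients,
               dice_mean = if (length(dvals)) mean(dvals) else NA_real_,
               dice_sd = if (length(dvals) > 1L) stats::sd(dvals)
               else NA_real_,
               precision = mean(g$precision, na.rm = TRUE),
               vd = mean(g$vd, na.rm = TRUE),
               osr = mean(g$osr, na.rm = TRUE),
               usr = mean(g$usr, na.rm = TRUE))
  }))
  per_case <- do.call(rbind, lapply(seq_along(cases), function(ci) {
    cf <- cases[[ci]]$case_confusion
    data.frame(case_id = case_ids[ci], dice = dice(cf),
               precision = precision(cf), vd = vd(cf), osr = osr(cf),
               usr = usr(cf),
               n_gt = length(cases[[ci]]$gt),
               n_detected = length(cases[[ci]]$detection$detected_gt_ids),
               n_fp = length(cases[[ci]]$detection$unmatched_pred_ids))
  }))
  structure(list(per_instance = per_instance, per_case = per_case,
                 per_category = per_category, n_patients = n_patients),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report over %d patients\n", x$n_patients))
  print(x$per_category, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' One row per case x size category plus per-category cohort rows
#' (case_id = "ALL").
#'
#' @param report An `evaluation_report`.
#' @param path Output CSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_evaluation_csv <- function(report, path) {
  rows <- list()
  for (cid in unique(report$per_case$case_id)) {
    pi <- report$per_instance
    pi <- pi[pi$case_id == cid, , drop = FALSE]
    for (cat in c("small", "medium", "large")) {
      g <- pi[pi$kind == "gt" & pi$category == cat, , drop = FALSE]
      f <- pi[pi$kind == "fp" & pi$category == cat, , drop = FALSE]
      if (nrow(g) == 0L && nrow(f) == 0L) next
      dv <- g$dice[!is.na(g$dice)]
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = cid, category = cat, n_gt = nrow(g),
        n_detected = sum(g$detected), n_fp = nrow(f),
        dice_mean = if (length(dv)) mean(dv) else NA_real_,
        dice_sd = if (length(dv) > 1) stats::sd(dv) else NA_real_,
        precision = mean(g$precision, na.rm = TRUE),
        vd = mean(g$vd, na.rm = TRUE), osr = mean(g$osr, na.rm = TRUE),
        usr = mean(g$usr, na.rm = TRUE))
    }
  }
  all_rows <- report$per_category
  all_rows <- data.frame(case_id = "ALL", category = all_rows$category,
                         n_gt = all_rows$n_gt,
                         n_detected = all_rows$n_detected,
                         n_fp = all_rows$n_fp, dice_mean = all_rows$dice_mean,
                         dice_sd = all_rows$dice_sd,
                         precision = all_rows$precision, vd = all_rows$vd,
                         osr = all_rows$osr, usr = all_rows$usr)
  out <- rbind(do.call(rbind, rows), all_rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Paired comparison of per-case Dice distributions
#'
#' Two-sided Wilcoxon signed-rank test on paired per-case Dice scores (exact
#' distribution at small n without ties); identical lists give p = 1.
#'
#' @param model_a,model_b Equal-length numeric vectors of per-case Dice.
#' @return The two-sided p-value.
#' @export
compare_dice <- function(model_a, model_b) {
  if (length(model_a) != length(model_b))
    stopf("paired lists must have equal length")
  if (length(model_a) < 5L) stopf("need at least 5 paired cases")
  d <- model_b - model_a
  if (all(d == 0)) return(1)
  res <- suppressWarnings(stats::wilcox.test(model_a, model_b,
                                             paired = TRUE))
  unname(res$p.value)
}
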