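# Dual-stage inference: preprocess -> organ segmentation -> VOI expansion
# and cropping -> tumor segmentation per VOI -> paste-back, with an optional
# resample to the native grid. A single-stage mode runs one network over the
# whole volume for comparison.

#' Pipeline configuration
#'
#' @param target_spacing Isotropic spacing for inference (mm, default 1.0).
#' @param expansion VOI expansion fraction (default 0.25).
#' @param kidney_threshold,tumor_threshold Probability thresholds.
#' @param min_component_voxels Minimum stage-one component size.
#' @param overlap Sliding-window overlap fraction (default 0.5).
#' @param native_grid Resample predictions back to the native spacing
#'   (nearest neighbour) instead of reporting on the isotropic grid?
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(target_spacing = 1.0, expansion = 0.25,
                            kidney_threshold = 0.5, tumor_threshold = 0.5,
                            min_component_voxels = 50L, overlap = 0.5,
                            native_grid = FALSE) {
  structure(list(target_spacing = target_spacing, expansion = expansion,
                 kidney_threshold = kidney_threshold,
                 tumor_threshold = tumor_threshold,
                 min_component_voxels = as.integer(min_component_voxels),
                 overlap = overlap, native_grid = isTRUE(native_grid)),
            class = "pipeline_config")
}

#' Run the dual-stage pipeline on one volume
#'
#' The organ network segments the kidney region on the normalized isotropic
#' grid; its connected components yield expanded VOIs; the tumor network is
#' applied inside each VOI with sliding windows, overlapping VOI predictions
#' are merged by voxel-wise maximum probability, and the merged field is
#' thresholded. Tumor probabilities exist only inside VOIs, so false
#' positives outside the kidney region are structurally impossible. An empty
#' VOI list ("no kidney found") yields an empty tumor mask.
#'
#' @param vol A native-grid [ct_volume()] (spacing metadata required).
#' @param organ_net,tumor_net Trained networks.
#' @param stats The [compute_intensity_stats()] frozen at training time.
#' @param cfg A [pipeline_config()].
#' @return A `case_prediction`: `kidney_mask`, `tumor_mask`, `vois`,
#'   `provenance`.
#' @export
run_dual_stage <- function(vol, organ_net, tumor_net, stats,
                           cfg = pipeline_config()) {
  stopifnot(inherits(vol, "ct_volume"))
  pre <- preprocess_case(vol, stats, target_spacing = cfg$target_spacing)
  nvol <- pre$vol
  kidney <- segment_kidney(nvol, organ_net, threshold = cfg$kidney_threshold)
  vois <- extract_vois(kidney, expansion = cfg$expansion,
                       min_component_voxels = cfg$min_component_voxels)
  tumor_prob <- array(0, grid_dim(nvol))
  win <- default_window(tumor_net, grid_dim(nvol))
  for (v in vois) {
    # run the network on a patch-sized block of real context around the
    # VOI (the same layout its training crops had), but emit probabilities
    # only inside the expanded VOI itself
    ext <- extend_box_to(v$start, v$stop, win, grid_dim(nvol))
    vext <- voi(ext$start, ext$stop)
    sub <- crop_volume(nvol, vext)
    prob_ext <- infer_sliding_window(sub$data, win,
                                     function(arr) tumor_net_forward(tumor_net, arr),
                                     overlap = cfg$overlap)
    rel <- lapply(1:3, function(ax)
      (v$start[ax] - vext$start[ax]) + seq_len(v$stop[ax] - v$start[ax]))
    prob <- prob_ext[rel[[1]], rel[[2]], rel[[3]], drop = FALSE]
    # merge overlapping VOIs by voxelwise maximum probability
    cur <- crop_volume(ct_volume(tumor_prob, nvol$spacing), v)$data
    tumor_prob <- paste_volume(tumor_prob, pmax(cur, prob), v)
  }
  tumor <- label_mask((tumor_prob >= cfg$tumor_threshold) * 2L,
                      nvol$spacing, nvol$origin)
  out <- finalize_prediction(kidney, tumor, vol, cfg)
  out$vois <- vois
  out$provenance <- list(mode = "dual_stage", stats = stats_to_list(stats),
                         thresholds = c(kidney = cfg$kidney_threshold,
                                        tumor = cfg$tumor_threshold),
                         expansion = cfg$expansion)
  out
}

#' Run a single network over the whole volume (single-stage mode)
#'
#' Comparator mode: one network simultaneously segments on the full grid
#' with no VOI restriction, so it may emit tumor voxels anywhere.
#'
#' @param vol A native-grid [ct_volume()].
#' @param net A trained network whose output is a tumor probability field.
#' @param stats Frozen intensity statistics.
#' @param cfg A [pipeline_config()].
#' @param organ_net Optional organ network run only to report a kidney mask;
#'   the tumor field is unrestricted either way.
#' @return A `case_prediction` with empty `vois`.
#' @export
run_single_stage <- function(vol, net, stats, cfg = pipeline_config(),
                             organ_net = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  pre <- preprocess_case(vol, stats, target_spacing = cfg$target_spacing)
  nvol <- pre$vol
  fwd <- if (inherits(net, "organ_net")) {
    function(arr) organ_net_forward(net, arr)
  } else {
    function(arr) tumor_net_forward(net, arr)
  }
  win <- default_window(net, grid_dim(nvol))
  prob <- infer_sliding_window(nvol$data, win, fwd, overlap = cfg$overlap)
  tumor <- label_mask((prob >= cfg$tumor_threshold) * 2L, nvol$spacing,
                      nvol$origin)
  kidney <- if (!is.null(organ_net))
    segment_kidney(nvol, organ_net, threshold = cfg$kidney_threshold)
  else label_mask(array(0L, grid_dim(nvol)), nvol$spacing, nvol$origin)
  out <- finalize_prediction(kidney, tumor, vol, cfg)
  out$vois <- list()
  out$provenance <- list(mode = "single_stage", stats = stats_to_list(stats),
                         thresholds = c(tumor = cfg$tumor_threshold))
  out
}

finalize_prediction <- function(kidney, tumor, native_vol, cfg) {
  if (cfg$native_grid) {
    kidney <- resample_mask_to(kidney, grid_dim(native_vol),
                               native_vol$spacing)
    tumor <- resample_mask_to(tumor, grid_dim(native_vol),
                              native_vol$spacing)
  }
  structure(list(kidney_mask = kidney, tumor_mask = tumor),
            class = "case_prediction")
}

# Nearest-neighbour resample of a mask onto an explicit target grid.
resample_mask_to <- function(mask, out_dims, out_spacing) {
  in_dims <- grid_dim(mask)
  scale <- out_spacing / mask$spacing
  A <- cbind(diag(scale), 0.5 * scale - 0.5)
  arr <- array(.resampleAffine3d(as.numeric(mask$data), as.integer(in_dims),
                                 A, as.integer(out_dims), 1L, 0),
               out_dims)
  label_mask(arr, out_spacing, mask$origin)
}

#' @export
print.case_prediction <- function(x, ...) {
  cat(sprintf("case_prediction (%s): %d kidney voxels, %d tumor voxels, %d VOIs\n",
              x$provenance$mode %||% "?", sum(x$kidney_mask$data != 0),
              sum(x$tumor_mask$data != 0), length(x$vois)))
  invisible(x)
}
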