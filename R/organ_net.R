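# Stage one: kidney-region segmentation and VOI extraction.
#
# The default backend is a shifted-window transformer encoder with a
# CNN decoder (residual blocks, instance normalization, deconvolution
# upsampling, pointwise + sigmoid head). A small pure-CNN residual UNet
# backend is also provided; stage one is a pluggable interface and either
# backend satisfies the same contract.

#' Configuration for the stage-one organ network
#'
#' @param backend `"swin"` (shifted-window transformer encoder, default) or
#'   `"cnn"` (small residual UNet).
#' @param encoder_steps Encoder steps; each holds
#'   `transformer_blocks_per_step` attention blocks (swin backend).
#' @param transformer_blocks_per_step Attention blocks per step.
#' @param window_input_size Intended per-axis input window for inference;
#'   must be divisible by `2^encoder_steps`.
#' @param window_size Attention window extent per axis; clamped to the grid
#'   at coarse resolutions and required to tile each grid exactly.
#' @param base_channels Embedding width; doubles at each encoder step.
#' @param leaky_slope LeakyReLU negative slope used in the decoder.
#' @param cnn_channels,cnn_blocks Stage widths and residual-block counts for
#'   the CNN backend.
#' @return An object of class `organ_net_config`.
#' @export
organ_net_config <- function(backend = c("swin", "cnn"),
                             encoder_steps = 4L,
                             transformer_blocks_per_step = 2L,
                             window_input_size = 128L,
                             window_size = 4L,
                             base_channels = 24L,
                             leaky_slope = 0.01,
                             cnn_channels = c(8L, 16L, 32L),
                             cnn_blocks = c(1L, 1L, 1L)) {
  backend <- match.arg(backend)
  encoder_steps <- as.integer(encoder_steps)
  if (encoder_steps < 1L) stopf("encoder_steps must be >= 1")
  if (window_input_size %% 2L^encoder_steps != 0L)
    stopf("window_input_size (%d) must be divisible by 2^encoder_steps (%d)",
          window_input_size, 2L^encoder_steps)
  structure(list(backend = backend,
                 encoder_steps = encoder_steps,
                 transformer_blocks_per_step =
                   as.integer(transformer_blocks_per_step),
                 window_input_size = as.integer(window_input_size),
                 window_size = as.integer(window_size),
                 base_channels = as.integer(base_channels),
                 leaky_slope = leaky_slope,
                 cnn_channels = as.integer(cnn_channels),
                 cnn_blocks = as.integer(cnn_blocks)),
            class = "organ_net_config")
}

largest_divisor_head <- function(c_, target) {
  h <- max(1L, min(target, c_))
  while (c_ %% h != 0L) h <- h - 1L
  h
}

#' Build the stage-one organ segmentation network
#'
#' The swin backend embeds the volume at half resolution, runs
#' `encoder_steps` steps of shifted-window attention blocks (alternating
#' unshifted/shifted windows) with a resolution-halving, width-doubling
#' downsampling between steps, and decodes with residual blocks, instance
#' normalization and deconvolution upsampling to a pointwise + sigmoid kidney
#' probability head.
#'
#' @param cfg An [organ_net_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `organ_net`.
#' @export
build_organ_net <- function(cfg = organ_net_config(), seed = NULL) {
  stopifnot(inherits(cfg, "organ_net_config"))
  with_seed(seed, {
    if (cfg$backend == "cnn") {
      ucfg <- tumor_net_config(n_stages = length(cfg$cnn_channels),
                               channels = cfg$cnn_channels,
                               residual_blocks = cfg$cnn_blocks,
                               attention_gates = FALSE,
                               leaky_slope = cfg$leaky_slope,
                               patch_size = rep(2L^(length(cfg$cnn_channels) - 1L) * 8L, 3L),
                               batch_size = 2L)
      unet <- build_tumor_net(ucfg)
      return(structure(list(cfg = cfg, unet = unet), class = "organ_net"))
    }
    c0 <- cfg$base_channels
    embed <- new_conv_unit(1L, c0, stride = 2L, name = "embed")
    steps <- vector("list", cfg$encoder_steps)
    for (i in seq_len(cfg$encoder_steps)) {
      ci <- c0 * 2L^(i - 1L)
      heads <- largest_divisor_head(ci, max(1L, ci %/% 8L))
      blocks <- lapply(seq_len(cfg$transformer_blocks_per_step), function(b)
        new_swin_block(ci, heads, shift = (b %% 2L == 0L),
                       name = sprintf("step%d.blk%d", i, b)))
      down <- if (i < cfg$encoder_steps)
        new_conv_unit(ci, 2L * ci, stride = 2L, name = sprintf("step%d.down", i))
      steps[[i]] <- list(blocks = blocks, down = down, channels = ci)
    }
    decoder <- vector("list", cfg$encoder_steps - 1L)
    for (i in seq.int(cfg$encoder_steps - 1L, 1L)) {
      ci <- c0 * 2L^(i - 1L)
      decoder[[i]] <- list(
        up = new_convt2(2L * ci, ci, name = sprintf("odec%d.up", i)),
        rb = new_residual_block(2L * ci, ci, name = sprintf("odec%d.rb", i)))
    }
    final_up <- new_convt2(c0, c0, name = "odec0.up")
    final_rb <- new_residual_block(c0, c0, name = "odec0.rb")
    head <- new_pointwise(c0, 1L, name = "ohead")
    structure(list(cfg = cfg, embed = embed, steps = steps, decoder = decoder,
                   final_up = final_up, final_rb = final_rb, head = head),
              class = "organ_net")
  })
}

forward_organ_tensor <- function(net, x) {
  cfg <- net$cfg
  if (cfg$backend == "cnn") return(forward_tumor_tensor(net$unet, x))
  div <- 2L^cfg$encoder_steps
  if (any(x$sdim %% div != 0L))
    stopf("input extents (%s) must be divisible by %d",
          paste(x$sdim, collapse = "x"), div)
  slope <- cfg$leaky_slope
  h <- fwd_conv_unit(x, net$embed, slope)
  skips <- vector("list", cfg$encoder_steps)
  for (i in seq_len(cfg$encoder_steps)) {
    for (blk in net$steps[[i]]$blocks)
      h <- fwd_swin_block(h, blk, cfg$window_size)
    skips[[i]] <- h
    if (!is.null(net$steps[[i]]$down))
      h <- fwd_conv_unit(h, net$steps[[i]]$down, slope)
  }
  for (i in seq.int(cfg$encoder_steps - 1L, 1L)) {
    h <- fwd_convt2(h, net$decoder[[i]]$up)
    h <- op_concat(skips[[i]], h)
    h <- fwd_residual_block(h, net$decoder[[i]]$rb, slope)
  }
  h <- fwd_convt2(h, net$final_up)
  h <- fwd_residual_block(h, net$final_rb, slope)
  op_sigmoid(fwd_conv(h, net$head))
}

#' Forward pass of the organ network
#' @param net An `organ_net`.
#' @param x A 3D numeric array of normalized intensities.
#' @return A 3D array of kidney-region probabilities, same extents as `x`.
#' @export
organ_net_forward <- function(net, x) {
  t_out <- forward_organ_tensor(net, as_input_tensor(x))
  array(t_out$value, t_out$sdim)
}

#' Introspect the organ encoder structure
#' @param net An `organ_net`.
#' @return A data.frame with one row per encoder step: step index, feature
#'   width, and number of attention blocks (swin) or residual blocks (cnn).
#' @export
organ_net_structure <- function(net) {
  stopifnot(inherits(net, "organ_net"))
  if (net$cfg$backend == "cnn") {
    ucfg <- net$unet$cfg
    return(data.frame(step = seq_len(ucfg$n_stages),
                      channels = ucfg$channels,
                      blocks = ucfg$residual_blocks,
                      kind = "residual"))
  }
  data.frame(step = seq_along(net$steps),
             channels = vapply(net$steps, function(s) as.integer(s$channels), 0L),
             blocks = vapply(net$steps, function(s) length(s$blocks), 0L),
             kind = "transformer")
}

#' Segment the kidney region of a preprocessed volume
#'
#' Runs sliding-window inference (50% overlap, Gaussian-weighted blending)
#' and thresholds the probability field. Volumes smaller than the window on
#' any axis are padded symmetrically and cropped back.
#'
#' @param vol A preprocessed (normalized, isotropic) [ct_volume()].
#' @param net An `organ_net`.
#' @param threshold Probability threshold (default 0.5).
#' @param window Per-axis inference window; defaults to a window compatible
#'   with the backend's divisibility constraint.
#' @return A [label_mask()] with 1 on kidney-region voxels.
#' @export
segment_kidney <- function(vol, net, threshold = 0.5, window = NULL) {
  stopifnot(inherits(vol, "ct_volume"), inherits(net, "organ_net"))
  window <- as.integer(window %||%
                         default_window(net, dim(vol$data)))
  prob <- infer_sliding_window(vol$data, window,
                               function(arr) organ_net_forward(net, arr))
  label_mask((prob >= threshold) * 1L, vol$spacing, vol$origin)
}

net_divisor <- function(net) {
  if (inherits(net, "organ_net")) {
    if (net$cfg$backend == "cnn") 2L^(net$unet$cfg$n_stages - 1L)
    else 2L^net$cfg$encoder_steps
  } else {
    2L^(net$cfg$n_stages - 1L)
  }
}

# The inference window is the network's training patch: smaller grids are
# then padded symmetrically exactly as training patches were, so the
# network never sees a voxel layout it was not trained on. (Fitting the
# window to the grid instead costs a large fraction of held-out Dice.)
default_window <- function(net, extent) {
  if (inherits(net, "organ_net")) {
    if (net$cfg$backend == "cnn") net$unet$cfg$patch_size
    else rep(net$cfg$window_input_size, 3L)
  } else {
    net$cfg$patch_size
  }
}
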