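# Kidney Tumor 3D UNet: residual encoder, attention-gated skips, mirrored
# decoder with one convolution per stage, pointwise + sigmoid head.

#' Configuration for the Kidney Tumor 3D UNet
#'
#' Defaults describe the full-scale network: six encoder stages with feature
#' widths 32, 64, 128, 256, 320, 320 and 1, 3, 4, 6, 6, 6 residual blocks per
#' stage, attention gates on every skip connection, LeakyReLU nonlinearities,
#' and a 192 x 128 x 128 training patch at batch size 5. Stage six acts as the
#' bottleneck, so the network downsamples five times and every patch extent
#' must be divisible by `2^(n_stages - 1)`.
#'
#' @param n_stages Number of encoder stages (the last is the bottleneck).
#' @param channels Per-stage feature widths; length `n_stages`.
#' @param residual_blocks Per-stage residual block counts; length `n_stages`.
#' @param decoder_convs_per_stage Convolutions per decoder stage.
#' @param leaky_slope Negative slope of the LeakyReLU nonlinearity.
#' @param attention_gates Gate each skip connection with additive attention?
#' @param patch_size Training patch extent per axis (voxels).
#' @param batch_size Training batch size (patches per optimizer step).
#' @param in_channels Input channels (1 for a single CT volume).
#' @return An object of class `tumor_net_config`.
#' @export
tumor_net_config <- function(n_stages = 6L,
                             channels = c(32L, 64L, 128L, 256L, 320L, 320L),
                             residual_blocks = c(1L, 3L, 4L, 6L, 6L, 6L),
                             decoder_convs_per_stage = 1L,
                             leaky_slope = 0.01,
                             attention_gates = TRUE,
                             patch_size = c(192L, 128L, 128L),
                             batch_size = 5L,
                             in_channels = 1L) {
  n_stages <- as.integer(n_stages)
  if (n_stages < 2L) stopf("n_stages must be at least 2, got %d", n_stages)
  if (length(channels) != n_stages)
    stopf("channels must have length n_stages (%d), got %d",
          n_stages, length(channels))
  if (length(residual_blocks) != n_stages)
    stopf("residual_blocks must have length n_stages (%d), got %d",
          n_stages, length(residual_blocks))
  if (any(residual_blocks < 1L)) stopf("residual_blocks must all be >= 1")
  div <- 2L^(n_stages - 1L)
  if (any(as.integer(patch_size) %% div != 0L))
    stopf("each patch extent must be divisible by 2^(n_stages-1) = %d", div)
  structure(list(n_stages = n_stages,
                 channels = as.integer(channels),
                 residual_blocks = as.integer(residual_blocks),
                 decoder_convs_per_stage = as.integer(decoder_convs_per_stage),
                 leaky_slope = leaky_slope,
                 attention_gates = isTRUE(attention_gates),
                 patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 in_channels = as.integer(in_channels)),
            class = "tumor_net_config")
}

#' Build the Kidney Tumor 3D UNet
#'
#' Instantiates the network described by a [tumor_net_config()]: encoder stage
#' `i` holds `residual_blocks[i]` residual units at `channels[i]` width, with
#' a strided convolution inside the first unit of stages 2..n downsampling by
#' 2 per axis; the decoder mirrors the encoder with a resolution-doubling
#' deconvolution and one convolution per stage, each skip connection passing
#' through an additive attention gate when enabled; the head is a pointwise
#' convolution followed by a sigmoid, yielding a per-voxel tumor probability.
#'
#' @param cfg A [tumor_net_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `tumor_net`.
#' @export
build_tumor_net <- function(cfg = tumor_net_config(), seed = NULL) {
  stopifnot(inherits(cfg, "tumor_net_config"))
  with_seed(seed, {
    n <- cfg$n_stages
    ch <- cfg$channels
    encoder <- vector("list", n)
    for (i in seq_len(n)) {
      blocks <- vector("list", cfg$residual_blocks[i])
      cin <- if (i == 1L) cfg$in_channels else ch[i - 1L]
      stride <- if (i == 1L) 1L else 2L
      blocks[[1L]] <- new_residual_block(cin, ch[i], stride = stride,
                                         name = sprintf("enc%d.rb1", i))
      for (b in seq_len(cfg$residual_blocks[i])[-1L]) {
        blocks[[b]] <- new_residual_block(ch[i], ch[i],
                                          name = sprintf("enc%d.rb%d", i, b))
      }
      encoder[[i]] <- list(blocks = blocks, channels = ch[i])
    }
    decoder <- vector("list", n - 1L)
    for (i in seq.int(n - 1L, 1L)) {
      up <- new_convt2(ch[i + 1L], ch[i], name = sprintf("dec%d.up", i))
      gate <- if (cfg$attention_gates)
        new_attention_gate(ch[i], ch[i], name = sprintf("dec%d.ag", i))
      convs <- vector("list", cfg$decoder_convs_per_stage)
      cin <- 2L * ch[i]
      for (j in seq_len(cfg$decoder_convs_per_stage)) {
        convs[[j]] <- new_conv_unit(cin, ch[i], name = sprintf("dec%d.c%d", i, j))
        cin <- ch[i]
      }
      decoder[[i]] <- list(up = up, gate = gate, convs = convs)
    }
    head <- new_pointwise(ch[1L], 1L, name = "head")
    structure(list(cfg = cfg, encoder = encoder, decoder = decoder,
                   head = head), class = "tumor_net")
  })
}

#' Forward pass of the tumor network
#'
#' @param net A `tumor_net`.
#' @param x A 3D numeric array (normalized intensities) whose extents satisfy
#'   the network's divisibility constraint.
#' @return A 3D array of tumor probabilities with the extents of `x`.
#' @export
tumor_net_forward <- function(net, x) {
  t_out <- forward_tumor_tensor(net, as_input_tensor(x))
  array(t_out$value, t_out$sdim)
}

forward_tumor_tensor <- function(net, x) {
  cfg <- net$cfg
  div <- 2L^(cfg$n_stages - 1L)
  if (any(x$sdim %% div != 0L))
    stopf("input extents (%s) must be divisible by %d",
          paste(x$sdim, collapse = "x"), div)
  slope <- cfg$leaky_slope
  skips <- vector("list", cfg$n_stages)
  h <- x
  for (i in seq_len(cfg$n_stages)) {
    for (blk in net$encoder[[i]]$blocks) h <- fwd_residual_block(h, blk, slope)
    skips[[i]] <- h
  }
  for (i in seq.int(cfg$n_stages - 1L, 1L)) {
    dec <- net$decoder[[i]]
    g <- fwd_convt2(h, dec$up)
    s <- skips[[i]]
    if (!is.null(dec$gate)) s <- fwd_attention_gate(s, g, dec$gate, slope)
    h <- op_concat(s, g)
    for (cu in dec$convs) h <- fwd_conv_unit(h, cu, slope)
  }
  op_sigmoid(fwd_conv(h, net$head))
}

#' Symbolic shape pass through the tumor network
#'
#' Propagates an input extent through the stage graph without computing any
#' values: checks the divisibility constraint and returns the per-stage
#' spatial extents, confirming that the network accepts the patch.
#'
#' @param net A `tumor_net` (or a `tumor_net_config`).
#' @param extent Integer vector of three input extents, e.g. `c(192,128,128)`.
#' @return A data.frame with one row per stage: stage index, feature width,
#'   residual block count, and the stage's output extent per axis.
#' @export
tumor_net_shape_pass <- function(net, extent = NULL) {
  cfg <- if (inherits(net, "tumor_net")) net$cfg else net
  stopifnot(inherits(cfg, "tumor_net_config"))
  extent <- as.integer(extent %||% cfg$patch_size)
  if (length(extent) != 3L) stopf("extent must have length 3")
  div <- 2L^(cfg$n_stages - 1L)
  if (any(extent %% div != 0L))
    stopf("patch extent (%s) not divisible by 2^(n_stages-1) = %d",
          paste(extent, collapse = "x"), div)
  ext <- extent
  rows <- vector("list", cfg$n_stages)
  for (i in seq_len(cfg$n_stages)) {
    if (i > 1L) ext <- ext %/% 2L
    rows[[i]] <- data.frame(stage = i, channels = cfg$channels[i],
                            residual_blocks = cfg$residual_blocks[i],
                            nx = ext[1L], ny = ext[2L], nz = ext[3L])
  }
  do.call(rbind, rows)
}

#' Does the network accept a patch of the given extent?
#'
#' @inheritParams tumor_net_shape_pass
#' @return `TRUE` if the shape pass succeeds, `FALSE` otherwise.
#' @export
accepts_patch <- function(net, extent) {
  !inherits(try(tumor_net_shape_pass(net, extent), silent = TRUE), "try-error")
}

#' @export
print.tumor_net <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("Kidney Tumor 3D UNet: %d stages, %s parameters\n",
              cfg$n_stages, format(param_count(x), big.mark = ",")))
  tab <- tumor_net_shape_pass(x, cfg$patch_size)
  cat(sprintf("patch %s, attention gates %s\n",
              paste(cfg$patch_size, collapse = "x"),
              if (cfg$attention_gates) "on" else "off"))
  print(tab, row.names = FALSE)
  invisible(x)
}
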