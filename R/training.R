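# Loss and optimization for both stages: DiceCE, SGD (tumor stage) and
# AdamW (organ stage), patch-based sampling with foreground oversampling.

#' DiceCE compound loss
#'
#' `(1 - soft Dice) + binary cross-entropy`, both averaged over the patch.
#'
#' @param pred Per-voxel probabilities in (0,1) (array or vector).
#' @param target Binary field of the same shape.
#' @return Non-negative scalar loss.
#' @export
dice_ce_loss <- function(pred, target) {
  if (length(pred) != length(target)) stopf("pred and target shapes differ")
  p <- ag_tensor(matrix(as.numeric(pred), nrow = 1L))
  as.numeric(op_dice_ce(p, matrix(as.numeric(target), nrow = 1L))$value)
}

#' Training configuration
#'
#' Stage defaults follow the published settings: the tumor stage uses SGD
#' (lr 0.001, momentum 0.99, nesterov, polynomial decay) and the organ stage
#' AdamW (lr 3.5e-4, weight decay scaled by the decayed schedule); both use
#' the DiceCE loss. Epoch counts and patch geometry are configuration, not
#' claims.
#'
#' @param stage `"organ"` or `"tumor"`.
#' @param epochs Training epochs (>= 1).
#' @param patch_size Patch extent per axis.
#' @param batch_size Patches per optimizer step.
#' @param patches_per_volume Patches drawn per case per epoch.
#' @param foreground_oversampling Fraction of patches centred on a
#'   foreground voxel (default 0.5).
#' @param lr Initial learning rate; default depends on stage.
#' @param momentum,nesterov SGD parameters (tumor stage).
#' @param weight_decay AdamW weight decay (organ stage).
#' @param grad_clip Global gradient-norm clip; high-momentum SGD amplifies
#'   a single gradient spike for ~1/(1-momentum) steps, so clipping is the
#'   standard stabilizer.
#' @param augment An [augment_params()] or `NULL` to disable augmentation.
#' @param seed RNG seed for sampling and augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(stage = c("tumor", "organ"), epochs = 20L,
                         patch_size = c(64L, 64L, 64L), batch_size = 2L,
                         patches_per_volume = 1L,
                         foreground_oversampling = 0.5,
                         lr = NULL, momentum = 0.99, nesterov = TRUE,
                         weight_decay = 1e-5, grad_clip = 12,
                         augment = NULL, seed = 1L) {
  stage <- match.arg(stage)
  lr <- lr %||% if (stage == "tumor") 0.001 else 3.5e-4
  if (lr <= 0) stopf("learning rate must be > 0")
  if (epochs < 1L) stopf("epochs must be >= 1")
  structure(list(stage = stage, epochs = as.integer(epochs),
                 patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 patches_per_volume = as.integer(patches_per_volume),
                 foreground_oversampling = foreground_oversampling,
                 lr = lr, momentum = momentum, nesterov = isTRUE(nesterov),
                 weight_decay = weight_decay, grad_clip = grad_clip,
                 optimizer = if (stage == "tumor") "sgd" else "adamw",
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

# ---- optimizers -----------------------------------------------------------

step_values <- function(p, f) {
  if (is.list(p$value)) {
    for (k in seq_along(p$value)) {
      upd <- f(p$value[[k]], p$grad[[k]], p, k)
      p$value[[k]] <- upd
    }
  } else {
    p$value <- f(p$value, p$grad, p, 0L)
  }
  p$grad <- NULL
}

sgd_step <- function(params, lr, momentum, nesterov) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$state$v)) {
      p$state$v <- if (is.list(p$value)) {
        lapply(p$value, function(w) w * 0)
      } else {
        p$value * 0
      }
    }
    step_values(p, function(w, g, pp, k) {
      v_old <- if (k > 0L) pp$state$v[[k]] else pp$state$v
      v <- momentum * v_old + g
      if (k > 0L) pp$state$v[[k]] <- v else pp$state$v <- v
      upd <- if (nesterov) g + momentum * v else v
      w - lr * upd
    })
  }
}

adamw_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 1e-5, t = 1L) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (p in params) {
    if (is.null(p$grad)) next
    zero <- function() if (is.list(p$value))
      lapply(p$value, function(w) w * 0) else p$value * 0
    if (is.null(p$state$m)) { p$state$m <- zero(); p$state$v2 <- zero() }
    step_values(p, function(w, g, pp, k) {
      m_old <- if (k > 0L) pp$state$m[[k]] else pp$state$m
      v_old <- if (k > 0L) pp$state$v2[[k]] else pp$state$v2
      m <- beta1 * m_old + (1 - beta1) * g
      v <- beta2 * v_old + (1 - beta2) * g^2
      if (k > 0L) { pp$state$m[[k]] <- m; pp$state$v2[[k]] <- v }
      else { pp$state$m <- m; pp$state$v2 <- v }
      w - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * w)
    })
  }
}

# Scale all gradients down when their global L2 norm exceeds max_norm.
clip_gradients <- function(params, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(invisible(NULL))
  sq <- 0
  for (p in params) {
    if (is.null(p$grad)) next
    sq <- sq + if (is.list(p$grad)) sum(vapply(p$grad, function(g)
      sum(g^2), 0)) else sum(p$grad^2)
  }
  nrm <- sqrt(sq)
  if (nrm > max_norm) {
    sc <- max_norm / nrm
    for (p in params) {
      if (is.null(p$grad)) next
      p$grad <- if (is.list(p$grad)) lapply(p$grad, function(g) g * sc)
      else p$grad * sc
    }
  }
  invisible(NULL)
}

# ---- patch sampling -------------------------------------------------------

# Crop a patch around `centre` (1-based), clamped to the grid. Axes smaller
# than the patch are padded symmetrically with `fill`, exactly as the
# sliding-window inference path pads, so patch layout is identical in
# training and inference.
extract_patch <- function(arr, centre, patch, fill) {
  dims <- dim(arr)
  lo <- pmax(pmin(centre - patch %/% 2L, dims - patch + 1L), 1L)
  hi <- pmin(lo + patch - 1L, dims)
  sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (any(dim(sub) < patch)) {
    out <- array(fill, patch)
    off <- (patch - dim(sub)) %/% 2L
    out[off[1] + seq_len(dim(sub)[1]), off[2] + seq_len(dim(sub)[2]),
        off[3] + seq_len(dim(sub)[3])] <- sub
    sub <- out
  }
  sub
}

# Foreground-biased sampling: with probability fg_fraction the patch is
# guaranteed to contain a (uniformly chosen) foreground voxel, placed at a
# uniformly random offset inside the patch so no position prior leaks into
# training; otherwise the patch centre is uniform over the grid.
sample_patch <- function(vol_data, target, patch, fg_fraction) {
  dims <- dim(vol_data)
  fg <- NULL
  if (stats::runif(1) < fg_fraction) {
    fg_idx <- which(target != 0)
    if (length(fg_idx) > 0L) {
      pick <- fg_idx[sample.int(length(fg_idx), 1L)]
      fg <- arrayInd(pick, dims)[1L, ]
    }
  }
  centre <- if (!is.null(fg)) {
    jit <- sapply(patch, function(p) sample.int(p, 1L) - (p %/% 2L + 1L))
    as.integer(fg) - jit
  } else {
    sapply(dims, function(d) sample.int(d, 1L))
  }
  list(x = extract_patch(vol_data, centre, patch, min(vol_data)),
       y = extract_patch(target, centre, patch, 0))
}

stage_target <- function(mask_data, stage) {
  if (stage == "organ") (mask_data > 0L) * 1L else (mask_data == 2L) * 1L
}

# ---- training loop --------------------------------------------------------

#' Train a segmentation stage
#'
#' Patch-based training with foreground oversampling: each epoch visits
#' every case `patches_per_volume` times in a shuffled order, samples a
#' patch (centred on a foreground voxel with the configured probability),
#' optionally augments it, and accumulates DiceCE gradients over
#' `batch_size` patches per optimizer step. The run is reproducible for a
#' fixed seed in single-threaded CPU mode.
#'
#' @param net A `tumor_net` or `organ_net`.
#' @param cases List of preprocessed cases, each `list(vol = ct_volume,
#'   mask = label_mask)` on the isotropic normalized grid.
#' @param cfg A [train_config()].
#' @return A list with the trained `net` and a `log` data.frame
#'   (epoch, mean loss, lr).
#' @export
train_stage <- function(net, cases, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  fwd <- function(x) {
    if (inherits(net, "organ_net")) forward_organ_tensor(net, x)
    else forward_tumor_tensor(net, x)
  }
  targets <- lapply(cases, function(cs) stage_target(cs$mask$data, cfg$stage))
  if (!any(vapply(targets, function(t) any(t != 0), TRUE)))
    stopf("no %s foreground anywhere in the training set", cfg$stage)
  params <- net_params(net)
  log_rows <- vector("list", cfg$epochs)
  step_t <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- if (cfg$optimizer == "sgd")
        cfg$lr * (1 - (epoch - 1) / cfg$epochs)^0.9 else cfg$lr
      order_idx <- rep(sample.int(length(cases)), cfg$patches_per_volume)
      losses <- numeric(0)
      batch_n <- 0L
      for (pos in seq_along(order_idx)) {
        ci <- order_idx[pos]
        vol_d <- cases[[ci]]$vol$data
        tgt <- targets[[ci]]
        if (!is.null(cfg$augment)) {
          aug <- random_augment(cases[[ci]]$vol,
                                cases[[ci]]$mask, cfg$augment)
          vol_d <- aug$vol$data
          tgt <- stage_target(aug$mask$data, cfg$stage)
        }
        pt <- sample_patch(vol_d, tgt, cfg$patch_size,
                           cfg$foreground_oversampling)
        ag_tape_start()
        p <- fwd(ag_tensor(matrix(as.numeric(pt$x), nrow = 1L),
                           dim(pt$x)))
        loss <- op_dice_ce(p, matrix(as.numeric(pt$y), nrow = 1L))
        losses <- c(losses, as.numeric(loss$value))
        ag_backward(loss)
        batch_n <- batch_n + 1L
        if (batch_n == cfg$batch_size || pos == length(order_idx)) {
          for (pp in params) {
            if (!is.null(pp$grad)) {
              pp$grad <- if (is.list(pp$grad))
                lapply(pp$grad, function(g) g / batch_n)
              else pp$grad / batch_n
            }
          }
          clip_gradients(params, cfg$grad_clip)
          step_t <- step_t + 1L
          if (cfg$optimizer == "sgd")
            sgd_step(params, lr, cfg$momentum, cfg$nesterov)
          else adamw_step(params, lr, weight_decay = cfg$weight_decay,
                          t = step_t)
          batch_n <- 0L
        }
      }
      log_rows[[epoch]] <- data.frame(epoch = epoch,
                                      loss = mean(losses), lr = lr)
    }
  })
  list(net = net, log = do.call(rbind, log_rows))
}
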