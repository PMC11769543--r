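# Reverse-mode tape over C x N feature maps.
#
# A "tensor" is an environment holding $value, a C x N double matrix whose
# columns enumerate voxels in column-major (x, y, z) order, with the spatial
# extents in $sdim. Operations record themselves on an implicit tape; calling
# ag_backward() on a scalar-valued node replays the tape in reverse and
# accumulates vector-Jacobian products into every upstream node, including
# parameter leaves. When no tape is active the same ops run value-only, which
# is the inference path.

.autograd <- new.env(parent = emptyenv())
.autograd$tape <- NULL

ag_tape_active <- function() !is.null(.autograd$tape)

ag_tape_start <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 512L)
  tape$n <- 0L
  .autograd$tape <- tape
  invisible(tape)
}

ag_tape_stop <- function() {
  .autograd$tape <- NULL
  invisible(NULL)
}

#' @noRd
ag_no_grad <- function(expr) {
  old <- .autograd$tape
  .autograd$tape <- NULL
  on.exit(.autograd$tape <- old)
  force(expr)
}

ag_tensor <- function(value, sdim = NULL) {
  node <- new.env(parent = emptyenv())
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  node$value <- value
  node$sdim <- sdim
  node$grad <- NULL
  node$param <- FALSE
  node
}

# Trainable leaf. $grad accumulates during backward; $state carries
# optimizer slots.
ag_param <- function(value, name = "") {
  node <- ag_tensor(value)
  node$param <- TRUE
  node$name <- name
  node$state <- list()
  node
}

ag_record <- function(node, parents, vjp) {
  tape <- .autograd$tape
  if (is.null(tape)) return(node)
  node$parents <- parents
  node$vjp <- vjp
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  tape$nodes[[tape$n]] <- node
  node
}

ag_accumulate <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g
  else if (is.list(g)) node$grad <- mapply(`+`, node$grad, g, SIMPLIFY = FALSE)
  else node$grad <- node$grad + g
}

# Backward pass from a scalar node. Clears intermediate grads as it goes;
# parameter grads persist until the optimizer consumes them.
ag_backward <- function(root) {
  tape <- .autograd$tape
  if (is.null(tape)) stop("no active tape; gradients were not recorded")
  root$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$vjp)) next
    gs <- node$vjp(node$grad)
    for (j in seq_along(node$parents)) {
      if (!is.null(gs[[j]])) ag_accumulate(node$parents[[j]], gs[[j]])
    }
    if (!node$param) node$grad <- NULL
  }
  ag_tape_stop()
  invisible(NULL)
}

# ---- elementwise and shape ops -------------------------------------------

op_add <- function(a, b) {
  out <- ag_tensor(a$value + b$value, a$sdim)
  ag_record(out, list(a, b), function(g) list(g, g))
}

op_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  out <- ag_tensor(av * bv, a$sdim)
  ag_record(out, list(a, b), function(g) list(g * bv, g * av))
}

# Multiply every channel of x (C x N) by a single-channel map alpha (1 x N).
op_scale <- function(x, alpha) {
  xv <- x$value
  al <- alpha$value
  out <- ag_tensor(xv * rep(al, each = nrow(xv)), x$sdim)
  ag_record(out, list(x, alpha), function(g) {
    list(g * rep(al, each = nrow(xv)),
         matrix(colSums(g * xv), nrow = 1L))
  })
}

op_concat <- function(a, b) {
  ca <- nrow(a$value)
  out <- ag_tensor(rbind(a$value, b$value), a$sdim)
  ag_record(out, list(a, b), function(g) {
    list(g[seq_len(ca), , drop = FALSE], g[-seq_len(ca), , drop = FALSE])
  })
}

op_leaky_relu <- function(x, slope = 0.01) {
  xv <- x$value
  neg <- xv < 0
  y <- xv
  y[neg] <- slope * xv[neg]
  out <- ag_tensor(y, x$sdim)
  ag_record(out, list(x), function(g) {
    gg <- g
    gg[neg] <- slope * g[neg]
    list(gg)
  })
}

op_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$value))
  out <- ag_tensor(y, x$sdim)
  ag_record(out, list(x), function(g) list(g * y * (1 - y)))
}

op_gelu <- function(x) {
  xv <- x$value
  p <- stats::pnorm(xv)
  out <- ag_tensor(xv * p, x$sdim)
  ag_record(out, list(x), function(g) list(g * (p + xv * stats::dnorm(xv))))
}

# ---- linear / convolution ops --------------------------------------------

# Pointwise (1x1x1) convolution, also the per-token linear layer.
op_linear <- function(x, W, b) {
  xv <- x$value
  y <- W$value %*% xv + b$value[, 1L]
  out <- ag_tensor(y, x$sdim)
  ag_record(out, list(x, W, b), function(g) {
    list(crossprod(W$value, g),
         tcrossprod(g, xv),
         matrix(rowSums(g), ncol = 1L))
  })
}

# k^3 convolution with 'same'-style zero padding, stride 1 or 2, lowered to
# tiled im2col + GEMM inside the C++ kernel. W is Cout x (Cin * k^3) in
# im2col row order (c + Cin * (kx + k * (ky + k * kz))).
op_conv3d <- function(x, W, b, stride = 1L, k = 3L, pad = 1L) {
  sdim <- x$sdim
  xv <- x$value
  y <- .conv3dForward(xv, as.integer(sdim), W$value, b$value[, 1L],
                      as.integer(k), as.integer(pad), as.integer(stride))
  odim <- (sdim + 2L * pad - k) %/% stride + 1L
  out <- ag_tensor(y, odim)
  ag_record(out, list(x, W, b), function(g) {
    bw <- .conv3dBackward(g, xv, as.integer(sdim), W$value,
                          as.integer(k), as.integer(pad), as.integer(stride))
    list(bw$dx, bw$dW, matrix(bw$db, ncol = 1L))
  })
}

# Index map for the 2x stride-2 transposed convolution: offset o in 0..7
# places input voxel (i,j,k) at output voxel (2i+ox, 2j+oy, 2k+oz).
.convt2_indices <- function(sdim) {
  nx <- sdim[1L]; ny <- sdim[2L]; nz <- sdim[3L]
  ox2 <- 2L * nx; oy2 <- 2L * ny
  i <- rep.int(seq_len(nx) - 1L, ny * nz)
  j <- rep.int(rep(seq_len(ny) - 1L, each = nx), nz)
  k <- rep(seq_len(nz) - 1L, each = nx * ny)
  lapply(0:7, function(o) {
    dx <- o %% 2L; dy <- (o %/% 2L) %% 2L; dz <- o %/% 4L
    (2L * i + dx) + ox2 * ((2L * j + dy) + oy2 * (2L * k + dz)) + 1L
  })
}

# Transposed convolution, kernel 2, stride 2 (resolution-doubling deconv).
# W is a list of 8 Cout x Cin matrices, one per output offset.
op_convt2 <- function(x, W, b) {
  sdim <- x$sdim
  xv <- x$value
  cout <- nrow(W$value[[1L]])
  idx <- .convt2_indices(sdim)
  y <- matrix(0, cout, 8L * ncol(xv))
  for (o in 1:8) y[, idx[[o]]] <- W$value[[o]] %*% xv
  y <- y + b$value[, 1L]
  out <- ag_tensor(y, 2L * sdim)
  ag_record(out, list(x, W, b), function(g) {
    dx <- matrix(0, nrow(xv), ncol(xv))
    dW <- vector("list", 8L)
    for (o in 1:8) {
      go <- g[, idx[[o]], drop = FALSE]
      dW[[o]] <- tcrossprod(go, xv)
      dx <- dx + crossprod(W$value[[o]], go)
    }
    list(dx, dW, matrix(rowSums(g), ncol = 1L))
  })
}

# ---- normalisation --------------------------------------------------------

# Instance normalization: per-channel moments over the spatial axes.
op_instance_norm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  n <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- xhat * gamma$value[, 1L] + beta$value[, 1L]
  out <- ag_tensor(y, x$sdim)
  ag_record(out, list(x, gamma, beta), function(g) {
    dxhat <- g * gamma$value[, 1L]
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    list(dx,
         matrix(rowSums(g * xhat), ncol = 1L),
         matrix(rowSums(g), ncol = 1L))
  })
}

# Layer normalization over channels, per voxel/token (columns).
op_layer_norm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  c_ <- nrow(xv)
  mu <- colMeans(xv)
  xc <- sweep(xv, 2L, mu)
  v <- colMeans(xc * xc)
  inv <- rep(1 / sqrt(v + eps), each = c_)
  xhat <- xc * inv
  y <- xhat * gamma$value[, 1L] + beta$value[, 1L]
  out <- ag_tensor(y, x$sdim)
  ag_record(out, list(x, gamma, beta), function(g) {
    dxhat <- g * gamma$value[, 1L]
    m1 <- rep(colMeans(dxhat), each = c_)
    m2 <- rep(colMeans(dxhat * xhat), each = c_)
    list((dxhat - m1 - xhat * m2) * inv,
         matrix(rowSums(g * xhat), ncol = 1L),
         matrix(rowSums(g), ncol = 1L))
  })
}

# ---- losses ---------------------------------------------------------------

# Compound segmentation loss: (1 - soft Dice) + binary cross-entropy, both
# over the whole patch. p are probabilities in (0,1); target is 0/1.
op_dice_ce <- function(p, target, smooth = 1, eps = 1e-7) {
  pv <- p$value
  tv <- target
  pc <- pmin(pmax(pv, eps), 1 - eps)
  inter <- sum(pv * tv)
  denom <- sum(pv) + sum(tv)
  dice <- (2 * inter + smooth) / (denom + smooth)
  ce <- -mean(tv * log(pc) + (1 - tv) * log(1 - pc))
  out <- ag_tensor(matrix((1 - dice) + ce, 1L, 1L), NULL)
  n <- length(pv)
  ag_record(out, list(p), function(g) {
    gd <- as.numeric(g)
    ddice <- -(2 * tv * (denom + smooth) - (2 * inter + smooth)) /
      (denom + smooth)^2
    dce <- -(tv / pc - (1 - tv) / (1 - pc)) / n
    inside <- (pv > eps) & (pv < 1 - eps)
    list(gd * (ddice + dce * inside))
  })
}
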