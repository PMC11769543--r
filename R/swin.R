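# Shifted-window multi-head self-attention over 3D feature maps.
#
# Tokens are voxels (columns of the C x N map). A window partition groups
# voxels into non-overlapping boxes of `window` voxels per axis (clamped to
# the grid extent); the shifted variant rolls the grid by half a window
# before partitioning, which lets information cross window borders on
# alternate blocks. Shifts are cyclic and unmasked.

# Column indices of each window, as a list of integer vectors.
window_partition_indices <- function(sdim, window, shift = FALSE) {
  w <- pmin(as.integer(window), sdim)
  nx <- sdim[1L]; ny <- sdim[2L]; nz <- sdim[3L]
  if (any(sdim %% w != 0L))
    stopf("grid extents (%s) not divisible by window (%s)",
          paste(sdim, collapse = "x"), paste(w, collapse = "x"))
  sh <- if (shift) w %/% 2L else c(0L, 0L, 0L)
  i <- rep.int(seq_len(nx) - 1L, ny * nz)
  j <- rep.int(rep(seq_len(ny) - 1L, each = nx), nz)
  k <- rep(seq_len(nz) - 1L, each = nx * ny)
  xs <- (i + sh[1L]) %% nx
  ys <- (j + sh[2L]) %% ny
  zs <- (k + sh[3L]) %% nz
  grp <- (xs %/% w[1L]) + (nx %/% w[1L]) *
    ((ys %/% w[2L]) + (ny %/% w[2L]) * (zs %/% w[3L]))
  split(seq_len(nx * ny * nz), grp)
}

# Fused windowed multi-head attention with hand-derived backward.
op_window_attention <- function(x, Wqkv, bqkv, Wproj, bproj,
                                window, shift = FALSE, heads = 2L) {
  sdim <- x$sdim
  xv <- x$value
  C <- nrow(xv)
  stopifnot(C %% heads == 0L)
  dh <- C %/% heads
  scale <- 1 / sqrt(dh)
  idx <- window_partition_indices(sdim, window, shift)
  y <- matrix(0, C, ncol(xv))
  cache <- vector("list", length(idx))
  for (wi in seq_along(idx)) {
    cols <- idx[[wi]]
    Xw <- xv[, cols, drop = FALSE]
    QKV <- Wqkv$value %*% Xw + bqkv$value[, 1L]
    Q <- QKV[seq_len(C), , drop = FALSE]
    K <- QKV[C + seq_len(C), , drop = FALSE]
    V <- QKV[2L * C + seq_len(C), , drop = FALSE]
    O <- matrix(0, C, length(cols))
    A_list <- vector("list", heads)
    for (h in seq_len(heads)) {
      rs <- (h - 1L) * dh + seq_len(dh)
      S <- crossprod(Q[rs, , drop = FALSE], K[rs, , drop = FALSE]) * scale
      S <- S - apply(S, 1L, max)            # row-wise stabilisation
      A <- exp(S)
      A <- A / rowSums(A)
      O[rs, ] <- V[rs, , drop = FALSE] %*% t(A)
      A_list[[h]] <- A
    }
    y[, cols] <- Wproj$value %*% O + bproj$value[, 1L]
    cache[[wi]] <- list(Xw = Xw, Q = Q, K = K, V = V, A = A_list, O = O)
  }
  out <- ag_tensor(y, sdim)
  ag_record(out, list(x, Wqkv, bqkv, Wproj, bproj), function(g) {
    dx <- matrix(0, C, ncol(xv))
    dWqkv <- matrix(0, 3L * C, C)
    dbqkv <- matrix(0, 3L * C, 1L)
    dWproj <- matrix(0, C, C)
    dbproj <- matrix(0, C, 1L)
    for (wi in seq_along(idx)) {
      cols <- idx[[wi]]
      cc <- cache[[wi]]
      gy <- g[, cols, drop = FALSE]
      dWproj <- dWproj + tcrossprod(gy, cc$O)
      dbproj <- dbproj + rowSums(gy)
      dO <- crossprod(Wproj$value, gy)
      dQKV <- matrix(0, 3L * C, length(cols))
      for (h in seq_len(heads)) {
        rs <- (h - 1L) * dh + seq_len(dh)
        A <- cc$A[[h]]
        Vh <- cc$V[rs, , drop = FALSE]
        dOh <- dO[rs, , drop = FALSE]
        dV <- dOh %*% A
        dA <- crossprod(dOh, Vh)
        dS <- A * (dA - rowSums(dA * A)) * scale
        dQKV[rs, ] <- cc$K[rs, , drop = FALSE] %*% t(dS)
        dQKV[C + rs, ] <- cc$Q[rs, , drop = FALSE] %*% dS
        dQKV[2L * C + rs, ] <- dV
      }
      dWqkv <- dWqkv + tcrossprod(dQKV, cc$Xw)
      dbqkv <- dbqkv + rowSums(dQKV)
      dx[, cols] <- dx[, cols] + crossprod(Wqkv$value, dQKV)
    }
    list(dx, dWqkv, matrix(dbqkv, ncol = 1L), dWproj,
         matrix(dbproj, ncol = 1L))
  })
}

# One transformer block: pre-norm windowed attention and a pre-norm MLP,
# each with a residual connection.
new_swin_block <- function(c_, heads, mlp_ratio = 2L, shift = FALSE,
                           name = "swin") {
  hidden <- c_ * mlp_ratio
  list(kind = "swin_block", shift = shift, heads = as.integer(heads),
       norm1 = new_norm(c_, paste0(name, ".ln1")),
       qkv_W = ag_param(matrix(stats::rnorm(3 * c_ * c_, sd = sqrt(1 / c_)),
                               3L * c_, c_), paste0(name, ".qkv")),
       qkv_b = ag_param(matrix(0, 3L * c_, 1L), paste0(name, ".qkv.b")),
       proj_W = ag_param(matrix(stats::rnorm(c_ * c_, sd = sqrt(1 / c_)),
                                c_, c_), paste0(name, ".proj")),
       proj_b = ag_param(matrix(0, c_, 1L), paste0(name, ".proj.b")),
       norm2 = new_norm(c_, paste0(name, ".ln2")),
       mlp1 = new_pointwise(c_, hidden, paste0(name, ".mlp1")),
       mlp2 = new_pointwise(hidden, c_, paste0(name, ".mlp2")))
}

fwd_swin_block <- function(x, blk, window) {
  a <- op_window_attention(fwd_lnorm(x, blk$norm1), blk$qkv_W, blk$qkv_b,
                           blk$proj_W, blk$proj_b, window,
                           shift = blk$shift, heads = blk$heads)
  x <- op_add(x, a)
  m <- fwd_conv(op_gelu(fwd_conv(fwd_lnorm(x, blk$norm2), blk$mlp1)), blk$mlp2)
  op_add(x, m)
}
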