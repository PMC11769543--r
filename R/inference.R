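# Sliding-window inference with Gaussian-weighted blending.

# Largest window <= max_window compatible with `divisor` that fits `extent`
# (per axis); volumes smaller than one divisor unit force padding.
fit_window <- function(extent, divisor, max_window) {
  w <- pmin(max_window, (extent %/% divisor) * divisor)
  pmax(w, divisor)
}

# Separable Gaussian importance map: windows overlap by `overlap`, and the
# centre of each window counts more than its rim, suppressing seam artifacts.
gaussian_window_weights <- function(window, sigma_scale = 0.125) {
  ws <- lapply(window, function(w) {
    x <- seq_len(w) - (w + 1) / 2
    g <- exp(-x^2 / (2 * (sigma_scale * w)^2))
    g / max(g)
  })
  out <- outer(outer(ws[[1]], ws[[2]]), ws[[3]])
  array(pmax(out, 1e-4), window)
}

window_starts <- function(d, w, overlap) {
  if (d <= w) return(0L)
  stride <- max(1L, as.integer(round(w * (1 - overlap))))
  s <- seq.int(0L, d - w, by = stride)
  if (s[length(s)] != d - w) s <- c(s, d - w)
  s
}

# Apply fwd_fun (3D array -> 3D probability array of identical extent) over
# the whole volume. Axes smaller than the window are padded symmetrically
# with the volume's minimum value and cropped back.
infer_sliding_window <- function(data, window, fwd_fun, overlap = 0.5) {
  dims <- dim(data)
  pad <- pmax(window - dims, 0L)
  lo <- pad %/% 2L
  if (any(pad > 0L)) {
    big <- array(min(data), dims + pad)
    big[lo[1] + seq_len(dims[1]), lo[2] + seq_len(dims[2]),
        lo[3] + seq_len(dims[3])] <- data
    data <- big
  }
  d <- dim(data)
  acc <- array(0, d)
  wsum <- array(0, d)
  wts <- gaussian_window_weights(window)
  sx <- window_starts(d[1], window[1], overlap)
  sy <- window_starts(d[2], window[2], overlap)
  sz <- window_starts(d[3], window[3], overlap)
  for (z0 in sz) for (y0 in sy) for (x0 in sx) {
    ix <- x0 + seq_len(window[1])
    iy <- y0 + seq_len(window[2])
    iz <- z0 + seq_len(window[3])
    p <- fwd_fun(data[ix, iy, iz, drop = FALSE])
    acc[ix, iy, iz] <- acc[ix, iy, iz] + p * wts
    wsum[ix, iy, iz] <- wsum[ix, iy, iz] + wts
  }
  prob <- acc / wsum
  prob[lo[1] + seq_len(dims[1]), lo[2] + seq_len(dims[2]),
       lo[3] + seq_len(dims[3]), drop = FALSE]
}
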