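# Shared fixtures, generated in code.

# A small noiseless phantom with one intrarenal tumor.
fixture_phantom <- function(ud_cm = 1.6, noise_sd = 0, seed = 3,
                            exophytic = FALSE, offset = -50) {
  generate_phantom(
    phantom_spec(noise_sd = noise_sd,
                 tumors = list(list(ud_cm = ud_cm, intensity_offset = offset,
                                    exophytic = exophytic))),
    rng = seed)
}

# Binary 3D array with given TRUE voxel coordinate rows.
mask_from_coords <- function(dims, coords) {
  arr <- array(0L, dims)
  arr[coords] <- 1L
  arr
}

# A tiny tumor-net configuration usable on 16^3 inputs.
tiny_tumor_cfg <- function(attention = TRUE) {
  tumor_net_config(n_stages = 3L, channels = c(4L, 8L, 12L),
                   residual_blocks = c(1L, 1L, 1L),
                   attention_gates = attention,
                   patch_size = c(16L, 16L, 16L), batch_size = 1L)
}

# Brute-force voxel confusion oracle: explicit per-voxel loop.
oracle_confusion <- function(pred, gt) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] != 0; g <- gt[i] != 0
    if (p && g) tp <- tp + 1L
    else if (p && !g) fp <- fp + 1L
    else if (!p && g) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Brute-force percentile oracle: sort + linear interpolation between order
# statistics (type-7 definition, computed from first principles).
oracle_percentile <- function(values, p) {
  s <- sort(values)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
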