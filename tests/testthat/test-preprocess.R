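# Percentile clipping, z-score normalization, isotropic resampling.

test_that("constant data yields degenerate stats and normalization refuses", {
  v <- ct_volume(array(40, c(4, 4, 4)), c(1, 1, 1))
  st <- compute_intensity_stats(list(v))
  expect_equal(st$lower_clip, 40)
  expect_equal(st$upper_clip, 40)
  expect_equal(st$mean, 40)
  expect_equal(st$std, 0)
  expect_error(clip_and_normalize(v, st), "standard deviation is 0")
})

test_that("pooled percentiles match the sort-based oracle", {
  set.seed(31)
  vals <- runif(1000, 0, 100)
  v <- ct_volume(array(vals, c(10, 10, 10)), c(1, 1, 1))
  st <- compute_intensity_stats(list(v))
  expect_equal(st$lower_clip, oracle_percentile(vals, 0.005))
  expect_equal(st$upper_clip, oracle_percentile(vals, 0.995))
  expect_equal(st$lower_clip, 0.5, tolerance = 0.5)
  expect_equal(st$upper_clip, 99.5, tolerance = 0.5)
  # smaller random instances, full agreement with the oracle
  for (rep in 1:20) {
    n <- sample(50:500, 1)
    vals <- rnorm(n, sample(-500:500, 1), runif(1, 1, 300))
    d <- c(n, 1L, 1L)
    st <- compute_intensity_stats(list(ct_volume(array(vals, d), c(1, 1, 1))))
    expect_equal(st$lower_clip, oracle_percentile(vals, 0.005))
    expect_equal(st$upper_clip, oracle_percentile(vals, 0.995))
  }
})

test_that("pooled stats equal stats of the concatenated voxels", {
  set.seed(32)
  v1 <- ct_volume(array(rnorm(4^3, -500, 50), c(4, 4, 4)), c(1, 1, 1))
  v2 <- ct_volume(array(rnorm(5^3, 300, 20), c(5, 5, 5)), c(1, 1, 1))
  st <- compute_intensity_stats(list(v1, v2))
  pool <- c(as.vector(v1$data), as.vector(v2$data))
  expect_equal(st$lower_clip, oracle_percentile(pool, 0.005))
  expect_equal(st$upper_clip, oracle_percentile(pool, 0.995))
  clipped <- pmin(pmax(pool, st$lower_clip), st$upper_clip)
  expect_equal(st$mean, mean(clipped))
  expect_equal(st$std, sd(clipped))
})

test_that("normalization maps the training pool to mean 0, variance 1", {
  set.seed(33)
  vols <- lapply(1:3, function(i)
    ct_volume(array(rnorm(8^3, 100 * i, 50), c(8, 8, 8)), c(1, 1, 1)))
  st <- compute_intensity_stats(vols)
  normed <- lapply(vols, clip_and_normalize, stats = st)
  pool <- unlist(lapply(normed, function(v) as.vector(v$data)))
  expect_equal(mean(pool), 0, tolerance = 1e-6)
  expect_equal(sd(pool), 1, tolerance = 1e-6)
  # re-deriving stats from the normalized pool is idempotent in
  # distribution (the second clipping pass may shave a sliver of the tails,
  # so this is a looser, distribution-level statement)
  st2 <- compute_intensity_stats(normed)
  expect_equal(st2$mean, 0, tolerance = 1e-3)
  expect_equal(st2$std, 1, tolerance = 1e-3)
})

test_that("single voxels obey the normalization definition", {
  v <- ct_volume(array(c(-100, 0, 40, 200), c(4, 1, 1)), c(1, 1, 1))
  st <- compute_intensity_stats(list(v))
  nv <- clip_and_normalize(ct_volume(array(st$mean, c(1, 1, 1)),
                                     c(1, 1, 1)), st)
  expect_equal(as.numeric(nv$data), 0)
  below <- clip_and_normalize(ct_volume(array(st$lower_clip - 999,
                                              c(1, 1, 1)), c(1, 1, 1)), st)
  expect_equal(as.numeric(below$data), (st$lower_clip - st$mean) / st$std)
})

test_that("resampling follows the extent formula and preserves identity", {
  v <- ct_volume(array(rnorm(1000), c(10, 10, 10)), c(2, 2, 2))
  r <- resample_isotropic(v, 1)
  expect_equal(dim(r$data), c(20L, 20L, 20L))
  expect_equal(r$spacing, c(1, 1, 1))
  v1 <- ct_volume(array(rnorm(8^3), c(8, 8, 8)), c(1, 1, 1))
  expect_equal(resample_isotropic(v1, 1)$data, v1$data, tolerance = 1e-12)
  expect_error(resample_isotropic(v1, 0), "> 0")
  expect_error(resample_isotropic(v1, -2), "> 0")
})

test_that("label volume is conserved when resampling a sphere 3mm -> 1mm", {
  dims <- c(24L, 24L, 24L)
  cx <- (seq_len(24) - 0.5) * 3
  co <- list(x = array(rep(cx, 24 * 24), dims),
             y = array(rep(rep(cx, each = 24), 24), dims),
             z = array(rep(cx, each = 24 * 24), dims))
  r_mm <- 15
  sph <- ((co$x - 36)^2 + (co$y - 36)^2 + (co$z - 36)^2) <= r_mm^2
  m <- label_mask(sph * 1L, c(3, 3, 3))
  rs <- resample_isotropic(m, 1)
  expect_setequal(unique(as.vector(rs$data)), c(0L, 1L))
  vol_in <- sum(m$data) * 27      # mm^3
  vol_out <- sum(rs$data) * 1
  expect_lt(abs(vol_out - vol_in) / vol_in, 0.10)
  # and against the analytic sphere volume
  expect_lt(abs(vol_out - 4 / 3 * pi * r_mm^3) / (4 / 3 * pi * r_mm^3), 0.10)
})

test_that("mask resampling never invents labels", {
  ph <- fixture_phantom(seed = 35)
  for (t in c(0.7, 1.3, 2.0)) {
    rs <- resample_isotropic(ph$mask, t)
    expect_true(all(rs$data %in% c(0L, 1L, 2L)))
  }
})

test_that("stats survive the config serialization round trip", {
  ph <- fixture_phantom(seed = 36)
  st <- compute_intensity_stats(list(ph$vol))
  back <- nephroseg:::stats_from_list(nephroseg:::stats_to_list(st))
  expect_equal(back$lower_clip, st$lower_clip)
  expect_equal(back$mean, st$mean)
  expect_equal(back$std, st$std)
})
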