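# Stage one: organ network structure, VOI extraction, crop/paste.

test_that("default organ encoder has four steps of two attention blocks", {
  net <- build_organ_net(organ_net_config(base_channels = 8L), seed = 1)
  st <- organ_net_structure(net)
  expect_equal(nrow(st), 4L)
  expect_true(all(st$blocks == 2L))
  expect_true(all(st$kind == "transformer"))
  expect_equal(st$channels, 8L * c(1L, 2L, 4L, 8L))
})

test_that("organ forward pass maps a window to probabilities of equal extent", {
  cfg <- organ_net_config(encoder_steps = 2L, window_input_size = 16L,
                          window_size = 2L, base_channels = 4L)
  net <- build_organ_net(cfg, seed = 2)
  x <- array(rnorm(16^3), c(16, 16, 16))
  p1 <- organ_net_forward(net, x)
  expect_equal(dim(p1), c(16L, 16L, 16L))
  expect_true(all(p1 > 0 & p1 < 1))
  # determinism in eval mode
  expect_identical(p1, organ_net_forward(net, x))
})

test_that("window_input_size must be divisible by 2^encoder_steps", {
  expect_error(organ_net_config(encoder_steps = 4L, window_input_size = 120L),
               "divisible")
})

test_that("a head forced strongly negative yields an empty mask, and a
           threshold of 1 always does", {
  cfg <- organ_net_config(backend = "cnn",
                          cnn_channels = c(4L, 8L), cnn_blocks = c(1L, 1L))
  net <- build_organ_net(cfg, seed = 3)
  ph <- fixture_phantom(seed = 41)
  st <- compute_intensity_stats(list(ph$vol))
  nv <- clip_and_normalize(ph$vol, st)
  net$unet$head$W$value[] <- 0
  net$unet$head$b$value[] <- -30
  m <- segment_kidney(nv, net, window = c(32L, 32L, 32L))
  expect_equal(sum(m$data), 0)
  net$unet$head$b$value[] <- 3
  m1 <- segment_kidney(nv, net, threshold = 1.0, window = c(32L, 32L, 32L))
  expect_equal(sum(m1$data), 0)
})

test_that("VOI expansion follows the 25% extent rule", {
  dims <- c(100L, 100L, 100L)
  arr <- array(0L, dims)
  arr[31:70, 31:70, 31:70] <- 1L   # extent 40 per axis, far from borders
  m <- label_mask(arr, c(1, 1, 1))
  vois <- extract_vois(m, expansion = 0.25, min_component_voxels = 10L)
  expect_length(vois, 1L)
  expect_equal(nephroseg:::voi_extent(vois[[1]]), c(50L, 50L, 50L))
  # centred: 5 voxels of margin per side
  expect_equal(vois[[1]]$start, vois[[1]]$source_start - 5L)
})

test_that("VOIs clip at the grid edge and keep at most the two largest
           components", {
  dims <- c(40L, 40L, 40L)
  arr <- array(0L, dims)
  arr[1:10, 1:10, 1:10] <- 1L        # touches the corner
  arr[25:38, 25:38, 25:38] <- 1L
  arr[20, 2, 38] <- 1L               # small noise blob below min size
  m <- label_mask(arr, c(1, 1, 1))
  vois <- extract_vois(m, min_component_voxels = 50L)
  expect_length(vois, 2L)
  expect_true(all(vapply(vois, function(v) all(v$start >= 0L), TRUE)))
  expect_true(all(vapply(vois, function(v) all(v$stop <= dims), TRUE)))
  # three large components: only the two largest survive
  arr[15:18, 15:18, 15:18] <- 1L
  vois3 <- extract_vois(label_mask(arr, c(1, 1, 1)),
                        min_component_voxels = 10L)
  expect_length(vois3, 2L)
  expect_length(extract_vois(label_mask(array(0L, dims), c(1, 1, 1))), 0L)
})

test_that("crop then paste restores the original inside the box", {
  ph <- fixture_phantom(seed = 42)
  organ <- label_mask((ph$mask$data > 0) * 1L, ph$mask$spacing)
  v <- extract_vois(organ)[[1]]
  sub <- crop_volume(ph$vol, v)
  expect_equal(dim(sub$data), nephroseg:::voi_extent(v))
  zero <- array(0, dim(ph$vol$data))
  back <- paste_volume(zero, sub$data, v)
  expect_equal(back[v$start[1] + seq_len(v$stop[1] - v$start[1]),
                    v$start[2] + seq_len(v$stop[2] - v$start[2]),
                    v$start[3] + seq_len(v$stop[3] - v$start[3])],
               sub$data)
  outside <- back
  outside[v$start[1] + seq_len(v$stop[1] - v$start[1]),
          v$start[2] + seq_len(v$stop[2] - v$start[2]),
          v$start[3] + seq_len(v$stop[3] - v$start[3])] <- 0
  expect_true(all(outside == 0))
  # full-volume voi is the identity
  full <- voi(c(0L, 0L, 0L), dim(ph$vol$data))
  expect_equal(crop_volume(ph$vol, full)$data, ph$vol$data)
  # a tumor fully inside the voi keeps its voxel count
  subm <- crop_volume(ph$mask, v)
  expect_equal(sum(subm$data == 2L), sum(ph$mask$data == 2L))
})

test_that("every tumor voxel lies inside an expanded VOI (GT organ masks)", {
  set.seed(43)
  for (seed in sample.int(10000, 25)) {
    ph <- generate_phantom(
      phantom_spec(noise_sd = 10,
                   tumors = list(list(ud_cm = runif(1, 0.8, 1.8),
                                      exophytic = runif(1) < 0.3))),
      rng = seed)
    organ <- label_mask((ph$mask$data > 0) * 1L, ph$mask$spacing)
    vois <- extract_vois(organ)
    tum <- which(ph$mask$data == 2L, arr.ind = TRUE) - 1L
    inside <- rep(FALSE, nrow(tum))
    for (v in vois) {
      inside <- inside |
        (tum[, 1] >= v$start[1] & tum[, 1] < v$stop[1] &
           tum[, 2] >= v$start[2] & tum[, 2] < v$stop[2] &
           tum[, 3] >= v$start[3] & tum[, 3] < v$stop[3])
    }
    expect_true(all(inside))
  }
})

test_that("VOI extraction is deterministic given the mask", {
  ph <- fixture_phantom(seed = 44, noise_sd = 10)
  organ <- label_mask((ph$mask$data > 0) * 1L, ph$mask$spacing)
  v1 <- extract_vois(organ)
  v2 <- extract_vois(organ)
  expect_identical(v1, v2)
  expect_lte(length(v1), 2L)
})
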