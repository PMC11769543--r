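# DiceCE loss, optimizers, and the patch-based training loop.

test_that("DiceCE obeys its closed forms", {
  t <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  # perfect hard prediction: loss vanishes up to the clamping constant
  expect_lt(dice_ce_loss(t, t), 1e-5)
  # uniform 0.5 prediction: the CE term is exactly ln 2
  p_half <- array(0.5, c(4, 4, 4))
  d_soft <- (2 * sum(0.5 * t) + 1) / (sum(p_half) + sum(t) + 1)
  expect_equal(dice_ce_loss(p_half, t), (1 - d_soft) + log(2),
               tolerance = 1e-12)
  expect_error(dice_ce_loss(array(0.5, c(2, 2, 2)), t), "shapes differ")
})

test_that("DiceCE matches a hand-computed 2x2x2 oracle", {
  set.seed(71)
  p <- array(runif(8, 0.05, 0.95), c(2, 2, 2))
  t <- array(c(1, 0, 0, 1, 1, 0, 0, 0), c(2, 2, 2))
  soft_dice <- (2 * sum(p * t) + 1) / (sum(p) + sum(t) + 1)
  ce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  expect_equal(dice_ce_loss(p, t), (1 - soft_dice) + ce, tolerance = 1e-12)
  expect_gte(dice_ce_loss(p, t), 0)
})

test_that("the loss is invariant to simultaneous mirroring", {
  set.seed(72)
  p <- array(runif(4^3, 0.01, 0.99), c(4, 4, 4))
  t <- array(rbinom(4^3, 1, 0.3), c(4, 4, 4))
  expect_equal(dice_ce_loss(p, t),
               dice_ce_loss(p[4:1, , ], t[4:1, , ]))
})

test_that("one epoch on two phantoms is bit-reproducible under a fixed seed", {
  coh <- generate_cohort(2, difficulty = "easy", seed = 73, preset = "desk")
  st <- compute_intensity_stats(lapply(coh$cases, `[[`, "vol"))
  cases <- lapply(coh$cases, function(cs) {
    pre <- preprocess_case(cs$vol, st, cs$mask)
    list(vol = pre$vol, mask = pre$mask)
  })
  cfg <- train_config(stage = "organ", epochs = 1L,
                      patch_size = c(16L, 16L, 16L), batch_size = 2L,
                      seed = 5L)
  run <- function() {
    net <- build_organ_net(
      organ_net_config(backend = "cnn", cnn_channels = c(4L, 8L),
                       cnn_blocks = c(1L, 1L)), seed = 6)
    train_stage(net, cases, cfg)$log$loss
  }
  expect_identical(run(), run())
})

test_that("training refuses a set with no foreground", {
  arr <- array(rnorm(16^3), c(16, 16, 16))
  cases <- list(list(vol = ct_volume(arr, c(1, 1, 1)),
                     mask = label_mask(array(0L, c(16, 16, 16)),
                                       c(1, 1, 1))))
  net <- build_organ_net(
    organ_net_config(backend = "cnn", cnn_channels = c(4L, 8L),
                     cnn_blocks = c(1L, 1L)), seed = 7)
  cfg <- train_config(stage = "tumor", epochs = 1L,
                      patch_size = c(16L, 16L, 16L))
  expect_error(train_stage(net, cases, cfg), "no tumor foreground")
})

test_that("full foreground oversampling puts a tumor voxel in every patch", {
  ns <- asNamespace("nephroseg")
  ph <- fixture_phantom(seed = 74, noise_sd = 10)
  tgt <- (ph$mask$data == 2L) * 1L
  set.seed(8)
  for (rep in 1:25) {
    pt <- ns$sample_patch(ph$vol$data, tgt, c(16L, 16L, 16L),
                          fg_fraction = 1.0)
    expect_gte(sum(pt$y), 1)
  }
})

test_that("optimizer steps descend a simple quadratic", {
  ns <- asNamespace("nephroseg")
  target <- matrix(c(1, -2, 3), 1)
  for (mode in c("sgd", "adamw")) {
    w <- ns$ag_param(matrix(0, 1, 3), "w")
    for (i in 1:200) {
      w$grad <- 2 * (w$value - target)
      if (mode == "sgd") ns$sgd_step(list(w), 0.01, 0.9, TRUE)
      else ns$adamw_step(list(w), 0.05, weight_decay = 0, t = i)
    }
    expect_equal(w$value, target, tolerance = 0.05)
  }
})

test_that("a short run reduces the training loss on phantoms", {
  coh <- generate_cohort(4, difficulty = "easy", seed = 75, preset = "desk")
  st <- compute_intensity_stats(lapply(coh$cases, `[[`, "vol"))
  cases <- lapply(coh$cases, function(cs) {
    pre <- preprocess_case(cs$vol, st, cs$mask)
    list(vol = pre$vol, mask = pre$mask)
  })
  net <- build_organ_net(
    organ_net_config(backend = "cnn", cnn_channels = c(4L, 8L),
                     cnn_blocks = c(1L, 1L)), seed = 9)
  cfg <- train_config(stage = "organ", epochs = 6L,
                      patch_size = c(16L, 16L, 16L), batch_size = 2L,
                      patches_per_volume = 2L, lr = 3e-3, seed = 10L)
  fit <- train_stage(net, cases, cfg)
  expect_lt(fit$log$loss[nrow(fit$log)], fit$log$loss[1L])
})
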