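# Kidney Tumor 3D UNet: structure, shape contract, attention gates,
# residual blocks.

test_that("the default configuration matches the published architecture", {
  cfg <- tumor_net_config()
  expect_equal(cfg$n_stages, 6L)
  expect_equal(cfg$channels, c(32L, 64L, 128L, 256L, 320L, 320L))
  expect_equal(cfg$residual_blocks, c(1L, 3L, 4L, 6L, 6L, 6L))
  expect_equal(cfg$patch_size, c(192L, 128L, 128L))
  expect_equal(cfg$batch_size, 5L)
  tab <- tumor_net_shape_pass(cfg)
  expect_equal(tab$channels, cfg$channels)
  expect_equal(tab$residual_blocks, cfg$residual_blocks)
  # deepest feature map extent: patch / 2^(n_stages - 1)
  expect_equal(unlist(tab[6, c("nx", "ny", "nz")], use.names = FALSE),
               c(6L, 4L, 4L))
  expect_true(accepts_patch(cfg, c(192L, 128L, 128L)))
  expect_false(accepts_patch(cfg, c(100L, 128L, 128L)))
  expect_error(tumor_net_shape_pass(cfg, c(100L, 128L, 128L)), "divisible")
})

test_that("config validation rejects inconsistent stage descriptions", {
  expect_error(tumor_net_config(n_stages = 6L, channels = c(32L, 64L)),
               "length")
  expect_error(tumor_net_config(patch_size = c(50L, 64L, 64L)), "divisible")
  expect_error(tumor_net_config(n_stages = 3L, channels = c(8L, 16L, 32L),
                                residual_blocks = c(0L, 1L, 1L),
                                patch_size = c(16L, 16L, 16L)), ">= 1")
})

test_that("a shrunken net maps an input to probabilities of equal extent", {
  net <- build_tumor_net(tiny_tumor_cfg(), seed = 11)
  x <- array(rnorm(16^3), c(16, 16, 16))
  p <- tumor_net_forward(net, x)
  expect_equal(dim(p), c(16L, 16L, 16L))
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, tumor_net_forward(net, x))
  expect_error(tumor_net_forward(net, array(0, c(15, 16, 16))), "divisible")
})

test_that("attention gates add parameters and builds are config-deterministic", {
  pc <- nephroseg:::param_count
  n_with <- pc(build_tumor_net(tiny_tumor_cfg(TRUE), seed = 1))
  n_without <- pc(build_tumor_net(tiny_tumor_cfg(FALSE), seed = 1))
  expect_gt(n_with, n_without)
  # parameter count is a pure function of the config
  expect_equal(pc(build_tumor_net(tiny_tumor_cfg(TRUE), seed = 99)), n_with)
})

test_that("the attention gate computes sigmoid-weighted skips", {
  ns <- asNamespace("nephroseg")
  set.seed(12)
  ag <- ns$new_attention_gate(3L, 3L, c_int = 2L)
  skip <- ns$ag_tensor(matrix(rnorm(3 * 8), 3), c(2L, 2L, 2L))
  gate <- ns$ag_tensor(matrix(rnorm(3 * 8), 3), c(2L, 2L, 2L))
  # force the combined pre-activation to zero: alpha = sigmoid(0) = 0.5
  ag$theta$W$value[] <- 0; ag$theta$b$value[] <- 0
  ag$phi$W$value[] <- 0; ag$phi$b$value[] <- 0
  ag$psi$W$value[] <- 0; ag$psi$b$value[] <- 0
  out <- ns$fwd_attention_gate(skip, gate, ag)
  expect_equal(out$value, skip$value / 2)
  # large positive pre-activation saturates alpha toward 1
  ag$psi$b$value[] <- 50
  out1 <- ns$fwd_attention_gate(skip, gate, ag)
  expect_equal(out1$value, skip$value, tolerance = 1e-10)
  # toy oracle: alpha computed by direct arithmetic
  set.seed(13)
  ag2 <- ns$new_attention_gate(2L, 2L, c_int = 2L)
  s2 <- ns$ag_tensor(matrix(rnorm(2 * 8), 2), c(2L, 2L, 2L))
  g2 <- ns$ag_tensor(matrix(rnorm(2 * 8), 2), c(2L, 2L, 2L))
  pre <- ag2$theta$W$value %*% s2$value + c(ag2$theta$b$value) +
    ag2$phi$W$value %*% g2$value + c(ag2$phi$b$value)
  act <- ifelse(pre > 0, pre, 0.01 * pre)
  alpha <- 1 / (1 + exp(-(ag2$psi$W$value %*% act + c(ag2$psi$b$value))))
  want <- s2$value * rep(alpha, each = 2)
  expect_equal(ns$fwd_attention_gate(s2, g2, ag2)$value, want,
               tolerance = 1e-12)
})

test_that("residual blocks reduce to the nonlinearity when the residual
           branch is silenced", {
  ns <- asNamespace("nephroseg")
  set.seed(14)
  blk <- ns$new_residual_block(3L, 3L)
  for (ly in list(blk$conv1, blk$conv2)) { ly$W$value[] <- 0; ly$b$value[] <- 0 }
  blk$norm2$gamma$value[] <- 0   # silence the residual branch entirely
  x <- ns$ag_tensor(matrix(rnorm(3 * 27), 3), c(3L, 3L, 3L))
  out <- ns$fwd_residual_block(x, blk, slope = 0.01)
  want <- ifelse(x$value > 0, x$value, 0.01 * x$value)
  expect_equal(out$value, want)
  # stacking preserves extent for any depth
  set.seed(15)
  h <- ns$ag_tensor(matrix(rnorm(4 * 64), 4), c(4L, 4L, 4L))
  for (i in 1:5) h <- ns$fwd_residual_block(h, ns$new_residual_block(4L, 4L))
  expect_equal(h$sdim, c(4L, 4L, 4L))
})

test_that("gradients reach the first residual block through a deep stack", {
  ns <- asNamespace("nephroseg")
  cfg <- tumor_net_config(n_stages = 2L, channels = c(3L, 5L),
                          residual_blocks = c(2L, 4L),
                          patch_size = c(8L, 8L, 8L), batch_size = 1L)
  net <- build_tumor_net(cfg, seed = 16)
  x <- array(rnorm(8^3), c(8, 8, 8))
  y <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
  ns$ag_tape_start()
  p <- ns$forward_tumor_tensor(net, ns$as_input_tensor(x))
  loss <- ns$op_dice_ce(p, matrix(as.numeric(y), nrow = 1))
  ns$ag_backward(loss)
  g <- net$encoder[[1]]$blocks[[1]]$conv1$W$grad
  expect_false(is.null(g))
  expect_gt(sqrt(sum(g^2)), 0)
  for (p_ in ns$net_params(net)) p_$grad <- NULL
})

test_that("analytic gradients match finite differences through the net", {
  ns <- asNamespace("nephroseg")
  net <- build_tumor_net(
    tumor_net_config(n_stages = 2L, channels = c(3L, 4L),
                     residual_blocks = c(1L, 1L),
                     patch_size = c(8L, 8L, 8L), batch_size = 1L), seed = 17)
  set.seed(18)
  x <- array(rnorm(8^3), c(8, 8, 8))
  y <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
  loss_fn <- function() {
    p <- ns$forward_tumor_tensor(net, ns$as_input_tensor(x))
    as.numeric(ns$op_dice_ce(p, matrix(as.numeric(y), nrow = 1))$value)
  }
  ns$ag_tape_start()
  p <- ns$forward_tumor_tensor(net, ns$as_input_tensor(x))
  loss <- ns$op_dice_ce(p, matrix(as.numeric(y), nrow = 1))
  ns$ag_backward(loss)
  params <- ns$net_params(net)
  for (pi in c(1, 4, length(params) - 1)) {
    pp <- params[[pi]]
    g <- if (is.list(pp$grad)) pp$grad[[1]] else pp$grad
    i <- which.max(abs(g))
    h <- 1e-5
    getv <- function() if (is.list(pp$value)) pp$value[[1]][i] else pp$value[i]
    setv <- function(v) {
      if (is.list(pp$value)) pp$value[[1]][i] <- v else pp$value[i] <- v
    }
    w0 <- getv()
    setv(w0 + h); Lp <- loss_fn()
    setv(w0 - h); Lm <- loss_fn()
    setv(w0)
    fd <- (Lp - Lm) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
  for (pp in params) pp$grad <- NULL
})
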