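# Layer constructors and forward helpers shared by both networks.
#
# A layer is a plain list of ag_param leaves plus metadata; forward functions
# thread ag tensors through the autodiff ops. Weight initialisation draws
# from the current R RNG stream, so builders seeded via with_seed() are
# reproducible.

new_conv3d <- function(cin, cout, k = 3L, stride = 1L, name = "conv") {
  fan_in <- cin * k^3
  W <- ag_param(matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                       cout, fan_in), name)
  b <- ag_param(matrix(0, cout, 1L), paste0(name, ".b"))
  list(kind = "conv3d", W = W, b = b, k = as.integer(k),
       stride = as.integer(stride), pad = if (k == 1L) 0L else 1L,
       cin = cin, cout = cout)
}

new_pointwise <- function(cin, cout, name = "pw") {
  new_conv3d(cin, cout, k = 1L, stride = 1L, name = name)
}

new_convt2 <- function(cin, cout, name = "deconv") {
  fan_in <- cin * 8
  Ws <- lapply(1:8, function(o)
    matrix(stats::rnorm(cout * cin, sd = sqrt(2 / fan_in)), cout, cin))
  W <- ag_param(matrix(0, 1, 1), name)
  W$value <- Ws   # list-valued parameter: 8 offset matrices
  b <- ag_param(matrix(0, cout, 1L), paste0(name, ".b"))
  list(kind = "convt2", W = W, b = b, cin = cin, cout = cout)
}

new_norm <- function(c_, name = "norm") {
  list(kind = "norm",
       gamma = ag_param(matrix(1, c_, 1L), name),
       beta = ag_param(matrix(0, c_, 1L), paste0(name, ".b")))
}

fwd_conv <- function(x, ly) {
  op_conv3d(x, ly$W, ly$b, stride = ly$stride, k = ly$k, pad = ly$pad)
}
fwd_convt2 <- function(x, ly) op_convt2(x, ly$W, ly$b)
fwd_inorm <- function(x, ly) op_instance_norm(x, ly$gamma, ly$beta)
fwd_lnorm <- function(x, ly) op_layer_norm(x, ly$gamma, ly$beta)

# conv -> instance norm -> LeakyReLU
new_conv_unit <- function(cin, cout, stride = 1L, name = "cu") {
  list(conv = new_conv3d(cin, cout, stride = stride, name = name),
       norm = new_norm(cout, paste0(name, ".in")))
}
fwd_conv_unit <- function(x, u, slope) {
  op_leaky_relu(fwd_inorm(fwd_conv(x, u$conv), u$norm), slope)
}

# Residual block: two conv+IN units with an identity (or projected) skip,
# nonlinearity after the addition. The first block of an encoder stage
# downsamples by carrying stride 2 in its first convolution and projecting
# the skip path with a strided pointwise convolution.
new_residual_block <- function(cin, cout, stride = 1L, name = "rb") {
  proj <- NULL
  if (cin != cout || stride != 1L) {
    proj <- list(conv = new_conv3d(cin, cout, k = 1L, stride = stride,
                                   name = paste0(name, ".proj")),
                 norm = new_norm(cout, paste0(name, ".projn")))
  }
  list(kind = "residual_block",
       conv1 = new_conv3d(cin, cout, stride = stride, name = paste0(name, ".c1")),
       norm1 = new_norm(cout, paste0(name, ".n1")),
       conv2 = new_conv3d(cout, cout, stride = 1L, name = paste0(name, ".c2")),
       norm2 = new_norm(cout, paste0(name, ".n2")),
       proj = proj)
}

fwd_residual_block <- function(x, blk, slope = 0.01) {
  h <- op_leaky_relu(fwd_inorm(fwd_conv(x, blk$conv1), blk$norm1), slope)
  h <- fwd_inorm(fwd_conv(h, blk$conv2), blk$norm2)
  s <- if (is.null(blk$proj)) x else fwd_inorm(fwd_conv(x, blk$proj$conv),
                                               blk$proj$norm)
  op_leaky_relu(op_add(h, s), slope)
}

# Additive attention gate on a skip connection: project skip and gating
# features to a common width, add, nonlinearity, project to one channel,
# sigmoid; the resulting per-voxel coefficients multiply the skip features.
new_attention_gate <- function(c_skip, c_gate, c_int = NULL, name = "ag") {
  c_int <- c_int %||% max(1L, c_skip %/% 2L)
  list(kind = "attention_gate",
       theta = new_pointwise(c_skip, c_int, paste0(name, ".theta")),
       phi = new_pointwise(c_gate, c_int, paste0(name, ".phi")),
       psi = new_pointwise(c_int, 1L, paste0(name, ".psi")))
}

fwd_attention_gate <- function(skip, gate, ag, slope = 0.01) {
  f <- op_leaky_relu(op_add(fwd_conv(skip, ag$theta), fwd_conv(gate, ag$phi)),
                     slope)
  alpha <- op_sigmoid(fwd_conv(f, ag$psi))
  op_scale(skip, alpha)
}

# Recursively collect every trainable leaf in a (nested) layer structure.
net_params <- function(x) {
  if (is.environment(x)) {
    if (isTRUE(x$param)) return(list(x))
    return(list())
  }
  if (is.list(x)) return(unlist(lapply(x, net_params), recursive = FALSE))
  list()
}

param_count <- function(x) {
  sum(vapply(net_params(x), function(p) {
    if (is.list(p$value)) sum(vapply(p$value, length, 0)) else length(p$value)
  }, 0))
}

# Wrap a 3D array (or C x N matrix with sdim) as an input tensor.
as_input_tensor <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    ag_tensor(matrix(as.numeric(x), nrow = 1L), dim(x))
  } else {
    stop("expected a 3D array input")
  }
}
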