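# Layer constructors. A "registry" collects named parameter nodes and
# normalization state so models can be checkpointed and reloaded by name;
# each layer constructor returns a forward closure f(x_node, training).

new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$params <- list()
  reg$states <- list()
  reg
}

reg_param <- function(reg, name, value) {
  node <- ag_param(value)
  reg$params[[name]] <- node
  node
}

init_he <- function(kh, kw, cin_g, cout) {
  array(stats::rnorm(kh * kw * cin_g * cout, sd = sqrt(2 / (kh * kw * cin_g))),
        dim = c(kh, kw, cin_g, cout))
}

layer_conv <- function(reg, name, kh, kw, cin, cout, stride = 1L, pad = 0L,
                       groups = 1L, bias = TRUE, init = c("he", "zero")) {
  init <- match.arg(init)
  # force all geometry now: these closures are built in loops and must not
  # capture lazily evaluated loop variables
  stride <- as.integer(stride); pad <- as.integer(pad)
  groups <- as.integer(groups); cin <- as.integer(cin); cout <- as.integer(cout)
  cin_g <- cin %/% groups
  wv <- if (init == "zero") array(0, dim = c(kh, kw, cin_g, cout))
        else init_he(kh, kw, cin_g, cout)
  w <- reg_param(reg, paste0(name, ".w"), wv)
  b <- if (bias) reg_param(reg, paste0(name, ".b"), numeric(cout)) else NULL
  function(x, training = FALSE) ag_conv2d(x, w, b, stride, pad, groups)
}

layer_bn <- function(reg, name, C) {
  gamma <- reg_param(reg, paste0(name, ".gamma"), rep(1, C))
  beta <- reg_param(reg, paste0(name, ".beta"), rep(0, C))
  state <- new.env(parent = emptyenv())
  state$mean <- rep(0, C)
  state$var <- rep(1, C)
  reg$states[[name]] <- state
  function(x, training = FALSE) ag_bn(x, gamma, beta, state, training)
}

# conv (+ batch norm) + relu; with norm = "none" the conv keeps its bias so
# the layer stays an exact Eq.-style affine map for oracle tests
layer_cbr <- function(reg, name, kh, cin, cout, stride = 1L, pad = (kh - 1L) %/% 2L,
                      groups = 1L, norm = "batch", relu = TRUE) {
  force(relu)
  conv <- layer_conv(reg, name, kh, kh, cin, cout, stride, pad, groups,
                     bias = (norm == "none"))
  bn <- if (norm == "batch") layer_bn(reg, paste0(name, ".bn"), cout)
  function(x, training = FALSE) {
    y <- conv(x, training)
    if (!is.null(bn)) y <- bn(y, training)
    if (relu) y <- ag_relu(y)
    y
  }
}

# deformable 3x3 convolution layer: a zero-initialized offset branch
# (so training starts at the standard-convolution fixed point) feeding the
# bilinear-sampled deformable kernel
layer_deform <- function(reg, name, cin, cout) {
  w <- reg_param(reg, paste0(name, ".w"), init_he(3L, 3L, cin, cout))
  b <- reg_param(reg, paste0(name, ".b"), numeric(cout))
  wo <- reg_param(reg, paste0(name, ".off.w"), array(0, dim = c(3L, 3L, cin, 18L)))
  bo <- reg_param(reg, paste0(name, ".off.b"), numeric(18L))
  function(x, training = FALSE) {
    off <- ag_conv2d(x, wo, bo, 1L, 1L)
    ag_deform_conv(x, w, b, off)
  }
}

layer_deform_block <- function(reg, name, cin, cout, norm = "batch") {
  dc <- layer_deform(reg, name, cin, cout)
  bn <- if (norm == "batch") layer_bn(reg, paste0(name, ".bn"), cout)
  function(x, training = FALSE) {
    y <- dc(x, training)
    if (!is.null(bn)) y <- bn(y, training)
    ag_relu(y)
  }
}

# concurrent spatial & channel squeeze-and-excitation, reduction ratio 2.
# Channel branch: GAP -> FC (C -> C/2) + relu -> FC (C/2 -> C) + sigmoid;
# spatial branch: 1x1 conv to a single channel + sigmoid; outputs summed.
layer_scse <- function(reg, name, C) {
  Cr <- max(1L, C %/% 2L)
  w1 <- reg_param(reg, paste0(name, ".fc1.w"),
                  matrix(stats::rnorm(Cr * C, sd = sqrt(2 / C)), Cr, C))
  b1 <- reg_param(reg, paste0(name, ".fc1.b"), numeric(Cr))
  w2 <- reg_param(reg, paste0(name, ".fc2.w"),
                  matrix(stats::rnorm(C * Cr, sd = sqrt(1 / Cr)), C, Cr))
  b2 <- reg_param(reg, paste0(name, ".fc2.b"), numeric(C))
  ws <- reg_param(reg, paste0(name, ".sp.w"), array(0, dim = c(1L, 1L, C, 1L)))
  bs <- reg_param(reg, paste0(name, ".sp.b"), numeric(1L))
  function(x, training = FALSE) {
    z <- ag_gap(x)
    h <- ag_relu(ag_fc(z, w1, b1))
    gc <- ag_sigmoid(ag_fc(h, w2, b2))
    cse_out <- ag_scale_channels(x, gc)
    gs <- ag_sigmoid(ag_conv2d(x, ws, bs, 1L, 0L))
    sse_out <- ag_scale_spatial(x, gs)
    ag_add(cse_out, sse_out)
  }
}

n_params_reg <- function(reg) sum(vapply(reg$params, function(p) length(p$value), 0))
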