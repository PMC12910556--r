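# Dense-network primitives: linear, activation, and batch-normalization
# layers with explicit forward caches and hand-derived backward passes.
# Shapes follow the "batch of rows" convention: inputs are n x d_in,
# weights d_in x d_out.

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# PyTorch-style default linear initialization: U(-1/sqrt(fan_in), +)
init_linear <- function(d_in, d_out) {
  a <- 1 / sqrt(d_in)
  list(W = matrix(runif(d_in * d_out, -a, a), d_in, d_out),
       b = runif(d_out, -a, a))
}

init_batchnorm <- function(d) {
  list(gamma = rep(1, d), beta = rep(0, d))
}

linear_forward <- function(x, W, b) {
  x %*% W + rep(b, each = nrow(x))
}

# returns list(dx, dW, db)
linear_backward <- function(dout, x, W) {
  list(dx = dout %*% t(W), dW = crossprod(x, dout), db = colSums(dout))
}

sigmoid_forward <- function(z) plogis(z)
sigmoid_backward <- function(dout, a) dout * a * (1 - a)

gelu_forward <- function(z) z * stats::pnorm(z)
gelu_backward <- function(dout, z) {
  dout * (stats::pnorm(z) + z * stats::dnorm(z))
}

act_forward <- function(z, activation) {
  switch(activation, sigmoid = sigmoid_forward(z), gelu = gelu_forward(z),
         zipo_stop(sprintf("unknown activation '%s'", activation)))
}

act_backward <- function(dout, z, a, activation) {
  switch(activation, sigmoid = sigmoid_backward(dout, a),
         gelu = gelu_backward(dout, z))
}

# Batch normalization. Training mode normalizes by batch statistics
# (biased variance) and updates running statistics (unbiased variance,
# momentum 0.1); evaluation mode uses the running statistics so outputs are
# independent of batch composition.
bn_forward <- function(x, gamma, beta, state, train) {
  n <- nrow(x)
  if (train && n > 0) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    v <- colMeans(xc^2)
    invstd <- 1 / sqrt(v + .bn_eps)
    xhat <- xc * rep(invstd, each = n)
    v_unbiased <- if (n > 1) v * n / (n - 1) else v
    state$rm <- (1 - .bn_momentum) * state$rm + .bn_momentum * mu
    state$rv <- (1 - .bn_momentum) * state$rv + .bn_momentum * v_unbiased
  } else {
    invstd <- 1 / sqrt(state$rv + .bn_eps)
    xhat <- (x - rep(state$rm, each = n)) * rep(invstd, each = n)
  }
  out <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = out, xhat = xhat, invstd = invstd, state = state)
}

# returns list(dx, dgamma, dbeta); train-mode statistics assumed
bn_backward <- function(dout, cache, gamma) {
  n <- nrow(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(gamma, each = n)
  mean_dxhat <- colMeans(dxhat)
  mean_dxhat_xhat <- colMeans(dxhat * xhat)
  dx <- (dxhat - rep(mean_dxhat, each = n) -
           xhat * rep(mean_dxhat_xhat, each = n)) *
    rep(cache$invstd, each = n)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# One encoder-style block: linear -> activation -> batch norm (in that
# order). `extra_pre` is an optional matrix added to the linear
# pre-activation (residual projections into the latent block).
block_forward <- function(x, par, state, activation, batch_norm, train,
                          extra_pre = NULL) {
  z <- linear_forward(x, par$W, par$b)
  if (!is.null(extra_pre)) z <- z + extra_pre
  a <- act_forward(z, activation)
  if (batch_norm) {
    bn <- bn_forward(a, par$gamma, par$beta, state, train)
    list(out = bn$out, cache = list(x = x, z = z, a = a, bn = bn),
         state = bn$state)
  } else {
    list(out = a, cache = list(x = x, z = z, a = a, bn = NULL), state = state)
  }
}

# returns list(dx, dz (pre-activation grad, for residual fan-out),
# grads = list(W, b, gamma, beta))
block_backward <- function(dout, cache, par, activation, batch_norm) {
  if (batch_norm) {
    bnb <- bn_backward(dout, cache$bn, par$gamma)
    da <- bnb$dx
    dgamma <- bnb$dgamma
    dbeta <- bnb$dbeta
  } else {
    da <- dout
    dgamma <- NULL
    dbeta <- NULL
  }
  dz <- act_backward(da, cache$z, cache$a, activation)
  lb <- linear_backward(dz, cache$x, par$W)
  list(dx = lb$dx, dz = dz,
       grads = list(W = lb$dW, b = lb$db, gamma = dgamma, beta = dbeta))
}

# Numerically stable helpers used throughout the likelihood code.
softplus <- function(t) {
  # log(1 + e^t) without overflow: max(t, 0) + log1p(e^{-|t|})
  pmax(t, 0) + log1p(exp(-abs(t)))
}

log_sigmoid <- function(t) -softplus(-t)
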