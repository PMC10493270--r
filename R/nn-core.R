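# Shared neural-network primitives (row-wise layer norm, GELU, softmax,
# cross-entropy, Adam). All operate on plain matrices; gradients are
# hand-derived and checked against numerical differentiation in the tests.

layernorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = sweep(xhat * gamma[col(xhat)], 2, beta, `+`),
       xhat = xhat, inv = inv)
}

layernorm_backward <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  d <- ncol(xhat)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * gamma[col(dout)]
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# tanh-approximation GELU (matches the compiled encoder's activation)
gelu <- function(x) {
  0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
}
gelu_grad <- function(x) {
  t <- tanh(sqrt(2 / pi) * (x + 0.044715 * x^3))
  0.5 * (1 + t) + 0.5 * x * (1 - t^2) * sqrt(2 / pi) * (1 + 3 * 0.044715 * x^2)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy over rows of logits; y is an integer class vector.
cross_entropy <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dlogits / n)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# 0.02-sd Gaussian init, the small-transformer convention.
init_mat <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, sd = sd), nr, nc)
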