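#' Spatial graph convolutional module (SGCM) configuration
#'
#' @param n_layers Number of graph convolutional layers L (>= 1).
#' @param hidden_dim Output width of each hidden graph layer.
#' @param n_classes Classifier output classes.
#' @param activation Nonlinearity applied by every graph layer: "relu"
#'   (default) or "identity".
#' @return An `sgcm_config` list. Readout is mean pooling over nodes
#'   followed by a linear classifier.
#' @export
sgcm_config <- function(n_layers = 2, hidden_dim = 64, n_classes = 3,
                        activation = c("relu", "identity")) {
  if (n_layers < 1) stop("n_layers must be >= 1")
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 n_classes = as.integer(n_classes),
                 activation = match.arg(activation)),
            class = "sgcm_config")
}

#' One spectral graph convolution layer
#'
#' Computes `sigma(A_norm %*% H %*% W)` where `A_norm` is the cached
#' symmetric normalization D_hat^{-1/2} (A + I) D_hat^{-1/2} of the electrode
#' graph. Node order of `H` must match the graph's node order.
#'
#' @param H Node-feature matrix, nodes x d.
#' @param graph An `electrode_graph` from [build_graph()].
#' @param W Weight matrix, d x d_out.
#' @param activation One of "identity" or "relu".
#' @return Node-feature matrix, nodes x d_out.
#' @export
gcn_layer <- function(H, graph, W, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (nrow(H) != length(graph$nodes)) {
    stop("H has ", nrow(H), " rows but the graph has ", length(graph$nodes),
         " nodes")
  }
  if (ncol(H) != nrow(W)) stop("dimension mismatch: ncol(H) != nrow(W)")
  Z <- graph$A_norm %*% H %*% W
  if (activation == "relu") pmax(Z, 0) else Z
}

#' Initialize SGCM parameters
#'
#' @param cfg An [sgcm_config()].
#' @param d_in Input node-feature dimension (the TTM embedding width).
#' @param seed RNG seed.
#' @return An `sgcm_model` list with `cfg` and `params`.
#' @export
sgcm_init <- function(cfg, d_in, seed = 1) {
  with_seed(seed, {
    params <- list()
    d <- d_in
    for (l in seq_len(cfg$n_layers)) {
      params[[paste0("W", l)]] <- init_mat(d, cfg$hidden_dim,
                                           sd = sqrt(2 / d))
      d <- cfg$hidden_dim
    }
    # zero-init classifier head: with few optimizer steps at small lr the
    # argmax then follows the learned class signal instead of init noise
    params$W_out <- matrix(0, d, cfg$n_classes)
    params$b_out <- numeric(cfg$n_classes)
    structure(list(cfg = cfg, params = params), class = "sgcm_model")
  })
}

#' SGCM forward pass
#'
#' Propagates one segment's 16 per-channel feature vectors through the
#' stacked graph convolutions (ReLU activations), mean-pools over nodes and
#' applies the linear classifier. Jointly permuting node features and the
#' graph leaves the logits unchanged.
#'
#' @param model An `sgcm_model`.
#' @param H Node-feature matrix (nodes x d_in), rows ordered as
#'   `graph$nodes`.
#' @param graph An `electrode_graph`.
#' @return Numeric vector of `n_classes` logits.
#' @export
sgcm_forward <- function(model, H, graph) {
  sgcm_forward_cached(model, H, graph)$logits
}

sgcm_forward_cached <- function(model, H, graph) {
  if (nrow(H) != length(graph$nodes)) {
    stop("need exactly one feature vector per graph node")
  }
  p <- model$params
  relu <- identical(model$cfg$activation %||% "relu", "relu")
  Hs <- list(H)
  Zs <- list()
  for (l in seq_len(model$cfg$n_layers)) {
    Z <- graph$A_norm %*% Hs[[l]] %*% p[[paste0("W", l)]]
    Zs[[l]] <- Z
    Hs[[l + 1]] <- if (relu) pmax(Z, 0) else Z
  }
  z <- colMeans(Hs[[model$cfg$n_layers + 1]])
  logits <- as.numeric(z %*% p$W_out + p$b_out)
  list(logits = logits, Hs = Hs, Zs = Zs, z = z)
}

# Backward for one segment; dlogits is length n_classes.
sgcm_backward <- function(model, graph, cache, dlogits) {
  p <- model$params
  L <- model$cfg$n_layers
  n <- length(graph$nodes)
  g <- list()
  g$W_out <- outer(cache$z, dlogits)
  g$b_out <- dlogits
  dz <- as.numeric(p$W_out %*% dlogits)
  relu <- identical(model$cfg$activation %||% "relu", "relu")
  dH <- matrix(dz, n, length(dz), byrow = TRUE) / n   # mean-pool backward
  for (l in rev(seq_len(L))) {
    dZ <- if (relu) dH * (cache$Zs[[l]] > 0) else dH
    AH <- graph$A_norm %*% cache$Hs[[l]]
    g[[paste0("W", l)]] <- crossprod(AH, dZ)
    dH <- graph$A_norm %*% (dZ %*% t(p[[paste0("W", l)]]))
  }
  g
}
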