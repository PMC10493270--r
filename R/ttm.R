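#' Temporal transformer (TTM) configuration
#'
#' Hyperparameters of the per-channel CPD-map feature extractor: a small-data
#' vision transformer with Shifted Patch Tokenization (SPT) and Locality
#' Self-Attention (LSA: diagonal of the score matrix masked to -Inf plus a
#' learnable per-head softmax temperature initialized at sqrt(d_k)).
#'
#' @param input_dim Integer c(freq_bins, time_frames) of the CPD input; the
#'   default matches [preprocess_config()] defaults (71 x 100).
#' @param patch Square patch side in pixels.
#' @param embed_dim Token embedding width; divisible by `n_heads`.
#' @param depth Number of transformer blocks.
#' @param n_heads Attention heads.
#' @param mlp_ratio Hidden-layer multiple of the block MLP.
#' @param n_classes Classifier output classes.
#' @param shift_set Matrix of 2-D pixel offsets (rows = c(drow, dcol)) whose
#'   shifted image copies are channel-concatenated before patching; default:
#'   the four half-patch diagonal shifts. An empty (0-row) matrix reduces SPT
#'   to standard ViT patching.
#' @param mask Logical: apply the LSA diagonal mask.
#' @return A `ttm_config` list.
#' @export
ttm_config <- function(input_dim = c(71, 100), patch = 8, embed_dim = 64,
                       depth = 4, n_heads = 4, mlp_ratio = 2, n_classes = 3,
                       shift_set = NULL, mask = TRUE) {
  if (embed_dim %% n_heads != 0) stop("embed_dim must be divisible by n_heads")
  if (patch > min(input_dim)) stop("patch_size exceeds image dimensions")
  if (is.null(shift_set)) {
    s <- floor(patch / 2)
    shift_set <- rbind(c(-s, -s), c(-s, s), c(s, -s), c(s, s))
  }
  shift_set <- matrix(as.integer(shift_set), ncol = 2)
  grid <- ceiling(input_dim / patch)
  structure(list(
    input_dim = as.integer(input_dim), patch = as.integer(patch),
    embed_dim = as.integer(embed_dim), depth = as.integer(depth),
    n_heads = as.integer(n_heads), mlp_ratio = mlp_ratio,
    n_classes = as.integer(n_classes), shift_set = shift_set, mask = mask,
    grid = as.integer(grid), n_tokens = as.integer(prod(grid)),
    patch_dim = as.integer(patch^2 * (1 + nrow(shift_set)))
  ), class = "ttm_config")
}

# Reflect-pad an image (bottom/right) to patch-divisible dimensions.
pad_to_patch <- function(img, patch) {
  kr <- ceiling(nrow(img) / patch) * patch - nrow(img)
  kc <- ceiling(ncol(img) / patch) * patch - ncol(img)
  if (kr >= nrow(img) || kc >= ncol(img)) {
    stop("image too small for patch size ", patch)
  }
  if (kr > 0) img <- rbind(img, img[seq(nrow(img) - 1, by = -1,
                                        length.out = kr), , drop = FALSE])
  if (kc > 0) img <- cbind(img, img[, seq(ncol(img) - 1, by = -1,
                                          length.out = kc), drop = FALSE])
  img
}

# Shift an image by (drow, dcol), zero-filling exposed borders.
shift_image <- function(img, drow, dcol) {
  out <- matrix(0, nrow(img), ncol(img))
  sr <- max(1, 1 + drow):min(nrow(img), nrow(img) + drow)
  sc <- max(1, 1 + dcol):min(ncol(img), ncol(img) + dcol)
  out[sr, sc] <- img[sr - drow, sc - dcol, drop = FALSE]
  out
}

# Patch-gather index for one padded channel: (n_tokens x patch^2) indices in
# row-major token order (time fastest).
patch_index <- function(dims, patch) {
  gh <- dims[1] %/% patch
  gw <- dims[2] %/% patch
  idx <- matrix(0L, gh * gw, patch^2)
  k <- 0L
  for (gi in seq_len(gh)) {
    for (gj in seq_len(gw)) {
      k <- k + 1L
      rows <- (gi - 1L) * patch + seq_len(patch)
      cols <- (gj - 1L) * patch + seq_len(patch)
      idx[k, ] <- as.integer(outer(rows, (cols - 1L) * dims[1], `+`))
    }
  }
  idx
}

#' Shifted Patch Tokenization
#'
#' Concatenates the input image with its `shift_set`-shifted copies along a
#' channel axis, divides the stack into non-overlapping `patch x patch`
#' patches and (when projection weights are given) linearly projects each
#' flattened patch to a token. With an empty shift set this is standard ViT
#' patching.
#'
#' @param img Numeric matrix (one model-input CPD map), or a `cpd_map`.
#' @param cfg A [ttm_config()].
#' @param W,b Optional projection weights (patch_dim x embed_dim) and bias;
#'   when omitted the raw flattened patches are returned.
#' @return Matrix with one token per row: `n_tokens x embed_dim` when
#'   projected, otherwise `n_tokens x patch_dim`.
#' @export
shifted_patch_tokenize <- function(img, cfg, W = NULL, b = NULL) {
  if (inherits(img, "cpd_map")) img <- cpd_to_input(img)
  if (any(dim(img) != cfg$input_dim)) {
    stop("input is ", nrow(img), "x", ncol(img), " but config expects ",
         cfg$input_dim[1], "x", cfg$input_dim[2])
  }
  pad <- pad_to_patch(img, cfg$patch)
  chans <- c(list(pad), lapply(seq_len(nrow(cfg$shift_set)), function(i) {
    shift_image(pad, cfg$shift_set[i, 1], cfg$shift_set[i, 2])
  }))
  idx <- patch_index(dim(pad), cfg$patch)
  patches <- do.call(cbind, lapply(chans, function(ch) {
    matrix(ch[idx], nrow(idx), ncol(idx))
  }))
  if (is.null(W)) return(patches)
  sweep(patches %*% W, 2, b, `+`)
}

#' Locality Self-Attention (reference implementation)
#'
#' Single-head scaled dot-product attention softmax(Q K^T / temperature) V
#' with the LSA modifications: the diagonal of the score matrix set to -Inf
#' (each token must attend elsewhere) and an arbitrary positive temperature
#' in place of the fixed sqrt(d_k). With `mask = FALSE` and
#' `temperature = sqrt(ncol(K))` this is exactly standard scaled dot-product
#' attention. This plain-R path is the oracle for the compiled batched
#' kernel used in training.
#'
#' @param Q,K,V Token-by-dimension matrices with equal row counts.
#' @param temperature Positive softmax temperature; default sqrt(d_k).
#' @param mask Logical: apply the diagonal mask. Requires >= 2 tokens.
#' @return List with `out` (tokens x dim(V)) and `weights` (the attention
#'   matrix; rows sum to 1, diagonal exactly 0 when masked).
#' @export
locality_self_attention <- function(Q, K, V, temperature = sqrt(ncol(K)),
                                    mask = TRUE) {
  if (temperature <= 0) stop("temperature must be positive")
  if (mask && nrow(Q) < 2) {
    stop("diagonal masking needs at least 2 tokens (all--Inf row undefined)")
  }
  S <- tcrossprod(Q, K) / temperature
  if (mask) diag(S) <- -Inf
  A <- softmax_rows(S)
  list(out = A %*% V, weights = A)
}

#' Initialize TTM parameters
#'
#' @param cfg A [ttm_config()].
#' @param seed RNG seed.
#' @return A `ttm_model`: list with `cfg` and named parameter list `params`.
#' @export
ttm_init <- function(cfg, seed = 1) {
  D <- cfg$embed_dim
  Tn <- cfg$n_tokens + 1L
  dh <- D / cfg$n_heads
  with_seed(seed, {
    params <- list(
      W_patch = init_mat(cfg$patch_dim, D), b_patch = numeric(D),
      cls = rnorm(D, sd = 0.02), pos = init_mat(Tn, D)
    )
    for (l in seq_len(cfg$depth)) {
      pre <- paste0("L", l, "_")
      params[[paste0(pre, "ln1_g")]] <- rep(1, D)
      params[[paste0(pre, "ln1_b")]] <- numeric(D)
      params[[paste0(pre, "Wqkv")]] <- init_mat(D, 3 * D)
      params[[paste0(pre, "bqkv")]] <- numeric(3 * D)
      params[[paste0(pre, "Wo")]] <- init_mat(D, D)
      params[[paste0(pre, "bo")]] <- numeric(D)
      params[[paste0(pre, "log_tau")]] <- rep(log(sqrt(dh)), cfg$n_heads)
      params[[paste0(pre, "ln2_g")]] <- rep(1, D)
      params[[paste0(pre, "ln2_b")]] <- numeric(D)
      params[[paste0(pre, "W1")]] <- init_mat(D, round(cfg$mlp_ratio * D))
      params[[paste0(pre, "b1")]] <- numeric(round(cfg$mlp_ratio * D))
      params[[paste0(pre, "W2")]] <- init_mat(round(cfg$mlp_ratio * D), D)
      params[[paste0(pre, "b2")]] <- numeric(D)
    }
    params$lnf_g <- rep(1, D)
    params$lnf_b <- numeric(D)
    params$W_head <- matrix(0, D, cfg$n_classes)  # zero-init head (see vignette)
    params$b_head <- numeric(cfg$n_classes)
    structure(list(cfg = cfg, params = params), class = "ttm_model")
  })
}

#' Convert a CPD map to a model input
#'
#' Applies `log10(power + 1e-12)` (spectrogram dynamic range spans orders of
#' magnitude) and standardizes the map to zero mean, unit variance so the
#' transformer sees bounded inputs of comparable scale.
#'
#' @param cpd A `cpd_map` from [build_cpd()] or a nonnegative matrix.
#' @return Numeric matrix, same shape.
#' @export
cpd_to_input <- function(cpd) {
  v <- if (inherits(cpd, "cpd_map")) cpd$values else cpd
  v <- log10(v + 1e-12)
  s <- stats::sd(v)
  if (s < 1e-12) s <- 1
  (v - mean(v)) / s
}

as_input_list <- function(x) {
  if (inherits(x, "cpd_map")) return(list(cpd_to_input(x)))
  if (is.matrix(x)) return(list(x))
  lapply(x, function(e) if (inherits(e, "cpd_map")) cpd_to_input(e) else e)
}

#' TTM forward pass
#'
#' Runs one or more CPD maps through the transformer and returns per-map
#' feature embeddings (final-layer-norm class token, the representation
#' handed to the graph module in stage 2) and class logits. Deterministic:
#' the model has no stochastic layers.
#'
#' @param model A `ttm_model` from [ttm_init()].
#' @param x A `cpd_map`, a model-input matrix, or a list of either.
#' @return List with `features` (n x embed_dim) and `logits` (n x
#'   n_classes).
#' @export
ttm_forward <- function(model, x) {
  fw <- ttm_forward_batch(model, as_input_list(x))
  list(features = fw$features, logits = fw$logits)
}

# Pack model parameters for the compiled kernel (temperature in tau space).
ttm_kernel_args <- function(model) {
  p <- model$params
  layer_list <- lapply(seq_len(model$cfg$depth), function(l) {
    pre <- paste0("L", l, "_")
    list(ln1_g = p[[paste0(pre, "ln1_g")]],
         ln1_b = p[[paste0(pre, "ln1_b")]],
         Wqkv = p[[paste0(pre, "Wqkv")]], bqkv = p[[paste0(pre, "bqkv")]],
         Wo = p[[paste0(pre, "Wo")]], bo = p[[paste0(pre, "bo")]],
         tau = exp(p[[paste0(pre, "log_tau")]]),
         ln2_g = p[[paste0(pre, "ln2_g")]],
         ln2_b = p[[paste0(pre, "ln2_b")]],
         W1 = p[[paste0(pre, "W1")]], b1 = p[[paste0(pre, "b1")]],
         W2 = p[[paste0(pre, "W2")]], b2 = p[[paste0(pre, "b2")]])
  })
  list(params = p[c("W_patch", "b_patch", "cls", "pos", "lnf_g", "lnf_b",
                    "W_head", "b_head")],
       layers = layer_list)
}

# Tokenize a list of model-input matrices into one stacked patch matrix.
ttm_patches <- function(model, inputs) {
  do.call(rbind, lapply(inputs, shifted_patch_tokenize, cfg = model$cfg))
}

# Batched inference; inputs is a list of model-input matrices.
ttm_forward_batch <- function(model, inputs, P = NULL) {
  if (model$cfg$mask && model$cfg$n_tokens + 1L < 2) {
    stop("sequence length 1 with masking enabled")
  }
  ka <- ttm_kernel_args(model)
  out <- .ttm_kernel_cpp(P %||% ttm_patches(model, inputs), ka$params,
                         ka$layers, integer(0), model$cfg$mask,
                         model$cfg$n_tokens + 1L, FALSE)
  list(features = out$features, logits = out$logits)
}

# One loss/gradient evaluation on a minibatch. y: integer class ids (1-based).
# Returns loss, logits and gradients named like model$params.
ttm_step <- function(model, inputs, y, P = NULL, want_grads = TRUE) {
  ka <- ttm_kernel_args(model)
  out <- .ttm_kernel_cpp(P %||% ttm_patches(model, inputs), ka$params,
                         ka$layers, as.integer(y), model$cfg$mask,
                         model$cfg$n_tokens + 1L, want_grads)
  res <- list(loss = out$loss, logits = out$logits, features = out$features)
  if (want_grads) {
    kg <- out$grads
    g <- list(W_patch = kg$W_patch, b_patch = as.numeric(kg$b_patch),
              cls = as.numeric(kg$cls), pos = kg$pos,
              lnf_g = as.numeric(kg$lnf_g), lnf_b = as.numeric(kg$lnf_b),
              W_head = kg$W_head, b_head = as.numeric(kg$b_head))
    for (l in seq_len(model$cfg$depth)) {
      pre <- paste0("L", l, "_")
      gl <- kg$layers[[l]]
      for (nm in c("ln1_g", "ln1_b", "bqkv", "bo", "log_tau", "ln2_g",
                   "ln2_b", "b1", "b2")) {
        g[[paste0(pre, nm)]] <- as.numeric(gl[[nm]])
      }
      for (nm in c("Wqkv", "Wo", "W1", "W2")) {
        g[[paste0(pre, nm)]] <- gl[[nm]]
      }
    }
    res$grads <- g
  }
  res
}
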