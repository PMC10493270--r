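test_that("shifted patch tokenization counts tokens and channels correctly", {
  cfg <- ttm_config(input_dim = c(8, 8), patch = 4, embed_dim = 8,
                    depth = 1, n_heads = 2)
  img <- matrix(rnorm(64), 8, 8)
  patches <- shifted_patch_tokenize(img, cfg)
  expect_equal(dim(patches), c(4, 4 * 4 * 5))   # 4 tokens, 1 + 4 shifts
  # zero image projects to the bias alone
  W <- matrix(rnorm(80 * 8), 80, 8)
  b <- rnorm(8)
  tok <- shifted_patch_tokenize(matrix(0, 8, 8), cfg, W, b)
  expect_equal(tok, matrix(b, 4, 8, byrow = TRUE), tolerance = 1e-12)
  # empty shift set reduces to standard ViT patching
  cfg0 <- ttm_config(input_dim = c(8, 8), patch = 4, embed_dim = 8,
                     depth = 1, n_heads = 2,
                     shift_set = matrix(integer(0), 0, 2))
  p0 <- shifted_patch_tokenize(img, cfg0)
  expect_equal(dim(p0), c(4, 16))
  expect_equal(p0[1, ], as.numeric(img[1:4, 1:4]))  # plain patch content
  expect_error(ttm_config(input_dim = c(6, 6), patch = 8), "patch")
  expect_error(shifted_patch_tokenize(matrix(0, 9, 9), cfg), "config expects")
})

test_that("locality self-attention obeys masking, normalization and the closed-form oracle", {
  set.seed(11)
  # two identical tokens, masked: each must attend fully to the other
  V <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  Q <- matrix(1, 2, 2)
  out <- locality_self_attention(Q, Q, V, mask = TRUE)
  expect_equal(out$out, V[2:1, ], ignore_attr = TRUE)
  expect_equal(diag(out$weights), c(0, 0))
  expect_equal(rowSums(out$weights), c(1, 1), tolerance = 1e-6)
  # mask off + temperature sqrt(dk): exactly scaled dot-product attention
  for (r in 1:5) {
    Q <- matrix(rnorm(6 * 4), 6, 4)
    K <- matrix(rnorm(6 * 4), 6, 4)
    V <- matrix(rnorm(6 * 4), 6, 4)
    got <- locality_self_attention(Q, K, V, temperature = sqrt(4),
                                   mask = FALSE)$out
    expect_lt(max(abs(got - sdp_attention(Q, K, V))), 1e-6)
  }
  # temperature -> 0+ sharpens onto the argmax
  Q <- matrix(rnorm(4 * 3), 4, 3)
  K <- matrix(rnorm(4 * 3), 4, 3)
  sharp <- locality_self_attention(Q, K, diag(4)[, 1:3], temperature = 1e-3,
                                   mask = FALSE)$weights
  expect_true(all(apply(sharp, 1, max) > 0.99))
  expect_error(locality_self_attention(Q[1, , drop = FALSE],
                                       K[1, , drop = FALSE],
                                       K[1, , drop = FALSE], mask = TRUE),
               "at least 2 tokens")
  expect_error(locality_self_attention(Q, K, K, temperature = 0), "positive")
})

test_that("compiled attention kernel agrees with the plain-R reference (dual route)", {
  set.seed(21)
  D <- 4; Tn <- 6
  X <- matrix(rnorm(Tn * D), Tn, D)
  I3 <- cbind(diag(D), diag(D), diag(D))     # Q = K = V = X
  for (mask in c(TRUE, FALSE)) {
    for (tau in c(0.7, 2)) {
      got <- scalpnet:::.lsa_forward_cpp(X, I3, numeric(3 * D), diag(D),
                                         numeric(D), tau, mask, Tn)
      ref <- locality_self_attention(X, X, X, temperature = tau, mask = mask)
      expect_lt(max(abs(got$out - ref$out)), 1e-10)
      expect_lt(max(abs(got$A - ref$weights)), 1e-10)
    }
  }
})

test_that("attention-weight rows sum to 1 with zero masked diagonal (property)", {
  set.seed(31)
  for (r in 1:10) {
    Tn <- sample(3:12, 1)
    d <- sample(c(2, 4, 8), 1)
    Q <- matrix(rnorm(Tn * d), Tn, d)
    K <- matrix(rnorm(Tn * d), Tn, d)
    V <- matrix(rnorm(Tn * d), Tn, d)
    w <- locality_self_attention(Q, K, V, temperature = runif(1, 0.5, 3))$weights
    expect_equal(rowSums(w), rep(1, Tn), tolerance = 1e-6)
    expect_true(all(diag(w) == 0))
  }
})

test_that("TTM forward batches, normalizes and is deterministic", {
  cfg <- tiny_ttm_cfg()
  model <- ttm_init(cfg, seed = 3)
  set.seed(4)
  maps <- lapply(1:5, function(i) matrix(rnorm(120), 12, 10))
  out <- ttm_forward(model, maps)
  expect_equal(dim(out$features), c(5, cfg$embed_dim))
  expect_equal(dim(out$logits), c(5, 3))
  expect_true(all(is.finite(out$logits)))
  sm <- exp(out$logits) / rowSums(exp(out$logits))
  expect_equal(rowSums(sm), rep(1, 5), tolerance = 1e-9)
  out2 <- ttm_forward(model, maps)
  expect_identical(out$logits, out2$logits)
  # identical inputs give identical rows
  out3 <- ttm_forward(model, list(maps[[1]], maps[[1]]))
  expect_equal(out3$features[1, ], out3$features[2, ], tolerance = 1e-12)
  expect_error(ttm_forward(model, matrix(0, 5, 5)), "config expects")
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- ttm_config(input_dim = c(8, 8), patch = 4, embed_dim = 8, depth = 2,
                    n_heads = 2, mlp_ratio = 2, n_classes = 3)
  model <- ttm_init(cfg, seed = 2)
  set.seed(3)
  inputs <- lapply(1:3, function(i) matrix(rnorm(64), 8, 8))
  y <- c(1, 2, 3)
  st <- scalpnet:::ttm_step(model, inputs, y)
  eps <- 1e-5
  set.seed(9)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- model; m2$params[[nm]][i] <- p[i] + eps
      m3 <- model; m3$params[[nm]][i] <- p[i] - eps
      num <- (scalpnet:::ttm_step(m2, inputs, y, want_grads = FALSE)$loss -
                scalpnet:::ttm_step(m3, inputs, y, want_grads = FALSE)$loss) /
        (2 * eps)
      ana <- st$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("the softmax temperature is learnable (changes after one step)", {
  ds <- make_tiny_cpd_dataset(2, seed = 7)
  cfg <- tiny_ttm_cfg()
  model <- ttm_init(cfg, seed = 5)
  tau_before <- model$params$L1_log_tau
  res <- train_stage1(model, ds,
                      train_config(stage1_epochs = 1, batch_size = 16,
                                   stage1_lr = 1e-3, seed = 1))
  expect_false(any(res$model$params$L1_log_tau == tau_before))
  expect_true(all(exp(res$model$params$L1_log_tau) > 0))
})
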