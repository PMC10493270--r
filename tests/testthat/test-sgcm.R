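test_that("build_graph matches the two-node hand computation", {
  g <- build_graph(c("C3", "C4"), rbind(c("C3", "C4")))
  expect_equal(unname(g$A), matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(g$A_hat), matrix(1, 2, 2))
  expect_equal(unname(g$D_hat), diag(c(2, 2)))
  expect_equal(unname(g$A_norm), matrix(0.5, 2, 2))
})

test_that("an edgeless graph normalizes to the identity", {
  g <- build_graph(c("O1", "O2", "Fp1"), matrix(character(0), 0, 2))
  expect_equal(unname(g$A_norm), diag(3))
})

test_that("the default electrode graph is a sane 16-node neighbor graph", {
  g <- build_graph()
  expect_length(g$nodes, 16)
  expect_equal(g$A, t(g$A))
  expect_true(all(g$A %in% c(0, 1)))
  expect_true(all(diag(g$A) == 0))
  expect_true(all(diag(g$A_hat) == 1))
  expect_gte(min(rowSums(g$A)), 2)          # every electrode has >= 2 neighbors
  expect_equal(g$A_norm, t(g$A_norm))
  # spectral radius <= 1 by power iteration
  v <- rep(1 / 4, 16)
  for (i in 1:200) {
    v <- g$A_norm %*% v
    v <- v / sqrt(sum(v^2))
  }
  lambda <- as.numeric(t(v) %*% g$A_norm %*% v)
  expect_lte(abs(lambda), 1 + 1e-9)
  expect_error(build_graph(montage_scalp16(), rbind(c("C3", "XX"))),
               "unknown electrode")
  expect_error(build_graph(montage_scalp16(), rbind(c("C3", "C3"))),
               "self-edge")
})

test_that("edge lists round-trip through plain text", {
  f <- withr::local_tempfile(fileext = ".txt")
  e <- default_electrode_edges()
  write_edge_list(e, f)
  e2 <- read_edge_list(f)
  expect_equal(unname(e2), unname(e))
})

test_that("gcn_layer equals the dense oracle and the hand cases", {
  set.seed(12)
  # identity adjacency, identity activation: output = H W exactly
  g0 <- build_graph(c("a", "b", "c"), matrix(character(0), 0, 2))
  H <- matrix(rnorm(9), 3)
  W <- matrix(rnorm(6), 3, 2)
  expect_equal(unname(gcn_layer(H, g0, W, "identity")), H %*% W)
  # constant features on a connected regular graph: all rows equal
  ring <- build_graph(c("a", "b", "c", "d"),
                      rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                            c("d", "a")))
  Hc <- matrix(1, 4, 3) * rep(c(2, -1, 0.5), each = 4)
  out <- gcn_layer(Hc, ring, diag(3), "identity")
  expect_lt(max(abs(sweep(out, 2, out[1, ]))), 1e-12)
  # 3-node path graph vs independently computed dense product
  path <- build_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  H3 <- matrix(c(1, 2, 3, -1, 0, 1), 3)
  expect_equal(unname(gcn_layer(H3, path, diag(2), "identity")),
               dense_gcn_oracle(unname(path$A), H3, diag(2)),
               tolerance = 1e-12)
  expect_error(gcn_layer(H3[1:2, ], path, diag(2)), "nodes")
  expect_error(gcn_layer(H3, path, diag(3)), "mismatch")
})

test_that("random small graphs match the dense oracle (property)", {
  set.seed(13)
  for (r in 1:25) {
    n <- sample(2:5, 1)
    nodes <- letters[1:n]
    A <- matrix(0, n, n)
    pairs <- which(upper.tri(A), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.5
    edges <- cbind(nodes[pairs[on, 1]], nodes[pairs[on, 2]])
    if (!sum(on)) edges <- matrix(character(0), 0, 2)
    g <- build_graph(nodes, edges)
    H <- matrix(rnorm(n * 3), n)
    W <- matrix(rnorm(3 * 2), 3, 2)
    expect_lt(max(abs(gcn_layer(H, g, W, "identity") -
                        dense_gcn_oracle(unname(g$A), H, W))), 1e-6)
  }
})

test_that("sgcm_forward is permutation equivariant and well normalized", {
  set.seed(14)
  g <- build_graph()
  model <- sgcm_init(sgcm_config(), d_in = 8, seed = 3)
  # zero-init head gives zero logits; perturb to make the test nontrivial
  model$params$W_out <- matrix(rnorm(64 * 3, sd = 0.1), 64, 3)
  H <- matrix(rnorm(16 * 8), 16, 8)
  lg <- sgcm_forward(model, H, g)
  expect_length(lg, 3)
  expect_true(all(is.finite(lg)))
  expect_equal(sum(exp(lg) / sum(exp(lg))), 1, tolerance = 1e-9)
  perm <- sample(16)
  gp <- build_graph(g$nodes[perm],
                    cbind(g$nodes[row(g$A)[g$A == 1 & upper.tri(g$A)]],
                          g$nodes[col(g$A)[g$A == 1 & upper.tri(g$A)]]))
  lg2 <- sgcm_forward(model, H[perm, ], gp)
  expect_equal(lg2, lg, tolerance = 1e-5)
  expect_error(sgcm_forward(model, H[1:5, ], g), "graph node")
})

test_that("L=1 with identity adjacency and mean readout reduces to a linear model", {
  set.seed(15)
  g0 <- build_graph(letters[1:4], matrix(character(0), 0, 2))
  model <- sgcm_init(sgcm_config(n_layers = 1, hidden_dim = 5,
                                 activation = "identity"), d_in = 3, seed = 4)
  model$params$W_out <- matrix(rnorm(15), 5, 3)
  H <- matrix(rnorm(12), 4, 3)
  lg <- sgcm_forward(model, H, g0)
  linear <- as.numeric(colMeans(H) %*% model$params$W1 %*% model$params$W_out +
                         model$params$b_out)
  expect_equal(lg, linear, tolerance = 1e-10)
})

test_that("SGCM analytic gradients match numerical differentiation", {
  set.seed(16)
  g <- build_graph(letters[1:4],
                   rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  model <- sgcm_init(sgcm_config(n_layers = 2, hidden_dim = 6), d_in = 5,
                     seed = 7)
  model$params$W_out <- matrix(rnorm(18, sd = 0.3), 6, 3)
  H <- matrix(rnorm(20), 4, 5)
  y <- 2L
  loss_of <- function(m) {
    scalpnet:::cross_entropy(matrix(sgcm_forward(m, H, g), 1), y)$loss
  }
  fwc <- scalpnet:::sgcm_forward_cached(model, H, g)
  ce <- scalpnet:::cross_entropy(matrix(fwc$logits, 1), y)
  gr <- scalpnet:::sgcm_backward(model, g, fwc, as.numeric(ce$dlogits))
  eps <- 1e-6
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      m2 <- model; m2$params[[nm]][i] <- p[i] + eps
      m3 <- model; m3$params[[nm]][i] <- p[i] - eps
      num <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]) /
                  max(1e-6, abs(num) + abs(gr[[nm]][i])), 1e-4)
    }
  }
})
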