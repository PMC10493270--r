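# FastICA (symmetric decorrelation, tanh contrast) on channels x samples
# data. Returns mixing/unmixing so that data ~ mixing %*% sources + mean.
fast_ica <- function(x, n_comp = nrow(x), max_iter = 200, tol = 1e-6,
                     seed = 1) {
  nch <- nrow(x)
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / n
  eig <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_comp)
  d <- eig$values[keep]
  d[d < 1e-12] <- 1e-12
  K <- diag(1 / sqrt(d), n_comp) %*% t(eig$vectors[, keep, drop = FALSE])
  z <- K %*% xc                               # whitened
  W <- with_seed(seed, matrix(rnorm(n_comp^2), n_comp))
  sym_decor <- function(W) {
    s <- La.svd(W)
    s$u %*% s$vt
  }
  W <- sym_decor(W)
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W1 <- g %*% t(z) / n - diag(rowMeans(gp), n_comp) %*% W
    W1 <- sym_decor(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  unmixing <- W %*% K                          # sources = unmixing %*% (x - mu)
  # mixing: least-squares pseudo-inverse maps sources back to sensor space
  mixing <- t(solve(tcrossprod(unmixing), unmixing %*% t(diag(nch))))
  list(unmixing = unmixing, mixing = mixing, mean = mu,
       sources = unmixing %*% xc)
}

#' Remove independent components from a recording
#'
#' Decomposes the recording with FastICA and reconstructs it with the listed
#' component indices zeroed out, mirroring expert-guided artifact rejection.
#' Component selection is intentionally manual: pass the indices a reviewer
#' chose (an empty list reproduces the input up to numerical error).
#'
#' @param rec An [eeg_recording()].
#' @param exclude Integer vector of component indices to remove (may be
#'   empty).
#' @param n_comp Number of components to estimate (default: channel count).
#' @param seed Seed for the FastICA initialization.
#' @return An [eeg_recording()] reconstructed without the excluded
#'   components.
#' @export
apply_component_exclusion <- function(rec, exclude = integer(0),
                                      n_comp = nrow(rec$data), seed = 1) {
  if (length(exclude) == 0) return(rec)
  if (any(exclude < 1 | exclude > n_comp)) {
    stop("component index out of range 1..", n_comp)
  }
  dec <- fast_ica(rec$data, n_comp = n_comp, seed = seed)
  S <- dec$sources
  S[exclude, ] <- 0
  recon <- dec$mixing %*% S + dec$mean
  rownames(recon) <- rec$channel_names
  set_data(rec, recon)
}
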