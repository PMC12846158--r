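# Shared fixture builders: everything is generated in code at test time.

# Random K x (N x S) data matrices (not whitened), deterministic per seed.
random_instance <- function(K = 2, N = 3, S = 500, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(K), function(k)
    matrix(rnorm(N * S), N, S)))
}

random_w <- function(K = 2, N = 3, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(K), function(k)
    matrix(rnorm(N * N), N, N)))
}

# Small desk configuration used by fast end-to-end tests (full-size desk
# experiments live in test-acceptance.R).
small_config <- function(seed = 1, ...) {
  synthetic_config(K = 3, N = 4, V = 1200, T = 40, noise_sd = 0.1,
                   seed = seed, ...)
}

# Independent reimplementation of the IVA-G objective: average
# multivariate-Gaussian negative log-likelihood over samples, minus the
# demixing log-determinants (full constants kept).
oracle_ivag_loglik_cost <- function(W, X, ridge_scale = 1e-8) {
  K <- length(X)
  N <- nrow(X[[1]])
  S <- ncol(X[[1]])
  Xc <- lapply(X, function(m) m - rowMeans(m))
  sh <- lapply(seq_len(K), function(k) W[[k]] %*% Xc[[k]])
  total <- 0
  for (n in seq_len(N)) {
    M <- do.call(rbind, lapply(sh, function(s) s[n, ]))
    Sig <- tcrossprod(M) / S
    Sig <- Sig + diag(ridge_scale * sum(diag(Sig)) / K, K)
    iSig <- solve(Sig)
    ld <- as.numeric(determinant(Sig)$modulus)
    ll <- 0
    for (v in seq_len(S)) {
      y <- M[, v]
      ll <- ll - 0.5 * drop(t(y) %*% iSig %*% y) - 0.5 * ld -
        (K / 2) * log(2 * pi)
    }
    total <- total - ll / S
  }
  total - sum(vapply(W, function(w) as.numeric(determinant(w)$modulus),
                     numeric(1)))
}

# Central finite differences of an arbitrary scalar function of the W list.
fd_gradient <- function(fn, W, h = 1e-6) {
  lapply(seq_along(W), function(k) {
    g <- matrix(0, nrow(W[[k]]), ncol(W[[k]]))
    for (i in seq_len(nrow(g))) {
      for (j in seq_len(ncol(g))) {
        Wp <- W; Wp[[k]][i, j] <- Wp[[k]][i, j] + h
        Wm <- W; Wm[[k]][i, j] <- Wm[[k]][i, j] - h
        g[i, j] <- (fn(Wp) - fn(Wm)) / (2 * h)
      }
    }
    g
  })
}

# relative error normalized by the largest reference entry, so finite-
# difference roundoff (~1e-9 absolute on O(1) costs) does not swamp the
# comparison on near-zero entries
max_rel_err <- function(a, b) {
  scale <- max(vapply(b, function(m) max(abs(m)), numeric(1)))
  mx <- 0
  for (k in seq_along(a)) {
    mx <- max(mx, max(abs(a[[k]] - b[[k]])) / scale)
  }
  mx
}

# Ground-truth joint ISI of a run against the generating mixing matrices,
# composed through the reduction operators.
ground_truth_isi <- function(run, reduced, truth) {
  G <- lapply(seq_along(reduced), function(k) {
    run$W$W[[k]] %*% (reduced[[k]]$reducer$projection %*% truth$A[[k]])
  })
  joint_isi(G)
}
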