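test_that("estimate_scv_covariances matches its definition", {
  # perfect correlation: dataset 2 copies dataset 1, rows unit variance
  withr::with_seed(71, s1 <- matrix(rnorm(2 * 400), 2, 400))
  s1 <- t(scale(t(s1))) * sqrt(400 / 399)  # unit variance, denominator S
  sc <- estimate_scv_covariances(list(s1, s1))
  for (n in 1:2) {
    expect_equal(sc$sigma[[n]], matrix(1, 2, 2) + diag(sc$ridge[n], 2),
                 tolerance = 1e-10)
  }

  # independence limit
  withr::with_seed(72, srcs <- lapply(1:2, function(k)
    matrix(rnorm(3 * 20000), 3, 20000)))
  sc2 <- estimate_scv_covariances(srcs)
  for (n in 1:3) {
    expect_lt(max(abs(sc2$sigma[[n]] - diag(2))), 0.05)
  }

  # direct elementwise-summation oracle, K = 3
  srcs3 <- random_instance(K = 3, N = 2, S = 50, seed = 73)
  sc3 <- estimate_scv_covariances(srcs3)
  for (n in 1:2) {
    oracle <- matrix(0, 3, 3)
    for (j in 1:3) for (l in 1:3) {
      a <- srcs3[[j]][n, ] - mean(srcs3[[j]][n, ])
      b <- srcs3[[l]][n, ] - mean(srcs3[[l]][n, ])
      oracle[j, l] <- sum(a * b) / 50
    }
    expect_equal(sc3$sigma[[n]], oracle + diag(sc3$ridge[n], 3),
                 tolerance = 1e-12)
  }

  expect_error(estimate_scv_covariances(list(matrix(1, 2, 1))), "at least 2")
  expect_warning(estimate_scv_covariances(random_instance(3, 2, 3, seed = 74)),
                 "sample-poor")
})

test_that("ivag_cost matches its definition and symmetries", {
  # K = 1, identity demixing, exactly whitened data -> cost 0
  withr::with_seed(81, Z <- matrix(rnorm(3 * 500), 3, 500))
  Zc <- Z - rowMeans(Z)
  Xw <- crossprod(solve(chol(tcrossprod(Zc) / 500)), Zc)
  c0 <- ivag_cost(list(diag(3)), list(Xw))
  expect_lt(abs(c0), 1e-6)  # ridge contributes ~1e-8

  # SCV relabeling symmetry: same permutation in every dataset
  X <- random_instance(K = 2, N = 4, S = 300, seed = 82)
  W <- random_w(K = 2, N = 4, seed = 83)
  perm <- c(3, 1, 4, 2)
  Wp <- lapply(W, function(w) w[perm, ])
  expect_equal(ivag_cost(Wp, X), ivag_cost(W, X), tolerance = 1e-12)

  expect_error(ivag_cost(list(matrix(0, 4, 4), W[[2]]), X), "singular")
})

test_that("ivag_gradient matches finite differences and the K=1 closed form", {
  # standing property: analytic == central finite differences
  for (seed in 1:3) {
    X <- random_instance(K = 2, N = 3, S = 200, seed = seed)
    W <- random_w(K = 2, N = 3, seed = seed + 100)
    g <- ivag_gradient(W, X)
    fd <- fd_gradient(function(w) ivag_cost(w, X), W)
    expect_lt(max_rel_err(g, fd), 1e-5)
  }

  # K = 1 closed form: each SCV covariance is the scalar variance of one
  # estimated source, so grad = diag(1/var_n) W C - W^{-T} with C the sample
  # covariance (ridge 1e-8 omitted from the oracle, hence the tolerance)
  X1 <- random_instance(K = 1, N = 4, S = 300, seed = 91)
  W1 <- random_w(K = 1, N = 4, seed = 92)
  Xc <- X1[[1]] - rowMeans(X1[[1]])
  C <- tcrossprod(Xc) / ncol(Xc)
  vars <- diag(W1[[1]] %*% C %*% t(W1[[1]]))
  closed <- (W1[[1]] %*% C) / vars - t(solve(W1[[1]]))
  g1 <- ivag_gradient(W1, X1)
  expect_equal(g1[[1]], closed, tolerance = 1e-6)
})

# sources with EXACT sample moments: empirically whitened noise colored by
# the SCV Cholesky factors, so cross-component sample covariances are
# exactly zero and W = A^{-1} is an exact stationary point
exact_moment_instance <- function(K = 2, N = 3, V = 1000, seed = 95) {
  withr::with_seed(seed, {
    Z <- matrix(rnorm(N * K * V), N * K, V)
    Zc <- Z - rowMeans(Z)
    Zw <- crossprod(solve(chol(tcrossprod(Zc) / V)), Zc)
    S <- lapply(seq_len(K), function(k) matrix(0, N, V))
    rhos <- seq(0.3, 0.8, length.out = N)
    for (n in seq_len(N)) {
      Cn <- matrix(rhos[n], K, K); diag(Cn) <- 1
      M <- crossprod(chol(Cn), Zw[n + N * (seq_len(K) - 1L), ])
      for (k in seq_len(K)) S[[k]][n, ] <- M[k, ]
    }
    A <- lapply(seq_len(K), function(k)
      qr.Q(qr(matrix(rnorm(N * N), N, N))) + 0.1 * diag(N))
    list(X = lapply(seq_len(K), function(k) A[[k]] %*% S[[k]]), A = A)
  })
}

test_that("gradient vanishes at the inverse-mixing optimum", {
  inst <- exact_moment_instance()
  Winv <- lapply(inst$A, solve)
  g <- ivag_gradient(Winv, inst$X)
  expect_lt(max(vapply(g, function(m) max(abs(m)), numeric(1))), 1e-6)
  # optimization started at the optimum stays put and stops immediately
  res <- iva_optimize(inst$X, optimizer_options(seed = 1), W_init = Winv)
  expect_true(res$converged)
  expect_lte(res$iterations, 2L)
  G <- lapply(seq_along(inst$A), function(k) res$W$W[[k]] %*% inst$A[[k]])
  expect_lt(joint_isi(G), 1e-6)
})

test_that("optimizer is monotone, seedable, and handles order 1", {
  X <- random_instance(K = 2, N = 3, S = 300, seed = 101)
  res <- iva_optimize(X, optimizer_options(seed = 5, max_iterations = 200))
  expect_true(all(diff(res$cost_trace) <= 1e-12))
  expect_true(all(is.finite(res$cost_trace)))

  res2 <- iva_optimize(X, optimizer_options(seed = 5, max_iterations = 200))
  expect_identical(res$cost_trace, res2$cost_trace)
  expect_identical(res$W$W, res2$W$W)

  # N = 1: single source per dataset, trivially exact up to sign/scale
  X1 <- lapply(random_instance(K = 2, N = 1, S = 100, seed = 102), abs)
  r1 <- iva_optimize(X1, optimizer_options(seed = 1, max_iterations = 20))
  expect_identical(dim(r1$W$W[[1]]), c(1L, 1L))
  expect_equal(abs(drop(r1$W$W[[1]])), 1)
})

test_that("multi_run is deterministic and collects failures gracefully", {
  X <- random_instance(K = 2, N = 3, S = 250, seed = 111)
  opts <- optimizer_options(max_iterations = 60)
  runs_a <- multi_run(X, n_runs = 3, base_seed = 42, opts = opts)
  runs_b <- multi_run(X, n_runs = 3, base_seed = 42, opts = opts)
  expect_identical(lapply(runs_a, `[[`, "cost_trace"),
                   lapply(runs_b, `[[`, "cost_trace"))

  single <- multi_run(X, n_runs = 1, base_seed = 7, opts = opts)
  o <- opts; o$seed <- 7L
  direct <- iva_optimize(X, o)
  expect_identical(single[[1]]$W$W, direct$W$W)
  expect_identical(vapply(runs_a, `[[`, integer(1), "seed"), 42:44)
})
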