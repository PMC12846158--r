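# IVA-G: K demixing matrices W[k] are estimated so that the source component
# vectors (SCVs) -- the K-vectors collecting the n-th estimated source from
# every dataset -- are maximally independent of one another while dependence
# within each SCV is exploited through its K x K covariance. Under the
# multivariate-Gaussian SCV model the (constant-dropped) negative
# log-likelihood is
#
#   J(W) = 1/2 sum_n log det Sigma_n  -  sum_k log |det W[k]|
#
# with Sigma_n the sample covariance of the n-th SCV. The additive
# (N K / 2) log(2 pi e) Gaussian normalization is omitted from reported
# costs; oracle comparisons must subtract it.

# ---- input plumbing ---------------------------------------------------------

as_source_list <- function(X) {
  if (inherits(X, "reduced_dataset")) X <- list(X)
  if (!is.list(X)) stop("X must be a list of reduced datasets or matrices")
  Xs <- lapply(X, function(x) {
    if (inherits(x, "reduced_dataset")) x$data else as.matrix(x)
  })
  dims <- vapply(Xs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all datasets must share dimensions N x S")
  }
  Xs
}

center_rows <- function(m) m - rowMeans(m)

as_w_list <- function(W) {
  if (inherits(W, "run_result")) W <- W$W
  if (inherits(W, "demixing_ensemble")) W <- W$W
  if (is.matrix(W)) W <- list(W)
  lapply(W, as.matrix)
}

#' Bundle K demixing matrices
#'
#' @param W List of K invertible N x N matrices.
#' @return `demixing_ensemble` with elements `W`, `order`, `dataset_count`.
#' @export
demixing_ensemble <- function(W) {
  W <- as_w_list(W)
  n <- unique(vapply(W, nrow, integer(1)))
  stopifnot(length(n) == 1L, all(vapply(W, ncol, integer(1)) == n))
  for (k in seq_along(W)) {
    if (abs(det(W[[k]])) <= 1e-12) {
      stop("demixing matrix singular (dataset ", k, ")")
    }
  }
  structure(list(W = W, order = n, dataset_count = length(W)),
            class = "demixing_ensemble")
}

#' Optimizer options for IVA-G
#'
#' @param max_iterations Maximum accepted descent steps.
#' @param w_change_tolerance Convergence threshold on the rotation-invariant
#'   demixing change `max_k (1 - min diag |W_new W_old'|)` (rows normalized).
#' @param step_size Initial line-search step.
#' @param seed Integer seed for the random-orthogonal initialization.
#' @param init `"random_orthogonal"` or `"supplied"` (then pass `W_init` to
#'   [iva_optimize()]).
#' @return List of class `optimizer_options`.
#' @export
optimizer_options <- function(max_iterations = 1024L,
                              w_change_tolerance = 1e-6,
                              step_size = 1, seed = 1L,
                              init = c("random_orthogonal", "supplied")) {
  stopifnot(max_iterations >= 1L, w_change_tolerance > 0, step_size > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 w_change_tolerance = w_change_tolerance,
                 step_size = step_size, seed = as.integer(seed),
                 init = match.arg(init)),
            class = "optimizer_options")
}

# Seeded random orthogonal matrix (QR of a Gaussian, signs fixed by R's
# positive diagonal so the distribution is Haar and reproducible).
random_orthogonal <- function(n) {
  qr_ <- qr(matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qr_)
  q * rep(sign(diag(qr.R(qr_))), each = n)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# ---- SCV covariances --------------------------------------------------------

#' Sample covariances of the source component vectors
#'
#' For each component n, the K x K sample covariance (denominator S, rows
#' centered) of the n-th source across the K datasets, with a small ridge
#' added to the diagonal to keep the matrices positive definite in the
#' sample-poor (tIVA) regime.
#'
#' @param sources List of K source matrices, each N x S.
#' @param ridge_scale Ridge as a fraction of `trace/K` added to diagonals.
#' @return `scv_covariances`: list with `sigma` (N matrices, K x K) and
#'   `ridge` (length-N vector of applied ridges).
#' @export
estimate_scv_covariances <- function(sources, ridge_scale = 1e-8) {
  Xs <- as_source_list(sources)
  K <- length(Xs)
  N <- nrow(Xs[[1]]); S <- ncol(Xs[[1]])
  if (S < 2L) stop("need at least 2 samples to estimate SCV covariances")
  if (S <= K) {
    warning("sample count S <= dataset count K: SCV covariance estimates ",
            "are rank-deficient (sample-poor regime)")
  }
  Xc <- lapply(Xs, center_rows)
  sigma <- vector("list", N)
  ridge <- numeric(N)
  for (n in seq_len(N)) {
    M <- do.call(rbind, lapply(Xc, function(x) x[n, ]))
    sig <- tcrossprod(M) / S
    ridge[n] <- ridge_scale * sum(diag(sig)) / K
    sigma[[n]] <- sig + diag(ridge[n], K)
  }
  structure(list(sigma = sigma, ridge = ridge), class = "scv_covariances")
}

# Internal cost returning +Inf on singular/ill-conditioned iterates so the
# line search can reject them; also returns byproducts reused by the gradient.
# The N SCV covariances are assembled from K(K+1)/2 row-wise cross products
# (one rowSums per dataset pair) rather than per-component slicing.
.ivag_eval <- function(W, Xc, ridge_scale = 1e-8, need_grad_parts = FALSE) {
  K <- length(Xc)
  N <- nrow(Xc[[1]]); S <- ncol(Xc[[1]])
  logdetW <- 0
  for (k in seq_len(K)) {
    ld <- determinant(W[[k]], logarithm = TRUE)
    if (!is.finite(ld$modulus) || abs(det(W[[k]])) <= 1e-12) {
      return(list(cost = Inf))
    }
    logdetW <- logdetW + as.numeric(ld$modulus)
  }
  Sc <- lapply(seq_len(K), function(k) W[[k]] %*% Xc[[k]])
  big <- tcrossprod(do.call(rbind, Sc)) / S   # (NK x NK); SCV blocks on the
  half_logdet <- 0                            # n-strided index sets
  sig_inv <- if (need_grad_parts) vector("list", N) else NULL
  for (n in seq_len(N)) {
    idx <- n + N * (seq_len(K) - 1L)
    sig <- big[idx, idx, drop = FALSE]
    sig <- sig + diag(ridge_scale * sum(diag(sig)) / K, K)
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) return(list(cost = Inf))
    half_logdet <- half_logdet + sum(log(diag(ch)))
    if (need_grad_parts) sig_inv[[n]] <- chol2inv(ch)
  }
  list(cost = half_logdet - logdetW, sources = Sc, sig_inv = sig_inv)
}

.ivag_grad <- function(W, Xc, eval) {
  K <- length(Xc)
  N <- nrow(Xc[[1]]); S <- ncol(Xc[[1]])
  Sc <- eval$sources
  # coef[[k]]: N x K matrix with coef[[k]][n, l] = (Sigma_n^{-1})[k, l]
  coef <- lapply(seq_len(K), function(k) {
    matrix(vapply(eval$sig_inv, function(si) si[k, ], numeric(K)),
           nrow = N, ncol = K, byrow = TRUE)
  })
  grads <- vector("list", K)
  for (k in seq_len(K)) {
    Y <- Sc[[1]] * coef[[k]][, 1]
    if (K > 1) for (l in 2:K) Y <- Y + Sc[[l]] * coef[[k]][, l]
    grads[[k]] <- tcrossprod(Y, Xc[[k]]) / S - t(solve(W[[k]]))
  }
  grads
}

#' IVA-G objective
#'
#' `1/2 sum_n log det(Sigma_hat_n) - sum_k log |det W[k]|`, with the sample
#' SCV covariances recomputed from `W %*% X`. The Gaussian additive constant
#' `(N K / 2) log(2 pi e)` is dropped.
#'
#' @param W `demixing_ensemble`, list of K matrices, or `run_result`.
#' @param X List of `reduced_dataset`s or N x S matrices.
#' @param ridge_scale Diagonal ridge fraction, see
#'   [estimate_scv_covariances()].
#' @return Scalar cost.
#' @export
ivag_cost <- function(W, X, ridge_scale = 1e-8) {
  W <- as_w_list(W)
  Xc <- lapply(as_source_list(X), center_rows)
  stopifnot(length(W) == length(Xc))
  for (k in seq_along(W)) {
    if (abs(det(W[[k]])) <= 1e-12) {
      stop("demixing matrix singular (dataset ", k, ")")
    }
  }
  ev <- .ivag_eval(W, Xc, ridge_scale)
  if (!is.finite(ev$cost)) stop("SCV covariance not positive definite")
  ev$cost
}

#' Gradient of the IVA-G objective
#'
#' @inheritParams ivag_cost
#' @return List of K matrices, each N x N: `d cost / d W[k]`.
#' @export
ivag_gradient <- function(W, X, ridge_scale = 1e-8) {
  W <- as_w_list(W)
  Xc <- lapply(as_source_list(X), center_rows)
  stopifnot(length(W) == length(Xc))
  ev <- .ivag_eval(W, Xc, ridge_scale, need_grad_parts = TRUE)
  if (!is.finite(ev$cost)) stop("SCV covariance not positive definite")
  .ivag_grad(W, Xc, ev)
}

# Rotation-invariant demixing-change metric between successive iterates.
w_change_metric <- function(W_new, W_old) {
  mx <- 0
  for (k in seq_along(W_new)) {
    a <- W_new[[k]] / sqrt(rowSums(W_new[[k]]^2))
    b <- W_old[[k]] / sqrt(rowSums(W_old[[k]]^2))
    mx <- max(mx, 1 - min(diag(abs(tcrossprod(a, b)))))
  }
  mx
}

row_skewness <- function(x) {
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 <= 0) return(0)
  mean(xc^3) / m2^1.5
}

# ---- optimizer --------------------------------------------------------------

#' Minimize the (constrained) IVA-G objective
#'
#' Gradient descent with backtracking line search on the full set of K
#' demixing matrices. When a `reference_set` is supplied the regularized
#' objective `J_IVA + (lambda/2) J_ref` is minimized instead, steering the
#' first M components toward their references. Accepted steps never increase
#' the objective; convergence is declared when the rotation-invariant
#' demixing change drops below the tolerance.
#'
#' On return, rows of each `W[k]` are L2-normalized and signs are fixed:
#' constrained components correlate positively with their reference,
#' unconstrained components have positive sample skewness.
#'
#' @param X List of K `reduced_dataset`s (or N x S matrices), a common N.
#' @param opts [optimizer_options()].
#' @param constraint Optional [reference_set()] on the sample axis.
#' @param W_init Optional list of K starting matrices (used with
#'   `init = "supplied"` or whenever given).
#' @param ridge_scale Diagonal ridge fraction for the SCV covariances.
#' @return `run_result`: `W` (`demixing_ensemble`), `sources`, `scv_cov`,
#'   `cost_trace`, `converged`, `iterations`, `seed`.
#' @export
iva_optimize <- function(X, opts = optimizer_options(), constraint = NULL,
                         W_init = NULL, ridge_scale = 1e-8) {
  Xs <- as_source_list(X)
  K <- length(Xs)
  N <- nrow(Xs[[1]]); S <- ncol(Xs[[1]])
  Xc <- lapply(Xs, center_rows)
  if (!is.null(constraint)) {
    stopifnot(inherits(constraint, "reference_set"))
    if (ncol(constraint$references) > N) {
      stop("more references than components (M > N)")
    }
    if (nrow(constraint$references) != S) {
      stop("reference length does not match the sample axis")
    }
  }
  lam <- if (is.null(constraint)) 0 else constraint$lambda

  # evaluations carry the gradient byproducts (cheap at K x K scale) so the
  # accepted line-search evaluation doubles as the next iteration's basis
  cost_fn <- function(W) {
    ev <- .ivag_eval(W, Xc, ridge_scale, need_grad_parts = TRUE)
    if (!is.finite(ev$cost)) return(list(cost = Inf))
    if (lam > 0) {
      ev$cost <- ev$cost + (lam / 2) * .jref_value(ev$sources, constraint)
    }
    ev
  }
  grad_fn <- function(W, ev) {
    g <- .ivag_grad(W, Xc, ev)
    if (lam > 0) {
      gj <- .jref_gradient(W, Xc, ev$sources, constraint)
      for (k in seq_len(K)) g[[k]] <- g[[k]] + (lam / 2) * gj[[k]]
    }
    g
  }

  if (!is.null(W_init)) {
    W <- lapply(as_w_list(W_init), as.matrix)
  } else {
    W <- with_seed(opts$seed, lapply(seq_len(K), function(k)
      random_orthogonal(N)))
  }
  ev <- cost_fn(W)
  if (!is.finite(ev$cost)) stop("initial demixing matrices are singular")
  cost_trace <- ev$cost
  alpha <- opts$step_size
  converged <- FALSE
  iter <- 0L
  while (iter < opts$max_iterations) {
    iter <- iter + 1L
    G <- grad_fn(W, ev)
    gnorm2 <- sum(vapply(G, function(g) sum(g^2), numeric(1)))
    accepted <- FALSE
    a <- alpha
    while (a > 1e-14) {
      W_new <- lapply(seq_len(K), function(k) W[[k]] - a * G[[k]])
      ev_new <- cost_fn(W_new)
      if (is.finite(ev_new$cost) &&
          ev_new$cost <= ev$cost - 1e-4 * a * gnorm2) {
        accepted <- TRUE
        break
      }
      a <- a / 2
    }
    if (!accepted) {  # step-size floor: gradient no longer a descent signal
      converged <- TRUE
      break
    }
    chg <- w_change_metric(W_new, W)
    W <- W_new
    ev <- ev_new
    cost_trace <- c(cost_trace, ev$cost)
    alpha <- min(a * 2, opts$step_size * 4)
    if (chg < opts$w_change_tolerance) {
      converged <- TRUE
      break
    }
  }
  if (any(!is.finite(cost_trace))) {
    stop("optimizer diverged (non-finite cost at iteration ",
         which(!is.finite(cost_trace))[1] - 1L, ")")
  }

  # pin BSS scale/sign: unit-L2 rows; constrained rows positively correlated
  # with their reference, others positively skewed
  M_ref <- if (is.null(constraint)) 0L else ncol(constraint$references)
  for (k in seq_len(K)) {
    W[[k]] <- W[[k]] / sqrt(rowSums(W[[k]]^2))
    s <- W[[k]] %*% Xc[[k]]
    for (n in seq_len(N)) {
      sgn <- if (n <= M_ref) {
        sign(stats::cor(constraint$references[, n], s[n, ]))
      } else {
        sign(row_skewness(s[n, ]))
      }
      if (is.na(sgn) || sgn == 0) sgn <- 1
      W[[k]][n, ] <- sgn * W[[k]][n, ]
    }
  }
  sources <- lapply(seq_len(K), function(k) W[[k]] %*% Xs[[k]])
  structure(
    list(W = demixing_ensemble(W), sources = sources,
         scv_cov = estimate_scv_covariances(sources, ridge_scale),
         cost_trace = cost_trace, converged = converged,
         iterations = iter, seed = opts$seed,
         constrained = !is.null(constraint) && lam > 0,
         n_constrained = M_ref),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "<run_result> K=%d N=%d, cost %.6g after %d iterations (%s)\n",
    x$W$dataset_count, x$W$order, x$cost_trace[length(x$cost_trace)],
    x$iterations, if (x$converged) "converged" else "max iterations"))
  invisible(x)
}

#' Repeated seeded IVA-G runs
#'
#' Executes [iva_optimize()] with seeds `base_seed .. base_seed + n_runs - 1`.
#' Per-run failures are caught and recorded without aborting the collection;
#' the result is deterministic given `base_seed`.
#'
#' @param X List of reduced datasets.
#' @param n_runs Number of runs (>= 1).
#' @param base_seed First seed.
#' @param constraint Optional [reference_set()].
#' @param opts Template [optimizer_options()]; its seed is overridden per
#'   run.
#' @return List of `run_result`s (class `run_list`) with attribute
#'   `failures`, a named character vector of error messages by seed.
#' @export
multi_run <- function(X, n_runs, base_seed = 1L, constraint = NULL,
                      opts = optimizer_options()) {
  stopifnot(n_runs >= 1L)
  runs <- list()
  failures <- character(0)
  for (i in seq_len(n_runs)) {
    seed_i <- as.integer(base_seed) + i - 1L
    o <- opts
    o$seed <- seed_i
    res <- tryCatch(iva_optimize(X, opts = o, constraint = constraint),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[as.character(seed_i)] <- conditionMessage(res)
    } else {
      runs[[length(runs) + 1L]] <- res
    }
  }
  structure(runs, class = "run_list", failures = failures)
}
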