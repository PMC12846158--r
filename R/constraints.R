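# Threshold-free reference constraint: each reference r_n is tied by index to
# component n (the first M of N components). The regularizer rewards squared
# correlation between r_n and its assigned component in every dataset and
# penalizes leakage of r_n into all other components:
#
#   J_ref(W) = sum_{n=1..M} sum_{k=1..K}
#                [ sum_{m != n} eps^2(r_n, s_m[k]) - eps^2(r_n, s_n[k]) ]
#
# with eps the Pearson correlation. No correlation threshold is involved; the
# weight lambda in L = J_IVA + (lambda/2) J_ref sets the strength.

#' Construct a reference set
#'
#' References are z-scored at construction; constant references and
#' duplicated labels are hard errors. Reference n constrains component n
#' (index assignment); components M+1..N stay unconstrained.
#'
#' @param references Numeric vector (one reference), S x M matrix, or list of
#'   length-S vectors. S is the sample-axis length of the datasets (voxels
#'   for standard IVA, subjects for tIVA).
#' @param labels Character labels, one per reference.
#' @param lambda Nonnegative regularization weight (field default 100).
#' @return `reference_set` with `references` (S x M, columns z-scored),
#'   `labels`, `lambda`.
#' @export
reference_set <- function(references, labels = NULL, lambda = 100) {
  if (is.list(references) && !is.data.frame(references)) {
    references <- do.call(cbind, references)
  }
  if (is.vector(references) && is.numeric(references)) {
    references <- matrix(references, ncol = 1)
  }
  references <- as.matrix(references)
  storage.mode(references) <- "double"
  if (anyNA(references)) stop("references contain missing values")
  M <- ncol(references)
  if (is.null(labels)) {
    labels <- colnames(references)
    if (is.null(labels)) labels <- paste0("ref", seq_len(M))
  }
  if (length(labels) != M) stop("one label per reference required")
  if (anyDuplicated(labels)) stop("duplicated reference labels")
  if (lambda < 0) stop("lambda must be nonnegative")
  for (j in seq_len(M)) {
    s <- stats::sd(references[, j])
    if (!is.finite(s) || s == 0) {
      stop("zero-variance (constant) reference: ", labels[j])
    }
    references[, j] <- (references[, j] - mean(references[, j])) / s
  }
  colnames(references) <- labels
  structure(list(references = references, labels = labels, lambda = lambda),
            class = "reference_set")
}

#' Squared-correlation similarity
#'
#' `eps^2(r, s)`: the squared Pearson correlation — bounded in `[0, 1]`,
#' symmetric, and invariant to affine rescaling of either argument (so it is
#' blind to the BSS sign/scale ambiguity).
#'
#' @param r,s Numeric vectors of equal length, both nonconstant.
#' @return Scalar in `[0, 1]`.
#' @export
similarity_eps2 <- function(r, s) {
  if (length(r) != length(s)) stop("vectors must have equal length")
  if (stats::sd(r) == 0 || stats::sd(s) == 0) {
    stop("zero-variance signal in similarity")
  }
  stats::cor(r, s)^2
}

# sources: list of K centered N x S matrices
.jref_value <- function(sources, R) {
  refs <- R$references
  M <- ncol(refs)
  K <- length(sources)
  N <- nrow(sources[[1]])
  total <- 0
  for (k in seq_len(K)) {
    s <- sources[[k]]
    # eps2[n, m] between reference n and component m of dataset k
    e2 <- stats::cor(refs, t(s))^2
    for (n in seq_len(M)) {
      total <- total + sum(e2[n, -n]) - e2[n, n]
    }
  }
  unname(total)
}

# d eps^2(u, w' X) / d w  with u centered, X row-centered:
#   eps^2 = c^2 / (|u|^2 q),  c = u' s,  q = s' s,  s = X' w  (s centered)
#   grad  = (2 c / (|u|^2 q)) (X u - (c / q) X s)
.eps2_grad_row <- function(u, uu, Xc, s_row) {
  cc <- sum(u * s_row)
  q <- sum(s_row * s_row)
  (2 * cc / (uu * q)) * (Xc %*% u - (cc / q) * (Xc %*% s_row))
}

# gradient of J_ref w.r.t. each W[k]; sources are the centered W Xc
.jref_gradient <- function(W, Xc, sources, R) {
  refs <- R$references
  M <- ncol(refs)
  K <- length(Xc)
  N <- nrow(Xc[[1]])
  uu <- colSums(refs^2)
  grads <- vector("list", K)
  for (k in seq_len(K)) {
    g <- matrix(0, N, N)
    s <- sources[[k]]
    for (m in seq_len(N)) {
      acc <- numeric(N)
      for (n in seq_len(M)) {
        if (n == m) next
        acc <- acc + .eps2_grad_row(refs[, n], uu[n], Xc[[k]], s[m, ])
      }
      if (m <= M) {
        acc <- acc - .eps2_grad_row(refs[, m], uu[m], Xc[[k]], s[m, ])
      }
      g[m, ] <- acc
    }
    grads[[k]] <- g
  }
  grads
}

#' Reference regularization term
#'
#' @param W `demixing_ensemble` or list of K matrices.
#' @param X List of reduced datasets or N x S matrices.
#' @param R [reference_set()].
#' @return Scalar `J_ref`; more negative is better alignment with less
#'   leakage.
#' @export
jref <- function(W, X, R) {
  stopifnot(inherits(R, "reference_set"))
  W <- as_w_list(W)
  Xc <- lapply(as_source_list(X), center_rows)
  if (nrow(R$references) != ncol(Xc[[1]])) {
    stop("reference length does not match the sample axis")
  }
  if (ncol(R$references) > nrow(Xc[[1]])) stop("more references than components")
  sources <- lapply(seq_along(W), function(k) W[[k]] %*% Xc[[k]])
  .jref_value(sources, R)
}

#' Regularized IVA-G objective
#'
#' `L_lambda = J_IVA + (lambda / 2) J_ref`. At `lambda = 0` this equals
#' [ivag_cost()] exactly.
#'
#' @inheritParams jref
#' @param ridge_scale Passed to [ivag_cost()].
#' @return Scalar.
#' @export
constrained_cost <- function(W, X, R, ridge_scale = 1e-8) {
  ivag_cost(W, X, ridge_scale) + (R$lambda / 2) * jref(W, X, R)
}

#' Gradient of the regularized objective
#'
#' @inheritParams constrained_cost
#' @return List of K matrices `d L / d W[k]`.
#' @export
constrained_gradient <- function(W, X, R, ridge_scale = 1e-8) {
  stopifnot(inherits(R, "reference_set"))
  W <- as_w_list(W)
  Xc <- lapply(as_source_list(X), center_rows)
  g <- ivag_gradient(W, Xc, ridge_scale)
  sources <- lapply(seq_along(W), function(k) W[[k]] %*% Xc[[k]])
  gj <- .jref_gradient(W, Xc, sources, R)
  lapply(seq_along(g), function(k) g[[k]] + (R$lambda / 2) * gj[[k]])
}
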