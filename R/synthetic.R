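# Ground-truth generator emulating a multi-subject, multi-task feature study
# at desk scale: K tasks, each a T x V subject-by-voxel matrix X[k] =
# A[k] S[k] + noise. The n-th rows of the S[k] form an SCV with a chosen
# K x K correlation profile; distinct profiles across components make the
# decomposition identifiable for a second-order (Gaussian) model. Group
# effects are injected into mixing columns (subject profiles) — where group
# differences are tested downstream — and references of tunable fidelity are
# derived from the true sources (spatial) or profiles (behavioral).
#
# Every generator is a pure function of (config, seed): sub-seeds are derived
# from cfg$seed with fixed offsets so the independently callable pieces stay
# independent and reproducible.

.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

#' Configuration for the synthetic multi-task generator
#'
#' Defaults define the desk-scale stand-in for a 3-task subject-by-voxel
#' study: K = 3 datasets, N = 6 components, T = 120 subjects (balanced
#' groups), V = 5000 voxels, SCV off-diagonal correlations spaced 0.3..0.9
#' across components (identifiability guard), weak observation noise.
#'
#' @param K,N,V,T Dataset count, component count, voxels, subjects.
#' @param scv_correlation Either a length-N vector of off-diagonal
#'   correlations (each expanded to a compound-symmetric K x K matrix) or a
#'   list of N positive-definite K x K matrices. Default `seq(0.3, 0.9,
#'   length.out = N)`.
#' @param effect_sizes Length-N vector of Cohen's d values injected into the
#'   corresponding mixing columns (0 = no effect).
#' @param noise_sd Standard deviation of additive observation noise.
#' @param group_fraction Fraction of subjects labeled 1 (patients).
#' @param seed Integer master seed.
#' @return `synthetic_config` list.
#' @export
synthetic_config <- function(K = 3, N = 6, V = 5000, T = 120,
                             scv_correlation = NULL,
                             effect_sizes = rep(0, N),
                             noise_sd = 0.1, group_fraction = 0.5,
                             seed = 1L) {
  stopifnot(K >= 1, N >= 1, V >= 1, T >= 1)
  if (is.null(scv_correlation)) {
    scv_correlation <- if (N == 1) 0.6 else seq(0.3, 0.9, length.out = N)
  }
  if (!is.list(scv_correlation)) {
    stopifnot(length(scv_correlation) == N)
    scv_correlation <- lapply(scv_correlation, function(rho) {
      m <- matrix(rho, K, K)
      diag(m) <- 1
      m
    })
  }
  stopifnot(length(scv_correlation) == N)
  for (C in scv_correlation) {
    stopifnot(all(dim(C) == c(K, K)))
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("SCV correlation target is not positive definite")
    }
  }
  if (length(effect_sizes) > N) stop("more effect sizes than components")
  effect_sizes <- c(effect_sizes, rep(0, N - length(effect_sizes)))
  stopifnot(noise_sd >= 0, group_fraction > 0, group_fraction < 1)
  structure(list(K = K, N = N, V = V, T = T,
                 scv_correlation = scv_correlation,
                 effect_sizes = effect_sizes, noise_sd = noise_sd,
                 group_fraction = group_fraction, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate SCV-structured Gaussian sources
#'
#' For each component n, draws V iid samples of a K-variate Gaussian with the
#' configured covariance, then z-scores each row (unit sample variance).
#' Identical covariance profiles across components are flagged: a
#' second-order model cannot separate them.
#'
#' @param cfg [synthetic_config()].
#' @return List with `S` (K matrices N x V) and `scv_cov_true` (N K x K
#'   target matrices).
#' @export
generate_scv_sources <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  # cross-dataset structure is what identifies components; with K = 1 there
  # is none to compare, and Gaussian sources are inherently unidentifiable
  if (cfg$K > 1L) for (n in seq_len(cfg$N - 1L)) {
    for (m in seq(n + 1L, length.out = cfg$N - n)) {
      if (isTRUE(all.equal(cfg$scv_correlation[[n]],
                           cfg$scv_correlation[[m]]))) {
        warning(sprintf(
          "components %d and %d share an SCV covariance profile: not identifiable",
          n, m))
      }
    }
  }
  with_seed(.sub_seed(cfg$seed, 11000L), {
    S <- lapply(seq_len(cfg$K), function(k) matrix(0, cfg$N, cfg$V))
    for (n in seq_len(cfg$N)) {
      L <- chol(cfg$scv_correlation[[n]])
      Z <- matrix(stats::rnorm(cfg$K * cfg$V), cfg$K, cfg$V)
      M <- crossprod(L, Z)           # K x V draws with target covariance
      for (k in seq_len(cfg$K)) {
        row <- M[k, ]
        S[[k]][n, ] <- (row - mean(row)) / stats::sd(row)
      }
    }
    list(S = S, scv_cov_true = cfg$scv_correlation)
  })
}

#' Generate mixing matrices with injected group effects
#'
#' Mixing entries are standard Gaussian; for each component with a nonzero
#' requested effect size, the group-1 entries of that column are shifted by d
#' (population pooled SD is 1, so the population Cohen's d equals the
#' request) in every dataset.
#'
#' @param cfg [synthetic_config()].
#' @return List with `A` (K matrices T x N) and `group_labels`
#'   ([group_labels()]; first block controls, remainder patients).
#' @export
generate_mixing_with_groups <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n1 <- round(cfg$T * cfg$group_fraction)
  labels <- c(rep(0L, cfg$T - n1), rep(1L, n1))
  if (any(cfg$effect_sizes != 0) && cfg$T < 4) {
    stop("injecting a group effect requires at least 4 subjects")
  }
  with_seed(.sub_seed(cfg$seed, 22000L), {
    A <- lapply(seq_len(cfg$K), function(k) {
      a <- matrix(stats::rnorm(cfg$T * cfg$N), cfg$T, cfg$N)
      for (n in seq_len(cfg$N)) {
        d <- cfg$effect_sizes[n]
        if (d != 0) a[labels == 1L, n] <- a[labels == 1L, n] + d
      }
      a
    })
    list(A = A, group_labels = group_labels(labels))
  })
}

#' Synthesize a multi-task dataset collection with ground truth
#'
#' `X[k] = A[k] S[k] + noise_sd * E`, returned as `feature_dataset`s (T x V)
#' together with the full ground truth. Bitwise deterministic per seed.
#'
#' @param cfg [synthetic_config()].
#' @return List with `datasets` (K [feature_dataset()]s) and `truth`
#'   (`ground_truth`: `A`, `S`, `scv_cov_true`, `group_labels`,
#'   `injected_components`, `config`).
#' @export
synthesize_multitask <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  src <- generate_scv_sources(cfg)
  mix <- generate_mixing_with_groups(cfg)
  noise <- with_seed(.sub_seed(cfg$seed, 33000L), {
    lapply(seq_len(cfg$K), function(k)
      if (cfg$noise_sd > 0)
        matrix(stats::rnorm(cfg$T * cfg$V, sd = cfg$noise_sd), cfg$T, cfg$V)
      else matrix(0, cfg$T, cfg$V))
  })
  datasets <- lapply(seq_len(cfg$K), function(k) {
    feature_dataset(mix$A[[k]] %*% src$S[[k]] + noise[[k]],
                    task_id = paste0("task", k))
  })
  truth <- structure(
    list(A = mix$A, S = src$S, scv_cov_true = src$scv_cov_true,
         group_labels = mix$group_labels,
         injected_components = which(cfg$effect_sizes != 0),
         effect_sizes = cfg$effect_sizes, config = cfg),
    class = "ground_truth")
  list(datasets = datasets, truth = truth)
}

#' Build a reference of tunable fidelity from the ground truth
#'
#' Returns the z-scored mixture `alpha * z(signal) + sqrt(1 - alpha^2) *
#' z(noise)` with `alpha = fidelity`, so the expected correlation with the
#' true signal equals the requested fidelity. Spatial references copy a true
#' source row (dataset 1); behavioral references copy a true profile column
#' (dataset 1).
#'
#' @param truth `ground_truth` from [synthesize_multitask()].
#' @param component Component index the reference should target.
#' @param fidelity Target correlation in `[0, 1]`.
#' @param kind `"spatial"` (length V) or `"behavioral"` (length T).
#' @param seed Seed for the reference noise (default derives from the
#'   config's master seed).
#' @return Numeric z-scored reference vector.
#' @export
make_noisy_reference <- function(truth, component, fidelity,
                                 kind = c("spatial", "behavioral"),
                                 seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(truth, "ground_truth"),
            fidelity >= 0, fidelity <= 1)
  if (component < 1 || component > truth$config$N) {
    stop("invalid component index: ", component)
  }
  signal <- if (kind == "spatial") truth$S[[1]][component, ]
            else truth$A[[1]][, component]
  if (is.null(seed)) seed <- .sub_seed(truth$config$seed, 44000L + component)
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  with_seed(seed, {
    noise <- zs(stats::rnorm(length(signal)))
    zs(fidelity * zs(signal) + sqrt(1 - fidelity^2) * noise)
  })
}
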