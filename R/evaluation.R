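# Stability selection and group statistics. Reproducibility across seeded
# runs is measured with a joint Amari-style inter-symbol-interference (ISI)
# score of the "global" matrices G[k]: G = W A for recovery against ground
# truth, and G = W_a inv(W_b) between two runs (cross-joint-ISI). The score
# is 0 exactly when the dataset-summed |G| is a generalized permutation
# matrix (perfect separation up to the BSS permutation/scale ambiguity) and
# 1 for the all-ones matrix.

#' Joint inter-symbol interference
#'
#' For K global matrices `G[k]` (N x N), with `gbar = sum_k |G[k]|`:
#' `[ sum_i (sum_j gbar_ij / max_j gbar_ij - 1)
#'  + sum_j (sum_i gbar_ij / max_i gbar_ij - 1) ] / (2 N (N - 1))`.
#'
#' @param G One N x N matrix or a list of K such matrices.
#' @return Scalar in `[0, 1]`; 0 for permutation-times-diagonal consistency,
#'   1 for all-ones. `N = 1` is defined as 0.
#' @export
joint_isi <- function(G) {
  if (is.matrix(G)) G <- list(G)
  N <- nrow(G[[1]])
  for (g in G) stopifnot(is.matrix(g), nrow(g) == N, ncol(g) == N)
  if (N == 1L) return(0)
  gbar <- Reduce(`+`, lapply(G, abs))
  row_max <- apply(gbar, 1, max)
  col_max <- apply(gbar, 2, max)
  if (any(row_max == 0) || any(col_max == 0)) {
    stop("zero row or column in the aggregated global matrix")
  }
  rows <- sum(rowSums(gbar) / row_max - 1)
  cols <- sum(colSums(gbar) / col_max - 1)
  (rows + cols) / (2 * N * (N - 1))
}

#' Cross-joint-ISI between two runs
#'
#' Joint ISI of the matrices `W_a[k] %*% solve(W_b[k])`, symmetrized as the
#' mean of the (a,b) and (b,a) values. Zero for identical runs and for runs
#' differing only by a consistent row permutation/rescaling (the inherent BSS
#' ambiguity); smaller values mean greater run-to-run reproducibility.
#'
#' @param a,b `run_result`s, `tiva_result`s, or lists of K demixing matrices.
#' @return Scalar in `[0, 1]`.
#' @export
cross_joint_isi <- function(a, b) {
  Wa <- as_w_list(if (inherits(a, "tiva_result")) a$run else a)
  Wb <- as_w_list(if (inherits(b, "tiva_result")) b$run else b)
  stopifnot(length(Wa) == length(Wb))
  inv_b <- lapply(Wb, solve)
  inv_a <- lapply(Wa, solve)
  g_ab <- lapply(seq_along(Wa), function(k) Wa[[k]] %*% inv_b[[k]])
  g_ba <- lapply(seq_along(Wa), function(k) Wb[[k]] %*% inv_a[[k]])
  (joint_isi(g_ab) + joint_isi(g_ba)) / 2
}

#' Select the most reproducible run
#'
#' Fills the pairwise cross-joint-ISI matrix over a collection of seeded runs
#' and selects the run minimizing the mean distance to all others (ties
#' broken by lowest index) — the stability-selection step performed after
#' repeated runs at a given model order.
#'
#' @param runs List of `run_result`s / `tiva_result`s (>= 2).
#' @return `run_collection`: `runs`, `cross_isi` (symmetric, zero diagonal),
#'   `selected_index`, `selected` (the winning run).
#' @export
select_most_reproducible <- function(runs) {
  n <- length(runs)
  if (n < 2L) stop("need at least 2 successful runs")
  cross <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- cross_joint_isi(runs[[i]], runs[[j]])
      cross[i, j] <- v
      cross[j, i] <- v
    }
  }
  mean_isi <- rowSums(cross) / (n - 1)
  sel <- which.min(mean_isi)  # which.min returns the first minimum: tie-break
  structure(list(runs = runs, cross_isi = cross,
                 mean_cross_isi = mean_isi,
                 selected_index = sel, selected = runs[[sel]]),
            class = "run_collection")
}

#' @export
print.run_collection <- function(x, ...) {
  cat(sprintf("<run_collection> %d runs, selected run %d (mean cross-ISI %.4f)\n",
              length(x$runs), x$selected_index,
              x$mean_cross_isi[x$selected_index]))
  invisible(x)
}

#' Model-order scan by run reproducibility
#'
#' For each candidate order, performs `n_runs` seeded runs, selects the most
#' reproducible one and records its mean cross-joint-ISI. The table is
#' returned for user-side selection; the minimizer is only reported. Orders
#' that fail (e.g. exceeding the data rank) are marked without aborting the
#' scan.
#'
#' @param datasets List of `feature_dataset`s.
#' @param orders Integer vector of candidate orders.
#' @param n_runs Runs per order.
#' @param base_seed First seed for each order's [multi_run()].
#' @param opts [optimizer_options()] template.
#' @param transposed Run the scan in the tIVA view (reduce the voxel axis).
#' @return Data frame: `order`, `mean_cross_isi`, `selected_index`,
#'   `failed`, `message`; attribute `best_order` = minimizer among
#'   non-failed rows.
#' @export
order_scan <- function(datasets, orders, n_runs = 10, base_seed = 1L,
                       opts = optimizer_options(), transposed = FALSE) {
  rows <- lapply(orders, function(ord) {
    res <- tryCatch({
      reduced <- lapply(datasets, function(ds) {
        d <- if (transposed) transpose_for_tiva(ds) else ds
        pca_whiten(d, ord)
      })
      runs <- multi_run(reduced, n_runs = n_runs, base_seed = base_seed,
                        opts = opts)
      coll <- select_most_reproducible(runs)
      data.frame(order = ord,
                 mean_cross_isi = coll$mean_cross_isi[coll$selected_index],
                 selected_index = coll$selected_index,
                 failed = FALSE, message = "")
    }, error = function(e) {
      data.frame(order = ord, mean_cross_isi = NA_real_,
                 selected_index = NA_integer_, failed = TRUE,
                 message = conditionMessage(e))
    })
    res
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$failed
  attr(tab, "best_order") <-
    if (any(ok)) tab$order[ok][which.min(tab$mean_cross_isi[ok])] else NA
  tab
}

# ---- group statistics -------------------------------------------------------

#' Binary group labels
#'
#' @param labels Vector coercible to 0/1 (0 = control, 1 = patient).
#' @return `group_labels` with `labels` and per-group `counts`.
#' @export
group_labels <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1")
  }
  counts <- c(n0 = sum(labels == 0L), n1 = sum(labels == 1L))
  if (any(counts == 0L)) stop("both groups must be non-empty")
  structure(list(labels = labels, counts = counts), class = "group_labels")
}

as_group_labels <- function(g) {
  if (inherits(g, "group_labels")) g else group_labels(g)
}

#' Pooled two-sample t-test
#'
#' Student (pooled-variance) two-sample t statistic with two-sided p from the
#' t distribution on `n0 + n1 - 2` degrees of freedom — pooled rather than
#' Welch, matching the pooled-SD convention of [cohens_d()].
#'
#' @param values Numeric vector, one value per subject.
#' @param groups [group_labels()] or 0/1 vector; each group needs >= 2
#'   members.
#' @return List with `t`, `p`, `df`. Degenerate zero-variance input with
#'   equal means gives `t = 0, p = 1`; with unequal means it is an error.
#' @export
two_sample_ttest <- function(values, groups) {
  g <- as_group_labels(groups)
  stopifnot(length(values) == length(g$labels))
  x0 <- values[g$labels == 0L]
  x1 <- values[g$labels == 1L]
  n0 <- length(x0); n1 <- length(x1)
  if (n0 < 2L || n1 < 2L) stop("each group needs at least 2 members")
  df <- n0 + n1 - 2
  sp2 <- ((n0 - 1) * stats::var(x0) + (n1 - 1) * stats::var(x1)) / df
  delta <- mean(x1) - mean(x0)
  if (sp2 <= 0) {
    if (delta == 0) return(list(t = 0, p = 1, df = df))
    stop("zero pooled variance with unequal means")
  }
  t_stat <- delta / sqrt(sp2 * (1 / n0 + 1 / n1))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df), df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and clipped at 1.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(group 1) - mean(group 0)) / s_pooled`, pooling variances with
#' `n - 1` denominators; quantifies group separation independent of sample
#' size.
#'
#' @inheritParams two_sample_ttest
#' @return Scalar effect size.
#' @export
cohens_d <- function(values, groups) {
  g <- as_group_labels(groups)
  stopifnot(length(values) == length(g$labels))
  x0 <- values[g$labels == 0L]
  x1 <- values[g$labels == 1L]
  if (length(x0) < 2L || length(x1) < 2L) stop("each group needs at least 2 members")
  sp2 <- ((length(x0) - 1) * stats::var(x0) +
          (length(x1) - 1) * stats::var(x1)) /
         (length(x0) + length(x1) - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(x1) - mean(x0)) / sqrt(sp2)
}

#' Per-component group statistics
#'
#' For each dataset and component: pooled two-sample t-test on the subject
#' profile, BH-FDR adjustment (within task by default — the narrowest
#' defensible family — or pooled across everything), Cohen's d, and a
#' significance flag at `alpha` on the adjusted p.
#'
#' @param profiles List of K matrices, each T x N (subjects by components) —
#'   e.g. back-projected mixing profiles (standard IVA) or `t(profiles[[k]])`
#'   from a `tiva_result`.
#' @param groups [group_labels()] or 0/1 vector of length T.
#' @param task_ids Optional labels for the K datasets.
#' @param alpha Significance level on adjusted p-values.
#' @param fdr_family `"task"` (adjust within each dataset) or `"all"`.
#' @return Data frame: `task`, `component`, `t`, `p`, `p_adj`, `d`,
#'   `significant`.
#' @export
component_group_stats <- function(profiles, groups, task_ids = NULL,
                                  alpha = 0.05,
                                  fdr_family = c("task", "all")) {
  fdr_family <- match.arg(fdr_family)
  g <- as_group_labels(groups)
  K <- length(profiles)
  if (is.null(task_ids)) task_ids <- paste0("task", seq_len(K))
  rows <- list()
  for (k in seq_len(K)) {
    P <- as.matrix(profiles[[k]])
    stopifnot(nrow(P) == length(g$labels))
    for (n in seq_len(ncol(P))) {
      tt <- two_sample_ttest(P[, n], g)
      rows[[length(rows) + 1L]] <- data.frame(
        task = task_ids[k], component = n, t = tt$t, p = tt$p,
        d = cohens_d(P[, n], g))
    }
  }
  tab <- do.call(rbind, rows)
  if (fdr_family == "task") {
    tab$p_adj <- NA_real_
    for (tk in unique(tab$task)) {
      sel <- tab$task == tk
      tab$p_adj[sel] <- fdr_adjust(tab$p[sel])
    }
  } else {
    tab$p_adj <- fdr_adjust(tab$p)
  }
  tab$significant <- tab$p_adj < alpha
  tab[, c("task", "component", "t", "p", "p_adj", "d", "significant")]
}

#' Correlations between constrained components and their references
#'
#' Per dataset and reference: absolute Pearson correlation between component
#' n (sources for standard IVA, profiles for tIVA) and reference n — the
#' post-analysis measure of reference quality in the threshold-free
#' framework.
#'
#' @param result `run_result` or `tiva_result`.
#' @param R [reference_set()].
#' @return Data frame: `task`, `reference`, `component`, `abs_correlation`.
#' @export
reference_correlation_table <- function(result, R) {
  stopifnot(inherits(R, "reference_set"))
  comps <- if (inherits(result, "tiva_result")) result$profiles
           else result$sources
  task_ids <- if (inherits(result, "tiva_result")) result$task_ids
              else paste0("task", seq_along(comps))
  M <- ncol(R$references)
  rows <- list()
  for (k in seq_along(comps)) {
    for (n in seq_len(M)) {
      rows[[length(rows) + 1L]] <- data.frame(
        task = task_ids[k], reference = R$labels[n], component = n,
        abs_correlation = abs(stats::cor(R$references[, n],
                                         comps[[k]][n, ])))
    }
  }
  do.call(rbind, rows)
}

#' Average component maps into one reference per network
#'
#' Template components belonging to the same brain network are arithmetically
#' averaged and z-scored to yield a single reference per network (the
#' network-averaged reference construction). A constant average is a hard
#' error: it cannot serve as a reference.
#'
#' @param networks Named list; each element a V x m matrix or list of
#'   length-V vectors (the network's component maps).
#' @param lambda Regularization weight for the resulting [reference_set()].
#' @return [reference_set()] with one z-scored reference per network.
#' @export
average_network_references <- function(networks, lambda = 100) {
  stopifnot(is.list(networks), length(networks) >= 1L)
  if (is.null(names(networks)) || any(names(networks) == "")) {
    stop("networks must be a named list")
  }
  means <- lapply(names(networks), function(nm) {
    maps <- networks[[nm]]
    if (is.list(maps)) maps <- do.call(cbind, maps)
    maps <- as.matrix(maps)
    if (ncol(maps) < 1L || nrow(maps) < 2L) stop("empty network: ", nm)
    rowMeans(maps)
  })
  reference_set(do.call(cbind, means), labels = names(networks),
                lambda = lambda)
}
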