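# Transposed IVA: each T x V feature dataset is transposed so that PCA acts
# on the voxel axis and the samples are the T subjects. The estimated sources
# are then subject profiles (one SCV = one profile across tasks) and the
# mixing columns, back-projected through the voxel-axis reducer, are spatial
# maps. Because the statistical sample axis is subjects, this is the
# sample-poor regime; an informative behavioral reference on the profile
# stabilizes the decomposition.

.tiva_run <- function(datasets, order, opts, constraint = NULL) {
  validate_collection(datasets)
  K <- length(datasets)
  Tn <- n_subjects(datasets[[1]])
  if (Tn < 3 * K) {
    warning(sprintf(
      "sample-poor regime: %d subjects for %d datasets; estimates may be unstable",
      Tn, K))
  }
  reduced <- lapply(datasets, function(ds)
    pca_whiten(transpose_for_tiva(ds), order))
  run <- iva_optimize(reduced, opts = opts, constraint = constraint)
  spatial_maps <- lapply(seq_len(K), function(k) {
    A_red <- solve(run$W$W[[k]])
    back_project_profiles(A_red, reduced[[k]]$reducer)
  })
  structure(
    list(profiles = run$sources, spatial_maps = spatial_maps,
         constrained_index = if (is.null(constraint)) NULL else 1L,
         run = run, reducers = lapply(reduced, `[[`, "reducer"),
         order = order, task_ids = vapply(datasets, `[[`, "", "task_id"),
         subject_ids = datasets[[1]]$subject_ids),
    class = "tiva_result"
  )
}

#' Constrained transposed IVA
#'
#' Transposes each dataset, reduces the voxel axis to `order` components, and
#' runs constrained IVA-G with a single behavioral reference on the subject
#' axis. The estimated sources are subject profiles; the constrained profile
#' is component 1. With `lambda = 0` the run is identical (bitwise, at equal
#' seed) to [run_tiva_unconstrained()].
#'
#' One reference per run is the default contract: behavioral measures often
#' probe overlapping constructs, so references are introduced individually
#' across separate runs rather than simultaneously. Pass a multi-column
#' [reference_set()] with `allow_multiple = TRUE` to override.
#'
#' @param datasets List of `feature_dataset`s sharing subjects.
#' @param behavioral_reference Numeric length-T vector (one value per
#'   subject), or a [reference_set()].
#' @param order Model order N (field default 6 for the transposed analysis).
#' @param opts [optimizer_options()].
#' @param lambda Regularization weight (default 100); ignored when a
#'   `reference_set` carrying its own lambda is given.
#' @param allow_multiple Permit M > 1 references in one run.
#' @return `tiva_result` with `profiles` (K matrices N x T), `spatial_maps`
#'   (K matrices V x N), `constrained_index`, `run` (the underlying
#'   `run_result`), and the voxel-axis `reducers`.
#' @export
run_constrained_tiva <- function(datasets, behavioral_reference, order = 6,
                                 opts = optimizer_options(), lambda = 100,
                                 allow_multiple = FALSE) {
  Tn <- n_subjects(datasets[[1]])
  if (inherits(behavioral_reference, "reference_set")) {
    R <- behavioral_reference
  } else {
    ref <- as.numeric(behavioral_reference)
    if (length(ref) != Tn) {
      stop("reference length (", length(ref), ") does not match subject count (",
           Tn, ")")
    }
    R <- reference_set(ref, labels = "behavioral", lambda = lambda)
  }
  if (ncol(R$references) > 1L && !allow_multiple) {
    stop("constrained tIVA applies one reference per run; set ",
         "allow_multiple = TRUE to override")
  }
  if (nrow(R$references) != Tn) {
    stop("reference length does not match subject count")
  }
  if (R$lambda == 0) {
    return(.tiva_run(datasets, order, opts, constraint = NULL))
  }
  .tiva_run(datasets, order, opts, constraint = R)
}

#' Unconstrained transposed IVA
#'
#' Baseline for the constrained-vs-unconstrained contrast: same pipeline as
#' [run_constrained_tiva()] without the reference term.
#'
#' @inheritParams run_constrained_tiva
#' @return `tiva_result`.
#' @export
run_tiva_unconstrained <- function(datasets, order = 6,
                                   opts = optimizer_options()) {
  .tiva_run(datasets, order, opts, constraint = NULL)
}

#' @export
print.tiva_result <- function(x, ...) {
  cat(sprintf("<tiva_result> K=%d N=%d, %d subjects%s\n",
              length(x$profiles), x$order, ncol(x$profiles[[1]]),
              if (is.null(x$constrained_index)) ""
              else sprintf(", constrained component %d", x$constrained_index)))
  invisible(x)
}

#' Match components of two decompositions by spatial correlation
#'
#' Greedy maximum-|correlation| assignment between the spatial maps of two
#' results (maps concatenated across datasets): repeatedly pairs the
#' remaining components with the largest absolute correlation.
#'
#' @param a,b `tiva_result`s (or lists with `spatial_maps`) over the same
#'   voxel grid and datasets.
#' @return Data frame with `component_a`, `component_b`,
#'   `abs_correlation`, ordered by `component_a`.
#' @export
match_components <- function(a, b) {
  stack <- function(x) do.call(rbind, x$spatial_maps)
  Ma <- stack(a); Mb <- stack(b)
  if (!all(dim(Ma) == dim(Mb))) stop("decompositions have mismatched shapes")
  N <- ncol(Ma)
  C <- abs(stats::cor(Ma, Mb))
  pair_a <- integer(N); pair_b <- integer(N); val <- numeric(N)
  C_work <- C
  for (i in seq_len(N)) {
    ij <- arrayInd(which.max(C_work), dim(C_work))
    pair_a[i] <- ij[1]; pair_b[i] <- ij[2]; val[i] <- C[ij[1], ij[2]]
    C_work[ij[1], ] <- -Inf
    C_work[, ij[2]] <- -Inf
  }
  o <- order(pair_a)
  data.frame(component_a = pair_a[o], component_b = pair_b[o],
             abs_correlation = val[o])
}
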