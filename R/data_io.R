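#' Construct a feature dataset
#'
#' Wraps one task's feature matrix (observations in rows, samples in columns)
#' together with axis metadata. In the standard orientation rows are subjects
#' and columns are voxels; after [transpose_for_tiva()] the roles are swapped.
#'
#' @param data Numeric matrix with at least 2 rows and 2 columns and no
#'   missing values.
#' @param task_id Character label for the task/dataset.
#' @param subject_ids Optional character vector of subject labels. Length must
#'   match the subject axis. Defaults to `sub1..subT`.
#' @param observed_axis Which axis the rows represent: `"subjects"` (standard
#'   feature matrix) or `"voxels"` (transposed, tIVA view).
#' @return An object of class `feature_dataset` with elements `data`,
#'   `task_id`, `subject_ids`, `observed_axis`.
#' @export
feature_dataset <- function(data, task_id = "task", subject_ids = NULL,
                            observed_axis = c("subjects", "voxels")) {
  observed_axis <- match.arg(observed_axis)
  data <- as.matrix(data)
  if (!is.numeric(data)) {
    stop("feature matrix must be numeric")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("feature matrix contains missing or non-finite values")
  }
  if (nrow(data) < 2L || ncol(data) < 2L) {
    stop("feature matrix must be at least 2 x 2")
  }
  n_subj <- if (observed_axis == "subjects") nrow(data) else ncol(data)
  if (is.null(subject_ids)) {
    subject_ids <- paste0("sub", seq_len(n_subj))
  }
  if (length(subject_ids) != n_subj) {
    stop("subject_ids length does not match the subject axis")
  }
  dimnames(data) <- NULL
  structure(
    list(data = data, task_id = as.character(task_id),
         subject_ids = as.character(subject_ids),
         observed_axis = observed_axis),
    class = "feature_dataset"
  )
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset '%s'> %d x %d (%s x %s)\n", x$task_id,
              nrow(x$data), ncol(x$data), x$observed_axis,
              if (x$observed_axis == "subjects") "voxels" else "subjects"))
  invisible(x)
}

n_subjects <- function(ds) {
  if (ds$observed_axis == "subjects") nrow(ds$data) else ncol(ds$data)
}

n_voxels <- function(ds) {
  if (ds$observed_axis == "subjects") ncol(ds$data) else nrow(ds$data)
}

#' Validate a multi-dataset collection
#'
#' All datasets of a collection must share the subject axis (standard IVA:
#' identical subject count and order) and, for the transposed analysis, the
#' voxel axis.
#'
#' @param datasets List of `feature_dataset` objects.
#' @param require_voxels If `TRUE` also require a common voxel count.
#' @return Invisibly `TRUE`; stops on violation.
#' @keywords internal
validate_collection <- function(datasets, require_voxels = TRUE) {
  stopifnot(length(datasets) >= 1L)
  for (ds in datasets) {
    if (!inherits(ds, "feature_dataset")) stop("expected feature_dataset objects")
  }
  ts <- vapply(datasets, n_subjects, integer(1))
  if (length(unique(ts)) != 1L) {
    stop("subject axis mismatch across datasets: ",
         paste(ts, collapse = ", "))
  }
  ids <- lapply(datasets, `[[`, "subject_ids")
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]]))) {
    stop("subject order mismatch across datasets")
  }
  if (require_voxels) {
    vs <- vapply(datasets, n_voxels, integer(1))
    if (length(unique(vs)) != 1L) {
      stop("voxel axis mismatch across datasets: ",
           paste(vs, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Load feature matrices from delimited text files
#'
#' Reads K per-task feature matrices (TSV/CSV, no header) and validates that
#' they form a consistent collection: identical subject axis (and voxel axis)
#' across files.
#'
#' @param paths Character vector of file paths, one per task.
#' @param layout `"subjects_by_voxels"` (rows are subjects; default) or
#'   `"voxels_by_subjects"`.
#' @param task_ids Optional labels, defaults to file base names.
#' @return List of [feature_dataset()] objects.
#' @export
load_feature_matrices <- function(paths,
                                  layout = c("subjects_by_voxels",
                                             "voxels_by_subjects"),
                                  task_ids = NULL) {
  layout <- match.arg(layout)
  if (is.null(task_ids)) {
    task_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  stopifnot(length(task_ids) == length(paths))
  datasets <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) stop("file not found: ", paths[i])
    dt <- data.table::fread(paths[i], header = FALSE)
    bad <- which(!vapply(dt, is.numeric, logical(1)))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric cell in '%s' (column %d)", paths[i], bad[1]))
    }
    m <- as.matrix(dt)
    if (layout == "voxels_by_subjects") m <- t(m)
    datasets[[i]] <- feature_dataset(m, task_id = task_ids[i])
  }
  tryCatch(validate_collection(datasets),
           error = function(e) stop(conditionMessage(e), " (while loading ",
                                    paste(basename(paths), collapse = ", "), ")",
                                    call. = FALSE))
  datasets
}

#' Write a feature matrix as TSV
#'
#' @param x `feature_dataset` or numeric matrix.
#' @param path Output file; tab-separated, no header.
#' @export
write_feature_matrix <- function(x, path) {
  m <- if (inherits(x, "feature_dataset")) x$data else as.matrix(x)
  # format with 17 significant digits so doubles round-trip bitwise
  ch <- array(formatC(m, digits = 17, format = "g"), dim = dim(m))
  data.table::fwrite(data.table::as.data.table(ch), path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' PCA reduction with whitening
#'
#' Centers each observed row, projects onto the top `order` principal
#' directions and rescales so the retained components are exactly white:
#' the sample covariance (denominator = number of samples S) of the output
#' rows equals the identity. The sign of each projection row is fixed so its
#' largest-magnitude entry is positive, for cross-platform reproducibility.
#'
#' @param ds A [feature_dataset()].
#' @param order Number of components N to retain; must not exceed the rank of
#'   the centered data.
#' @return `reduced_dataset`: list with `data` (N x S), `sample_axis`,
#'   `reducer` (a `reduction_operator` with `projection`, `mean_vector`,
#'   `back_projection`).
#' @export
pca_whiten <- function(ds, order) {
  stopifnot(inherits(ds, "feature_dataset"))
  X <- ds$data
  D <- nrow(X); S <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  sv <- svd(Xc, nu = min(D, S), nv = 0)
  tol <- max(sv$d) * max(D, S) * .Machine$double.eps
  if (!is.finite(tol) || max(sv$d) == 0) stop("zero-variance input")
  rank <- sum(sv$d > tol)
  if (order > rank) {
    stop(sprintf("order exceeds data rank (order %d > rank %d)", order, rank))
  }
  U <- sv$u[, seq_len(order), drop = FALSE]
  d <- sv$d[seq_len(order)]
  # fix sign per principal direction: largest |entry| of the row positive
  sgn <- vapply(seq_len(order), function(j) {
    u <- U[, j]
    s <- sign(u[which.max(abs(u))])
    if (s == 0) 1 else s
  }, numeric(1))
  U <- sweep(U, 2L, sgn, `*`)
  projection <- sqrt(S) * (t(U) / d)         # N x D
  back_projection <- U %*% (diag(d, order) / sqrt(S))  # D x N
  reducer <- structure(
    list(projection = projection, mean_vector = mu,
         back_projection = back_projection, order = order,
         observed_axis = ds$observed_axis),
    class = "reduction_operator"
  )
  sample_axis <- if (ds$observed_axis == "subjects") "voxels" else "subjects"
  structure(
    list(data = projection %*% Xc, sample_axis = sample_axis,
         reducer = reducer, task_id = ds$task_id),
    class = "reduced_dataset"
  )
}

#' Transpose a dataset for the tIVA view
#'
#' Swaps the roles of subjects and voxels so that subsequent PCA reduction
#' acts on the voxel axis and estimated sources are subject profiles.
#' Applying it twice returns the original dataset.
#'
#' @param ds A [feature_dataset()].
#' @return Transposed `feature_dataset`.
#' @export
transpose_for_tiva <- function(ds) {
  stopifnot(inherits(ds, "feature_dataset"))
  feature_dataset(t(ds$data), task_id = ds$task_id,
                  subject_ids = ds$subject_ids,
                  observed_axis = if (ds$observed_axis == "subjects")
                    "voxels" else "subjects")
}

#' Back-project reduced mixing profiles into the observed axis
#'
#' Maps an N x N mixing matrix estimated in the whitened space back to the
#' original observed axis (subjects for standard IVA, voxels for tIVA) via
#' the reducer's pseudo-inverse, so its columns are mixing profiles ready for
#' group testing or spatial-map export.
#'
#' @param A_reduced N x N (or N x m) matrix of mixing columns in reduced
#'   space.
#' @param reducer A `reduction_operator` from [pca_whiten()].
#' @return D x m matrix, one profile per column.
#' @export
back_project_profiles <- function(A_reduced, reducer) {
  stopifnot(inherits(reducer, "reduction_operator"))
  A_reduced <- as.matrix(A_reduced)
  if (nrow(A_reduced) != reducer$order) {
    stop("shape mismatch: mixing matrix rows != reducer order")
  }
  reducer$back_projection %*% A_reduced
}
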