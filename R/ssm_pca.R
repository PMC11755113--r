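#' Principal component decomposition of the SRP matrix
#'
#' Decomposes the subjects-by-voxels subject residual profile matrix into
#' orthonormal voxel eigenvectors, per-subject component scores and variance
#' fractions, and selects the smallest number of components that together
#' explain at least `variance_target` of the total variance.
#'
#' No additional centering is applied before the decomposition: the SRP is
#' already referenced to the control-group mean profile, so "variance" here
#' means total squared SRP mass. Set `center_columns = TRUE` to additionally
#' demean each voxel across subjects first.
#'
#' Because the voxel count far exceeds the subject count, the decomposition
#' runs through the small subject-by-subject covariance matrix
#' (eigendecomposition of `S S^T`), which is algebraically identical to the
#' singular value decomposition of the SRP. Eigenvector signs are fixed
#' deterministically: the largest-magnitude voxel loading of each component
#' is made positive. Downstream patterns are invariant to this choice since
#' regression coefficients absorb signs.
#'
#' @param srp An `srp_matrix` from [compute_srp()], or a plain subjects x
#'   voxels matrix.
#' @param variance_target Cumulative variance fraction the selected
#'   components must reach (default 0.90).
#' @param center_columns Demean each voxel across subjects before the
#'   decomposition (default `FALSE`).
#' @return A `pc_basis` object: `eigenvectors` (components x voxels,
#'   orthonormal rows), `scores` (subjects x components), `variance_fraction`,
#'   `n_selected`, `variance_target`, `subject_ids`.
#' @export
fit_pca <- function(srp, variance_target = 0.90, center_columns = FALSE) {
  mat <- if (inherits(srp, "srp_matrix")) srp$srp else srp
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2L) abort("need at least 2 subjects")
  if (ncol(mat) < 2L) abort("need at least 2 voxels")
  stopifnot(variance_target > 0, variance_target <= 1)
  if (center_columns) mat <- scale(mat, center = TRUE, scale = FALSE)

  total <- sum(mat^2)
  if (total == 0) abort("SRP matrix is all zeros (rank 0)")

  # eigen route on the small subject-covariance matrix; d^2 = eigenvalues
  small <- tcrossprod(mat)
  eig <- eigen(small, symmetric = TRUE)
  tol <- max(eig$values) * 1e-12
  keep <- which(eig$values > tol)
  d2 <- eig$values[keep]
  u <- eig$vectors[, keep, drop = FALSE]
  d <- sqrt(d2)
  # voxel eigenvectors: v_j = S^T u_j / d_j  (rows of the returned matrix)
  eigenvectors <- t(crossprod(mat, u) / rep(d, each = ncol(mat)))
  scores <- u * rep(d, each = nrow(u))

  # deterministic sign: largest-|loading| voxel positive
  for (j in seq_len(nrow(eigenvectors))) {
    pivot <- which.max(abs(eigenvectors[j, ]))
    if (eigenvectors[j, pivot] < 0) {
      eigenvectors[j, ] <- -eigenvectors[j, ]
      scores[, j] <- -scores[, j]
    }
  }

  variance_fraction <- d2 / sum(d2)
  n_selected <- which(cumsum(variance_fraction) >= variance_target - 1e-12)[1]
  if (is.na(n_selected)) n_selected <- length(variance_fraction)

  rownames(scores) <- rownames(mat)
  structure(
    list(
      eigenvectors = eigenvectors,
      scores = scores,
      variance_fraction = variance_fraction,
      n_selected = as.integer(n_selected),
      variance_target = variance_target,
      subject_ids = rownames(mat)
    ),
    class = "pc_basis"
  )
}

#' Project an SRP row onto a fitted component basis
#'
#' Computes component scores for a (possibly held-out) subject as inner
#' products of the subject's residual profile with each voxel eigenvector.
#' For a training subject this reproduces the stored score row exactly.
#'
#' @param basis A `pc_basis` from [fit_pca()].
#' @param srp_row Numeric vector over the basis's masked voxels.
#' @return Numeric vector of component scores (length = number of components).
#' @export
project_onto_basis <- function(basis, srp_row) {
  stopifnot(inherits(basis, "pc_basis"))
  if (length(srp_row) != ncol(basis$eigenvectors)) {
    abort("srp_row length does not match the basis voxel count")
  }
  drop(basis$eigenvectors %*% as.numeric(srp_row))
}

#' @export
print.pc_basis <- function(x, ...) {
  cat("<pc_basis> ", length(x$variance_fraction), " components over ",
      ncol(x$eigenvectors), " voxels\n", sep = "")
  cat("  selected: ", x$n_selected, " components explaining ",
      sprintf("%.1f%%", 100 * sum(x$variance_fraction[seq_len(x$n_selected)])),
      " of variance (target ", sprintf("%.0f%%", 100 * x$variance_target),
      ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.pc_basis <- function(x, ...) {
  tibble(
    component = seq_along(x$variance_fraction),
    variance_fraction = x$variance_fraction,
    cumulative_variance = cumsum(x$variance_fraction),
    selected = seq_along(x$variance_fraction) <= x$n_selected
  )
}

#' @export
glance.pc_basis <- function(x, ...) {
  tibble(
    n_components = length(x$variance_fraction),
    n_selected = x$n_selected,
    variance_target = x$variance_target,
    variance_selected = sum(x$variance_fraction[seq_len(x$n_selected)])
  )
}

#' Scree plot of a component basis
#'
#' @param object A `pc_basis`.
#' @param ... Unused.
#' @return A ggplot: per-component variance fraction, selected components
#'   highlighted.
#' @export
autoplot.pc_basis <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$variance_fraction,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey70")) +
    ggplot2::labs(x = "Component", y = "Variance fraction",
                  fill = "Selected") +
    ggplot2::theme_minimal()
}
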