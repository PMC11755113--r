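#' Bootstrap voxel-stability analysis of a covariance pattern
#'
#' Re-runs the pattern determination (component decomposition, stepwise
#' selection, reconstruction) on bootstrap resamples of the subjects and
#' derives a per-voxel two-tailed 95% percentile confidence interval for the
#' pattern weights. Voxels whose interval straddles zero are excluded from
#' the original pattern; the remainder form the stable pattern.
#'
#' The common mask and control-group mean profile are held fixed at their
#' original-sample values inside replicates so every replicate pattern lives
#' on the same voxel space (per-voxel quantiles would otherwise be
#' undefined). For the disease pattern, resampling is stratified by class,
#' preserving both group counts, so no replicate can lose a class; for
#' cognition patterns, patients are resampled simply, and a replicate with a
#' constant response is redrawn (count reported). Replicates whose stepwise
#' model is intercept-only contribute an all-zero weight vector — a
#' conservative choice that widens intervals toward zero. Pattern
#' orientation across replicates is pinned by the response coding (positive
#' class = 1; higher cognition z = better), not by eigenvector signs.
#'
#' @param srp An `srp_matrix` (for cognition patterns, pass the
#'   patient-group rows only).
#' @param response Per-row response: two-level factor for `family =
#'   "logistic"` (second level = positive class), numeric composite for
#'   `"linear"`.
#' @param family `"logistic"` or `"linear"`.
#' @param variance_target Cumulative variance target for component selection.
#' @param direction Stepwise direction.
#' @param n_boot Number of bootstrap replicates (default 5000).
#' @param seed Integer seed; all replicate draws consume one random stream,
#'   so identical seed and inputs give a bit-identical summary.
#' @param conf Confidence level of the two-tailed percentile interval.
#' @return A `bootstrap_summary`: `ci_lo`/`ci_hi` (per-voxel percentile
#'   bounds), `stable` (logical per voxel: CI excludes 0 and the original
#'   weight is non-zero), `stable_pattern` (original weights restricted to
#'   stable voxels), `original` (the original `voxel_pattern`, or `NULL` if
#'   the original model was intercept-only), `n_boot`, `seed`,
#'   `n_empty_replicates`, `n_redraws`.
#' @export
bootstrap_pattern <- function(srp, response, family = c("logistic", "linear"),
                              variance_target = 0.90, direction = "both",
                              n_boot = 5000, seed = 1L, conf = 0.95) {
  family <- match.arg(family)
  stopifnot(inherits(srp, "srp_matrix"), n_boot >= 2)
  mat <- srp$srp
  n <- nrow(mat)
  p <- ncol(mat)
  if (length(response) != n) abort("response length does not match SRP rows")

  if (family == "logistic") {
    g <- factor(response)
    if (nlevels(g) != 2L) abort("logistic response must have 2 classes")
    strata <- split(seq_len(n), g)
  } else {
    response <- as.numeric(response)
    if (any(is.na(response))) abort("linear bootstrap response must be fully defined")
  }

  fit_weights <- function(rows) {
    basis <- fit_pca(mat[rows, , drop = FALSE], variance_target)
    y <- if (family == "logistic") factor(response[rows], levels = levels(factor(response)))
         else response[rows]
    model <- quiet_cap_warnings(
      stepwise_fit(basis, y, family = family, direction = direction)
    )
    if (length(model$included) == 0) NULL else reconstruct_pattern(basis, model)
  }

  # original fit (all subjects, original mask/profile)
  original <- fit_weights(seq_len(n))
  w0 <- if (is.null(original)) rep(0, p) else original$weights

  boot_w <- matrix(0, nrow = n_boot, ncol = p)
  n_empty <- 0L
  n_redraws <- 0L
  run_with_seed(seed, {
    for (b in seq_len(n_boot)) {
      if (family == "logistic") {
        rows <- unlist(lapply(strata, function(s) sample(s, length(s), replace = TRUE)),
                       use.names = FALSE)
      } else {
        repeat {
          rows <- sample.int(n, n, replace = TRUE)
          if (stats::sd(response[rows]) > 0) break
          n_redraws <<- n_redraws + 1L
        }
      }
      pat <- fit_weights(rows)
      if (is.null(pat)) n_empty <- n_empty + 1L else boot_w[b, ] <- pat$weights
    }
  })

  alpha <- (1 - conf) / 2
  ci <- apply(boot_w, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 7)
  ci_lo <- ci[1, ]
  ci_hi <- ci[2, ]
  stable <- (ci_lo > 0 | ci_hi < 0) & w0 != 0

  structure(
    list(
      ci_lo = ci_lo, ci_hi = ci_hi, stable = stable,
      stable_pattern = ifelse(stable, w0, 0),
      original = original, family = family,
      n_boot = as.integer(n_boot), seed = as.integer(seed), conf = conf,
      n_empty_replicates = n_empty, n_redraws = n_redraws,
      mask = srp$mask
    ),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("<bootstrap_summary> ", x$n_boot, " replicates (seed ", x$seed, ")\n", sep = "")
  cat("  stable voxels: ", sum(x$stable), " / ", length(x$stable),
      sprintf(" (%.1f%%)", 100 * mean(x$stable)), "\n", sep = "")
  if (x$n_empty_replicates > 0) {
    cat("  intercept-only replicates: ", x$n_empty_replicates, "\n", sep = "")
  }
  if (x$n_redraws > 0) cat("  constant-response redraws: ", x$n_redraws, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.bootstrap_summary <- function(x, ...) {
  tibble(
    voxel = seq_along(x$stable),
    weight = if (is.null(x$original)) rep(0, length(x$stable)) else x$original$weights,
    ci_lo = x$ci_lo,
    ci_hi = x$ci_hi,
    stable = x$stable
  )
}

#' @export
glance.bootstrap_summary <- function(x, ...) {
  tibble(
    family = x$family,
    n_boot = x$n_boot,
    seed = x$seed,
    n_voxels = length(x$stable),
    n_stable = sum(x$stable),
    stable_fraction = mean(x$stable),
    n_empty_replicates = x$n_empty_replicates
  )
}

#' Mid-axial slice of the stable pattern
#'
#' @param object A `bootstrap_summary` whose `srp` carried a mask.
#' @param slice Axial slice index (default: middle of the grid).
#' @param ... Unused.
#' @return A ggplot raster of stable-pattern weights on that slice.
#' @export
autoplot.bootstrap_summary <- function(object, slice = NULL, ...) {
  if (is.null(object$mask)) abort("no mask recorded; cannot map voxels to the grid")
  vol <- unvectorize(object$stable_pattern, object$mask)
  slice <- slice %||% ceiling(dim(vol)[3] / 2)
  df <- expand.grid(x = seq_len(dim(vol)[1]), y = seq_len(dim(vol)[2]))
  df$weight <- as.vector(vol[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey95", high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("Stable pattern, axial slice ", slice),
                  fill = "Weight") +
    ggplot2::theme_minimal()
}
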