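# Stepwise component selection under BIC, and voxel-pattern reconstruction.
#
# BIC conventions (fixed, so refits are bit-identical):
#   logistic: -2 * log-likelihood + k * ln n
#   linear (Gaussian, profiled variance): n * ln(RSS/n) + k * ln n
# with k counting the intercept. Additive constants are dropped consistently,
# so only BIC differences matter, which is all stepwise selection uses.

bic_linear <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  if (rss <= 0) rss <- .Machine$double.xmin  # perfect fit: keep BIC finite
  n * log(rss / n) + ncol(X) * log(n)
}

# rescale the whole coefficient vector so max|beta| = cap; preserves the
# decision boundary (eta is scaled by a positive constant)
cap_beta <- function(beta, cap) {
  mx <- max(abs(beta))
  if (mx > cap) beta * (cap / mx) else beta
}

# returns list(bic, capped); coefficients capped at |beta| <= cap when the
# fit diverges (perfect separation in small samples)
bic_logistic <- function(X, y, cap = 20) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  capped <- any(abs(beta) > cap) || !fit$converged
  if (capped) beta <- cap_beta(beta, cap)
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  list(bic = -2 * ll + ncol(X) * log(length(y)), capped = capped, beta = beta)
}

model_bic <- function(scores, y, included, family, cap = 20) {
  X <- cbind(1, scores[, included, drop = FALSE])
  if (family == "linear") {
    list(bic = bic_linear(X, y), capped = FALSE)
  } else {
    out <- bic_logistic(X, y, cap = cap)
    out[c("bic", "capped")]
  }
}

#' Stepwise regression of a response on component scores under BIC
#'
#' Selects which principal components enter the pattern model by stepwise
#' regression with the Bayesian information criterion: forward selection from
#' the intercept-only model, each step adding the candidate whose inclusion
#' most decreases BIC, interleaved with backward passes removing any term
#' whose removal decreases BIC, until no move improves BIC. Ties are broken
#' toward the lowest component index, so the result is independent of
#' candidate ordering.
#'
#' The logistic family models disease state (reference class coded 0,
#' positive class 1); the linear family models a cognition z-score. When a
#' logistic fit diverges (perfect separation, common at small n), the
#' candidate is scored with its coefficients capped at `|beta| <= cap`,
#' keeping BIC finite and selection deterministic, and a warning is raised.
#'
#' @param scores A `pc_basis` (candidates are its selected components) or a
#'   subjects x components numeric matrix.
#' @param response Numeric vector (linear), or a two-level factor / 0-1
#'   vector (logistic; second factor level is the positive class). `NA`
#'   responses drop that subject from the fit (with a message).
#' @param family `"logistic"` or `"linear"`.
#' @param direction `"both"` (default) or `"forward"` (no backward passes).
#' @param cap Coefficient magnitude cap for diverging logistic fits.
#' @return A `stepwise_model`: `family`, `included` (component indices,
#'   ascending), `coefficients` (named numeric, no intercept), `intercept`,
#'   `bic`, `total_variance_selected` (sum of included components' variance
#'   fractions when fitted from a `pc_basis`, otherwise `NA`), `n`,
#'   `positive_class`.
#' @export
stepwise_fit <- function(scores, response, family = c("logistic", "linear"),
                         direction = c("both", "forward"), cap = 20) {
  family <- match.arg(family)
  direction <- match.arg(direction)

  basis <- NULL
  if (inherits(scores, "pc_basis")) {
    basis <- scores
    scores <- basis$scores[, seq_len(basis$n_selected), drop = FALSE]
  }
  stopifnot(is.matrix(scores))

  if (family == "logistic") {
    if (is.factor(response) || is.character(response)) {
      f <- factor(response)
      if (nlevels(f) != 2L) abort("logistic response must have exactly 2 classes")
      positive_class <- levels(f)[2]
      y <- as.numeric(f == positive_class)
    } else {
      y <- as.numeric(response)
      if (!all(y %in% c(0, 1))) abort("numeric logistic response must be 0/1")
      positive_class <- "1"
    }
  } else {
    y <- as.numeric(response)
    positive_class <- NA_character_
  }
  if (length(y) != nrow(scores)) abort("response length does not match score rows")

  keep <- !is.na(y)
  if (!all(keep)) {
    inform(paste0(sum(!keep), " subject(s) without a defined response dropped from the fit"))
    y <- y[keep]
    scores <- scores[keep, , drop = FALSE]
  }
  n <- length(y)
  if (n < 3L) abort("too few subjects with a defined response")
  if (family == "logistic" && length(unique(y)) < 2L) {
    abort("logistic response contains a single class")
  }

  p <- ncol(scores)
  included <- integer(0)
  current <- model_bic(scores, y, included, family, cap)
  bic_now <- current$bic
  any_capped <- current$capped

  repeat {
    moved <- FALSE
    # forward: best single addition
    candidates <- setdiff(seq_len(p), included)
    if (length(candidates) > 0) {
      bics <- vapply(candidates, function(j) {
        res <- model_bic(scores, y, sort(c(included, j)), family, cap)
        if (res$capped) any_capped <<- TRUE
        res$bic
      }, numeric(1))
      best <- which.min(bics)  # ties -> first = lowest index
      if (bics[best] < bic_now - 1e-10) {
        included <- sort(c(included, candidates[best]))
        bic_now <- bics[best]
        moved <- TRUE
      }
    }
    # backward sweep: keep removing while removal improves BIC
    if (direction == "both") {
      repeat {
        if (length(included) == 0) break
        bics <- vapply(included, function(j) {
          model_bic(scores, y, setdiff(included, j), family, cap)$bic
        }, numeric(1))
        best <- which.min(bics)
        if (bics[best] < bic_now - 1e-10) {
          included <- setdiff(included, included[best])
          bic_now <- bics[best]
          moved <- TRUE
        } else break
      }
    }
    if (!moved) break
  }

  if (any_capped) {
    warn(paste0("one or more logistic fits diverged; coefficients capped at |beta| <= ", cap))
  }

  # final coefficients on the selected set
  X <- cbind(1, scores[, included, drop = FALSE])
  if (family == "linear") {
    beta <- stats::lm.fit(X, y)$coefficients
  } else {
    beta <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))$coefficients
    beta[is.na(beta)] <- 0
    beta <- cap_beta(beta, cap)
  }
  coefs <- beta[-1]
  names(coefs) <- as.character(included)

  tvs <- if (!is.null(basis) && length(included) > 0) {
    sum(basis$variance_fraction[included])
  } else if (length(included) == 0) 0 else NA_real_

  structure(
    list(
      family = family,
      included = as.integer(included),
      coefficients = coefs,
      intercept = unname(beta[1]),
      bic = bic_now,
      total_variance_selected = tvs,
      n = n,
      positive_class = positive_class
    ),
    class = "stepwise_model"
  )
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat("<stepwise_model> ", x$family, " regression on ", x$n, " subjects\n", sep = "")
  if (length(x$included) == 0) {
    cat("  intercept-only model (no component selected)\n")
  } else {
    cat("  components: {", paste(x$included, collapse = ", "), "}",
        if (!is.na(x$total_variance_selected)) {
          sprintf(" explaining %.1f%% of variance", 100 * x$total_variance_selected)
        } else "", "\n", sep = "")
  }
  cat("  BIC: ", sprintf("%.3f", x$bic), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.stepwise_model <- function(x, ...) {
  tibble(
    term = c("(Intercept)", paste0("PC", x$included)),
    component = c(NA_integer_, x$included),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @export
glance.stepwise_model <- function(x, ...) {
  tibble(
    family = x$family,
    n = x$n,
    n_components = length(x$included),
    bic = x$bic,
    total_variance_selected = x$total_variance_selected
  )
}

#' Reconstruct a voxel-weight pattern from a selected model
#'
#' Forms the spatial covariance pattern as the coefficient-weighted sum of
#' the eigenvectors of the components retained by the stepwise model. The
#' intercept is not spatialized.
#'
#' @param basis A `pc_basis` the model was fitted on.
#' @param model A `stepwise_model` with at least one included component.
#' @return A `voxel_pattern`: `weights` (vector over masked voxels),
#'   `family`, `included`, `coefficients`, `intercept`.
#' @export
reconstruct_pattern <- function(basis, model) {
  stopifnot(inherits(basis, "pc_basis"), inherits(model, "stepwise_model"))
  if (length(model$included) == 0) {
    abort("no pattern identified: the stepwise model is intercept-only")
  }
  w <- drop(crossprod(basis$eigenvectors[model$included, , drop = FALSE],
                      unname(model$coefficients)))
  structure(
    list(
      weights = w,
      family = model$family,
      included = model$included,
      coefficients = model$coefficients,
      intercept = model$intercept,
      total_variance_selected = model$total_variance_selected
    ),
    class = "voxel_pattern"
  )
}

#' @export
print.voxel_pattern <- function(x, ...) {
  cat("<voxel_pattern> ", length(x$weights), " voxel weights from components {",
      paste(x$included, collapse = ", "), "} (", x$family, ")\n", sep = "")
  invisible(x)
}

#' Pattern expression in a subject (subject score)
#'
#' The degree to which a covariance pattern is expressed in an individual:
#' the inner product of the pattern's voxel weights with the subject's
#' residual profile, over all common-mask voxels, with no post-hoc
#' standardization. For a training subject this equals the
#' coefficient-weighted sum of the subject's component scores.
#'
#' @param pattern A `voxel_pattern`.
#' @param srp_row Numeric vector: one subject's residual profile on the same
#'   mask.
#' @return A single numeric score.
#' @export
subject_score <- function(pattern, srp_row) {
  stopifnot(inherits(pattern, "voxel_pattern"))
  if (length(srp_row) != length(pattern$weights)) {
    abort("srp_row length does not match the pattern voxel count")
  }
  sum(pattern$weights * as.numeric(srp_row))
}

#' Subject scores for a whole cohort
#'
#' @param pattern A `voxel_pattern`.
#' @param srp An `srp_matrix` (or subjects x voxels matrix).
#' @return A tibble with `subject_id` and `score`.
#' @export
subject_scores <- function(pattern, srp) {
  mat <- if (inherits(srp, "srp_matrix")) srp$srp else srp
  stopifnot(is.matrix(mat))
  if (ncol(mat) != length(pattern$weights)) {
    abort("srp voxel count does not match the pattern")
  }
  tibble(
    subject_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    score = drop(mat %*% pattern$weights)
  )
}
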