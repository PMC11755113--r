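# Pattern derivation wrappers and leave-one-out cross-validation.

hc_ids_of <- function(labels, reference) {
  stopifnot(is.data.frame(labels), all(c("subject_id", "group") %in% names(labels)))
  ids <- labels$subject_id[labels$group == reference]
  if (length(ids) == 0) abort(paste0("no subjects in reference group '", reference, "'"))
  ids
}

# mask -> srp for a set of volumes; profile referenced to the HC subset
prep_srp <- function(vols, hc_ids, mask_fraction, masks = NULL) {
  masks <- masks %||% lapply(vols, build_subject_mask, fraction = mask_fraction)
  cmask <- build_common_mask(masks)
  logmat <- extract_log_matrix(vols, cmask)
  profile <- group_mean_profile(logmat, intersect(rownames(logmat), hc_ids))
  srp <- compute_srp(logmat, profile, mask = cmask)
  list(mask = cmask, logmat = logmat, profile = profile, srp = srp)
}

# vectorize a held-out volume on a training mask, clamping non-positive
# values to the smallest positive masked training value (scoring-time only)
vectorize_heldout <- function(vol, mask, logmat, subject_id) {
  x <- vol[mask_index(mask)]
  if (any(x <= 0 | !is.finite(x))) {
    floor_val <- exp(min(logmat))
    warn(paste0("non-positive value(s) inside training mask for held-out subject ",
                subject_id, "; clamped to smallest positive masked training value"))
    x[x <= 0 | !is.finite(x)] <- floor_val
  }
  x
}

quiet_cap_warnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("capped", conditionMessage(w))) invokeRestart("muffleWarning")
  })
}

#' Derive the disease-related covariance pattern for a cohort
#'
#' Runs the full identification chain on one cohort: per-subject fractional
#' masks, common mask, log transform, control-group mean profile, subject
#' residual profiles, principal component decomposition with the cumulative
#' variance selection rule, stepwise logistic regression of group membership
#' on component scores under BIC, and reconstruction of the voxel-weight
#' pattern.
#'
#' @param vols Named list of 3-D uptake arrays (all subjects).
#' @param labels Tibble with `subject_id`, `group`; `reference` names the
#'   control group (profile reference and logistic reference class).
#' @param mask_fraction Fractional-maximum threshold for subject masks.
#' @param variance_target Cumulative variance target for component selection.
#' @param direction Stepwise direction, `"both"` or `"forward"`.
#' @param reference Control group label (default `"HC"`).
#' @return A `pattern_fit` list: `mask`, `profile`, `srp`, `basis`, `model`,
#'   `pattern` (`NULL` when the stepwise model is intercept-only), `scores`
#'   (training-subject scores tibble), `labels`, `target = "disease"`.
#' @export
derive_disease_pattern <- function(vols, labels, mask_fraction = 0.03,
                                   variance_target = 0.90,
                                   direction = "both", reference = "HC") {
  hc <- hc_ids_of(labels, reference)
  prep <- prep_srp(vols, hc, mask_fraction)
  basis <- fit_pca(prep$srp, variance_target)
  grp <- factor(labels$group[match(rownames(prep$logmat), labels$subject_id)],
                levels = c(reference, setdiff(unique(as.character(labels$group)), reference)))
  model <- quiet_cap_warnings(
    stepwise_fit(basis, grp, family = "logistic", direction = direction)
  )
  pattern <- if (length(model$included) > 0) reconstruct_pattern(basis, model) else NULL
  scores <- if (!is.null(pattern)) subject_scores(pattern, prep$srp) else NULL
  structure(
    list(target = "disease", mask = prep$mask, profile = prep$profile,
         srp = prep$srp, basis = basis, model = model, pattern = pattern,
         scores = scores, labels = labels, reference = reference),
    class = "pattern_fit"
  )
}

#' Derive a cognition-related covariance pattern (patient-group PCA)
#'
#' As [derive_disease_pattern()], but the principal component decomposition
#' is applied to the patient-group residual profiles only, and component
#' selection is a stepwise linear regression of the chosen composite
#' cognition z-score under BIC. The control group still fixes the mean
#' profile the residuals are referenced to. Patients without a defined
#' composite in the domain are kept in the decomposition but dropped from
#' the regression.
#'
#' @inheritParams derive_disease_pattern
#' @param composites Composite score tibble from [composite_scores()].
#' @param domain One of `"memory"`, `"attention"`, `"executive"`,
#'   `"visuospatial"`, `"global"`.
#' @return A `pattern_fit` (see [derive_disease_pattern()]), with `target =
#'   domain` and `scores` covering the patient group.
#' @export
derive_cognition_pattern <- function(vols, labels, composites, domain,
                                     mask_fraction = 0.03,
                                     variance_target = 0.90,
                                     direction = "both", reference = "HC") {
  stopifnot(domain %in% c(cognition_domains(), "global"))
  hc <- hc_ids_of(labels, reference)
  pd_ids <- setdiff(labels$subject_id, hc)
  prep <- prep_srp(vols, hc, mask_fraction)
  pd_rows <- intersect(rownames(prep$logmat), pd_ids)
  srp_pd <- prep$srp$srp[pd_rows, , drop = FALSE]
  basis <- fit_pca(srp_pd, variance_target)
  response <- composites[[domain]][match(pd_rows, composites$subject_id)]
  model <- stepwise_fit(basis, response, family = "linear", direction = direction)
  pattern <- if (length(model$included) > 0) reconstruct_pattern(basis, model) else NULL
  scores <- if (!is.null(pattern)) subject_scores(pattern, srp_pd) else NULL
  structure(
    list(target = domain, mask = prep$mask, profile = prep$profile,
         srp = prep$srp, basis = basis, model = model, pattern = pattern,
         scores = scores, labels = labels, reference = reference),
    class = "pattern_fit"
  )
}

#' @export
print.pattern_fit <- function(x, ...) {
  cat("<pattern_fit> target: ", x$target, "\n", sep = "")
  print(x$basis)
  print(x$model)
  invisible(x)
}

#' Two-sample pooled-variance t-test on subject scores
#'
#' Student's t-test (equal-variance, two-tailed) comparing pattern-expression
#' scores between the two groups, in factor-level order (first level minus
#' second).
#'
#' @param scores Numeric vector of subject scores.
#' @param labels Two-level factor (or coercible) aligned with `scores`.
#' @return A list with `t`, `p`, `df`.
#' @export
ttest_scores <- function(scores, labels) {
  g <- factor(labels)
  if (nlevels(g) != 2L) abort("labels must have exactly 2 levels")
  if (any(table(g) < 2L)) abort("need at least 2 scores per group")
  x1 <- scores[g == levels(g)[1]]
  x2 <- scores[g == levels(g)[2]]
  if (stats::var(x1) + stats::var(x2) == 0) abort("zero pooled variance")
  tt <- stats::t.test(x1, x2, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' ROC curve, AUC and Youden operating point for subject scores
#'
#' AUC is the Mann-Whitney probability that a random positive-class score
#' exceeds a random negative-class score, with ties counted 0.5 (computed by
#' the rank formula). The reported operating point maximizes Youden's J =
#' sensitivity + specificity - 1 over thresholds of the form "score >=
#' threshold is positive"; ties go to the threshold with higher specificity.
#'
#' @param scores Numeric subject scores.
#' @param labels Two-level factor aligned with `scores`.
#' @param positive Positive-class label (default: second factor level).
#' @return A list with `auc`, `sensitivity`, `specificity`, `threshold`,
#'   `positive`, and `curve` (tibble of threshold/sensitivity/specificity).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  g <- factor(labels)
  if (nlevels(g) != 2L) abort("labels must have exactly 2 classes")
  positive <- positive %||% levels(g)[2]
  if (!positive %in% levels(g)) abort("positive class not found in labels")
  pos <- scores[g == positive]
  neg <- scores[g != positive]
  if (length(pos) == 0 || length(neg) == 0) abort("both classes must be present")

  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))

  thresholds <- c(sort(unique(scores)), Inf)
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  ord <- order(-j, -spec, -thresholds)  # max J; ties -> higher specificity
  best <- ord[1]

  list(
    auc = auc,
    sensitivity = sens[best],
    specificity = spec[best],
    threshold = thresholds[best],
    positive = positive,
    curve = tibble(threshold = thresholds, sensitivity = sens, specificity = spec)
  )
}

#' Pearson correlation of subject scores with cognition scores
#'
#' Product-moment correlation with a two-tailed p-value from the
#' t-distribution with n - 2 degrees of freedom.
#'
#' @param scores Numeric subject scores.
#' @param z Numeric cognition z-scores, same length.
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_r <- function(scores, z) {
  keep <- is.finite(scores) & is.finite(z)
  scores <- scores[keep]
  z <- z[keep]
  if (length(scores) < 3L) abort("need at least 3 paired observations")
  if (stats::sd(scores) == 0 || stats::sd(z) == 0) abort("constant input")
  ct <- stats::cor.test(scores, z, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(scores))
}

new_crossval_result <- function(target, scores, folds, summary, artifacts = NULL) {
  structure(
    list(target = target, scores = scores, folds = folds, summary = summary,
         artifacts = artifacts),
    class = "crossval_result"
  )
}

#' Leave-one-out cross-validation of the disease pattern
#'
#' Each subject is held out in turn; subject masks, common mask, control
#' mean profile, residual profiles, component basis, stepwise logistic model
#' and pattern are all recomputed on the training subjects only, and the
#' held-out subject's volume is vectorized on the training common mask and
#' scored by the inner product with the training pattern. Folds whose
#' stepwise model is intercept-only yield a score of 0 with a flag.
#'
#' @inheritParams derive_disease_pattern
#' @param keep_artifacts Keep per-fold training artifacts (mask index,
#'   profile, pattern weights) for leakage auditing (default `FALSE`).
#' @return A `crossval_result`: `scores` (tibble `subject_id`, `group`,
#'   `score`, `empty_model`), `folds` (tibble of per-fold model summaries),
#'   `summary` (list: `t`, `p`, `auc`, `sensitivity`, `specificity`,
#'   `threshold`), and optionally `artifacts`.
#' @export
loocv_disease <- function(vols, labels, mask_fraction = 0.03,
                          variance_target = 0.90, direction = "both",
                          reference = "HC", keep_artifacts = FALSE) {
  ids <- names(vols)
  stopifnot(all(labels$subject_id %in% ids), all(ids %in% labels$subject_id))
  grp_all <- labels$group[match(ids, labels$subject_id)]
  if (any(table(grp_all) < 2L)) abort("both classes need at least 2 members")
  masks <- lapply(vols, build_subject_mask, fraction = mask_fraction)

  out <- vector("list", length(ids))
  artifacts <- if (keep_artifacts) vector("list", length(ids)) else NULL
  for (i in seq_along(ids)) {
    held <- ids[i]
    train <- setdiff(ids, held)
    hc_train <- intersect(train, hc_ids_of(labels, reference))
    if (length(hc_train) == 0) abort("a fold lost all reference subjects")
    prep <- prep_srp(vols[train], hc_train, mask_fraction, masks = masks[train])
    basis <- fit_pca(prep$srp, variance_target)
    grp <- factor(labels$group[match(train, labels$subject_id)],
                  levels = levels(factor(grp_all)))
    model <- quiet_cap_warnings(
      stepwise_fit(basis, grp, family = "logistic", direction = direction)
    )
    empty <- length(model$included) == 0
    if (empty) {
      score <- 0
      weights <- NULL
    } else {
      pattern <- reconstruct_pattern(basis, model)
      x <- vectorize_heldout(vols[[held]], prep$mask, prep$logmat, held)
      score <- subject_score(pattern, log(x) - prep$profile)
      weights <- pattern$weights
    }
    out[[i]] <- tibble(
      subject_id = held,
      group = labels$group[match(held, labels$subject_id)],
      score = score,
      empty_model = empty,
      n_components = length(model$included),
      bic = model$bic
    )
    if (keep_artifacts) {
      artifacts[[i]] <- list(mask_index = mask_index(prep$mask),
                             profile = prep$profile,
                             scores = basis$scores,
                             included = model$included,
                             weights = weights)
    }
  }
  scores <- dplyr::bind_rows(out)
  if (keep_artifacts) names(artifacts) <- ids

  tt <- ttest_scores(scores$score, scores$group)
  roc <- roc_auc(scores$score, scores$group)
  new_crossval_result(
    target = "disease",
    scores = scores[, c("subject_id", "group", "score", "empty_model")],
    folds = scores[, c("subject_id", "n_components", "bic", "empty_model")],
    summary = list(t = tt$t, p = tt$p, auc = roc$auc,
                   sensitivity = roc$sensitivity, specificity = roc$specificity,
                   threshold = roc$threshold),
    artifacts = artifacts
  )
}

#' Leave-one-out cross-validation of a cognition pattern
#'
#' Folds rotate over patients only: the control group is never held out and
#' supplies the fixed mean profile in every fold. Per fold, the common mask
#' is recomputed from the training subjects (controls plus remaining
#' patients), the component basis is refitted on the training patients'
#' residual profiles, the stepwise linear model refitted on their composite
#' scores, and the held-out patient scored by the inner product.
#'
#' @inheritParams derive_cognition_pattern
#' @param keep_artifacts Keep per-fold training artifacts (default `FALSE`).
#' @return A `crossval_result` with `summary` list (`r`, `p`, `n`).
#' @export
loocv_cognition <- function(vols, labels, composites, domain,
                            mask_fraction = 0.03, variance_target = 0.90,
                            direction = "both", reference = "HC",
                            keep_artifacts = FALSE) {
  stopifnot(domain %in% c(cognition_domains(), "global"))
  ids <- names(vols)
  hc <- intersect(ids, hc_ids_of(labels, reference))
  pd <- setdiff(ids, hc)
  comp <- composites[[domain]][match(pd, composites$subject_id)]
  eligible <- pd[!is.na(comp)]
  if (length(eligible) < 5L) {
    abort("need at least 5 patients with a defined composite in the domain")
  }
  if (length(eligible) < length(pd)) {
    inform(paste0(length(pd) - length(eligible),
                  " patient(s) without a defined '", domain,
                  "' composite excluded from cross-validation"))
  }
  masks <- lapply(vols, build_subject_mask, fraction = mask_fraction)

  out <- vector("list", length(eligible))
  artifacts <- if (keep_artifacts) vector("list", length(eligible)) else NULL
  for (i in seq_along(eligible)) {
    held <- eligible[i]
    train <- setdiff(ids, held)
    prep <- prep_srp(vols[train], hc, mask_fraction, masks = masks[train])
    pd_train <- intersect(rownames(prep$logmat), pd)
    basis <- fit_pca(prep$srp$srp[pd_train, , drop = FALSE], variance_target)
    response <- composites[[domain]][match(pd_train, composites$subject_id)]
    model <- stepwise_fit(basis, response, family = "linear", direction = direction)
    empty <- length(model$included) == 0
    if (empty) {
      score <- 0
      weights <- NULL
    } else {
      pattern <- reconstruct_pattern(basis, model)
      x <- vectorize_heldout(vols[[held]], prep$mask, prep$logmat, held)
      score <- subject_score(pattern, log(x) - prep$profile)
      weights <- pattern$weights
    }
    out[[i]] <- tibble(
      subject_id = held,
      composite = composites[[domain]][match(held, composites$subject_id)],
      score = score,
      empty_model = empty,
      n_components = length(model$included),
      bic = model$bic
    )
    if (keep_artifacts) {
      artifacts[[i]] <- list(mask_index = mask_index(prep$mask),
                             profile = prep$profile,
                             included = model$included,
                             weights = weights)
    }
  }
  scores <- dplyr::bind_rows(out)
  if (keep_artifacts) names(artifacts) <- eligible

  pr <- pearson_r(scores$score, scores$composite)
  new_crossval_result(
    target = domain,
    scores = scores[, c("subject_id", "composite", "score", "empty_model")],
    folds = scores[, c("subject_id", "n_components", "bic", "empty_model")],
    summary = list(r = pr$r, p = pr$p, n = pr$n),
    artifacts = artifacts
  )
}

#' @export
print.crossval_result <- function(x, ...) {
  cat("<crossval_result> target: ", x$target, " (", nrow(x$scores),
      " held-out subjects)\n", sep = "")
  s <- x$summary
  if (x$target == "disease") {
    cat(sprintf("  t = %.3f, p = %.3g, AUC = %.3f, sens = %.2f, spec = %.2f\n",
                s$t, s$p, s$auc, s$sensitivity, s$specificity))
  } else {
    cat(sprintf("  r = %.3f, p = %.3g (n = %d)\n", s$r, s$p, s$n))
  }
  if (any(x$scores$empty_model)) {
    cat("  ", sum(x$scores$empty_model), " fold(s) with an intercept-only model (score 0)\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.crossval_result <- function(x, ...) x$scores

#' @export
glance.crossval_result <- function(x, ...) {
  as_tibble(c(list(target = x$target, n_folds = nrow(x$scores),
                   n_empty = sum(x$scores$empty_model)), x$summary))
}

#' Plot a cross-validation result
#'
#' Disease targets: held-out score distributions per group. Cognition
#' targets: held-out score against the measured composite.
#'
#' @param object A `crossval_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crossval_result <- function(object, ...) {
  if (object$target == "disease") {
    ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$group, y = .data$score)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
      ggplot2::labs(x = NULL, y = "Held-out subject score",
                    title = sprintf("Disease pattern LOOCV (AUC = %.2f)",
                                    object$summary$auc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$score, y = .data$composite)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.5, colour = "steelblue") +
      ggplot2::labs(x = "Held-out subject score",
                    y = paste0("Composite z (", object$target, ")"),
                    title = sprintf("%s pattern LOOCV (r = %.2f)",
                                    object$target, object$summary$r)) +
      ggplot2::theme_minimal()
  }
}

#' ROC curve plot for a disease cross-validation result
#'
#' @param cv A `crossval_result` with a disease target.
#' @return A ggplot of the ROC curve.
#' @export
plot_roc <- function(cv) {
  stopifnot(inherits(cv, "crossval_result"), cv$target == "disease")
  roc <- roc_auc(cv$scores$score, cv$scores$group)
  df <- roc$curve |> arrange(1 - .data$specificity, .data$sensitivity)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.2f)", roc$auc)) +
    ggplot2::theme_minimal()
}
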