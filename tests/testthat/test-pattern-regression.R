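test_that("the linear BIC convention matches its closed form", {
  # intercept + one zero regressor on a +/-1 response: fitted mean 0,
  # so n = 10, RSS = 10, k = 2 -> BIC = 10*ln(10/10) + 2*ln(10)
  X <- cbind(1, rep(0, 10))
  y <- rep(c(-1, 1), 5)
  expect_equal(covpattern:::bic_linear(X, y), 10 * log(1) + 2 * log(10),
               tolerance = 1e-12)
  expect_equal(covpattern:::bic_linear(X, y), 4.60517, tolerance = 1e-5)
})

test_that("stepwise selection recovers a constructed single-component signal", {
  # exact construction: with the response equal to 2 x the first component
  # score, forward selection must take component 1 alone (RSS drops to zero,
  # so any further term only pays the BIC penalty)
  m <- make_toy_matrix(30, 60, rank = 5, seed = 7)
  basis <- fit_pca(m, variance_target = 0.90)
  y <- 2.0 * basis$scores[, 1]
  model <- stepwise_fit(basis, y, family = "linear")
  expect_equal(model$included, 1L)
  expect_equal(unname(model$coefficients), 2.0, tolerance = 1e-8)
  expect_equal(model$total_variance_selected, basis$variance_fraction[1],
               tolerance = 1e-12)
  # refitting reproduces the BIC bit-identically
  model2 <- stepwise_fit(basis, y, family = "linear")
  expect_identical(model$bic, model2$bic)
})

test_that("a response independent of all candidates usually yields the intercept-only model", {
  # per spurious candidate, BIC admits it with probability ~7-8% at this n,
  # so with a three-component pool the intercept-only model should dominate
  m <- make_toy_matrix(40, 80, rank = 5, seed = 9)
  basis <- fit_pca(m, variance_target = 0.90)
  expect_lte(basis$n_selected, 4L)
  n_null <- 0
  for (seed in 1:20) {
    y <- withr::with_seed(100 + seed, rnorm(40))
    model <- stepwise_fit(basis, y, family = "linear")
    if (length(model$included) == 0) n_null <- n_null + 1
  }
  expect_gte(n_null, 12)  # large majority of seeds
})

test_that("stepwise logistic separates classes and caps diverging coefficients", {
  m <- make_toy_matrix(24, 50, rank = 5, seed = 10, noise_sd = 0.05)
  basis <- fit_pca(m, variance_target = 0.99)
  # class determined by component 2's score: perfect separation
  cls <- factor(ifelse(basis$scores[, 2] > stats::median(basis$scores[, 2]), "PD", "HC"),
                levels = c("HC", "PD"))
  expect_warning(model <- stepwise_fit(basis, cls, family = "logistic"), "capped")
  expect_true(2L %in% model$included)
  expect_lte(max(abs(c(model$intercept, model$coefficients))), 20 + 1e-12)
  expect_error(stepwise_fit(basis, factor(rep("PD", 24))), "2 classes")
})

test_that("pattern reconstruction is the coefficient-weighted eigenvector sum", {
  m <- make_toy_matrix(10, 30, rank = 4, seed = 11)
  basis <- fit_pca(m, variance_target = 0.99)

  model <- structure(list(family = "linear", included = c(1L, 3L),
                          coefficients = c(`1` = 2, `3` = -1), intercept = 5,
                          bic = 0, total_variance_selected = NA_real_, n = 10,
                          positive_class = NA_character_),
                     class = "stepwise_model")
  pat <- reconstruct_pattern(basis, model)
  expect_equal(pat$weights,
               2 * basis$eigenvectors[1, ] - 1 * basis$eigenvectors[3, ],
               tolerance = 1e-12)
  # orthonormal eigenvectors: squared norm = 2^2 + 1^2
  expect_equal(sum(pat$weights^2), 5, tolerance = 1e-10)

  model1 <- model
  model1$included <- 2L
  model1$coefficients <- c(`2` = 1)
  expect_equal(reconstruct_pattern(basis, model1)$weights, basis$eigenvectors[2, ],
               tolerance = 1e-12)

  empty <- model; empty$included <- integer(0); empty$coefficients <- numeric(0)
  expect_error(reconstruct_pattern(basis, empty), "no pattern")
})

test_that("subject scores satisfy the inner-product identities", {
  m <- make_toy_matrix(12, 40, rank = 5, seed = 12, noise_sd = 0.05)
  basis <- fit_pca(m, variance_target = 0.99)
  y <- withr::with_seed(13, basis$scores[, 1] - 0.5 * basis$scores[, 2] + rnorm(12, 0, 0.01))
  model <- stepwise_fit(basis, y, family = "linear")
  pat <- reconstruct_pattern(basis, model)

  # central algebraic identity: inner-product score = coefficient-weighted
  # sum of stored component scores, for every training subject
  for (i in seq_len(nrow(m))) {
    expect_equal(subject_score(pat, unclass(m)[i, ]),
                 sum(model$coefficients * basis$scores[i, model$included]),
                 tolerance = 1e-8)
  }

  # orthogonal row scores 0; the weights themselves score their squared norm
  expect_equal(subject_score(pat, rep(0, 40)), 0)
  expect_equal(subject_score(pat, pat$weights), sum(pat$weights^2), tolerance = 1e-12)
  expect_error(subject_score(pat, rep(1, 7)), "length")

  sc <- subject_scores(pat, m)
  expect_equal(sc$score, drop(unclass(m)[, ] %*% pat$weights), tolerance = 1e-12)
})

test_that("results are invariant to eigenvector sign flips and candidate order", {
  m <- make_toy_matrix(20, 45, rank = 5, seed = 14, noise_sd = 0.05)
  basis <- fit_pca(m, variance_target = 0.99)
  y <- withr::with_seed(15, 1.5 * basis$scores[, 2] + rnorm(20, 0, 0.02))

  model <- stepwise_fit(basis, y, family = "linear")
  pat <- reconstruct_pattern(basis, model)

  flipped <- basis
  flipped$eigenvectors[2, ] <- -flipped$eigenvectors[2, ]
  flipped$scores[, 2] <- -flipped$scores[, 2]
  model_f <- stepwise_fit(flipped, y, family = "linear")
  pat_f <- reconstruct_pattern(flipped, model_f)
  expect_equal(model_f$included, model$included)
  expect_equal(pat_f$weights, pat$weights, tolerance = 1e-10)

  # column order of a plain score matrix does not change the selected set
  sc <- basis$scores[, 1:5]
  m1 <- stepwise_fit(sc, y, family = "linear")
  perm <- c(3, 1, 5, 2, 4)
  m2 <- stepwise_fit(sc[, perm], y, family = "linear")
  expect_setequal(perm[m2$included], m1$included)
})
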