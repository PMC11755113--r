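test_that("the pooled-variance t-test matches the closed form", {
  # {1,2,3} vs {4,5,6}: pooled SD 1, t = (2-5)/sqrt(1*(1/3+1/3))
  tt <- ttest_scores(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(tt$t, -3.67423461, tolerance = 1e-6)
  expect_equal(tt$df, 4)

  # identical means, equal n -> t = 0, p = 1
  tt0 <- ttest_scores(c(1, 3, 1, 3), rep(c("a", "b"), each = 2))
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p, 1)

  # scale invariance
  x <- c(0.3, 1.2, 0.7, 2.5, 3.1, 2.2)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(ttest_scores(x, g)$t, ttest_scores(7 * x, g)$t, tolerance = 1e-12)

  expect_error(ttest_scores(rep(1, 6), g), "pooled variance")
})

test_that("AUC equals the exhaustive pairwise count, with the stated operating point", {
  # HC {1, 2}, PD {1.5, 3}: concordant pairs 3 of 4
  roc <- roc_auc(c(1, 2, 1.5, 3), factor(c("HC", "HC", "PD", "PD")))
  expect_equal(roc$auc, 3 / 4)

  # perfectly separated scores
  roc2 <- roc_auc(c(1, 2, 5, 6), factor(c("HC", "HC", "PD", "PD")))
  expect_equal(roc2$auc, 1.0)
  expect_equal(roc2$sensitivity, 1.0)
  expect_equal(roc2$specificity, 1.0)

  # all ties
  roc3 <- roc_auc(rep(2, 6), factor(rep(c("HC", "PD"), 3)))
  expect_equal(roc3$auc, 0.5)

  expect_error(roc_auc(1:3, factor(rep("PD", 3))), "2 classes")
})

test_that("AUC agrees with an independent ROC implementation on random data", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- sample(6:40, 1)
      g <- factor(c(rep("HC", ceiling(n / 3)), rep("PD", n - ceiling(n / 3))))
      s <- round(rnorm(n), 1)  # rounding forces ties
    })
    ours <- roc_auc(s, g)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(g, s, levels = c("HC", "PD"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("Pearson correlation matches the covariance formula and edge cases", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(1:5, -(1:5))$r, -1, tolerance = 1e-12)

  x <- c(0.2, 1.5, -0.7, 2.2, 0.9)
  y <- c(1.1, 0.3, -0.2, 1.8, 0.4)
  hand_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  pr <- pearson_r(x, y)
  expect_equal(pr$r, hand_r, tolerance = 1e-12)
  hand_t <- hand_r * sqrt((5 - 2) / (1 - hand_r^2))
  expect_equal(pr$p, 2 * stats::pt(-abs(hand_t), df = 3), tolerance = 1e-12)

  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("disease LOOCV scores every subject once and separates a strong phantom", {
  ph <- small_phantom(seed = 21)
  cv <- loocv_disease(ph$volumes, ph$labels)
  expect_equal(nrow(cv$scores), length(ph$volumes))
  expect_identical(sort(cv$scores$subject_id), sort(names(ph$volumes)))
  # the small quick phantom (5 HC / 12 PD on a 16^3 grid) separates less
  # sharply than the default-size cohort exercised in the acceptance suite
  expect_gte(cv$summary$auc, 0.8)
  expect_true(is.finite(cv$summary$t))
})

test_that("no training artifact of a fold depends on the held-out subject", {
  ph <- small_phantom(seed = 22)
  cv1 <- loocv_disease(ph$volumes, ph$labels, keep_artifacts = TRUE)

  # replace one held-out subject's volume by arbitrary positive data
  target <- names(ph$volumes)[7]
  vols2 <- ph$volumes
  vols2[[target]] <- withr::with_seed(5, {
    array(exp(stats::rnorm(length(ph$volumes[[1]]), 0.5, 0.4)),
          dim = dim(ph$volumes[[1]]))
  })
  cv2 <- loocv_disease(vols2, ph$labels, keep_artifacts = TRUE)

  a1 <- cv1$artifacts[[target]]
  a2 <- cv2$artifacts[[target]]
  expect_identical(a1$mask_index, a2$mask_index)
  expect_identical(a1$profile, a2$profile)
  expect_identical(a1$scores, a2$scores)
  expect_identical(a1$included, a2$included)
  expect_identical(a1$weights, a2$weights)
  # while that fold's held-out score does change
  expect_false(isTRUE(all.equal(cv1$scores$score[cv1$scores$subject_id == target],
                                cv2$scores$score[cv2$scores$subject_id == target])))
})

test_that("cognition LOOCV rotates over patients only and recovers a strong link", {
  ph <- small_phantom(seed = 23)
  comps <- phantom_composites(ph)
  cv <- loocv_cognition(ph$volumes, ph$labels, comps, "attention")
  pd_ids <- ph$labels$subject_id[ph$labels$group == "PD"]
  expect_setequal(cv$scores$subject_id, pd_ids)   # controls never held out
  expect_gt(cv$summary$r, 0.5)
  expect_lt(cv$summary$p, 0.05)
})

test_that("cognition LOOCV shows no association on a decoupled phantom", {
  rs <- sapply(1:3, function(seed) {
    ph <- small_phantom(seed = 30 + seed, cog_slope = 0)
    comps <- phantom_composites(ph)
    loocv_cognition(ph$volumes, ph$labels, comps, "attention")$summary$r
  })
  expect_lt(mean(abs(rs)), 0.45)
})

test_that("disease scores do not track cognition when the embedded patterns are orthogonal", {
  rs <- sapply(1:3, function(seed) {
    ph <- small_phantom(seed = 40 + seed)
    comps <- phantom_composites(ph)
    cv <- loocv_disease(ph$volumes, ph$labels)
    pd <- cv$scores[cv$scores$group == "PD", ]
    z <- comps$global[match(pd$subject_id, comps$subject_id)]
    pearson_r(pd$score, z)$r
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("non-positive held-out values are clamped at scoring time with a warning", {
  ph <- small_phantom(seed = 25)
  target <- names(ph$volumes)[3]
  # plant a zero inside the brain support of the held-out subject only
  idx <- which(ph$ground_truth$support)[100]
  ph$volumes[[target]][idx] <- 0
  expect_warning(cv <- loocv_disease(ph$volumes, ph$labels), "clamped")
  expect_equal(nrow(cv$scores), length(ph$volumes))
})
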