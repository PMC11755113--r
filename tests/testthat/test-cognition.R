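test_that("z-scores are referenced to the control group, with inversion", {
  zt <- zscore_quiet(tiny_cognition(), c("r1", "r2"), domain_map = tiny_map())

  # reference subject at the reference mean has z = 0
  # sdmt: ref {10, 12}, sample SD = sqrt(2); patient raw 9 -> (9-11)/sqrt(2)
  z_p1 <- zt$z[zt$subject_id == "p1" & zt$test_id == "sdmt"]
  expect_equal(z_p1, (9 - 11) / sqrt(2), tolerance = 1e-12)
  expect_equal(z_p1, -1.41421356, tolerance = 1e-6)

  # tmt_a is inverted: ref {30, 40}, patient 50 -> raw z = (50-35)/sd, sign flipped
  z_inv <- zt$z[zt$subject_id == "p1" & zt$test_id == "tmt_a"]
  expect_equal(z_inv, -(50 - 35) / stats::sd(c(30, 40)), tolerance = 1e-12)
  expect_lt(z_inv, 0)

  # reference columns have mean 0 and sample SD 1
  ref <- zt[zt$subject_id %in% c("r1", "r2"), ]
  for (tid in unique(ref$test_id)) {
    expect_equal(mean(ref$z[ref$test_id == tid]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(ref$z[ref$test_id == tid]), 1, tolerance = 1e-10)
  }
})

test_that("inversion flips sign exactly and standardization removes affine rescaling", {
  cog <- full_map_cognition(n_subj = 8)
  ref <- sprintf("s%02d", 1:4)

  z1 <- zscore_tests(cog, ref)
  map_flip <- default_domain_map()
  map_flip$invert <- !map_flip$invert
  z2 <- zscore_tests(cog, ref, domain_map = map_flip)
  expect_equal(z1$z, -z2$z, tolerance = 1e-12)

  # affine rescaling of raw units (a > 0) leaves z-scores unchanged
  cog_scaled <- dplyr::mutate(cog, raw_score = 3.7 * raw_score + 11)
  z3 <- zscore_tests(cog_scaled, ref)
  expect_equal(z1$z, z3$z, tolerance = 1e-9)
})

test_that("degenerate reference data is rejected with the test named", {
  cog <- tiny_cognition()
  cog$raw_score[cog$test_id == "sdmt" & cog$subject_id %in% c("r1", "r2")] <- 7
  expect_error(zscore_quiet(cog, c("r1", "r2"), domain_map = tiny_map()), "sdmt")

  # a single reference observation is also rejected
  cog2 <- tiny_cognition()[-1, ]  # drop r1's sdmt
  expect_error(zscore_quiet(cog2, c("r1", "r2"), domain_map = tiny_map()),
               "fewer than 2")

  # duplicate subject-test pair
  cog3 <- dplyr::bind_rows(tiny_cognition(), tiny_cognition()[1, ])
  expect_error(zscore_quiet(cog3, c("r1", "r2"), domain_map = tiny_map()),
               "duplicate")

  # unmapped test
  cog4 <- tiny_cognition()
  cog4$test_id[1] <- "mystery"
  expect_error(zscore_quiet(cog4, c("r1", "r2"), domain_map = tiny_map()),
               "mystery")
})

test_that("reference subjects missing a test fall back to available reference data", {
  cog <- full_map_cognition(n_subj = 6)
  ref <- sprintf("s%02d", 1:3)
  cog_missing <- cog[!(cog$subject_id == "s01" & cog$test_id == "vat"), ]
  expect_message(zt <- zscore_tests(cog_missing, ref), "available reference")
  # vat reference statistics now use s02, s03 only
  vat <- cog$raw_score[cog$subject_id %in% c("s02", "s03") & cog$test_id == "vat"]
  z_s04 <- zt$z[zt$subject_id == "s04" & zt$test_id == "vat"]
  raw_s04 <- cog$raw_score[cog$subject_id == "s04" & cog$test_id == "vat"]
  expect_equal(z_s04, (raw_s04 - mean(vat)) / stats::sd(vat), tolerance = 1e-12)
})

test_that("composites average within domains; global averages the four composites", {
  zt <- tibble::tibble(
    subject_id = "s1",
    test_id = letters[1:5],
    domain = c("attention", "attention", "memory", "executive", "visuospatial"),
    z = c(1.0, -0.5, 2.0, 0.5, -1.0)
  )
  cs <- composite_scores(zt)
  expect_equal(cs$attention, 0.25)      # mean(1, -0.5)
  expect_equal(cs$memory, 2.0)          # one test per domain -> that z
  expect_equal(cs$global, mean(c(0.25, 2.0, 0.5, -1.0)))

  # all four composites equal c -> global = c
  zt2 <- tibble::tibble(
    subject_id = "s1", test_id = letters[1:4],
    domain = c("memory", "attention", "executive", "visuospatial"),
    z = rep(0.7, 4)
  )
  expect_equal(composite_scores(zt2)$global, 0.7)

  # missing domain -> NA composite and NA global
  zt3 <- zt[zt$domain != "memory", ]
  cs3 <- composite_scores(zt3)
  expect_true(is.na(cs3$memory))
  expect_true(is.na(cs3$global))
})

test_that("the control-group mean of every composite is zero on complete batteries", {
  cog <- full_map_cognition(n_subj = 10, seed = 9)
  ref <- sprintf("s%02d", 1:5)
  cs <- composite_scores(zscore_tests(cog, ref))
  ref_rows <- cs[cs$subject_id %in% ref, ]
  for (d in c("memory", "attention", "executive", "visuospatial", "global")) {
    expect_equal(mean(ref_rows[[d]]), 0, tolerance = 1e-10)
  }
})

test_that("domain map validation flags thin and malformed maps", {
  map1 <- tiny_map()[1, ]  # attention only, single test
  expect_error(zscore_tests(tiny_cognition()[1:3, ], c("r1", "r2"),
                            domain_map = map1), "no mapped test")
  full <- default_domain_map()
  thin <- full[full$test_id != "vat", ]  # memory left with one test
  expect_warning(validate_map <- covpattern:::validate_domain_map(thin),
                 "fewer than 2")
})
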