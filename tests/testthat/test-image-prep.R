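test_that("subject masks threshold at the stated fraction of the maximum, inclusively", {
  vol <- array(0.1, dim = c(4, 4, 4))
  vol[1, 1, 1] <- 10
  vol[2, 1, 1] <- 0.3   # exactly 3% of max: included
  vol[3, 1, 1] <- 0.2   # below threshold
  vol[4, 1, 1] <- 5.0
  m <- build_subject_mask(vol, fraction = 0.03)
  expect_true(m[1, 1, 1])
  expect_true(m[2, 1, 1])
  expect_false(m[3, 1, 1])
  expect_true(m[4, 1, 1])

  # uniform positive volume: every voxel equals the max, all included
  expect_true(all(build_subject_mask(toy_volume(base = 1))))

  # degenerate volumes are rejected
  expect_error(build_subject_mask(array(0, dim = c(3, 3, 3))), "not positive")
  expect_error(build_subject_mask(array(c(NA, rep(1, 26)), dim = c(3, 3, 3))),
               "non-finite")
})

test_that("the common mask is the intersection, order-invariant and associative", {
  a <- array(TRUE, dim = c(3, 3, 3))
  b <- a; b[1, , ] <- FALSE
  c <- a; c[, 1, ] <- FALSE

  expect_identical(build_common_mask(list(a, a)), a)          # idempotent
  expect_identical(build_common_mask(list(a, b)), b)          # subset absorbs
  expect_identical(build_common_mask(list(a, b, c)),
                   build_common_mask(list(c, b, a)))          # order-invariant
  expect_identical(build_common_mask(list(build_common_mask(list(a, b)), c)),
                   build_common_mask(list(a, build_common_mask(list(b, c)))))

  disjoint <- a; disjoint[] <- FALSE; disjoint[1, 1, 1] <- TRUE
  other <- a; other[] <- FALSE; other[2, 2, 2] <- TRUE
  expect_error(build_common_mask(list(disjoint, other)), "empty")
})

test_that("masked vectorization round-trips bit-exactly", {
  vol <- toy_volume(seed = 5)
  mask <- build_subject_mask(vol, fraction = 0.9)
  expect_true(any(mask) && !all(mask))
  v <- vectorize_volume(vol, mask)
  back <- unvectorize(v, mask)
  expect_identical(back[mask_index(mask)], vol[mask_index(mask)])
  expect_true(all(back[!mask] == 0))
})

test_that("log matrix extraction is elementwise natural log in subject order", {
  mask <- array(TRUE, dim = c(3, 1, 1))
  vols <- list(
    s1 = array(c(1, exp(1), 2), dim = c(3, 1, 1)),
    s2 = array(c(4, 0.5, 1), dim = c(3, 1, 1))
  )
  lm <- extract_log_matrix(vols, mask)
  expect_identical(rownames(lm), c("s1", "s2"))
  expect_equal(lm[1, ], c(0, 1, log(2)), tolerance = 1e-15)
  expect_equal(lm[2, ], c(log(4), log(0.5), 0), tolerance = 1e-15)

  # non-positive masked value: error naming the subject
  vols$s2[2, 1, 1] <- 0
  expect_error(extract_log_matrix(vols, mask), "s2")
})

test_that("group mean profile and SRP follow the centering identities", {
  mask <- array(TRUE, dim = c(2, 2, 1))
  withr::with_seed(11, {
    vols <- purrr::map(1:3, ~ array(exp(stats::rnorm(4)), dim = c(2, 2, 1)))
  })
  names(vols) <- c("h1", "h2", "p1")
  lm <- extract_log_matrix(vols, mask)

  prof <- group_mean_profile(lm, c("h1", "h2"))
  expect_equal(as.numeric(prof), colMeans(lm[c("h1", "h2"), ]), tolerance = 1e-15)

  # single reference subject: profile equals its own row
  prof1 <- group_mean_profile(lm, "h1")
  expect_equal(as.numeric(prof1), unname(lm["h1", ]), tolerance = 1e-15)

  srp <- compute_srp(lm, prof, mask = mask)
  # hand-checked: row i minus profile
  expect_equal(srp$srp, sweep(lm, 2, as.numeric(prof)), tolerance = 1e-15)
  # reference rows average to zero
  expect_equal(colMeans(srp$srp[c("h1", "h2"), ]), rep(0, 4), tolerance = 1e-10)
  # adding the profile back restores the log matrix exactly
  expect_equal(sweep(srp$srp, 2, as.numeric(prof), `+`), lm, tolerance = 1e-15)
  # a subject identical to the profile gets a zero row
  lm2 <- rbind(lm, same = as.numeric(prof))
  expect_equal(unname(compute_srp(lm2, prof)$srp["same", ]), rep(0, 4),
               tolerance = 1e-15)

  expect_error(compute_srp(lm, prof[-1]), "length")
  expect_error(group_mean_profile(lm, character(0)), "non-empty")
})

test_that("NIfTI round trip preserves volumes and masks", {
  dir <- withr::local_tempdir()
  vol <- toy_volume(seed = 3)
  path <- file.path(dir, "s1.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  vols <- read_suvr_volumes(c(s1 = path))
  expect_equal(vols$s1, vol, tolerance = 1e-6, ignore_attr = TRUE)

  mask <- build_subject_mask(vol, 0.5)
  w <- seq_len(sum(mask)) / sum(mask)
  out <- file.path(dir, "w.nii.gz")
  write_masked_nifti(w, mask, out)
  back <- RNifti::readNifti(out)
  expect_equal(as.numeric(back[mask_index(mask)]), w, tolerance = 1e-6)
  expect_true(all(back[!mask] == 0))
})
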