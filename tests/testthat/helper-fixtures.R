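# Shared in-code fixtures. Everything is generated programmatically; the
# small phantom keeps whole-pipeline tests fast while the default-size
# phantom is reserved for the acceptance suite.

tiny_cognition <- function() {
  # two reference subjects, one patient, two tests (one inverted)
  tibble::tibble(
    subject_id = rep(c("r1", "r2", "p1"), times = 2),
    test_id = rep(c("sdmt", "tmt_a"), each = 3),
    raw_score = c(10, 12, 9, 30, 40, 50)
  )
}

tiny_map <- function() {
  # minimal map covering all four domains (single-test domains warn)
  tibble::tibble(
    test_id = c("sdmt", "tmt_a", "vat", "tmt_b", "jolo"),
    domain = c("attention", "attention", "memory", "executive", "visuospatial"),
    invert = c(FALSE, TRUE, FALSE, TRUE, FALSE)
  )
}

# zscore_tests over a thin map, muffling the single-test-domain warning
zscore_quiet <- function(...) suppressWarnings(zscore_tests(...))

full_map_cognition <- function(n_subj = 6, seed = 42) {
  # complete battery for n_subj subjects under the default domain map
  dmap <- default_domain_map()
  withr::with_seed(seed, {
    tidyr::expand_grid(
      subject_id = sprintf("s%02d", seq_len(n_subj)),
      test_id = dmap$test_id
    ) |>
      dplyr::mutate(raw_score = stats::rnorm(dplyr::n(), mean = 50, sd = 10))
  })
}

# small uptake volume: positive plateau with a simple gradient
toy_volume <- function(dim = c(6, 6, 6), base = 2, seed = NULL) {
  if (!is.null(seed)) {
    withr::with_seed(seed, array(base * exp(stats::rnorm(prod(dim), 0, 0.1)), dim = dim))
  } else {
    array(base, dim = dim)
  }
}

small_phantom <- function(seed = 1, ...) {
  make_phantom_cohort(phantom_spec(dim = c(16, 16, 16), n_hc = 5, n_pd = 12,
                                   seed = seed, ...))
}

default_phantom <- function(seed = 1, ...) {
  make_phantom_cohort(phantom_spec(seed = seed, ...))
}

phantom_composites <- function(ph) {
  hc <- ph$labels$subject_id[ph$labels$group == "HC"]
  composite_scores(zscore_tests(ph$cognition, hc))
}

truth_on_mask <- function(ph, mask) {
  ph$ground_truth$disease_pattern[mask_index(mask)]
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
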