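#' Default neuropsychological test battery and domain map
#'
#' Returns the default assignment of each neuropsychological test to one of
#' the four cognitive domains (memory, attention, executive, visuospatial),
#' together with an inversion flag per test. Tests whose raw endpoint is a
#' completion time (Trail Making Test A/B, Stroop card times) are flagged for
#' inversion so that, after z-scoring, a higher score always reflects better
#' performance. The inversion set is an editable assumption: pass your own
#' map to [zscore_tests()] when your battery differs.
#'
#' @return A tibble with columns `test_id`, `domain` (one of `"memory"`,
#'   `"attention"`, `"executive"`, `"visuospatial"`) and `invert` (logical;
#'   `TRUE` means the z-score is multiplied by -1).
#' @examples
#' default_domain_map()
#' @export
default_domain_map <- function() {
  tibble::tribble(
    ~test_id,         ~domain,        ~invert,
    "vat",            "memory",        FALSE,
    "moca_mis",       "memory",        FALSE,
    "sdmt",           "attention",     FALSE,
    "tmt_a",          "attention",     TRUE,
    "stroop_b",       "attention",     TRUE,
    "stroop_cb",      "executive",     TRUE,
    "tmt_b",          "executive",     TRUE,
    "letter_fluency", "executive",     FALSE,
    "vosp_cube",      "visuospatial",  FALSE,
    "tea_map_search", "visuospatial",  FALSE,
    "jolo",           "visuospatial",  FALSE
  )
}

cognition_domains <- function() {
  c("memory", "attention", "executive", "visuospatial")
}

validate_domain_map <- function(domain_map) {
  stopifnot(is.data.frame(domain_map))
  need <- c("test_id", "domain", "invert")
  missing_cols <- setdiff(need, names(domain_map))
  if (length(missing_cols) > 0) {
    abort(paste0("domain_map lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(domain_map$test_id)) {
    abort("domain_map assigns some test_id to more than one domain")
  }
  bad <- setdiff(unique(domain_map$domain), cognition_domains())
  if (length(bad) > 0) {
    abort(paste0("unknown domain(s) in map: ", paste(bad, collapse = ", ")))
  }
  counts <- table(factor(domain_map$domain, levels = cognition_domains()))
  if (any(counts == 0)) {
    abort(paste0("domain(s) with no mapped test: ",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  }
  if (any(counts < 2)) {
    warn(paste0("domain(s) with fewer than 2 mapped tests: ",
                paste(names(counts)[counts < 2], collapse = ", "),
                " (at least two tests per domain are recommended)"))
  }
  invisible(domain_map)
}

#' Z-score neuropsychological test scores against a reference group
#'
#' Standardizes each test to the reference (healthy-control) group: the
#' reference mean is subtracted and the result divided by the reference-group
#' sample standard deviation (n - 1 denominator). Tests flagged `invert` in
#' the domain map have their z-scores multiplied by -1 so that higher always
#' means better performance.
#'
#' @param cognition Long-format data frame with columns `subject_id`,
#'   `test_id`, `raw_score`; one row per subject-test pair.
#' @param reference_ids Character vector of subject ids forming the reference
#'   group (standardization target). Reference subjects missing a test are
#'   dropped from that test's reference statistics (with a message).
#' @param domain_map Test-to-domain map with inversion flags; see
#'   [default_domain_map()].
#' @return A tibble with columns `subject_id`, `test_id`, `domain`, `z`.
#'   Within the reference group every test's z column has mean 0 and sample
#'   SD 1.
#' @examples
#' cog <- tibble::tibble(
#'   subject_id = c("r1", "r2", "p1"),
#'   test_id = "sdmt",
#'   raw_score = c(10, 12, 9)
#' )
#' zscore_tests(cog, c("r1", "r2"),
#'              domain_map = tibble::tibble(test_id = "sdmt",
#'                                          domain = "attention",
#'                                          invert = FALSE))
#' @export
zscore_tests <- function(cognition, reference_ids, domain_map = default_domain_map()) {
  stopifnot(is.data.frame(cognition))
  need <- c("subject_id", "test_id", "raw_score")
  if (!all(need %in% names(cognition))) {
    abort("cognition table needs columns subject_id, test_id, raw_score")
  }
  if (length(reference_ids) == 0) abort("reference_ids must be non-empty")
  validate_domain_map(domain_map)

  cognition <- as_tibble(cognition)
  if (anyDuplicated(cognition[, c("subject_id", "test_id")])) {
    abort("duplicate (subject_id, test_id) pairs in cognition table")
  }
  unmapped <- setdiff(unique(cognition$test_id), domain_map$test_id)
  if (length(unmapped) > 0) {
    abort(paste0("test(s) absent from domain_map: ", paste(unmapped, collapse = ", ")))
  }

  ref <- cognition |> filter(.data$subject_id %in% reference_ids)
  missing_ref <- ref |>
    group_by(.data$test_id) |>
    summarise(n_ref = dplyr::n(), .groups = "drop") |>
    filter(.data$n_ref < length(reference_ids))
  if (nrow(missing_ref) > 0) {
    inform(paste0("reference subjects missing for test(s) ",
                  paste(missing_ref$test_id, collapse = ", "),
                  "; reference statistics use available reference subjects only"))
  }

  ref_stats <- ref |>
    group_by(.data$test_id) |>
    summarise(ref_mean = mean(.data$raw_score),
              ref_sd = stats::sd(.data$raw_score),
              n_ref = dplyr::n(), .groups = "drop")
  no_ref <- setdiff(unique(cognition$test_id), ref_stats$test_id)
  if (length(no_ref) > 0) {
    abort(paste0("no reference observations for test(s): ",
                 paste(no_ref, collapse = ", ")))
  }
  too_few <- ref_stats$test_id[ref_stats$n_ref < 2]
  if (length(too_few) > 0) {
    abort(paste0("fewer than 2 reference observations for test(s): ",
                 paste(too_few, collapse = ", ")))
  }
  degenerate <- ref_stats$test_id[ref_stats$ref_sd == 0 | !is.finite(ref_stats$ref_sd)]
  if (length(degenerate) > 0) {
    abort(paste0("zero reference-group SD for test(s): ",
                 paste(degenerate, collapse = ", ")))
  }

  cognition |>
    left_join(ref_stats, by = "test_id") |>
    left_join(domain_map, by = "test_id") |>
    mutate(z = (.data$raw_score - .data$ref_mean) / .data$ref_sd,
           z = ifelse(.data$invert, -.data$z, .data$z)) |>
    select("subject_id", "test_id", "domain", "z")
}

#' Composite cognitive domain scores and global cognition
#'
#' Averages a subject's test z-scores within each cognitive domain into a
#' composite score, and the four domain composites into a global cognition
#' score. Missing tests are simply omitted from the domain mean (no
#' imputation); a subject with no test in a domain gets `NA` for that domain
#' and for the global score.
#'
#' @param ztable Output of [zscore_tests()]: columns `subject_id`, `test_id`,
#'   `domain`, `z`.
#' @return A tibble with one row per subject and columns `subject_id`,
#'   `memory`, `attention`, `executive`, `visuospatial`, `global`.
#' @examples
#' zt <- tibble::tibble(
#'   subject_id = "s1",
#'   test_id = c("a", "b"),
#'   domain = c("attention", "attention"),
#'   z = c(1, -0.5)
#' )
#' # attention composite = 0.25; other domains NA
#' composite_scores(zt)
#' @export
composite_scores <- function(ztable) {
  stopifnot(is.data.frame(ztable))
  if (!all(c("subject_id", "domain", "z") %in% names(ztable))) {
    abort("ztable needs columns subject_id, domain, z (from zscore_tests)")
  }
  if (all(is.na(ztable$z))) abort("no defined z-scores in any domain")

  wide <- ztable |>
    group_by(.data$subject_id, .data$domain) |>
    summarise(composite = mean(.data$z, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "domain", values_from = "composite")
  for (d in setdiff(cognition_domains(), names(wide))) wide[[d]] <- NA_real_
  wide <- wide[, c("subject_id", cognition_domains())]

  all_missing <- apply(is.na(wide[, cognition_domains()]), 1, all)
  if (any(all_missing)) {
    abort(paste0("subject(s) with no test in any domain: ",
                 paste(wide$subject_id[all_missing], collapse = ", ")))
  }
  wide$global <- rowMeans(wide[, cognition_domains()])
  as_tibble(wide)
}

#' Read a long-format cognition table from TSV
#'
#' @param path TSV file with columns `subject_id`, `test_id`, `raw_score`.
#' @return A tibble.
#' @export
read_cognition_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    test_id = readr::col_character(),
    raw_score = readr::col_double()
  ))
}
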