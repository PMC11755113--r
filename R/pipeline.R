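# Run orchestration: derive all patterns for a cohort, persist artifacts
# with a manifest, and summarize a completed run directory.

#' Run configuration
#'
#' Collects the tunable thresholds of the pipeline with their standard
#' defaults: 3% fractional-maximum subject masks, 90% cumulative variance
#' for component selection, bidirectional stepwise BIC selection, 5000
#' bootstrap replicates, and the default test battery map.
#'
#' @param mask_fraction Subject-mask threshold as a fraction of the volume
#'   maximum.
#' @param variance_target Cumulative variance fraction for component
#'   selection.
#' @param direction Stepwise direction (`"both"` or `"forward"`).
#' @param n_boot Bootstrap replicate count.
#' @param seed Global integer seed; stages derive named sub-streams from it.
#' @param reference Control-group label.
#' @param domain_map Test-to-domain map (see [default_domain_map()]).
#' @return A `covpattern_config` list.
#' @export
covpattern_config <- function(mask_fraction = 0.03, variance_target = 0.90,
                              direction = "both", n_boot = 5000, seed = 1L,
                              reference = "HC", domain_map = default_domain_map()) {
  structure(
    list(mask_fraction = mask_fraction, variance_target = variance_target,
         direction = direction, n_boot = as.integer(n_boot),
         seed = as.integer(seed), reference = reference,
         domain_map = domain_map),
    class = "covpattern_config"
  )
}

write_pattern_artifacts <- function(fit, name, out_dir) {
  stem <- file.path(out_dir, name)
  files <- character(0)
  if (!is.null(fit$pattern)) {
    write_masked_nifti(fit$pattern$weights, fit$mask, paste0(stem, "_pattern.nii.gz"))
    files <- c(files, paste0(name, "_pattern.nii.gz"))
    readr::write_tsv(fit$scores, paste0(stem, "_scores.tsv"))
    files <- c(files, paste0(name, "_scores.tsv"))
  }
  sidecar <- list(
    target = fit$target,
    family = fit$model$family,
    included_components = fit$model$included,
    coefficients = as.list(fit$model$coefficients),
    intercept = fit$model$intercept,
    bic = fit$model$bic,
    total_variance_selected = fit$model$total_variance_selected,
    n_components_basis = fit$basis$n_selected,
    variance_explained_basis = sum(fit$basis$variance_fraction[seq_len(fit$basis$n_selected)]),
    empty_model = length(fit$model$included) == 0
  )
  jsonlite::write_json(sidecar, paste0(stem, "_model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(files, paste0(name, "_model.json"))
}

#' Derive all patterns for a cohort and persist the run
#'
#' Executes the full identification pipeline: the disease pattern on all
#' subjects (stepwise logistic regression of group on component scores) and,
#' when a cognition table is supplied, one pattern per cognitive domain plus
#' global cognition (patient-group decomposition, stepwise linear
#' regression). Writes patterns (NIfTI + JSON sidecar), subject scores
#' (TSV), composite scores, the common mask, and a manifest binding the
#' configuration to every output file.
#'
#' @param vols Named list of 3-D uptake arrays.
#' @param labels Tibble `subject_id`, `group`.
#' @param out_dir Output directory (created if needed).
#' @param cognition Optional long-format cognition table (`subject_id`,
#'   `test_id`, `raw_score`).
#' @param config A [covpattern_config()].
#' @param targets Cognition targets to derive when `cognition` is given.
#' @return Invisibly, a list of the `pattern_fit` objects keyed by target,
#'   with the manifest path as attribute `manifest`.
#' @export
run_derive <- function(vols, labels, out_dir, cognition = NULL,
                       config = covpattern_config(),
                       targets = c(cognition_domains(), "global")) {
  stopifnot(inherits(config, "covpattern_config"))
  if (is.null(cognition) && length(targets) > 0 && !is.null(attr(targets, "explicit"))) {
    abort("cognition targets requested but no cognition table supplied")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  fits <- list()
  disease <- derive_disease_pattern(vols, labels,
                                    mask_fraction = config$mask_fraction,
                                    variance_target = config$variance_target,
                                    direction = config$direction,
                                    reference = config$reference)
  fits$disease <- disease
  write_masked_nifti(disease$mask, disease$mask, file.path(out_dir, "common_mask.nii.gz"))
  files <- c(files, "common_mask.nii.gz")
  files <- c(files, write_pattern_artifacts(disease, "disease", out_dir))

  if (!is.null(cognition)) {
    hc <- hc_ids_of(labels, config$reference)
    ztab <- zscore_tests(cognition, hc, domain_map = config$domain_map)
    composites <- composite_scores(ztab)
    readr::write_tsv(composites, file.path(out_dir, "composites.tsv"))
    files <- c(files, "composites.tsv")
    for (target in targets) {
      fit <- derive_cognition_pattern(vols, labels, composites, target,
                                      mask_fraction = config$mask_fraction,
                                      variance_target = config$variance_target,
                                      direction = config$direction,
                                      reference = config$reference)
      fits[[target]] <- fit
      files <- c(files, write_pattern_artifacts(fit, target, out_dir))
    }
  }

  manifest <- list(
    package = "covpattern",
    version = as.character(utils::packageVersion("covpattern")),
    config = list(mask_fraction = config$mask_fraction,
                  variance_target = config$variance_target,
                  direction = config$direction,
                  n_boot = config$n_boot, seed = config$seed,
                  reference = config$reference),
    domain_map = config$domain_map,
    subjects = labels,
    targets = names(fits),
    files = files
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(fits, "manifest") <- manifest_path
  invisible(fits)
}

#' Summarize a completed run directory
#'
#' Tabulates, per derived target, the selected components, total variance
#' selected, cross-validation statistics (when a `<target>_crossval.json`
#' exists) and stable-voxel counts (when a `<target>_bootstrap.json`
#' exists). Absent validation artifacts are reported as `NA`, not errors.
#'
#' @param results_dir A directory written by [run_derive()] (and optionally
#'   augmented by the cross-validation / bootstrap commands).
#' @return A tibble with one row per target.
#' @export
run_report <- function(results_dir) {
  manifest_path <- file.path(results_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(paste0("incomplete run: missing ", manifest_path))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  missing <- manifest$files[!file.exists(file.path(results_dir, manifest$files))]
  if (length(missing) > 0) {
    abort(paste0("incomplete run: missing artifact(s) ",
                 paste(missing, collapse = ", ")))
  }
  rows <- purrr::map(manifest$targets, function(target) {
    model <- jsonlite::read_json(file.path(results_dir, paste0(target, "_model.json")),
                                 simplifyVector = TRUE)
    row <- tibble(
      target = target,
      family = model$family,
      n_components = length(model$included_components),
      total_variance_selected = model$total_variance_selected %||% NA_real_,
      bic = model$bic,
      t = NA_real_, p = NA_real_, auc = NA_real_,
      sensitivity = NA_real_, specificity = NA_real_, r = NA_real_,
      n_stable_voxels = NA_integer_
    )
    cv_path <- file.path(results_dir, paste0(target, "_crossval.json"))
    if (file.exists(cv_path)) {
      cv <- jsonlite::read_json(cv_path, simplifyVector = TRUE)
      for (f in c("t", "p", "auc", "sensitivity", "specificity", "r")) {
        if (!is.null(cv[[f]])) row[[f]] <- cv[[f]]
      }
    }
    bs_path <- file.path(results_dir, paste0(target, "_bootstrap.json"))
    if (file.exists(bs_path)) {
      bs <- jsonlite::read_json(bs_path, simplifyVector = TRUE)
      row$n_stable_voxels <- bs$n_stable %||% NA_integer_
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Write a phantom cohort to disk
#'
#' Writes NIfTI volumes, a labels TSV, the cognition TSV, and ground-truth
#' pattern NIfTIs plus a JSON summary, in the layout the CLI and
#' [run_derive()] read back.
#'
#' @param cohort A `phantom_cohort` from [make_phantom_cohort()].
#' @param out_dir Output directory.
#' @return The directory, invisibly.
#' @export
write_phantom_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(file.path(out_dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$volumes)) {
    RNifti::writeNifti(RNifti::asNifti(cohort$volumes[[id]]),
                       file.path(out_dir, "volumes", paste0(id, ".nii.gz")))
  }
  readr::write_tsv(cohort$labels, file.path(out_dir, "labels.tsv"))
  readr::write_tsv(cohort$cognition, file.path(out_dir, "cognition.tsv"))
  gt <- cohort$ground_truth
  RNifti::writeNifti(RNifti::asNifti(gt$disease_pattern),
                     file.path(out_dir, "truth_disease_pattern.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(gt$cog_pattern),
                     file.path(out_dir, "truth_cog_pattern.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(gt$support * 1),
                     file.path(out_dir, "truth_support.nii.gz"))
  jsonlite::write_json(
    list(spec = unclass(gt$spec), lambda = gt$lambda, abilities = gt$abilities),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
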