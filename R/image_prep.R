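#' Threshold mask for one subject's uptake volume
#'
#' Builds the per-subject analysis mask: all voxels whose uptake is at least
#' `fraction` of the volume's maximum (inclusive at the threshold). With the
#' default 3% fraction this retains cortical gray matter in typical SUVr
#' images while excluding background.
#'
#' @param vol 3-D numeric array of strictly positive uptake values (SUVr).
#' @param fraction Threshold as a fraction of the volume maximum (default 0.03).
#' @return Logical array of the same shape.
#' @export
build_subject_mask <- function(vol, fraction = 0.03) {
  stopifnot(is.array(vol), length(dim(vol)) == 3L,
            is.numeric(fraction), length(fraction) == 1L, fraction >= 0)
  if (any(!is.finite(vol))) abort("volume contains non-finite values")
  mx <- max(vol)
  if (!is.finite(mx) || mx <= 0) abort("volume maximum is not positive")
  vol >= fraction * mx
}

#' Intersect subject masks into the common analysis mask
#'
#' @param masks List of logical arrays on the same grid (per-subject masks).
#' @return Logical array: voxels present in every subject's mask.
#' @export
build_common_mask <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  dims <- lapply(masks, dim)
  if (!all(vapply(dims, identical, logical(1), y = dims[[1]]))) {
    abort("masks are not all on the same grid")
  }
  common <- Reduce(`&`, masks)
  if (!any(common)) abort("common mask is empty: no voxel is present in every subject mask")
  common
}

#' Deterministic voxel index of a mask
#'
#' Maps masked voxels to vector positions in R's native (column-major) array
#' order; the ordering is identical for every subject in a run.
#'
#' @param mask Logical 3-D array.
#' @return Integer vector of linear voxel indices.
#' @export
mask_index <- function(mask) {
  stopifnot(is.logical(mask))
  which(mask)
}

#' Vectorize a volume over a mask / restore a vector into a volume
#'
#' `vectorize_volume()` extracts masked voxel values in the deterministic
#' order of [mask_index()]; `unvectorize()` writes such a vector back into a
#' full-grid array (zero outside the mask). Round-tripping reproduces the
#' masked values exactly.
#'
#' @param vol 3-D numeric array.
#' @param mask Logical array of the same shape.
#' @param values Numeric vector of length `sum(mask)`.
#' @return `vectorize_volume()`: numeric vector; `unvectorize()`: 3-D array.
#' @export
vectorize_volume <- function(vol, mask) {
  stopifnot(identical(dim(vol), dim(mask)))
  vol[mask_index(mask)]
}

#' @rdname vectorize_volume
#' @export
unvectorize <- function(values, mask) {
  stopifnot(length(values) == sum(mask))
  out <- array(0, dim = dim(mask))
  out[mask_index(mask)] <- values
  out
}

#' Log-transformed uptake matrix over the common mask
#'
#' Extracts every subject's uptake within the common mask and natural-log
#' transforms it, giving the subjects-by-voxels matrix the scaled subprofile
#' model decomposes. Non-positive values inside the mask are an error at
#' training time (no silent clamping): they indicate the mask and the data
#' disagree.
#'
#' @param vols Named list of 3-D numeric arrays (names are subject ids).
#' @param mask Logical array: the common mask.
#' @return Numeric matrix, subjects (rows, named) x masked voxels (columns).
#' @export
extract_log_matrix <- function(vols, mask) {
  stopifnot(is.list(vols), length(vols) >= 1L)
  if (is.null(names(vols)) || anyDuplicated(names(vols))) {
    abort("vols must be a named list with unique subject ids")
  }
  idx <- mask_index(mask)
  out <- matrix(NA_real_, nrow = length(vols), ncol = length(idx),
                dimnames = list(names(vols), NULL))
  for (i in seq_along(vols)) {
    v <- vols[[i]]
    if (!identical(dim(v), dim(mask))) {
      abort(paste0("volume for subject ", names(vols)[i], " is not on the mask grid"))
    }
    x <- v[idx]
    bad <- which(x <= 0 | !is.finite(x))
    if (length(bad) > 0) {
      abort(paste0("non-positive uptake inside mask for subject ",
                   names(vols)[i], " at masked voxel ", bad[1],
                   " (grid index ", idx[bad[1]], ")"))
    }
    out[i, ] <- log(x)
  }
  out
}

#' Reference-group mean profile of log uptake
#'
#' Voxelwise arithmetic mean of the log-transformed images of the reference
#' (healthy-control) subjects; the profile every subject residual profile is
#' measured against.
#'
#' @param logmat Subjects x voxels log-uptake matrix from [extract_log_matrix()].
#' @param reference_ids Subject ids (row names of `logmat`) of the reference group.
#' @return Numeric vector of length `ncol(logmat)` with attribute
#'   `reference_ids`.
#' @export
group_mean_profile <- function(logmat, reference_ids) {
  stopifnot(is.matrix(logmat))
  if (length(reference_ids) == 0) abort("reference_ids must be non-empty")
  missing <- setdiff(reference_ids, rownames(logmat))
  if (length(missing) > 0) {
    abort(paste0("reference id(s) not in matrix: ", paste(missing, collapse = ", ")))
  }
  profile <- colMeans(logmat[reference_ids, , drop = FALSE])
  attr(profile, "reference_ids") <- reference_ids
  profile
}

#' Subject residual profiles (SRP)
#'
#' Subtracts the reference-group mean profile from each subject's
#' log-uptake row. No further row or column demeaning is applied: uptake
#' normalization happened upstream in the SUVr calculation, and the only
#' centering in the model is against the reference profile.
#'
#' @param logmat Subjects x voxels log-uptake matrix.
#' @param profile Reference profile from [group_mean_profile()].
#' @param mask Optional logical array recording the common mask the matrix
#'   was extracted on (carried as metadata).
#' @return An `srp_matrix` object: list with `srp` (subjects x voxels
#'   matrix), `subject_ids`, `profile`, `reference_ids`, `mask`.
#' @export
compute_srp <- function(logmat, profile, mask = NULL) {
  stopifnot(is.matrix(logmat))
  if (length(profile) != ncol(logmat)) {
    abort("profile length does not match number of masked voxels")
  }
  srp <- sweep(logmat, 2L, as.numeric(profile), `-`)
  structure(
    list(
      srp = srp,
      subject_ids = rownames(logmat),
      profile = as.numeric(profile),
      reference_ids = attr(profile, "reference_ids"),
      mask = mask
    ),
    class = "srp_matrix"
  )
}

#' @export
print.srp_matrix <- function(x, ...) {
  cat("<srp_matrix> ", nrow(x$srp), " subjects x ", ncol(x$srp),
      " masked voxels\n", sep = "")
  if (!is.null(x$reference_ids)) {
    cat("  reference group: ", length(x$reference_ids), " subjects\n", sep = "")
  }
  invisible(x)
}

#' Read SUVr volumes from NIfTI files
#'
#' @param paths Character vector of NIfTI file paths; names (or file stems)
#'   become subject ids.
#' @return Named list of 3-D arrays; all volumes must share grid shape.
#' @export
read_suvr_volumes <- function(paths) {
  ids <- names(paths) %||% sub("\\.nii(\\.gz)?$", "", basename(paths))
  vols <- lapply(paths, function(p) {
    v <- RNifti::readNifti(p)
    array(as.numeric(v), dim = dim(v))
  })
  names(vols) <- ids
  dims <- lapply(vols, dim)
  if (!all(vapply(dims, identical, logical(1), y = dims[[1]]))) {
    abort("volumes do not share a common grid shape")
  }
  vols
}

#' Write a masked voxel-weight vector as a NIfTI volume
#'
#' @param values Numeric vector over masked voxels (or a logical/numeric array).
#' @param mask Logical array defining the grid and voxel order.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_masked_nifti <- function(values, mask, path) {
  vol <- if (is.array(values) && identical(dim(values), dim(mask))) {
    values * 1.0
  } else {
    unvectorize(as.numeric(values), mask)
  }
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
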