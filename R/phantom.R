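# Synthetic phantom cohorts with known embedded covariance patterns.
#
# Effects are embedded additively in log-uptake space so the pipeline's log
# transform linearizes them exactly and ground truth is directly comparable
# to derived patterns. Background voxels sit near (not exactly at) zero so
# the fractional-maximum mask rule is exercised without log-domain errors.

run_with_seed <- function(seed, code) {
  env <- globalenv()
  has_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = env)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# separable truncated-Gaussian smoothing along the three array axes
smooth_kernel_matrix <- function(n, sigma) {
  i <- seq_len(n)
  K <- outer(i, i, function(a, b) {
    d <- abs(a - b)
    ifelse(d <= ceiling(3 * sigma), exp(-d^2 / (2 * sigma^2)), 0)
  })
  K / rowSums(K)
}

smooth_volume <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  for (axis in 1:3) {
    K <- smooth_kernel_matrix(d[axis], sigma)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(vol, perm)
    da <- dim(a)
    a <- array(K %*% matrix(a, nrow = da[1]), dim = da)
    vol <- aperm(a, order(perm))
  }
  vol
}

# truncated Gaussian blob on the grid, zero beyond `trunc` SDs; the default
# truncation keeps patterns focal (boundary weight ~20% of peak), so a
# pattern's support contains only voxels carrying a non-negligible effect
blob <- function(dim, center, sigma, trunc = 1.8) {
  g <- array(0, dim = dim)
  coords <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
  d2 <- (coords$x - center[1])^2 + (coords$y - center[2])^2 + (coords$z - center[3])^2
  v <- exp(-d2 / (2 * sigma^2))
  v[d2 > (trunc * sigma)^2] <- 0
  g[] <- v
  g
}

#' Specification of a synthetic phantom cohort
#'
#' Defines the generative model for a two-group phantom cohort of uptake
#' volumes with embedded covariance structure: a spatially structured
#' disease-difference pattern `D` added to patient log-uptake, one
#' cognition-linked pattern `C` expressed with per-subject loadings
#' `lambda ~ N(0, tau^2)` in every subject, spatially smoothed voxel noise,
#' and a neuropsychological test table whose scores are driven by latent
#' domain abilities tied to those loadings.
#'
#' Generated log-uptake is
#' `baseline(v) + delta * 1[PD] * D(v) + lambda_i * C(v) + noise_i(v)`
#' inside an ellipsoidal brain-shaped support, with near-zero uptake outside,
#' and volumes are its exponential (hence strictly positive).
#'
#' @param dim Grid shape (default `c(32, 32, 32)`).
#' @param n_hc,n_pd Group sizes (defaults 10 healthy controls, 34 patients).
#' @param support_radius Ellipsoid semi-axes as a fraction of the half-extent
#'   of the grid (default 0.8).
#' @param baseline_max Peak uptake (SUVr units) at the support center.
#' @param baseline_gradient Fractional radial falloff of log baseline.
#' @param background_uptake Uptake outside the support (well below any
#'   fractional-maximum mask threshold).
#' @param delta Disease effect size in log-uptake units applied along `D` to
#'   patients (default 0.2).
#' @param severity_sd SD of the per-patient multiplicative severity factor
#'   on the disease effect (`delta * s_i`, `s_i ~ N(1, severity_sd^2)`),
#'   emulating the heterogeneous disease stage of a real patient group.
#' @param tau SDs of the per-subject loadings on the latent covariance
#'   patterns, one per pattern (scalar values are recycled). The first
#'   pattern is the cognition-linked one; the rest are nuisance networks
#'   that give the cohort the multi-component covariance structure real
#'   data has.
#' @param sigma Voxel noise SD in log-uptake units, before smoothing.
#' @param smooth_sigma Gaussian smoothing width (voxels) applied to the noise
#'   field for spatial correlation.
#' @param orthogonal_cog Orthogonalize the latent patterns against the
#'   disease pattern and each other within the support (default `TRUE`).
#' @param cog_slope Slope linking the first pattern's loading to latent
#'   domain ability (`ability = cog_slope * lambda_1 + noise`); 0 decouples
#'   cognition from uptake.
#' @param cog_noise_sd SD of the per-subject, per-domain ability noise.
#' @param test_noise_sd SD of per-test measurement noise around the ability.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(32L, 32L, 32L), n_hc = 10L, n_pd = 34L,
                         support_radius = 0.8, baseline_max = 4,
                         baseline_gradient = 0.25, background_uptake = 0.02,
                         delta = 0.2, severity_sd = 0.3,
                         tau = c(0.15, 0.12, 0.10), sigma = 0.02,
                         smooth_sigma = 1, orthogonal_cog = TRUE,
                         cog_slope = 10, cog_noise_sd = 0.5,
                         test_noise_sd = 0.3, seed = 1L) {
  stopifnot(length(dim) == 3L, all(dim >= 8L), n_hc >= 0, n_pd >= 0,
            sigma >= 0, all(tau >= 0), length(tau) >= 1,
            support_radius > 0, support_radius <= 1,
            baseline_max > 0, background_uptake > 0)
  if (length(tau) == 1L) tau <- rep(tau, 3L)
  stopifnot(severity_sd >= 0)
  structure(
    list(dim = as.integer(dim), n_hc = as.integer(n_hc), n_pd = as.integer(n_pd),
         support_radius = support_radius, baseline_max = baseline_max,
         baseline_gradient = baseline_gradient,
         background_uptake = background_uptake, delta = delta,
         severity_sd = severity_sd, tau = tau,
         sigma = sigma, smooth_sigma = smooth_sigma,
         orthogonal_cog = orthogonal_cog, cog_slope = cog_slope,
         cog_noise_sd = cog_noise_sd, test_noise_sd = test_noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

phantom_geometry <- function(spec) {
  d <- spec$dim
  center <- (d + 1) / 2
  semi <- spec$support_radius * (d / 2 - 1)
  coords <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r2 <- ((coords$x - center[1]) / semi[1])^2 +
    ((coords$y - center[2]) / semi[2])^2 +
    ((coords$z - center[3]) / semi[3])^2
  support <- array(r2 <= 1, dim = d)
  r2a <- array(pmin(r2, 1), dim = d)

  baseline <- array(log(spec$background_uptake), dim = d)
  baseline[support] <- log(spec$baseline_max) * (1 - spec$baseline_gradient * r2a[support])

  # disease pattern: posterior deficit blob + smaller anterior increase
  D <- -1.0 * blob(d, center + c(-0.35, -0.15, 0) * semi, sigma = 0.22 * min(semi)) +
    0.6 * blob(d, center + c(0.40, 0.25, 0.1) * semi, sigma = 0.16 * min(semi))
  D[!support] <- 0
  D <- D / sqrt(sum(D^2))

  # latent covariance patterns: the first is cognition-linked, the rest are
  # nuisance networks; orthogonalized (Gram-Schmidt) against D and each other
  raw <- list(
    blob(d, center + c(0, 0.40, -0.30) * semi, sigma = 0.20 * min(semi)) -
      0.8 * blob(d, center + c(0.15, -0.45, 0.35) * semi, sigma = 0.16 * min(semi)),
    blob(d, center + c(-0.30, 0.30, 0.30) * semi, sigma = 0.18 * min(semi)) -
      0.7 * blob(d, center + c(0.35, 0.05, -0.35) * semi, sigma = 0.15 * min(semi)),
    blob(d, center + c(0.05, -0.10, -0.45) * semi, sigma = 0.17 * min(semi)) -
      0.9 * blob(d, center + c(-0.40, -0.30, 0.05) * semi, sigma = 0.14 * min(semi))
  )
  n_pat <- length(spec$tau)
  C <- vector("list", n_pat)
  prev <- list(D)
  for (k in seq_len(n_pat)) {
    ck <- raw[[((k - 1) %% length(raw)) + 1]]
    ck[!support] <- 0
    if (spec$orthogonal_cog) {
      for (q in prev) ck <- ck - sum(ck * q) * q
    }
    ck <- ck / sqrt(sum(ck^2))
    C[[k]] <- ck
    prev <- c(prev, list(ck))
  }

  list(support = support, baseline = baseline, D = D, C = C)
}

#' Generate a synthetic phantom cohort
#'
#' Draws a full cohort from a [phantom_spec()]: strictly positive uptake
#' volumes with the embedded disease and cognition patterns, group labels,
#' a long-format neuropsychological test table, and the generating ground
#' truth (patterns, loadings, latent domain abilities).
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_cohort` list: `volumes` (named list of 3-D arrays),
#'   `labels` (tibble `subject_id`, `group`), `cognition` (tibble
#'   `subject_id`, `test_id`, `raw_score`), and `ground_truth` (support mask,
#'   baseline, `disease_pattern`, `cog_pattern`, `lambda`, `abilities`
#'   tibble, and the spec).
#' @examples
#' ph <- make_phantom_cohort(phantom_spec(dim = c(12, 12, 12), n_hc = 3,
#'                                        n_pd = 4, seed = 7))
#' length(ph$volumes)
#' @export
make_phantom_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  d <- spec$dim
  n <- spec$n_hc + spec$n_pd
  if (n == 0) abort("empty cohort: n_hc + n_pd must be positive")

  ids <- c(sprintf("hc%02d", seq_len(spec$n_hc)), sprintf("pd%02d", seq_len(spec$n_pd)))
  group <- factor(rep(c("HC", "PD"), c(spec$n_hc, spec$n_pd)), levels = c("HC", "PD"))
  domains <- cognition_domains()
  dmap <- default_domain_map()

  n_pat <- length(spec$tau)
  run_with_seed(spec$seed, {
    lambda <- sapply(seq_len(n_pat), function(k) rnorm(n, 0, spec$tau[k]))
    lambda <- matrix(lambda, nrow = n, ncol = n_pat,
                     dimnames = list(ids, paste0("lambda", seq_len(n_pat))))
    severity <- ifelse(group == "PD", rnorm(n, 1, spec$severity_sd), 0)
    volumes <- vector("list", n)
    names(volumes) <- ids
    for (i in seq_len(n)) {
      logv <- geo$baseline
      for (k in seq_len(n_pat)) logv <- logv + lambda[i, k] * geo$C[[k]]
      if (group[i] == "PD") logv <- logv + spec$delta * severity[i] * geo$D
      if (spec$sigma > 0) {
        noise <- smooth_volume(array(rnorm(prod(d), 0, spec$sigma), dim = d),
                               spec$smooth_sigma)
        logv <- logv + noise
      }
      volumes[[i]] <- exp(logv)
    }

    # latent domain abilities tied to the first (cognition-linked) loading
    abilities <- matrix(NA_real_, n, length(domains),
                        dimnames = list(ids, domains))
    for (k in seq_along(domains)) {
      abilities[, k] <- spec$cog_slope * lambda[, 1] + rnorm(n, 0, spec$cog_noise_sd)
    }

    # raw test scores: per-test affine transform of ability + test noise;
    # inverted tests are time-like (higher raw = worse)
    cog_rows <- purrr::map(seq_len(nrow(dmap)), function(t) {
      test <- dmap$test_id[t]
      dom <- dmap$domain[t]
      mu <- 20 + 5 * t
      sc <- 3 + 0.5 * t
      g <- unname(abilities[, dom]) + rnorm(n, 0, spec$test_noise_sd)
      raw <- if (dmap$invert[t]) mu - sc * g else mu + sc * g
      tibble(subject_id = ids, test_id = test, raw_score = raw)
    })
    cognition <- dplyr::bind_rows(cog_rows) |> arrange(.data$subject_id, .data$test_id)

    structure(
      list(
        volumes = volumes,
        labels = tibble(subject_id = ids, group = group),
        cognition = cognition,
        ground_truth = list(
          support = geo$support,
          baseline = geo$baseline,
          disease_pattern = geo$D,
          cog_pattern = geo$C[[1]],
          latent_patterns = geo$C,
          lambda = as_tibble(cbind(tibble(subject_id = ids),
                                   as.data.frame(lambda))),
          severity = tibble(subject_id = ids, severity = severity),
          abilities = as_tibble(cbind(tibble(subject_id = ids),
                                      as.data.frame(abilities))),
          spec = spec
        )
      ),
      class = "phantom_cohort"
    )
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", length(x$volumes), " volumes (",
      sum(x$labels$group == "HC"), " HC / ", sum(x$labels$group == "PD"),
      " PD) on a ", paste(dim(x$volumes[[1]]), collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Small low-rank test matrix with known singular structure
#'
#' Builds a reproducible subjects-by-voxels matrix as a sum of `rank` outer
#' products with singular values `4 * rank, 4 * (rank - 1), ..., 4`, plus
#' optional white noise. Used as a controlled fixture for decomposition
#' tests.
#'
#' @param n_subjects,n_voxels Matrix shape.
#' @param rank Number of non-zero singular values; at most
#'   `min(n_subjects, n_voxels)`.
#' @param seed Integer seed.
#' @param noise_sd SD of added white noise (default 0).
#' @return A matrix with attributes `u`, `d`, `v` holding the generating
#'   singular structure.
#' @export
make_toy_matrix <- function(n_subjects, n_voxels, rank, seed = 1L, noise_sd = 0) {
  if (rank < 1 || rank > min(n_subjects, n_voxels)) {
    abort("rank must be between 1 and min(n_subjects, n_voxels)")
  }
  run_with_seed(seed, {
    u <- qr.Q(qr(matrix(rnorm(n_subjects * rank), n_subjects, rank)))
    v <- qr.Q(qr(matrix(rnorm(n_voxels * rank), n_voxels, rank)))
    dvals <- 4 * (rank:1)
    m <- u %*% (dvals * t(v))
    if (noise_sd > 0) m <- m + matrix(rnorm(n_subjects * n_voxels, 0, noise_sd),
                                      n_subjects, n_voxels)
    rownames(m) <- sprintf("s%02d", seq_len(n_subjects))
    attr(m, "u") <- u
    attr(m, "d") <- dvals
    attr(m, "v") <- v
    m
  })
}
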