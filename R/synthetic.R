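#' Specification of a synthetic resting-state study
#'
#' Describes the shape and statistical structure of a synthetic
#' multi-subject dataset: a modular population correlation matrix (strong
#' positive blocks, designated anticorrelated block pairs, a weak positive
#' background elsewhere) from which per-subject region-by-time panels are
#' drawn. Defaults emulate a 30-subject study with 230 retained timepoints
#' over 105 regions whose full-density absolute thresholding yields roughly
#' 70 percent positive and 30 percent negative links.
#'
#' @param n_subjects,n_timepoints,n_regions study shape.
#' @param n_modules number of positive modules (regions split as evenly as
#'   possible).
#' @param within_module_corr correlation inside a module, in `(0, 1)`.
#' @param between_module_corr correlation across anticorrelated module
#'   pairs, in `(-1, 0]`.
#' @param background_corr weak positive correlation across the remaining
#'   module pairs (a global-signal-like floor that keeps unstructured pairs
#'   on the positive side, as in resting-state BOLD).
#' @param anticorrelated_pairs list of 2-vectors of module indices that
#'   anticorrelate; the default 4 pairs over 5 modules place about 32
#'   percent of region pairs on the negative side.
#' @param subject_noise_sd sd of the symmetric perturbation applied to the
#'   population matrix per subject (individual variability).
#' @param seed integer seed.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_subjects = 30L, n_timepoints = 230L,
                         n_regions = 105L, n_modules = 5L,
                         within_module_corr = 0.6,
                         between_module_corr = -0.3,
                         background_corr = 0.15,
                         anticorrelated_pairs = list(c(1, 2), c(3, 4),
                                                     c(2, 5), c(1, 4)),
                         subject_noise_sd = 0.05, seed = 1L) {
  stopifnot(n_subjects >= 1, n_timepoints >= 3, n_regions >= 2,
            n_modules >= 1, n_modules <= n_regions,
            within_module_corr > 0, within_module_corr < 1,
            between_module_corr <= 0, between_module_corr > -1,
            subject_noise_sd >= 0)
  for (p in anticorrelated_pairs)
    stopifnot(length(p) == 2L, all(p %in% seq_len(n_modules)), p[1] != p[2])
  structure(list(n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 n_regions = as.integer(n_regions),
                 n_modules = as.integer(n_modules),
                 within_module_corr = within_module_corr,
                 between_module_corr = between_module_corr,
                 background_corr = background_corr,
                 anticorrelated_pairs = anticorrelated_pairs,
                 subject_noise_sd = subject_noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

module_assignment <- function(spec) {
  sizes <- rep(spec$n_regions %/% spec$n_modules, spec$n_modules)
  extra <- spec$n_regions %% spec$n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(spec$n_modules), sizes)
}

# Eigenvalue-clipping repair to the nearest correlation-like PSD matrix:
# clip negative eigenvalues, rebuild, rescale to unit diagonal.
nearest_psd_corr <- function(R, eps = 1e-8) {
  ed <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(ed$values) >= -eps) return(R)
  v <- pmax(ed$values, eps)
  M <- ed$vectors %*% (v * t(ed$vectors))
  D <- 1 / sqrt(diag(M))
  M <- M * tcrossprod(D)
  (M + t(M)) / 2
}

#' Population connectivity of a fixture spec
#'
#' Builds the block-structured population correlation matrix:
#' `within_module_corr` inside modules, `between_module_corr` across the
#' designated anticorrelated module pairs, `background_corr` elsewhere, with
#' unit diagonal. Positive semi-definiteness is checked; a repairable
#' violation triggers an eigenvalue-clipping fix with a message, and an
#' irreparable spec errors with the offending eigenvalue.
#'
#' @param spec a [fixture_spec()].
#' @return a [conn_matrix()] with a `modules` attribute (region-to-module
#'   assignment).
#' @export
make_population_connectivity <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  mod <- module_assignment(spec)
  n <- spec$n_regions
  R <- matrix(spec$background_corr, n, n)
  for (m in seq_len(spec$n_modules))
    R[mod == m, mod == m] <- spec$within_module_corr
  for (p in spec$anticorrelated_pairs) {
    R[mod == p[1], mod == p[2]] <- spec$between_module_corr
    R[mod == p[2], mod == p[1]] <- spec$between_module_corr
  }
  diag(R) <- 1
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    if (ev_min < -0.1)
      stop("population matrix is far from PSD (min eigenvalue ",
           format(ev_min), "); adjust the spec")
    message("population matrix slightly non-PSD (min eigenvalue ",
            format(ev_min), "); applying eigenvalue-clipping repair")
    R <- nearest_psd_corr(R)
  }
  out <- conn_matrix(R, paste0("R", seq_len(n)))
  attr(out, "modules") <- mod
  out
}

# Draw T x n zero-mean Gaussian rows with covariance Sigma via eigen
# factorization (tolerates the semi-definite case, unlike chol).
rmvnorm_eigen <- function(T, Sigma) {
  ed <- eigen(Sigma, symmetric = TRUE)
  v <- pmax(ed$values, 0)
  Z <- matrix(stats::rnorm(T * ncol(Sigma)), T)
  Z %*% (t(ed$vectors) * sqrt(v))
}

#' Sample per-subject panels from a population matrix
#'
#' Each subject's panel is drawn from a zero-mean multivariate normal whose
#' correlation is the population matrix perturbed (off-diagonal) by
#' symmetric Gaussian noise of sd `subject_noise_sd`, clipped to
#' `[-0.99, 0.99]` and PSD-repaired when needed. Fully seeded: the same
#' spec reproduces the same panels.
#'
#' @param population a [conn_matrix()] (e.g. from
#'   [make_population_connectivity()]).
#' @param spec a [fixture_spec()].
#' @return list of `spec$n_subjects` [ts_panel()] objects.
#' @export
sample_subject_panels <- function(population, spec) {
  stopifnot(inherits(population, "conn_matrix"), inherits(spec, "fixture_spec"))
  n <- nrow(population)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  lapply(seq_len(spec$n_subjects), function(s) {
    Rs <- unclass(population)
    if (spec$subject_noise_sd > 0) {
      E <- matrix(stats::rnorm(n * n, sd = spec$subject_noise_sd), n)
      E <- (E + t(E)) / 2
      diag(E) <- 0
      Rs <- pmin(pmax(Rs + E, -0.99), 0.99)
      diag(Rs) <- 1
      Rs <- nearest_psd_corr(Rs)
    }
    ts_panel(rmvnorm_eigen(spec$n_timepoints, Rs),
             region_labels = rownames(population),
             subject_id = sprintf("sub-%03d", s))
  })
}

#' Full synthetic study in one call
#'
#' Convenience wrapper: builds the population matrix, samples the subject
#' panels, estimates each subject's connectivity and the group average.
#'
#' @param spec a [fixture_spec()].
#' @return list with `population`, `panels`, `subject_connectivity`,
#'   `group` (the group-average [conn_matrix()]).
#' @export
synthetic_study <- function(spec = fixture_spec()) {
  population <- make_population_connectivity(spec)
  panels <- sample_subject_panels(population, spec)
  mats <- lapply(panels, pearson_connectivity)
  list(population = population, panels = panels,
       subject_connectivity = mats, group = group_average(mats))
}
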