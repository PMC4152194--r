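#' Specify a planted-partition cohort
#'
#' Defines the generating model for a synthetic resting-state cohort: a
#' block-structured correlation matrix with a known ("planted") module
#' partition, positive correlation within modules, weak correlation between
#' modules, and optional anti-correlated module pairs. Per-subject
#' covariances are jittered copies of this matrix; time series are sampled
#' from them. Defaults emulate a 40-subject cohort of 165 timepoints over
#' 36 regions with six unequally sized modules.
#'
#' @param n_nodes Number of regions (default 36).
#' @param module_sizes Integer vector summing to `n_nodes`
#'   (default `c(5, 4, 8, 8, 3, 8)`).
#' @param within_corr Correlation for same-module pairs, in (0, 1)
#'   (default 0.6).
#' @param between_corr Baseline correlation for different-module pairs
#'   (default 0.05).
#' @param anti_pairs List of 2-vectors of module indices whose
#'   between-module correlation is `anti_corr`; default pairs the first two
#'   modules with the last.
#' @param anti_corr Correlation assigned to `anti_pairs` (default -0.2).
#' @param n_timepoints Timepoints per subject (default 165; must exceed
#'   `n_nodes` so the sample covariance is well conditioned).
#' @param n_subjects Cohort size (default 40).
#' @param subject_sd SD of Gaussian jitter added to each off-diagonal
#'   correlation per subject before sampling (default 0.05).
#' @param seed Master seed (default 1).
#' @return A list of class `"planted_spec"`.
#' @export
planted_partition_spec <- function(n_nodes = 36L,
                                   module_sizes = c(5L, 4L, 8L, 8L, 3L, 8L),
                                   within_corr = 0.6,
                                   between_corr = 0.05,
                                   anti_pairs = list(c(1L, 6L), c(2L, 6L)),
                                   anti_corr = -0.2,
                                   n_timepoints = 165L,
                                   n_subjects = 40L,
                                   subject_sd = 0.05,
                                   seed = 1L) {
  spec <- structure(list(n_nodes = as.integer(n_nodes),
                         module_sizes = as.integer(module_sizes),
                         within_corr = within_corr,
                         between_corr = between_corr,
                         anti_pairs = lapply(anti_pairs, as.integer),
                         anti_corr = anti_corr,
                         n_timepoints = as.integer(n_timepoints),
                         n_subjects = as.integer(n_subjects),
                         subject_sd = subject_sd,
                         seed = as.integer(seed)),
                    class = "planted_spec")
  validate_planted_spec(spec)
}

validate_planted_spec <- function(spec) {
  with(spec, {
    if (sum(module_sizes) != n_nodes)
      stop("module_sizes must sum to n_nodes", call. = FALSE)
    if (any(module_sizes < 1L))
      stop("module_sizes must be positive", call. = FALSE)
    corrs <- c(within_corr, between_corr, anti_corr)
    if (any(abs(corrs) >= 1))
      stop("all correlations must lie in (-1, 1)", call. = FALSE)
    if (within_corr <= 0)
      stop("within_corr must be positive", call. = FALSE)
    if (n_timepoints <= n_nodes)
      stop("n_timepoints must exceed n_nodes for a well-conditioned ",
           "sample covariance", call. = FALSE)
    if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
    if (subject_sd < 0) stop("subject_sd must be >= 0", call. = FALSE)
    m <- length(module_sizes)
    for (p in anti_pairs)
      if (length(p) != 2L || any(p < 1L) || any(p > m) || p[1] == p[2])
        stop("anti_pairs entries must be distinct module indices", call. = FALSE)
  })
  spec
}

#' Ground-truth partition implied by a planted spec
#'
#' @param spec A [planted_partition_spec()].
#' @return A [as_partition()] with labels `1..m` in block order.
#' @export
true_partition <- function(spec) {
  as_partition(rep(seq_along(spec$module_sizes), spec$module_sizes))
}

#' Build the planted block correlation matrix
#'
#' Assembles the block-structured correlation matrix with unit diagonal:
#' `within_corr` for same-module pairs, `between_corr` (or `anti_corr` for
#' configured module pairs) otherwise. If the raw block matrix is not
#' positive definite, eigenvalues are floored at a small positive epsilon
#' and the result rescaled to unit diagonal; the repair refuses to move any
#' entry by more than `max_perturbation`.
#'
#' @param spec A [planted_partition_spec()].
#' @param max_perturbation Largest entry-wise change the PD repair may
#'   introduce (default 0.05).
#' @return Symmetric positive-definite correlation matrix.
#' @export
build_block_covariance <- function(spec, max_perturbation = 0.05) {
  spec <- validate_planted_spec(spec)
  mod <- unclass(true_partition(spec))
  n <- spec$n_nodes
  sigma <- matrix(spec$between_corr, n, n)
  for (u in seq_along(spec$module_sizes)) {
    idx <- which(mod == u)
    sigma[idx, idx] <- spec$within_corr
  }
  for (p in spec$anti_pairs) {
    i <- which(mod == p[1]); j <- which(mod == p[2])
    sigma[i, j] <- spec$anti_corr
    sigma[j, i] <- spec$anti_corr
  }
  diag(sigma) <- 1
  repair_pd(sigma, max_perturbation = max_perturbation)
}

# Floor eigenvalues at a small positive epsilon and rescale to unit
# diagonal. Errors if the repair would move any entry more than the bound
# (signals an infeasible correlation configuration).
repair_pd <- function(sigma, eps = 1e-6, max_perturbation = 0.05) {
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) > eps) return(sigma)
  v <- pmax(e$values, eps)
  fixed <- e$vectors %*% (v * t(e$vectors))
  fixed <- stats::cov2cor(fixed)
  fixed <- (fixed + t(fixed)) / 2
  shift <- max(abs(fixed - sigma))
  if (shift > max_perturbation)
    stop(sprintf(paste0("positive-definite repair would perturb an entry by ",
                        "%.4f (> %.4f); correlation configuration is ",
                        "infeasible"), shift, max_perturbation), call. = FALSE)
  fixed
}

#' One subject's ROI time series
#'
#' @param values T x N numeric matrix (timepoints x regions).
#' @param roi_labels Character vector of N region labels.
#' @param subject_id Subject identifier string.
#' @return A list of class `"roi_timeseries"`.
#' @export
roi_timeseries <- function(values, roi_labels = colnames(values),
                           subject_id = "subject") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (anyNA(values)) stop("time series contain missing values", call. = FALSE)
  if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(ncol(values)))
  if (length(roi_labels) != ncol(values))
    stop("roi_labels length must match the number of columns", call. = FALSE)
  colnames(values) <- roi_labels
  structure(list(values = values,
                 roi_labels = as.character(roi_labels),
                 subject_id = as.character(subject_id)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("roi_timeseries:", x$subject_id, "-", nrow(x$values), "timepoints x",
      ncol(x$values), "ROIs\n")
  invisible(x)
}

#' Simulate a multi-subject cohort of ROI time series
#'
#' Each subject gets a private covariance: the planted block matrix with
#' independent Gaussian jitter (sd `subject_sd`) added to every off-diagonal
#' entry, re-repaired to positive definiteness, from which `n_timepoints`
#' i.i.d. multivariate-normal vectors are drawn via Cholesky factorization.
#' Subject seeds are derived deterministically from `spec$seed`, so the
#' cohort is fully reproducible.
#'
#' @param spec A [planted_partition_spec()].
#' @return List of `n_subjects` [roi_timeseries()] objects.
#' @export
generate_cohort <- function(spec) {
  spec <- validate_planted_spec(spec)
  base_sigma <- build_block_covariance(spec)
  labels <- paste0("ROI", formatC(seq_len(spec$n_nodes), width = 2,
                                  flag = "0"))
  seeds <- derive_seeds(spec$seed, spec$n_subjects)
  lapply(seq_len(spec$n_subjects), function(s) {
    withr::with_seed(seeds[s], {
      sigma <- jitter_covariance(base_sigma, spec$subject_sd)
      x <- sample_mvn(spec$n_timepoints, sigma)
    })
    roi_timeseries(x, labels, sprintf("sub%02d", s))
  })
}

jitter_covariance <- function(sigma, sd) {
  if (sd == 0) return(sigma)
  n <- nrow(sigma)
  noise <- matrix(0, n, n)
  noise[upper.tri(noise)] <- stats::rnorm(n * (n - 1) / 2, sd = sd)
  noise <- noise + t(noise)
  jittered <- sigma + noise
  jittered[jittered > 0.99] <- 0.99
  jittered[jittered < -0.99] <- -0.99
  diag(jittered) <- 1
  # Unstructured symmetric jitter spreads eigenvalues by ~2*sd*sqrt(n), so
  # the jittered matrix routinely loses positive definiteness. Floor its
  # spectrum at the planted matrix's own smallest eigenvalue: subject
  # covariances then inherit the planted matrix's conditioning, so jitter
  # perturbs the correlation structure without degrading invertibility (a
  # near-singular floor would make the subject's true partial correlations
  # degenerate and swamp the planted structure with inversion noise).
  floor_eps <- max(1e-6, min(eigen(sigma, symmetric = TRUE,
                                   only.values = TRUE)$values))
  repair_pd(jittered, eps = floor_eps, max_perturbation = 0.5)
}

sample_mvn <- function(n, sigma) {
  r <- chol(sigma)
  z <- matrix(stats::rnorm(n * nrow(sigma)), n, nrow(sigma))
  z %*% r
}

#' Write a simulated cohort to disk
#'
#' One TSV per subject (rows = timepoints, columns = ROI labels) plus a
#' JSON sidecar recording the generating spec and the true partition.
#'
#' @param cohort List of [roi_timeseries()] (e.g. from [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @param spec Optional [planted_partition_spec()] stored in the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort, function(ts) {
    path <- file.path(dir, paste0(ts$subject_id, "_timeseries.tsv"))
    write_timeseries_tsv(ts, path)
    path
  }, character(1))
  if (!is.null(spec)) {
    sidecar <- list(spec = unclass(spec),
                    true_partition = unclass(true_partition(spec)))
    jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, file.path(dir, "cohort.json"))
  }
  invisible(paths)
}
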