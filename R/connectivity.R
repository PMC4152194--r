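#' Partial correlation matrix of ROI time series
#'
#' Estimates the direct (full-conditional) association between every pair
#' of regions: the partial correlation of columns i and j given all other
#' columns, computed from the inverse of the sample correlation matrix as
#' `pcorr(i, j) = -omega_ij / sqrt(omega_ii * omega_jj)`. Working on the
#' correlation (not covariance) scale makes the result invariant to
#' per-region signal amplitude.
#'
#' With `shrinkage = TRUE` the sample correlation matrix is shrunk toward
#' the identity, `(1 - lambda) R + lambda I`, before inversion, which keeps
#' the estimate defined when T <= N or R is near-singular. The intensity is
#' the Schafer-Strimmer analytic estimate (variance of the off-diagonal
#' correlations over their sum of squares), clipped to \[0, 1\].
#'
#' @param ts A [roi_timeseries()] or plain T x N matrix.
#' @param shrinkage Shrink toward the identity before inversion
#'   (default FALSE; the T > N default design does not need it).
#' @return N x N symmetric matrix of partial correlations with zero
#'   diagonal, labelled by ROI.
#' @export
partial_correlation <- function(ts, shrinkage = FALSE) {
  x <- if (inherits(ts, "roi_timeseries")) ts$values else ts
  if (!is.matrix(x) || !is.numeric(x) || anyNA(x))
    stop("time series must be a complete numeric matrix", call. = FALSE)
  n <- ncol(x)
  if (!shrinkage && nrow(x) <= n)
    stop("T <= N: sample correlation is singular; enable shrinkage",
         call. = FALSE)
  r <- stats::cor(x)
  if (shrinkage) {
    lambda <- shrinkage_intensity(x, r)
    r <- (1 - lambda) * r + lambda * diag(n)
  }
  kap <- kappa(r, exact = FALSE)
  if (!shrinkage && (!is.finite(kap) || kap > 1e12))
    stop(sprintf(paste0("sample correlation matrix is numerically singular ",
                        "(condition number %.3g); enable shrinkage"), kap),
         call. = FALSE)
  omega <- solve(r)
  d <- sqrt(diag(omega))
  p <- -omega / (d %o% d)
  p <- (p + t(p)) / 2
  diag(p) <- 0
  p[p > 1] <- 1
  p[p < -1] <- -1
  if (inherits(ts, "roi_timeseries"))
    dimnames(p) <- list(ts$roi_labels, ts$roi_labels)
  p
}

# Schafer-Strimmer-style intensity for shrinking R toward the identity:
# sum of estimated variances of off-diagonal sample correlations over the
# sum of their squares.
shrinkage_intensity <- function(x, r) {
  t_n <- nrow(x)
  xs <- scale(x)
  w_bar_var <- 0
  off <- which(upper.tri(r))
  ij <- arrayInd(off, dim(r))
  # var of r_ij estimated from the per-timepoint products of standardized
  # columns
  prod_var <- vapply(seq_len(nrow(ij)), function(k) {
    w <- xs[, ij[k, 1]] * xs[, ij[k, 2]]
    stats::var(w) * t_n / (t_n - 1)^2
  }, numeric(1))
  lambda <- sum(prod_var) / sum(r[off]^2)
  min(1, max(0, lambda))
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = arctanh(r)`, variance-stabilizing correlations before averaging and
#' other algebraic operations. Inputs are clipped to `|r| <= 1 - 1e-7` so
#' boundary values stay finite.
#'
#' @param r Numeric vector/matrix of correlations.
#' @return Same shape as `r`.
#' @export
fisher_z <- function(r) {
  clip <- 1 - 1e-7
  atanh(pmin(pmax(r, -clip), clip))
}

#' Functional-connectivity matrix container
#'
#' A symmetric N x N matrix of Fisher-z partial correlations: the weighted
#' adjacency of the fully connected signed network. Diagonal is stored as
#' zero and excluded from all graph sums (self-connections are never used).
#'
#' @param z Symmetric numeric matrix (Fisher-z scale).
#' @param roi_labels Region labels (default taken from `z` dimnames).
#' @param n_subjects_averaged How many subjects the matrix averages
#'   (1 for a single-subject matrix).
#' @return A list of class `"fc_matrix"`.
#' @export
fc_matrix <- function(z, roi_labels = rownames(z), n_subjects_averaged = 1L) {
  assert_square_symmetric(z, "FC matrix")
  if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(nrow(z)))
  diag(z) <- 0
  dimnames(z) <- list(roi_labels, roi_labels)
  structure(list(z = z,
                 roi_labels = as.character(roi_labels),
                 n_subjects_averaged = as.integer(n_subjects_averaged)),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("fc_matrix:", nrow(x$z), "ROIs, averaged over",
      x$n_subjects_averaged, "subject(s)\n")
  invisible(x)
}

#' Fisher-z partial-correlation FC matrix for one subject
#'
#' Convenience composition: [partial_correlation()] then [fisher_z()].
#'
#' @inheritParams partial_correlation
#' @return An [fc_matrix()].
#' @export
subject_fc <- function(ts, shrinkage = FALSE) {
  p <- partial_correlation(ts, shrinkage = shrinkage)
  z <- fisher_z(p)
  diag(z) <- 0
  labels <- if (inherits(ts, "roi_timeseries")) ts$roi_labels else rownames(p)
  fc_matrix(z, labels, n_subjects_averaged = 1L)
}

#' Average FC matrices across subjects
#'
#' Element-wise mean on the Fisher-z scale, with the element-wise sample
#' standard deviation (n - 1 convention) as companion.
#'
#' @param matrices Non-empty list of [fc_matrix()] with identical labels.
#' @return List with `mean` (an [fc_matrix()]) and `sd` (numeric matrix).
#' @export
mean_fc <- function(matrices) {
  if (length(matrices) < 1L) stop("need at least one FC matrix", call. = FALSE)
  labels <- matrices[[1]]$roi_labels
  for (m in matrices)
    if (!identical(m$roi_labels, labels))
      stop("ROI labels differ between FC matrices", call. = FALSE)
  zs <- vapply(matrices, function(m) m$z,
               matrix(0, length(labels), length(labels)))
  mu <- apply(zs, c(1, 2), mean)
  sdm <- if (length(matrices) > 1L) apply(zs, c(1, 2), stats::sd) else
    matrix(0, length(labels), length(labels))
  mu <- (mu + t(mu)) / 2; diag(mu) <- 0
  sdm <- (sdm + t(sdm)) / 2; diag(sdm) <- 0
  dimnames(sdm) <- list(labels, labels)
  list(mean = fc_matrix(mu, labels, n_subjects_averaged = length(matrices)),
       sd = sdm)
}

#' Seeded split of subjects into groups of near-equal size
#'
#' Group sizes differ by at most one; assignment is a seeded shuffle.
#'
#' @param n_subjects Number of subjects.
#' @param n_groups Number of groups (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of group labels `1..n_groups`, length
#'   `n_subjects`.
#' @export
split_groups <- function(n_subjects, n_groups, seed) {
  if (n_groups < 2L) stop("n_groups must be >= 2", call. = FALSE)
  if (n_groups > n_subjects)
    stop("n_groups exceeds the number of subjects", call. = FALSE)
  sizes <- rep(n_subjects %/% n_groups, n_groups)
  extra <- n_subjects %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  assignment <- rep(seq_len(n_groups), times = sizes)
  withr::with_seed(as.integer(seed), assignment[sample.int(n_subjects)])
}

#' Between-group reproducibility of the FC pattern
#'
#' Randomly splits subjects into groups (seeded), averages FC within each
#' group, and correlates (Pearson) the vectorized upper triangles of every
#' pair of group means. High pairwise r indicates the connectivity pattern
#' is reproducible across independent subject groups.
#'
#' @param matrices List of per-subject [fc_matrix()].
#' @param n_groups Number of groups (default 4).
#' @param seed Integer seed for the split.
#' @return List with `r` (n_groups x n_groups matrix, NA below diagonal and
#'   on it), `group_fc` (list of upper-triangle FC vectors per group, the
#'   histogram data), and `assignment`.
#' @export
group_split_fc_correlation <- function(matrices, n_groups = 4L, seed = 1L) {
  assignment <- split_groups(length(matrices), n_groups, seed)
  group_fc <- lapply(seq_len(n_groups), function(g) {
    gm <- mean_fc(matrices[assignment == g])$mean
    gm$z[upper.tri(gm$z)]
  })
  r <- matrix(NA_real_, n_groups, n_groups)
  for (a in seq_len(n_groups - 1L))
    for (b in seq(a + 1L, n_groups))
      r[a, b] <- stats::cor(group_fc[[a]], group_fc[[b]])
  list(r = r, group_fc = group_fc, assignment = assignment)
}
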