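# Shared fixtures, built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Default study-design cohort (40 x 165 x 36, planted 6 modules, seed 1)
# and its per-subject Fisher-z partial-correlation matrices.
default_spec <- function() planted_partition_spec()

default_cohort <- function() {
  cached("cohort", generate_cohort(default_spec()))
}

default_fcs <- function() {
  cached("fcs", lapply(default_cohort(), subject_fc))
}

default_mean_fc <- function() {
  cached("mean_fc", mean_fc(default_fcs()))
}

# Random signed symmetric weight matrix with zero diagonal.
random_signed_weights <- function(n, density = 1, scale = 1) {
  w <- matrix(0, n, n)
  m <- n * (n - 1) / 2
  vals <- stats::runif(m, -scale, scale)
  if (density < 1) vals[stats::runif(m) > density] <- 0
  w[upper.tri(w)] <- vals
  w + t(w)
}

random_partition <- function(n, max_modules = n) {
  as_partition(sample.int(max_modules, n, replace = TRUE))
}
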