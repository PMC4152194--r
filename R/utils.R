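#' Derive child seeds from a master seed
#'
#' Stochastic stages (subject sampling, optimizer restarts, group splits,
#' null networks) each consume their own integer seed derived
#' deterministically from a single master seed, so that the full pipeline
#' is reproducible end to end while stages stay independent.
#'
#' @param seed Master seed (single integer).
#' @param n Number of child seeds to draw.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n), length(n) == 1L, n >= 1)
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# shared input checks ------------------------------------------------------

assert_square_symmetric <- function(w, what = "weight matrix", tol = 1e-8) {
  if (!is.matrix(w) || !is.numeric(w) || nrow(w) != ncol(w))
    stop(what, " must be a square numeric matrix", call. = FALSE)
  if (anyNA(w) || any(!is.finite(w)))
    stop(what, " contains non-finite values", call. = FALSE)
  if (max(abs(w - t(w))) > tol)
    stop(what, " is not symmetric", call. = FALSE)
  invisible(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
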