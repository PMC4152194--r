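#' Module-affiliation partitions
#'
#' A partition (module-affiliation vector) assigns every network node a
#' module label. Internally labels are always stored in canonical form:
#' consecutive integers `1..m` numbered by first appearance, so two
#' partitions are equal iff they describe the same grouping.
#'
#' @param affiliation Integer-like vector of module labels, one per node.
#' @return An integer vector of class `"partition"` with attribute
#'   `n_modules`.
#' @examples
#' as_partition(c("b", "b", "a", "a"))  # canonicalizes to 1 1 2 2
#' @export
as_partition <- function(affiliation) {
  if (inherits(affiliation, "partition")) return(affiliation)
  if (length(affiliation) < 1L || anyNA(affiliation))
    stop("affiliation must be a non-empty vector without missing values",
         call. = FALSE)
  canon <- match(affiliation, unique(affiliation))
  structure(as.integer(canon),
            n_modules = length(unique(canon)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("partition:", length(x), "nodes,", n_modules(x), "modules\n")
  print(unclass(x))
  invisible(x)
}

#' Number of modules in a partition
#' @param p A partition (coerced with [as_partition()]).
#' @return Integer module count.
#' @export
n_modules <- function(p) {
  p <- as_partition(p)
  attr(p, "n_modules")
}

#' Test whether two partitions describe the same grouping
#' @param p,q Partitions (coerced).
#' @return Logical.
#' @export
same_partition <- function(p, q) {
  p <- as_partition(p); q <- as_partition(q)
  length(p) == length(q) && all(unclass(p) == unclass(q))
}
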