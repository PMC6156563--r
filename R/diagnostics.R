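#' Split-chain Gelman--Rubin statistic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so within-chain drift also inflates the statistic). Convergence is
#' conventionally declared at R-hat < 1.05.
#'
#' @param draws list of numeric vectors (one per chain, equal lengths), or
#'   an iterations-by-chains matrix.
#' @return The split R-hat value.
#' @export
#' @examples
#' set.seed(1)
#' gelmanRhat(list(rnorm(2000), rnorm(2000)))  # close to 1
gelmanRhat <- function(draws) {
  if (is.matrix(draws))
    draws <- lapply(seq_len(ncol(draws)), function(j) draws[, j])
  if (!is.list(draws) || length(draws) < 2L)
    stop("need at least 2 chains")
  n <- unique(lengths(draws))
  if (length(n) != 1L) stop("chains must have equal length")
  if (n < 4L) stop("chains too short to split")
  half <- n %/% 2L
  split_chains <- unlist(lapply(draws, function(x) {
    x <- x[seq_len(2L * half)]
    list(x[seq_len(half)], x[half + seq_len(half)])
  }), recursive = FALSE)
  m <- length(split_chains)
  means <- vapply(split_chains, mean, numeric(1))
  vars <- vapply(split_chains, var, numeric(1))
  W <- mean(vars)
  if (!is.finite(W) || W < .Machine$double.eps)
    stop("degenerate within-chain variance (constant draws)")
  B <- half * var(means)
  sqrt(((half - 1) / half * W + B / half) / W)
}
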