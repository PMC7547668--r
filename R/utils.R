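#' @keywords internal
"_PACKAGE"

# Numeric tolerance used for row-stochasticity checks throughout.
.STOCH_TOL <- 1e-9

#' Check that a matrix is row-stochastic
#'
#' @param A numeric matrix.
#' @param tol tolerance on each row sum.
#' @return TRUE invisibly; stops with the offending row index otherwise.
#' @keywords internal
check_row_stochastic <- function(A, tol = .STOCH_TOL) {
  if (any(A < -tol) || any(A > 1 + tol)) {
    bad <- which(A < -tol | A > 1 + tol, arr.ind = TRUE)[1, 1]
    stop("transition matrix row ", bad, " has entries outside [0, 1]")
  }
  rs <- rowSums(A)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad) > 0) {
    stop("transition matrix row ", bad[1], " sums to ", format(rs[bad[1]]),
         ", not 1")
  }
  invisible(TRUE)
}

#' Derive a per-stage seed from a global seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @param seed integer global seed.
#' @param stage integer stage offset.
#' @keywords internal
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + 104729 * stage) %% 2147483647L)
}

#' Log-sum-exp of a numeric vector
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Stable column names for disease indicators: d_0001, d_0002, ...
disease_names <- function(D) sprintf("d_%04d", seq_len(D))

# Best-permutation alignment of estimated cluster labels to reference labels,
# by exhaustive search over permutations (intended for small C).
#' Align cluster labels to a reference by exhaustive permutation search
#'
#' @param cost C x C matrix; `cost[i, j]` is the cost of mapping estimated
#'   cluster `i` to reference cluster `j`.
#' @return integer vector `perm` with `perm[i]` = reference label assigned to
#'   estimated label `i`, minimizing total cost.
#' @keywords internal
best_permutation <- function(cost) {
  C <- nrow(cost)
  perms <- all_permutations(C)
  scores <- vapply(seq_len(nrow(perms)), function(k) {
    sum(cost[cbind(seq_len(C), perms[k, ])])
  }, numeric(1))
  perms[which.min(scores), ]
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}
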