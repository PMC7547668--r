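#' Fuzzy C-means clustering
#'
#' Minimizes the fuzzified within-cluster sum of squares
#' \eqn{J = \sum_i \sum_c u_{ic}^m \|x_i - v_c\|^2} by alternating membership
#' and centroid updates. Memberships follow the standard inverse-distance
#' rule \eqn{u_{ic} \propto (1/\|x_i - v_c\|^2)^{1/(m-1)}}; a point exactly
#' coinciding with a centroid receives crisp membership 1 for that centroid.
#'
#' @param X numeric matrix or `reduced_features` object.
#' @param C number of clusters (>= 1).
#' @param m fuzzifier (> 1); the canonical 2 by default.
#' @param tol stop when the objective improves by less than this.
#' @param max_iter iteration cap.
#' @param seed RNG seed for the initial centroids (k-means++-style seeding
#'   on data rows).
#' @param n_starts number of seeded starts; the run with the lowest final
#'   objective is returned.
#' @param init optional C x p matrix of initial centroids (overrides seeding
#'   and forces a single start).
#' @return object of class `fcm_fit`: `memberships` (rows sum to 1),
#'   `centroids`, `m`, `objective_trace` (non-increasing), `n_iter`,
#'   `converged`.
#' @export
fcm_fit <- function(X, C, m = 2, tol = 1e-8, max_iter = 300, seed = 1L,
                    n_starts = 5, init = NULL) {
  if (is.null(init) && n_starts > 1) {
    runs <- lapply(seq_len(n_starts), function(s) {
      fcm_fit(X, C, m = m, tol = tol, max_iter = max_iter,
              seed = derive_seed(seed, s), n_starts = 1)
    })
    objs <- vapply(runs, function(r) utils::tail(r$objective_trace, 1),
                   numeric(1))
    return(runs[[which.min(objs)]])
  }
  fcm_fit_single(X, C, m, tol, max_iter, seed, init)
}

fcm_fit_single <- function(X, C, m = 2, tol = 1e-8, max_iter = 300,
                           seed = 1L, init = NULL) {
  if (inherits(X, "reduced_features")) X <- feature_matrix(X)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(C >= 1, m > 1, max_iter >= 1)
  n_distinct <- nrow(unique(X))
  if (C > n_distinct) {
    stop("C = ", C, " exceeds the number of distinct rows (", n_distinct, ")")
  }
  if (C == 1) {
    v <- matrix(colMeans(X), 1, ncol(X))
    u <- matrix(1, n, 1)
    obj <- sum(rowSums((X - v[rep(1, n), , drop = FALSE])^2))
    return(structure(list(memberships = u, centroids = v, m = m,
                          objective_trace = obj, n_iter = 0L,
                          converged = TRUE), class = "fcm_fit"))
  }
  if (is.null(init)) {
    set.seed(seed)
    init <- kmeanspp_centroids(X, C)
  }
  v <- as.matrix(init)
  stopifnot(nrow(v) == C, ncol(v) == ncol(X))

  d2 <- function(v) {
    # n x C squared Euclidean distances
    outer(rowSums(X^2), rep(1, C)) - 2 * X %*% t(v) +
      outer(rep(1, n), rowSums(v^2))
  }
  memberships_from_d2 <- function(D2) {
    D2 <- pmax(D2, 0)
    u <- matrix(0, n, C)
    zero <- D2 < 1e-300
    sing <- rowSums(zero) > 0
    if (any(sing)) {
      # crisp assignment at coincident centroids (lowest index on ties)
      first <- apply(zero[sing, , drop = FALSE], 1, which.max)
      u[cbind(which(sing), first)] <- 1
    }
    if (any(!sing)) {
      w <- D2[!sing, , drop = FALSE]^(-1 / (m - 1))
      u[!sing, ] <- w / rowSums(w)
    }
    u
  }

  obj_trace <- numeric(0)
  u <- memberships_from_d2(d2(v))
  for (it in seq_len(max_iter)) {
    um <- u^m
    v <- crossprod(um, X) / colSums(um)
    D2 <- d2(v)
    u <- memberships_from_d2(D2)
    obj <- sum(u^m * pmax(D2, 0))
    obj_trace <- c(obj_trace, obj)
    if (it > 1 && abs(obj_trace[it - 1] - obj) < tol) break
  }
  structure(list(memberships = u, centroids = v, m = m,
                 objective_trace = obj_trace, n_iter = length(obj_trace),
                 converged = length(obj_trace) < max_iter),
            class = "fcm_fit")
}

# k-means++ seeding: first centroid uniform over distinct rows, then each
# next one with probability proportional to squared distance from the
# nearest centroid chosen so far.
kmeanspp_centroids <- function(X, C) {
  distinct <- which(!duplicated(X))
  picks <- distinct[sample.int(length(distinct), 1)]
  while (length(picks) < C) {
    d2min <- rep(Inf, nrow(X))
    for (p in picks) {
      d2 <- rowSums(sweep(X, 2, X[p, ], `-`)^2)
      d2min <- pmin(d2min, d2)
    }
    d2min[picks] <- 0
    if (sum(d2min) == 0) {
      cand <- setdiff(distinct, picks)
      picks <- c(picks, cand[sample.int(length(cand), 1)])
    } else {
      picks <- c(picks, sample.int(nrow(X), 1, prob = d2min))
    }
  }
  X[picks, , drop = FALSE]
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("<fcm_fit> C =", ncol(x$memberships), " m =", x$m,
      " iterations =", x$n_iter,
      " objective =", format(utils::tail(x$objective_trace, 1)), "\n")
  invisible(x)
}

#' Initialize HMM parameters from a fuzzy segmentation
#'
#' Converts baseline fuzzy memberships into starting values for the hidden
#' Markov model: initial cluster probabilities are membership column means,
#' emission means/variances are membership-weighted moments of the reduced
#' features (variances floored), and the annual transition matrix starts
#' diagonal-dominant with a small mass to each absorbing state. The dropout
#' and death rows are exact one-hot self-loops and stay frozen during
#' fitting.
#'
#' @param fcm an [fcm_fit()] computed on the year-0 rows of `X`.
#' @param X the matrix (or `reduced_features` rows) the memberships refer to.
#' @param self_transition initial self-transition probability of each disease
#'   cluster (default 0.8).
#' @param absorbing_mass initial per-year mass to each of dropout and death
#'   (default 0.02); the row is renormalized.
#' @param var_floor lower bound for emission variances, kept through fitting.
#'   Component scores are standardized to unit overall variance, so the
#'   default 0.05 means no cluster may shrink below 5% of the total variance
#'   of a dimension; this blocks the degenerate likelihood maxima in which a
#'   Gaussian collapses onto an atom of the quasi-discrete MCA score
#'   distribution.
#' @return an object of class `hmm_params` (see [hmm_params()]).
#' @export
init_hmm_from_fcm <- function(fcm, X, self_transition = 0.8,
                              absorbing_mass = 0.02, var_floor = 0.05) {
  stopifnot(inherits(fcm, "fcm_fit"))
  if (inherits(X, "reduced_features")) X <- feature_matrix(X)
  X <- as.matrix(X)
  u <- fcm$memberships
  stopifnot(nrow(u) == nrow(X))
  C <- ncol(u); n <- nrow(u); p <- ncol(X)
  colsum <- colSums(u)
  if (any(colsum < 1e-6 * n)) {
    stop("empty fuzzy cluster (total membership ~ 0); reduce C")
  }
  pi <- colsum / n
  means <- crossprod(u, X) / colsum
  vars <- matrix(0, C, p)
  for (c in seq_len(C)) {
    dev <- sweep(X, 2, means[c, ])
    vars[c, ] <- colSums(u[, c] * dev^2) / colsum[c]
  }
  vars <- pmax(vars, var_floor)

  K <- C + 2L
  A <- matrix(0, K, K)
  for (c in seq_len(C)) {
    row <- rep(0, K)
    row[seq_len(C)] <- if (C > 1) (1 - self_transition) / (C - 1) else 0
    row[c] <- self_transition
    row[C + 1L] <- absorbing_mass
    row[C + 2L] <- absorbing_mass
    A[c, ] <- row / sum(row)
  }
  A[C + 1L, C + 1L] <- 1
  A[C + 2L, C + 2L] <- 1
  hmm_params(pi = pi, A = A, means = means, vars = vars,
             var_floor = var_floor)
}
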