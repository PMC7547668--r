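# Shared fixtures and independent oracles used across the suite.

# Small cohort configuration with well-separated disease profiles.
test_config <- function(n = 300, C = 2, D = 8, seed = 1, ...) {
  cohort_config(n_persons = n, n_clusters = C, n_diseases = D, seed = seed,
                ...)
}

# Toy HMM with C disease clusters on a 1-D feature space.
toy_hmm <- function(C = 2, self = 0.7, dropout = 0.05, death = 0.1,
                    sep = 3, var = 0.5) {
  A <- default_transition(C, self = self, dropout = dropout, death = death)
  hmm_params(pi = rep(1 / C, C), A = A,
             means = matrix(sep * (seq_len(C) - 1), C, 1),
             vars = matrix(var, C, 1), var_floor = 1e-4)
}

# Brute-force log-likelihood: exhaustive sum over all state paths. Active
# years emit the diagonal-Gaussian density; a terminal dropped/dead year is
# an indicator emission (1 for the matching absorbing state). Transitions
# into/out of states follow A; absorbing states are valid path states only
# where observed.
brute_force_loglik <- function(params, x, status) {
  C <- params$C; K <- params$K
  Tn <- length(status)
  x <- as.matrix(x)
  emit <- function(state, t) {
    if (status[t] == "active") {
      if (state > C) return(0)
      prod(stats::dnorm(x[t, ], params$means[state, ],
                        sqrt(params$vars[state, ])))
    } else {
      target <- if (status[t] == "dropped") C + 1L else C + 2L
      as.numeric(state == target)
    }
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  total <- 0
  pi_full <- c(params$pi, 0, 0)
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- pi_full[s[1]] * emit(s[1], 1)
    if (Tn > 1) for (t in 2:Tn) {
      p <- p * params$A[s[t - 1], s[t]] * emit(s[t], t)
    }
    total <- total + p
  }
  log(total)
}

# Brute-force Viterbi: argmax path over the same enumeration.
brute_force_viterbi <- function(params, x, status) {
  C <- params$C; K <- params$K
  Tn <- length(status)
  x <- as.matrix(x)
  emit <- function(state, t) {
    if (status[t] == "active") {
      if (state > C) return(0)
      prod(stats::dnorm(x[t, ], params$means[state, ],
                        sqrt(params$vars[state, ])))
    } else {
      target <- if (status[t] == "dropped") C + 1L else C + 2L
      as.numeric(state == target)
    }
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  pi_full <- c(params$pi, 0, 0)
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- log(pi_full[s[1]]) + log(emit(s[1], 1))
    if (Tn > 1) for (t in 2:Tn) {
      p <- p + log(params$A[s[t - 1], s[t]]) + log(emit(s[t], t))
    }
    if (is.finite(p) && p > best + 1e-12) { best <- p; best_path <- unname(s) }
  }
  list(logprob = best, path = best_path)
}

# Agreement between decoded and true person-year cluster labels under the
# best label permutation (absorbing states matched identically).
decode_agreement <- function(trajectories, ground_truth, C) {
  key <- paste(trajectories$person_id, trajectories$year)
  dec <- trajectories$state[match(paste(ground_truth$person_id,
                                        ground_truth$year), key)]
  live <- ground_truth$state <= C & !is.na(dec)
  tab <- table(factor(ground_truth$state[live], seq_len(C)),
               factor(dec[live], seq_len(C)))
  perms <- mmtraj:::all_permutations(C)
  accs <- apply(perms, 1, function(p) sum(tab[cbind(seq_len(C), p)]))
  perm <- perms[which.max(accs), ]
  list(agreement = max(accs) / sum(tab), perm = perm)
}

# Reduced-feature rows restricted to year 0, keeping the class.
year0_rows <- function(X) {
  x0 <- X[X$year == 0, ]
  class(x0) <- class(X)
  x0
}

# One fitted end-to-end model on a small panel, memoised per session so
# several tests can share it.
fitted_demo <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- test_config(n = 600, C = 2, D = 10, seed = 402,
                       cluster_visit_rates = c(4, 14),
                       cluster_drug_rates = c(2, 7))
    panel <- generate_cohort(cfg)
    X <- assemble_features(panel, 2, 2)
    fcm <- fcm_fit(year0_rows(X), 2, seed = 8)
    init <- init_hmm_from_fcm(fcm, year0_rows(X))
    fit <- suppressWarnings(baum_welch(panel, X, init))
    traj <- viterbi_decode(fit, panel, X)
    cache <<- list(cfg = cfg, panel = panel, X = X, fit = fit, traj = traj)
    cache
  }
})
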