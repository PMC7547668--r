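test_that("forward log-likelihood matches exhaustive path enumeration", {
  params <- toy_hmm(C = 2) # K = 4 states
  set.seed(3)
  cases <- list(
    list(x = matrix(rnorm(3), 3, 1), status = rep("active", 3)),
    list(x = matrix(rnorm(2), 2, 1), status = c("active", "active", "dead")),
    list(x = matrix(rnorm(1), 1, 1), status = c("active", "dropped")),
    list(x = matrix(rnorm(4, 2), 4, 1), status = rep("active", 4))
  )
  for (cs in cases) {
    expect_equal(as.numeric(sequence_loglik(params, cs$x, cs$status)),
                 brute_force_loglik(params, cs$x, cs$status),
                 tolerance = 1e-10)
  }
})

test_that("single-cluster chain reduces to summed Gaussian log-densities", {
  A <- diag(3) # C = 1, no absorption mass
  params <- hmm_params(pi = 1, A = A, means = matrix(0.7, 1, 2),
                       vars = matrix(2, 1, 2), var_floor = 1e-4)
  set.seed(4)
  x <- matrix(rnorm(6), 3, 2)
  direct <- sum(stats::dnorm(x, 0.7, sqrt(2), log = TRUE))
  expect_equal(as.numeric(sequence_loglik(params, x)), direct,
               tolerance = 1e-10)
})

test_that("sequences impossible under the model return -Inf, not an error", {
  A <- diag(3) # single cluster with zero mass to absorbing states
  params <- hmm_params(pi = 1, A = A, means = matrix(0, 1, 1),
                       vars = matrix(1, 1, 1), var_floor = 1e-4)
  ll <- sequence_loglik(params, matrix(0, 1, 1), c("active", "dead"))
  expect_identical(as.numeric(ll), -Inf)
  expect_match(attr(ll, "diagnostic"), "zero probability")
})

test_that("Viterbi agrees with exhaustive argmax and respects absorption", {
  params <- toy_hmm(C = 2, sep = 2, var = 1)
  set.seed(6)
  for (case in 1:4) {
    n_active <- sample(2:3, 1)
    status <- rep("active", n_active)
    if (case %% 2 == 0) status <- c(status, sample(c("dropped", "dead"), 1))
    x <- matrix(rnorm(n_active, mean = sample(0:2, 1)), n_active, 1)
    bf <- brute_force_viterbi(params, x, status)

    sim_panel <- structure(list(
      observations = data.frame(person_id = 1, year = seq_along(status) - 1,
                                status = status),
      persons = data.frame(person_id = 1),
      ground_truth = NULL, n_clusters = 2, n_diseases = 0,
      n_years = length(status), disease_cols = character(0)),
      class = "cohort_panel")
    X <- data.frame(person_id = 1, year = seq_len(n_active) - 1, f1 = x[, 1])
    traj <- viterbi_decode(params, sim_panel, X)
    expect_equal(traj$state, bf$path)
    expect_equal(as.numeric(attr(traj, "logprob")), bf$logprob,
                 tolerance = 1e-10)
    if (status[length(status)] != "active") {
      expect_equal(traj$state[length(status)],
                   if (status[length(status)] == "dropped") 3L else 4L)
    }
  }
})

test_that("Viterbi breaks exact ties toward the lowest state index", {
  # two identical clusters: every path through them is equally likely
  A <- default_transition(2, self = 0.45, dropout = 0.05, death = 0.05)
  A[1, 2] <- A[2, 1] <- 0.45
  params <- hmm_params(pi = c(0.5, 0.5), A = A, means = matrix(0, 2, 1),
                       vars = matrix(1, 2, 1), var_floor = 1e-4)
  sim_panel <- structure(list(
    observations = data.frame(person_id = 1, year = 0:2, status = "active"),
    persons = data.frame(person_id = 1), ground_truth = NULL,
    n_clusters = 2, n_diseases = 0, n_years = 3,
    disease_cols = character(0)), class = "cohort_panel")
  X <- data.frame(person_id = 1, year = 0:2, f1 = c(0.3, -0.2, 0.1))
  traj <- viterbi_decode(params, sim_panel, X)
  expect_equal(traj$state, rep(1L, 3))
})

test_that("EM iterations never decrease the total log-likelihood", {
  for (s in c(101, 202)) {
    sim <- simulate_from_hmm(toy_hmm(C = 2, sep = 2), n = 120, seed = s)
    init <- jittered <- toy_hmm(C = 2, sep = 1.5, var = 1)
    fit <- suppressWarnings(baum_welch(sim$panel, sim$X, init,
                                       max_iter = 25))
    expect_true(all(diff(fit$loglik_trace) >= -1e-8), info = paste("seed", s))
  }
})

test_that("absorbing transition rows stay exactly one-hot through fitting", {
  sim <- simulate_from_hmm(toy_hmm(C = 2), n = 150, seed = 5)
  fit <- suppressWarnings(baum_welch(sim$panel, sim$X,
                                     toy_hmm(C = 2, sep = 2), max_iter = 15))
  expect_identical(fit$A[3, ], c(0, 0, 1, 0))
  expect_identical(fit$A[4, ], c(0, 0, 0, 1))
  expect_true(all(abs(rowSums(fit$A) - 1) < 1e-9))
})

test_that("restart wrapper is a faithful argmax over restarts", {
  sim <- simulate_from_hmm(toy_hmm(C = 2, sep = 3), n = 100, seed = 9)
  init <- toy_hmm(C = 2, sep = 2)
  single <- suppressWarnings(baum_welch(sim$panel, sim$X, init,
                                        max_iter = 40))
  one <- suppressWarnings(fit_with_restarts(sim$panel, sim$X, init,
                                            n_restarts = 1, seed = 4,
                                            max_iter = 40))
  expect_equal(one$loglik, single$loglik, tolerance = 1e-10)
  expect_equal(one$A, single$A, tolerance = 1e-10)

  multi <- suppressWarnings(fit_with_restarts(sim$panel, sim$X, init,
                                              n_restarts = 4, seed = 4,
                                              max_iter = 40))
  expect_equal(multi$loglik, max(multi$restart_logliks), tolerance = 1e-12)
  expect_length(multi$restart_logliks, 4)

  again <- suppressWarnings(fit_with_restarts(sim$panel, sim$X, init,
                                              n_restarts = 4, seed = 4,
                                              max_iter = 40))
  expect_identical(multi$A, again$A)
  expect_identical(multi$loglik, again$loglik)
})

test_that("transition summaries are row-stochastic cross-tabulations", {
  d <- fitted_demo()
  s2e <- transition_summary(d$traj, "start_to_end")
  ann <- transition_summary(d$traj, "annual")
  for (s in list(s2e, ann)) {
    rs <- rowSums(s$proportions, na.rm = TRUE)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
  }
  # absorbing rows one-hot
  expect_equal(s2e$proportions["Dropout", "Dropout"], 1)
  expect_equal(s2e$proportions["Death", "Death"], 1)
  expect_equal(ann$proportions["Dropout", "Dropout"], 1)
  expect_equal(ann$proportions["Death", "Death"], 1)
})

test_that("full permanence decodes to an identity start-to-end summary", {
  A <- diag(4)
  params <- hmm_params(pi = c(0.5, 0.5), A = A,
                       means = matrix(c(-3, 3), 2, 1),
                       vars = matrix(0.5, 2, 1), var_floor = 1e-4)
  sim <- simulate_from_hmm(params, n = 200, seed = 12)
  traj <- viterbi_decode(params, sim$panel, sim$X)
  s2e <- transition_summary(traj, "start_to_end")
  expect_equal(unname(s2e$proportions[1:2, 1:2]), diag(2))
})

test_that("model and decoded transitions agree on self-simulated data", {
  d <- fitted_demo()
  sim <- simulate_from_hmm(d$fit, n = 2000, seed = 31)
  traj <- viterbi_decode(d$fit, sim$panel, sim$X)
  cmp <- validate_bw_vs_decoded(d$fit, traj)
  expect_lte(cmp$max_abs_diff, 0.05)
  # absorbing rows differ by exactly zero
  tab <- cmp$table
  absorbing <- tab$from %in% c("Dropout", "Death")
  expect_true(all(tab$abs_diff[absorbing] == 0))
})

test_that("fitted parameters survive a JSON round-trip", {
  d <- fitted_demo()
  path <- withr::local_tempfile(fileext = ".json")
  hmm_to_json(d$fit, path)
  back <- hmm_from_json(path)
  expect_equal(back$A, d$fit$A, ignore_attr = TRUE)
  expect_equal(back$pi, d$fit$pi)
  expect_equal(back$means, d$fit$means, ignore_attr = TRUE)
  expect_equal(back$loglik, d$fit$loglik)
})

test_that("ground-truth structure is recovered on a separable panel", {
  d <- fitted_demo()
  agr <- decode_agreement(d$traj, d$panel$ground_truth, 2)
  expect_gte(agr$agreement, 0.8)
  expect_lt(max(abs(sort(d$fit$pi) - sort(d$cfg$init_probs))), 0.05)
})
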