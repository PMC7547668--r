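# Minimal panel/trajectory pair with controlled outcomes.
survival_fixture <- function(status_by_person, n_years = 5) {
  # status_by_person: list of per-person status vectors
  rows <- list()
  for (i in seq_along(status_by_person)) {
    st <- status_by_person[[i]]
    rows[[i]] <- data.frame(person_id = i, year = seq_along(st) - 1,
                            status = st, age = 70 + i, visits = 3L,
                            drugs = 2L, d_0001 = 0L)
  }
  obs <- do.call(rbind, rows)
  n <- length(status_by_person)
  panel <- structure(list(
    observations = obs,
    persons = data.frame(person_id = seq_len(n),
                         sex = rep(c("female", "male"), length.out = n),
                         ses_quintile = rep(1:5, length.out = n),
                         baseline_age = 70 + seq_len(n)),
    ground_truth = NULL, n_clusters = 1, n_diseases = 1,
    n_years = n_years, disease_cols = "d_0001"), class = "cohort_panel")
  traj <- structure(data.frame(person_id = obs$person_id, year = obs$year,
                               state = ifelse(obs$status == "active", 1L,
                                              ifelse(obs$status == "dropped",
                                                     2L, 3L))),
                    C = 1, class = c("trajectory_set", "data.frame"))
  list(panel = panel, traj = traj)
}

test_that("survival records encode the stated time/event conventions", {
  fx <- survival_fixture(list(
    rep("active", 5),                       # survivor: time 5, censored
    c("active", "active", "active", "dead"),# dead in year 3: time 2.5
    c("active", "active", "dropped")        # dropout year 2: time 2, censored
  ))
  rec <- build_survival_records(fx$panel, fx$traj)
  expect_equal(rec$time, c(5, 2.5, 2))
  expect_equal(rec$event, c(0L, 1L, 0L))
  rec_end <- build_survival_records(fx$panel, fx$traj,
                                    death_time = "year_end")
  expect_equal(rec_end$time[2], 3)
})

test_that("record counts tally with generator ground truth", {
  panel <- generate_cohort(test_config(n = 500, C = 2, D = 6, seed = 61))
  gt_traj <- structure(panel$ground_truth[, c("person_id", "year", "state")],
                       C = 2, class = c("trajectory_set", "data.frame"))
  rec <- build_survival_records(panel, gt_traj)
  expect_equal(nrow(rec), nrow(panel$persons))
  obs <- panel$observations
  expect_equal(sum(rec$event), sum(obs$status == "dead"))
  expect_equal(sum(rec$time == 5 & rec$event == 0),
               sum(tapply(obs$status, obs$person_id,
                          function(s) all(s == "active"))))
})

test_that("Cox partial likelihood matches the hand-computed 4-subject oracle",
{
  # subjects die at distinct times 1 < 2 < 3 < 4; binary covariate 1,0,1,0.
  # Breslow partial log-likelihood at beta = 0:
  #   -log(4) - log(3) - log(2) - log(1) = -log(24)
  # score at beta = 0: (1-2/4) + (0-1/3) + (1-1/2) + 0 = 2/3
  rec <- data.frame(person_id = 1:4, time = 1:4, event = 1L,
                    baseline_cluster = c(2L, 1L, 2L, 1L),
                    age = 70, sex = "female", ses_quintile = 1L)
  class(rec) <- c("survival_records", "data.frame")

  pl <- function(beta) { # independent direct evaluation
    x <- c(1, 0, 1, 0)
    ll <- 0
    for (i in 1:4) {
      risk <- which(rec$time >= rec$time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  expect_equal(pl(0), -log(24), tolerance = 1e-12)
  score0 <- (pl(1e-6) - pl(-1e-6)) / 2e-6
  expect_equal(score0, 2 / 3, tolerance = 1e-6)

  fit <- fit_cox(rec, "cluster")
  cox <- attr(fit, "fit")
  expect_equal(cox$loglik[1], -log(24), tolerance = 1e-10)
  # the coxph estimate maximizes the independent partial likelihood
  beta_hat <- fit$estimate
  expect_gt(pl(beta_hat), pl(beta_hat + 0.01))
  expect_gt(pl(beta_hat), pl(beta_hat - 0.01))
  expect_equal(pl(beta_hat), cox$loglik[2], tolerance = 1e-8)
})

test_that("hazard ratios are invariant to time rescaling", {
  set.seed(71)
  n <- 400
  rec <- data.frame(person_id = seq_len(n),
                    time = rexp(n, 0.2),
                    event = rbinom(n, 1, 0.7),
                    baseline_cluster = sample(1:2, n, TRUE),
                    age = rnorm(n, 75, 5),
                    sex = sample(c("female", "male"), n, TRUE),
                    ses_quintile = sample(1:5, n, TRUE))
  class(rec) <- c("survival_records", "data.frame")
  f1 <- fit_cox(rec, c("cluster", "age", "sex", "ses"))
  rec2 <- rec; rec2$time <- rec$time * 37.3
  f2 <- fit_cox(rec2, c("cluster", "age", "sex", "ses"))
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-8)
})

test_that("null simulation keeps type-I error near nominal", {
  set.seed(81)
  rejections <- 0; coverage <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    n <- 400
    rec <- data.frame(person_id = seq_len(n),
                      time = rexp(n, 0.15),
                      event = 1L,
                      baseline_cluster = rep(1:2, each = n / 2),
                      age = 75, sex = "female", ses_quintile = 1L)
    cens <- rec$time > 8
    rec$time[cens] <- 8; rec$event[cens] <- 0L
    class(rec) <- c("survival_records", "data.frame")
    f <- fit_cox(rec, "cluster")
    z <- f$estimate / f$se
    rejections <- rejections + (abs(z) > stats::qnorm(0.975))
    ci <- f$estimate + c(-1, 1) * stats::qnorm(0.975) * f$se
    coverage <- coverage + (ci[1] <= 0 && ci[2] >= 0)
  }
  expect_gte(rejections / n_rep, 0.02)
  expect_lte(rejections / n_rep, 0.08)
  expect_gte(coverage / n_rep, 0.90)
})

test_that("chained imputation preserves observed values and MCAR margins", {
  set.seed(91)
  n <- 6000
  rec <- data.frame(person_id = seq_len(n),
                    time = pmin(rexp(n, 0.1), 5),
                    event = rbinom(n, 1, 0.2),
                    baseline_cluster = sample(1:3, n, TRUE),
                    age = rnorm(n, 75, 6),
                    sex = sample(c("female", "male"), n, TRUE),
                    ses_quintile = sample(1:5, n, TRUE,
                                          prob = c(0.3, 0.25, 0.2, 0.15, 0.1)))
  class(rec) <- c("survival_records", "data.frame")
  obs_dist <- prop.table(table(rec$ses_quintile))
  miss <- sample(n, round(0.07 * n))
  rec$ses_quintile[miss] <- NA
  imp <- impute_chained(rec, m = 7, seed = 17)
  expect_length(imp, 7)
  for (k in 1:7) {
    expect_false(anyNA(imp[[k]]$ses_quintile))
    expect_identical(imp[[k]]$ses_quintile[-miss], rec$ses_quintile[-miss])
  }
  pooled_draws <- unlist(lapply(imp, function(d) d$ses_quintile[miss]))
  imp_dist <- prop.table(table(factor(pooled_draws, 1:5)))
  se <- sqrt(obs_dist * (1 - obs_dist) / length(miss))
  expect_true(all(abs(imp_dist - obs_dist) <= 3 * se))
})

test_that("imputation degenerate cases behave as specified", {
  rec <- data.frame(person_id = 1:20, time = 1:20 / 4, event = 0L,
                    baseline_cluster = 1L, age = 75, sex = "female",
                    ses_quintile = rep(1:5, 4))
  class(rec) <- c("survival_records", "data.frame")
  imp <- impute_chained(rec, m = 3, seed = 1)
  expect_length(imp, 3)
  for (k in 1:3) expect_identical(imp[[k]], as.data.frame(rec))

  rec$ses_quintile <- NA_integer_
  expect_error(impute_chained(rec, m = 3), "100%")
})

test_that("Rubin pooling reproduces the closed-form toy and its identities", {
  pooled <- pool_rubin(matrix(c(1, 2), 2, 1), matrix(c(0.5, 0.5), 2, 1))
  expect_equal(pooled$estimate, 1.5)
  expect_equal(pooled$within, 0.25)
  expect_equal(pooled$between, 0.5)
  expect_equal(pooled$total, 1.0)
  expect_equal(pooled$total, pooled$within + (1 + 1 / 2) * pooled$between,
               tolerance = 1e-12)

  same <- pool_rubin(matrix(c(1.2, 1.2, 1.2), 3, 1),
                     matrix(c(0.3, 0.3, 0.3), 3, 1))
  expect_equal(same$estimate, 1.2)
  expect_equal(same$between, 0)
  expect_equal(same$total, same$within)

  # widening CI as between-variance grows at fixed within
  w1 <- pool_rubin(matrix(c(1, 1.2), 2, 1), matrix(c(0.3, 0.3), 2, 1))
  w2 <- pool_rubin(matrix(c(0.5, 1.7), 2, 1), matrix(c(0.3, 0.3), 2, 1))
  expect_gt(log(w2$ci_upper) - log(w2$ci_lower),
            log(w1$ci_upper) - log(w1$ci_lower))
  expect_error(pool_rubin(matrix(1:4, 2), matrix(1:2, 1)), "mismatch")
})

test_that("an injected cluster mortality offset is recovered by the stage", {
  A <- default_transition(2, self = 0.95, dropout = 0.02, death = 0.03)
  A[1, 2] <- A[2, 1] <- 0 # freeze cluster membership
  A[1, 1] <- A[2, 2] <- 0.95
  cfg <- test_config(n = 4000, C = 2, D = 4, seed = 111,
                     annual_transition = A,
                     init_probs = c(0.5, 0.5),
                     cluster_log_hazard = c(0, 0.7))
  panel <- generate_cohort(cfg)
  gt_traj <- structure(panel$ground_truth[, c("person_id", "year", "state")],
                       C = 2, class = c("trajectory_set", "data.frame"))
  rec <- build_survival_records(panel, gt_traj)
  fit <- fit_cox(rec, "cluster")
  # renormalisation shrinks the realised annual-probability ratio slightly
  # below exp(0.7); accept a generous window around it
  expect_gt(exp(fit$estimate), 1.6)
  expect_lt(exp(fit$estimate), 2.5)
})
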