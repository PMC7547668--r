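#' Hidden Markov model parameters with absorbing dropout/death states
#'
#' The state space has `K = C + 2` states: disease clusters `1..C` with
#' diagonal-covariance Gaussian emissions over the reduced feature space, and
#' two absorbing states — dropout (`C + 1`) and death (`C + 2`) — that are
#' observed events rather than latent: their emission is an indicator on the
#' recorded status, their transition rows are exact one-hot self-loops, and
#' they carry zero initial mass (inclusion required surviving to the index
#' date).
#'
#' @param pi length-C initial probabilities over disease clusters.
#' @param A K x K row-stochastic transition matrix; rows `C+1`, `C+2` must be
#'   exact one-hot self-loops.
#' @param means,vars C x p emission means and diagonal variances.
#' @param var_floor lower bound enforced on variances.
#' @param loglik,converged,n_iter,restart_logliks,seed fitting metadata.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(pi, A, means, vars, var_floor = 1e-4,
                       loglik = NA_real_, converged = NA, n_iter = 0L,
                       restart_logliks = NULL, seed = NA_integer_) {
  means <- as.matrix(means); vars <- as.matrix(vars); A <- as.matrix(A)
  C <- length(pi); K <- C + 2L
  stopifnot(nrow(means) == C, all(dim(vars) == dim(means)),
            all(dim(A) == c(K, K)))
  if (abs(sum(pi) - 1) > .STOCH_TOL || any(pi < 0)) {
    stop("pi must be a probability vector over the ", C, " disease clusters")
  }
  check_row_stochastic(A)
  for (r in c(C + 1L, C + 2L)) {
    if (!identical(as.numeric(A[r, ]), as.numeric(seq_len(K) == r))) {
      stop("absorbing row ", r, " of A must be an exact one-hot self-loop")
    }
  }
  if (any(vars < var_floor - 1e-12)) stop("emission variances below the floor")
  structure(list(C = C, K = K, pi = as.numeric(pi), A = A, means = means,
                 vars = vars, var_floor = var_floor, loglik = loglik,
                 converged = converged, n_iter = n_iter,
                 restart_logliks = restart_logliks, seed = seed),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> C =", x$C, "disease clusters + dropout + death\n")
  cat("  loglik:", format(x$loglik), " iterations:", x$n_iter,
      " converged:", x$converged, "\n")
  invisible(x)
}

.DROP <- function(C) C + 1L
.DEAD <- function(C) C + 2L

status_state <- function(status, C) {
  ifelse(status == "dropped", .DROP(C), ifelse(status == "dead", .DEAD(C), NA))
}

# Stack a panel + reduced features into the arrays the HMM routines use.
# Persons are indexed 1..N in order of first appearance; `lens[i]` counts the
# person's rows including a terminal absorbed observation.
build_hmm_data <- function(panel, X, C) {
  obs <- panel$observations[, c("person_id", "year", "status")]
  obs <- obs[order(obs$person_id, obs$year), ]
  ids <- unique(obs$person_id)
  drop0 <- ids[obs$status[match(ids, obs$person_id)] != "active"]
  if (length(drop0) > 0) {
    warning(length(drop0), " person(s) with no active years skipped")
    obs <- obs[!obs$person_id %in% drop0, ]
    ids <- setdiff(ids, drop0)
  }
  N <- length(ids)
  pidx <- match(obs$person_id, ids)
  lens <- tabulate(pidx, N)
  Tn <- max(obs$year) + 1L

  act <- obs$status == "active"
  Xdf <- as.data.frame(X)
  key_obs <- paste(obs$person_id, obs$year)
  key_X <- paste(Xdf$person_id, Xdf$year)
  mi <- match(key_obs[act], key_X)
  if (anyNA(mi)) stop("reduced features missing for some active person-years")
  Xact <- as.matrix(Xdf[mi, setdiff(names(Xdf), c("person_id", "year")),
                        drop = FALSE])
  list(N = N, Tn = Tn, ids = ids, lens = lens,
       act_pidx = pidx[act], act_year = obs$year[act], Xact = Xact,
       abs_pidx = pidx[!act], abs_year = obs$year[!act],
       abs_state = status_state(obs$status[!act], C))
}

# Per-cluster diagonal-Gaussian log density of each row of X.
gaussian_logdens <- function(X, means, vars) {
  C <- nrow(means)
  out <- matrix(0, nrow(X), C)
  for (c in seq_len(C)) {
    dev <- sweep(X, 2, means[c, ], `-`)
    out[, c] <- -0.5 * sum(log(2 * pi * vars[c, ])) -
      0.5 * rowSums(sweep(dev^2, 2, vars[c, ], `/`))
  }
  out
}

# Emission log-probability array [N, K, T]: Gaussian log densities for active
# person-years on disease-cluster states, indicator (log 1 / -Inf) for
# observed dropout/death, -Inf elsewhere.
emission_logB <- function(dat, params) {
  C <- params$C; K <- params$K
  logB <- array(-Inf, c(dat$N, K, dat$Tn))
  ld <- gaussian_logdens(dat$Xact, params$means, params$vars)
  for (c in seq_len(C)) {
    logB[cbind(dat$act_pidx, c, dat$act_year + 1L)] <- ld[, c]
  }
  if (length(dat$abs_pidx)) {
    logB[cbind(dat$abs_pidx, dat$abs_state, dat$abs_year + 1L)] <- 0
  }
  logB
}

# Scaled forward-backward over all sequences at once. Returns per-person
# log-likelihoods and, if `posteriors`, the smoothed state probabilities
# (gamma, [N, K, T]) and the summed transition posteriors (xi_sum, K x K).
forward_backward <- function(dat, params, posteriors = FALSE) {
  N <- dat$N; K <- params$K; Tn <- dat$Tn; C <- params$C
  logB <- emission_logB(dat, params)
  pi_full <- c(params$pi, 0, 0)
  A <- params$A
  alphahat <- array(NA_real_, c(N, K, Tn))
  Bs <- array(NA_real_, c(N, K, Tn))   # exp(logB - rowmax)
  logc <- matrix(NA_real_, N, Tn)      # log scale factors incl. rowmax
  loglik <- rep(0, N)

  for (t in seq_len(Tn)) {
    pres <- which(dat$lens >= t)
    if (length(pres) == 0) break
    w <- logB[pres, , t, drop = FALSE]; dim(w) <- c(length(pres), K)
    m <- apply(w, 1, max)
    B <- exp(w - m)
    Bs[pres, , t] <- B
    a <- if (t == 1) {
      B * rep(pi_full, each = length(pres))
    } else {
      prev <- alphahat[pres, , t - 1, drop = FALSE]
      dim(prev) <- c(length(pres), K)
      (prev %*% A) * B
    }
    ct <- rowSums(a)
    dead_seq <- ct <= 0
    ct[dead_seq] <- 1 # keep arithmetic finite; loglik becomes -Inf below
    alphahat[pres, , t] <- a / ct
    logc[pres, t] <- ifelse(dead_seq, -Inf, log(ct) + m)
    loglik[pres] <- loglik[pres] + logc[pres, t]
  }

  if (!posteriors) return(list(loglik = loglik))

  betahat <- array(NA_real_, c(N, K, Tn))
  for (i in seq_len(N)) betahat[i, , dat$lens[i]] <- 1
  xi_sum <- matrix(0, K, K)
  if (Tn > 1) {
    for (t in seq(Tn - 1, 1)) {
      pres <- which(dat$lens >= t + 1)
      if (length(pres) == 0) next
      bb <- betahat[pres, , t + 1, drop = FALSE]; dim(bb) <- c(length(pres), K)
      BB <- Bs[pres, , t + 1, drop = FALSE]; dim(BB) <- c(length(pres), K)
      tmp <- BB * bb / exp(logc[pres, t + 1] -
                             apply(logB[pres, , t + 1, drop = FALSE], 1, max,
                                   na.rm = TRUE))
      # tmp = B*beta / c with the rowmax cancelling; logc = log(c) + m
      betahat[pres, , t] <- tmp %*% t(A)
      aa <- alphahat[pres, , t, drop = FALSE]; dim(aa) <- c(length(pres), K)
      xi_sum <- xi_sum + A * crossprod(aa, tmp)
    }
  }
  gamma <- alphahat * betahat
  # normalize each person-year slice (guards accumulated rounding)
  for (t in seq_len(Tn)) {
    s <- rowSums(gamma[, , t, drop = FALSE][, , 1])
    gamma[, , t] <- gamma[, , t] / ifelse(is.na(s) | s == 0, 1, s)
  }
  list(loglik = loglik, gamma = gamma, xi_sum = xi_sum, logB = logB)
}

#' Log-likelihood of a single person-sequence
#'
#' Scaled-forward log-likelihood of one person's annual observation sequence
#' under the model: diagonal-Gaussian emission densities for active years and
#' an indicator emission for an observed terminal dropout/death. Returns
#' `-Inf` (with an attribute `"diagnostic"`) for sequences impossible under
#' the parameters rather than raising an error.
#'
#' @param params an `hmm_params`.
#' @param x matrix of reduced features, one row per active year in order.
#' @param status character vector, one entry per observed year (including a
#'   terminal `"dropped"`/`"dead"` year, which contributes no feature row).
#' @return scalar log-likelihood.
#' @export
sequence_loglik <- function(params, x, status = rep("active", nrow(x))) {
  x <- as.matrix(x)
  n_active <- sum(status == "active")
  if (n_active < 1) stop("sequence needs at least one active year")
  if (nrow(x) != n_active) {
    stop("x must have one row per active year (", n_active, ")")
  }
  nonactive <- which(status != "active")
  if (length(nonactive) > 0 &&
      (length(nonactive) > 1 || nonactive != length(status))) {
    stop("dropout/death must be a single terminal observation")
  }
  Tn <- length(status)
  dat <- list(N = 1L, Tn = Tn, ids = 1L, lens = Tn,
              act_pidx = rep(1L, n_active),
              act_year = seq_len(n_active) - 1L, Xact = x,
              abs_pidx = if (Tn > n_active) 1L else integer(0),
              abs_year = if (Tn > n_active) Tn - 1L else integer(0),
              abs_state = status_state(status[status != "active"], params$C))
  ll <- forward_backward(dat, params)$loglik
  if (!is.finite(ll)) {
    attr(ll, "diagnostic") <- "sequence has zero probability under params"
  }
  ll
}

#' Baum-Welch estimation over many short sequences
#'
#' Expectation-maximization for the absorbing-state HMM, treating each
#' person's five-wave sequence as an independent realization. The E-step
#' computes per-sequence posteriors by scaled forward-backward; the M-step
#' re-estimates the initial cluster probabilities (year-0 posteriors), the
#' disease-cluster rows of the transition matrix (including their mass into
#' dropout/death), and the Gaussian emission moments. The dropout and death
#' rows are never re-estimated: they remain exact one-hot self-loops, and
#' emission variances are floored at `init$var_floor`.
#'
#' @param panel a `cohort_panel`.
#' @param X reduced features from [assemble_features()] (or any data frame
#'   with `person_id`, `year` and score columns).
#' @param init starting `hmm_params`.
#' @param tol relative log-likelihood improvement at which to stop.
#' @param max_iter maximum EM iterations.
#' @param verbose print per-iteration log-likelihoods.
#' @return fitted `hmm_params` with `loglik`, `loglik_trace`, `converged`.
#' @export
baum_welch <- function(panel, X, init, tol = 1e-6, max_iter = 500,
                       verbose = FALSE) {
  stopifnot(inherits(init, "hmm_params"))
  C <- init$C
  dat <- build_hmm_data(panel, X, C)
  params <- init
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    fb <- forward_backward(dat, params, posteriors = TRUE)
    ll <- sum(fb$loglik)
    if (!is.finite(ll)) {
      stop("non-finite total log-likelihood at iteration ", it,
           " (", sum(!is.finite(fb$loglik)), " impossible sequence(s))")
    }
    trace <- c(trace, ll)
    if (verbose) message("iter ", it, " loglik ", format(ll))
    if (it > 1 && (ll - ll_old) < tol * abs(ll_old)) {
      params$loglik <- ll
      params$converged <- TRUE
      params$n_iter <- it
      params$loglik_trace <- trace
      return(params)
    }
    ll_old <- ll

    # M-step
    g1 <- fb$gamma[, seq_len(C), 1, drop = FALSE]
    dim(g1) <- c(dat$N, C)
    pi_new <- colSums(g1) / sum(g1)
    A_new <- params$A
    gsum_from <- rep(0, C)
    for (t in seq_len(dat$Tn - 1)) {
      pres <- dat$lens >= t + 1
      g <- fb$gamma[pres, seq_len(C), t, drop = FALSE]
      dim(g) <- c(sum(pres), C)
      gsum_from <- gsum_from + colSums(g)
    }
    for (c in seq_len(C)) {
      if (gsum_from[c] > 0) A_new[c, ] <- fb$xi_sum[c, ] / gsum_from[c]
      A_new[c, ] <- A_new[c, ] / sum(A_new[c, ])
    }

    W <- matrix(0, nrow(dat$Xact), C)
    for (c in seq_len(C)) {
      W[, c] <- fb$gamma[cbind(dat$act_pidx, c, dat$act_year + 1L)]
    }
    wsum <- colSums(W)
    if (any(wsum < 1e-10)) {
      stop("cluster ", which.min(wsum), " received no posterior mass; ",
           "reduce C or improve the initialization")
    }
    means_new <- crossprod(W, dat$Xact) / wsum
    vars_new <- matrix(0, C, ncol(dat$Xact))
    for (c in seq_len(C)) {
      dev <- sweep(dat$Xact, 2, means_new[c, ])
      vars_new[c, ] <- colSums(W[, c] * dev^2) / wsum[c]
    }
    if (any(vars_new < params$var_floor)) {
      warning("emission variance collapsed; floored at ", params$var_floor)
    }
    vars_new <- pmax(vars_new, params$var_floor)

    params <- hmm_params(pi = pi_new, A = A_new, means = means_new,
                         vars = vars_new, var_floor = params$var_floor,
                         seed = params$seed)
  }
  fb <- forward_backward(dat, params)
  params$loglik <- sum(fb$loglik)
  params$converged <- FALSE
  params$n_iter <- max_iter
  params$loglik_trace <- trace
  params
}

#' Fit the HMM with multiple seeded restarts
#'
#' Runs [baum_welch()] from the supplied initialization and from
#' `n_restarts - 1` jittered copies (seeded Gaussian noise on the emission
#' means and multiplicative noise on the living transition rows, which are
#' then renormalized; absorbing rows stay one-hot). Returns the fit with the
#' highest final log-likelihood — the model giving the highest probability of
#' the available data among local optima.
#'
#' @inheritParams baum_welch
#' @param n_restarts number of Baum-Welch realizations (>= 1).
#' @param seed seed controlling the jitter.
#' @param jitter_sd standard deviation of the mean jitter, in units of each
#'   component's emission SD.
#' @return best `hmm_params`, with `restart_logliks` listing every restart's
#'   final log-likelihood.
#' @export
fit_with_restarts <- function(panel, X, init, n_restarts = 10, seed = 1L,
                              tol = 1e-6, max_iter = 500, jitter_sd = 0.5) {
  stopifnot(n_restarts >= 1)
  fits <- vector("list", n_restarts)
  errs <- character(n_restarts)
  for (r in seq_len(n_restarts)) {
    start <- if (r == 1) init else jitter_init(init, derive_seed(seed, r),
                                               jitter_sd)
    fits[[r]] <- tryCatch(baum_welch(panel, X, start, tol = tol,
                                     max_iter = max_iter),
                          error = function(e) {
                            errs[r] <<- conditionMessage(e)
                            NULL
                          })
  }
  lls <- vapply(fits, function(f) if (is.null(f)) -Inf else f$loglik,
                numeric(1))
  if (all(!is.finite(lls))) {
    stop("all ", n_restarts, " restarts failed: ",
         paste(unique(errs[nzchar(errs)]), collapse = "; "))
  }
  best <- fits[[which.max(lls)]]
  best$restart_logliks <- lls
  best$seed <- as.integer(seed)
  best
}

jitter_init <- function(init, seed, jitter_sd) {
  set.seed(seed)
  C <- init$C
  means <- init$means +
    matrix(stats::rnorm(length(init$means), 0, jitter_sd), C) *
    sqrt(init$vars)
  A <- init$A
  for (c in seq_len(C)) {
    row <- A[c, ] * exp(stats::rnorm(init$K, 0, 0.3))
    A[c, ] <- row / sum(row)
  }
  pi <- init$pi * exp(stats::rnorm(C, 0, 0.3))
  hmm_params(pi = pi / sum(pi), A = A, means = means, vars = init$vars,
             var_floor = init$var_floor, seed = seed)
}

#' Viterbi decoding of individual trajectories
#'
#' Most-probable hidden-state path per person given the fitted model, by
#' dynamic programming in log space. Ties are broken toward the lowest state
#' index. Observed dropout/death years decode to the matching absorbing
#' state by construction of the indicator emissions.
#'
#' @param params fitted `hmm_params`.
#' @param panel a `cohort_panel`.
#' @param X reduced features.
#' @return object of class `trajectory_set`: data frame `person_id`, `year`,
#'   `state` (1..C clusters, C+1 dropout, C+2 death) with per-person decoded
#'   log-probabilities in `attr(, "logprob")` and `C` in `attr(, "C")`.
#' @export
viterbi_decode <- function(params, panel, X) {
  C <- params$C; K <- params$K
  dat <- build_hmm_data(panel, X, C)
  logB <- emission_logB(dat, params)
  logA <- log(params$A)
  log_pi <- log(c(params$pi, 0, 0))
  N <- dat$N; Tn <- dat$Tn

  delta <- matrix(rep(log_pi, each = N), N, K) + logB[, , 1]
  psi <- array(NA_integer_, c(N, K, Tn))
  deltas <- array(NA_real_, c(N, K, Tn))
  deltas[, , 1] <- delta
  if (Tn > 1) {
    for (t in 2:Tn) {
      pres <- which(dat$lens >= t)
      if (length(pres) == 0) break
      dprev <- deltas[pres, , t - 1, drop = FALSE]
      dim(dprev) <- c(length(pres), K)
      for (j in seq_len(K)) {
        cand <- dprev + rep(logA[, j], each = length(pres))
        best <- max.col(cand, ties.method = "first")
        psi[pres, j, t] <- best
        deltas[pres, j, t] <- cand[cbind(seq_along(pres), best)] +
          logB[pres, j, t]
      }
    }
  }
  states <- matrix(NA_integer_, N, Tn)
  logprob <- numeric(N)
  for (i in seq_len(N)) {
    L <- dat$lens[i]
    last <- deltas[i, , L]
    s <- which.max(last) # first max = lowest index on ties
    logprob[i] <- last[s]
    states[i, L] <- s
    if (L > 1) for (t in seq(L, 2)) states[i, t - 1] <- psi[i, states[i, t], t]
  }
  out <- data.frame(
    person_id = rep(dat$ids, dat$lens),
    year = unlist(lapply(dat$lens, function(l) seq_len(l) - 1L)),
    state = as.integer(t(states))[as.logical(t(!is.na(states)))]
  )
  structure(out, logprob = stats::setNames(logprob, dat$ids), C = C,
            class = c("trajectory_set", "data.frame"))
}

#' Decoded transition summary
#'
#' Cross-tabulates decoded states either year-over-year (`annual`) or
#' baseline-versus-final (`start_to_end`), the latter mirroring a
#' start-to-end trajectory table: each person's baseline cluster against the
#' state occupied at the end of follow-up (the absorbing state if the person
#' dropped out or died). Absorbing origins are structurally one-hot — once a
#' person is absorbed they remain so through the horizon — and are reported
#' as such (with their observed self-transition counts).
#'
#' @param trajectories a `trajectory_set`.
#' @param mode `"annual"` or `"start_to_end"`.
#' @param horizon number of waves; defaults to the maximum decoded year + 1.
#' @return list of class `transition_summary` with `counts`, `proportions`
#'   (rows sum to 1) and `mode`.
#' @export
transition_summary <- function(trajectories,
                               mode = c("annual", "start_to_end"),
                               horizon = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(trajectories, "trajectory_set"))
  if (nrow(trajectories) == 0) stop("empty trajectory set")
  C <- attr(trajectories, "C"); K <- C + 2L
  if (is.null(horizon)) horizon <- max(trajectories$year) + 1L
  tr <- trajectories[order(trajectories$person_id, trajectories$year), ]
  sp <- split(tr$state, tr$person_id)
  labels <- c(paste0("C", seq_len(C)), "Dropout", "Death")
  counts <- matrix(0, K, K, dimnames = list(labels, labels))
  if (mode == "annual") {
    for (s in sp) {
      # absorbed persons persist in the absorbing state through the horizon
      s_full <- c(s, rep(s[length(s)], horizon - length(s)))
      from <- s_full[-horizon]; to <- s_full[-1]
      for (k in seq_along(from)) counts[from[k], to[k]] <-
          counts[from[k], to[k]] + 1
    }
  } else {
    for (s in sp) counts[s[1], s[length(s)]] <- counts[s[1], s[length(s)]] + 1
  }
  props <- counts / pmax(rowSums(counts), 1)
  # structurally one-hot absorbing rows even when unvisited
  for (r in c(C + 1L, C + 2L)) {
    if (sum(counts[r, ]) == 0) props[r, r] <- 1
  }
  empty_living <- which(rowSums(counts[seq_len(C), , drop = FALSE]) == 0)
  for (r in empty_living) props[r, ] <- NA_real_
  structure(list(counts = counts, proportions = props, mode = mode),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("<transition_summary> mode:", x$mode, "\n")
  print(round(100 * x$proportions, 1))
  invisible(x)
}

#' Compare fitted and decoded transition probabilities
#'
#' Model-validation table contrasting the Baum-Welch transition matrix with
#' the annual proportions observed in the Viterbi-decoded trajectories; good
#' agreement indicates the fitted dynamics describe the decoded ones.
#'
#' @param params fitted `hmm_params`.
#' @param trajectories decoded `trajectory_set` from the same data.
#' @return list with `table` (from, to, model, decoded, abs_diff) and
#'   `max_abs_diff`.
#' @export
validate_bw_vs_decoded <- function(params, trajectories) {
  ts <- transition_summary(trajectories, "annual")
  K <- params$K
  dec <- ts$proportions
  tab <- data.frame(
    from = rep(rownames(dec), K),
    to = rep(colnames(dec), each = K),
    model = as.vector(params$A),
    decoded = as.vector(dec)
  )
  tab$abs_diff <- abs(tab$model - tab$decoded)
  list(table = tab, max_abs_diff = max(tab$abs_diff, na.rm = TRUE))
}

#' Simulate observation sequences directly from HMM parameters
#'
#' Samples latent paths from `pi` and `A` and Gaussian emissions from the
#' cluster distributions, producing a minimal panel + feature pair suitable
#' for [viterbi_decode()] and [baum_welch()]. Used for model-based
#' self-consistency checks.
#'
#' @param params an `hmm_params`.
#' @param n number of persons.
#' @param n_years horizon T.
#' @param seed RNG seed.
#' @return list with `panel` (a minimal `cohort_panel`), `X` (a
#'   `reduced_features` data frame) and `states` (true latent paths, rows =
#'   persons).
#' @export
simulate_from_hmm <- function(params, n, n_years = 5, seed = 1L) {
  set.seed(seed)
  C <- params$C; K <- params$K; p <- ncol(params$means)
  states <- matrix(NA_integer_, n, n_years)
  states[, 1] <- sample.int(C, n, replace = TRUE, prob = params$pi)
  if (n_years > 1) {
    for (t in 2:n_years) {
      cur <- states[, t - 1]
      nxt <- cur
      for (s in seq_len(C)) {
        idx <- which(cur == s)
        if (length(idx)) nxt[idx] <- sample.int(K, length(idx), TRUE,
                                                prob = params$A[s, ])
      }
      states[, t] <- nxt
    }
  }
  rows <- list(); xrows <- list()
  for (i in seq_len(n)) {
    path <- states[i, ]
    stop_at <- which(path > C)[1]
    L <- if (is.na(stop_at)) n_years else stop_at
    status <- ifelse(path[seq_len(L)] <= C, "active",
                     ifelse(path[seq_len(L)] == C + 1L, "dropped", "dead"))
    rows[[i]] <- data.frame(person_id = i, year = seq_len(L) - 1L,
                            status = status)
    act <- which(status == "active")
    xm <- params$means[path[act], , drop = FALSE] +
      matrix(stats::rnorm(length(act) * p), length(act), p) *
      sqrt(params$vars[path[act], , drop = FALSE])
    xrows[[i]] <- data.frame(person_id = i, year = act - 1L,
                             as.data.frame(xm))
  }
  obs <- do.call(rbind, rows)
  X <- do.call(rbind, xrows)
  names(X) <- c("person_id", "year", paste0("f", seq_len(p)))
  class(X) <- c("reduced_features", "data.frame")
  panel <- structure(list(observations = obs,
                          persons = data.frame(person_id = seq_len(n)),
                          ground_truth = data.frame(
                            person_id = obs$person_id, year = obs$year,
                            state = states[cbind(obs$person_id, obs$year + 1L)]),
                          n_clusters = C, n_diseases = 0L,
                          n_years = n_years, disease_cols = character(0)),
                     class = "cohort_panel")
  list(panel = panel, X = X, states = states)
}

#' Serialize fitted HMM parameters to JSON
#' @param params an `hmm_params`.
#' @param path output path.
#' @export
hmm_to_json <- function(params, path) {
  jsonlite::write_json(list(
    C = params$C, pi = params$pi, A = params$A, means = params$means,
    vars = params$vars, var_floor = params$var_floor,
    loglik = params$loglik, n_iter = params$n_iter,
    converged = params$converged, seed = params$seed,
    restart_logliks = params$restart_logliks
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read fitted HMM parameters from JSON
#' @param path JSON path written by [hmm_to_json()].
#' @export
hmm_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  hmm_params(pi = j$pi, A = j$A, means = j$means, vars = j$vars,
             var_floor = j$var_floor, loglik = j$loglik,
             converged = j$converged, n_iter = j$n_iter,
             restart_logliks = j$restart_logliks, seed = j$seed)
}
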