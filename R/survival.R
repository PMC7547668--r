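#' Build per-person survival records from a decoded panel
#'
#' One record per person: time from risk start to death or censoring,
#' the event indicator, the baseline decoded cluster, and the adjustment
#' covariates (baseline age, sex, SES quintile). The panel is annual, so a
#' death observed in year t is assigned continuous time `t - 0.5` (mid-year
#' convention) or `t` (`"year_end"`); dropouts are censored at their dropout
#' year and survivors administratively at the horizon.
#'
#' @param panel a `cohort_panel`.
#' @param trajectories decoded `trajectory_set` (baseline states are read
#'   from year 0).
#' @param death_time `"mid_year"` (default) or `"year_end"`.
#' @return data frame of class `survival_records`: `person_id, time, event,
#'   baseline_cluster, age, sex, ses_quintile`.
#' @export
build_survival_records <- function(panel, trajectories,
                                   death_time = c("mid_year", "year_end")) {
  death_time <- match.arg(death_time)
  stopifnot(inherits(panel, "cohort_panel"))
  C <- attr(trajectories, "C")
  obs <- panel$observations[order(panel$observations$person_id,
                                  panel$observations$year), ]
  last <- obs[!duplicated(obs$person_id, fromLast = TRUE), ]
  horizon <- max(obs$year) + 1L

  key <- paste(trajectories$person_id, trajectories$year)
  base_state <- trajectories$state[match(paste(last$person_id, 0), key)]
  bad <- is.na(base_state) | base_state > C
  if (any(bad)) {
    warning(sum(bad), " person(s) absorbed or undecoded at baseline excluded")
    last <- last[!bad, ]; base_state <- base_state[!bad]
  }
  time <- ifelse(last$status == "dead",
                 last$year - if (death_time == "mid_year") 0.5 else 0,
                 ifelse(last$status == "dropped", last$year, horizon))
  rec <- data.frame(
    person_id = last$person_id,
    time = as.numeric(time),
    event = as.integer(last$status == "dead"),
    baseline_cluster = as.integer(base_state),
    stringsAsFactors = FALSE
  )
  per <- panel$persons
  rec$age <- per$baseline_age[match(rec$person_id, per$person_id)]
  rec$sex <- per$sex[match(rec$person_id, per$person_id)]
  rec$ses_quintile <- per$ses_quintile[match(rec$person_id, per$person_id)]
  stopifnot(all(rec$time > 0))
  class(rec) <- c("survival_records", "data.frame")
  rec
}

#' Cox proportional-hazards fit of pattern-specific mortality
#'
#' Partial-likelihood fit (Breslow tie handling by default, Efron available)
#' of all-cause mortality on the baseline multimorbidity cluster, with
#' cluster 1 as the reference, optionally adjusted for baseline age, sex,
#' and SES quintile (quintile 1 reference).
#'
#' @param records a `survival_records` data frame with no missing values in
#'   the requested covariates (run per completed dataset under imputation).
#' @param covariates `"cluster"` for the unadjusted model or a character
#'   vector adding `"age"`, `"sex"`, `"ses"`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return data frame `term, estimate, se` (log-hazard scale) with the fitted
#'   `coxph` object in `attr(, "fit")`.
#' @export
fit_cox <- function(records, covariates = "cluster",
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(sum(records$event) >= 1)
  df <- as.data.frame(records)
  df$cluster <- factor(df$baseline_cluster,
                       levels = sort(unique(df$baseline_cluster)))
  terms <- "cluster"
  if ("age" %in% covariates) terms <- c(terms, "age")
  if ("sex" %in% covariates) { df$sex <- factor(df$sex); terms <- c(terms, "sex") }
  if ("ses" %in% covariates) {
    if (anyNA(df$ses_quintile)) {
      stop("ses_quintile has missing values; impute first (impute_chained)")
    }
    df$ses <- droplevels(factor(df$ses_quintile, levels = 1:5))
    terms <- c(terms, "ses")
  }
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(terms, collapse = " + ")))
  fit <- survival::coxph(f, data = df, ties = ties)
  cf <- stats::coef(fit)
  aliased <- !is.finite(cf)
  if (any(aliased)) {
    if (any(aliased & startsWith(names(cf), "cluster"))) {
      stop("Cox model failed: non-finite cluster coefficient (",
           paste(names(cf)[aliased], collapse = ", "), ")")
    }
    warning("dropping aliased covariate(s): ",
            paste(names(cf)[aliased], collapse = ", "))
  }
  ev_by_cluster <- tapply(df$event, df$cluster, sum)
  if (any(ev_by_cluster == 0)) {
    warning("cluster(s) with zero events: unstable coefficient(s) for ",
            paste(names(ev_by_cluster)[ev_by_cluster == 0], collapse = ", "))
  }
  keep <- which(!aliased)
  out <- data.frame(term = names(cf)[keep],
                    estimate = as.numeric(cf[keep]),
                    se = sqrt(diag(stats::vcov(fit))[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Chained-equation imputation of missing SES quintiles
#'
#' Multiple imputation for the socio-economic quintile (the only incomplete
#' variable in scope). Each of the `m` imputations refits a proportional-odds
#' model for SES on age, sex, baseline cluster, the event indicator and a
#' Nelson-Aalen cumulative-hazard proxy, on a bootstrap resample of the
#' complete rows (approximating a posterior draw of the model parameters),
#' and draws each missing quintile from the fitted conditional distribution.
#' Observed values are never altered. With no missing values the `m` returned
#' sets are identical copies of the input.
#'
#' @param records a `survival_records` data frame.
#' @param m number of imputed datasets (default 7).
#' @param seed RNG seed.
#' @return list of `m` completed data frames.
#' @export
impute_chained <- function(records, m = 7, seed = 1L) {
  stopifnot(m >= 2)
  df <- as.data.frame(records)
  miss <- is.na(df$ses_quintile)
  if (all(miss)) stop("ses_quintile is 100% missing; nothing to condition on")
  if (!any(miss)) return(replicate(m, df, simplify = FALSE))
  set.seed(seed)

  # Nelson-Aalen cumulative hazard at each person's exit time
  na_est <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
  H <- stats::stepfun(na_est$time, c(0, cumsum(na_est$n.event /
                                                 na_est$n.risk)))
  df$cumhaz <- H(df$time)
  df$clusterF <- factor(df$baseline_cluster)
  df$sexF <- factor(df$sex)
  obs_rows <- which(!miss)

  out <- vector("list", m)
  for (k in seq_len(m)) {
    boot <- df[sample(obs_rows, length(obs_rows), replace = TRUE), ]
    boot$sesF <- factor(boot$ses_quintile, levels = 1:5, ordered = TRUE)
    probs <- tryCatch({
      rhs <- c("age", "cumhaz", "event",
               if (nlevels(droplevels(boot$sexF)) > 1) "sexF",
               if (nlevels(droplevels(boot$clusterF)) > 1) "clusterF")
      fit <- MASS::polr(stats::as.formula(
        paste("sesF ~", paste(rhs, collapse = " + "))), data = boot)
      stats::predict(fit, newdata = df[miss, , drop = FALSE], type = "probs")
    }, error = function(e) {
      # degenerate bootstrap sample: fall back to its empirical distribution
      p <- tabulate(boot$ses_quintile, 5) / nrow(boot)
      matrix(p, sum(miss), 5, byrow = TRUE)
    })
    if (is.null(dim(probs))) probs <- matrix(probs, 1)
    drawn <- apply(probs, 1, function(p) sample.int(5L, 1, prob = p))
    comp <- df[, setdiff(names(df), c("cumhaz", "clusterF", "sexF"))]
    comp$ses_quintile[miss] <- as.integer(drawn)
    out[[k]] <- comp
  }
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled point estimate = mean of the per-imputation estimates; within
#' variance = mean squared SE; between variance = sample variance of the
#' estimates; total variance = within + (1 + 1/m) between. Confidence
#' intervals use a t reference with Rubin's degrees of freedom
#' (normal when the between component is zero).
#'
#' @param estimates numeric matrix (m x q) or vector of per-imputation
#'   point estimates (log-hazard scale).
#' @param ses matching matrix/vector of standard errors.
#' @param conf confidence level (default 0.95).
#' @return data frame of class `pooled_hazard`: `term, estimate, hr, se,
#'   ci_lower, ci_upper` (HR scale), `within, between, total, df, m`.
#' @export
pool_rubin <- function(estimates, ses, conf = 0.95) {
  est <- as.matrix(estimates); se <- as.matrix(ses)
  if (!all(dim(est) == dim(se))) stop("estimates and SEs have mismatched dimensions")
  m <- nrow(est)
  if (m < 2) stop("Rubin pooling needs m >= 2 imputations")
  qbar <- colMeans(est)
  within <- colMeans(se^2)
  between <- apply(est, 2, stats::var)
  total <- within + (1 + 1 / m) * between
  r <- (1 + 1 / m) * between / within
  df <- ifelse(between > 0, (m - 1) * (1 + 1 / r)^2, Inf)
  tq <- ifelse(is.finite(df), stats::qt(1 - (1 - conf) / 2, df),
               stats::qnorm(1 - (1 - conf) / 2))
  terms <- colnames(est)
  if (is.null(terms)) terms <- paste0("term", seq_along(qbar))
  out <- data.frame(
    term = terms, estimate = qbar, hr = exp(qbar), se = sqrt(total),
    ci_lower = exp(qbar - tq * sqrt(total)),
    ci_upper = exp(qbar + tq * sqrt(total)),
    within = within, between = between, total = total, df = df, m = m,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("pooled_hazard", "data.frame")
  out
}

#' Pattern-specific mortality hazards with multiple imputation
#'
#' The full survival stage: unadjusted Cox fit, complete-case adjusted fit,
#' and the multiply-imputed adjusted fit pooled by Rubin's rules, mirroring
#' the unadjusted / adjusted (complete cases) / adjusted (multiple
#' imputation) presentation of pattern mortality tables.
#'
#' @param records a `survival_records` data frame.
#' @param m number of imputations (default 7).
#' @param seed RNG seed for the imputation draws.
#' @param ties tie handling passed to [fit_cox()].
#' @return list with `unadjusted`, `adjusted_complete_case` (both
#'   term/estimate/se tables with HR columns added) and `adjusted_mi`
#'   (a `pooled_hazard` table).
#' @export
hazard_table <- function(records, m = 7, seed = 1L, ties = "breslow") {
  unadj <- fit_cox(records, "cluster", ties = ties)
  cc <- records[!is.na(records$ses_quintile), , drop = FALSE]
  adj_cc <- fit_cox(cc, c("cluster", "age", "sex", "ses"), ties = ties)
  imp <- impute_chained(records, m = m, seed = seed)
  fits <- lapply(imp, fit_cox, covariates = c("cluster", "age", "sex", "ses"),
                 ties = ties)
  est <- do.call(rbind, lapply(fits, function(f) stats::setNames(f$estimate,
                                                                 f$term)))
  sem <- do.call(rbind, lapply(fits, function(f) f$se))
  colnames(sem) <- colnames(est)
  pooled <- pool_rubin(est, sem)
  add_hr <- function(tab, conf = 0.95) {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    tab$hr <- exp(tab$estimate)
    tab$ci_lower <- exp(tab$estimate - z * tab$se)
    tab$ci_upper <- exp(tab$estimate + z * tab$se)
    tab
  }
  list(unadjusted = add_hr(unadj), adjusted_complete_case = add_hr(adj_cc),
       adjusted_mi = pooled, m = m)
}
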