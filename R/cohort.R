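#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model for a closed elderly cohort observed over
#' `n_years` annual waves: a latent multimorbidity-cluster process with
#' mostly-diagonal annual transitions and two absorbing states (dropout,
#' death), cluster-specific chronic-disease prevalences, Poisson utilization
#' counts, deterministic ageing, and socio-economic quintiles with
#' missingness.
#'
#' The latent state space has `n_clusters + 2` states: disease clusters
#' `1..C`, dropout `C + 1`, death `C + 2`. The last two rows of
#' `annual_transition` must be exact one-hot self-loops.
#'
#' @param n_persons number of persons at baseline (no new entries later).
#' @param n_clusters number of disease clusters C.
#' @param n_diseases number of chronic disease indicators D.
#' @param n_years number of annual waves T (default 5).
#' @param baseline_age_mean,baseline_age_sd baseline age distribution (years).
#' @param cluster_disease_prevalence C x D matrix of baseline prevalence
#'   probabilities per cluster.
#' @param cluster_visit_rates,cluster_drug_rates length-C vectors of per-year
#'   Poisson means for primary-care visits and distinct invoiced drugs.
#' @param init_probs length-C baseline cluster probabilities (sum to 1).
#' @param annual_transition (C+2) x (C+2) row-stochastic annual transition
#'   matrix; rows C+1 (dropout) and C+2 (death) must be exact one-hot.
#' @param female_fraction probability of female sex.
#' @param ses_missing_fraction probability that the socio-economic quintile is
#'   missing (default 0.07).
#' @param ses_missing_mode `"mcar"` (default) or `"mar"`; under `"mar"` the
#'   missingness probability scales linearly with the baseline cluster index
#'   while keeping the marginal rate at `ses_missing_fraction`.
#' @param cluster_log_hazard length-C log-hazard offsets multiplying the
#'   death-transition probability of each cluster (then renormalized).
#' @param annual_incidence_factor per-year onset probability of a not-yet
#'   present disease, as a multiple of its cluster prevalence; 0 freezes the
#'   baseline flags (chronic flags are always monotone non-decreasing).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_persons = 100, n_clusters = 2, n_diseases = 6,
#'                      seed = 1)
#' panel <- generate_cohort(cfg)
#' @export
cohort_config <- function(n_persons,
                          n_clusters,
                          n_diseases,
                          n_years = 5,
                          baseline_age_mean = 75.4,
                          baseline_age_sd = 7.4,
                          cluster_disease_prevalence = NULL,
                          cluster_visit_rates = NULL,
                          cluster_drug_rates = NULL,
                          init_probs = NULL,
                          annual_transition = NULL,
                          female_fraction = 0.577,
                          ses_missing_fraction = 0.07,
                          ses_missing_mode = c("mcar", "mar"),
                          cluster_log_hazard = NULL,
                          annual_incidence_factor = 0.1,
                          seed = 1L) {
  C <- as.integer(n_clusters); D <- as.integer(n_diseases)
  Tn <- as.integer(n_years)
  stopifnot(n_persons >= 1, C >= 1, D >= 1, Tn >= 1)
  ses_missing_mode <- match.arg(ses_missing_mode)

  if (is.null(cluster_disease_prevalence)) {
    cluster_disease_prevalence <- default_prevalence(C, D)
  }
  cluster_disease_prevalence <- as.matrix(cluster_disease_prevalence)
  if (!all(dim(cluster_disease_prevalence) == c(C, D))) {
    stop("cluster_disease_prevalence must be a ", C, " x ", D, " matrix")
  }
  if (any(cluster_disease_prevalence < 0 | cluster_disease_prevalence > 1)) {
    stop("cluster_disease_prevalence entries must lie in [0, 1]")
  }
  # default utilization gradients: sicker clusters consult more and take
  # more drugs (per-cluster medians spanning roughly 6-18 visits, 3-8 drugs)
  if (is.null(cluster_visit_rates)) {
    cluster_visit_rates <- if (C > 1) seq(6, 18, length.out = C) else 8
  }
  if (is.null(cluster_drug_rates)) {
    cluster_drug_rates <- if (C > 1) seq(3, 8, length.out = C) else 4
  }
  if (is.null(init_probs)) init_probs <- rep(1 / C, C)
  if (is.null(cluster_log_hazard)) cluster_log_hazard <- rep(0, C)
  stopifnot(length(cluster_visit_rates) == C, all(cluster_visit_rates > 0),
            length(cluster_drug_rates) == C, all(cluster_drug_rates > 0),
            length(init_probs) == C, abs(sum(init_probs) - 1) < 1e-9,
            length(cluster_log_hazard) == C,
            female_fraction >= 0, female_fraction <= 1,
            ses_missing_fraction >= 0, ses_missing_fraction <= 1,
            annual_incidence_factor >= 0)

  if (is.null(annual_transition)) {
    annual_transition <- default_transition(C, self = 0.85,
                                            dropout = 0.02, death = 0.03)
  }
  annual_transition <- as.matrix(annual_transition)
  K <- C + 2L
  if (!all(dim(annual_transition) == c(K, K))) {
    stop("annual_transition must be a ", K, " x ", K, " matrix")
  }
  check_row_stochastic(annual_transition)
  for (r in c(C + 1L, C + 2L)) {
    one_hot <- as.numeric(seq_len(K) == r)
    if (!identical(as.numeric(annual_transition[r, ]), one_hot)) {
      stop("annual_transition row ", r,
           " (absorbing state) must be an exact one-hot self-transition")
    }
  }

  structure(list(
    n_persons = as.integer(n_persons), n_clusters = C, n_diseases = D,
    n_years = Tn,
    baseline_age_mean = baseline_age_mean, baseline_age_sd = baseline_age_sd,
    cluster_disease_prevalence = cluster_disease_prevalence,
    cluster_visit_rates = cluster_visit_rates,
    cluster_drug_rates = cluster_drug_rates,
    init_probs = init_probs, annual_transition = annual_transition,
    female_fraction = female_fraction,
    ses_missing_fraction = ses_missing_fraction,
    ses_missing_mode = ses_missing_mode,
    cluster_log_hazard = cluster_log_hazard,
    annual_incidence_factor = annual_incidence_factor,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Well-separated default prevalence profiles: each cluster gets a contiguous
# block of "nuclear" diseases at high prevalence over a low background.
default_prevalence <- function(C, D, high = 0.6, low = 0.05) {
  P <- matrix(low, C, D)
  block <- max(1L, D %/% C)
  for (c in seq_len(C)) {
    idx <- ((c - 1L) * block + 1L):min(c * block, D)
    P[c, idx] <- high
  }
  P
}

#' Build a diagonal-dominant annual transition matrix with absorbing states
#'
#' @param C number of disease clusters.
#' @param self self-transition probability of each disease cluster.
#' @param dropout,death per-year probabilities of transitioning to the
#'   absorbing dropout/death states.
#' @return a (C+2) x (C+2) row-stochastic matrix; rows C+1 and C+2 one-hot.
#' @export
default_transition <- function(C, self = 0.85, dropout = 0.02, death = 0.03) {
  K <- C + 2L
  A <- matrix(0, K, K)
  off <- 1 - self - dropout - death
  if (off < -1e-12) stop("self + dropout + death exceeds 1")
  for (c in seq_len(C)) {
    A[c, seq_len(C)] <- if (C > 1) off / (C - 1) else 0
    A[c, c] <- self + if (C == 1) off else 0
    A[c, C + 1L] <- dropout
    A[c, C + 2L] <- death
  }
  A[C + 1L, C + 1L] <- 1
  A[C + 2L, C + 2L] <- 1
  A
}

#' Generate a synthetic cohort panel
#'
#' Samples a closed cohort according to a [cohort_config()]: a latent cluster
#' path per person from `init_probs` and `annual_transition` (with the
#' cluster's mortality offset applied multiplicatively to the death
#' transition and the row renormalized), monotone chronic-disease flags whose
#' year-0 cross-section matches `cluster_disease_prevalence`, Poisson visit
#' and drug counts, deterministic ageing, and SES quintiles with missingness.
#' Persons absorbed at year t contribute a final observation at year t with
#' status `"dropped"` or `"dead"` and nothing afterwards.
#'
#' @param config a [cohort_config()].
#' @return an object of class `cohort_panel`: a list with `observations` (one
#'   row per person-year), `persons` (one row per person), and `ground_truth`
#'   (latent state per person-year, states `1..C` clusters, `C+1` dropout,
#'   `C+2` death).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_persons; C <- config$n_clusters; D <- config$n_diseases
  Tn <- config$n_years; K <- C + 2L
  A <- config$annual_transition
  prev <- config$cluster_disease_prevalence
  dnames <- disease_names(D)

  # persons table
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  ses <- sample.int(5L, n, replace = TRUE)
  state0 <- sample.int(C, n, replace = TRUE, prob = config$init_probs)
  miss_p <- rep(config$ses_missing_fraction, n)
  if (config$ses_missing_mode == "mar" && C > 1) {
    # linear in baseline cluster index, rescaled to the marginal rate
    w <- state0 / mean(state0)
    miss_p <- pmin(1, config$ses_missing_fraction * w)
  }
  ses[stats::runif(n) < miss_p] <- NA_integer_
  age0 <- round(stats::rnorm(n, config$baseline_age_mean,
                             config$baseline_age_sd), 1)

  # latent paths, with the cluster mortality modifier applied per draw
  states <- matrix(NA_integer_, n, Tn)
  states[, 1] <- state0
  if (Tn > 1) {
    for (t in 2:Tn) {
      cur <- states[, t - 1]
      nxt <- cur # absorbing states stay (but absorbed persons get no row)
      for (c in seq_len(C)) {
        idx <- which(cur == c)
        if (length(idx) == 0) next
        row <- A[c, ]
        row[C + 2L] <- row[C + 2L] * exp(config$cluster_log_hazard[c])
        row <- row / sum(row)
        nxt[idx] <- sample.int(K, length(idx), replace = TRUE, prob = row)
      }
      states[, t] <- nxt
    }
  }

  # disease flags: year-0 cross-section Bernoulli(prev), then monotone onset
  flags <- matrix(0L, n, D)
  flags[] <- as.integer(stats::runif(n * D) < prev[states[, 1], ])
  obs_list <- vector("list", Tn)
  active <- rep(TRUE, n) # still contributing rows
  for (t in seq_len(Tn)) {
    st <- states[, t]
    if (t > 1) {
      # onset only for persons still in a disease cluster this year
      live <- active & st <= C
      if (any(live) && config$annual_incidence_factor > 0) {
        p_on <- config$annual_incidence_factor * prev[pmin(st, C), ]
        onset <- (flags == 0L) & live &
          (matrix(stats::runif(n * D), n, D) < p_on)
        flags[onset] <- 1L
      }
    }
    status <- ifelse(st <= C, "active", ifelse(st == C + 1L, "dropped", "dead"))
    absorbed_now <- active & st > C
    keep <- active
    visits <- integer(n); drugs <- integer(n)
    live_idx <- which(keep & st <= C)
    if (length(live_idx)) {
      visits[live_idx] <- stats::rpois(length(live_idx),
                                       config$cluster_visit_rates[st[live_idx]])
      drugs[live_idx] <- stats::rpois(length(live_idx),
                                      config$cluster_drug_rates[st[live_idx]])
    }
    ob <- data.frame(person_id = which(keep),
                     year = t - 1L,
                     status = status[keep],
                     age = age0[keep] + (t - 1L),
                     visits = visits[keep],
                     drugs = drugs[keep],
                     stringsAsFactors = FALSE)
    fl <- flags[keep, , drop = FALSE]
    colnames(fl) <- dnames
    obs_list[[t]] <- cbind(ob, as.data.frame(fl))
    active <- active & st <= C
  }
  observations <- do.call(rbind, obs_list)
  observations <- observations[order(observations$person_id,
                                     observations$year), ]
  rownames(observations) <- NULL

  persons <- data.frame(person_id = seq_len(n), sex = sex,
                        ses_quintile = ses, baseline_age = age0,
                        stringsAsFactors = FALSE)

  gt <- observations[, c("person_id", "year")]
  gt$state <- states[cbind(gt$person_id, gt$year + 1L)]

  structure(list(observations = observations, persons = persons,
                 ground_truth = gt, n_clusters = C, n_diseases = D,
                 n_years = Tn, disease_cols = dnames),
            class = "cohort_panel")
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat("<cohort_panel>\n")
  cat("  persons:      ", nrow(x$persons), "\n")
  cat("  person-years: ", nrow(x$observations), "\n")
  cat("  diseases:     ", length(x$disease_cols), "\n")
  cat("  years:        ", x$n_years, "\n")
  st <- table(x$observations$status)
  cat("  final status rows:",
      paste(names(st), as.integer(st), collapse = ", "), "\n")
  invisible(x)
}

#' Write a cohort panel to CSV
#'
#' One row per person-year with columns `person_id, year, status, age,
#' visits, drugs, sex, ses_quintile` (empty field = missing), an optional
#' `true_state` column when ground truth is present, and the disease flag
#' columns `d_0001...`.
#'
#' @param panel a `cohort_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "cohort_panel"))
  df <- merge(panel$observations,
              panel$persons[, c("person_id", "sex", "ses_quintile")],
              by = "person_id", sort = FALSE)
  front <- c("person_id", "year", "status", "age", "visits", "drugs",
             "sex", "ses_quintile")
  if (!is.null(panel$ground_truth)) {
    df <- merge(df, panel$ground_truth, by = c("person_id", "year"),
                sort = FALSE)
    names(df)[names(df) == "state"] <- "true_state"
    front <- c(front, "true_state")
  }
  df <- df[order(df$person_id, df$year), c(front, panel$disease_cols)]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort panel from CSV
#'
#' Inverse of [write_panel()]; validates the schema and reconstructs the
#' per-person table from year-0 rows.
#'
#' @param path CSV file path.
#' @return a `cohort_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty file: ", path, " is not a panel")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty file: ", path, " has no panel rows")
  required <- c("person_id", "year", "status", "age", "visits", "drugs",
                "sex", "ses_quintile")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("panel file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dcols <- grep("^d_\\d+$", names(df), value = TRUE)
  if (length(dcols) == 0) stop("panel file has no disease columns (d_XXXX)")
  bad <- which(!df$status %in% c("active", "dropped", "dead"))
  if (length(bad) > 0) {
    stop("malformed status value at line ", bad[1] + 1L,
         " (", df$status[bad[1]], ")")
  }
  bad <- which(is.na(df$year) | df$year < 0 | df$year != round(df$year))
  if (length(bad) > 0) stop("malformed year at line ", bad[1] + 1L)
  df <- df[order(df$person_id, df$year), ]

  base <- df[df$year == 0, ]
  if (!all(unique(df$person_id) %in% base$person_id)) {
    stop("panel violates the closed-cohort invariant: some persons lack a ",
         "year-0 row")
  }
  persons <- data.frame(person_id = base$person_id, sex = base$sex,
                        ses_quintile = base$ses_quintile,
                        baseline_age = base$age, stringsAsFactors = FALSE)
  gt <- NULL
  if ("true_state" %in% names(df)) {
    gt <- data.frame(person_id = df$person_id, year = df$year,
                     state = df$true_state)
  }
  obs <- df[, c("person_id", "year", "status", "age", "visits", "drugs",
                dcols)]
  rownames(obs) <- NULL
  structure(list(observations = obs, persons = persons, ground_truth = gt,
                 n_clusters = NA_integer_, n_diseases = length(dcols),
                 n_years = max(df$year) + 1L, disease_cols = dcols),
            class = "cohort_panel")
}
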