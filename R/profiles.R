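#' Multimorbidity pattern profile for one year
#'
#' For every (cluster, disease) pair among the persons active in the given
#' year: the within-cluster prevalence O (%), the overall prevalence in the
#' active population (%), the observed/expected ratio O/E (cluster prevalence
#' over overall prevalence), the exclusivity E (% of all patients with the
#' disease who are in the cluster), and the pattern-membership call
#' (O/E-ratio at or above `oe_threshold`, default 2). Absorbed persons are
#' excluded from all denominators: after dropout or death a person ceases to
#' contribute to the dynamic characterization of the patterns. Setting
#' `denominator = "baseline"` instead keeps the year-0 cohort as denominator.
#'
#' @param panel a `cohort_panel`.
#' @param trajectories decoded `trajectory_set`.
#' @param year wave index (0-based).
#' @param oe_threshold O/E ratio at which a disease belongs to the pattern.
#' @param denominator `"active"` (default) or `"baseline"`.
#' @return data frame: `year, cluster, disease, n_cluster, O,
#'   overall_prevalence, oe_ratio, exclusivity, in_pattern`; `oe_ratio` is
#'   `NA` (undefined, not infinite) when the overall prevalence is zero.
#' @export
compute_profile <- function(panel, trajectories, year, oe_threshold = 2,
                            denominator = c("active", "baseline")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(panel, "cohort_panel"),
            inherits(trajectories, "trajectory_set"))
  C <- attr(trajectories, "C")
  if (year < 0 || year > max(panel$observations$year)) {
    stop("year ", year, " is outside the panel horizon")
  }
  obs <- panel$observations
  key <- paste(trajectories$person_id, trajectories$year)
  if (denominator == "active") {
    rows <- obs[obs$year == year & obs$status == "active", , drop = FALSE]
    st <- trajectories$state[match(paste(rows$person_id, year), key)]
  } else {
    # whole baseline cohort, classified by baseline decoded cluster; persons
    # absorbed by `year` contribute their last observed flags
    last <- obs[obs$year <= year, ]
    last <- last[order(last$person_id, last$year), ]
    rows <- last[!duplicated(last$person_id, fromLast = TRUE), , drop = FALSE]
    st <- trajectories$state[match(paste(rows$person_id, 0), key)]
  }
  keep <- !is.na(st) & st <= C
  rows <- rows[keep, , drop = FALSE]; st <- st[keep]
  if (nrow(rows) == 0) stop("no decoded active persons in year ", year)

  flags <- as.matrix(rows[, panel$disease_cols, drop = FALSE])
  n_total <- nrow(flags)
  overall_n <- colSums(flags)
  overall_prev <- 100 * overall_n / n_total

  out <- vector("list", C)
  for (c in seq_len(C)) {
    inc <- st == c
    n_c <- sum(inc)
    case_c <- if (n_c > 0) colSums(flags[inc, , drop = FALSE]) else
      rep(0, ncol(flags))
    O <- if (n_c > 0) 100 * case_c / n_c else rep(NA_real_, ncol(flags))
    oe <- ifelse(overall_n > 0, O / overall_prev, NA_real_)
    excl <- ifelse(overall_n > 0, 100 * case_c / overall_n, NA_real_)
    out[[c]] <- data.frame(
      year = year, cluster = c, disease = panel$disease_cols,
      n_cluster = n_c, O = O, overall_prevalence = overall_prev,
      oe_ratio = oe, exclusivity = excl,
      in_pattern = !is.na(oe) & oe >= oe_threshold,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Longitudinal pattern profiles across all waves
#'
#' [compute_profile()] per year, stacked into one tidy table for plotting the
#' evolution of prevalence and O/E ratio per cluster.
#'
#' @inheritParams compute_profile
#' @return data frame with one row per (year, cluster, disease).
#' @export
longitudinal_profile <- function(panel, trajectories, oe_threshold = 2,
                                 denominator = "active") {
  years <- sort(unique(trajectories$year[trajectories$state <=
                                           attr(trajectories, "C")]))
  res <- lapply(years, function(y) {
    compute_profile(panel, trajectories, y, oe_threshold, denominator)
  })
  do.call(rbind, res)
}

#' Per-cluster descriptive table
#'
#' For each decoded cluster in the given year: size, % female, mean age,
#' median chronic-disease count, % multimorbid (two or more diagnoses),
#' median drug count, % polypharmacy (five or more different drugs), median
#' visits, and the cumulative % dead and % dropped out by end of follow-up
#' among the cluster's members.
#'
#' @inheritParams compute_profile
#' @return one row per cluster; empty clusters get `n = 0` and `NA`
#'   statistics.
#' @export
describe_clusters <- function(panel, trajectories, year = 0) {
  stopifnot(inherits(panel, "cohort_panel"))
  C <- attr(trajectories, "C")
  obs <- panel$observations
  if (year < 0 || year > max(obs$year)) {
    stop("year ", year, " is outside the panel horizon")
  }
  rows <- obs[obs$year == year & obs$status == "active", , drop = FALSE]
  key <- paste(trajectories$person_id, trajectories$year)
  st <- trajectories$state[match(paste(rows$person_id, year), key)]
  rows <- rows[!is.na(st) & st <= C, , drop = FALSE]
  st <- st[!is.na(st) & st <= C]
  rows <- merge(rows, panel$persons[, c("person_id", "sex")],
                by = "person_id", sort = FALSE)

  # final observed status per person (for cumulative absorption)
  last <- obs[order(obs$person_id, obs$year), ]
  last <- last[!duplicated(last$person_id, fromLast = TRUE),
               c("person_id", "status")]
  final_status <- last$status[match(rows$person_id, last$person_id)]

  ndis <- rowSums(as.matrix(rows[, panel$disease_cols, drop = FALSE]))
  out <- lapply(seq_len(C), function(c) {
    i <- st == c
    if (!any(i)) {
      return(data.frame(cluster = c, n = 0L, pct_female = NA_real_,
                        mean_age = NA_real_, median_diseases = NA_real_,
                        pct_multimorbid = NA_real_, median_drugs = NA_real_,
                        pct_polypharmacy = NA_real_, median_visits = NA_real_,
                        pct_dead = NA_real_, pct_dropped = NA_real_))
    }
    data.frame(
      cluster = c, n = sum(i),
      pct_female = 100 * mean(rows$sex[i] == "female"),
      mean_age = mean(rows$age[i]),
      median_diseases = stats::median(ndis[i]),
      pct_multimorbid = 100 * mean(ndis[i] >= 2),
      median_drugs = stats::median(rows$drugs[i]),
      pct_polypharmacy = 100 * mean(rows$drugs[i] >= 5),
      median_visits = stats::median(rows$visits[i]),
      pct_dead = 100 * mean(final_status[i] == "dead"),
      pct_dropped = 100 * mean(final_status[i] == "dropped")
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Naming evidence: top over-represented diseases per cluster
#'
#' The k diseases with the highest O/E ratio in each cluster, the evidence
#' from which users assign clinical pattern names.
#'
#' @inheritParams compute_profile
#' @param k number of diseases per cluster.
#' @export
top_diseases <- function(panel, trajectories, year = 0, k = 5) {
  prof <- compute_profile(panel, trajectories, year)
  prof <- prof[order(prof$cluster, -ifelse(is.na(prof$oe_ratio), -Inf,
                                           prof$oe_ratio)), ]
  do.call(rbind, lapply(split(prof, prof$cluster), utils::head, k))
}
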