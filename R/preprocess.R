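#' Exclude rarely prevalent diseases at baseline
#'
#' Drops every disease whose year-0 prevalence (share of persons with the
#' flag set at year 0) is below `threshold`. The default 2% guards the
#' downstream model against statistical noise from very rare conditions.
#'
#' @param panel a `cohort_panel`.
#' @param threshold prevalence proportion in `[0, 1]` (default 0.02).
#' @return a list with `panel` (excluded columns removed) and `excluded`
#'   (data frame of dropped diseases and their baseline prevalences).
#' @export
filter_rare_diseases <- function(panel, threshold = 0.02) {
  stopifnot(inherits(panel, "cohort_panel"))
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1], got ", threshold)
  }
  obs <- panel$observations
  base <- obs[obs$year == 0, panel$disease_cols, drop = FALSE]
  if (nrow(base) == 0) stop("panel has no year-0 cross-section")
  prev <- colMeans(base)
  drop <- names(prev)[prev < threshold]
  excluded <- data.frame(disease = drop,
                         baseline_prevalence = unname(prev[drop]),
                         stringsAsFactors = FALSE)
  keep <- setdiff(panel$disease_cols, drop)
  panel$observations <- obs[, c(setdiff(names(obs), panel$disease_cols), keep)]
  panel$disease_cols <- keep
  panel$n_diseases <- length(keep)
  list(panel = panel, excluded = excluded)
}

#' Principal component analysis of continuous features
#'
#' Centres and scales each column to unit variance, then projects on the top
#' eigenvectors of the correlation structure. Constant columns are dropped
#' with a warning rather than dividing by zero. The sign of each component is
#' fixed so that its largest-magnitude loading is positive.
#'
#' @param x numeric matrix (rows = observations).
#' @param n_components integer number of components, or a fraction in (0, 1)
#'   interpreted as the explained-variance target (smallest number of
#'   components reaching it).
#' @return list with `scores`, `loadings` (columns orthonormal), `center`,
#'   `scale`, `explained_variance` (all eigenvalue fractions, non-increasing),
#'   `kept_cols`.
#' @export
fit_pca <- function(x, n_components = 0.8) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows for PCA")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) == 0) stop("no non-constant continuous columns left")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- resolve_n_components(n_components, evf, ncol(x))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  xs <- scale(x, center = pc$center, scale = pc$scale)
  list(scores = xs %*% rot, loadings = rot, center = pc$center,
       scale = pc$scale, explained_variance = evf,
       kept_cols = colnames(x))
}

resolve_n_components <- function(n_components, fractions, p_max) {
  if (n_components >= 1) {
    k <- as.integer(n_components)
    if (k > p_max) stop("requested ", k, " components but only ", p_max,
                        " dimensions available")
    return(k)
  }
  max(1L, which(cumsum(fractions) >= n_components - 1e-12)[1])
}

#' Multiple correspondence analysis of categorical features
#'
#' Correspondence analysis of the complete indicator matrix: every level of
#' every categorical variable becomes an indicator column; the centred,
#' mass-weighted matrix is decomposed by SVD. Row principal coordinates are
#' the continuous scores used downstream. Single-level columns are dropped
#' with a warning. Component signs follow the same largest-loading-positive
#' convention as [fit_pca()].
#'
#' @param x data frame or matrix of categorical variables (factors, character
#'   or 0/1 codes).
#' @param n_components integer, or a fraction in (0, 1) interpreted as the
#'   target share of the above-average-dimension inertia.
#' @return list with `scores` (row principal coordinates),
#'   `category_coordinates` (standard coordinates of the levels), `inertias`
#'   (non-increasing), `col_masses`, `levels`, `kept_cols`.
#' @export
fit_mca <- function(x, n_components = 0.8) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  nlev <- vapply(x, function(v) length(unique(v)), integer(1))
  if (any(nlev < 2)) {
    warning("dropping single-level column(s): ",
            paste(names(x)[nlev < 2], collapse = ", "))
    x <- x[, nlev >= 2, drop = FALSE]
  }
  if (ncol(x) == 0) stop("no multi-level categorical columns left")
  Z <- indicator_matrix(x)
  P <- Z / sum(Z)
  r <- rowSums(P); cm <- colSums(P)
  # S = D_r^{-1/2} (P - r c') D_c^{-1/2}
  S <- (P - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
  if (max(abs(S)) < 1e-12) stop("degenerate input: all rows identical, zero inertia")
  sv <- svd(S)
  inertias <- sv$d^2
  pos <- inertias > 1e-12
  k_max <- sum(pos)
  if (n_components < 1) {
    # Benzécri-style cap: only dimensions above the average inertia count
    avg <- mean(inertias[pos])
    above <- inertias >= avg - 1e-12
    frac <- inertias * above / sum(inertias[above])
    k <- max(1L, which(cumsum(frac) >= n_components - 1e-12)[1])
  } else {
    k <- resolve_n_components(n_components, inertias / sum(inertias), k_max)
  }
  k <- min(k, k_max)
  V <- sv$v[, seq_len(k), drop = FALSE]
  U <- sv$u[, seq_len(k), drop = FALSE]
  # standard column coordinates Gamma = D_c^{-1/2} V
  gamma <- V / sqrt(cm)
  # row principal coordinates F = D_r^{-1/2} U D
  Fscores <- sweep(U / sqrt(r), 2, sv$d[seq_len(k)], `*`)
  for (j in seq_len(k)) {
    i <- which.max(abs(gamma[, j]))
    if (gamma[i, j] < 0) { gamma[, j] <- -gamma[, j]; Fscores[, j] <- -Fscores[, j] }
  }
  rownames(gamma) <- colnames(Z)
  list(scores = Fscores, category_coordinates = gamma,
       inertias = inertias, col_masses = cm,
       levels = attr(Z, "level_map"), kept_cols = names(x))
}

# Complete indicator (disjunctive) matrix; remembers the level coding so new
# rows can be expanded identically at transform time.
indicator_matrix <- function(x, level_map = NULL) {
  blocks <- vector("list", ncol(x))
  new_map <- vector("list", ncol(x))
  names(new_map) <- names(x)
  for (j in seq_along(x)) {
    v <- as.character(x[[j]])
    levs <- if (is.null(level_map)) sort(unique(v)) else level_map[[names(x)[j]]]
    B <- matrix(0, length(v), length(levs))
    hit <- match(v, levs)
    ok <- !is.na(hit)
    B[cbind(which(ok), hit[ok])] <- 1
    colnames(B) <- paste0(names(x)[j], "=", levs)
    blocks[[j]] <- B
    new_map[[j]] <- levs
  }
  Z <- do.call(cbind, blocks)
  attr(Z, "level_map") <- if (is.null(level_map)) new_map else level_map
  Z
}

# Supplementary-row projection: (row profile - column masses)' D_c^{-1/2} V,
# i.e. indicator profile times standard coordinates.
mca_transform <- function(fit, x) {
  Z <- indicator_matrix(x[, fit$kept_cols, drop = FALSE],
                        level_map = fit$levels)
  n_seen <- rowSums(Z)
  if (any(n_seen < length(fit$kept_cols))) {
    warning("categories unseen at fit time mapped to zero contribution")
  }
  prof <- Z / pmax(n_seen, 1)
  sweep(prof, 2, fit$col_masses) %*% fit$category_coordinates
}

#' Assemble the reduced feature matrix for clustering and the HMM
#'
#' Concatenates PCA scores of the continuous features (age, visits, drugs)
#' and MCA scores of the categorical features (disease flags and sex) for
#' every active person-year. Projection maps are fitted on the pooled active
#' person-years of all waves (so all years share one space) or, optionally,
#' on year-0 rows only, and then applied to all active rows.
#'
#' @param panel a `cohort_panel`, already passed through
#'   [filter_rare_diseases()].
#' @param n_components_continuous,n_components_categorical integer counts or
#'   variance/inertia fractions, as in [fit_pca()] and [fit_mca()].
#' @param fit_on `"pooled"` (default) or `"year0"`.
#' @param scale_scores standardize every retained component score to unit
#'   variance over the fitting rows (default `TRUE`), so that Euclidean
#'   methods (fuzzy C-means, k-means) weight PCA and MCA components equally;
#'   MCA principal coordinates otherwise carry much smaller variance than
#'   standardized PCA scores.
#' @param continuous_features,categorical_extra column names; disease flags
#'   are always categorical.
#' @return an object of class `reduced_features`: data frame with
#'   `person_id`, `year` and score columns `pc1.., mc1..`; the fitted maps
#'   are stored in `attr(, "maps")`.
#' @export
assemble_features <- function(panel,
                              n_components_continuous = 2,
                              n_components_categorical = 2,
                              fit_on = c("pooled", "year0"),
                              scale_scores = TRUE,
                              continuous_features = c("age", "visits", "drugs"),
                              categorical_extra = "sex") {
  stopifnot(inherits(panel, "cohort_panel"))
  fit_on <- match.arg(fit_on)
  obs <- panel$observations
  act <- obs[obs$status == "active", , drop = FALSE]
  if (nrow(act) == 0) stop("panel has no active person-years")
  act <- merge(act, panel$persons[, c("person_id", "sex")], by = "person_id",
               sort = FALSE)
  act <- act[order(act$person_id, act$year), ]

  fit_rows <- if (fit_on == "year0") act$year == 0 else rep(TRUE, nrow(act))
  cont <- as.matrix(act[, continuous_features, drop = FALSE])
  cat_cols <- c(panel$disease_cols,
                intersect(categorical_extra, names(act)))
  catx <- act[, cat_cols, drop = FALSE]

  pca <- fit_pca(cont[fit_rows, , drop = FALSE], n_components_continuous)
  mca <- fit_mca(catx[fit_rows, , drop = FALSE], n_components_categorical)

  pc_scores <- scale(cont[, pca$kept_cols, drop = FALSE],
                     center = pca$center, scale = pca$scale) %*% pca$loadings
  mc_scores <- mca_transform(mca, catx)
  colnames(pc_scores) <- paste0("pc", seq_len(ncol(pc_scores)))
  colnames(mc_scores) <- paste0("mc", seq_len(ncol(mc_scores)))
  score_sds <- NULL
  if (scale_scores) {
    score_sds <- apply(cbind(pc_scores, mc_scores)[fit_rows, , drop = FALSE],
                       2, stats::sd)
    score_sds[score_sds == 0] <- 1
    pc_scores <- sweep(pc_scores, 2,
                       score_sds[seq_len(ncol(pc_scores))], `/`)
    mc_scores <- sweep(mc_scores, 2,
                       score_sds[ncol(pc_scores) + seq_len(ncol(mc_scores))],
                       `/`)
  }

  out <- cbind(act[, c("person_id", "year")],
               as.data.frame(pc_scores), as.data.frame(mc_scores))
  rownames(out) <- NULL
  attr(out, "maps") <- list(pca = pca, mca = mca,
                            continuous_features = pca$kept_cols,
                            categorical_features = cat_cols,
                            fit_on = fit_on, score_sds = score_sds)
  class(out) <- c("reduced_features", "data.frame")
  out
}

#' @export
print.reduced_features <- function(x, ...) {
  cat("<reduced_features> ", nrow(x), " active person-years, ",
      ncol(x) - 2L, " components\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4))
  invisible(x)
}

# Score columns of a reduced_features object, as a plain matrix.
feature_matrix <- function(reduced) {
  as.matrix(reduced[, setdiff(names(reduced), c("person_id", "year")),
                    drop = FALSE])
}
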