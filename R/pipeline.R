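#' Default demo pipeline configuration
#'
#' A desk-scale configuration exercising the whole analysis: N persons, C
#' latent clusters with well-separated disease profiles, D diseases, T annual
#' waves. All stage parameters can be overridden through `...`.
#'
#' @param n_persons,n_clusters,n_diseases,n_years cohort dimensions.
#' @param seed single global seed; per-stage seeds are derived from it.
#' @param out_dir output directory for all stage artifacts.
#' @param ... overrides for any other field (e.g. `n_restarts`,
#'   `oe_threshold`, `m_imputations`, `panel_path` to skip simulation).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_persons = 2000, n_clusters = 3,
                            n_diseases = 20, n_years = 5, seed = 1L,
                            out_dir = tempfile("mmtraj_run_"), ...) {
  cfg <- list(
    n_persons = n_persons, n_clusters = n_clusters, n_diseases = n_diseases,
    n_years = n_years, seed = as.integer(seed), out_dir = out_dir,
    prevalence_threshold = 0.02,
    n_components_continuous = 2, n_components_categorical = 2,
    fcm_m = 2, n_restarts = 5, tol = 1e-6, max_iter = 200,
    oe_threshold = 2, m_imputations = 7,
    panel_path = NULL, skip = character(0)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown pipeline option(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full multimorbidity-trajectory pipeline
#'
#' Executes simulate -> reduce -> cluster -> fit -> decode -> profile ->
#' survival from a single configuration, writing every intermediate artifact
#' (panel CSV, reduced features CSV, model JSON, trajectory CSV, profile and
#' hazard tables) plus a manifest with the derived per-stage seeds, parameter
#' hash, per-stage runtimes and an MD5 content hash of every output file.
#' Reruns with the same configuration reproduce all outputs bit-for-bit.
#'
#' @param config a `pipeline_config` (or YAML path).
#' @param quiet suppress stage log lines.
#' @return list with all in-memory stage results and the `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (!quiet) message("[", stage, "] ", ...)
  }
  runtimes <- c(); outputs <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    runtimes[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # simulate (or load a provided panel)
  panel <- stage("simulate", {
    if (!is.null(config$panel_path)) {
      say("simulate", "skipped; reading ", config$panel_path)
      read_panel(config$panel_path)
    } else {
      say("simulate", "N=", config$n_persons, " C=", config$n_clusters,
          " D=", config$n_diseases, " T=", config$n_years)
      cfg <- cohort_config(
        n_persons = config$n_persons, n_clusters = config$n_clusters,
        n_diseases = config$n_diseases, n_years = config$n_years,
        seed = derive_seed(config$seed, 1)
      )
      p <- generate_cohort(cfg)
      write_panel(p, file.path(config$out_dir, "panel.csv"))
      p
    }
  })
  if (is.null(config$panel_path)) outputs <- c(outputs, "panel.csv")

  red_res <- stage("reduce", {
    flt <- filter_rare_diseases(panel, config$prevalence_threshold)
    say("reduce", "excluded ", nrow(flt$excluded), " rare disease(s)")
    X <- assemble_features(flt$panel,
                           n_components_continuous =
                             config$n_components_continuous,
                           n_components_categorical =
                             config$n_components_categorical)
    utils::write.csv(as.data.frame(X),
                     file.path(config$out_dir, "reduced.csv"),
                     row.names = FALSE)
    list(panel = flt$panel, X = X)
  })
  panel <- red_res$panel
  reduced <- red_res$X
  outputs <- c(outputs, "reduced.csv")

  init <- stage("cluster", {
    x0 <- reduced[reduced$year == 0, , drop = FALSE]
    class(x0) <- class(reduced)
    fcm <- fcm_fit(x0, C = config$n_clusters, m = config$fcm_m,
                   seed = derive_seed(config$seed, 2))
    say("cluster", "FCM converged in ", fcm$n_iter, " iterations")
    init_hmm_from_fcm(fcm, x0)
  })

  model <- stage("fit", {
    fit <- fit_with_restarts(panel, reduced, init,
                             n_restarts = config$n_restarts,
                             seed = derive_seed(config$seed, 3),
                             tol = config$tol, max_iter = config$max_iter)
    say("fit", "best loglik ", format(fit$loglik), " over ",
        config$n_restarts, " restarts")
    hmm_to_json(fit, file.path(config$out_dir, "model.json"))
    fit
  })
  outputs <- c(outputs, "model.json")

  traj <- stage("decode", {
    tr <- viterbi_decode(model, panel, reduced)
    utils::write.csv(as.data.frame(tr),
                     file.path(config$out_dir, "trajectories.csv"),
                     row.names = FALSE)
    tr
  })
  outputs <- c(outputs, "trajectories.csv")

  summaries <- stage("transitions", {
    s2e <- transition_summary(traj, "start_to_end")
    ann <- transition_summary(traj, "annual")
    agree <- validate_bw_vs_decoded(model, traj)
    say("transitions", "BW vs decoded max |diff| ",
        format(round(agree$max_abs_diff, 4)))
    utils::write.csv(as.data.frame(100 * s2e$proportions),
                     file.path(config$out_dir, "transitions_start_to_end.csv"))
    list(start_to_end = s2e, annual = ann, agreement = agree)
  })
  outputs <- c(outputs, "transitions_start_to_end.csv")

  profiles <- stage("profile", {
    prof <- longitudinal_profile(panel, traj, config$oe_threshold)
    utils::write.csv(prof, file.path(config$out_dir, "profiles.csv"),
                     row.names = FALSE)
    prof
  })
  outputs <- c(outputs, "profiles.csv")

  hazards <- stage("survival", {
    rec <- build_survival_records(panel, traj)
    hz <- hazard_table(rec, m = config$m_imputations,
                       seed = derive_seed(config$seed, 4))
    utils::write.csv(hz$adjusted_mi,
                     file.path(config$out_dir, "hazards_mi.csv"),
                     row.names = FALSE)
    hz
  })
  outputs <- c(outputs, "hazards_mi.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("mmtraj")),
    seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, 1),
                       cluster = derive_seed(config$seed, 2),
                       fit = derive_seed(config$seed, 3),
                       survival = derive_seed(config$seed, 4)),
    parameters_hash = param_hash(config),
    runtimes_sec = as.list(runtimes),
    files = file_hashes(config$out_dir, outputs)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(panel = panel, reduced = reduced, model = model,
                 trajectories = traj, summaries = summaries,
                 profiles = profiles, hazards = hazards,
                 manifest = manifest, out_dir = config$out_dir))
}

param_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

file_hashes <- function(dir, files) {
  files <- unique(files[!is.na(files)])
  h <- tools::md5sum(file.path(dir, files))
  stats::setNames(as.list(unname(h)), files)
}
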