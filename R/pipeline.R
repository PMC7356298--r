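#' In-memory analysis of a cohort
#'
#' Runs the core analysis chain on an existing cohort: per-subject network
#' construction (two-stage normalization + exponential kernel), global and
#' nodal graph indices, and the covariate-adjusted group comparisons with FDR
#' and LSD post-hoc tests.
#'
#' @param cohort An `iscn_cohort`.
#' @param control_group Label of the control group.
#' @param covariate Name of the metadata column used as ANCOVA covariate
#'   (NULL for an unadjusted comparison).
#' @param alpha Significance level for the FDR-gated post-hoc stage.
#' @param nodal Also run the 148-region nodal comparison (slightly slower).
#' @param control_scoring Passed to [build_cohort_scns()].
#' @return List with `reference`, `deviations`, `metrics` (global data frame
#'   + nodal clustering matrix), `global_comparison` and (optionally)
#'   `nodal_comparison`.
#' @export
analyze_cohort <- function(cohort, control_group = "control",
                           covariate = "premorbid_iq", alpha = 0.05,
                           nodal = TRUE,
                           control_scoring = c("in-sample", "loo")) {
  built <- build_cohort_scns(cohort, control_group = control_group,
                             control_scoring = match.arg(control_scoring))
  mets <- cohort_metrics(built$scns)
  covv <- if (is.null(covariate)) NULL else cohort$metadata[[covariate]]
  glob <- compare_global(mets$global, cohort$metadata$group, covv,
                         alpha = alpha)
  out <- list(reference = built$reference, deviations = built$deviations,
              metrics = mets, global_comparison = glob)
  if (nodal)
    out$nodal_comparison <- compare_nodal(mets$nodal_clustering,
                                          cohort$metadata$group, covv,
                                          alpha = alpha)
  out
}

#' Run the full pipeline to an output directory
#'
#' One-command orchestration: simulate or ingest a cohort, build the
#' per-subject networks, compute metrics, run the statistics, and write every
#' stage product plus a run manifest. Reruns with an identical configuration
#' and seed reproduce byte-identical outputs (the manifest records content
#' hashes; no timestamps are written). Stages fail fast with a stage-named
#' error.
#'
#' @param config List of run options:
#'   \describe{
#'     \item{simulate}{an [sim_config()] — or NULL to ingest files}
#'     \item{thickness_path, metadata_path}{input TSVs when not simulating}
#'     \item{atlas}{region registry (default [destrieux_atlas()])}
#'     \item{control_group}{control label (default "control")}
#'     \item{covariate}{ANCOVA covariate column (default "premorbid_iq")}
#'     \item{alpha}{significance level (default 0.05)}
#'     \item{n_boot}{bootstrap resamples for correlations (default 5000)}
#'     \item{seed}{root seed for the stochastic statistics (default 1)}
#'     \item{screens}{optional list(index_cols, score_cols,
#'       covariates_by_group) for the correlation stage}
#'     \item{write_matrices}{write one TSV per subject matrix (default TRUE)}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  defaults <- list(simulate = NULL, thickness_path = NULL,
                   metadata_path = NULL, atlas = NULL,
                   control_group = "control", covariate = "premorbid_iq",
                   alpha = 0.05, n_boot = 5000L, seed = 1L,
                   screens = NULL, write_matrices = TRUE)
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, msg)
    message(sprintf("[iscn] stage=%s %s", stage, msg))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # stage 1: ingest or simulate
  cohort <- run_stage("ingest", {
    if (!is.null(config$simulate)) {
      log_stage("ingest", "simulating cohort")
      co <- simulate_cohort(config$simulate)
      write_cohort(co, file.path(out_dir, "thickness.tsv"),
                   file.path(out_dir, "metadata.tsv"))
      gt <- co$ground_truth
      gt$config <- unclass(gt$config)
      jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      co
    } else {
      if (is.null(config$thickness_path) || is.null(config$metadata_path))
        stop("need thickness_path and metadata_path (or a simulate config)")
      log_stage("ingest", paste("reading", config$thickness_path))
      atlas <- if (is.null(config$atlas)) destrieux_atlas() else config$atlas
      read_cohort(config$thickness_path, config$metadata_path, atlas)
    }
  })

  # stage 2: network construction
  built <- run_stage("build", {
    log_stage("build", sprintf("building %d matrices", nrow(cohort$thickness)))
    b <- build_cohort_scns(cohort, control_group = config$control_group)
    write_reference(b$reference, file.path(out_dir, "reference_model.tsv"))
    if (isTRUE(config$write_matrices)) {
      mdir <- file.path(out_dir, "scn")
      dir.create(mdir, showWarnings = FALSE)
      for (sid in names(b$scns))
        write_scn_matrix(b$scns[[sid]],
                         file.path(mdir, paste0(sid, ".tsv")))
    }
    b
  })

  # stage 3: graph metrics
  mets <- run_stage("metrics", {
    log_stage("metrics", "computing global and nodal indices")
    m <- cohort_metrics(built$scns)
    utils::write.table(m$global, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    nod <- data.frame(subject_id = rownames(m$nodal_clustering),
                      m$nodal_clustering, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(nod, file.path(out_dir, "nodal_cc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    m
  })

  # stage 4: statistics
  stats_out <- run_stage("stats", {
    log_stage("stats", "group comparisons and correlation screens")
    covv <- if (is.null(config$covariate)) NULL
            else cohort$metadata[[config$covariate]]
    glob <- compare_global(mets$global, cohort$metadata$group, covv,
                           alpha = config$alpha)
    utils::write.table(glob$omnibus,
                       file.path(out_dir, "global_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(glob$posthoc,
                       file.path(out_dir, "global_posthoc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    nodc <- compare_nodal(mets$nodal_clustering, cohort$metadata$group,
                          covv, alpha = config$alpha)
    utils::write.table(nodc$omnibus,
                       file.path(out_dir, "nodal_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    screens <- config$screens
    if (is.null(screens)) screens <- default_screens(cohort)
    corr <- NULL
    if (!is.null(screens)) {
      dat <- cbind(mets$global, cohort$metadata[setdiff(
        names(cohort$metadata), "subject_id")])
      for (rg in intersect(screens$index_cols, colnames(mets$nodal_clustering)))
        dat[[rg]] <- mets$nodal_clustering[, rg]
      corr <- correlation_screen(
        dat, cohort$metadata$group,
        index_cols = screens$index_cols,
        score_cols = screens$score_cols,
        covariates_by_group = screens$covariates_by_group,
        n_boot = config$n_boot, seed = config$seed)
      utils::write.table(corr, file.path(out_dir, "correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(global_comparison = glob, nodal_comparison = nodc,
         correlations = corr)
  })

  # manifest: config + content hashes of every product (no timestamps, so a
  # rerun with the same seed yields byte-identical files)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "iscn",
    version = as.character(utils::packageVersion("iscn")),
    seed = config$seed, n_boot = config$n_boot, alpha = config$alpha,
    covariate = config$covariate,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(c(list(cohort = cohort, reference = built$reference,
                   metrics = mets), stats_out))
}

# default correlation screens: the four global indices (plus the planted
# nodal region for simulated cohorts) against whatever score columns exist;
# patient groups adjusted for medication dose and illness duration
default_screens <- function(cohort) {
  md <- cohort$metadata
  known_scores <- intersect(c("panss_positive", "ymrs", "verbal_fluency",
                              "kavlt_trial5"), names(md))
  if (length(known_scores) == 0L) return(NULL)
  index_cols <- c("strength", "clustering", "path_length", "efficiency")
  if (inherits(cohort, "iscn_sim_cohort")) {
    sc <- cohort$ground_truth$score
    if (identical(sc$index$type, "nodal_clustering"))
      index_cols <- c(index_cols, sc$index$region)
  }
  covs <- intersect(c("medication_dose", "illness_duration"), names(md))
  groups <- unique(md$group)
  # adjust for medication/illness duration only where those covariates are
  # actually recorded for the whole group (i.e. patient groups)
  cbg <- lapply(groups, function(g) {
    vals <- md[md$group == g, covs, drop = FALSE]
    if (length(covs) > 0L && all(vapply(vals, function(v)
      all(is.finite(v)), logical(1)))) covs else character(0)
  })
  names(cbg) <- groups
  list(index_cols = index_cols, score_cols = known_scores,
       covariates_by_group = cbg)
}
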