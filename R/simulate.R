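#' Simulation configuration for synthetic cohorts
#'
#' Assembles and validates the parameters of the synthetic cohort generator.
#' The defaults emulate the study design the pipeline targets: three groups
#' (schizophrenia n = 39, bipolar disorder n = 37, healthy controls n = 32),
#' 148 Destrieux regions with mean thickness drawn uniformly in 1.5-4.5 mm, a
#' per-subject global scale factor, Gaussian regional noise, and planted
#' patient-specific regional deviation heterogeneity that weakens network
#' similarity. Clinical covariates and scores are generated with
#' group-specific means on realistic scales, and one named score is
#' constructed to correlate at `score_effect` with one named network index.
#'
#' `deviation_sd` is expressed in normative z units (multiples of the
#' per-region control variability): a patient with `deviation_sd = 1` on a
#' region deviates from the control norm about sqrt(2) times as much as a
#' typical control. Pathology is modeled as increased regional heterogeneity
#' (random per-subject offsets, resampled per subject), not a uniform
#' thinning: a uniform shift would be removed by the within-subject
#' standardization and could not change the network.
#'
#' @param n_per_group Named integer vector of group sizes; names are the
#'   group labels, one of which must be `control_group`.
#' @param n_regions Number of atlas regions (148 uses the shipped Destrieux
#'   registry, anything else a synthetic registry).
#' @param region_mean_range Range (mm) for the shared per-region mean
#'   thickness.
#' @param subject_scale_sd SD of the per-subject global scale factor
#'   (around 1).
#' @param region_noise_sd SD (mm) of the per-subject, per-region thickness
#'   noise.
#' @param deviation_sd Named vector: per-group SD (normative z units) of the
#'   planted regional deviations.
#' @param affected_regions Named list: per group, `"all"`, an integer vector
#'   of region ids, or a character vector of region names.
#' @param score_effect Planted correlation between `score_name` and
#'   `score_index` in `score_group` (0 disables the construction).
#' @param score_group,score_name Which group's score carries the planted
#'   correlation, and its column name.
#' @param score_index List describing the network index the score tracks:
#'   either `list(type = "nodal_clustering", region = <name>)` or
#'   `list(type = "global", index = <one of strength/clustering/path_length/
#'   efficiency>)`.
#' @param control_group Label of the control group.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Validated config list of class `iscn_sim_config`.
#' @export
sim_config <- function(n_per_group = c(schizophrenia = 39, bipolar = 37,
                                       control = 32),
                       n_regions = 148,
                       region_mean_range = c(1.5, 4.5),
                       subject_scale_sd = 0.05,
                       region_noise_sd = 0.12,
                       deviation_sd = c(schizophrenia = 0.32, bipolar = 0.24,
                                        control = 0),
                       affected_regions = list(schizophrenia = "all",
                                               bipolar = "all"),
                       score_effect = 0.45,
                       score_group = "bipolar",
                       score_name = "ymrs",
                       score_index = NULL,
                       control_group = "control",
                       seed = 1L) {
  if (is.null(names(n_per_group)) || any(names(n_per_group) == ""))
    stop("n_per_group must be a named vector of group sizes")
  if (any(n_per_group < 2L)) stop("every group needs at least 2 subjects")
  if (!(control_group %in% names(n_per_group)))
    stop("control group '", control_group, "' absent from n_per_group")
  if (n_regions < 3L) stop("need at least 3 regions")
  if (any(deviation_sd < 0)) stop("deviation_sd must be >= 0")
  missing_dev <- setdiff(names(n_per_group), names(deviation_sd))
  deviation_sd[missing_dev] <- 0
  if (is.null(score_index)) {
    score_index <- if (n_regions == 148)
      list(type = "nodal_clustering",
           region = "left superior occipital gyrus")
    else list(type = "global", index = "strength")
  }
  structure(list(n_per_group = n_per_group, n_regions = n_regions,
                 region_mean_range = region_mean_range,
                 subject_scale_sd = subject_scale_sd,
                 region_noise_sd = region_noise_sd,
                 deviation_sd = deviation_sd,
                 affected_regions = affected_regions,
                 score_effect = score_effect, score_group = score_group,
                 score_name = score_name, score_index = score_index,
                 control_group = control_group, seed = as.integer(seed)),
            class = "iscn_sim_config")
}

#' Simulate a cohort with planted network effects
#'
#' Generates regional thickness tables, covariates and clinical scores
#' according to a [sim_config()]. Control thickness is
#' `t_s(i) = a_s * mu_i + eps_s(i)`; patient groups additionally receive
#' per-subject regional offsets with SD `deviation_sd * region_noise_sd` mm
#' on their affected regions, which after the two-stage normalization planted
#' deviations of about `deviation_sd` normative z units. The named clinical
#' score is built as a linear blend of the standardized target network index
#' and independent noise, so its population correlation with that index is
#' `score_effect`.
#'
#' @param config An `iscn_sim_config`.
#' @return An `iscn_cohort` with an extra `ground_truth` element (region
#'   means, per-subject planted offsets, affected region sets, score
#'   construction) and class `iscn_sim_cohort` prepended.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "iscn_sim_config")) stop("config must be a sim_config")
  atlas <- if (config$n_regions == 148) destrieux_atlas()
           else synthetic_atlas(config$n_regions)
  R <- config$n_regions
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  subject_id <- sprintf("S%03d", seq_len(n))

  cohort <- NULL
  local_rng({
    set.seed(config$seed)
    mu <- stats::runif(R, config$region_mean_range[1L],
                       config$region_mean_range[2L])
    a <- pmax(stats::rnorm(n, 1, config$subject_scale_sd), 0.5)
    eps <- matrix(stats::rnorm(n * R, 0, config$region_noise_sd), n, R)
    delta <- matrix(0, n, R)
    for (g in names(config$n_per_group)) {
      sdg <- config$deviation_sd[[g]]
      if (sdg <= 0) next
      aff <- config$affected_regions[[g]]
      if (is.null(aff)) next
      ids <- if (identical(aff, "all")) seq_len(R)
             else if (is.character(aff)) region_id(atlas, aff)
             else as.integer(aff)
      rows <- which(groups == g)
      delta[rows, ids] <- stats::rnorm(length(rows) * length(ids), 0,
                                       sdg * config$region_noise_sd)
    }
    thickness <- a * matrix(mu, n, R, byrow = TRUE) + eps + delta
    thickness <- pmax(thickness, 0.1)  # guard: thickness must stay positive
    dimnames(thickness) <- list(subject_id, atlas$name)

    md <- data.frame(subject_id = subject_id, group = groups,
                     stringsAsFactors = FALSE)
    # group-wise Gaussian draws on loosely realistic clinical scales; groups
    # without an entry in `means` get NA (score not administered)
    draw <- function(means, sds, floor = -Inf) {
      v <- rep(NA_real_, n)
      for (g in names(means))
        v[groups == g] <- stats::rnorm(sum(groups == g), means[[g]], sds[[g]])
      pmax(v, floor)
    }
    pat <- setdiff(names(config$n_per_group), config$control_group)
    ctrl <- config$control_group
    iq_means <- stats::setNames(
      c(rep_len(c(100.6, 97.7), length(pat)), 107),
      c(pat, ctrl))
    md$premorbid_iq <- draw(iq_means,
                            stats::setNames(rep(9.5, length(iq_means)),
                                            names(iq_means)))
    pat_named <- function(x) stats::setNames(rep(x, length(pat)), pat)
    md$medication_dose <- draw(pat_named(400), pat_named(350), floor = 0)
    md$illness_duration <- draw(pat_named(11), pat_named(8), floor = 0.5)
    everyone <- function(x)
      stats::setNames(rep(x, length(config$n_per_group)),
                      names(config$n_per_group))
    md$verbal_fluency <- draw(everyone(16), everyone(5.5), floor = 0)
    md$kavlt_trial5 <- draw(everyone(10), everyone(2.5), floor = 0)
    if ("schizophrenia" %in% pat)
      md$panss_positive <- draw(c(schizophrenia = 13.7),
                                c(schizophrenia = 7.2), floor = 7)

    # planted score: blend of the standardized target index and fresh noise
    score <- rep(NA_real_, n)
    rows <- which(groups == config$score_group)
    if (length(rows) > 0L && !is.null(config$score_name)) {
      rho <- config$score_effect
      zi <- if (rho != 0)
        as.numeric(scale(target_index_values(thickness, groups, rows,
                                             config, atlas)))
      else 0
      noise <- stats::rnorm(length(rows))
      score[rows] <- 6 + 3 * (rho * zi + sqrt(max(0, 1 - rho^2)) * noise)
    }
    md[[config$score_name]] <- score

    cohort <- new_cohort(thickness, md, atlas)
    cohort$ground_truth <- list(
      region_means = mu, subject_scale = a, planted_offsets = delta,
      affected_regions = config$affected_regions,
      deviation_sd = config$deviation_sd,
      score = list(group = config$score_group, name = config$score_name,
                   index = config$score_index, effect = config$score_effect),
      config = config)
    class(cohort) <- c("iscn_sim_cohort", class(cohort))
  })
  cohort
}

# network index values used to plant the score-index correlation: runs the
# normalization + kernel for the score group's subjects only
target_index_values <- function(thickness, groups, rows, config, atlas) {
  z <- t(apply(thickness, 1L, within_subject_normalize))
  reference <- fit_reference(
    z[groups == config$control_group, , drop = FALSE])
  target <- config$score_index
  vapply(rows, function(i) {
    W <- build_scn(deviation_profile(z[i, ], reference), atlas = atlas)
    if (identical(target$type, "nodal_clustering")) {
      nodal_clustering(W)[[region_id(atlas, target$region)]]
    } else {
      switch(target$index,
             strength = global_strength(W),
             clustering = global_clustering(W),
             path_length = characteristic_path_length(shortest_path_matrix(W)),
             efficiency = global_efficiency(shortest_path_matrix(W)),
             stop("unknown global index: ", target$index))
    }
  }, numeric(1))
}

#' Hand-checkable worked fixture
#'
#' A deliberately tiny cohort (5 regions, groups of 3/3/4) with hard-coded
#' thickness values, small enough that every stage — standardization,
#' reference fitting, kernel weights, graph indices, one ANCOVA — can be
#' verified by direct hand or brute-force computation. Also returns two
#' reference deviation profiles whose kernel matrices have closed-form
#' entries (all ones off-diagonal; edges `exp(-1)` to one deviant region).
#'
#' @return List with `cohort` (an `iscn_cohort`), and `deviations` (list of
#'   named example deviation profiles `zero` and `unit_region2`).
#' @export
make_worked_fixture <- function() {
  atlas <- synthetic_atlas(5L)
  thickness <- matrix(c(
    2.10, 2.60, 3.10, 3.60, 4.10,
    2.00, 2.70, 3.00, 3.70, 4.00,
    2.20, 2.50, 3.20, 3.50, 4.20,
    2.05, 2.65, 3.05, 3.65, 4.05,
    2.15, 2.55, 3.15, 3.55, 4.15,
    1.95, 2.75, 2.95, 3.75, 3.95,
    2.12, 2.58, 3.12, 3.58, 4.12,
    2.08, 2.62, 3.08, 3.62, 4.08,
    2.18, 2.52, 3.18, 3.52, 4.18,
    2.02, 2.68, 3.02, 3.68, 4.02), nrow = 10L, byrow = TRUE)
  subject_id <- sprintf("F%02d", 1:10)
  dimnames(thickness) <- list(subject_id, atlas$name)
  metadata <- data.frame(
    subject_id = subject_id,
    group = rep(c("groupA", "groupB", "control"), c(3L, 3L, 4L)),
    premorbid_iq = c(101, 99, 103, 97, 100, 98, 108, 105, 110, 106),
    score = c(12, 15, 10, 14, 9, 11, 8, 7, 9, 8),
    stringsAsFactors = FALSE)
  list(cohort = new_cohort(thickness, metadata, atlas),
       deviations = list(zero = numeric(5L),
                         unit_region2 = c(0, 1, 0, 0, 0)))
}
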