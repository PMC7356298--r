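#' Covariate-adjusted one-way group comparison (ANCOVA)
#'
#' Fits the linear model `value ~ covariate + group` and reports the group
#' effect adjusted for the covariate: F statistic, raw p value and partial
#' eta squared `SS_group / (SS_group + SS_residual)`. With a null (constant
#' or absent) covariate this reduces exactly to the classical one-way ANOVA.
#'
#' @param values Numeric outcome vector (one value per subject).
#' @param group Group labels (factor or character), >= 2 groups with >= 2
#'   subjects each.
#' @param covariate Optional numeric covariate (e.g. premorbid IQ). A
#'   zero-variance covariate is dropped; a covariate collinear with the group
#'   coding is an error.
#' @return List with `F`, `df1`, `df2`, `p`, `partial_eta_sq`, `ss_group`,
#'   `ss_error`, and the fitted `model`.
#' @export
ancova_per_index <- function(values, group, covariate = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 subjects")
  if (!all(is.finite(values))) stop("values must be finite")
  if (stats::sd(values) == 0) stop("degenerate input: constant values")
  dat <- data.frame(.value = values, .group = group)
  if (!is.null(covariate)) {
    if (!all(is.finite(covariate))) stop("covariate must be finite")
    if (stats::sd(covariate) == 0) covariate <- NULL
  }
  if (is.null(covariate)) {
    fit <- stats::lm(.value ~ .group, data = dat)
  } else {
    dat$.cov <- covariate
    fit <- stats::lm(.value ~ .cov + .group, data = dat)
  }
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: covariate is collinear with the group coding")
  an <- stats::anova(fit)
  i <- which(rownames(an) == ".group")
  ss_g <- an[i, "Sum Sq"]
  ss_e <- an["Residuals", "Sum Sq"]
  list(F = an[i, "F value"], df1 = an[i, "Df"], df2 = an["Residuals", "Df"],
       p = an[i, "Pr(>F)"], partial_eta_sq = ss_g / (ss_g + ss_e),
       ss_group = ss_g, ss_error = ss_e, model = fit)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values, monotone-enforced and capped at 1, returned in
#' the input order.
#'
#' @param p Numeric vector of p values in [0, 1].
#' @return Adjusted p values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop("p values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' LSD post-hoc pairwise comparisons under ANCOVA
#'
#' Least-significant-difference comparisons of covariate-adjusted group
#' means: for each group pair, the difference of adjusted means is tested
#' with the pooled residual mean square and residual degrees of freedom of
#' the omnibus model; p values are deliberately unadjusted (LSD convention).
#'
#' @inheritParams ancova_per_index
#' @return Data frame with one row per group pair: `group1`, `group2`,
#'   `diff` (adjusted mean group1 - group2), `se`, `t`, `df`, `p`.
#' @export
lsd_posthoc <- function(values, group, covariate = NULL) {
  fit <- ancova_per_index(values, group, covariate)$model
  group <- droplevels(as.factor(group))
  lev <- levels(group)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  df_res <- stats::df.residual(fit)
  # treatment contrasts: adjusted mean difference between levels a and b is
  # coef[.groupa] - coef[.groupb] (0 for the reference level)
  coef_of <- function(g) {
    nm <- paste0(".group", g)
    if (nm %in% names(cf)) nm else NA_character_
  }
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    L <- stats::setNames(numeric(length(cf)), names(cf))
    n1 <- coef_of(pr[1L]); n2 <- coef_of(pr[2L])
    if (!is.na(n1)) L[n1] <- 1
    if (!is.na(n2)) L[n2] <- L[n2] - 1
    diff <- sum(L * cf)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tval <- diff / se
    data.frame(group1 = pr[1L], group2 = pr[2L], diff = diff, se = se,
               t = tval, df = df_res,
               p = 2 * stats::pt(-abs(tval), df_res),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare the four global network indices across groups
#'
#' Per-index ANCOVA with the supplied covariate, FDR adjustment across the
#' family of indices, and LSD post-hoc pairwise comparisons for indices that
#' remain significant after FDR.
#'
#' @param global_df Data frame from [cohort_metrics()]`$global` (columns
#'   `strength`, `clustering`, `path_length`, `efficiency`).
#' @param group Group labels, one per row of `global_df`.
#' @param covariate Optional numeric covariate (the analyzed configuration
#'   uses premorbid IQ).
#' @param alpha Significance level for the FDR-gated post-hoc stage.
#' @return List with `omnibus` (data frame: index, F, dfs, p_raw, p_fdr,
#'   partial_eta_sq) and `posthoc` (data frame of LSD pairs for
#'   FDR-significant indices; empty when none).
#' @export
compare_global <- function(global_df, group, covariate = NULL, alpha = 0.05) {
  idx <- c("strength", "clustering", "path_length", "efficiency")
  missing <- setdiff(idx, names(global_df))
  if (length(missing) > 0L)
    stop("global metrics table lacks column(s): ",
         paste(missing, collapse = ", "))
  fits <- lapply(idx, function(v)
    ancova_per_index(global_df[[v]], group, covariate))
  omnibus <- data.frame(
    index = idx,
    F = vapply(fits, `[[`, numeric(1), "F"),
    df1 = vapply(fits, `[[`, numeric(1), "df1"),
    df2 = vapply(fits, `[[`, numeric(1), "df2"),
    p_raw = vapply(fits, `[[`, numeric(1), "p"),
    partial_eta_sq = vapply(fits, `[[`, numeric(1), "partial_eta_sq"),
    stringsAsFactors = FALSE)
  omnibus$p_fdr <- fdr_adjust(omnibus$p_raw)
  sig <- omnibus$index[omnibus$p_fdr < alpha]
  posthoc <- do.call(rbind, lapply(sig, function(v) {
    ph <- lsd_posthoc(global_df[[v]], group, covariate)
    cbind(index = v, ph, stringsAsFactors = FALSE)
  }))
  if (is.null(posthoc))
    posthoc <- data.frame(index = character(), group1 = character(),
                          group2 = character(), diff = numeric(),
                          se = numeric(), t = numeric(), df = numeric(),
                          p = numeric(), stringsAsFactors = FALSE)
  list(omnibus = omnibus, posthoc = posthoc)
}

#' Compare nodal clustering coefficients across groups, region by region
#'
#' The same ANCOVA as [compare_global()] applied per region, with FDR across
#' the family of testable regions and LSD post-hoc for the FDR-significant
#' ones. Regions with zero variance across subjects cannot be tested; they
#' are excluded with a warning and the FDR family size reduced accordingly.
#'
#' @param nodal_mat Subjects x regions matrix of nodal clustering
#'   coefficients ([cohort_metrics()]`$nodal_clustering`).
#' @inheritParams compare_global
#' @return List with `omnibus` (one row per tested region), `posthoc`
#'   (LSD pairs for FDR-significant regions) and `excluded` (names of
#'   degenerate regions).
#' @export
compare_nodal <- function(nodal_mat, group, covariate = NULL, alpha = 0.05) {
  regions <- colnames(nodal_mat)
  if (is.null(regions)) regions <- paste0("region_", seq_len(ncol(nodal_mat)))
  sds <- apply(nodal_mat, 2L, stats::sd)
  excluded <- regions[sds == 0]
  if (length(excluded) > 0L)
    warning("excluding ", length(excluded),
            " degenerate region(s) with constant nodal CC: ",
            paste(utils::head(excluded, 5L), collapse = ", "),
            if (length(excluded) > 5L) ", ...")
  keep <- which(sds > 0)
  fits <- lapply(keep, function(j)
    ancova_per_index(nodal_mat[, j], group, covariate))
  omnibus <- data.frame(
    region = regions[keep],
    F = vapply(fits, `[[`, numeric(1), "F"),
    df1 = vapply(fits, `[[`, numeric(1), "df1"),
    df2 = vapply(fits, `[[`, numeric(1), "df2"),
    p_raw = vapply(fits, `[[`, numeric(1), "p"),
    partial_eta_sq = vapply(fits, `[[`, numeric(1), "partial_eta_sq"),
    stringsAsFactors = FALSE)
  omnibus$p_fdr <- fdr_adjust(omnibus$p_raw)
  sig <- omnibus$region[omnibus$p_fdr < alpha]
  posthoc <- do.call(rbind, lapply(sig, function(rg) {
    ph <- lsd_posthoc(nodal_mat[, rg], group, covariate)
    cbind(region = rg, ph, stringsAsFactors = FALSE)
  }))
  if (is.null(posthoc))
    posthoc <- data.frame(region = character(), group1 = character(),
                          group2 = character(), diff = numeric(),
                          se = numeric(), t = numeric(), df = numeric(),
                          p = numeric(), stringsAsFactors = FALSE)
  list(omnibus = omnibus, posthoc = posthoc, excluded = excluded)
}

#' Multivariate omnibus pre-test (Wilks' lambda)
#'
#' Optional multivariate check across the four global indices before the
#' per-index comparisons: a one-way MANOVA of the index matrix on group,
#' adjusted for the covariate, summarized by Wilks' lambda.
#'
#' @inheritParams compare_global
#' @return List with `wilks`, `F`, `df1`, `df2`, `p`.
#' @export
manova_pretest <- function(global_df, group, covariate = NULL) {
  Y <- as.matrix(global_df[, c("strength", "clustering",
                               "path_length", "efficiency")])
  group <- droplevels(as.factor(group))
  fit <- if (is.null(covariate)) stats::manova(Y ~ group)
         else stats::manova(Y ~ covariate + group)
  sm <- summary(fit, test = "Wilks")$stats
  i <- grep("group", rownames(sm))
  list(wilks = sm[i, "Wilks"], F = sm[i, "approx F"],
       df1 = sm[i, "num Df"], df2 = sm[i, "den Df"], p = sm[i, "Pr(>F)"])
}

#' Partial Pearson correlation
#'
#' Pearson correlation between the residuals of `x` and `y` after linear
#' regression on the covariates, with the parametric p value from the t
#' distribution on `n - 2 - k` degrees of freedom (k covariates). With no
#' covariates this is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix / data frame of covariates
#'   (columns), or NULL.
#' @return List with `r`, `p`, `df`, `n`, `n_covariates`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per subject")
    k <- ncol(covariates)
  }
  if (n <= k + 2L)
    stop("insufficient n: need more than ", k + 2L, " subjects, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: constant x or y")
  if (k > 0L) {
    Z <- cbind(1, covariates)
    rx <- stats::lm.fit(Z, x)$residuals
    ry <- stats::lm.fit(Z, y)$residuals
  } else {
    rx <- x; ry <- y
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("degenerate input: x or y is collinear with the covariates")
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df,
       n = n, n_covariates = k)
}

#' Bootstrap-supported partial correlation
#'
#' Recomputes the partial correlation on `n_boot` resamples of subjects
#' (with replacement) and reports the percentile 95% confidence interval
#' alongside the point estimate and parametric p value. Resamples with
#' degenerate variance (constant x, y or covariate column) are redrawn and
#' counted. Deterministic given `seed`; the caller's RNG state is left
#' untouched.
#'
#' @inheritParams partial_correlation
#' @param n_boot Number of bootstrap resamples (5000 in the analyzed
#'   configuration).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level of the percentile interval.
#' @return List of class `iscn_correlation` with `r`, `p_parametric`,
#'   `ci_low`, `ci_high`, `n_boot`, `n_redrawn`, `seed`, `n`,
#'   `n_covariates`, `conf`.
#' @export
bootstrap_partial_correlation <- function(x, y, covariates = NULL,
                                          n_boot = 5000L, seed = 1L,
                                          conf = 0.95) {
  point <- partial_correlation(x, y, covariates)
  n <- point$n
  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  rs <- numeric(n_boot)
  n_redrawn <- 0L
  local_rng({
    set.seed(seed)
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx]; yb <- y[idx]
        cb <- if (is.null(covm)) NULL else covm[idx, , drop = FALSE]
        ok <- stats::sd(xb) > 0 && stats::sd(yb) > 0 &&
          (is.null(cb) || qr(cbind(1, cb))$rank == ncol(cb) + 1L)
        if (ok) {
          rb <- tryCatch(partial_correlation(xb, yb, cb)$r,
                         error = function(e) NA_real_)
          if (!is.na(rb)) { rs[b] <- rb; break }
        }
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100L * n_boot)
          stop("bootstrap cannot find non-degenerate resamples")
      }
    }
  })
  qs <- stats::quantile(rs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  structure(list(r = point$r, p_parametric = point$p,
                 ci_low = qs[1L], ci_high = qs[2L],
                 n_boot = n_boot, n_redrawn = n_redrawn, seed = seed,
                 n = n, n_covariates = point$n_covariates, conf = conf,
                 method = "percentile"),
            class = "iscn_correlation")
}

#' @export
print.iscn_correlation <- function(x, ...) {
  cat(sprintf("r = %.3f (parametric p = %.4g), %d%% bootstrap CI [%.3f, %.3f], n = %d, %d resamples\n",
              x$r, x$p_parametric, round(100 * x$conf), x$ci_low, x$ci_high,
              x$n, x$n_boot))
  invisible(x)
}

#' Screen network indices against clinical scores, per group
#'
#' Within each group, runs bootstrap-supported partial correlations of every
#' requested index column against every requested score column, using that
#' group's covariate set (e.g. medication dose and illness duration for
#' patient groups, none for controls). Rows with missing values in the index,
#' score or covariates are dropped pairwise.
#'
#' @param data Data frame with one row per subject, containing the index,
#'   score and covariate columns plus `group`.
#' @param group Group labels, one per row.
#' @param index_cols Character vector of index column names.
#' @param score_cols Character vector of score column names.
#' @param covariates_by_group Named list: for each group label, a character
#'   vector of covariate column names (possibly empty).
#' @param n_boot,seed,conf Passed to [bootstrap_partial_correlation()];
#'   the seed is advanced deterministically per screen.
#' @return Data frame: one row per (group, index, score) screen with r,
#'   parametric and bootstrap summaries.
#' @export
correlation_screen <- function(data, group, index_cols, score_cols,
                               covariates_by_group = list(),
                               n_boot = 5000L, seed = 1L, conf = 0.95) {
  group <- as.character(group)
  out <- list()
  counter <- 0L
  for (g in unique(group)) {
    covs <- covariates_by_group[[g]]
    rows <- which(group == g)
    for (ix in index_cols) for (sc in score_cols) {
      counter <- counter + 1L
      sub <- data[rows, c(ix, sc, covs), drop = FALSE]
      keep <- stats::complete.cases(sub)
      sub <- sub[keep, , drop = FALSE]
      if (nrow(sub) == 0L) next  # score not administered in this group
      covm <- if (length(covs) > 0L) as.matrix(sub[covs]) else NULL
      res <- bootstrap_partial_correlation(
        sub[[ix]], sub[[sc]], covm,
        n_boot = n_boot, seed = seed + counter, conf = conf)
      out[[length(out) + 1L]] <- data.frame(
        group = g, index = ix, score = sc,
        covariates = paste(covs, collapse = ","),
        n = res$n, r = res$r, p_parametric = res$p_parametric,
        ci_low = res$ci_low, ci_high = res$ci_high,
        n_boot = res$n_boot, n_redrawn = res$n_redrawn,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# run code under a private RNG stream, restoring the caller's state
local_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  eval.parent(substitute(expr))
}
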