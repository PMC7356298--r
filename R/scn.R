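#' Within-subject standardization of a thickness profile
#'
#' First normalization stage: a subject's regional thickness values are
#' standardized across that subject's own regions, removing global offsets and
#' scale (e.g. overall thicker or thinner cortex) so that only the regional
#' pattern remains. The sample standard deviation (n - 1 denominator) is used
#' throughout the package.
#'
#' @param thickness Numeric vector of regional thickness values (mm), all
#'   finite and strictly positive.
#' @return Numeric vector `z` with `mean(z) == 0` and `sd(z) == 1`.
#' @examples
#' within_subject_normalize(c(2, 3, 4))   # -1 0 1
#' @export
within_subject_normalize <- function(thickness) {
  if (!is.numeric(thickness) || !all(is.finite(thickness)))
    stop("thickness must be a finite numeric vector")
  if (any(thickness <= 0)) stop("thickness values must be strictly positive")
  s <- stats::sd(thickness)
  if (s == 0) stop("degenerate input: constant thickness profile (zero SD)")
  (thickness - mean(thickness)) / s
}

#' Fit the normative reference from control profiles
#'
#' Second normalization stage, fitting step: per-region mean and sample SD of
#' the within-subject standardized profiles over the healthy-control group.
#' Every subject (patients and the controls themselves) is subsequently
#' z-scored against this reference.
#'
#' @param control_z Numeric matrix, controls x regions, of within-subject
#'   standardized profiles (rows as returned by [within_subject_normalize()]).
#' @return An `iscn_reference`: list with `mu`, `sigma` (length-R vectors) and
#'   `n_controls`.
#' @export
fit_reference <- function(control_z) {
  if (!is.matrix(control_z)) control_z <- as.matrix(control_z)
  if (nrow(control_z) < 2L)
    stop("reference fitting needs at least 2 control profiles")
  mu <- colMeans(control_z)
  sigma <- apply(control_z, 2L, stats::sd)
  if (any(sigma == 0)) {
    bad <- colnames(control_z)[sigma == 0]
    if (is.null(bad)) bad <- which(sigma == 0)
    stop("degenerate reference: zero control SD in region(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(mu = mu, sigma = sigma, n_controls = nrow(control_z)),
            class = "iscn_reference")
}

#' Deviation profile of a subject against the normative reference
#'
#' @param z Within-subject standardized profile (length R).
#' @param reference An `iscn_reference` from [fit_reference()].
#' @return Numeric vector `n` with `n[i] = (z[i] - mu[i]) / sigma[i]`, the
#'   region-wise deviation of this subject from the control norm.
#' @export
deviation_profile <- function(z, reference) {
  if (length(z) != length(reference$mu))
    stop("profile has ", length(z), " regions but the reference has ",
         length(reference$mu))
  (z - reference$mu) / reference$sigma
}

#' Build one individualized structural covariance matrix
#'
#' Converts a deviation profile into a symmetric weighted network: the edge
#' between regions i and j is `exp(-(n[i] - n[j])^2)`, i.e. 1 when the two
#' regions deviate identically from the norm and decaying with the squared
#' difference of their deviations. Self-connections are excluded (diagonal 0),
#' leaving R(R-1)/2 unique pairs — 10,878 for the 148-region atlas.
#'
#' Weights can underflow to exactly 0 for |n[i] - n[j]| beyond about 27; such
#' entries are kept as 0 and treated as absent edges downstream.
#'
#' @param n Numeric deviation profile (length R, finite).
#' @param atlas Optional registry supplying region dimnames.
#' @return R x R symmetric weight matrix with zero diagonal.
#' @examples
#' W <- build_scn(c(0, 1))
#' W[1, 2]            # exp(-1)
#' @export
build_scn <- function(n, atlas = NULL) {
  if (!is.numeric(n) || !all(is.finite(n)))
    stop("deviation profile must be finite numeric")
  d <- outer(n, n, "-")
  W <- exp(-d * d)
  diag(W) <- 0
  W <- (W + t(W)) / 2  # exact symmetry against FP asymmetries in outer()
  if (!is.null(atlas)) dimnames(W) <- list(atlas$name, atlas$name)
  W
}

#' Build the individualized networks for a whole cohort
#'
#' Orchestrates the two-stage normalization and kernel for every subject:
#' each subject is standardized across their own regions, the normative
#' reference is fitted on the control group only (including each control in
#' its own reference — no leave-one-out), every subject is scored against
#' that reference, and one weighted matrix per subject is built.
#'
#' `normalization = "single-stage"` is provided for sensitivity analysis: it
#' skips the within-subject standardization and z-scores raw thickness
#' against the per-region control mean/SD. The two-stage composition is the
#' default and the analyzed configuration.
#'
#' `control_scoring` governs how the controls themselves are scored. The
#' default, `"in-sample"`, scores every subject — controls included — against
#' the reference fitted on all controls, exactly as the normative-z formula
#' is written. Because each control then contributes to its own norm, control
#' deviations are slightly shrunken relative to out-of-sample patients (about
#' 10% in variance for a 32-control reference), which by itself depresses
#' patient network indices even when no true group difference exists.
#' `"loo"` scores each control against a reference fitted on the other
#' controls, putting both sides on an equal out-of-sample footing; it is
#' offered for sensitivity analyses of that bias. Patients are always scored
#' against the full-control reference.
#'
#' @param cohort An `iscn_cohort`.
#' @param control_group Label identifying controls in `cohort$metadata$group`.
#' @param normalization `"two-stage"` (default) or `"single-stage"`.
#' @param control_scoring `"in-sample"` (default) or `"loo"`.
#' @return A list with `scns` (named list of weight matrices, one per
#'   subject, in cohort order), `deviations` (subjects x regions matrix of
#'   deviation profiles) and `reference` (the fitted `iscn_reference`).
#' @export
build_cohort_scns <- function(cohort, control_group = "control",
                              normalization = c("two-stage", "single-stage"),
                              control_scoring = c("in-sample", "loo")) {
  normalization <- match.arg(normalization)
  control_scoring <- match.arg(control_scoring)
  is_control <- cohort$metadata$group == control_group
  if (!any(is_control))
    stop("no subjects with control group label '", control_group, "'")
  base <- if (normalization == "two-stage") {
    t(apply(cohort$thickness, 1L, within_subject_normalize))
  } else {
    cohort$thickness
  }
  ctrl_rows <- which(is_control)
  reference <- fit_reference(base[ctrl_rows, , drop = FALSE])
  dev <- t(apply(base, 1L, deviation_profile, reference = reference))
  if (control_scoring == "loo") {
    for (i in ctrl_rows) {
      ref_i <- fit_reference(base[setdiff(ctrl_rows, i), , drop = FALSE])
      dev[i, ] <- deviation_profile(base[i, ], ref_i)
    }
  }
  dimnames(dev) <- dimnames(cohort$thickness)
  scns <- lapply(seq_len(nrow(dev)),
                 function(i) build_scn(dev[i, ], atlas = cohort$atlas))
  names(scns) <- rownames(dev)
  list(scns = scns, deviations = dev, reference = reference)
}

#' @export
print.iscn_reference <- function(x, ...) {
  cat("<iscn_reference> ", length(x$mu), " regions, fitted on ",
      x$n_controls, " controls\n", sep = "")
  invisible(x)
}

#' Write / read a fitted reference model as TSV
#'
#' @param reference An `iscn_reference`.
#' @param path File path.
#' @export
write_reference <- function(reference, path) {
  nm <- names(reference$mu)
  if (is.null(nm)) nm <- paste0("region_", seq_along(reference$mu))
  df <- data.frame(region = nm,
                   mu = formatC(reference$mu, format = "g", digits = 17),
                   sigma = formatC(reference$sigma, format = "g", digits = 17),
                   n_controls = reference$n_controls,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(reference)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  structure(list(mu = stats::setNames(as.numeric(df$mu), df$region),
                 sigma = stats::setNames(as.numeric(df$sigma), df$region),
                 n_controls = df$n_controls[1L]),
            class = "iscn_reference")
}
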