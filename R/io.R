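#' Read a cohort from thickness and metadata tables
#'
#' Reads a regional cortical thickness table (one row per subject, one column
#' per atlas region, values in mm) together with a subject metadata table
#' (group label plus covariate / clinical-score columns), and returns a
#' validated cohort with regions re-ordered to the atlas ordering.
#'
#' Both files are tab-separated UTF-8 with a mandatory header row and `.` as
#' the decimal separator. The first column of the thickness file is the
#' subject identifier; the remaining column names must match the atlas region
#' names exactly (after whitespace trimming and case folding), in any order.
#' The metadata file is keyed by its `subject_id` column and must contain a
#' `group` column; all other columns are carried along as covariates /
#' clinical scores. Subjects appearing in the thickness file but not in the
#' metadata are an error; metadata-only subjects are dropped. Row order
#' follows the thickness file.
#'
#' Missing, non-numeric or non-positive thickness values are rejected (no
#' imputation), naming the offending subject and region.
#'
#' @param thickness_path Path to the thickness TSV.
#' @param metadata_path Path to the metadata TSV.
#' @param atlas Region registry; defaults to [destrieux_atlas()].
#' @return An `iscn_cohort`: a list with `thickness` (subjects x regions
#'   numeric matrix, atlas column order), `metadata` (data frame, one row per
#'   subject) and `atlas`.
#' @export
read_cohort <- function(thickness_path, metadata_path,
                        atlas = destrieux_atlas()) {
  if (!file.exists(thickness_path))
    stop("thickness file not found: ", thickness_path)
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  th <- utils::read.delim(thickness_path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  md <- utils::read.delim(metadata_path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(th) < 2L) stop("thickness file has no region columns")

  subject_id <- as.character(th[[1L]])
  region_cols <- names(th)[-1L]
  key <- normalize_region_name(region_cols)
  atlas_key <- normalize_region_name(atlas$name)

  extra <- region_cols[!(key %in% atlas_key)]
  if (length(extra) > 0L)
    stop("thickness file has column(s) not in the atlas: ",
         paste(extra, collapse = ", "))
  missing <- atlas$name[!(atlas_key %in% key)]
  if (length(missing) > 0L)
    stop("thickness file is missing region column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(key))
    stop("thickness file has duplicated region column(s)")

  # re-order columns to atlas order
  mat <- as.matrix(th[-1L])[, match(atlas_key, key), drop = FALSE]
  storage.mode(mat) <- "double"
  dimnames(mat) <- list(subject_id, atlas$name)
  bad <- which(!is.finite(mat) | mat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric or non-positive thickness for subject '",
         subject_id[bad[1L, 1L]], "', region '",
         atlas$name[bad[1L, 2L]], "'")

  if (!("subject_id" %in% names(md)))
    stop("metadata file lacks a subject_id column")
  if (!("group" %in% names(md)))
    stop("metadata file lacks a group column")
  md$subject_id <- as.character(md$subject_id)
  absent <- setdiff(subject_id, md$subject_id)
  if (length(absent) > 0L)
    stop("subject(s) in thickness file absent from metadata: ",
         paste(absent, collapse = ", "))
  md <- md[match(subject_id, md$subject_id), , drop = FALSE]
  rownames(md) <- NULL

  new_cohort(mat, md, atlas)
}

#' Assemble a cohort from in-memory pieces
#'
#' Constructor for programmatic use (the file-based entry point is
#' [read_cohort()]): validates that thickness rows line up with metadata rows
#' and that every declared group has at least two subjects.
#'
#' @param thickness Numeric matrix, subjects x regions, in atlas column
#'   order, with subject ids as row names.
#' @param metadata Data frame with one row per subject (`subject_id`,
#'   `group`, covariates, scores).
#' @param atlas An `iscn_atlas`.
#' @return An `iscn_cohort`.
#' @export
new_cohort <- function(thickness, metadata, atlas) {
  stopifnot(is.matrix(thickness), nrow(thickness) == nrow(metadata))
  tab <- table(metadata$group)
  if (any(tab < 2L))
    stop("every declared group needs at least 2 subjects; offending group(s): ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  structure(list(thickness = thickness, metadata = metadata, atlas = atlas),
            class = "iscn_cohort")
}

#' @export
print.iscn_cohort <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat("<iscn_cohort> ", nrow(x$thickness), " subjects x ",
      ncol(x$thickness), " regions (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Write a cohort back to thickness/metadata TSV files
#'
#' Inverse of [read_cohort()]; round trips are lossless to the stored
#' precision (`%.17g`).
#'
#' @param cohort An `iscn_cohort`.
#' @param thickness_path,metadata_path Output paths.
#' @export
write_cohort <- function(cohort, thickness_path, metadata_path) {
  mat <- cohort$thickness
  df <- data.frame(subject_id = rownames(mat),
                   as.data.frame(formatC(mat, format = "g", digits = 17)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("subject_id", colnames(mat))
  utils::write.table(df, thickness_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(cohort$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(cohort)
}

#' Write / read a network matrix as TSV
#'
#' Matrices are stored tab-separated with a region-name header row and a
#' leading region-name column, at full double precision so that
#' `read_scn_matrix(write_scn_matrix(W))` reproduces `W` exactly.
#'
#' @param W Symmetric, zero-diagonal weight matrix with region dimnames.
#' @param path File path.
#' @export
write_scn_matrix <- function(W, path) {
  validate_scn(W)
  txt <- formatC(W, format = "g", digits = 17)
  df <- data.frame(region = rownames(W), txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("region", colnames(W))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(W)
}

#' @rdname write_scn_matrix
#' @param atlas Optional registry to validate dimensions and names against.
#' @return `read_scn_matrix` returns the validated weight matrix.
#' @export
read_scn_matrix <- function(path, atlas = NULL) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  rn <- as.character(df[[1L]])
  W <- as.matrix(df[-1L])
  storage.mode(W) <- "double"
  rownames(W) <- rn
  if (!is.null(atlas)) {
    if (nrow(W) != nrow(atlas) || ncol(W) != nrow(atlas))
      stop("matrix in ", path, " is ", nrow(W), "x", ncol(W),
           " but the atlas has ", nrow(atlas), " regions")
    if (!identical(normalize_region_name(rn),
                   normalize_region_name(atlas$name)))
      stop("matrix row names in ", path, " do not match the atlas ordering")
  }
  validate_scn(W)
  W
}

validate_scn <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("network matrix must be square")
  if (!all(is.finite(W))) stop("network matrix has non-finite entries")
  if (!isTRUE(all(W == t(W)))) stop("network matrix is not symmetric")
  if (any(diag(W) != 0)) stop("network matrix diagonal must be zero")
  if (any(W < 0) || any(W > 1))
    stop("network weights must lie in [0, 1]")
  invisible(W)
}
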