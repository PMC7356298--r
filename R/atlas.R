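#' Destrieux cortical parcellation registry
#'
#' Returns the region registry used by the default pipeline: the Destrieux
#' surface parcellation with 74 sulco-gyral areas per hemisphere, 148 regions
#' in total. Region ordering is fixed (left hemisphere 1-74, then right
#' 75-148) and persisted with the package, so that thickness tables, deviation
#' profiles and network matrices always line up.
#'
#' @return A data frame of class `iscn_atlas` with columns `region_id`
#'   (1-based ordinal), `name` (descriptive label, e.g.
#'   `"left suborbital sulcus"`), `code` (FreeSurfer-style `a2009s` code) and
#'   `hemisphere` (`"left"` or `"right"`).
#' @examples
#' atlas <- destrieux_atlas()
#' nrow(atlas)                                   # 148
#' region_id(atlas, "left superior occipital gyrus")
#' @export
destrieux_atlas <- function() {
  path <- system.file("extdata", "destrieux_148.tsv", package = "iscn",
                      mustWork = TRUE)
  read_atlas(path)
}

#' Read a region registry from a tab-separated file
#'
#' The file must have columns `region_id`, `name` and `hemisphere`
#' (a `code` column is optional and preserved when present).
#'
#' @param path Path to a UTF-8, tab-separated registry file.
#' @return An `iscn_atlas` data frame.
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  needed <- c("region_id", "name", "hemisphere")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L)
    stop("atlas file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  as_atlas(df)
}

#' Construct a synthetic region registry
#'
#' Convenience for simulations at reduced region counts: labels regions
#' `"left region 1"`, ..., splitting hemispheres as evenly as possible.
#'
#' @param n_regions Number of regions (>= 3).
#' @return An `iscn_atlas` data frame.
#' @export
synthetic_atlas <- function(n_regions) {
  if (n_regions < 3L) stop("an atlas needs at least 3 regions")
  n_left <- ceiling(n_regions / 2)
  hemi <- rep(c("left", "right"), c(n_left, n_regions - n_left))
  idx <- c(seq_len(n_left), seq_len(n_regions - n_left))
  as_atlas(data.frame(
    region_id = seq_len(n_regions),
    name = paste(hemi, "region", idx),
    hemisphere = hemi,
    stringsAsFactors = FALSE))
}

as_atlas <- function(df) {
  df$name <- trimws(df$name)
  if (anyDuplicated(tolower(df$name)))
    stop("atlas region names are not unique")
  if (!all(df$hemisphere %in% c("left", "right")))
    stop("atlas hemisphere labels must be 'left' or 'right'")
  if (!identical(as.integer(df$region_id), seq_len(nrow(df))))
    stop("atlas region_id must be 1..R in order")
  df$region_id <- as.integer(df$region_id)
  class(df) <- c("iscn_atlas", "data.frame")
  df
}

# exact match after whitespace trimming and case folding; atlas exports vary
# in case, so lookups are case-insensitive by design
normalize_region_name <- function(x) tolower(trimws(x))

#' Look up region ids by name
#'
#' Matching is exact after whitespace trimming and case folding.
#'
#' @param atlas An `iscn_atlas`.
#' @param name Character vector of region names.
#' @return Integer vector of region ids (1-based).
#' @export
region_id <- function(atlas, name) {
  idx <- match(normalize_region_name(name), normalize_region_name(atlas$name))
  if (anyNA(idx))
    stop("region(s) not in atlas: ",
         paste(name[is.na(idx)], collapse = ", "))
  atlas$region_id[idx]
}

#' @export
print.iscn_atlas <- function(x, ...) {
  cat("<iscn_atlas> ", nrow(x), " regions (",
      sum(x$hemisphere == "left"), " left / ",
      sum(x$hemisphere == "right"), " right)\n", sep = "")
  invisible(x)
}
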