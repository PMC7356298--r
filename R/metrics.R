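#' Nodal strength (weighted degree)
#'
#' @param W Symmetric weight matrix with zero diagonal.
#' @return Vector of per-node sums of incident edge weights.
#' @export
node_strength <- function(W) {
  validate_scn(W)
  rowSums(W)
}

#' Global strength
#'
#' Mean nodal strength over all regions. On the similarity-kernel networks
#' built here (weights in (0, 1], up to 147 neighbours) this is the index on
#' the scale of tens reported for whole-cohort comparisons.
#'
#' @inheritParams node_strength
#' @return Scalar.
#' @export
global_strength <- function(W) mean(node_strength(W))

#' Weighted nodal clustering coefficient (Onnela variant)
#'
#' Geometric-mean triangle intensity on max-normalized weights: with
#' `w' = W / max(W)`, the coefficient of node i is the sum over neighbour
#' pairs (j, h) of `(w'_ij w'_ih w'_jh)^(1/3)`, divided by `k_i (k_i - 1)`
#' where `k_i` counts neighbours with nonzero weight. Nodes with fewer than
#' two neighbours get 0. Values lie in [0, 1]; a complete graph with uniform
#' weights scores 1 at every node.
#'
#' @inheritParams node_strength
#' @return Vector of per-node coefficients in [0, 1].
#' @export
nodal_clustering <- function(W) {
  validate_scn(W)
  .nodal_clustering_unchecked(W)
}

.nodal_clustering_unchecked <- function(W) {
  mx <- max(W)
  if (mx == 0) return(stats::setNames(numeric(nrow(W)), rownames(W)))
  W13 <- (W / mx)^(1 / 3)
  cyc <- diag(W13 %*% W13 %*% W13)  # 2x the triangle intensity around i
  k <- rowSums(W > 0)
  C <- ifelse(k < 2, 0, cyc / (k * (k - 1)))
  stats::setNames(C, rownames(W))
}

#' Global clustering coefficient
#'
#' Unweighted mean of the nodal coefficients over all regions.
#'
#' @inheritParams node_strength
#' @return Scalar in [0, 1].
#' @export
global_clustering <- function(W) mean(nodal_clustering(W))

#' All-pairs shortest path lengths
#'
#' Similarity weights are mapped to lengths by `l = 1/w` (strong edges are
#' short); zero weights are absent edges. Distances are computed by
#' Dijkstra's algorithm from every source, in compiled code specialized to
#' the dense matrices the similarity kernel produces; unreachable pairs get
#' `Inf`.
#'
#' @inheritParams node_strength
#' @return Symmetric R x R distance matrix with zero diagonal.
#' @export
shortest_path_matrix <- function(W) {
  validate_scn(W)
  .shortest_path_unchecked(W)
}

.shortest_path_unchecked <- function(W) {
  L <- matrix(Inf, nrow(W), ncol(W))
  L[W > 0] <- 1 / W[W > 0]
  D <- .dijkstra_all_pairs(L)
  dimnames(D) <- dimnames(W)
  D
}

#' Characteristic path length
#'
#' Mean shortest-path length over ordered pairs i != j with finite distance;
#' `Inf` when no finite pair exists (fully disconnected network).
#'
#' @param D Distance matrix from [shortest_path_matrix()].
#' @return Scalar.
#' @export
characteristic_path_length <- function(D) {
  off <- D[row(D) != col(D)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0L) return(Inf)
  mean(fin)
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered pairs i != j, with
#' `1/Inf = 0` so disconnected pairs contribute nothing.
#'
#' @inheritParams characteristic_path_length
#' @return Scalar in [0, 1] for kernel-weighted networks.
#' @export
global_efficiency <- function(D) {
  off <- D[row(D) != col(D)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

#' All network indices for one subject
#'
#' @inheritParams node_strength
#' @return List with `global` (named vector: `strength`, `clustering`,
#'   `path_length`, `efficiency`) and `nodal` (list with per-region `strength`
#'   and `clustering` vectors).
#' @export
compute_metrics <- function(W) {
  validate_scn(W)
  .compute_metrics_unchecked(W)
}

.compute_metrics_unchecked <- function(W) {
  ns <- rowSums(W)
  nc <- .nodal_clustering_unchecked(W)
  D <- .shortest_path_unchecked(W)
  list(
    global = c(strength = mean(ns),
               clustering = mean(nc),
               path_length = characteristic_path_length(D),
               efficiency = global_efficiency(D)),
    nodal = list(strength = ns, clustering = nc))
}

#' Network indices for a whole cohort
#'
#' @param scns Named list of weight matrices (one per subject), e.g. the
#'   `scns` element of [build_cohort_scns()].
#' @return List with `global` (data frame: subject_id + the four global
#'   indices) and `nodal_clustering` (subjects x regions matrix).
#' @export
cohort_metrics <- function(scns) {
  lapply(scns, validate_scn)
  res <- lapply(scns, .compute_metrics_unchecked)
  glob <- do.call(rbind, lapply(res, function(m) m$global))
  nodal <- do.call(rbind, lapply(res, function(m) m$nodal$clustering))
  rownames(glob) <- rownames(nodal) <- names(scns)
  list(global = data.frame(subject_id = names(scns),
                           glob, row.names = NULL,
                           stringsAsFactors = FALSE),
       nodal_clustering = nodal)
}
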