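# Independent brute-force oracles used to cross-check the graph-metric and
# statistics implementations. Deliberately written in the most literal way
# possible (scalar loops, textbook algorithms), never sharing code with the
# package internals they check.

oracle_strength <- function(W) {
  n <- nrow(W)
  s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j != i) s[i] <- s[i] + W[i, j]
  s
}

# Onnela weighted clustering: exhaustive enumeration of ordered neighbour
# pairs on max-normalized weights
oracle_onnela <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(numeric(n))
  Wh <- W / mx
  C <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    acc <- 0
    for (j in nb) for (h in nb) if (j != h)
      acc <- acc + (Wh[i, j] * Wh[i, h] * Wh[j, h])^(1 / 3)
    C[i] <- acc / (k * (k - 1))
  }
  C
}

# all-pairs shortest paths by Floyd-Warshall on l = 1/w lengths
oracle_floyd_warshall <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  D[W > 0] <- 1 / W[W > 0]
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_path_length <- function(D) {
  vals <- c()
  n <- nrow(D)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) vals <- c(vals, D[i, j])
  if (length(vals) == 0) Inf else mean(vals)
}

oracle_efficiency <- function(D) {
  vals <- c()
  n <- nrow(D)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) vals <- c(vals, if (is.finite(D[i, j])) 1 / D[i, j] else 0)
  mean(vals)
}

# partial correlation through the inverse of the joint correlation matrix —
# an algebraically different route from residual regression
oracle_pcor <- function(x, y, Z) {
  P <- solve(stats::cor(cbind(x, y, Z)))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# random symmetric weight matrix in [0,1], zero diagonal, optional sparsity
random_weight_matrix <- function(n, p_zero = 0.3) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  w <- stats::runif(sum(ut))
  w[stats::runif(length(w)) < p_zero] <- 0
  W[ut] <- w
  W + t(W)
}

# complete uniform-weight graph
uniform_graph <- function(n, w) {
  W <- matrix(w, n, n)
  diag(W) <- 0
  W
}

# fixed study regions carrying the planted nodal effects in recovery tests
planted_regions <- c(
  "left suborbital sulcus",
  "right superior frontal sulcus",
  "right long insular gyrus and central insular sulcus",
  "left superior occipital gyrus")
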