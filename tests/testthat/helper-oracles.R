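# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: covariances by brute-force path intersection,
# factorials by direct multiplication, soft thresholding in closed form.

# Random binary rooted tree with positive branch lengths.
rand_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05  # keep lengths well above zero
  tr
}

# Brute-force Brownian covariance: C[i, j] is the summed length of the
# edges shared by the root-to-i and root-to-j paths.
bf_brownian_cov <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2L]] <- tree$edge.length
  path_edges <- function(tip) {
    e <- integer(0)
    nd <- tip
    while (nd != root) {
      e <- c(e, nd)  # identify each edge by its child node
      nd <- parent[nd]
    }
    e
  }
  paths <- lapply(seq_len(n), path_edges)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
  }
  C
}

# Direct factorial Brillouin for small counts.
bf_brillouin <- function(counts) {
  N <- sum(counts)
  (log(factorial(N)) - sum(log(factorial(counts)))) / N
}

# All partitions of N into at most k nonnegative parts (ordered,
# exhaustive) -- small N only.
all_partitions <- function(N, k) {
  if (k == 1L) return(list(N))
  out <- list()
  for (first in 0:N) {
    for (rest in all_partitions(N - first, k - 1L)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

# Univariate soft-threshold lasso solution for a standardized predictor
# (x'x/m = 1): sign(rho) * max(|rho| - lambda, 0), rho = x'y/m.
bf_soft_threshold <- function(x, y, lambda) {
  m <- length(y)
  rho <- sum(x * y) / m
  sign(rho) * max(abs(rho) - lambda, 0)
}

# Named trait vector of Brownian draws for a tree (thin convenience).
bm_trait <- function(tree, rate = 1, seed = 1) {
  drop(simulate_bm(tree, rate = rate, n_traits = 1, seed = seed))
}
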