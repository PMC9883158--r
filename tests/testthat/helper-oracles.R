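# Shared oracles and fixture builders. All fixtures are generated in code
# under fixed seeds; nothing is read from disk.

# Exhaustive enumeration of the CTMC likelihood over all internal-state
# assignments (feasible for <= 6 tips). Independent of the pruning code:
# uses R matrix exponentials via transition_probabilities.
brute_force_ctmc_loglik <- function(tree, states, Q, root_freq = rep(0.25, 4)) {
  tp <- ape::reorder.phylo(tree, "postorder")
  n <- length(tp$tip.label)
  m <- tp$Nnode
  P <- lapply(seq_len(nrow(tp$edge)),
              function(e) transition_probabilities(Q, tp$edge.length[e]))
  combos <- expand.grid(rep(list(0:3), m))
  tips <- states[tp$tip.label]
  tot <- 0
  for (r in seq_len(nrow(combos))) {
    full <- c(tips, as.integer(combos[r, ]))
    root <- tp$edge[nrow(tp$edge), 1]
    pr <- root_freq[full[root] + 1]
    for (e in seq_len(nrow(tp$edge))) {
      pr <- pr * P[[e]][full[tp$edge[e, 1]] + 1, full[tp$edge[e, 2]] + 1]
    }
    tot <- tot + pr
  }
  log(tot)
}

# Euler-Maruyama simulation of the OU SDE, for checking exact transition
# moments. Returns empirical mean and covariance of X(t) | X(0) = x0.
euler_ou_moments <- function(A, b, S, x0, t_end, dt = 1e-3, n_paths = 1e5,
                             seed = 1) {
  set.seed(seed)
  D <- nrow(A)
  X <- matrix(rep(x0, each = n_paths), n_paths, D)
  n_steps <- round(t_end / dt)
  sq <- sqrt(dt)
  for (k in seq_len(n_steps)) {
    drift <- X %*% t(A) + matrix(b, n_paths, D, byrow = TRUE)
    X <- X + drift * dt + (matrix(stats::rnorm(n_paths * D), n_paths, D) %*% t(S)) * sq
  }
  list(mean = colMeans(X), cov = stats::cov(X), n = n_paths)
}

# A random stable selection matrix (all eigenvalue real parts < 0).
random_stable_A <- function(D = 2) {
  A <- matrix(stats::rnorm(D * D, 0, 0.6), D, D)
  shift <- max(Re(eigen(A, only.values = TRUE)$values))
  A - diag(shift + stats::runif(1, 0.3, 1.2), D)
}

# Random rooted tree with branch lengths, via ape.
random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr
}

make_society_table <- function(tree, ordinal, struct = NULL, coords = NULL) {
  n <- length(tree$tip.label)
  tab <- data.frame(society = sprintf("SOC%03d", seq_len(n)),
                    taxon = tree$tip.label,
                    political_authority = ordinal[, 1],
                    religious_authority = ordinal[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(struct)) tab$authority_structure <- as.integer(struct)
  if (!is.null(coords)) { tab$lat <- coords[, 1]; tab$lon <- coords[, 2] }
  tab
}
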