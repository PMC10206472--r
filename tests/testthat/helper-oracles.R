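# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# Brownian motion simulated edge by edge (root value 0, each edge adds an
# independent N(0, edge length) increment). Structurally independent of
# ape::vcv / phylo_covariance: the only shared input is the tree itself.
# Returns an nrep x ntip matrix of tip values.
bm_edgewalk <- function(tree, nrep) {
  tre <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  n_node <- max(tre$edge)
  ntip <- length(tre$tip.label)
  vals <- matrix(0, n_node, nrep)
  for (i in seq_len(nrow(tre$edge))) {
    par <- tre$edge[i, 1]; child <- tre$edge[i, 2]
    vals[child, ] <- vals[par, ] +
      stats::rnorm(nrep, sd = sqrt(tre$edge.length[i]))
  }
  out <- t(vals[seq_len(ntip), , drop = FALSE])
  colnames(out) <- tre$tip.label
  out
}

# Closed-form one-way ANOVA variance components for a balanced layout
# (s groups x m replicates): sigma2_e = MSW, sigma2_p = (MSB - MSW)/m.
anova_components <- function(y, group) {
  m <- unique(table(group))
  stopifnot(length(m) == 1L)
  s <- length(unique(group))
  gm <- tapply(y, group, mean)
  msw <- sum(tapply(y, group, function(v) sum((v - mean(v))^2))) /
    (s * (m - 1))
  msb <- m * sum((gm - mean(y))^2) / (s - 1)
  list(sigma2_e = msw, sigma2_p = (msb - msw) / m)
}

# Balanced one-way dataset with clear between-group variance.
balanced_oneway <- function(s = 8, m = 5, sd_between = 2, seed = 7) {
  withr::with_seed(seed, {
    g <- rep(sprintf("sp%02d", seq_len(s)), each = m)
    y <- rep(stats::rnorm(s, sd = sd_between), each = m) +
      stats::rnorm(s * m)
    data.frame(species = g, y = y)
  })
}

# The six-pair toy whose permutation null is exhaustively enumerable.
toy_pairs <- function() {
  data.frame(pair_type = rep(c("host", "random"), each = 3),
             abs_difference = c(1, 1, 2, 5, 5, 6))
}

# Exact two-sided permutation p for a two-group mean difference by full
# enumeration of the label assignments.
exact_perm_p <- function(d, n_host) {
  obs <- mean(d[-seq_len(n_host)]) - mean(d[seq_len(n_host)])
  combs <- utils::combn(length(d), n_host)
  ests <- apply(combs, 2, function(ix) mean(d[-ix]) - mean(d[ix]))
  mean(abs(ests) >= abs(obs) - 1e-12)
}

# One synthetic dataset plus its standardized covariance, for model tests.
sim_dataset <- function(seed, n_species = 45, n_parasites = 14,
                        eggs_per_species = 4, sigma2_p = 9, sigma2_e = 1,
                        beta_parasitism = 0, convergence_w = 0, mu = 0,
                        trait_name = "y") {
  cfg <- simulation_config(
    n_species = n_species, n_parasites = n_parasites,
    eggs_per_species = eggs_per_species, mu = mu,
    sigma2_p = sigma2_p, sigma2_e = sigma2_e,
    beta_parasitism = beta_parasitism, convergence_w = convergence_w,
    trait_name = trait_name)
  tree <- simulate_tree(n_species, seed = seed)
  ds <- simulate_traits(tree, cfg, seed = seed + 1L)
  ds$A <- phylo_covariance(tree)$A
  ds
}
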