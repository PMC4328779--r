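# Shared fixtures and independent oracles, all built in code.

tree2 <- function() parse_newick("(A:1,B:1);")
tree3 <- function() parse_newick("((A:1,B:1):1,C:2);")
tree4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

# Dense-algebra GLS log-likelihood oracle: explicit inverse and determinant,
# no Cholesky, no profiling shortcuts.
dense_bm_logL <- function(C, x) {
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  a <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  dev <- x - a
  s2 <- as.numeric(dev %*% Ci %*% dev) / n
  as.numeric(-0.5 * (n * log(2 * pi * s2) + log(det(C)) + n))
}

# From-scratch K oracle with explicit matrix inverses.
dense_k <- function(C, x) {
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  a <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  dev <- x - a
  mse0 <- sum(dev^2) / (n - 1)
  mse <- as.numeric(dev %*% Ci %*% dev) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  (mse0 / mse) / expected
}

# Path-based covariance oracle: C_ij = (depth_i + depth_j - d_ij) / 2, with
# patristic distances from ape::cophenetic.phylo (a different code path from
# ape::vcv.phylo used in the implementation).
path_vcv <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  dep <- tip_depths(tree)[rownames(d)]
  (outer(dep, dep, "+") - d) / 2
}

# Brute-force two-stage aggregation using base tapply only.
tapply_taxon_means <- function(verses, trait) {
  ind_means <- tapply(verses[[trait]],
                      interaction(verses$taxon, verses$individual, drop = TRUE),
                      mean)
  taxon_of <- sub("\\..*$", "", names(ind_means))
  tapply(ind_means, taxon_of, mean)
}

# Correlated pair of Brownian traits with tip-level correlation rho.
sim_bm_pair <- function(tree, rho) {
  x <- simulate_trait(tree, "BM")
  y <- rho * x + sqrt(1 - rho^2) * simulate_trait(tree, "BM")
  list(x = x, y = y)
}

small_study <- function(seed = 11, n_taxa = 30) {
  simulate_study(synth_config(n_taxa = n_taxa), seed = seed)
}
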