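#' Blomberg's K statistic of phylogenetic signal
#'
#' K compares the observed partitioning of trait variance to its
#' Brownian-motion expectation on the given tree. With `C` the phylogenetic
#' covariance and `a_hat` the GLS (phylogenetic) mean,
#' `K = (MSE0/MSE) / E[MSE0/MSE]`, where `MSE0` is the ordinary mean squared
#' deviation from `a_hat`, `MSE` the phylogenetically corrected one
#' (`(x-a)' C^-1 (x-a)/(n-1)`), and the expectation under BM is
#' `(tr(C) - n/sum(C^-1)) / (n-1)`. K = 1 matches the Brownian expectation;
#' K near 0 indicates no phylogenetic signal; K > 1 means relatives resemble
#' each other even more than BM predicts.
#'
#' @param tree A rooted binary `phylo` object with branch lengths.
#' @param x Tip values (named by taxon or in `tree$tip.label` order).
#' @return K (non-negative scalar).
#' @export
blomberg_k <- function(tree, x) {
  tree <- validate_song_tree(tree)
  x <- as.numeric(align_to_tips(x, tree))
  if (stats::sd(x) == 0) stop("constant trait: K undefined", call. = FALSE)
  C <- phylo_vcv(tree)
  n <- length(x)
  cd <- chol_logdet(C)
  ones <- matrix(1, n, 1)
  xw <- whiten(cd$U, x)
  ow <- whiten(cd$U, ones)
  a_hat <- sum(ow * xw) / sum(ow * ow)
  dev <- x - a_hat
  mse0 <- sum(dev^2) / (n - 1)
  devw <- whiten(cd$U, dev)
  mse <- sum(devw^2) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(ow * ow)) / (n - 1)
  (mse0 / mse) / expected
}

#' Randomization test for phylogenetic signal
#'
#' Tests whether trait values are randomly distributed over the tips of the
#' tree. The test statistic is the variance of the standardized independent
#' contrasts — small when related taxa resemble each other. Tip values are
#' shuffled across taxa `n_perm` times and the one-sided permutation
#' p-value is `(#(perm <= observed) + 1) / (n_perm + 1)`, so the smallest
#' attainable p with 999 permutations is 0.001.
#'
#' @param tree A rooted binary `phylo` object.
#' @param x Tip values.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed for reproducibility.
#' @return A list: `P`, `observed` (contrast variance), `perm_stats`,
#'   `n_perm`, `seed`.
#' @export
signal_randomization <- function(tree, x, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  tree <- validate_song_tree(tree)
  x <- as.numeric(align_to_tips(x, tree))
  if (stats::sd(x) == 0) stop("constant trait: test undefined", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eng <- pic_engine(tree)
  obs <- stats::var(eng(x)$contrast)
  perm <- vapply(seq_len(n_perm), function(i) {
    stats::var(eng(sample(x))$contrast)
  }, numeric(1))
  list(P = (sum(perm <= obs) + 1) / (n_perm + 1),
       observed = obs, perm_stats = perm, n_perm = n_perm, seed = seed)
}

# Profile log-likelihood of the lambda model at a fixed lambda:
# root state and sigma2 are profiled analytically.
lambda_profile_logL <- function(x, C, lambda) {
  V <- C * lambda
  diag(V) <- diag(C)
  n <- length(x)
  fit <- gls_profile(x, matrix(1, n, 1), V)
  fit$logL
}

#' Pagel's lambda by profile maximum likelihood
#'
#' Pagel's lambda rescales the off-diagonal (shared-history) entries of the
#' phylogenetic covariance: lambda = 1 recovers Brownian motion, lambda = 0
#' phylogenetic independence. The root state and rate are profiled
#' analytically; lambda is maximised over `[0, 1]` by a coarse grid followed
#' by bounded golden-section refinement (tolerance 1e-8), with both
#' endpoints always evaluated — the profile can be multimodal on small
#' trees, so the search is restarted around the best grid point.
#'
#' @param tree A rooted binary `phylo` object.
#' @param x Tip values (non-constant).
#' @return A list: `lambda` (the ML estimate), `logL`, `sigma2`,
#'   `root_state`.
#' @export
pagel_lambda <- function(tree, x) {
  tree <- validate_song_tree(tree)
  x <- as.numeric(align_to_tips(x, tree))
  if (stats::sd(x) == 0) stop("constant trait: lambda undefined", call. = FALSE)
  C <- phylo_vcv(tree)
  f <- function(l) lambda_profile_logL(x, C, l)
  grid <- seq(0, 1, length.out = 21)
  gl <- vapply(grid, f, numeric(1))
  g <- grid[which.max(gl)]
  lo <- max(0, g - 0.1); hi <- min(1, g + 0.1)
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1, g)
  cand_l <- c(opt$objective, gl[1], gl[length(gl)], max(gl))
  best <- which.max(cand_l)
  lam <- cand[best]
  V <- C * lam
  diag(V) <- diag(C)
  fit <- gls_profile(x, matrix(1, length(x), 1), V)
  list(lambda = lam, logL = fit$logL, sigma2 = fit$sigma2_ml,
       root_state = unname(fit$beta))
}

#' Per-trait phylogenetic signal table
#'
#' Two-step signal inference for each trait column: the contrast-variance
#' randomization test (detection), then Blomberg's K (strength) and Pagel's
#' lambda by profile ML (strength under the lambda model).
#'
#' @param data Per-taxon trait table with a `taxon` column.
#' @param tree The analysis tree.
#' @param traits Character vector of trait columns to test.
#' @param n_perm Permutations for the randomization test.
#' @param seed Integer master seed; trait i uses `seed + i` so results do
#'   not depend on which traits are run together.
#' @return A tibble: `trait`, `K`, `P`, `lambda`, `logL_lambda`, `n_perm`,
#'   `seed`.
#' @export
phylo_signal <- function(data, tree, traits, n_perm = 999, seed = 1) {
  check_taxa_match(data, tree)
  purrr::map_dfr(seq_along(traits), function(i) {
    x <- trait_vector(data, traits[i])
    rt <- signal_randomization(tree, x, n_perm = n_perm, seed = seed + i)
    pl <- pagel_lambda(tree, x)
    tibble::tibble(trait = traits[i],
                   K = blomberg_k(tree, x),
                   P = rt$P,
                   lambda = pl$lambda,
                   logL_lambda = pl$logL,
                   n_perm = n_perm,
                   seed = seed + i)
  })
}
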