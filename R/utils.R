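# Internal numerical helpers shared by the signal / model / pGLS machinery.
# All likelihood code funnels through a Cholesky factorisation so that
# log-determinants are accumulated in log space (80x80 covariance matrices
# under small lambda can underflow a naive det()).

# Cholesky factor and log-determinant of a covariance matrix.
# Errors informatively when C is not positive definite (e.g. duplicate
# zero-length terminal branches under lambda = 1).
chol_logdet <- function(C) {
  U <- tryCatch(chol(C), error = function(e) {
    stop("phylogenetic covariance matrix is singular or not positive definite",
         call. = FALSE)
  })
  list(U = U, logdet = 2 * sum(log(diag(U))))
}

# Whiten columns of M by the transpose-inverse of the upper Cholesky factor:
# returns U'^{-1} M, so that whitened vectors have identity covariance.
whiten <- function(U, M) {
  backsolve(U, M, transpose = TRUE)
}

# Profile ML of a Gaussian GLS model y ~ X with covariance sigma2 * C:
# beta and sigma2 are profiled analytically. Returns the ML quantities and
# the pieces needed for Wald t-tests.
gls_profile <- function(y, X, C) {
  n <- length(y)
  cd <- chol_logdet(C)
  yw <- whiten(cd$U, y)
  Xw <- whiten(cd$U, X)
  colnames(Xw) <- colnames(X)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient after whitening", call. = FALSE)
  }
  beta <- qr.coef(qrX, yw)
  resid_w <- yw - Xw %*% beta
  rss <- sum(resid_w^2)
  sigma2_ml <- rss / n
  logL <- -0.5 * (n * log(2 * pi * sigma2_ml) + cd$logdet + n)
  XtX_inv <- chol2inv(qr.R(qrX))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  list(beta = drop(beta), rss = rss, sigma2_ml = sigma2_ml, logL = logL,
       XtX_inv = XtX_inv, U = cd$U, logdet = cd$logdet)
}

# Generalized (phylogenetic) mean: the GLS intercept a_hat = (1'C^-1 x)/(1'C^-1 1).
phylo_mean <- function(x, C) {
  ones <- matrix(1, length(x), 1)
  gls_profile(x, ones, C)$beta
}

# Reorder a named trait vector to match tree tip labels; error on mismatch.
align_to_tips <- function(x, tree, what = "trait values") {
  tips <- tree$tip.label
  if (!is.null(names(x))) {
    missing <- setdiff(tips, names(x))
    extra <- setdiff(names(x), tips)
    if (length(missing) || length(extra)) {
      stop(sprintf("%s do not match tree tips (missing: %s; extra: %s)",
                   what,
                   paste(utils::head(missing, 5), collapse = ", "),
                   paste(utils::head(extra, 5), collapse = ", ")),
           call. = FALSE)
    }
    x <- x[tips]
  } else if (length(x) != length(tips)) {
    stop(sprintf("%s must be named by taxon or have one entry per tip", what),
         call. = FALSE)
  }
  x
}

# Extract a named tip-value vector for one trait column of a taxon table.
trait_vector <- function(data, trait, taxon_col = "taxon") {
  stats::setNames(data[[trait]], data[[taxon_col]])
}
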