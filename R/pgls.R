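#' @importFrom stats as.formula model.matrix reformulate terms
NULL

# Build response vector and predictor matrix (no intercept column) from a
# formula and data, with an informative error on rank deficiency.
build_design <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(y = y, X = X)
}

new_gls_fit <- function(response, coef_tbl, lambda, lambda_mode, logL, AIC,
                        n, df_residual, sigma2, formula, method) {
  structure(
    list(response = response, coefficients = coef_tbl, lambda = lambda,
         lambda_mode = lambda_mode, logL = logL, AIC = AIC, n = n,
         df_residual = df_residual, sigma2 = sigma2, formula = formula,
         method = method),
    class = "pgls_fit"
  )
}

coef_table <- function(beta, se, df) {
  tstat <- unname(beta / se)
  tibble::tibble(term = names(beta), estimate = unname(beta),
                 std.error = unname(se), statistic = tstat,
                 p.value = 2 * stats::pt(-abs(tstat), df))
}

#' Ordinary least-squares fit with classical t-tests
#'
#' Identity-covariance special case of the fitting machinery used by
#' [pgls_fit()]; returned in the same `pgls_fit` container so the two are
#' directly comparable.
#'
#' @param data Per-taxon table.
#' @param formula Model formula, e.g. `tges ~ migration + lat_equator`.
#' @param standardize Z-score the numeric predictors before fitting so
#'   coefficient magnitudes are comparable (does not change t or p).
#' @return A `pgls_fit` object with `lambda = 0`, `method = "OLS"`.
#' @export
ols_fit <- function(data, formula, standardize = TRUE) {
  if (standardize) data <- standardize_predictors(data, formula)
  d <- build_design(formula, data)
  n <- length(d$y); p <- ncol(d$X)
  if (n <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  fit <- gls_profile(d$y, d$X, diag(1, n))
  sigma2 <- fit$rss / (n - p)
  se <- sqrt(sigma2 * diag(fit$XtX_inv))
  new_gls_fit(all.vars(formula)[1], coef_table(fit$beta, se, n - p),
              lambda = 0, lambda_mode = "fixed", logL = fit$logL,
              AIC = -2 * fit$logL + 2 * (p + 1), n = n,
              df_residual = n - p, sigma2 = sigma2, formula = formula,
              method = "OLS")
}

standardize_predictors <- function(data, formula) {
  vars <- all.vars(formula)[-1]
  vars <- intersect(vars, names(data))
  for (v in vars) {
    if (is.numeric(data[[v]]) && stats::sd(data[[v]]) > 0) {
      data[[v]] <- as.numeric(scale(data[[v]]))
    }
  }
  data
}

#' Phylogenetic generalized least squares with lambda covariance
#'
#' GLS regression whose error covariance is the lambda-transformed
#' phylogenetic covariance `C(lambda)`:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`. `lambda` is either fixed or estimated
#' by profile maximum likelihood over `[0, 1]` (grid + golden-section
#' refinement, endpoints included). Coefficient t-tests use `df = n - p`.
#' `lambda = 0` reduces to OLS; `lambda = 1` is the Brownian-motion GLS,
#' whose slopes equal through-origin regression on independent contrasts.
#'
#' @param data Per-taxon table with a `taxon` column matching the tree tips.
#' @param tree The analysis tree.
#' @param formula Model formula.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @param standardize Z-score numeric predictors (default TRUE).
#' @return A `pgls_fit` object.
#' @export
pgls_fit <- function(data, tree, formula, lambda = "ML", standardize = TRUE) {
  check_taxa_match(data, tree)
  data <- data[match(tree$tip.label, data$taxon), ]
  if (standardize) data <- standardize_predictors(data, formula)
  d <- build_design(formula, data)
  n <- length(d$y); p <- ncol(d$X)
  if (n <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  C <- phylo_vcv(tree)

  lam_cov <- function(l) {
    V <- C * l
    diag(V) <- diag(C)
    V
  }
  if (identical(lambda, "ML")) {
    f <- function(l) gls_profile(d$y, d$X, lam_cov(l))$logL
    grid <- seq(0, 1, length.out = 21)
    gl <- vapply(grid, f, numeric(1))
    g <- grid[which.max(gl)]
    opt <- stats::optimize(f, c(max(0, g - 0.1), min(1, g + 0.1)),
                           maximum = TRUE, tol = 1e-8)
    cand <- c(opt$maximum, 0, 1, g)
    cand_l <- c(opt$objective, gl[1], gl[length(gl)], max(gl))
    lam <- cand[which.max(cand_l)]
    mode <- "ML"
    k_extra <- 2L  # sigma2 + lambda
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lam <- lambda
    mode <- "fixed"
    k_extra <- 1L  # sigma2
  }
  fit <- gls_profile(d$y, d$X, lam_cov(lam))
  sigma2 <- fit$rss / (n - p)
  se <- sqrt(sigma2 * diag(fit$XtX_inv))
  new_gls_fit(all.vars(formula)[1], coef_table(fit$beta, se, n - p),
              lambda = lam, lambda_mode = mode, logL = fit$logL,
              AIC = -2 * fit$logL + 2 * (p + k_extra), n = n,
              df_residual = n - p, sigma2 = sigma2, formula = formula,
              method = "pGLS")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("%s fit of %s (n = %d", x$method, x$response, x$n))
  if (x$method == "pGLS") {
    cat(sprintf(", lambda = %.4f [%s]", x$lambda, x$lambda_mode))
  }
  cat(sprintf("), logL = %.4f\n", x$logL))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(response = x$response, method = x$method, lambda = x$lambda,
                 logL = x$logL, AIC = x$AIC, n = x$n,
                 df.residual = x$df_residual, sigma2 = x$sigma2)
}

# Remove predictors that are exact linear combinations of earlier ones
# (e.g. a range midpoint alongside both range limits), keeping column order.
# Backward elimination from an aliased full model would be undefined.
drop_aliased <- function(data, response, predictors) {
  X <- stats::model.matrix(reformulate(predictors, response), data)
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) return(predictors)
  aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
  message("dropping aliased predictor(s): ", paste(aliased, collapse = ", "))
  setdiff(predictors, aliased)
}

step_aic <- function(rss, n, k) n * log(rss / n) + 2 * k

rss_of <- function(data, response, predictors) {
  f <- if (length(predictors)) reformulate(predictors, response) else
    as.formula(paste(response, "~ 1"))
  sum(stats::resid(stats::lm(f, data = data))^2)
}

#' Backward stepwise reduction of a linear model
#'
#' Starting from the full predictor set, repeatedly removes the single
#' predictor whose removal most improves the criterion, stopping when no
#' removal improves it. Two criteria are available: `"aic"` (default)
#' drops the predictor giving the largest AIC decrease
#' (`AIC = n log(RSS/n) + 2k` up to a constant); `"pvalue"` drops the
#' largest-p predictor while any p exceeds `p_threshold`. Ties are broken
#' by column order (earliest listed predictor dropped first).
#'
#' @param data Per-taxon table.
#' @param formula Full model formula.
#' @param mode `"aic"` or `"pvalue"`.
#' @param p_threshold Removal threshold for `mode = "pvalue"`.
#' @return An object of class `step_trace`: list with `trace` (tibble:
#'   `step`, `dropped`, `aic`, `n_predictors`), `predictors` (final set),
#'   `response`, `formula` (reduced formula).
#' @export
stepwise_reduce <- function(data, formula, mode = c("aic", "pvalue"),
                            p_threshold = 0.1) {
  mode <- match.arg(mode)
  response <- all.vars(formula)[1]
  preds <- attr(terms(formula, data = data), "term.labels")
  n <- nrow(data)
  # full-model rank check up front
  invisible(build_design(formula, data))

  trace <- tibble::tibble(step = 0L, dropped = NA_character_,
                          aic = step_aic(rss_of(data, response, preds), n,
                                         length(preds) + 1),
                          n_predictors = length(preds))
  step_i <- 0L
  repeat {
    if (!length(preds)) break
    if (mode == "aic") {
      cur_aic <- trace$aic[nrow(trace)]
      cand <- vapply(seq_along(preds), function(j) {
        step_aic(rss_of(data, response, preds[-j]), n, length(preds[-j]) + 1)
      }, numeric(1))
      j <- which.min(cand)  # first minimum = column-order tie-break
      if (cand[j] >= cur_aic) break
      step_i <- step_i + 1L
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        step = step_i, dropped = preds[j], aic = cand[j],
        n_predictors = length(preds) - 1L))
      preds <- preds[-j]
    } else {
      f <- reformulate(preds, response)
      sm <- summary(stats::lm(f, data = data))$coefficients
      pv <- sm[, 4]
      pv <- pv[names(pv) != "(Intercept)"]
      if (all(pv <= p_threshold)) break
      j <- which.max(pv)  # which.max takes the first maximum
      drop_name <- names(pv)[j]
      preds <- setdiff(preds, drop_name)
      step_i <- step_i + 1L
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        step = step_i, dropped = drop_name,
        aic = step_aic(rss_of(data, response, preds), n, length(preds) + 1),
        n_predictors = length(preds)))
    }
  }
  final_formula <- if (length(preds)) reformulate(preds, response) else
    as.formula(paste(response, "~ 1"))
  structure(list(trace = trace, predictors = preds, response = response,
                 formula = final_formula, mode = mode),
            class = "step_trace")
}

#' @export
print.step_trace <- function(x, ...) {
  cat("Backward stepwise reduction of", x$response,
      sprintf("(%s criterion)\n", x$mode))
  print(as.data.frame(x$trace), row.names = FALSE)
  cat("Final predictors:",
      if (length(x$predictors)) paste(x$predictors, collapse = ", ")
      else "(intercept only)", "\n")
  invisible(x)
}

#' @export
tidy.step_trace <- function(x, ...) x$trace

#' Full single-trait modelling chain: OLS, stepwise reduction, pGLS
#'
#' Fits the ordinary linear model of one song trait on all explanatory
#' variables, reduces it backward to a minimal model, then refits the
#' reduced predictor set (including its non-significant members) as a
#' phylogenetic GLS with ML-estimated lambda. The summary marks predictors
#' significant in the pGLS at `alpha` and the strongest contributor
#' (smallest p).
#'
#' @param data Per-taxon trait table with a `taxon` column.
#' @param tree The analysis tree.
#' @param trait Response song-trait column name.
#' @param predictors Explanatory columns (default the standard fifteen).
#' @param step_mode Passed to [stepwise_reduce()].
#' @param alpha Significance threshold for the pGLS markers.
#' @param lambda `"ML"` or fixed value, passed to [pgls_fit()].
#' @return An object of class `trait_model`: list with `trace`
#'   (`step_trace`), `pgls` (`pgls_fit`), and `summary` (tibble: `term`,
#'   `estimate`, `p.value`, `significant`, `strongest`).
#' @export
run_trait_model <- function(data, tree, trait,
                            predictors = intersect(explanatory_traits(), names(data)),
                            step_mode = "aic", alpha = 0.05, lambda = "ML") {
  check_taxa_match(data, tree)
  predictors <- drop_aliased(data, trait, predictors)
  data_std <- standardize_predictors(data, reformulate(predictors, trait))
  full <- reformulate(predictors, trait)
  trace <- stepwise_reduce(data_std, full, mode = step_mode)
  pg <- pgls_fit(data_std, tree, trace$formula, lambda = lambda,
                 standardize = FALSE)
  ct <- pg$coefficients[pg$coefficients$term != "(Intercept)", ]
  summary <- dplyr::mutate(
    ct,
    significant = .data$p.value < alpha,
    strongest = seq_len(nrow(ct)) == ifelse(nrow(ct), which.min(ct$p.value), 0L)
  )
  structure(list(trait = trait, trace = trace, pgls = pg, summary = summary),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  print(x$trace)
  cat("\n")
  print(x$pgls)
  sig <- x$summary$term[x$summary$significant]
  cat("\npGLS-significant predictors:",
      if (length(sig)) paste(sig, collapse = ", ") else "(none)", "\n")
  if (any(x$summary$strongest)) {
    cat("Strongest contributor:", x$summary$term[x$summary$strongest], "\n")
  }
  invisible(x)
}

#' @export
tidy.trait_model <- function(x, ...) x$summary
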