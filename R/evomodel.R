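#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`. Requires `n > k + 1`.
#'
#' @param logL Maximised log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (number of tips).
#' @return The AICc value.
#' @export
aicc <- function(logL, k, n) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1", call. = FALSE)
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Canonical model-name order
#'
#' The five continuous-trait models in the fixed order used for exact-tie
#' breaking in model selection.
#'
#' @return Character vector `c("BM", "OU", "EB", "lambda", "white")`.
#' @export
evomodel_names <- function() c("BM", "OU", "EB", "lambda", "white")

#' Maximum-likelihood fit of one continuous-trait evolution model
#'
#' Fits one of the five standard models of continuous trait evolution on a
#' time tree by maximum likelihood. The root state and rate `sigma2` are
#' profiled analytically in every model; the single shape parameter of OU
#' (`alpha`, searched on a log scale over `[1e-8/T, 50/T]` with T the tree
#' depth), EB (`r` over `[log(1e-5)/T, -1e-8]`) and lambda (over `[0, 1]`)
#' is maximised by bounded one-dimensional search. Parameter counts are 2
#' for BM and white (root + rate) and 3 for OU, EB and lambda.
#'
#' @param tree A rooted binary `phylo` object; must be ultrametric for OU
#'   and EB.
#' @param x Tip values.
#' @param model One of `"BM"`, `"OU"`, `"EB"`, `"lambda"`, `"white"`.
#' @return An object of class `evomodel_fit`: list with `model`, `params`
#'   (named list: `sigma2`, `root_state`, and the shape parameter if any),
#'   `logL`, `k`, `n`, `AICc`, `boundary` (TRUE if the shape estimate sits
#'   on a search bound).
#' @export
fit_evomodel <- function(tree, x, model = c("BM", "OU", "EB", "lambda", "white")) {
  model <- match.arg(model)
  tree <- validate_song_tree(tree)
  x <- as.numeric(align_to_tips(x, tree))
  n <- length(x)
  C <- phylo_vcv(tree)
  ones <- matrix(1, n, 1)
  if (model %in% c("OU", "EB") && !isTRUE(attr(tree, "ultrametric"))) {
    stop(model, " fitting requires an ultrametric tree", call. = FALSE)
  }
  if (model %in% c("OU", "lambda")) {
    term <- tree$edge[, 2] <= n
    if (any(tree$edge.length[term] == 0)) {
      stop("zero-length terminal branches make the ", model,
           " covariance singular", call. = FALSE)
    }
  }
  T_depth <- max(diag(C))

  fit_fixed_shape <- function(V) gls_profile(x, ones, V)

  boundary <- FALSE
  if (model == "BM") {
    fit <- fit_fixed_shape(C)
    params <- list(sigma2 = fit$sigma2_ml, root_state = unname(fit$beta))
    k <- 2L
  } else if (model == "white") {
    V <- diag(1, n)
    fit <- fit_fixed_shape(V)
    params <- list(sigma2 = fit$sigma2_ml, root_state = unname(fit$beta))
    k <- 2L
  } else if (model == "lambda") {
    pl <- pagel_lambda(tree, x)
    fit <- list(logL = pl$logL)
    params <- list(sigma2 = pl$sigma2, root_state = pl$root_state,
                   lambda = pl$lambda)
    boundary <- pl$lambda %in% c(0, 1)
    k <- 3L
  } else if (model == "OU") {
    bounds <- log(c(1e-8 / T_depth, 50 / T_depth))
    f <- function(la) {
      fit_fixed_shape(transform_vcv(C, "OU", sigma2 = 1, alpha = exp(la)))$logL
    }
    opt <- stats::optimize(f, bounds, maximum = TRUE, tol = 1e-8)
    # guard against a flat profile near the BM (alpha -> 0) boundary
    end_lo <- f(bounds[1])
    if (end_lo > opt$objective) opt <- list(maximum = bounds[1], objective = end_lo)
    alpha <- exp(opt$maximum)
    fit <- fit_fixed_shape(transform_vcv(C, "OU", sigma2 = 1, alpha = alpha))
    params <- list(sigma2 = fit$sigma2_ml, root_state = unname(fit$beta),
                   alpha = alpha)
    boundary <- min(abs(opt$maximum - bounds)) < 1e-6
    k <- 3L
  } else { # EB
    bounds <- c(log(1e-5) / T_depth, -1e-8)
    f <- function(r) {
      fit_fixed_shape(transform_vcv(C, "EB", sigma2 = 1, r = r))$logL
    }
    opt <- stats::optimize(f, bounds, maximum = TRUE, tol = 1e-10)
    end_hi <- f(bounds[2])
    if (end_hi > opt$objective) opt <- list(maximum = bounds[2], objective = end_hi)
    r <- opt$maximum
    fit <- fit_fixed_shape(transform_vcv(C, "EB", sigma2 = 1, r = r))
    params <- list(sigma2 = fit$sigma2_ml, root_state = unname(fit$beta),
                   r = r)
    boundary <- min(abs(r - bounds)) < 1e-6 * abs(bounds[1])
    k <- 3L
  }
  if (model %in% c("OU", "EB")) {
    params$sigma2 <- params$sigma2  # rate is relative to the unit-sigma2 transform
  }
  structure(
    list(model = model, params = params, logL = fit$logL, k = k, n = n,
         AICc = if (n > k + 1) aicc(fit$logL, k, n) else NA_real_,
         boundary = boundary),
    class = "evomodel_fit"
  )
}

#' @export
print.evomodel_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): logL = %.4f, AICc = %.4f\n",
              x$model, x$n, x$logL, x$AICc))
  cat("  params:", paste(names(x$params), signif(unlist(x$params), 5),
                         sep = " = ", collapse = ", "), "\n")
  if (x$boundary) cat("  note: shape parameter at search boundary\n")
  invisible(x)
}

#' @export
glance.evomodel_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logL = x$logL, k = x$k, n = x$n,
                 AICc = x$AICc, boundary = x$boundary)
}

#' @export
tidy.evomodel_fit <- function(x, ...) {
  tibble::tibble(model = x$model, parameter = names(x$params),
                 estimate = unlist(x$params, use.names = FALSE))
}

#' AICc model selection across the five trait-evolution models
#'
#' Fits BM, OU, EB, lambda and white-noise models and ranks them by AICc.
#' The best model is the AICc minimum (exact ties broken by the fixed model
#' order BM < OU < EB < lambda < white); models within `delta_aicc_tie`
#' AICc units of the best are reported as near-tied alternatives.
#'
#' @param tree A rooted binary `phylo` object.
#' @param x Tip values.
#' @param models Which models to fit.
#' @param delta_aicc_tie Near-tie threshold on delta-AICc (default 2).
#' @return An object of class `evomodel_selection`: list with `fits`
#'   (tibble of per-model logL/AICc/delta), `best`, `alternatives`,
#'   `fit_objects`.
#' @export
select_evomodel <- function(tree, x, models = evomodel_names(),
                            delta_aicc_tie = 2) {
  models <- match.arg(models, evomodel_names(), several.ok = TRUE)
  models <- evomodel_names()[evomodel_names() %in% models]  # canonical order
  fits <- list()
  errs <- character()
  for (m in models) {
    f <- tryCatch(fit_evomodel(tree, x, m), error = function(e) e)
    if (inherits(f, "error")) {
      errs[m] <- conditionMessage(f)
      warning(sprintf("%s fit failed: %s", m, conditionMessage(f)),
              call. = FALSE)
    } else {
      fits[[m]] <- f
    }
  }
  if (!length(fits)) {
    stop("all model fits failed: ", paste(errs, collapse = "; "), call. = FALSE)
  }
  tbl <- purrr::map_dfr(fits, glance.evomodel_fit)
  tbl$delta_AICc <- tbl$AICc - min(tbl$AICc)
  best <- tbl$model[which.min(tbl$AICc)]  # first minimum = canonical order
  alternatives <- tbl$model[tbl$model != best & tbl$delta_AICc < delta_aicc_tie]
  structure(
    list(fits = tbl, best = best, alternatives = alternatives,
         fit_objects = fits),
    class = "evomodel_selection"
  )
}

#' @export
print.evomodel_selection <- function(x, ...) {
  alt <- if (length(x$alternatives)) {
    paste0(" (", paste(x$alternatives, collapse = ", "), ")")
  } else ""
  cat("Best model:", x$best, alt, "\n")
  print(as.data.frame(x$fits), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.evomodel_selection <- function(x, ...) x$fits

#' @export
glance.evomodel_selection <- function(x, ...) {
  tibble::tibble(best = x$best,
                 alternatives = paste(x$alternatives, collapse = ","),
                 n = x$fits$n[1])
}

#' Per-trait model selection table
#'
#' @param data Per-taxon trait table with a `taxon` column.
#' @param tree The analysis tree.
#' @param traits Trait columns to fit.
#' @param ... Passed to [select_evomodel()].
#' @return Tibble: `trait`, `best`, `alternatives` (comma-separated), plus
#'   one `AICc_<model>` column per model.
#' @export
model_selection_table <- function(data, tree, traits, ...) {
  check_taxa_match(data, tree)
  purrr::map_dfr(traits, function(tr) {
    sel <- select_evomodel(tree, trait_vector(data, tr), ...)
    wide <- stats::setNames(as.list(sel$fits$AICc),
                            paste0("AICc_", sel$fits$model))
    dplyr::bind_cols(
      tibble::tibble(trait = tr, best = sel$best,
                     alternatives = paste(sel$alternatives, collapse = ",")),
      tibble::as_tibble(wide)
    )
  })
}
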