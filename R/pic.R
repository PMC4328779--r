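#' Felsenstein's phylogenetically independent contrasts
#'
#' Post-order pruning pass: at each internal node with child values
#' `x1, x2` on (adjusted) branches `b1, b2`, the standardized contrast is
#' `(x1 - x2)/sqrt(b1 + b2)`, the inferred ancestral value is the
#' branch-length-weighted average `(x1/b1 + x2/b2)/(1/b1 + 1/b2)`, and the
#' parent branch is lengthened by `b1*b2/(b1 + b2)` to carry the estimation
#' uncertainty rootward. A binary tree with n tips yields exactly n - 1
#' contrasts, mutually independent under Brownian motion.
#'
#' @param tree A rooted binary `phylo` object with branch lengths.
#' @param x Tip values, named by taxon or ordered as `tree$tip.label`.
#' @param scaled Standardize each contrast by its expected standard
#'   deviation `sqrt(b1 + b2)` (default) or return raw differences.
#' @return A tibble with one row per internal node: `node` (ape node id),
#'   `contrast`, and `sum_bl`, the adjusted branch-length sum that
#'   standardized the contrast. Attribute `root_value` holds the inferred
#'   root state.
#' @export
pic_contrasts <- function(tree, x, scaled = TRUE) {
  tree <- validate_song_tree(tree)
  x <- align_to_tips(x, tree)
  eng <- pic_engine(tree)
  res <- eng(as.numeric(x), scaled = scaled)
  n <- length(tree$tip.label)
  out <- tibble::tibble(node = res$nodes, contrast = res$contrast,
                        sum_bl = res$sum_bl)
  attr(out, "root_value") <- res$root_value
  out
}

# Precompiled pruning traversal: validates and orders the tree once, then
# returns a function computing contrasts for any tip-value vector (in
# tip-label order). Used by the permutation test, where the same tree is
# traversed hundreds of times.
pic_engine <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  blen0 <- numeric(n + nn)
  blen0[tree$edge[, 2]] <- tree$edge.length
  po <- ape::reorder.phylo(tree, "postorder")
  parents <- po$edge[, 1]
  # process each internal node after its complete subtree: order parents by
  # the position of their last out-edge in the postorder edge list
  last_edge <- tapply(seq_along(parents), parents, max)
  ord <- as.integer(names(last_edge))[order(last_edge)]
  kid_list <- split(tree$edge[, 2], tree$edge[, 1])
  ch1 <- vapply(as.character(ord), function(k) kid_list[[k]][1], integer(1))
  ch2 <- vapply(as.character(ord), function(k) kid_list[[k]][2], integer(1))

  function(x, scaled = TRUE) {
    val <- numeric(n + nn)
    val[seq_len(n)] <- x
    blen <- blen0
    contrast <- numeric(nn)
    sum_bl <- numeric(nn)
    for (i in seq_along(ord)) {
      node <- ord[i]
      k1 <- ch1[i]; k2 <- ch2[i]
      b1 <- blen[k1]; b2 <- blen[k2]
      s <- b1 + b2
      if (s == 0) {
        stop(sprintf("zero branch-length sum at node %d: contrast undefined",
                     node), call. = FALSE)
      }
      j <- node - n
      contrast[j] <- (val[k1] - val[k2]) / if (scaled) sqrt(s) else 1
      sum_bl[j] <- s
      val[node] <- if (b1 == 0) val[k1] else if (b2 == 0) val[k2] else
        (val[k1] / b1 + val[k2] / b2) / (1 / b1 + 1 / b2)
      blen[node] <- blen[node] + b1 * b2 / s
    }
    list(nodes = n + seq_len(nn), contrast = contrast, sum_bl = sum_bl,
         root_value = val[n + 1L])
  }
}

#' Through-origin correlation of independent contrasts
#'
#' Contrasts have arbitrary sign (which child is subtracted is a
#' convention), so their joint relationship must be estimated through the
#' origin: `r = sum(u*v)/sqrt(sum(u^2) * sum(v^2))` over the contrast pairs,
#' with a t-test on `df = n_contrasts - 1` degrees of freedom (one fewer
#' than the contrast count, the through-origin regression convention).
#'
#' @param tree A rooted binary `phylo` object.
#' @param x,y Tip values for the two variables (named or in tip order).
#' @return A one-row tibble: `r_pic`, `p_pic`, `df`, `n` (number of tips).
#' @export
pic_correlation <- function(tree, x, y) {
  if (stats::sd(as.numeric(x)) == 0 || stats::sd(as.numeric(y)) == 0) {
    stop("constant tip values: all contrasts are zero, correlation undefined",
         call. = FALSE)
  }
  u <- pic_contrasts(tree, x)$contrast
  v <- pic_contrasts(tree, y)$contrast
  su <- sum(u^2); sv <- sum(v^2)
  if (su == 0 || sv == 0) {
    stop("all contrasts are zero for one variable: correlation undefined",
         call. = FALSE)
  }
  r <- sum(u * v) / sqrt(su * sv)
  df <- length(u) - 1
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  tibble::tibble(r_pic = r, p_pic = p, df = df, n = length(u) + 1L)
}

#' Ordinary (non-phylogenetic) Pearson correlation of tip values
#'
#' @param x,y Numeric vectors of per-taxon values.
#' @return A one-row tibble: `r_raw`, `p_raw`, `n`.
#' @export
raw_correlation <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r_raw = unname(ct$estimate), p_raw = ct$p.value,
                 n = length(x))
}

#' All pairwise trait-predictor correlations, raw and phylogenetic
#'
#' For every (song trait, explanatory variable) pair, computes the ordinary
#' Pearson correlation on tip values and the through-origin correlation of
#' independent contrasts. Holm-adjusted p-value columns are appended for
#' convenience; the per-pair (unadjusted) p-values are the primary output.
#'
#' @param data Per-taxon trait table with a `taxon` column.
#' @param tree The analysis tree; tips must match `data$taxon`.
#' @param song_vars,expl_vars Column sets to pair up.
#' @return A long tibble: `trait`, `predictor`, `r_raw`, `p_raw`, `r_pic`,
#'   `p_pic`, `df_pic`, `n`, `p_raw_holm`, `p_pic_holm`.
#' @export
correlate_traits <- function(data, tree,
                             song_vars = intersect(c(song_traits(), pc_traits()), names(data)),
                             expl_vars = intersect(explanatory_traits(), names(data))) {
  check_taxa_match(data, tree)
  data <- data[match(tree$tip.label, data$taxon), ]
  # contrasts per variable computed once
  all_vars <- unique(c(song_vars, expl_vars))
  contr <- lapply(all_vars, function(v) pic_contrasts(tree, trait_vector(data, v))$contrast)
  names(contr) <- all_vars
  grid <- tidyr::expand_grid(trait = song_vars, predictor = expl_vars)
  res <- purrr::pmap_dfr(grid, function(trait, predictor) {
    x <- data[[trait]]; y <- data[[predictor]]
    raw <- raw_correlation(x, y)
    u <- contr[[trait]]; v <- contr[[predictor]]
    r <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    df <- length(u) - 1
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    tibble::tibble(trait = trait, predictor = predictor,
                   r_raw = raw$r_raw, p_raw = raw$p_raw,
                   r_pic = r, p_pic = 2 * stats::pt(-abs(tstat), df),
                   df_pic = df, n = length(x))
  })
  res$p_raw_holm <- stats::p.adjust(res$p_raw, method = "holm")
  res$p_pic_holm <- stats::p.adjust(res$p_pic, method = "holm")
  res
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Correlation matrix layout (predictors x traits)
#'
#' Reshapes the long output of [correlate_traits()] into the familiar
#' matrix layout: rows are explanatory variables, columns song traits,
#' cells `r` with significance stars (`*` < 0.05, `**` < 0.01,
#' `***` < 0.001) for the chosen variant.
#'
#' @param cor_tbl Output of [correlate_traits()].
#' @param which `"raw"` or `"pic"`.
#' @param digits Rounding for the displayed coefficients.
#' @return A tibble, one row per predictor.
#' @export
correlation_matrix <- function(cor_tbl, which = c("raw", "pic"), digits = 2) {
  which <- match.arg(which)
  r <- cor_tbl[[paste0("r_", which)]]
  p <- cor_tbl[[paste0("p_", which)]]
  cells <- paste0(formatC(round(r, digits), format = "f", digits = digits),
                  significance_stars(p))
  tidyr::pivot_wider(
    tibble::tibble(predictor = cor_tbl$predictor, trait = cor_tbl$trait,
                   cell = cells),
    names_from = "trait", values_from = "cell"
  )
}

check_taxa_match <- function(data, tree) {
  miss <- setdiff(tree$tip.label, data$taxon)
  extra <- setdiff(data$taxon, tree$tip.label)
  if (length(miss) || length(extra)) {
    stop(sprintf("taxa mismatch between table and tree (missing from table: %s; absent from tree: %s)",
                 paste(utils::head(miss, 5), collapse = ", "),
                 paste(utils::head(extra, 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
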