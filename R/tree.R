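#' Parse a rooted binary chronogram from a newick string
#'
#' Strict newick reader for the analysis tree: branch lengths are required,
#' the tree must be rooted and strictly bifurcating, and tip labels must be
#' unique. Support values after closing parentheses are parsed and stored in
#' `node.label` but otherwise ignored. Polytomies are rejected rather than
#' silently resolved with zero branches, because zero-branch resolution would
#' change the number (and standardisation) of independent contrasts.
#'
#' @param text A newick string (single tree, terminated by `;`).
#' @return An [ape::phylo] object with an `ultrametric` logical attribute.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' attr(tr, "ultrametric")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  check_newick_syntax(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed newick string", call. = FALSE)
  validate_song_tree(tree)
}

#' Read the analysis tree from a newick file
#'
#' @param file Path to a newick file containing one tree.
#' @return An [ape::phylo] object, validated as for [parse_newick()].
#' @export
read_song_tree <- function(file) {
  parse_newick(paste(readLines(file, warn = FALSE), collapse = ""))
}

#' Write a tree to a newick string or file
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @return The newick string, invisibly when writing to a file.
#' @export
write_song_tree <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Character-level well-formedness scan so parse failures report an offset.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed newick: unmatched ')' at character %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed newick: %d unclosed '(' at end of string", depth),
         call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop(sprintf("malformed newick: missing ';' terminator at character %d",
                 nchar(text)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a tree for comparative analysis
#'
#' Checks the invariants the downstream methods rely on: a single root, a
#' strictly binary topology, branch lengths present and non-negative, unique
#' tip labels. Sets attribute `ultrametric` to `TRUE` iff all root-to-tip
#' depths agree within relative tolerance `tol` (chronograms from dating
#' software carry rounding noise, so exact equality is not required).
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance on root-to-tip depth spread.
#' @return The tree, with the `ultrametric` attribute set.
#' @export
validate_song_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; a chronogram is required", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels", call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  if (n_tip < 2) stop("tree must have at least 2 tips", call. = FALSE)
  kids <- tabulate(tree$edge[, 1], nbins = n_tip + tree$Nnode)
  internal <- kids[(n_tip + 1):(n_tip + tree$Nnode)]
  if (any(internal > 2)) {
    stop("non-binary tree: polytomies are not supported", call. = FALSE)
  }
  if (any(internal == 1)) {
    stop("tree contains singleton (unbranched) internal nodes", call. = FALSE)
  }
  depths <- tip_depths(tree)
  T_max <- max(depths)
  attr(tree, "ultrametric") <- (T_max - min(depths)) <= tol * max(T_max, .Machine$double.eps)
  tree
}

#' Root-to-tip path lengths
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Named numeric vector of root-to-tip depths, in tip-label order.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  stats::setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Total depth (age) of an ultrametric tree
#'
#' @param tree A `phylo` object.
#' @return Maximum root-to-tip path length.
#' @export
tree_depth <- function(tree) max(tip_depths(tree))

#' Binary star tree
#'
#' A star phylogeny (all tips attached at the root, no shared history) in
#' strictly binary form: a pectinate topology whose internal branches all
#' have length zero. Its covariance is `depth * I`, Blomberg's K equals 1
#' for any non-constant trait, and contrasts carry no phylogenetic
#' structure.
#'
#' @param n Number of tips (>= 2).
#' @param depth Root-to-tip branch length.
#' @param labels Optional tip labels (default `t1..tn`).
#' @return A validated binary `phylo` object.
#' @export
star_tree <- function(n, depth = 1, labels = paste0("t", seq_len(n))) {
  stopifnot(n >= 2, depth > 0, length(labels) == n)
  nwk <- paste0(labels[1], ":", depth)
  for (i in seq_len(n)[-1]) {
    nwk <- paste0("(", nwk, ",", labels[i], ":", depth, "):",
                  if (i == n) "0;" else "0")
  }
  parse_newick(nwk)
}

is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  (max(d) - min(d)) <= tol * max(max(d), .Machine$double.eps)
}

#' Phylogenetic variance-covariance matrix
#'
#' C[i, j] is the shared path length from the root to the most recent common
#' ancestor of tips i and j; C[i, i] is the root-to-tip depth. This is the
#' Brownian-motion trait covariance (up to the rate) implied by the tree, and
#' the object every signal, model-selection and pGLS computation is built on.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A symmetric matrix with tip labels as dimnames, in tip-label order.
#' @export
phylo_vcv <- function(tree) {
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label]
}

#' Model-specific transformation of the phylogenetic covariance
#'
#' Builds the trait covariance implied by each of the five continuous-trait
#' models from the Brownian-motion covariance `C` (see [phylo_vcv()]):
#'
#' * `BM`: `sigma2 * C`.
#' * `lambda`: off-diagonal entries multiplied by `lambda` (Pagel's branch
#'   length transform), diagonal unchanged, then scaled by `sigma2`.
#' * `white`: `sigma2 * I` — no phylogenetic covariance at all.
#' * `OU`: the root-conditioned (non-stationary) Ornstein-Uhlenbeck form
#'   `V[i,j] = sigma2/(2*alpha) * exp(-alpha*d_ij) * (1 - exp(-2*alpha*s_ij))`
#'   with `s_ij = C[i,j]` the shared path and `d_ij` the patristic distance.
#' * `EB`: early burst with exponentially decaying rate,
#'   `V[i,j] = sigma2 * (exp(r*s_ij) - 1)/r`, reducing to BM as `r -> 0`.
#'
#' OU and EB require an ultrametric `C` (equal diagonal within relative 1e-6).
#'
#' @param C Phylogenetic covariance matrix from [phylo_vcv()].
#' @param model One of `"BM"`, `"OU"`, `"EB"`, `"lambda"`, `"white"`.
#' @param sigma2 Evolutionary rate (trait^2 per unit time), > 0.
#' @param lambda Pagel's lambda in `[0, 1]` (lambda model only).
#' @param alpha OU pull strength (1/time), > 0 (OU only).
#' @param r EB rate-decay exponent (1/time), <= 0 (EB only).
#' @return The transformed covariance matrix.
#' @export
transform_vcv <- function(C, model = c("BM", "OU", "EB", "lambda", "white"),
                          sigma2 = 1, lambda = NULL, alpha = NULL, r = NULL) {
  model <- match.arg(model)
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  dg <- diag(C)
  ultra <- (max(dg) - min(dg)) <= 1e-6 * max(dg)
  switch(model,
    BM = sigma2 * C,
    white = {
      V <- diag(sigma2, nrow(C))
      dimnames(V) <- dimnames(C)
      V
    },
    lambda = {
      if (is.null(lambda) || lambda < 0 || lambda > 1) {
        stop("lambda must lie in [0, 1]", call. = FALSE)
      }
      V <- C * lambda
      diag(V) <- dg
      sigma2 * V
    },
    OU = {
      if (!ultra) stop("OU transform requires an ultrametric tree", call. = FALSE)
      if (is.null(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
      d <- outer(dg, dg, "+") - 2 * C
      sigma2 / (2 * alpha) * exp(-alpha * d) * (1 - exp(-2 * alpha * C))
    },
    EB = {
      if (!ultra) stop("EB transform requires an ultrametric tree", call. = FALSE)
      if (is.null(r) || r > 0) stop("r must be <= 0", call. = FALSE)
      if (abs(r) < 1e-12) sigma2 * C else sigma2 * (exp(r * C) - 1) / r
    }
  )
}
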