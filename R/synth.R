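#' Simulate a Yule / birth-death chronogram
#'
#' Birth-death tree conditioned on the number of surviving tips (via
#' [ape::rphylo()]), rescaled so the root-to-tip depth equals `depth`.
#' The default (death rate 0) is a pure-birth Yule tree.
#'
#' @param n_taxa Number of tips.
#' @param birth,death Speciation and extinction rates (> 0, >= 0).
#' @param depth Target root-to-tip depth after rescaling.
#' @param seed Optional integer seed.
#' @return An ultrametric binary `phylo` object with tips `t1..tn`.
#' @export
simulate_tree <- function(n_taxa = 80, birth = 1, death = 0, depth = 1,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- NULL
  for (i in seq_len(50)) {
    tree <- tryCatch(ape::rphylo(n_taxa, birth = birth, death = death),
                     error = function(e) NULL)
    if (!is.null(tree)) break
  }
  if (is.null(tree)) {
    stop("birth-death simulation failed repeatedly (all lineages extinct?)",
         call. = FALSE)
  }
  tree$edge.length <- tree$edge.length * (depth / max(ape::node.depth.edgelength(tree)))
  validate_song_tree(tree)
}

#' Simulate a continuous trait under one of the five models
#'
#' Draws tip values from the multivariate normal distribution with mean
#' `root_state` and covariance `transform_vcv(C, model, ...)`.
#'
#' @param tree A rooted binary `phylo` object (ultrametric for OU/EB).
#' @param model,sigma2,lambda,alpha,r Model and parameters as in
#'   [transform_vcv()].
#' @param root_state Trait value at the root.
#' @param nsim Number of independent replicate traits.
#' @param seed Optional integer seed.
#' @return A named vector of tip values (`nsim = 1`) or an `nsim` x n
#'   matrix with tip labels as column names.
#' @export
simulate_trait <- function(tree, model = "BM", sigma2 = 1, root_state = 0,
                           lambda = NULL, alpha = NULL, r = NULL,
                           nsim = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- validate_song_tree(tree)
  C <- phylo_vcv(tree)
  V <- transform_vcv(C, model, sigma2 = sigma2, lambda = lambda,
                     alpha = alpha, r = r)
  n <- nrow(V)
  x <- MASS::mvrnorm(nsim, mu = rep(root_state, n), Sigma = V)
  if (nsim == 1) stats::setNames(drop(x), tree$tip.label)
  else `colnames<-`(x, tree$tip.label)
}

# Standardize a simulated trait to zero mean / unit sd across tips.
# Affine, so it preserves the planted K and lambda structure exactly.
std_trait <- function(x) (x - mean(x)) / stats::sd(x)

# One latent draw under a model spec list(model=, lambda=, alpha=, r=).
sim_latent <- function(tree, spec) {
  std_trait(simulate_trait(tree, model = spec$model, sigma2 = 1,
                           lambda = spec$lambda, alpha = spec$alpha,
                           r = spec$r))
}

# Marginal truncation-resampling: redraw the evolutionary residual of
# out-of-range entries from the marginal N(m, s) until inside [lo, hi].
# Any planted fixed effect (per-taxon `offset`) is preserved through the
# redraw; only the phylogenetic correlation of the redrawn tail taxa is
# sacrificed (rare under the default scales).
resample_into <- function(x, lo, hi, m, s, offset = 0, max_tries = 1000) {
  offset <- rep_len(offset, length(x))
  bad <- which(x < lo | x > hi)
  tries <- 0
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), m, s) + offset[bad]
    bad <- which(x < lo | x > hi)
    tries <- tries + 1
    if (tries > max_tries) {
      stop("infeasible range clipping: limits inconsistent with scale",
           call. = FALSE)
    }
  }
  x
}

#' Synthetic-study configuration
#'
#' Defaults emulate the reference study design: 80 taxa on a depth-1 Yule
#' tree, five individuals per taxon with five measured verses each (ten for
#' a random 20% of "large-repertoire" taxa), hierarchical measurement noise
#' of 10% (between individuals) and 5% (between verses) of the taxon-level
#' trait scale, per-trait generating models mirroring the reference
#' best-model column, and a planted negative body-size effect on song
#' frequency of `-0.3` kHz per cm body length.
#'
#' @param n_taxa,birth,death,depth Tree simulation settings.
#' @param individuals,verses,large_rep_verses,large_rep_frac Sampling design.
#' @param noise_indiv,noise_verse Hierarchical noise SDs as fractions of the
#'   taxon-level latent scale.
#' @param body_size_slope Planted effect of body length (cm) on minimum and
#'   maximum frequency (kHz), applied on the frequency scale.
#' @param tempo_norm Normalising constant for complexity3 downstream.
#' @param models Optional per-latent model overrides (named list of
#'   `list(model =, lambda =, alpha =, r =)`).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_taxa = 80, birth = 1, death = 0, depth = 1,
                         individuals = 5, verses = 5,
                         large_rep_verses = 10, large_rep_frac = 0.2,
                         noise_indiv = 0.10, noise_verse = 0.05,
                         body_size_slope = -0.3, tempo_norm = 30.268,
                         models = list()) {
  stopifnot(n_taxa >= 4, birth > 0, death >= 0, depth > 0,
            individuals >= 1, verses >= 1,
            noise_indiv >= 0, noise_verse >= 0)
  defaults <- default_latent_models()
  for (nm in names(models)) defaults[[nm]] <- models[[nm]]
  structure(
    list(n_taxa = n_taxa, birth = birth, death = death, depth = depth,
         individuals = individuals, verses = verses,
         large_rep_verses = large_rep_verses, large_rep_frac = large_rep_frac,
         noise_indiv = noise_indiv, noise_verse = noise_verse,
         body_size_slope = body_size_slope, tempo_norm = tempo_norm,
         models = defaults),
    class = "synth_config"
  )
}

# Generating model per latent variable; lambda values track the reference
# signal estimates so synthetic data carry comparable phylogenetic structure.
default_latent_models <- function() {
  list(
    tges      = list(model = "lambda", lambda = 0.87),
    rt_max    = list(model = "BM"),
    rt_min    = list(model = "BM"),
    tempo     = list(model = "OU", alpha = 2),
    frac_type = list(model = "lambda", lambda = 0.98),
    fmin      = list(model = "lambda", lambda = 0.88),
    df        = list(model = "lambda", lambda = 0.74),
    dfmin     = list(model = "lambda", lambda = 0.92),
    dratio    = list(model = "lambda", lambda = 0.85),
    fmodend   = list(model = "lambda", lambda = 0.36),
    length    = list(model = "BM"),
    mass      = list(model = "BM"),
    migration = list(model = "OU", alpha = 2),
    region    = list(model = "lambda", lambda = 0.99),
    habitat   = list(model = "BM"),
    lat_mean  = list(model = "lambda", lambda = 1),
    lat_span  = list(model = "lambda", lambda = 0.6),
    long_mean = list(model = "lambda", lambda = 0.64),
    long_span = list(model = "lambda", lambda = 0.6),
    ele_mean  = list(model = "OU", alpha = 2),
    ele_span  = list(model = "lambda", lambda = 0.6)
  )
}

# Latent location/scale/range table. Scales are chosen so that +-3 latent SD
# stays inside the printed trait ranges of the reference cohort.
latent_scales <- function() {
  tibble::tribble(
    ~latent,     ~scale,   ~m,           ~s,    ~lo,        ~hi,
    "length",    "id",     11.0,         0.70,  9.5,        13.0,
    "tges",      "log",    log(1.7),     0.42,  log(0.46),  log(5.31),
    "rt_max",    "logit",  -2.2,         0.55,  -6,         -0.05,
    "rt_min",    "logit",  0.4,          0.5,   -4,         4,
    "tempo",     "log",    log(6.0),     0.62,  log(0.7),   log(30.2),
    "frac_type", "logit",  -0.6,         0.9,   -4,         4,
    "fmin",      "id",     3.11,         0.80,  1.30,       6.85,
    "df",        "id",     4.44,         0.90,  1.52,       7.39,
    "dfmin",     "id",     2.05,         0.60,  0.66,       4.42,
    "dratio",    "log1p",  -0.2,         0.5,   -3,         1.55,
    "fmodend",   "id",     -0.11,        0.70,  -2.90,      2.47,
    "lat_mean",  "id",     31.0,         13.0,  -18,        59,
    "lat_span",  "log",    log(22),      0.35,  log(4),     log(60),
    "long_mean", "id",     90.0,         28.0,  -17,        150,
    "long_span", "log",    log(35),      0.40,  log(8),     log(120),
    "ele_mean",  "id",     1945,         750,   450,        3965,
    "ele_span",  "log",    log(1800),    0.35,  log(400),   log(4400)
  )
}

from_latent <- function(z, scale) {
  switch(scale,
         id = z, log = exp(z), logit = stats::plogis(z),
         log1p = 1 + exp(z))
}

# Thresholds turning a latent ordering into discrete classes with fixed
# marginal counts (keeps the cohort score means at their reference values).
classify_by_counts <- function(z, counts, values) {
  n <- length(z)
  k <- round(n * counts / sum(counts))
  k[length(k)] <- n - sum(k[-length(k)])
  cls <- values[rep(seq_along(values), k)]
  cls[order(order(z))]  # lowest latent -> first class
}

#' Simulate a complete synthetic study
#'
#' Generates the full stand-in for the reference data set: a Yule
#' chronogram, taxon-level latent traits evolved under per-trait models
#' (with the planted body-size-to-frequency effect), a verse-level
#' measurement table built by adding hierarchical individual- and
#' verse-level noise on the latent scale, and a per-taxon explanatory table.
#' Transformed (log/logit) latent scales guarantee the measurement
#' invariants by construction; values are kept inside the printed trait
#' ranges by marginal truncation-resampling. Every planted quantity is
#' returned in the `truth` element.
#'
#' @param config A [synth_config()] list.
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @return A list of class `synth_study`: `tree`, `verses` (tibble),
#'   `explanatory` (tibble), `truth` (list), `config`, `seed`.
#' @export
simulate_study <- function(config = synth_config(), seed = 1) {
  set.seed(seed)
  tree <- simulate_tree(config$n_taxa, config$birth, config$death,
                        config$depth)
  taxa <- tree$tip.label
  n <- length(taxa)
  sc <- latent_scales()

  # planted body-size constraint on frequency (kHz per cm), centred so the
  # cohort mean frequency is unchanged
  b <- config$body_size_slope
  lat <- list()
  for (i in seq_len(nrow(sc))) {
    row <- sc[i, ]
    z <- sim_latent(tree, config$models[[row$latent]])
    offset <- 0
    if (row$latent == "fmin") {
      offset <- b * (lat$length - mean(lat$length))
    }
    lat[[row$latent]] <- resample_into(row$m + row$s * z + offset,
                                       row$lo, row$hi, row$m, row$s,
                                       offset = offset)
  }

  # discrete explanatory scores with reference marginal counts
  mig <- classify_by_counts(sim_latent(tree, config$models$migration),
                            c(12, 31, 37), 0:2)
  reg <- classify_by_counts(sim_latent(tree, config$models$region),
                            c(26, 39, 13, 2), 1:4)
  hab <- classify_by_counts(sim_latent(tree, config$models$habitat),
                            c(3, 7, 13, 13, 44), 1:5)
  mass <- 7.8 + 1.7 * std_trait(0.8 * std_trait(lat$length) +
                                  0.6 * sim_latent(tree, config$models$mass))
  mass <- resample_into(mass, 5.0, 11.8, 7.8, 1.5)

  explanatory <- tibble::tibble(
    taxon = taxa,
    length = lat$length,
    mass = mass,
    migration = mig,
    region = reg,
    lat_max = pmin(lat$lat_mean + exp(lat$lat_span) / 2, 71),
    lat_min = pmax(lat$lat_mean - exp(lat$lat_span) / 2, -34),
    long_max = pmin(lat$long_mean + exp(lat$long_span) / 2, 180),
    long_min = pmax(lat$long_mean - exp(lat$long_span) / 2, -30),
    ele_max = pmin(lat$ele_mean + exp(lat$ele_span) / 2, 4880),
    ele_min = pmax(lat$ele_mean - exp(lat$ele_span) / 2, 0),
    habitat = hab
  )

  # verse-level table: hierarchical noise added on the latent scale
  song_latents <- c("tges", "rt_max", "rt_min", "tempo", "frac_type",
                    "fmin", "df", "dfmin", "dratio", "fmodend")
  latent_sd <- stats::setNames(sc$s, sc$latent)
  large_rep <- stats::runif(n) < config$large_rep_frac
  rows <- vector("list", n)
  for (ti in seq_len(n)) {
    n_verse <- if (large_rep[ti]) config$large_rep_verses else config$verses
    n_ind <- config$individuals
    per <- expand.grid(individual = seq_len(n_ind), verse = seq_len(n_verse))
    vals <- list()
    for (lv in song_latents) {
      s <- latent_sd[[lv]]
      ind_eff <- stats::rnorm(n_ind, 0, config$noise_indiv * s)
      verse_eff <- stats::rnorm(nrow(per), 0, config$noise_verse * s)
      row_sc <- sc[sc$latent == lv, ]
      zz <- lat[[lv]][ti] + ind_eff[per$individual] + verse_eff
      # redraw verse noise for out-of-range draws (truncation, not clamping)
      bad <- which(zz < row_sc$lo | zz > row_sc$hi)
      tries <- 0
      while (length(bad)) {
        zz[bad] <- lat[[lv]][ti] + ind_eff[per$individual[bad]] +
          stats::rnorm(length(bad), 0, config$noise_verse * s)
        bad <- which(zz < row_sc$lo | zz > row_sc$hi)
        tries <- tries + 1
        if (tries > 100) {
          # individual effect itself out of range: fall back to taxon latent
          zz[bad] <- lat[[lv]][ti]
          break
        }
      }
      vals[[lv]] <- from_latent(zz, row_sc$scale)
    }
    tges <- vals$tges
    tmax <- tges * vals$rt_max
    tmin <- tmax * vals$rt_min
    zel <- pmax(1, round(vals$tempo * tges))
    zeltype <- pmin(zel, pmax(1, round(vals$frac_type * zel)))
    fmin <- vals$fmin
    fmax <- fmin + vals$df
    dfmin <- vals$dfmin
    dfmax <- dfmin * vals$dratio
    rows[[ti]] <- tibble::tibble(
      taxon = taxa[ti], individual = per$individual, verse = per$verse,
      tges = round(tges, 3), tmax = round(tmax, 3),
      tmin = round(pmax(tmin, 0.001), 3),
      zel = zel, zeltype = zeltype,
      fmax = round(fmax, 3), fmin = round(fmin, 3),
      dfmax = round(dfmax, 3), dfmin = round(pmax(dfmin, 0.001), 3),
      fmodend = round(vals$fmodend, 3)
    )
  }
  verses <- dplyr::bind_rows(rows)
  validate_verses(verses)
  validate_explanatory(explanatory)

  truth <- list(
    seed = seed,
    models = config$models,
    body_size_slope = b,
    latent_values = lat,
    large_repertoire = stats::setNames(large_rep, taxa),
    tempo_norm = config$tempo_norm
  )
  structure(list(tree = tree, verses = verses, explanatory = explanatory,
                 truth = truth, config = config, seed = seed),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d taxa, %d verse rows, seed %d\n",
              length(x$tree$tip.label), nrow(x$verses), x$seed))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the newick tree, the tab-delimited verse and explanatory tables,
#' and a flat key-value ground-truth manifest.
#'
#' @param study A `synth_study` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_song_tree(study$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(study$verses, file.path(dir, "verses.tsv"))
  readr::write_tsv(study$explanatory, file.path(dir, "explanatory.tsv"))
  tr <- study$truth
  kv <- c(
    paste0("seed=", tr$seed),
    paste0("body_size_slope=", tr$body_size_slope),
    paste0("tempo_norm=", tr$tempo_norm),
    vapply(names(tr$models), function(nm) {
      m <- tr$models[[nm]]
      extra <- setdiff(names(m), "model")
      paste0("model.", nm, "=", m$model,
             if (length(extra)) paste0(",", paste(extra, unlist(m[extra]),
                                                  sep = "=", collapse = ",")))
    }, character(1))
  )
  writeLines(kv, file.path(dir, "truth.txt"))
  invisible(dir)
}

#' Read study tables written by [write_study()]
#'
#' @param dir Directory containing `tree.nwk`, `verses.tsv`,
#'   `explanatory.tsv`.
#' @return A list with `tree`, `verses`, `explanatory`.
#' @export
read_study <- function(dir) {
  list(tree = read_song_tree(file.path(dir, "tree.nwk")),
       verses = readr::read_tsv(file.path(dir, "verses.tsv"),
                                show_col_types = FALSE),
       explanatory = readr::read_tsv(file.path(dir, "explanatory.tsv"),
                                     show_col_types = FALSE))
}
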