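#' @importFrom rlang .data
NULL

#' Song and explanatory trait sets
#'
#' Column-name constants for the trait tables: the ten directly measured
#' song parameters, the six derived ones, the principal-component score
#' columns, and the fifteen explanatory variables. `song_trait_categories()`
#' maps each song trait to its category (composition = temporal/structural
#' measures, frequency = spectral measures, plus derived complexity indices
#' and PC scores).
#'
#' @return Character vectors of column names.
#' @export
song_measured_traits <- function() {
  c("tges", "tmax", "tmin", "zel", "zeltype",
    "fmax", "fmin", "dfmax", "dfmin", "fmodend")
}

#' @rdname song_measured_traits
#' @export
song_traits <- function() {
  c("tges", "tmax", "tmin", "zel", "zeltges", "zeltype",
    "fmax", "fmin", "fmean", "df", "dfmax", "dfmin", "fmodend",
    "complexity1", "complexity2", "complexity3")
}

#' @rdname song_measured_traits
#' @export
pc_traits <- function() {
  c("PCall1", "PCall2", "PCcomp1", "PCcomp2", "PCfreq1", "PCfreq2")
}

#' @rdname song_measured_traits
#' @export
explanatory_traits <- function() {
  c("length", "mass", "migration", "region",
    "lat_max", "lat_min", "lat_mean", "lat_equator",
    "long_max", "long_min", "long_mean",
    "ele_max", "ele_min", "ele_mean", "habitat")
}

#' @rdname song_measured_traits
#' @export
song_trait_categories <- function() {
  tibble::tibble(
    trait = c(song_traits(), pc_traits()),
    category = c(rep("composition", 6), rep("frequency", 7),
                 rep("derived", 3), rep("pc", 6))
  )
}

# PCA variable subsets: "all" = the ten measured parameters,
# "comp" = compositional measures, "freq" = frequency measures.
pca_subsets <- function() {
  list(
    all  = song_measured_traits(),
    comp = c("tges", "tmax", "tmin", "zel", "zeltype"),
    freq = c("fmax", "fmin", "dfmax", "dfmin", "fmodend")
  )
}

#' Validate a verse-level measurement table
#'
#' Enforces the physical invariants of the measured parameters: verse
#' duration at least as long as its longest element, element durations
#' positive, element counts at least the number of unique element types,
#' frequencies positive with `fmax > fmin`, bandwidths positive with
#' `dfmax >= dfmin`.
#'
#' @param verses Data frame with columns `taxon`, `individual`, `verse` and
#'   the ten measured song parameters (see [song_measured_traits()]).
#' @return The input, invisibly, or an error describing the violated rule.
#' @export
validate_verses <- function(verses) {
  need <- c("taxon", "individual", "verse", song_measured_traits())
  miss <- setdiff(need, names(verses))
  if (length(miss)) {
    stop("verse table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  with(verses, {
    if (any(!(tges >= tmax & tmax >= tmin & tmin > 0))) {
      stop("need tges >= tmax >= tmin > 0 in every verse", call. = FALSE)
    }
    if (any(!(zel >= zeltype & zeltype >= 1))) {
      stop("need zel >= zeltype >= 1 in every verse", call. = FALSE)
    }
    if (any(!(fmax > fmin & fmin > 0))) {
      stop("need fmax > fmin > 0 in every verse", call. = FALSE)
    }
    if (any(!(dfmax >= dfmin & dfmin > 0))) {
      stop("need dfmax >= dfmin > 0 in every verse", call. = FALSE)
    }
  })
  invisible(verses)
}

#' Derive the six computed song parameters per verse
#'
#' Adds to each verse row: delivery tempo `zeltges = zel/tges` (elements/s),
#' mean frequency `fmean = (fmin + fmax)/2`, bandwidth `df = fmax - fmin`,
#' relative element dissimilarity
#' `complexity1 = (dfmax/dfmin + tmax/tmin)/2` (analytic floor 1 when all
#' elements are alike), relative element diversity `complexity2 =
#' zeltype/zel`, and the diversity-tempo index `complexity3 = complexity2 +
#' zeltges/tempo_norm`, whose tempo component is normalised so that the
#' fastest delivery rate in the reference data set maps to exactly 1.
#'
#' @param verses Verse table (see [validate_verses()]).
#' @param tempo_norm Normalising tempo in elements/s; the default 30.268 is
#'   the fastest delivery rate in the reference leaf-warbler data set.
#' @return The table with the six derived columns appended.
#' @export
derive_song_traits <- function(verses, tempo_norm = 30.268) {
  validate_verses(verses)
  dplyr::mutate(
    tibble::as_tibble(verses),
    zeltges = .data$zel / .data$tges,
    fmean = (.data$fmin + .data$fmax) / 2,
    df = .data$fmax - .data$fmin,
    complexity1 = (.data$dfmax / .data$dfmin + .data$tmax / .data$tmin) / 2,
    complexity2 = .data$zeltype / .data$zel,
    complexity3 = .data$complexity2 + .data$zeltges / tempo_norm
  )
}

#' Aggregate verse measurements to taxon means
#'
#' Two-stage unweighted aggregation: each individual's verses are averaged
#' first, then the individual averages are averaged within taxon. This is
#' deliberately *not* a pooled mean over verses — individuals with more
#' recorded verses carry no extra weight.
#'
#' @param verses Verse table, normally after [derive_song_traits()].
#' @param traits Columns to aggregate (default: every derived song trait
#'   present in the table).
#' @return A tibble with one row per taxon and one column per trait.
#' @export
aggregate_taxon_means <- function(verses, traits = NULL) {
  if (is.null(traits)) {
    traits <- intersect(c(song_traits()), names(verses))
  }
  if (!nrow(verses)) stop("empty verse table", call. = FALSE)
  verses |>
    dplyr::group_by(.data$taxon, .data$individual) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(traits), mean),
                     .groups = "drop_last") |>
    dplyr::summarise(dplyr::across(dplyr::all_of(traits), mean),
                     .groups = "drop")
}

#' Validate a per-taxon explanatory table
#'
#' @param expl Data frame with one row per taxon and the raw explanatory
#'   columns `length`, `mass`, `migration`, `region`, `lat_max`, `lat_min`,
#'   `long_max`, `long_min`, `ele_max`, `ele_min`, `habitat`.
#' @return The input, invisibly.
#' @export
validate_explanatory <- function(expl) {
  need <- c("taxon", "length", "mass", "migration", "region",
            "lat_max", "lat_min", "long_max", "long_min",
            "ele_max", "ele_min", "habitat")
  miss <- setdiff(need, names(expl))
  if (length(miss)) {
    stop("explanatory table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  with(expl, {
    if (any(lat_max < lat_min)) stop("need lat_max >= lat_min", call. = FALSE)
    if (any(ele_max < ele_min)) stop("need ele_max >= ele_min", call. = FALSE)
    if (any(length <= 0) || any(mass <= 0)) {
      stop("body length and mass must be positive", call. = FALSE)
    }
    if (!all(migration %in% 0:2)) stop("migration score must be 0, 1 or 2", call. = FALSE)
    if (!all(habitat %in% 1:5)) stop("habitat class must be 1..5", call. = FALSE)
  })
  invisible(expl)
}

#' Derive range-summary explanatory variables
#'
#' Adds mean latitude/longitude/elevation as midpoints of the range limits,
#' `lat_equator` as the mean of the *absolute* latitudinal extremes (mean
#' distance of the range from the equator — an all-southern range gets a
#' positive value), and, for comparison, `lat_equator_alt = |lat_mean|`.
#'
#' @param expl Explanatory table (see [validate_explanatory()]).
#' @return The table with `lat_mean`, `long_mean`, `ele_mean`, `lat_equator`
#'   and `lat_equator_alt` appended.
#' @export
derive_explanatory <- function(expl) {
  validate_explanatory(expl)
  dplyr::mutate(
    tibble::as_tibble(expl),
    lat_mean = (.data$lat_max + .data$lat_min) / 2,
    long_mean = (.data$long_max + .data$long_min) / 2,
    ele_mean = (.data$ele_max + .data$ele_min) / 2,
    lat_equator = (abs(.data$lat_max) + abs(.data$lat_min)) / 2,
    lat_equator_alt = abs(.data$lat_mean)
  )
}

#' Cohort summary of explanatory variables
#'
#' Unweighted mean and standard deviation of every numeric explanatory
#' column across taxa (e.g. average migratoriness of the cohort from the
#' per-taxon 0/1/2 scores).
#'
#' @param expl Explanatory table (raw or derived).
#' @param variables Columns to summarise; defaults to every numeric column
#'   except the taxon id.
#' @return Tibble with columns `variable`, `mean`, `sd`, `n`.
#' @export
summarize_cohort <- function(expl, variables = NULL) {
  if (!nrow(expl)) stop("empty explanatory table", call. = FALSE)
  if (is.null(variables)) {
    variables <- names(expl)[vapply(expl, is.numeric, logical(1))]
    variables <- setdiff(variables, "taxon")
  }
  purrr::map_dfr(variables, function(v) {
    tibble::tibble(variable = v,
                   mean = mean(expl[[v]]),
                   sd = stats::sd(expl[[v]]),
                   n = sum(!is.na(expl[[v]])))
  })
}

#' Scaled principal component analysis of song parameters
#'
#' Runs [stats::prcomp()] on centred, unit-variance variables for one of the
#' three standard subsets of the measured song parameters (`"all"`, `"comp"`,
#' `"freq"`) or an explicit variable list. Component standard deviations are
#' the square roots of the correlation-matrix eigenvalues, so the squared
#' sdevs sum to the number of variables. Loading signs are fixed by flipping
#' each component so its largest-magnitude loading is positive (PCA signs
#' are arbitrary; a deterministic convention keeps runs comparable).
#'
#' @param data Per-taxon trait table containing a `taxon` column.
#' @param subset `"all"`, `"comp"`, `"freq"`, or a character vector of
#'   column names.
#' @param prefix Name prefix for the score columns (e.g. `"PCfreq"`).
#' @return Object of class `song_pca`: list with `sdev`, `loadings`,
#'   `scores` (tibble with `taxon` and score columns), `subset`, `prefix`.
#' @export
pca_scaled <- function(data, subset = "all", prefix = NULL) {
  if (is.character(subset) && length(subset) == 1 && subset %in% names(pca_subsets())) {
    vars <- pca_subsets()[[subset]]
    if (is.null(prefix)) prefix <- paste0("PC", subset)
  } else {
    vars <- subset
    if (is.null(prefix)) prefix <- "PC"
  }
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop("PCA subset columns missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(data[vars])
  if (nrow(X) <= length(vars)) {
    stop("PCA needs more taxa than variables", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s) in PCA subset: ",
         paste(vars[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  # deterministic sign: largest-magnitude loading of each component positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  scores <- tibble::as_tibble(pc$x)
  names(scores) <- paste0(prefix, seq_len(ncol(scores)))
  structure(
    list(sdev = pc$sdev, loadings = pc$rotation,
         scores = dplyr::bind_cols(tibble::tibble(taxon = data$taxon), scores),
         subset = vars, prefix = prefix),
    class = "song_pca"
  )
}

#' @export
print.song_pca <- function(x, ...) {
  cat("Scaled PCA on", length(x$subset), "variables:",
      paste(x$subset, collapse = ", "), "\n")
  cat("Component sdev:", paste(signif(x$sdev, 4), collapse = ", "), "\n")
  cat("Variance shares:",
      paste(sprintf("%.1f%%", 100 * x$sdev^2 / sum(x$sdev^2)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
tidy.song_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0(x$prefix, seq_along(x$sdev)),
    sdev = x$sdev,
    eigenvalue = x$sdev^2,
    prop_variance = x$sdev^2 / sum(x$sdev^2)
  )
}

#' Build the full per-taxon trait table
#'
#' Chains verse-level derivation, two-stage aggregation to taxon means, the
#' three scaled PCAs (scores appended as `PCall1/2`, `PCcomp1/2`,
#' `PCfreq1/2`), and the derived explanatory variables, joined by taxon.
#'
#' @param verses Verse-level measurement table.
#' @param explanatory Per-taxon explanatory table.
#' @param tempo_norm Passed to [derive_song_traits()].
#' @return A tibble with one row per taxon: 16 song traits, 6 PC scores and
#'   the explanatory variables.
#' @export
build_trait_table <- function(verses, explanatory, tempo_norm = 30.268) {
  song <- verses |>
    derive_song_traits(tempo_norm = tempo_norm) |>
    aggregate_taxon_means()
  pcs <- lapply(c("all", "comp", "freq"), function(s) {
    pca_scaled(song, s)$scores[, 1:3]  # taxon + first two components
  })
  song <- Reduce(function(a, b) dplyr::left_join(a, b, by = "taxon"),
                 pcs, song)
  expl <- derive_explanatory(explanatory)
  out <- dplyr::inner_join(song, expl, by = "taxon")
  if (nrow(out) < nrow(song)) {
    stop("explanatory table is missing taxa present in the verse table",
         call. = FALSE)
  }
  out
}
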