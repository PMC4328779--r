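#' Pipeline configuration
#'
#' @param n_perm Permutations for the signal randomization test.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param models Trait-evolution models to fit.
#' @param step_mode Stepwise criterion, `"aic"` or `"pvalue"`.
#' @param alpha pGLS significance threshold.
#' @param delta_aicc_tie Near-tie threshold for alternative models.
#' @param exclude_traits Song traits dropped from the correlation/model
#'   stage after signal testing (post-hoc filter; by default the second
#'   frequency PC, which lacks phylogenetic signal in the reference data).
#' @param tempo_norm Normalising tempo for complexity3.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_perm = 999, seed = 20150120,
                            models = evomodel_names(), step_mode = "aic",
                            alpha = 0.05, delta_aicc_tie = 2,
                            exclude_traits = "PCfreq2",
                            tempo_norm = 30.268) {
  structure(
    list(n_perm = n_perm, seed = seed, models = models,
         step_mode = step_mode, alpha = alpha,
         delta_aicc_tie = delta_aicc_tie, exclude_traits = exclude_traits,
         tempo_norm = tempo_norm),
    class = "pipeline_config"
  )
}

#' Run the full comparative analysis
#'
#' Orchestrates every stage on a tree plus verse-level and explanatory
#' tables: trait derivation and aggregation, the three scaled PCAs,
#' per-trait phylogenetic signal (randomization P, Blomberg's K, Pagel's
#' lambda) and AICc model selection for all song traits, PC scores and
#' explanatory variables (the "table 1" analogue); all pairwise raw and
#' contrast-based correlations plus the per-trait stepwise-LM-to-pGLS chain
#' (the "table 2" analogue).
#'
#' @param tree The analysis tree (or a newick file path).
#' @param verses Verse-level measurement table (or a TSV path).
#' @param explanatory Per-taxon explanatory table (or a TSV path).
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_report`: list with `traits`
#'   (per-taxon trait table), `table1`, `table2`, `trait_models` (named
#'   list of `trait_model`), `pca` (the three `song_pca` objects),
#'   `manifest`.
#' @export
run_pipeline <- function(tree, verses, explanatory,
                         config = pipeline_config()) {
  if (is.character(tree)) tree <- read_song_tree(tree)
  if (is.character(verses)) {
    verses <- readr::read_tsv(verses, show_col_types = FALSE)
  }
  if (is.character(explanatory)) {
    explanatory <- readr::read_tsv(explanatory, show_col_types = FALSE)
  }
  tree <- validate_song_tree(tree)
  traits <- build_trait_table(verses, explanatory,
                              tempo_norm = config$tempo_norm)
  check_taxa_match(traits, tree)

  pca <- lapply(stats::setNames(nm = c("all", "comp", "freq")), function(s) {
    pca_scaled(aggregate_taxon_means(derive_song_traits(
      verses, tempo_norm = config$tempo_norm)), s)
  })

  song_rows <- c(song_traits(), pc_traits())
  expl_rows <- explanatory_traits()
  all_rows <- c(song_rows, expl_rows)

  signal <- phylo_signal(traits, tree, all_rows, n_perm = config$n_perm,
                         seed = config$seed)
  msel <- model_selection_table(traits, tree, all_rows,
                                models = config$models,
                                delta_aicc_tie = config$delta_aicc_tie)
  table1 <- signal |>
    dplyr::left_join(msel, by = "trait") |>
    dplyr::left_join(song_trait_categories(), by = "trait") |>
    dplyr::mutate(category = dplyr::coalesce(.data$category, "explanatory")) |>
    dplyr::relocate("category")

  cor_rows <- setdiff(song_rows, config$exclude_traits)
  table2 <- correlate_traits(traits, tree, song_vars = cor_rows,
                             expl_vars = expl_rows)

  trait_models <- lapply(stats::setNames(nm = cor_rows), function(tr) {
    run_trait_model(traits, tree, tr, predictors = expl_rows,
                    step_mode = config$step_mode, alpha = config$alpha)
  })
  pgls_marks <- purrr::map_dfr(trait_models, function(tm) {
    s <- tm$summary
    tibble::tibble(trait = tm$trait, predictor = s$term,
                   pgls_significant = s$significant,
                   pgls_strongest = s$strongest)
  })
  table2 <- dplyr::left_join(table2, pgls_marks,
                             by = c("trait", "predictor")) |>
    dplyr::mutate(
      pgls_significant = dplyr::coalesce(.data$pgls_significant, FALSE),
      pgls_strongest = dplyr::coalesce(.data$pgls_strongest, FALSE)
    )

  manifest <- list(
    package_version = as.character(utils::packageVersion("phylosong")),
    r_version = R.version.string,
    seed = config$seed,
    n_perm = config$n_perm,
    n_taxa = length(tree$tip.label),
    n_verses = nrow(verses),
    config = unclass(config),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  structure(list(traits = traits, table1 = table1, table2 = table2,
                 trait_models = trait_models, pca = pca,
                 manifest = manifest),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Comparative analysis report: %d taxa, %d signal rows, %d trait-predictor pairs\n",
              x$manifest$n_taxa, nrow(x$table1), nrow(x$table2)))
  cat("Stages: traits + PCA -> signal (K, P, lambda) -> model selection -> correlations (raw/PIC) -> stepwise LM -> pGLS\n")
  invisible(x)
}

#' Mean signal strength by song-trait category
#'
#' Arithmetic means of Blomberg's K (reported to 1 decimal) and Pagel's
#' lambda (2 decimals) within song-trait categories, the comparison used to
#' ask whether frequency traits are more or less conserved than
#' compositional ones.
#'
#' @param table1 A signal table with `category`, `K` and `lambda` columns
#'   (e.g. `report$table1`).
#' @param categories Which categories to average.
#' @return Tibble: `category`, `K_mean`, `lambda_mean` (rounded to the
#'   reporting precision), `K_mean_raw`, `lambda_mean_raw`, `n_traits`.
#' @export
summarize_signal_by_category <- function(table1,
                                         categories = c("composition", "frequency")) {
  table1 |>
    dplyr::filter(.data$category %in% categories) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(K_mean_raw = mean(.data$K),
                     lambda_mean_raw = mean(.data$lambda),
                     n_traits = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(K_mean = round(.data$K_mean_raw, 1),
                  lambda_mean = round(.data$lambda_mean_raw, 2)) |>
    dplyr::relocate("category", "K_mean", "lambda_mean")
}

#' Write every report table to a directory
#'
#' Emits tab-delimited files: the trait table, signal/model table, long and
#' matrix-layout correlation tables, per-trait reduction traces and pGLS
#' coefficient tables, and a flat key-value run manifest.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$traits, file.path(dir, "trait_table.tsv"))
  readr::write_tsv(report$table1, file.path(dir, "table1_signal_models.tsv"))
  readr::write_tsv(report$table2, file.path(dir, "table2_correlations.tsv"))
  readr::write_tsv(correlation_matrix(report$table2, "raw"),
                   file.path(dir, "table2_matrix_raw.tsv"))
  readr::write_tsv(correlation_matrix(report$table2, "pic"),
                   file.path(dir, "table2_matrix_pic.tsv"))
  traces <- purrr::map_dfr(report$trait_models, function(tm) {
    dplyr::mutate(tm$trace$trace, trait = tm$trait, .before = 1)
  })
  readr::write_tsv(traces, file.path(dir, "stepwise_traces.tsv"))
  coefs <- purrr::map_dfr(report$trait_models, function(tm) {
    dplyr::mutate(tidy.pgls_fit(tm$pgls), trait = tm$trait,
                  lambda = tm$pgls$lambda, .before = 1)
  })
  readr::write_tsv(coefs, file.path(dir, "pgls_coefficients.tsv"))
  mf <- report$manifest
  flat <- c(
    paste0("package_version=", mf$package_version),
    paste0("r_version=", mf$r_version),
    paste0("seed=", mf$seed),
    paste0("n_perm=", mf$n_perm),
    paste0("n_taxa=", mf$n_taxa),
    paste0("n_verses=", mf$n_verses),
    paste0("step_mode=", mf$config$step_mode),
    paste0("alpha=", mf$config$alpha),
    paste0("exclude_traits=", paste(mf$config$exclude_traits, collapse = ","))
  )
  writeLines(flat, file.path(dir, "run_manifest.txt"))
  invisible(dir)
}
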