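#' Configure an end-to-end pipeline run
#'
#' Bundles the inputs and tuning knobs of [run_pipeline()] into a single
#' serializable object. Inputs may be in-memory tibbles or file paths (CSV,
#' read through the package readers).
#'
#' @param abundance Species-level abundance tibble or CSV path.
#' @param metadata Subject metadata tibble or CSV path.
#' @param taxonomy Taxonomy tibble or CSV/JSON path.
#' @param peaks,is_table Optional raw peak and internal-standard tables (or
#'   paths); when both are given, NOMIS normalization replaces `abundance`.
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed; stage-specific seeds are derived from it.
#' @param n_reps MCCV repetitions (default 200).
#' @param test_frac,inner_frac Outer/inner holdout fractions (default 0.2
#'   each).
#' @param fractions Stage-1 class-fraction scan grid.
#' @param k_grid Stage-2 selection-size scan grid.
#' @param grid Random-forest hyperparameter grid.
#' @param drop_frac,impute Missing-data policy (see [handle_missing()]).
#' @param alpha,conf_level Significance level and CI level for validation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(abundance, metadata, taxonomy,
                            peaks = NULL, is_table = NULL,
                            out_dir = tempfile("lipidrank-run-"),
                            seed = 1, n_reps = 200,
                            test_frac = 0.2, inner_frac = 0.2,
                            fractions = seq(0.1, 1, by = 0.1),
                            k_grid = seq(5, 25, by = 5),
                            grid = rf_grid(),
                            drop_frac = 0.2, impute = "half_min",
                            alpha = 0.05, conf_level = 0.95) {
  structure(
    list(
      abundance = abundance, metadata = metadata, taxonomy = taxonomy,
      peaks = peaks, is_table = is_table, out_dir = out_dir,
      seed = as.integer(seed), n_reps = n_reps,
      test_frac = test_frac, inner_frac = inner_frac,
      fractions = fractions, k_grid = k_grid, grid = grid,
      drop_frac = drop_frac, impute = impute,
      alpha = alpha, conf_level = conf_level
    ),
    class = "pipeline_config"
  )
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full discovery pipeline
#'
#' Executes every stage in order: optional NOMIS normalization, missing-data
#' filtering/imputation, species-to-class aggregation, stage-1 class
#' selection, stage-2 species selection by both methods (Method 2 seeded
#' with the stage-1 classes), and the statistical validation battery on each
#' selected set. All results are returned as a bundle and written to
#' `out_dir` as CSV/JSON artifacts (metrics, ranked validated tables, scan
#' tables, run log). A run is fully determined by its configuration: the
#' same config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `class_selection`, `species_m1`, `species_m2`
#'   (selection results), `class_table`, `species_table_m1`,
#'   `species_table_m2` (validated ranked tibbles), `class_ranking`,
#'   `metrics`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  abundance <- resolve_input(config$abundance, read_abundance)
  metadata <- resolve_input(config$metadata, read_metadata)
  taxonomy <- resolve_input(config$taxonomy, read_taxonomy)

  nomis <- NULL
  if (!is.null(config$peaks) && !is.null(config$is_table)) {
    peaks <- resolve_input(config$peaks, read_abundance)
    is_table <- resolve_input(config$is_table, read_abundance)
    nomis <- stage("normalize", fit_nomis(peaks, is_table))
    abundance <- stage("normalize", apply_nomis(nomis, peaks, is_table))
  }

  abundance <- stage(
    "missing-data",
    handle_missing(abundance, config$drop_frac, config$impute)
  )
  class_ab <- stage("aggregate", aggregate_to_classes(abundance, taxonomy))
  species_ft <- stage("design", build_feature_table(abundance, metadata))
  class_ft <- stage("design", build_feature_table(class_ab, metadata))

  plan1 <- make_split_plan(class_ft$group,
    n_reps = config$n_reps, test_frac = config$test_frac,
    inner_frac = config$inner_frac, seed = config$seed
  )
  plan2 <- make_split_plan(species_ft$group,
    n_reps = config$n_reps, test_frac = config$test_frac,
    inner_frac = config$inner_frac, seed = config$seed + 1L
  )
  plan3 <- make_split_plan(species_ft$group,
    n_reps = config$n_reps, test_frac = config$test_frac,
    inner_frac = config$inner_frac, seed = config$seed + 2L
  )

  sel_class <- stage(
    "stage1-classes",
    select_classes(class_ft, plan1, config$fractions, config$grid)
  )
  sel_m1 <- stage(
    "stage2-method1",
    select_species(species_ft, plan2, config$k_grid,
      method = 1, grid = config$grid
    )
  )
  sel_m2 <- stage(
    "stage2-method2",
    select_species(species_ft, plan3, config$k_grid,
      method = 2, top_classes = sel_class$selected,
      taxonomy = taxonomy, grid = config$grid
    )
  )

  class_table <- stage("validate", validate_selection(
    class_ft, sel_class$selected,
    conf_level = config$conf_level, alpha = config$alpha,
    seed = config$seed + 10L
  ))
  class_dirs <- class_table[, c("feature", "direction")]
  species_table_m1 <- stage("validate", validate_selection(
    species_ft, sel_m1$selected,
    taxonomy = taxonomy, class_directions = class_dirs,
    conf_level = config$conf_level, alpha = config$alpha,
    seed = config$seed + 11L
  ))
  species_table_m2 <- stage("validate", validate_selection(
    species_ft, sel_m2$selected,
    taxonomy = taxonomy, class_directions = class_dirs,
    conf_level = config$conf_level, alpha = config$alpha,
    seed = config$seed + 12L
  ))

  metrics <- dplyr::bind_rows(
    glance(sel_class), glance(sel_m1), glance(sel_m2)
  )
  bundle <- list(
    class_selection = sel_class, species_m1 = sel_m1, species_m2 = sel_m2,
    class_table = class_table,
    species_table_m1 = species_table_m1,
    species_table_m2 = species_table_m2,
    class_ranking = sel_class$ranked,
    nomis = nomis,
    metrics = metrics,
    out_dir = config$out_dir
  )
  write_bundle(bundle, config)
  invisible(bundle)
}

# run one stage, prefixing any error with the stage name
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
  })
}

write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  readr::write_csv(render_ranked_table(bundle$class_table), out("class_table.csv"))
  readr::write_csv(
    render_ranked_table(bundle$species_table_m1), out("species_table_m1.csv")
  )
  readr::write_csv(
    render_ranked_table(bundle$species_table_m2), out("species_table_m2.csv")
  )
  readr::write_csv(bundle$class_ranking, out("class_ranking.csv"))
  readr::write_csv(bundle$class_selection$scan, out("scan_classes.csv"))
  readr::write_csv(bundle$species_m1$scan, out("scan_species_m1.csv"))
  readr::write_csv(bundle$species_m2$scan, out("scan_species_m2.csv"))
  jsonlite::write_json(
    list(
      metrics = bundle$metrics,
      selected = list(
        classes = bundle$class_selection$selected,
        species_m1 = bundle$species_m1$selected,
        species_m2 = bundle$species_m2$selected
      )
    ),
    out("metrics.json"),
    digits = NA, auto_unbox = TRUE
  )
  jsonlite::write_json(
    list(
      seed = config$seed, n_reps = config$n_reps,
      test_frac = config$test_frac, inner_frac = config$inner_frac,
      fractions = config$fractions, k_grid = config$k_grid,
      drop_frac = config$drop_frac, impute = config$impute,
      alpha = config$alpha, conf_level = config$conf_level,
      package_version = as.character(utils::packageVersion("lipidrank")),
      ci_convention = "case - control"
    ),
    out("run_log.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(config$out_dir)
}

#' Render a validated selection as a publication-shaped table
#'
#' Formats a [validate_selection()] tibble the way the ranked report tables
#' are printed: `Rank`, `Feature`, `Direction`, optional `Class` and
#' `Class direction`, a `95% CI` string `(low, high)` for the case − control
#' mean difference, and `p value`. No statistic is recomputed — every number
#' comes from the validated table.
#'
#' @param validated Tibble from [validate_selection()] (possibly with zero
#'   rows for an empty selection: the rendered table is then header-only).
#' @return A tibble of formatted character/numeric display columns.
#' @export
render_ranked_table <- function(validated) {
  has_class <- "class" %in% names(validated)
  has_cdir <- "class_direction" %in% names(validated)
  out <- tibble::tibble(
    Rank = validated$rank,
    Feature = validated$feature,
    Direction = validated$direction
  )
  if (has_class) out$Class <- validated$class
  if (has_cdir) out$`Class direction` <- validated$class_direction
  out$`95% CI` <- sprintf(
    "(%.4g, %.4g)", validated$conf.low, validated$conf.high
  )
  out$`p value` <- signif(validated$p.value, 3)
  out$Univariate <- validated$univariate_significant
  out$Multivariate <- validated$in_sfs | validated$in_sbs | validated$in_sffs
  if (nrow(validated) == 0) out$`95% CI` <- character()
  out
}
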