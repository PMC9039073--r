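#' Take the top fraction of a ranked variable table
#'
#' Returns the top `round_half_up(fraction * p)` lipid features of a ranking
#' (minimum 1). Covariate rows (age, sex) are excluded from both the count
#' and the result when `exclude_covariates` is set — selecting "30% of the
#' classes" means 30% of the lipid classes, with the covariates re-attached
#' later by the modelling step.
#'
#' @param ranked Ranked tibble from [rank_variables()].
#' @param fraction Fraction of features to keep, in `(0, 1]`.
#' @param exclude_covariates Drop covariate rows before counting (default
#'   `TRUE`).
#' @return Character vector of feature ids in rank order.
#' @export
select_top_fraction <- function(ranked, fraction, exclude_covariates = TRUE) {
  stopifnot(fraction > 0, fraction <= 1)
  pool <- ranked
  if (exclude_covariates && "is_covariate" %in% names(pool)) {
    pool <- pool[!pool$is_covariate, ]
  }
  pool <- pool[order(pool$rank), ]
  k <- max(1L, round_half_up(fraction * nrow(pool)))
  head(pool$variable, k)
}

new_selection_result <- function(stage, selected, report, scan, ranked,
                                 n_candidates, params = list()) {
  structure(
    list(
      stage = stage, selected = selected, size = length(selected),
      report = report, scan = scan, ranked = ranked,
      n_candidates = n_candidates, params = params
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  s <- x$report$summary
  cat(sprintf(
    "Selection (%s): %d of %d candidates | accuracy %.1f%% TPR %.1f%% TNR %.1f%% AUC %.3f\n",
    x$stage, x$size, x$n_candidates,
    100 * s$accuracy, 100 * s$tpr, 100 * s$tnr, s$auc
  ))
  cat("  ", paste(head(x$selected, 10), collapse = ", "),
    if (x$size > 10) ", ..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn select_classes Selected features with their ranking rows.
#' @param x A `selection_result`.
#' @param ... Unused.
#' @export
tidy.selection_result <- function(x, ...) {
  out <- x$ranked[match(x$selected, x$ranked$variable), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' @describeIn select_classes One-row summary: stage, size and mean metrics
#'   of the winning model.
#' @export
glance.selection_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      stage = x$stage, size = x$size, n_candidates = x$n_candidates
    ),
    x$report$summary
  )
}

# evaluate a candidate feature set (always with covariates) on a plan
eval_subset <- function(ft, features, plan, grid) {
  mccv_evaluate(ft_keep_features(ft, features), plan, grid)
}

#' Stage 1: select the most contributing lipid classes
#'
#' Ranks all classes (with the age and sex covariates participating in the
#' models) by Monte Carlo-aggregated random-forest importance, then
#' re-evaluates the classifier on the top fraction of classes for every
#' fraction of the scan grid. The fraction maximizing mean AUC wins (ties go
#' to the smaller model, then grid order); the full scan table is kept so
#' the choice can be audited under any other metric.
#'
#' @param ft Class-level feature table.
#' @param plan Split plan for the same subjects.
#' @param fractions Scan grid of class fractions (default 0.1 to 1 in steps
#'   of 0.1).
#' @param grid Hyperparameter grid.
#' @return A `selection_result` with `stage = "class"`: selected class ids
#'   in rank order, the winning model's `mccv_report`, and the scan table
#'   (`fraction`, `size`, mean metrics).
#' @export
select_classes <- function(ft, plan, fractions = seq(0.1, 1, by = 0.1),
                           grid = rf_grid()) {
  stopifnot(length(fractions) >= 1)
  ranked <- rank_variables(ft, plan, grid)
  sets <- lapply(fractions, function(f) select_top_fraction(ranked, f))
  reports <- lapply(sets, function(s) eval_subset(ft, s, plan, grid))
  scan <- dplyr::bind_cols(
    tibble::tibble(
      fraction = fractions,
      size = lengths(sets)
    ),
    dplyr::bind_rows(lapply(reports, `[[`, "summary"))
  )
  best <- order(-scan$auc, scan$size, seq_len(nrow(scan)))[1]
  new_selection_result(
    stage = "class", selected = sets[[best]], report = reports[[best]],
    scan = scan, ranked = ranked,
    n_candidates = sum(!ranked$is_covariate),
    params = list(fraction = fractions[best])
  )
}

#' Stage 2: select the most contributing lipid species
#'
#' Two species-selection strategies share one engine. Method 1 ranks *all*
#' species and evaluates the classifier on the top k species together with
#' age and sex, for each k of the grid. Method 2 first restricts the
#' candidate pool to species whose class is among `top_classes` (typically
#' the stage-1 winners) and then proceeds identically — on the default panel
#' with the ten leading classes this candidate pool holds 176 species. The
#' k maximizing mean AUC wins (ties to the smaller k).
#'
#' @param ft Species-level feature table.
#' @param plan Split plan (use a fresh plan with a derived seed, not the
#'   stage-1 plan).
#' @param k_grid Candidate selection sizes (default 5 to 25 in steps of 5).
#' @param method 1 (global) or 2 (within top classes).
#' @param top_classes Class ids defining the Method 2 pool.
#' @param taxonomy Taxonomy mapping species to classes (Method 2 only).
#' @param grid Hyperparameter grid.
#' @return A `selection_result` with `stage = "species_m1"` or
#'   `"species_m2"`, including the scan table over k and the candidate pool
#'   size.
#' @export
select_species <- function(ft, plan, k_grid = seq(5, 25, by = 5),
                           method = 1, top_classes = NULL, taxonomy = NULL,
                           grid = rf_grid()) {
  stopifnot(method %in% c(1, 2), length(k_grid) >= 1)
  all_species <- ft_features(ft)
  if (method == 2) {
    if (is.null(top_classes) || is.null(taxonomy)) {
      abort("method 2 needs top_classes and taxonomy")
    }
    if (length(top_classes) == 0) abort("top_classes must be non-empty")
    pool <- taxonomy$species_id[taxonomy$class_id %in% top_classes]
    candidates <- intersect(all_species, pool)
    if (length(candidates) == 0) abort("no species fall in top_classes")
    cand_ft <- ft_keep_features(ft, candidates)
  } else {
    candidates <- all_species
    cand_ft <- ft
  }
  k_grid <- sort(unique(pmin(k_grid, length(candidates))))
  ranked <- rank_variables(cand_ft, plan, grid)
  lipid_rank <- ranked$variable[!ranked$is_covariate]
  sets <- lapply(k_grid, function(k) head(lipid_rank, k))
  reports <- lapply(sets, function(s) eval_subset(ft, s, plan, grid))
  scan <- dplyr::bind_cols(
    tibble::tibble(k = k_grid, size = lengths(sets)),
    dplyr::bind_rows(lapply(reports, `[[`, "summary"))
  )
  best <- order(-scan$auc, scan$size, seq_len(nrow(scan)))[1]
  new_selection_result(
    stage = if (method == 1) "species_m1" else "species_m2",
    selected = sets[[best]], report = reports[[best]],
    scan = scan, ranked = ranked, n_candidates = length(candidates),
    params = list(k = k_grid[best], top_classes = top_classes)
  )
}
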