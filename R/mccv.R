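#' Build a Monte Carlo cross-validation split plan
#'
#' Repeated random train/test partitions without replacement: per repetition,
#' `round(test_frac * n)` subjects form the test set (round half away from
#' zero) and the rest the outer training set; the outer training set is
#' further split into an inner training and validation set (a fraction
#' `inner_frac` of the training set) for hyperparameter tuning. Sampling is
#' stratified by outcome by default so that both classes appear in every
#' set — with 22 cases and 30 controls and `test_frac = 0.2` every test set
#' has 4 cases and 6 controls.
#'
#' @param groups Outcome vector (factor or character, values `case` /
#'   `control`), one entry per subject in table order.
#' @param n_reps Number of repetitions (default 200).
#' @param test_frac Fraction of subjects held out for testing (default 0.2).
#' @param inner_frac Fraction of the outer training set held out for
#'   validation (default 0.2).
#' @param stratify Stratify splits by outcome (default `TRUE`). Unstratified
#'   sampling risks single-class sets at small n.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A `split_plan`: list of per-rep index sets (`train`, `test`,
#'   `inner_train`, `inner_val`) plus the parameters.
#' @export
make_split_plan <- function(groups, n_reps = 200, test_frac = 0.2,
                            inner_frac = 0.2, stratify = TRUE, seed = 1) {
  stopifnot(n_reps >= 1, test_frac > 0, test_frac < 1,
            inner_frac > 0, inner_frac < 1)
  groups <- as.character(groups)
  n <- length(groups)
  lev <- unique(groups)
  if (length(lev) != 2) abort("groups must contain exactly two classes")
  n_test <- round_half_up(test_frac * n)
  if (n_test < 2 || n - n_test < 2) abort("test_frac leaves a degenerate set")
  min_group <- min(table(groups))
  if (stratify && min_group < 3) {
    abort(paste0(
      "a group has only ", min_group, " member(s); ",
      "need at least 3 per group for stratified outer+inner splits"
    ))
  }

  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      test <- draw_holdout(groups, seq_len(n), n_test, stratify)
      train <- setdiff(seq_len(n), test)
      n_val <- max(1L, round_half_up(inner_frac * length(train)))
      inner_val <- draw_holdout(groups, train, n_val, stratify)
      inner_train <- setdiff(train, inner_val)
      list(
        train = train, test = test,
        inner_train = inner_train, inner_val = inner_val
      )
    })
  })
  if (!stratify) {
    ok <- vapply(reps, function(r) {
      all(vapply(r, function(idx) length(unique(groups[idx])) == 2, logical(1)))
    }, logical(1))
    if (!all(ok)) {
      abort(paste0(
        sum(!ok), " of ", n_reps, " repetitions have a single-class set; ",
        "use stratify = TRUE or fewer repetitions"
      ))
    }
  }
  structure(
    list(
      reps = reps, n = n, n_reps = n_reps, test_frac = test_frac,
      inner_frac = inner_frac, stratify = stratify, seed = seed
    ),
    class = "split_plan"
  )
}

round_half_up <- function(x) floor(x + 0.5)

# sample a holdout of size n_out from pool, proportionally per stratum
draw_holdout <- function(groups, pool, n_out, stratify) {
  if (!stratify) {
    return(sort(sample(pool, n_out)))
  }
  g <- groups[pool]
  lev <- sort(unique(g))
  sizes <- table(factor(g, levels = lev))
  take <- round_half_up(n_out * as.numeric(sizes) / length(pool))
  # repair rounding drift while keeping each stratum non-empty and proper
  while (sum(take) != n_out) {
    d <- sign(n_out - sum(take))
    j <- if (d > 0) which.max(sizes - take) else which.max(take)
    take[j] <- take[j] + d
  }
  take <- pmin(pmax(take, 1L), as.numeric(sizes) - 1L)
  sort(unlist(lapply(seq_along(lev), function(j) {
    sample(pool[g == lev[j]], take[j])
  }), use.names = FALSE))
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo CV plan: %d reps, n = %d, test %.0f%%, inner val %.0f%%%s, seed %d\n",
    x$n_reps, x$n, 100 * x$test_frac, 100 * x$inner_frac,
    if (x$stratify) ", stratified" else "", x$seed
  ))
  invisible(x)
}

#' Random-forest hyperparameter grid
#'
#' The default grid crosses number of trees \{200, 500\}, features tried per
#' split \{sqrt(p), p/3\}, and minimum node size \{1, 5\}. `mtry` entries are
#' symbolic (`"sqrt"`, `"third"`) and resolved against the number of
#' predictors at fit time.
#'
#' @param num_trees,mtry,min_node Vectors of candidate values.
#' @return A tibble with one row per configuration.
#' @export
rf_grid <- function(num_trees = c(200, 500), mtry = c("sqrt", "third"),
                    min_node = c(1, 5)) {
  tidyr::expand_grid(num_trees = num_trees, mtry = mtry, min_node = min_node)
}

resolve_mtry <- function(mtry, p) {
  if (is.numeric(mtry)) return(max(1L, min(p, as.integer(mtry))))
  switch(as.character(mtry),
    sqrt = max(1L, floor(sqrt(p))),
    third = max(1L, floor(p / 3)),
    abort(paste0("unknown mtry spec: ", mtry))
  )
}

# single ranger fit; x data.frame of predictors, y factor control/case
fit_rf <- function(x, y, config, seed, importance = "none") {
  ranger::ranger(
    x = x, y = y, probability = TRUE,
    num.trees = config$num_trees,
    mtry = resolve_mtry(config$mtry, ncol(x)),
    min.node.size = config$min_node,
    importance = importance,
    seed = seed, num.threads = 1
  )
}

predict_case_prob <- function(fit, x) {
  predict(fit, data = x, num.threads = 1)$predictions[, "case"]
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' Equals the proportion of (case, control) pairs where the case scores
#' higher, counting ties as one half. With all scores equal the AUC is 0.5.
#'
#' @param scores Numeric vector of predicted case scores/probabilities.
#' @param is_case Logical vector, `TRUE` for cases.
#' @return The AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, is_case) {
  stopifnot(length(scores) == length(is_case))
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) abort("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# accuracy / TPR / TNR at probability threshold 0.5 (case if prob >= 0.5)
confusion_metrics <- function(prob, is_case, threshold = 0.5) {
  pred_case <- prob >= threshold
  tp <- sum(pred_case & is_case)
  tn <- sum(!pred_case & !is_case)
  fp <- sum(pred_case & !is_case)
  fn <- sum(!pred_case & is_case)
  c(
    accuracy = (tp + tn) / length(prob),
    tpr = tp / (tp + fn),
    tnr = tn / (tn + fp)
  )
}

#' Select a hyperparameter configuration on an inner validation split
#'
#' Fits every configuration of the grid on the inner training subjects and
#' scores it on the validation subjects by AUC; ties are broken by accuracy,
#' then by grid order. A degenerate (single-class) validation set triggers a
#' fallback to the out-of-bag score on the inner training set, with a
#' warning.
#'
#' @param x Predictor data frame (all subjects).
#' @param y Outcome factor (levels `control`, `case`).
#' @param inner_train,inner_val Row index sets.
#' @param grid Configuration tibble from [rf_grid()].
#' @param seed Integer seed for the candidate fits.
#' @return The winning one-row configuration.
#' @export
tune_rf <- function(x, y, inner_train, inner_val, grid, seed = 1) {
  stopifnot(nrow(grid) >= 1)
  if (nrow(grid) == 1) return(grid)
  val_degenerate <- length(unique(y[inner_val])) < 2
  if (val_degenerate) {
    warn("single-class validation set; tuning on out-of-bag score instead")
  }
  scores <- purrr::map(seq_len(nrow(grid)), function(i) {
    cfg <- grid[i, ]
    fit <- fit_rf(x[inner_train, , drop = FALSE], y[inner_train], cfg,
      seed = seed + i
    )
    if (val_degenerate) {
      prob <- fit$predictions[, "case"] # out-of-bag
      idx <- inner_train
    } else {
      prob <- predict_case_prob(fit, x[inner_val, , drop = FALSE])
      idx <- inner_val
    }
    keep <- !is.na(prob)
    is_case <- y[idx] == "case"
    c(
      auc = auc_mann_whitney(prob[keep], is_case[keep]),
      acc = unname(confusion_metrics(prob[keep], is_case[keep])["accuracy"])
    )
  })
  auc <- vapply(scores, `[[`, numeric(1), "auc")
  acc <- vapply(scores, `[[`, numeric(1), "acc")
  grid[order(-auc, -acc, seq_along(auc))[1], ]
}

#' Monte Carlo cross-validated random-forest evaluation
#'
#' The package's core evaluation loop. Per repetition of the plan: tune the
#' hyperparameters on the inner split, refit the chosen configuration on the
#' full outer training set, and score the held-out test set — accuracy, true
#' positive rate (sensitivity), true negative rate (specificity) at
#' probability threshold 0.5, and AUC by the rank formulation, with `case`
#' as the positive class. Per-repetition variable importances (impurity
#' decrease by default) are normalized to sum to one and stored for
#' aggregation by [rank_variables()].
#'
#' @param ft Feature table from [build_feature_table()] (no missing values;
#'   run [handle_missing()] first).
#' @param plan A [make_split_plan()] plan for the same subjects.
#' @param grid Hyperparameter grid (default [rf_grid()]).
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @return An `mccv_report`: per-rep metric tibble, normalized importance
#'   matrix (reps x variables), and summary means.
#' @export
mccv_evaluate <- function(ft, plan, grid = rf_grid(),
                          importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  stopifnot(inherits(plan, "split_plan"))
  if (nrow(ft) != plan$n) abort("feature table and plan disagree on n")
  d <- ft_design(ft)
  if (anyNA(d$x)) abort("feature table contains missing values; run handle_missing() first")
  y <- d$y
  p <- ncol(d$x)

  zero_var_events <- 0L
  rows <- vector("list", plan$n_reps)
  imp <- matrix(NA_real_, plan$n_reps, p, dimnames = list(NULL, names(d$x)))
  for (r in seq_len(plan$n_reps)) {
    sp <- plan$reps[[r]]
    rep_seed <- plan$seed + r
    cfg <- tune_rf(d$x, y, sp$inner_train, sp$inner_val, grid,
      seed = rep_seed * 1000L %% .Machine$integer.max
    )
    train_x <- d$x[sp$train, , drop = FALSE]
    if (any(vapply(train_x, function(v) sd(v) == 0, logical(1)))) {
      zero_var_events <- zero_var_events + 1L # retained: RF tolerates
    }
    fit <- fit_rf(train_x, y[sp$train], cfg,
      seed = rep_seed, importance = importance
    )
    prob <- predict_case_prob(fit, d$x[sp$test, , drop = FALSE])
    is_case <- y[sp$test] == "case"
    cm <- confusion_metrics(prob, is_case)
    iv <- fit$variable.importance
    iv <- pmax(iv, 0)
    imp[r, names(iv)] <- if (sum(iv) > 0) iv / sum(iv) else rep(1 / p, p)
    rows[[r]] <- tibble::tibble(
      rep = r,
      accuracy = cm[["accuracy"]], tpr = cm[["tpr"]], tnr = cm[["tnr"]],
      auc = auc_mann_whitney(prob, is_case),
      num_trees = cfg$num_trees, mtry = as.character(cfg$mtry),
      min_node = cfg$min_node
    )
  }
  metrics <- dplyr::bind_rows(rows)
  structure(
    list(
      metrics = metrics,
      importance = imp,
      variables = names(d$x),
      covariates = ft_covariates(ft),
      summary = dplyr::summarise(
        metrics,
        dplyr::across(c("accuracy", "tpr", "tnr", "auc"), mean)
      ),
      zero_variance_events = zero_var_events,
      n_reps = plan$n_reps, plan_seed = plan$seed
    ),
    class = "mccv_report"
  )
}

#' @export
print.mccv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "MCCV report: %d reps | accuracy %.1f%% TPR %.1f%% TNR %.1f%% AUC %.3f\n",
    x$n_reps, 100 * s$accuracy, 100 * s$tpr, 100 * s$tnr, s$auc
  ))
  invisible(x)
}

#' @describeIn mccv_evaluate Per-repetition metrics as a tibble.
#' @param x An `mccv_report`.
#' @param ... Unused.
#' @export
tidy.mccv_report <- function(x, ...) x$metrics

#' @describeIn mccv_evaluate One-row summary of mean metrics.
#' @export
glance.mccv_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_reps = x$n_reps), x$summary)
}

# aggregate a report's importances into a ranked table
importance_ranking <- function(report) {
  imp <- report$importance
  mean_imp <- colMeans(imp)
  per_rep_rank <- t(apply(-imp, 1, rank, ties.method = "average"))
  if (ncol(imp) == 1) per_rep_rank <- matrix(1, nrow(imp), 1)
  mean_rank <- colMeans(per_rep_rank)
  out <- tibble::tibble(
    variable = colnames(imp),
    mean_importance = mean_imp,
    mean_rank = mean_rank,
    is_covariate = colnames(imp) %in% report$covariates
  )
  out <- out[order(-out$mean_importance, out$mean_rank, out$variable), ]
  out$rank <- seq_len(nrow(out))
  out[, c("rank", "variable", "mean_importance", "mean_rank", "is_covariate")]
}

#' Rank variables by Monte Carlo-aggregated random-forest importance
#'
#' Runs the MCCV loop of [mccv_evaluate()] and averages the per-repetition
#' normalized importances; variables (lipid features and the age/sex
#' covariates alike) are returned in descending order of mean importance,
#' ties broken by mean per-rep rank and then name. At class level on the
#' default panel the table has 36 rows (34 classes + age + sex).
#'
#' @inheritParams mccv_evaluate
#' @return A tibble: `rank`, `variable`, `mean_importance`, `mean_rank`,
#'   `is_covariate`.
#' @export
rank_variables <- function(ft, plan, grid = rf_grid(),
                           importance = c("impurity", "permutation")) {
  importance_ranking(mccv_evaluate(ft, plan, grid, importance))
}
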