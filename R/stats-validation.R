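#' Two-tailed Welch's t test
#'
#' Welch's unequal-variance t test, implemented directly from the
#' Welch-Satterthwaite formulas: statistic
#' \eqn{t = (\bar a - \bar b)/\sqrt{s_a^2/n_a + s_b^2/n_b}}, degrees of
#' freedom by the Satterthwaite approximation, two-sided p from the t
#' distribution, and a confidence interval for the mean difference
#' (convention: first argument minus second; in group comparisons the
#' package always passes case first, so the estimate is case − control).
#'
#' @param a,b Numeric vectors (missing values dropped); each needs at least
#'   two non-missing values.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return One-row tibble: `estimate` (mean of `a` − mean of `b`),
#'   `statistic`, `df`, `p.value`, `conf.low`, `conf.high`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @details Two degenerate inputs are handled explicitly: if both groups are
#'   constant with equal means the difference is exactly zero with no
#'   sampling noise (`t = 0`, `p = 1`, a zero-width interval); if both are
#'   constant with unequal means the standard error is zero and the
#'   statistic undefined, which is an error.
#' @export
welch_test <- function(a, b, conf_level = 0.95) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("welch_test needs at least 2 non-missing values per group")
  }
  na <- length(a)
  nb <- length(b)
  ma <- mean(a)
  mb <- mean(b)
  va <- var(a)
  vb <- var(b)
  est <- ma - mb
  if (va == 0 && vb == 0) {
    if (est == 0) {
      return(tibble::tibble(
        estimate = 0, statistic = 0, df = na + nb - 2, p.value = 1,
        conf.low = 0, conf.high = 0, mean_a = ma, mean_b = mb,
        n_a = na, n_b = nb
      ))
    }
    abort("zero variance in both groups with unequal means: standard error undefined")
  }
  se <- sqrt(va / na + vb / nb)
  stat <- est / se
  df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(stat), df)
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  tibble::tibble(
    estimate = est, statistic = stat, df = df, p.value = p,
    conf.low = est - tcrit * se, conf.high = est + tcrit * se,
    mean_a = ma, mean_b = mb, n_a = na, n_b = nb
  )
}

#' Bonferroni-adjusted per-test significance threshold
#'
#' For `m` simultaneous tests at family-wise level `alpha`, the per-test
#' threshold is `alpha / m`. Report tables print it to two significant
#' digits, so 0.05 over 17 species reads 0.0029.
#'
#' @param alpha Family-wise significance level.
#' @param m Number of tests (≥ 1).
#' @return The unrounded threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Log2 fold change of group means
#'
#' @param case,control Numeric vectors of linear-scale concentrations;
#'   missing values dropped. Both group means must be positive.
#' @return `log2(mean(case) / mean(control))`.
#' @export
log2_fold_change <- function(case, control) {
  mc <- mean(case, na.rm = TRUE)
  mk <- mean(control, na.rm = TRUE)
  if (!(mc > 0 && mk > 0)) abort("log2_fold_change needs positive group means")
  log2(mc / mk)
}

#' Univariate logistic regression of outcome on one feature
#'
#' Maximum-likelihood fit of `outcome ~ feature`; the reported p-value is
#' the Wald test on the slope. Perfect separation is detected (the fitted
#' probabilities collapse to 0/1) and flagged instead of reporting an
#' unusable p-value.
#'
#' @param feature Numeric predictor.
#' @param labels Outcome (factor/character/logical); `case` (or `TRUE`) is
#'   the positive class.
#' @return One-row tibble: `estimate`, `std.error`, `statistic`, `p.value`,
#'   `separation` (logical; when `TRUE` the inferential columns are `NA`).
#' @export
univariate_logistic <- function(feature, labels) {
  y <- as_case_indicator(labels)
  keep <- !is.na(feature) & !is.na(y)
  feature <- feature[keep]
  y <- y[keep]
  if (length(unique(y)) < 2) abort("both outcome levels must be present")
  fit <- suppressWarnings(glm(y ~ feature, family = binomial()))
  probs <- fitted(fit)
  separated <- all(abs(probs - y) < 1e-6) || max(abs(coef(fit)[-1])) > 20
  if (separated) {
    return(tibble::tibble(
      estimate = unname(coef(fit)[2]), std.error = NA_real_,
      statistic = NA_real_, p.value = NA_real_, separation = TRUE
    ))
  }
  sm <- summary(fit)$coefficients
  tibble::tibble(
    estimate = sm[2, 1], std.error = sm[2, 2],
    statistic = sm[2, 3], p.value = sm[2, 4], separation = FALSE
  )
}

as_case_indicator <- function(labels) {
  if (is.logical(labels)) return(as.numeric(labels))
  as.numeric(as.character(labels) == "case")
}

# likelihood-ratio p for adding `feature` to glm with predictors `base`
# on data frame df with response y
lrt_add_p <- function(df, y, base, feature) {
  f0 <- glm_deviance(df, y, base)
  f1 <- glm_deviance(df, y, c(base, feature))
  pchisq(f0 - f1, df = 1, lower.tail = FALSE)
}

glm_deviance <- function(df, y, vars) {
  if (length(vars) == 0) {
    return(suppressWarnings(glm(y ~ 1, family = binomial()))$deviance)
  }
  x <- as.matrix(df[, vars, drop = FALSE])
  suppressWarnings(glm(y ~ x, family = binomial()))$deviance
}

#' Sequential logistic feature selection (SFS, SBS, SFFS)
#'
#' Wrapper selection over logistic regression driven by likelihood-ratio
#' tests. Forward selection (SFS) repeatedly adds the candidate with the
#' smallest LRT p-value while it is below `enter_p`; backward selection
#' (SBS) starts from the full model and repeatedly removes the feature whose
#' removal has the largest p-value while it exceeds `remove_p`; floating
#' forward selection (SFFS) is forward selection with a conditional backward
#' sweep after every inclusion (the just-added feature is exempt from
#' immediate removal). Ties are broken by candidate order, making the whole
#' procedure deterministic.
#'
#' @param ft Feature table (or any tibble with a `group` column and numeric
#'   candidate columns).
#' @param method `"SFS"`, `"SBS"`, or `"SFFS"`.
#' @param candidates Candidate column names; defaults to the lipid features
#'   of `ft`.
#' @param enter_p LRT p-value required to enter the model (default 0.05).
#' @param remove_p LRT p-value above which a feature is removed (default
#'   0.10).
#' @return A list: `selected` (character vector, inclusion order for
#'   forward methods), `log` (tibble of every step: `step`, `action`,
#'   `feature`, `p.value`, `model_size`), `method`.
#' @export
sequential_logistic_selection <- function(ft, method = c("SFS", "SBS", "SFFS"),
                                          candidates = NULL,
                                          enter_p = 0.05, remove_p = 0.10) {
  method <- match.arg(method)
  candidates <- candidates %||% ft_features(ft)
  if (length(candidates) < 2) abort("need at least 2 candidate features")
  y <- as_case_indicator(ft$group)
  df <- as.data.frame(ft[, candidates, drop = FALSE])
  steps <- list()
  log_step <- function(action, feature, p, size) {
    steps[[length(steps) + 1]] <<- tibble::tibble(
      step = length(steps) + 1, action = action, feature = feature,
      p.value = p, model_size = size
    )
  }

  best_addition <- function(sel) {
    rest <- setdiff(candidates, sel)
    if (length(rest) == 0) return(NULL)
    ps <- vapply(rest, function(f) lrt_add_p(df, y, sel, f), numeric(1))
    list(feature = rest[which.min(ps)], p = min(ps))
  }
  worst_member <- function(sel, exempt = character()) {
    pool <- setdiff(sel, exempt)
    if (length(pool) == 0) return(NULL)
    ps <- vapply(pool, function(f) {
      lrt_add_p(df, y, setdiff(sel, f), f) # p of f given the others
    }, numeric(1))
    list(feature = pool[which.max(ps)], p = max(ps))
  }

  sel <- character()
  if (method == "SBS") {
    sel <- candidates
    repeat {
      w <- worst_member(sel)
      if (is.null(w) || w$p <= remove_p) break
      sel <- setdiff(sel, w$feature)
      log_step("remove", w$feature, w$p, length(sel))
      if (length(sel) == 0) break
    }
  } else {
    repeat {
      a <- best_addition(sel)
      if (is.null(a) || a$p >= enter_p) break
      sel <- c(sel, a$feature)
      log_step("add", a$feature, a$p, length(sel))
      if (method == "SFFS") {
        repeat {
          w <- worst_member(sel, exempt = a$feature)
          if (is.null(w) || w$p <= remove_p) break
          sel <- setdiff(sel, w$feature)
          log_step("remove", w$feature, w$p, length(sel))
        }
      }
    }
  }
  log_tbl <- if (length(steps) == 0) {
    tibble::tibble(
      step = integer(), action = character(), feature = character(),
      p.value = numeric(), model_size = integer()
    )
  } else {
    dplyr::bind_rows(steps)
  }
  list(selected = sel, log = log_tbl, method = method,
       enter_p = enter_p, remove_p = remove_p)
}

#' Direction of effect by ridge-penalized logistic regression
#'
#' Fits an L2-penalized logistic regression of case status on all supplied
#' features, standardized to zero mean and unit variance so the coefficient
#' signs are comparable across features. The sign of each coefficient is the
#' direction of impact: positive means higher concentration raises the
#' predicted probability of being a case. When no penalty is supplied it is
#' chosen by 5-fold cross-validated deviance.
#'
#' @param ft Feature table.
#' @param features Feature columns to fit jointly; defaults to all lipid
#'   features.
#' @param penalty Ridge penalty (glmnet lambda); `NULL` (default) picks it
#'   by cross-validation.
#' @param seed Seed for the cross-validation folds.
#' @return A tibble: `feature`, `coefficient` (standardized scale),
#'   `direction` (`"Positive"`, `"Negative"`, or `"Indeterminate"` for an
#'   exactly zero coefficient), with the penalty in attribute `"penalty"`.
#' @export
ridge_direction <- function(ft, features = NULL, penalty = NULL, seed = 1) {
  features <- features %||% ft_features(ft)
  y <- as_case_indicator(ft$group)
  x <- as.matrix(ft[, features, drop = FALSE])
  sds <- apply(x, 2, sd)
  xs <- scale(x)
  xs[, sds == 0] <- 0
  fit_x <- if (ncol(xs) == 1) cbind(xs, .zero. = 0) else xs
  if (is.null(penalty)) {
    foldid <- withr::with_seed(seed, sample(rep_len(1:5, length(y))))
    cv <- glmnet::cv.glmnet(fit_x, y,
      family = "binomial", alpha = 0,
      foldid = foldid, standardize = FALSE
    )
    penalty <- cv$lambda.min
  }
  fit <- glmnet::glmnet(fit_x, y,
    family = "binomial", alpha = 0,
    lambda = penalty, standardize = FALSE
  )
  co <- as.numeric(coef(fit))[-1][seq_along(features)]
  out <- tibble::tibble(
    feature = features,
    coefficient = co,
    direction = dplyr::case_when(
      co > 0 ~ "Positive",
      co < 0 ~ "Negative",
      TRUE ~ "Indeterminate"
    )
  )
  attr(out, "penalty") <- penalty
  out
}

#' Statistical validation of a selected feature set
#'
#' Builds the report-table record for each selected feature: Welch test of
#' case versus control concentrations (estimate, 95% CI, p), ridge-based
#' direction of effect fitted jointly on the selected set, the
#' Bonferroni-corrected significance flag, the univariate logistic flag,
#' and membership in the models chosen by the three sequential multivariate
#' selection variants.
#'
#' @param ft Feature table containing the selected features.
#' @param selected Feature ids in rank order.
#' @param taxonomy Optional taxonomy; adds a `class` column (species
#'   tables).
#' @param class_directions Optional tibble (`feature`, `direction`) of
#'   class-level directions; adds a `class_direction` column.
#' @param conf_level Welch confidence level (default 0.95).
#' @param alpha Family-wise significance level (default 0.05); the
#'   Bonferroni family size is the number of selected features.
#' @param seed Seed for the ridge penalty cross-validation.
#' @return A tibble, one row per selected feature in rank order: `rank`,
#'   `feature`, `direction`, optional `class`/`class_direction`, `estimate`
#'   (case − control), `conf.low`, `conf.high`, `p.value`,
#'   `significant_unadjusted`, `significant_bonferroni`,
#'   `univariate_significant`, `in_sfs`, `in_sbs`, `in_sffs`.
#' @export
validate_selection <- function(ft, selected, taxonomy = NULL,
                               class_directions = NULL,
                               conf_level = 0.95, alpha = 0.05, seed = 1) {
  stopifnot(length(selected) >= 1)
  missing_feats <- setdiff(selected, names(ft))
  if (length(missing_feats) > 0) {
    abort(paste0(
      "selected features absent from table: ",
      paste(missing_feats, collapse = ", ")
    ))
  }
  is_case <- ft$group == "case"
  welch <- dplyr::bind_rows(lapply(selected, function(f) {
    welch_test(ft[[f]][is_case], ft[[f]][!is_case], conf_level)
  }))
  dirs <- ridge_direction(ft, features = selected, seed = seed)
  uni <- dplyr::bind_rows(lapply(selected, function(f) {
    univariate_logistic(ft[[f]], ft$group)
  }))
  seq_sets <- lapply(c("SFS", "SBS", "SFFS"), function(m) {
    if (length(selected) >= 2) {
      sequential_logistic_selection(ft, method = m, candidates = selected)$selected
    } else {
      character()
    }
  })
  thr <- bonferroni_threshold(alpha, length(selected))

  out <- tibble::tibble(
    rank = seq_along(selected),
    feature = selected,
    direction = dirs$direction[match(selected, dirs$feature)],
    estimate = welch$estimate,
    conf.low = welch$conf.low,
    conf.high = welch$conf.high,
    p.value = welch$p.value,
    significant_unadjusted = welch$p.value < alpha,
    significant_bonferroni = welch$p.value < thr,
    univariate_significant = !uni$separation &
      !is.na(uni$p.value) & uni$p.value < alpha,
    in_sfs = selected %in% seq_sets[[1]],
    in_sbs = selected %in% seq_sets[[2]],
    in_sffs = selected %in% seq_sets[[3]]
  )
  if (!is.null(taxonomy)) {
    out$class <- taxonomy$class_id[match(out$feature, taxonomy$species_id)]
    if (!is.null(class_directions)) {
      out$class_direction <- class_directions$direction[
        match(out$class, class_directions$feature)
      ]
    }
    front <- c("rank", "feature", "direction", "class",
               if (!is.null(class_directions)) "class_direction")
    out <- out[, c(front, setdiff(names(out), front))]
  }
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "conf_level") <- conf_level
  out
}
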