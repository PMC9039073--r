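#' Fit a NOMIS normalization model
#'
#' Normalization using Optimal selection of Multiple Internal Standards:
#' every candidate subset of internal standards (up to `max_subset` of them,
#' including the empty no-correction subset) is scored by regressing each
#' feature's log-peak on the centered log-IS intensities of the subset and
#' measuring the mean leave-one-out squared prediction residual (PRESS/n)
#' across features. The winner is chosen by a one-standard-error parsimony
#' rule: among subsets whose criterion is within one standard error of the
#' minimum, the smallest subset wins — so standards that track no real
#' technical variation cannot displace the no-correction model. Per-feature
#' coefficients of the winning subset define the correction applied by
#' [apply_nomis()].
#'
#' Inputs are linear-scale intensity tables; all fitting happens on the
#' natural-log scale internally.
#'
#' @param peaks Wide tibble of raw peak intensities (`subject_id` +
#'   features), linear scale.
#' @param is_table Wide tibble of internal-standard intensities for the same
#'   samples, linear scale.
#' @param max_subset Largest IS subset size searched (default `min(5, #IS)`).
#' @return A `nomis_model`: winning subset, per-feature coefficients and
#'   intercepts, training IS centers, and the audit table of criterion
#'   values for every candidate subset.
#' @details Internal standards with zero variance carry no information about
#'   technical drift; they are excluded from the candidate pool with a
#'   warning. If every IS is constant the model degenerates to the identity
#'   (no correction), also with a warning. Samples with any missing IS
#'   measurement are excluded from fitting.
#' @export
fit_nomis <- function(peaks, is_table, max_subset = NULL) {
  if (!identical(peaks$subject_id, is_table$subject_id)) {
    abort("peaks and is_table must cover the same samples in the same order")
  }
  y_all <- log(abundance_matrix(peaks))
  z_all <- log(abundance_matrix(is_table))
  if (nrow(y_all) < 3) abort("NOMIS needs at least 3 samples")
  ok <- complete.cases(z_all)
  y <- y_all[ok, , drop = FALSE]
  z <- z_all[ok, , drop = FALSE]

  is_names <- colnames(z)
  sds <- apply(z, 2, sd)
  if (any(sds == 0)) {
    warn(paste0(
      "constant internal standard(s) excluded: ",
      paste(is_names[sds == 0], collapse = ", ")
    ))
  }
  usable <- is_names[sds > 0]
  if (length(usable) == 0) {
    warn("all internal standards are constant; returning identity model")
    return(new_nomis_model(
      subset = character(), coefficients = NULL, centers = numeric(),
      criterion = NA_real_, audit = tibble::tibble(), features = colnames(y)
    ))
  }
  max_subset <- max_subset %||% min(5L, length(usable))
  stopifnot(max_subset >= 1, max_subset <= length(usable))

  # the empty subset (no correction) competes too: NOMIS degrades to the
  # identity when no internal standard lowers the leave-one-out criterion
  subsets <- c(
    list(character()),
    unlist(
      lapply(seq_len(max_subset), function(k) {
        utils::combn(usable, k, simplify = FALSE)
      }),
      recursive = FALSE
    )
  )
  press <- lapply(subsets, function(s) nomis_press(y, z[, s, drop = FALSE]))
  crits <- vapply(press, `[[`, numeric(1), "mean")
  ses <- vapply(press, `[[`, numeric(1), "se")
  audit <- tibble::tibble(
    subset = vapply(
      subsets,
      function(s) if (length(s) == 0) "(none)" else paste(s, collapse = "+"),
      character(1)
    ),
    size = lengths(subsets),
    criterion = crits,
    criterion_se = ses
  )
  # one-standard-error parsimony rule: among subsets whose criterion is
  # within one SE of the minimum, take the smallest (ties by criterion) —
  # so pure-noise standards cannot displace the no-correction model
  i_min <- which.min(crits)
  eligible <- which(crits <= crits[i_min] + ses[i_min])
  i_best <- eligible[order(lengths(subsets)[eligible], crits[eligible])][1]
  best <- subsets[[i_best]]
  if (length(best) == 0) {
    return(new_nomis_model(
      subset = character(), coefficients = NULL, centers = numeric(),
      criterion = crits[i_best], audit = audit, features = colnames(y)
    ))
  }

  centers <- colMeans(z[, best, drop = FALSE])
  zc <- sweep(z[, best, drop = FALSE], 2, centers)
  X <- cbind(`(Intercept)` = 1, zc)
  B <- qr.coef(qr(X), y) # (1+k) x features
  new_nomis_model(
    subset = best,
    coefficients = B[-1, , drop = FALSE],
    intercepts = B[1, ],
    centers = centers,
    criterion = crits[i_best],
    audit = audit,
    features = colnames(y)
  )
}

# mean (and its standard error across features) of the per-feature mean
# squared leave-one-out residual for the regression on centered IS columns
nomis_press <- function(y, z) {
  zc <- scale(z, center = TRUE, scale = FALSE)
  X <- cbind(1, zc)
  qx <- qr(X)
  h <- rowSums(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]^2)
  press_j <- vapply(seq_len(ncol(y)), function(j) {
    yy <- y[, j]
    obs <- !is.na(yy)
    if (sum(obs) <= ncol(X)) {
      return(NA_real_)
    }
    if (all(obs)) {
      e <- yy - X %*% qr.coef(qx, yy)
      mean((e / (1 - h))^2)
    } else {
      q2 <- qr(X[obs, , drop = FALSE])
      h2 <- rowSums(qr.Q(q2)[, seq_len(q2$rank), drop = FALSE]^2)
      e <- yy[obs] - X[obs, , drop = FALSE] %*% qr.coef(q2, yy[obs])
      mean((e / (1 - h2))^2)
    }
  }, numeric(1))
  ok <- press_j[!is.na(press_j)]
  list(mean = mean(ok), se = sd(ok) / sqrt(length(ok)))
}

new_nomis_model <- function(subset, coefficients, centers, criterion, audit,
                            features, intercepts = NULL) {
  structure(
    list(
      subset = subset, coefficients = coefficients,
      intercepts = intercepts, centers = centers,
      criterion = criterion, audit = audit, features = features
    ),
    class = "nomis_model"
  )
}

#' @export
print.nomis_model <- function(x, ...) {
  cat("NOMIS model\n")
  if (length(x$subset) == 0) {
    cat("  identity (no internal-standard correction)\n")
  } else {
    cat(
      "  selected IS subset:", paste(x$subset, collapse = " + "),
      sprintf("(LOO criterion %.4g)\n", x$criterion)
    )
    cat("  features:", length(x$features), "\n")
  }
  invisible(x)
}

#' Apply a fitted NOMIS model to a peak table
#'
#' Subtracts the fitted internal-standard component from each log-peak:
#' normalized log-value = raw log-value − Σ coefficient × (log-IS − training
#' center); the result is returned on the linear concentration scale.
#' Missing raw entries stay missing; a sample missing any selected IS
#' measurement has all its features flagged missing.
#'
#' @param model A `nomis_model` from [fit_nomis()].
#' @param peaks Wide tibble of raw peak intensities, linear scale. Must
#'   contain the model's features.
#' @param is_table Wide IS tibble for the same samples, containing the
#'   model's selected IS columns.
#' @return A wide abundance tibble of normalized concentrations.
#' @export
apply_nomis <- function(model, peaks, is_table) {
  y <- log(abundance_matrix(peaks))
  if (length(model$subset) == 0) {
    return(matrix_to_abundance(exp(y)))
  }
  missing_is <- setdiff(model$subset, names(is_table))
  if (length(missing_is) > 0) {
    abort(paste0(
      "is_table lacks selected internal standard(s): ",
      paste(missing_is, collapse = ", ")
    ))
  }
  feats <- intersect(colnames(y), model$features)
  if (length(feats) < ncol(y)) {
    abort("peaks contain features unknown to the model")
  }
  z <- log(abundance_matrix(is_table))[, model$subset, drop = FALSE]
  zc <- sweep(z, 2, model$centers)
  corr <- zc %*% model$coefficients[, colnames(y), drop = FALSE]
  out <- y - corr
  out[!complete.cases(z), ] <- NA_real_
  matrix_to_abundance(exp(out))
}

#' @describeIn fit_nomis Per-feature coefficients of the winning subset as a
#'   long tibble (`feature`, `is_id`, `estimate`).
#' @param x A `nomis_model`.
#' @param ... Unused.
#' @export
tidy.nomis_model <- function(x, ...) {
  if (length(x$subset) == 0) {
    return(tibble::tibble(
      feature = character(), is_id = character(), estimate = numeric()
    ))
  }
  tidyr::pivot_longer(
    dplyr::bind_cols(
      tibble::tibble(is_id = rownames(x$coefficients)),
      tibble::as_tibble(x$coefficients)
    ),
    -"is_id",
    names_to = "feature", values_to = "estimate"
  )[, c("feature", "is_id", "estimate")]
}

#' @describeIn fit_nomis One-row summary (subset, size, criterion).
#' @export
glance.nomis_model <- function(x, ...) {
  tibble::tibble(
    subset = paste(x$subset, collapse = "+"),
    n_is = length(x$subset),
    n_features = length(x$features),
    criterion = x$criterion
  )
}
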