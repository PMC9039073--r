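#' Specify ground-truth group effects for the cohort generator
#'
#' Effects are additive mean shifts on the natural-log concentration scale,
#' applied to cases. A class effect shifts every member species of that
#' class; a species effect adds an extra shift to one species. The sign of
#' the total shift is the ground-truth direction of effect (positive = higher
#' in cases).
#'
#' @param class_effects Named numeric vector, names are class ids.
#' @param species_effects Named numeric vector, names are species ids.
#' @return An `effect_spec` list with elements `class_effects` and
#'   `species_effects`.
#' @export
effect_spec <- function(class_effects = numeric(), species_effects = numeric()) {
  stopifnot(is.numeric(class_effects), is.numeric(species_effects))
  if (length(class_effects) > 0 && is.null(names(class_effects))) {
    abort("class_effects must be named by class id")
  }
  if (length(species_effects) > 0 && is.null(names(species_effects))) {
    abort("species_effects must be named by species id")
  }
  structure(
    list(
      class_effects = class_effects,
      species_effects = species_effects
    ),
    class = "effect_spec"
  )
}

#' Demonstration effect template for the default panel
#'
#' Mirrors the directions reported for the ten leading serum classes
#' (PC, DG, TG, Cer, MhCer, BMP, LPS up in cases; GB3, NAPS, NAPE down);
#' the magnitudes are free demonstration parameters, not estimates.
#'
#' @param magnitude Absolute log-scale shift applied to each named class.
#' @return An [effect_spec()].
#' @export
default_effect_spec <- function(magnitude = 0.4) {
  dirs <- c(
    PC = 1, DG = 1, TG = 1, Cer = 1, MhCer = 1, BMP = 1, LPS = 1,
    GB3 = -1, NAPS = -1, NAPE = -1
  )
  effect_spec(class_effects = magnitude * dirs)
}

#' Simulate a case-control lipidomics cohort with known ground truth
#'
#' Concentrations are log-normal: for subject \eqn{i} and species \eqn{s} of
#' class \eqn{c},
#' \deqn{\log y_{is} = \mu_c + \mu_s + \mathrm{case}_i\,(\delta_c + \delta_s)
#'   + \varepsilon_{is},\quad \varepsilon_{is} \sim N(0, \sigma^2),}
#' with class baselines \eqn{\mu_c \sim N(b_0, \sigma_c^2)}, species
#' baselines \eqn{\mu_s \sim N(0, \sigma_s^2)}, and the case shifts
#' \eqn{\delta} taken from `effects`. Ages are normal (mean 51, sd 12),
#' truncated to 30–85, matching the age structure of the cohort the package
#' models; sex is Bernoulli per group (55% female in cases, 67% in
#' controls). A small per-cell dropout probability produces sporadic
#' below-detection missing values.
#'
#' @param taxonomy Taxonomy tibble; defaults to [default_taxonomy()].
#' @param n_case,n_control Group sizes (default 22 cases, 30 controls — the
#'   primary-analysis cohort size this generator emulates). Both must be
#'   at least 2.
#' @param effects An [effect_spec()]; default no effects (a null cohort).
#' @param noise_sd Log-scale residual standard deviation (default 1, a
#'   typical between-subject coefficient of variation for serum lipids).
#' @param baseline_mean,class_baseline_sd,species_baseline_sd Log-scale
#'   location and spread of class/species baselines.
#' @param p_female Named vector of female proportions for `case`/`control`.
#' @param dropout_prob Per-cell probability of a missing (undetectable)
#'   measurement. Default 0.01.
#' @param seed Integer seed; identical inputs give bitwise-identical output.
#' @return A list with elements `abundance` (wide tibble, linear scale),
#'   `metadata`, and `truth` (the effect spec, the informative class and
#'   species ids, and all generator parameters).
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' nrow(cohort$metadata) # 52
#' @export
simulate_cohort <- function(taxonomy = default_taxonomy(),
                            n_case = 22, n_control = 30,
                            effects = effect_spec(),
                            noise_sd = 1,
                            baseline_mean = 2,
                            class_baseline_sd = 0.8,
                            species_baseline_sd = 0.5,
                            p_female = c(case = 0.55, control = 0.67),
                            dropout_prob = 0.01,
                            seed = 1) {
  stopifnot(n_case >= 2, n_control >= 2, noise_sd >= 0)
  validate_taxonomy(taxonomy)
  bad_cls <- setdiff(names(effects$class_effects), unique(taxonomy$class_id))
  bad_sp <- setdiff(names(effects$species_effects), taxonomy$species_id)
  if (length(bad_cls) > 0 || length(bad_sp) > 0) {
    abort(paste0(
      "effects reference unknown ids: ",
      paste(c(bad_cls, bad_sp), collapse = ", ")
    ))
  }

  n <- n_case + n_control
  classes <- unique(taxonomy$class_id)
  p <- nrow(taxonomy)
  class_of <- taxonomy$class_id

  withr::with_seed(seed, {
    mu_class <- setNames(
      rnorm(length(classes), baseline_mean, class_baseline_sd), classes
    )
    mu_species <- rnorm(p, 0, species_baseline_sd)
    is_case <- rep(c(1, 0), c(n_case, n_control))
    delta <- rep(0, p)
    idx <- match(class_of, names(effects$class_effects))
    delta <- delta + ifelse(is.na(idx), 0, effects$class_effects[idx])
    idx <- match(taxonomy$species_id, names(effects$species_effects))
    delta <- delta + ifelse(is.na(idx), 0, effects$species_effects[idx])

    log_mean <- outer(is_case, delta) +
      matrix(mu_class[class_of] + mu_species, n, p, byrow = TRUE)
    logy <- log_mean + matrix(rnorm(n * p, 0, noise_sd), n, p)
    y <- exp(logy)
    if (dropout_prob > 0) {
      y[matrix(runif(n * p) < dropout_prob, n, p)] <- NA_real_
    }
    colnames(y) <- taxonomy$species_id
    rownames(y) <- sprintf("S%03d", seq_len(n))

    age <- rnorm(n, 51, 12)
    while (any(bad <- age < 30 | age > 85)) {
      age[bad] <- rnorm(sum(bad), 51, 12)
    }
    sex_p <- ifelse(is_case == 1, p_female[["case"]], p_female[["control"]])
    sex <- ifelse(runif(n) < sex_p, "female", "male")
  })

  metadata <- tibble::tibble(
    subject_id = rownames(y),
    group = factor(ifelse(is_case == 1, "case", "control"),
      levels = c("control", "case")
    ),
    age = round(age, 1),
    sex = factor(sex, levels = c("male", "female"))
  )
  informative_classes <- names(effects$class_effects)[effects$class_effects != 0]
  informative_species <- unique(c(
    names(effects$species_effects)[effects$species_effects != 0],
    taxonomy$species_id[class_of %in% informative_classes]
  ))
  truth <- list(
    effects = effects,
    informative_classes = informative_classes,
    informative_species = informative_species,
    params = list(
      n_case = n_case, n_control = n_control, noise_sd = noise_sd,
      baseline_mean = baseline_mean, class_baseline_sd = class_baseline_sd,
      species_baseline_sd = species_baseline_sd,
      dropout_prob = dropout_prob, seed = seed
    )
  )
  list(abundance = matrix_to_abundance(y), metadata = metadata, truth = truth)
}

#' Simulate raw LC-MS peaks with internal-standard drift
#'
#' Adds a latent per-sample technical factor to a true abundance table and
#' generates internal-standard (IS) intensities that track the same factor —
#' the input fixture for NOMIS normalization. On the log scale:
#' raw peak = true value + loading × factor + measurement noise; each IS =
#' its own constant + loading × factor + measurement noise.
#'
#' @param abundance True (drift-free) wide abundance tibble, linear scale.
#' @param n_is Number of internal standards (≥ 1). Default 3.
#' @param drift_sd Standard deviation of the latent technical factor on the
#'   log scale. `0` disables drift.
#' @param meas_sd Log-scale measurement noise sd (default 0.05).
#' @param feature_loading,is_loading Loadings of peaks / IS on the factor
#'   (default 1 each).
#' @param seed Integer seed.
#' @return A list: `peaks` (wide tibble, linear scale, same shape as
#'   `abundance`), `is_table` (wide tibble `subject_id` + one column per IS,
#'   linear scale), and `factor` (the latent per-sample technical factor,
#'   for testing).
#' @export
simulate_raw_peaks <- function(abundance, n_is = 3, drift_sd = 0.5,
                               meas_sd = 0.05, feature_loading = 1,
                               is_loading = 1, seed = 1) {
  stopifnot(n_is >= 1, drift_sd >= 0, meas_sd >= 0)
  m <- abundance_matrix(abundance)
  n <- nrow(m)
  p <- ncol(m)
  withr::with_seed(seed, {
    f <- rnorm(n, 0, drift_sd)
    raw_log <- log(m) + feature_loading * f +
      matrix(rnorm(n * p, 0, meas_sd), n, p)
    is_const <- seq(4, length.out = n_is, by = 0.5)
    is_log <- outer(rep(1, n), is_const) + is_loading * f +
      matrix(rnorm(n * n_is, 0, meas_sd), n, n_is)
  })
  colnames(is_log) <- paste0("IS", seq_len(n_is))
  rownames(is_log) <- rownames(m)
  list(
    peaks = matrix_to_abundance(exp(raw_log)),
    is_table = matrix_to_abundance(exp(is_log)),
    factor = setNames(f, rownames(m))
  )
}

#' Write a simulated cohort to disk
#'
#' Writes the abundance, metadata and taxonomy as CSV and the ground truth
#' as JSON, so a cohort can be round-tripped through the file readers.
#'
#' @param cohort A list as returned by [simulate_cohort()].
#' @param taxonomy The taxonomy used to generate it.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, taxonomy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$abundance, file.path(dir, "abundance.csv"), na = "")
  readr::write_csv(cohort$metadata, file.path(dir, "metadata.csv"))
  readr::write_csv(taxonomy, file.path(dir, "taxonomy.csv"))
  truth <- cohort$truth
  truth$effects <- lapply(unclass(truth$effects), as.list)
  jsonlite::write_json(
    truth, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
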