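# shared fixtures: small panels, cohorts and grids used across test files

# a compact taxonomy: n_classes classes x species_per class, dotted names
toy_taxonomy <- function(n_classes = 8, species_per = 5) {
  classes <- paste0("CL", seq_len(n_classes))
  dplyr::bind_rows(lapply(classes, function(cl) {
    tibble::tibble(
      species_id = paste(cl, seq(30, by = 2, length.out = species_per),
        rep(0:4, length.out = species_per),
        sep = "."
      ),
      class_id = cl
    )
  }))
}

# singleton hyperparameter configuration: fast, no inner tuning loop
fast_grid <- function() rf_grid(num_trees = 200, mtry = "sqrt", min_node = 5)

# cohort with a known class-level spike, no dropout
spiked_cohort <- function(taxonomy = toy_taxonomy(), spiked = c("CL1", "CL2"),
                          effect = 1.5, n_case = 22, n_control = 30,
                          noise_sd = 0.6, seed = 1) {
  eff <- effect_spec(class_effects = setNames(rep(effect, length(spiked)), spiked))
  simulate_cohort(taxonomy,
    n_case = n_case, n_control = n_control,
    effects = eff, noise_sd = noise_sd, dropout_prob = 0, seed = seed
  )
}

cohort_feature_tables <- function(cohort, taxonomy) {
  list(
    species = build_feature_table(cohort$abundance, cohort$metadata),
    class = build_feature_table(
      aggregate_to_classes(cohort$abundance, taxonomy), cohort$metadata
    )
  )
}
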