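# independent oracles coded here, against which the implementation is checked
auc_brute_force <- function(scores, is_case) {
  cs <- scores[is_case]
  ks <- scores[!is_case]
  total <- 0
  for (a in cs) {
    for (b in ks) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(cs) * length(ks))
}

confusion_oracle <- function(prob, is_case) {
  pred <- prob >= 0.5
  tab <- table(
    factor(pred, levels = c(FALSE, TRUE)),
    factor(is_case, levels = c(FALSE, TRUE))
  )
  tp <- tab["TRUE", "TRUE"]; tn <- tab["FALSE", "FALSE"]
  fp <- tab["TRUE", "FALSE"]; fn <- tab["FALSE", "TRUE"]
  c((tp + tn) / length(prob), tp / (tp + fn), tn / (tn + fp))
}

test_that("split plan partitions subjects with the stated sizes", {
  groups <- rep(c("case", "control"), c(22, 30))
  plan <- make_split_plan(groups, n_reps = 50, test_frac = 0.2, seed = 3)
  for (r in plan$reps) {
    expect_length(r$test, 10) # round(0.2 * 52)
    expect_length(intersect(r$train, r$test), 0)
    expect_setequal(c(r$train, r$test), 1:52)
    expect_setequal(c(r$inner_train, r$inner_val), r$train)
    expect_length(intersect(r$inner_train, r$inner_val), 0)
    for (idx in r) expect_length(unique(groups[idx]), 2)
  }
})

test_that("stratified test sets track group proportions within one subject", {
  groups <- rep(c("case", "control"), c(22, 30))
  plan <- make_split_plan(groups, n_reps = 100, seed = 4)
  n_case_test <- vapply(
    plan$reps, function(r) sum(groups[r$test] == "case"), numeric(1)
  )
  expect_true(all(abs(n_case_test - 4) <= 1)) # 22/52 * 10 = 4.2
})

test_that("split plans are reproducible and reject impossible groups", {
  groups <- rep(c("case", "control"), c(22, 30))
  expect_identical(
    make_split_plan(groups, n_reps = 5, seed = 9),
    make_split_plan(groups, n_reps = 5, seed = 9)
  )
  tiny <- rep(c("case", "control"), c(2, 30))
  expect_error(make_split_plan(tiny, n_reps = 5, seed = 1), "at least 3")
})

test_that("AUC matches brute-force pair counting on random instances", {
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(4:20, 1)
      is_case <- c(TRUE, FALSE, runif(n - 2) < 0.5)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
      expect_equal(
        auc_mann_whitney(scores, is_case),
        auc_brute_force(scores, is_case)
      )
    }
  })
})

test_that("all-tied scores give AUC one half", {
  expect_equal(auc_mann_whitney(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
})

test_that("accuracy, TPR and TNR agree with the confusion-matrix oracle", {
  withr::with_seed(43, {
    for (i in 1:50) {
      n <- sample(6:30, 1)
      is_case <- c(TRUE, FALSE, runif(n - 2) < 0.4)
      prob <- round(runif(n), 2)
      got <- lipidrank:::confusion_metrics(prob, is_case)
      expect_equal(unname(got), unname(confusion_oracle(prob, is_case)))
    }
  })
})

test_that("tuning returns the singleton config and is deterministic", {
  tax <- toy_taxonomy(3, 3)
  co <- spiked_cohort(tax, spiked = "CL1", effect = 2, seed = 31)
  ft <- cohort_feature_tables(co, tax)$class
  d <- lipidrank:::ft_design(ft)
  g1 <- fast_grid()
  inner_train <- c(1:15, 23:40) # both classes in both inner sets
  inner_val <- c(16:22, 41:52)
  expect_identical(tune_rf(d$x, d$y, inner_train, inner_val, g1, seed = 1), g1)
  grid <- rf_grid(num_trees = c(100, 300), mtry = "sqrt", min_node = 5)
  pick1 <- tune_rf(d$x, d$y, inner_train, inner_val, grid, seed = 5)
  pick2 <- tune_rf(d$x, d$y, inner_train, inner_val, grid, seed = 5)
  expect_identical(pick1, pick2)
})

test_that("tuning prefers a real forest over a single-tree forest", {
  tax <- toy_taxonomy(4, 4)
  grid <- rf_grid(num_trees = c(1, 500), mtry = "sqrt", min_node = 5)
  wins <- 0
  for (s in 1:10) {
    co <- spiked_cohort(tax, spiked = c("CL1", "CL2"), effect = 1.2,
      noise_sd = 1, seed = 40 + s
    )
    ft <- cohort_feature_tables(co, tax)$class
    d <- lipidrank:::ft_design(ft)
    plan <- make_split_plan(ft$group, n_reps = 1, seed = 40 + s)
    sp <- plan$reps[[1]]
    pick <- tune_rf(d$x, d$y, sp$inner_train, sp$inner_val, grid, seed = s)
    wins <- wins + (pick$num_trees == 500)
  }
  expect_gt(wins, 5)
})

test_that("a degenerate validation set falls back to out-of-bag tuning", {
  tax <- toy_taxonomy(3, 3)
  co <- spiked_cohort(tax, spiked = "CL1", effect = 2, seed = 33)
  ft <- cohort_feature_tables(co, tax)$class
  d <- lipidrank:::ft_design(ft)
  grid <- rf_grid(num_trees = c(100, 300), mtry = "sqrt", min_node = 5)
  val <- which(d$y == "case")[1:3] # single-class validation set
  expect_warning(
    pick <- tune_rf(d$x, d$y, setdiff(1:52, val), val, grid, seed = 2),
    "out-of-bag"
  )
  expect_equal(nrow(pick), 1)
})

test_that("a strongly separable cohort is classified nearly perfectly", {
  tax <- toy_taxonomy(5, 4)
  co <- spiked_cohort(tax, spiked = c("CL1", "CL2"), effect = 3,
    noise_sd = 0.5, seed = 50
  )
  ft <- cohort_feature_tables(co, tax)$class
  plan <- make_split_plan(ft$group, n_reps = 20, seed = 51)
  rep <- mccv_evaluate(ft, plan, fast_grid())
  expect_gte(rep$summary$auc, 0.95)
  expect_true(all(rep$metrics[, c("accuracy", "tpr", "tnr", "auc")] >= 0))
  expect_true(all(rep$metrics[, c("accuracy", "tpr", "tnr", "auc")] <= 1))
  expect_equal(nrow(rep$metrics), 20)
})

test_that("mean AUC degrades as generator noise grows", {
  tax <- toy_taxonomy(4, 4)
  auc_at <- vapply(c(0.4, 3), function(noise) {
    co <- spiked_cohort(tax, spiked = "CL1", effect = 1, noise_sd = noise, seed = 55)
    ft <- cohort_feature_tables(co, tax)$class
    plan <- make_split_plan(ft$group, n_reps = 15, seed = 56)
    mccv_evaluate(ft, plan, fast_grid())$summary$auc
  }, numeric(1))
  expect_gt(auc_at[1], auc_at[2] + 0.05)
})

test_that("per-rep importances are normalized and a lone signal ranks first", {
  tax <- toy_taxonomy(6, 3)
  co <- spiked_cohort(tax, spiked = "CL4", effect = 2, noise_sd = 0.6, seed = 60)
  ft <- cohort_feature_tables(co, tax)$class
  plan <- make_split_plan(ft$group, n_reps = 25, seed = 61)
  rep <- mccv_evaluate(ft, plan, fast_grid())
  expect_equal(unname(rowSums(rep$importance)), rep(1, 25), tolerance = 1e-12)
  ranked <- rank_variables(ft, plan, fast_grid())
  expect_equal(nrow(ranked), 6 + 2) # classes + age + sex
  expect_identical(ranked$variable[1], "CL4")
  expect_identical(ranked$rank, 1:8)
})

test_that("evaluation is reproducible given the same plan", {
  tax <- toy_taxonomy(3, 3)
  co <- spiked_cohort(tax, spiked = "CL1", effect = 1, seed = 65)
  ft <- cohort_feature_tables(co, tax)$class
  plan <- make_split_plan(ft$group, n_reps = 5, seed = 66)
  r1 <- mccv_evaluate(ft, plan, fast_grid())
  r2 <- mccv_evaluate(ft, plan, fast_grid())
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$importance, r2$importance)
})

test_that("report tidiers expose per-rep metrics and the summary", {
  tax <- toy_taxonomy(3, 3)
  co <- spiked_cohort(tax, spiked = "CL1", effect = 1, seed = 67)
  ft <- cohort_feature_tables(co, tax)$class
  plan <- make_split_plan(ft$group, n_reps = 4, seed = 68)
  rep <- mccv_evaluate(ft, plan, fast_grid())
  expect_equal(nrow(tidy(rep)), 4)
  gl <- glance(rep)
  expect_equal(gl$auc, mean(tidy(rep)$auc))
  expect_s3_class(autoplot(rep), "ggplot")
})
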