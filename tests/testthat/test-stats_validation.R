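# exhaustive best-subset oracle: smallest deviance among all subsets of a size
best_subset_deviance <- function(df, y, candidates, size) {
  subsets <- utils::combn(candidates, size, simplify = FALSE)
  devs <- vapply(subsets, function(s) {
    lipidrank:::glm_deviance(df, y, s)
  }, numeric(1))
  list(best = subsets[[which.min(devs)]], deviance = min(devs))
}

test_that("welch test matches stats::t.test on random instances", {
  withr::with_seed(101, {
    for (i in 1:200) {
      a <- rnorm(sample(3:15, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
      b <- rnorm(sample(3:15, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
      got <- welch_test(a, b)
      ref <- t.test(a, b) # Welch by default
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$df, unname(ref$parameter))
      expect_equal(got$p.value, ref$p.value)
      expect_equal(c(got$conf.low, got$conf.high), as.numeric(ref$conf.int))
    }
  })
})

test_that("welch test reproduces the worked three-point example", {
  w <- welch_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(w$statistic, -1.549193, tolerance = 1e-6)
  expect_equal(w$df, 2.941176, tolerance = 1e-6)
  expect_equal(w$p.value, 0.22, tolerance = 0.01)
})

test_that("welch test handles identity, symmetry and degenerate inputs", {
  a <- c(1.2, 3.4, 2.2, 5.0)
  same <- welch_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_equal(same$conf.low, -same$conf.high)

  ab <- welch_test(a, a * 2)
  ba <- welch_test(a * 2, a)
  expect_equal(ab$p.value, ba$p.value)
  expect_equal(ab$conf.low, -ba$conf.high)
  expect_equal(ab$estimate, -ba$estimate)

  const <- welch_test(c(2, 2, 2), c(2, 2))
  expect_equal(const$statistic, 0)
  expect_equal(const$p.value, 1)
  expect_error(welch_test(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_test(1, c(1, 2)), "at least 2")

  gaps <- welch_test(c(1, NA, 2, 3), c(2, 4, NA, 6))
  expect_equal(gaps$statistic, welch_test(c(1, 2, 3), c(2, 4, 6))$statistic)
})

test_that("bonferroni thresholds follow alpha over m", {
  expect_equal(signif(bonferroni_threshold(0.05, 17), 2), 0.0029)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 34), 2), 0.0015)
})

test_that("log2 fold change is the log ratio of group means", {
  expect_equal(log2_fold_change(c(1, 3), c(1, 3)), 0)
  expect_equal(log2_fold_change(c(4, 4), c(1, 1)), 2)
  expect_error(log2_fold_change(c(0, 0), c(1, 1)), "positive")
})

test_that("fold change pairs with the welch test for two-group screens", {
  tax <- toy_taxonomy(3, 4)
  co <- spiked_cohort(tax, spiked = "CL1", effect = 1.5, noise_sd = 0.5, seed = 90)
  is_case <- co$metadata$group == "case"
  records <- lapply(names(co$abundance)[-1], function(f) {
    v <- co$abundance[[f]]
    w <- welch_test(log(v[is_case]), log(v[!is_case]))
    tibble::tibble(
      feature = f,
      lfc = log2_fold_change(v[is_case], v[!is_case]),
      significant = w$p.value < 0.05
    )
  })
  screen <- dplyr::bind_rows(records)
  spiked <- screen[grepl("^CL1", screen$feature), ]
  expect_true(all(spiked$significant))
  expect_true(all(spiked$lfc > 1)) # log2 of an e^1.5-fold shift ~ 2.2
})

test_that("univariate logistic p-values are uniform under the null", {
  ps <- withr::with_seed(102, {
    vapply(1:200, function(i) {
      x <- rnorm(500)
      y <- factor(rep(c("case", "control"), 250), levels = c("control", "case"))
      univariate_logistic(x, y)$p.value
    }, numeric(1))
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("univariate logistic flags perfect separation and finds real signal", {
  y <- factor(rep(c("control", "case"), each = 20), levels = c("control", "case"))
  sep <- univariate_logistic(as.numeric(y == "case"), y)
  expect_true(sep$separation)
  expect_true(is.na(sep$p.value))

  withr::with_seed(103, {
    x <- rnorm(100) + 1.5 * rep(0:1, each = 50)
    yy <- factor(rep(c("control", "case"), each = 50), levels = c("control", "case"))
    fit <- univariate_logistic(x, yy)
    expect_false(fit$separation)
    expect_gt(fit$estimate, 0)
    expect_lt(fit$p.value, 0.05)
  })
})

seq_fixture <- function(seed = 109, n = 150) {
  withr::with_seed(seed, {
    x1 <- rnorm(n)
    x2 <- 0.9 * x1 + sqrt(1 - 0.9^2) * rnorm(n) # near-duplicate of x1
    signal <- x1 - x2 # only jointly predictive
    y <- rbinom(n, 1, plogis(8 * signal))
    # noisy proxy of the signal: individually attractive, jointly redundant
    decoy <- signal + 0.5 * sd(signal) * rnorm(n)
    noise <- rnorm(n)
  })
  ft <- tibble::tibble(
    group = factor(ifelse(y == 1, "case", "control"), levels = c("control", "case")),
    decoy = decoy, xA = x1, xB = x2, z = noise
  )
  attr(ft, "covariates") <- character()
  ft
}

test_that("every sequential method finds a unique single signal", {
  withr::with_seed(105, {
    x <- rnorm(80)
    y <- rbinom(80, 1, plogis(2.5 * x))
    ft <- tibble::tibble(
      group = factor(ifelse(y == 1, "case", "control"), levels = c("control", "case")),
      A = x, B = rnorm(80), C = rnorm(80)
    )
  })
  attr(ft, "covariates") <- character()
  for (m in c("SFS", "SBS", "SFFS")) {
    res <- sequential_logistic_selection(ft, method = m)
    expect_identical(sort(res$selected), "A")
  }
})

test_that("floating selection backtracks to the exhaustive best subset", {
  ft <- seq_fixture()
  y <- as.numeric(ft$group == "case")
  df <- as.data.frame(ft[, c("decoy", "xA", "xB", "z")])
  res <- sequential_logistic_selection(ft,
    method = "SFFS",
    candidates = c("decoy", "xA", "xB", "z")
  )
  expect_true(any(res$log$action == "remove")) # the float actually fired
  oracle <- best_subset_deviance(df, y, names(df), length(res$selected))
  expect_setequal(res$selected, oracle$best)
})

test_that("selection step logs replay exactly", {
  ft <- seq_fixture(seed = 117)
  res <- sequential_logistic_selection(ft,
    method = "SFFS",
    candidates = c("decoy", "xA", "xB", "z")
  )
  y <- as.numeric(ft$group == "case")
  df <- as.data.frame(ft[, c("decoy", "xA", "xB", "z")])
  state <- character()
  for (i in seq_len(nrow(res$log))) {
    row <- res$log[i, ]
    if (row$action == "add") {
      rest <- setdiff(names(df), state)
      ps <- vapply(rest, function(f) lipidrank:::lrt_add_p(df, y, state, f), numeric(1))
      expect_identical(rest[which.min(ps)], row$feature)
      expect_equal(min(ps), row$p.value)
      state <- c(state, row$feature)
    } else {
      p_here <- lipidrank:::lrt_add_p(df, y, setdiff(state, row$feature), row$feature)
      expect_equal(p_here, row$p.value)
      state <- setdiff(state, row$feature)
    }
    expect_length(state, row$model_size)
  }
  expect_setequal(state, res$selected)
})

test_that("no qualifying candidate yields an empty selection with a log", {
  withr::with_seed(107, {
    ft <- tibble::tibble(
      group = factor(rep(c("control", "case"), 25), levels = c("control", "case")),
      A = rnorm(50), B = rnorm(50)
    )
  })
  attr(ft, "covariates") <- character()
  res <- sequential_logistic_selection(ft, method = "SFS", enter_p = 1e-6)
  expect_length(res$selected, 0)
  expect_equal(nrow(res$log), 0)
})

test_that("ridge directions track the sign of the group difference", {
  withr::with_seed(108, {
    n <- 60
    up <- rnorm(n) + 2 * rep(0:1, each = n / 2)
    down <- rnorm(n) - 2 * rep(0:1, each = n / 2)
    ft <- tibble::tibble(
      group = factor(rep(c("control", "case"), each = n / 2),
        levels = c("control", "case")
      ),
      up = up, down = down, up_copy = up
    )
  })
  attr(ft, "covariates") <- character()
  d1 <- ridge_direction(ft, features = "up")
  expect_identical(d1$direction, "Positive")
  d2 <- ridge_direction(ft, features = "down")
  expect_identical(d2$direction, "Negative")

  d3 <- ridge_direction(ft, features = c("up", "down", "up_copy"), penalty = 0.5)
  expect_identical(
    setNames(d3$direction, d3$feature)[c("up", "down")],
    c(up = "Positive", down = "Negative")
  )
  # ridge shares weight equally across duplicated predictors
  expect_equal(
    d3$coefficient[d3$feature == "up"],
    d3$coefficient[d3$feature == "up_copy"],
    tolerance = 1e-3
  )
})

test_that("direction labels flip when the group labels are swapped", {
  withr::with_seed(109, {
    n <- 60
    ft <- tibble::tibble(
      group = factor(rep(c("control", "case"), each = n / 2),
        levels = c("control", "case")
      ),
      f1 = rnorm(n) + 1.5 * rep(0:1, each = n / 2),
      f2 = rnorm(n) - 1.0 * rep(0:1, each = n / 2)
    )
  })
  attr(ft, "covariates") <- character()
  flipped <- ft
  flipped$group <- factor(
    ifelse(ft$group == "case", "control", "case"),
    levels = c("control", "case")
  )
  d <- ridge_direction(ft, penalty = 0.3)
  df <- ridge_direction(flipped, penalty = 0.3)
  swap <- c(Positive = "Negative", Negative = "Positive")
  expect_identical(unname(swap[d$direction]), df$direction)
})

test_that("validated tables carry the full report-record shape", {
  tax <- toy_taxonomy(4, 4)
  co <- spiked_cohort(tax, spiked = c("CL1", "CL2"), effect = 1.5,
    noise_sd = 0.6, seed = 110
  )
  fts <- cohort_feature_tables(co, tax)
  selected <- c("CL1.30.0", "CL1.32.1", "CL2.30.0", "CL3.30.0")
  class_dirs <- tibble::tibble(
    feature = c("CL1", "CL2", "CL3"),
    direction = c("Positive", "Positive", "Negative")
  )
  v <- validate_selection(fts$species, selected,
    taxonomy = tax,
    class_directions = class_dirs, seed = 3
  )
  expect_identical(v$feature, selected)
  expect_identical(v$rank, 1:4)
  expect_identical(v$class, c("CL1", "CL1", "CL2", "CL3"))
  expect_identical(v$class_direction, c("Positive", "Positive", "Positive", "Negative"))
  expect_true(all(v$conf.low < v$conf.high))
  expect_equal(
    attr(v, "bonferroni_threshold"),
    bonferroni_threshold(0.05, 4)
  )
  # spiked species have positive case-minus-control differences
  expect_true(all(v$estimate[1:3] > 0))
  expect_true(all(v$direction[1:3] == "Positive"))
})
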