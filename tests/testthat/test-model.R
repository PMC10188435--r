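# small separable design reused across model tests: one informative
# component plus noise, in feature-matrix form
make_separable <- function(n_per_class = 30, n_noise = 9, seed = 101) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c("HRD", "HRP"), each = n_per_class)
  fm <- tibble::tibble(sample_id = sprintf("S%03d", seq_len(n)))
  fm$informative <- ifelse(lab == "HRD", 10, 0) + stats::rpois(n, 2)
  for (j in seq_len(n_noise)) {
    fm[[paste0("noise", j)]] <- stats::rpois(n, 5)
  }
  list(features = fm,
       labels = tibble::tibble(sample_id = fm$sample_id, label = lab))
}

test_that("the stratified split is exact, disjoint and seed-stable", {
  d <- make_separable(50)
  sp1 <- split_train_heldout(d$features, d$labels, ratio = 0.8, seed = 9)
  sp2 <- split_train_heldout(d$features, d$labels, ratio = 0.8, seed = 9)
  expect_equal(nrow(sp1$train$features), 80)
  expect_equal(nrow(sp1$heldout$features), 20)
  expect_equal(table(sp1$train$labels$label),
               table(c(rep("HRD", 40), rep("HRP", 40))))
  expect_identical(sp1$train$features$sample_id, sp2$train$features$sample_id)
  expect_length(intersect(sp1$train$features$sample_id,
                          sp1$heldout$features$sample_id), 0)
  expect_setequal(c(sp1$train$features$sample_id,
                    sp1$heldout$features$sample_id),
                  d$features$sample_id)

  one <- d$labels
  one$label[-1] <- "HRP"
  expect_error(split_train_heldout(d$features, one), "at least 2")
})

test_that("tree-count tuning tracks the CV Bernoulli deviance", {
  d <- make_separable(30)
  hp <- hrd_hyperparams(max_trees = 150, cv_folds = 5, seed = 2)
  tune <- tune_tree_count(d$features, d$labels, hp)
  expect_true(tune$n_trees >= 1 && tune$n_trees <= 150)
  expect_equal(nrow(tune$curve), 150)
  sel <- tune$curve$cv_deviance[tune$curve$trees == tune$n_trees]
  expect_lt(sel, tune$curve$cv_deviance[1])   # better than a single tree

  # max_trees = 1 returns 1
  hp1 <- hrd_hyperparams(max_trees = 1, cv_folds = 5, seed = 2)
  expect_equal(tune_tree_count(d$features, d$labels, hp1)$n_trees, 1)

  all_hrd <- d$labels
  all_hrd$label <- "HRD"
  expect_error(tune_tree_count(d$features, all_hrd, hp), "both classes")
})

test_that("uninformative features floor at the class-prior deviance", {
  set.seed(7)
  n <- 60
  fm <- tibble::tibble(sample_id = sprintf("N%02d", 1:n))
  for (j in 1:5) fm[[paste0("noise", j)]] <- stats::rnorm(n)
  labels <- tibble::tibble(sample_id = fm$sample_id,
                           label = rep(c("HRD", "HRP"), n / 2))
  hp <- hrd_hyperparams(max_trees = 150, cv_folds = 5, seed = 7)
  tune <- tune_tree_count(fm, labels, hp)
  floor_dev <- min(tune$curve$cv_deviance)
  # balanced classes: Bernoulli deviance of the prior is 2 ln 2 = 1.386
  expect_lt(abs(floor_dev - 2 * log(2)), 0.2)
})

test_that("fits are seeded, reproducible and serialize bit-exactly", {
  d <- make_separable(30)
  hp <- hrd_hyperparams(max_trees = 100, seed = 31)
  f1 <- fit_gbm(d$features, d$labels, hp, 100)
  f2 <- fit_gbm(d$features, d$labels, hp, 100)
  p1 <- predict(f1, d$features)
  expect_identical(p1$score, predict(f2, d$features)$score)
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  # training AUC on a separable design is 1
  expect_equal(eval_roc(p1$score, d$labels$label)$auc, 1)

  path <- tempfile(fileext = ".json")
  write_hrd_model(f1, path)
  f3 <- read_hrd_model(path)
  expect_identical(predict(f3, d$features)$score, p1$score)
  expect_equal(f3$feature_names, f1$feature_names)
  expect_equal(f3$cutoff, f1$cutoff)

  # scoring data without the model's columns fails
  expect_error(predict(f1, d$features[, 1:3]), "missing component")
  bad <- d$features
  bad$informative[1] <- NA
  expect_error(fit_gbm(bad, d$labels, hp, 10), "non-finite")
})

test_that("relative influence finds the informative feature and sums to 100", {
  d <- make_separable(40)
  hp <- hrd_hyperparams(max_trees = 150, seed = 13)
  fit <- fit_gbm(d$features, d$labels, hp, 150)
  inf <- relative_influence(fit)
  expect_equal(sum(inf$influence), 100)
  expect_true(all(inf$influence >= 0))
  expect_equal(inf$label[which.max(inf$influence)], "informative")
})

test_that("Monte-Carlo influence is reproducible and degenerates correctly", {
  d <- make_separable(25)
  hp <- hrd_hyperparams(max_trees = 60, mc_repeats = 3, seed = 17)
  r1 <- monte_carlo_influence(d$features, d$labels, hp, 60)
  r2 <- monte_carlo_influence(d$features, d$labels, hp, 60)
  expect_identical(r1, r2)
  expect_equal(r1$label[r1$rank == 1], "informative")

  # mc_fraction = 1, one repeat: equals the single-fit influence
  hp1 <- hrd_hyperparams(max_trees = 60, mc_repeats = 1, mc_fraction = 1,
                         seed = 18)
  r3 <- monte_carlo_influence(d$features, d$labels, hp1, 60)
  hp1$seed <- hp1$seed + 1L   # the single repeat uses seed + 1
  single <- relative_influence(fit_gbm(d$features, d$labels, hp1, 60))
  expect_equal(r3$mean_influence, single$influence)
})

test_that("feature selection honours k and breaks ties canonically", {
  report <- tibble::tibble(label = c("A", "B", "C", "D"),
                           mean_influence = c(5, 10, 5, 0),
                           rank = c(2, 1, 3, 4))
  expect_equal(select_features(report, 2), c("B", "A"))
  expect_error(select_features(report, 9), "cannot select")

  # ranks from tied influences follow canonical (input) order
  d <- make_separable(10)
  hp <- hrd_hyperparams(max_trees = 5, mc_repeats = 1, seed = 3)
  rep <- monte_carlo_influence(d$features, d$labels, hp, 5)
  tied <- rep$label[rep$mean_influence == 0]
  canonical <- setdiff(names(d$features), "sample_id")
  expect_equal(tied, intersect(canonical, tied))
})

test_that("the HRD call is inclusive at the cutoff", {
  expect_equal(call_hr_status(c(0.25, 0.19, 0.20), cutoff = 0.2),
               c("HRD", "HRP", "HRD"))
})

test_that("the full procedure keeps top_k features and recovers the signal", {
  d <- make_separable(30, n_noise = 14)
  hp <- hrd_hyperparams(max_trees = 80, mc_repeats = 4, top_k = 5, seed = 23)
  fit <- hrd_train(d$features, d$labels, hp)
  expect_length(fit$feature_names, 5)
  expect_true("informative" %in% fit$feature_names)
  expect_s3_class(fit$influence, "tbl_df")
  expect_equal(nrow(fit$influence), 15)

  fit2 <- hrd_train(d$features, d$labels, hp)
  expect_identical(predict(fit, d$features)$score,
                   predict(fit2, d$features)$score)

  # broom-style accessors
  g <- glance(fit)
  expect_equal(g$n_features, 5)
  expect_equal(g$n_hrd, 30)
  td <- tidy(fit)
  expect_true(all(c("label", "final_influence") %in% names(td)))
})

test_that("scores are row-order invariant with duplicate rows equal", {
  d <- make_separable(20)
  hp <- hrd_hyperparams(max_trees = 50, seed = 5)
  fit <- fit_gbm(d$features, d$labels, hp, 50)
  rev_scores <- predict(fit, d$features[rev(seq_len(40)), ])
  fwd_scores <- predict(fit, d$features)
  expect_equal(dplyr::arrange(rev_scores, sample_id),
               dplyr::arrange(fwd_scores, sample_id))
  dup <- d$features[c(1, 1), ]
  expect_equal(predict(fit, dup)$score[1], predict(fit, dup)$score[2])
})
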