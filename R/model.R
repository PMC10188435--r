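#' Hyperparameters for the boosted HRD classifier
#'
#' Defaults follow the training procedure the classifier is built around:
#' a small learning rate (0.01) with a large tree budget (6000), bagging
#' fraction 0.8, stumps (interaction depth 1), tree count chosen by 10-fold
#' cross-validated Bernoulli deviance, and feature selection by mean
#' relative influence over 500 Monte-Carlo refits on 80% subsamples,
#' keeping the top 10 components.
#'
#' @param learning_rate Shrinkage applied to each tree (default 0.01).
#' @param max_trees Largest tree count considered (default 6000).
#' @param bag_fraction Row subsampling fraction per tree (default 0.8).
#' @param cv_folds Folds for tree-count selection (default 10).
#' @param interaction_depth Tree depth (default 1, stumps).
#' @param mc_repeats Monte-Carlo refits for influence estimation
#'   (default 500).
#' @param mc_fraction Subsample fraction per Monte-Carlo refit (default 0.8).
#' @param top_k Number of components kept after influence ranking
#'   (default 10).
#' @param cutoff Probability threshold for the HRD call (default 0.2; a
#'   sample is called HRD iff its score is `>= cutoff`).
#' @param seed Integer seed controlling every stochastic step (subsampling,
#'   folds, bagging).
#' @return A list of class `"hrd_hyperparams"`.
#' @export
hrd_hyperparams <- function(learning_rate = 0.01, max_trees = 6000,
                            bag_fraction = 0.8, cv_folds = 10,
                            interaction_depth = 1, mc_repeats = 500,
                            mc_fraction = 0.8, top_k = 10, cutoff = 0.2,
                            seed = 1L) {
  hp <- list(learning_rate = learning_rate, max_trees = as.integer(max_trees),
             bag_fraction = bag_fraction, cv_folds = as.integer(cv_folds),
             interaction_depth = as.integer(interaction_depth),
             mc_repeats = as.integer(mc_repeats), mc_fraction = mc_fraction,
             top_k = as.integer(top_k), cutoff = cutoff,
             seed = as.integer(seed))
  stopifnot(hp$learning_rate > 0, hp$max_trees >= 1,
            hp$bag_fraction > 0, hp$bag_fraction <= 1,
            hp$cv_folds >= 2, hp$interaction_depth >= 1,
            hp$mc_repeats >= 1, hp$mc_fraction > 0, hp$mc_fraction <= 1,
            hp$top_k >= 1, hp$cutoff >= 0, hp$cutoff <= 1)
  structure(hp, class = "hrd_hyperparams")
}

# ---- internal helpers -------------------------------------------------------

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

feature_cols <- function(features) setdiff(names(features), "sample_id")

as_feature_matrix <- function(features, feature_names = NULL) {
  feature_names <- feature_names %||% feature_cols(features)
  missing <- setdiff(feature_names, names(features))
  if (length(missing) > 0) {
    stop("feature matrix is missing component column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(features[, feature_names, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) {
    stop("non-finite feature values", call. = FALSE)
  }
  rownames(m) <- features$sample_id
  m
}

# labels: tibble (sample_id, label) or vector aligned with feature rows;
# returns 0/1 with 1 = HRD, aligned to `features`
align_labels <- function(features, labels) {
  if (is.data.frame(labels)) {
    lab_col <- intersect(c("label", "status", "class"), names(labels))[1]
    if (is.na(lab_col) || !"sample_id" %in% names(labels)) {
      stop("labels data frame needs columns sample_id and label",
           call. = FALSE)
    }
    lab <- labels[[lab_col]][match(features$sample_id, labels$sample_id)]
  } else {
    if (length(labels) != nrow(features)) {
      stop("labels length does not match number of samples", call. = FALSE)
    }
    lab <- labels
  }
  lab <- as.character(lab)
  if (any(is.na(lab))) stop("missing label for some samples", call. = FALSE)
  bad <- setdiff(unique(lab), c("HRD", "HRP"))
  if (length(bad) > 0) {
    stop("labels must be HRD or HRP; got: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  as.integer(lab == "HRD")
}

xgb_params <- function(hp, seed) {
  list(objective = "binary:logistic", eta = hp$learning_rate,
       max_depth = hp$interaction_depth, subsample = hp$bag_fraction,
       nthread = 1, seed = as.integer(seed))
}

# ---- operations -------------------------------------------------------------

#' Stratified train/held-out split
#'
#' @param features A feature-matrix tibble (`sample_id` + component columns).
#' @param labels HRD/HRP labels: a tibble with `sample_id` and `label`, or a
#'   vector aligned with the feature rows.
#' @param ratio Fraction of each class assigned to training (default 0.8).
#' @param seed Integer seed; the split is deterministic per seed.
#' @return A list with elements `train` and `heldout`, each a list of
#'   `features` and `labels` (tibbles).
#' @export
split_train_heldout <- function(features, labels, ratio = 0.8, seed = 1L) {
  y <- align_labels(features, labels)
  if (min(table(y)) < 2) {
    stop("need at least 2 samples per class to split", call. = FALSE)
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, round(ratio * length(idx)))
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  mk <- function(idx) list(
    features = features[idx, , drop = FALSE],
    labels = tibble::tibble(sample_id = features$sample_id[idx],
                            label = ifelse(y[idx] == 1, "HRD", "HRP"))
  )
  list(train = mk(train_idx), heldout = mk(setdiff(seq_along(y), train_idx)))
}

#' Select the tree count by cross-validated Bernoulli deviance
#'
#' Runs stratified k-fold cross-validation of the boosted classifier over
#' `1..max_trees` trees and returns the count minimizing the mean
#' out-of-fold Bernoulli deviance `-2 * mean(y log p + (1-y) log(1-p))`.
#' The fold count is capped at the minority-class size so every fold holds
#' both classes.
#'
#' @inheritParams split_train_heldout
#' @param hyperparams An [hrd_hyperparams()] list.
#' @return A list: `n_trees` (selected count) and `curve`, a tibble of
#'   `trees`, `train_deviance`, `cv_deviance` for inspection.
#' @export
tune_tree_count <- function(features, labels, hyperparams = hrd_hyperparams()) {
  y <- align_labels(features, labels)
  if (length(unique(y)) < 2) {
    stop("tree-count tuning needs both classes present", call. = FALSE)
  }
  x <- as_feature_matrix(features)
  # stratified fold assignment, deterministic per seed; every fold must
  # hold at least one sample of each class
  n_folds <- min(hyperparams$cv_folds, min(table(y)))
  folds <- with_seed(hyperparams$seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    f
  })
  test_ll <- train_ll <- matrix(
    NA_real_, nrow = hyperparams$max_trees, ncol = n_folds)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    dtrain <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr],
                                   nthread = 1)
    dtest <- xgboost::xgb.DMatrix(x[!tr, , drop = FALSE], label = y[!tr],
                                  nthread = 1)
    booster <- xgboost::xgb.train(
      params = xgb_params(hyperparams, hyperparams$seed + k),
      data = dtrain, nrounds = hyperparams$max_trees,
      evals = list(train = dtrain, test = dtest), verbose = 0
    )
    log <- as.data.frame(attr(booster, "evaluation_log"))
    train_ll[, k] <- log$train_logloss
    test_ll[, k] <- log$test_logloss
  }
  # Bernoulli deviance = 2 * mean negative binomial log-likelihood
  curve <- tibble::tibble(
    trees = seq_len(hyperparams$max_trees),
    train_deviance = 2 * rowMeans(train_ll),
    cv_deviance = 2 * rowMeans(test_ll)
  )
  list(n_trees = curve$trees[which.min(curve$cv_deviance)], curve = curve)
}

#' Fit the boosted classifier with a fixed tree count
#'
#' Bernoulli-loss gradient-boosted trees with the stated learning rate,
#' bagging fraction and depth. Fits are deterministic per seed and the
#' fitted ensemble serializes losslessly ([write_hrd_model()]).
#'
#' @inheritParams tune_tree_count
#' @param n_trees Number of boosting rounds (must not exceed `max_trees`).
#' @return An object of class `"hrd_model"`: the fitted ensemble plus the
#'   retained feature names, tree count, hyperparameters, cutoff and
#'   training metadata.
#' @export
fit_gbm <- function(features, labels, hyperparams = hrd_hyperparams(),
                    n_trees) {
  stopifnot(n_trees >= 1, n_trees <= hyperparams$max_trees)
  y <- align_labels(features, labels)
  x <- as_feature_matrix(features)
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = xgb_params(hyperparams, hyperparams$seed),
    data = dm, nrounds = n_trees, verbose = 0
  )
  structure(list(
    booster = booster,
    feature_names = colnames(x),
    n_trees = as.integer(n_trees),
    hyperparams = hyperparams,
    cutoff = hyperparams$cutoff,
    metadata = list(n_samples = nrow(x),
                    n_hrd = sum(y == 1), n_hrp = sum(y == 0),
                    seed = hyperparams$seed)
  ), class = "hrd_model")
}

#' Relative influence of each feature in a fitted ensemble
#'
#' Per-feature importance from the improvement in loss at each split,
#' averaged over all trees using the feature, normalized to sum to 100.
#' Features never used by the ensemble score 0.
#'
#' @param object An `"hrd_model"` fit.
#' @return A tibble `label`, `influence` covering every model feature, in
#'   the model's canonical feature order.
#' @export
relative_influence <- function(object) {
  stopifnot(inherits(object, "hrd_model"))
  imp <- xgboost::xgb.importance(model = object$booster)
  inf <- stats::setNames(numeric(length(object$feature_names)),
                         object$feature_names)
  if (!is.null(imp) && nrow(imp) > 0) {
    inf[imp$Feature] <- imp$Gain
  }
  if (sum(inf) > 0) inf <- 100 * inf / sum(inf)
  tibble::tibble(label = names(inf), influence = unname(inf))
}

#' Monte-Carlo relative-influence report
#'
#' Refits the classifier on `mc_repeats` stratified subsamples of
#' `mc_fraction` of the training set and averages each component's relative
#' influence across refits.
#'
#' @inheritParams tune_tree_count
#' @param n_trees Tree count used for every refit (typically the value
#'   selected by [tune_tree_count()]).
#' @return A tibble `label`, `mean_influence`, `rank` (1 = most influential;
#'   ties broken by canonical feature order).
#' @export
monte_carlo_influence <- function(features, labels,
                                  hyperparams = hrd_hyperparams(), n_trees) {
  y <- align_labels(features, labels)
  idx_by_class <- split(seq_along(y), y)
  scores <- matrix(0, nrow = hyperparams$mc_repeats,
                   ncol = length(feature_cols(features)),
                   dimnames = list(NULL, feature_cols(features)))
  for (r in seq_len(hyperparams$mc_repeats)) {
    rep_seed <- hyperparams$seed + r
    idx <- with_seed(rep_seed, {
      sort(unlist(lapply(idx_by_class, function(i) {
        sample(i, max(1, round(hyperparams$mc_fraction * length(i))))
      }), use.names = FALSE))
    })
    hp_r <- hyperparams
    hp_r$seed <- rep_seed
    fit <- fit_gbm(features[idx, , drop = FALSE],
                   ifelse(y[idx] == 1, "HRD", "HRP"), hp_r, n_trees)
    scores[r, ] <- relative_influence(fit)$influence
  }
  mean_inf <- colMeans(scores)
  ord <- order(-mean_inf)          # stable: ties keep canonical order
  rank <- integer(length(mean_inf))
  rank[ord] <- seq_along(ord)
  tibble::tibble(label = names(mean_inf), mean_influence = unname(mean_inf),
                 rank = rank)
}

#' Select the top-k components by mean influence
#'
#' @param report An influence report from [monte_carlo_influence()].
#' @param k Number of components to keep.
#' @return Character vector of `k` component labels, ordered by rank.
#' @export
select_features <- function(report, k = 10) {
  if (k > nrow(report)) {
    stop("cannot select ", k, " features from ", nrow(report), call. = FALSE)
  }
  report$label[order(report$rank)][seq_len(k)]
}

#' The full four-step training procedure
#'
#' 1. Optionally restrict to components that differ between classes
#'    (two-sided Wilcoxon rank-sum, Benjamini-Hochberg q < `filter_q`;
#'    off by default — the filtered subset is cohort-specific).
#' 2. Select the tree count on the full feature set by cross-validated
#'    Bernoulli deviance.
#' 3. Estimate each component's mean relative influence over Monte-Carlo
#'    refits and keep the top `top_k`.
#' 4. Re-select the tree count on the retained components and fit the final
#'    ensemble.
#'
#' @inheritParams tune_tree_count
#' @param filter_features If `TRUE`, apply the Wilcoxon pre-filter (step 1).
#' @param filter_q BH-adjusted significance threshold for the pre-filter.
#' @return An `"hrd_model"` with the influence report (`$influence`), the
#'   two tuning curves (`$tuning`), and the retained `feature_names`.
#' @examples
#' \donttest{
#' sim <- simulate_profiles(n_hrd = 20, n_hrp = 20, seed = 7)
#' fm <- extract_cna_features(sim$segments, sim$annotation)
#' hp <- hrd_hyperparams(max_trees = 200, mc_repeats = 5, seed = 7)
#' fit <- hrd_train(fm, sim$labels, hp)
#' predict(fit, fm)
#' }
#' @export
hrd_train <- function(features, labels, hyperparams = hrd_hyperparams(),
                      filter_features = FALSE, filter_q = 0.05) {
  y <- align_labels(features, labels)
  keep <- feature_cols(features)
  if (filter_features) {
    p <- vapply(keep, function(f) {
      v <- features[[f]]
      if (length(unique(v)) < 2) return(1)
      suppressWarnings(stats::wilcox.test(v[y == 1], v[y == 0])$p.value)
    }, numeric(1))
    keep_f <- keep[stats::p.adjust(p, "BH") < filter_q]
    if (length(keep_f) >= hyperparams$top_k) keep <- keep_f
  }
  feats <- features[, c("sample_id", keep), drop = FALSE]
  tune1 <- tune_tree_count(feats, labels, hyperparams)
  report <- monte_carlo_influence(feats, labels, hyperparams, tune1$n_trees)
  selected <- select_features(report, hyperparams$top_k)
  feats_top <- features[, c("sample_id", selected), drop = FALSE]
  tune2 <- tune_tree_count(feats_top, labels, hyperparams)
  fit <- fit_gbm(feats_top, labels, hyperparams, tune2$n_trees)
  fit$influence <- report
  fit$tuning <- list(full = tune1, selected = tune2)
  fit
}

#' Score samples with a fitted HRD model
#'
#' @param object An `"hrd_model"`.
#' @param newdata A feature-matrix tibble containing the model's feature
#'   columns (extra columns are ignored).
#' @param ... Unused.
#' @return A tibble `sample_id`, `score` (probability of HRD in `[0, 1]`),
#'   `call` (`"HRD"` iff `score >= cutoff`).
#' @export
predict.hrd_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata, object$feature_names)
  score <- predict(object$booster, xgboost::xgb.DMatrix(x, nthread = 1))
  tibble::tibble(sample_id = newdata$sample_id, score = as.numeric(score),
                 call = call_hr_status(score, object$cutoff))
}

#' Dichotomize HRD probabilities at a fixed cutoff
#'
#' @param scores Numeric probabilities in `[0, 1]`.
#' @param cutoff Call threshold (default 0.2); the boundary is inclusive,
#'   so a score exactly at the cutoff is called HRD.
#' @return Character vector of `"HRD"`/`"HRP"` calls.
#' @export
call_hr_status <- function(scores, cutoff = 0.2) {
  ifelse(scores >= cutoff, "HRD", "HRP")
}

#' @export
print.hrd_model <- function(x, ...) {
  cat("<hrd_model>\n")
  cat("  features:", length(x$feature_names), "components\n")
  cat("  trees:   ", x$n_trees, "\n")
  cat("  cutoff:  ", x$cutoff, "\n")
  cat("  training:", x$metadata$n_hrd, "HRD /", x$metadata$n_hrp, "HRP\n")
  invisible(x)
}

#' Broom-style accessors for a fitted HRD model
#'
#' `tidy()` returns one row per model feature with its mean Monte-Carlo
#' influence (when available) and final-fit relative influence; `glance()`
#' returns a one-row model summary.
#'
#' @param x An `"hrd_model"`.
#' @param ... Unused.
#' @export
tidy.hrd_model <- function(x, ...) {
  out <- relative_influence(x)
  names(out)[2] <- "final_influence"
  if (!is.null(x$influence)) {
    out <- dplyr::left_join(out, x$influence, by = "label")
  }
  dplyr::arrange(out, dplyr::desc(.data$final_influence))
}

#' @rdname tidy.hrd_model
#' @export
glance.hrd_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names), n_trees = x$n_trees,
    cutoff = x$cutoff, n_samples = x$metadata$n_samples,
    n_hrd = x$metadata$n_hrd, n_hrp = x$metadata$n_hrp,
    seed = x$metadata$seed
  )
}

# re-export generics so tidy()/glance() work without loading broom
#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Serialize / restore a fitted HRD model
#'
#' The bundle is a single JSON file: metadata (feature names, tree count,
#' hyperparameters, cutoff, training counts) plus the base64-encoded raw
#' ensemble. Restoring reproduces scores bit-identically.
#'
#' @param object An `"hrd_model"`.
#' @param path Output/input path (a `.json` file).
#' @return `write_hrd_model()` returns `path` invisibly; `read_hrd_model()`
#'   returns the restored `"hrd_model"`.
#' @export
write_hrd_model <- function(object, path) {
  stopifnot(inherits(object, "hrd_model"))
  payload <- list(
    format = "cnahrd/hrd_model/1",
    feature_names = object$feature_names,
    n_trees = object$n_trees,
    cutoff = object$cutoff,
    hyperparams = unclass(object$hyperparams),
    metadata = object$metadata,
    influence = object$influence,
    booster_raw = jsonlite::base64_enc(
      as.raw(xgboost::xgb.save.raw(object$booster, raw_format = "ubj")))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_hrd_model
#' @export
read_hrd_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "cnahrd/hrd_model/1")) {
    stop("not a serialized hrd_model: ", path, call. = FALSE)
  }
  hp <- do.call(hrd_hyperparams, payload$hyperparams)
  structure(list(
    booster = xgboost::xgb.load.raw(jsonlite::base64_dec(payload$booster_raw)),
    feature_names = payload$feature_names,
    n_trees = as.integer(payload$n_trees),
    hyperparams = hp,
    cutoff = payload$cutoff,
    metadata = payload$metadata,
    influence = if (!is.null(payload$influence))
      tibble::as_tibble(payload$influence)
  ), class = "hrd_model")
}
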