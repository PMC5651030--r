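#' Subject-grouped fold plan
#'
#' Assigns whole groups (subjects) to folds so that repeated measurements of
#' one subject never straddle the train/test split: distinct group IDs are
#' shuffled under `seed` and dealt round-robin into `n_folds` folds. With
#' singleton groups (one instance per group, as in simulated data) this
#' reduces to plain k-fold cross-validation.
#'
#' @param group_ids group identifier per instance.
#' @param n_folds number of folds; must not exceed the number of distinct
#'   groups.
#' @param seed integer seed for the shuffle.
#' @return object of class `fold_plan`: list with `n_folds`, `assignment`
#'   (named integer vector, group -> fold) and `seed`.
#' @export
make_fold_plan <- function(group_ids, n_folds, seed = 1L) {
  assert_that(is_count(n_folds, min = 2L), "n_folds must be an integer >= 2")
  groups <- unique(as.character(group_ids))
  assert_that(length(groups) >= n_folds,
              "fewer distinct groups (", length(groups),
              ") than folds (", n_folds, ")")
  shuffled <- with_seed(seed, sample(groups))
  assignment <- ((seq_along(shuffled) - 1L) %% n_folds) + 1L
  names(assignment) <- shuffled
  structure(list(n_folds = as.integer(n_folds), assignment = assignment,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> ", x$n_folds, " folds over ", length(x$assignment),
      " groups (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Fold index of every instance under a plan
#' @param plan a [make_fold_plan()] result.
#' @param group_ids group identifier per instance.
#' @return integer vector of fold indices.
#' @export
instance_folds <- function(plan, group_ids) {
  stopifnot(inherits(plan, "fold_plan"))
  f <- plan$assignment[as.character(group_ids)]
  assert_that(!anyNA(f), "group_ids contain groups missing from the plan")
  unname(f)
}

#' Cumulative binomial distribution function
#'
#' Probability of at most `k` successes in `n` independent trials with
#' success probability `p`; the chance-level machinery evaluates it at
#' p = 0.5.
#'
#' @param n number of trials.
#' @param k success count (0 <= k <= n).
#' @param p success probability.
#' @return cumulative probability.
#' @export
binomial_cdf <- function(n, k, p = 0.5) {
  assert_that(is_count(n, min = 0L), "n must be a non-negative integer")
  assert_that(is_count(k, min = 0L) && k <= n, "k must satisfy 0 <= k <= n")
  assert_that(is.numeric(p) && p >= 0 && p <= 1, "p must be in [0, 1]")
  pbinom(k, n, p)
}

#' Binomial chance-level accuracy baseline
#'
#' A coin-flip classifier on a balanced two-class task gets each label right
#' with probability p = 0.5; the chance baseline is the smallest accuracy
#' that such a classifier exceeds with probability below 1 - `threshold`.
#' Formally k is the smallest correct-count with cumulative binomial
#' probability >= `threshold`, and the baseline accuracy is k/n. For n = 150
#' this gives 56.67% (k = 85), for n = 146 it gives 56.85% (k = 83).
#'
#' @param n number of classified instances.
#' @param threshold cumulative-probability threshold (default 0.95).
#' @param p per-instance success probability of the null classifier.
#' @return object of class `binomial_baseline`: list with `n`, `k`, `p`,
#'   `threshold`, `baseline_accuracy` (= k/n) and `cdf_at_k`.
#' @export
chance_baseline <- function(n, threshold = 0.95, p = 0.5) {
  assert_that(is_count(n, min = 1L), "n must be a positive integer")
  assert_that(is.numeric(threshold) && threshold > 0 && threshold < 1,
              "threshold must be in (0, 1)")
  k <- 0L
  while (k <= n && pbinom(k, n, p) < threshold) k <- k + 1L
  structure(list(n = as.integer(n), k = as.integer(k), p = p,
                 threshold = threshold,
                 baseline_accuracy = k / n,
                 cdf_at_k = pbinom(k, n, p)),
            class = "binomial_baseline")
}

#' @export
print.binomial_baseline <- function(x, ...) {
  cat("<binomial_baseline> n = ", x$n, ": k = ", x$k, ", baseline accuracy ",
      sprintf("%.2f%%", 100 * x$baseline_accuracy),
      " (CDF at k = ", sprintf("%.3f", x$cdf_at_k), ")\n", sep = "")
  invisible(x)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic of the
#' positive-class scores; tied scores count 1/2.
#'
#' @param prob_positive score (e.g. softmax probability) of the positive
#'   class per instance.
#' @param truth binary ground truth; the larger label is the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(prob_positive, truth) {
  assert_that(length(prob_positive) == length(truth),
              "prob_positive and truth must have equal length")
  classes <- sort(unique(truth))
  assert_that(length(classes) == 2L,
              "truth must contain exactly two classes")
  pos <- truth == classes[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(prob_positive)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Exact paired comparison of two classifiers
#'
#' Two-sided exact binomial test at p = 0.5 restricted to the discordant
#' instances — those where exactly one of the two classifiers is correct
#' (the McNemar-style exact test). Returns 1 when the classifiers agree
#' everywhere.
#'
#' @param pred_a,pred_b predicted labels of the two classifiers.
#' @param truth true labels.
#' @return two-sided p-value in (0, 1].
#' @export
compare_classifiers <- function(pred_a, pred_b, truth) {
  assert_that(length(pred_a) == length(truth) &&
                length(pred_b) == length(truth),
              "prediction vectors must match the length of truth")
  a_ok <- pred_a == truth
  b_ok <- pred_b == truth
  b_only_a <- sum(a_ok & !b_ok)
  b_only_b <- sum(!a_ok & b_ok)
  n_disc <- b_only_a + b_only_b
  if (n_disc == 0) return(1.0)
  min(stats::binom.test(b_only_a, n_disc, p = 0.5)$p.value, 1.0)
}

#' Grouped cross-validated evaluation of a classifier
#'
#' For every fold of the plan, trains a fresh model (seeded per fold from
#' `model_config$seed`) on the complement and scores the held-out
#' instances; accuracy and AUC are pooled over the out-of-fold predictions
#' of all instances.
#'
#' @param config a [model_config()].
#' @param dataset a [connectome_dataset()].
#' @param fold_plan a [make_fold_plan()] over the dataset's groups.
#' @return object of class `cv_result`: list with `predictions` (data frame
#'   with instance, fold, truth, predicted label and positive-class
#'   probability), pooled `accuracy`, pooled `auc`, `per_fold_accuracy`,
#'   and `n_folds`.
#' @export
cross_validate <- function(config, dataset, fold_plan) {
  assert_that(inherits(config, "model_config"), "config must be a model_config")
  assert_that(inherits(dataset, "connectome_dataset"),
              "dataset must be a connectome_dataset")
  stopifnot(inherits(fold_plan, "fold_plan"))
  folds <- instance_folds(fold_plan, dataset$group_ids)
  n_inst <- length(folds)
  pred_label <- rep(NA_integer_, n_inst)
  prob_pos <- rep(NA_real_, n_inst)
  classes <- sort(unique(dataset$labels))
  for (f in sort(unique(folds))) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    if (length(unique(dataset$labels[train_idx])) < 2L) {
      stop_invalid("training complement of fold ", f, " has a single class")
    }
    cfg_f <- config
    cfg_f$seed <- derive_seed(config$seed, 100L + f)
    model <- build_model(cfg_f)
    model <- train_model(model, dataset, train_idx)
    p <- predict_proba(model, dataset, test_idx)
    pos_col <- match(as.character(classes[length(classes)]), colnames(p))
    prob_pos[test_idx] <- p[, pos_col]
    pred_label[test_idx] <- model$classes[max.col(p, ties.method = "first")]
  }
  predictions <- data.frame(instance = seq_len(n_inst), fold = folds,
                            truth = dataset$labels, pred = pred_label,
                            prob_positive = prob_pos)
  acc <- mean(pred_label == dataset$labels)
  structure(list(predictions = predictions,
                 accuracy = acc,
                 auc = auc_score(prob_pos, dataset$labels),
                 per_fold_accuracy = vapply(
                   sort(unique(folds)),
                   function(f) mean((pred_label == dataset$labels)[folds == f]),
                   numeric(1)),
                 n_folds = fold_plan$n_folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$n_folds, "-fold CV over ", nrow(x$predictions),
      " instances: accuracy ", sprintf("%.1f%%", 100 * x$accuracy),
      ", AUC ", sprintf("%.3f", x$auc), "\n", sep = "")
  invisible(x)
}
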