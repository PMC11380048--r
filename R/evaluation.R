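#' ROC AUC (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen resistant sample scores above a
#' randomly chosen sensitive one, ties counted one half; computed from rank
#' sums, so it is invariant under strictly increasing score transforms.
#'
#' @param scores Numeric prediction scores, higher = more resistant.
#' @param labels Binary labels (TRUE/1 = resistant); both classes required.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(as.numeric(labels))
  if (!any(y) || all(y)) stop_data("roc_auc needs both classes")
  r <- rank(scores)
  n_pos <- sum(y); n_neg <- sum(!y)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Sensitivity and specificity at a threshold
#'
#' Predicts resistant iff score >= threshold; sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), with resistant the positive class.
#'
#' @inheritParams roc_auc
#' @param threshold Decision cutoff.
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @export
sens_spec_at <- function(scores, labels, threshold) {
  y <- as.logical(as.numeric(labels))
  if (!any(y) || all(y)) stop_data("sens_spec_at needs both classes")
  pred <- scores >= threshold
  c(sensitivity = sum(pred & y) / sum(y),
    specificity = sum(!pred & !y) / sum(!y))
}

#' Sensitivity-prioritized decision threshold
#'
#' Among candidate thresholds (the observed scores plus -Inf), returns the
#' one maximizing specificity subject to sensitivity >= `sens_floor`; ties
#' resolve to the higher threshold. With the >=-rule and floor <= 1 the
#' constraint is always attainable (-Inf captures every positive).
#'
#' @inheritParams roc_auc
#' @param sens_floor Required minimum sensitivity, in (0, 1\].
#' @return The selected threshold.
#' @export
threshold_max_spec_at_sens <- function(scores, labels, sens_floor = 1.0) {
  y <- as.logical(as.numeric(labels))
  if (!any(y) || all(y)) stop_data("threshold selection needs both classes")
  if (sens_floor <= 0 || sens_floor > 1)
    stop_config("sens_floor must be in (0, 1]", field = "sens_floor")
  cand <- c(-Inf, sort(unique(scores)))
  sens <- vapply(cand, function(th) mean(scores[y] >= th), 0)
  spec <- vapply(cand, function(th) mean(scores[!y] < th), 0)
  ok <- sens >= sens_floor
  if (!any(ok)) stop_data("sensitivity floor unattainable")  # defensive
  best_spec <- max(spec[ok])
  max(cand[ok & spec == best_spec])  # ties -> higher threshold
}

#' Evaluate ensemble predictions on one cohort
#'
#' @param ens A `resist_ensemble`.
#' @param test An [expression_matrix()].
#' @param threshold Decision cutoff; default the ensemble's stored one.
#' @return A one-row data.frame: cohort, auc, sensitivity, specificity,
#'   threshold, n_resistant, n_sensitive.
#' @export
evaluate_cohort <- function(ens, test, threshold = ens$threshold) {
  scores <- predict_proba(ens, test)
  y <- is_resistant(test)
  ss <- sens_spec_at(scores, y, threshold)
  data.frame(cohort = test$cohort[1],
             auc = roc_auc(scores, y),
             sensitivity = ss[["sensitivity"]],
             specificity = ss[["specificity"]],
             threshold = threshold,
             n_resistant = sum(y), n_sensitive = sum(!y),
             row.names = NULL)
}

#' Random-gene-panel null distribution for the ensemble AUC
#'
#' Draws `n_draws` panels of `panel_size` genes uniformly (without
#' replacement, unrestricted) from the filtered gene pool, retrains the
#' ensemble on each and records its ROC AUC on the selection cohort's test
#' split. The empirical p-value for the observed AUC uses the add-one
#' permutation estimator (1 + #\{null >= observed\}) / (1 + n_draws).
#'
#' @param split A `split_dataset` (see [stratified_split()]).
#' @param panel_size Number of genes per random panel.
#' @param n_draws Number of null draws.
#' @param grid Reduced hyperparameter grid for the null ensembles.
#' @param k Folds per ensemble.
#' @param seed Integer seed governing draws and training.
#' @param observed_auc AUC of the discovered-panel ensemble on the same
#'   evaluation split.
#' @param train_cohort,selection_cohort Cohort names for the primary
#'   (fitting) and selection/evaluation roles; default first and last.
#' @return An object of class `null_comparison` with `observed_auc`,
#'   `null_aucs`, `empirical_p`, `panel_size`, `n_draws`, `seed`.
#' @export
random_panel_null <- function(split, panel_size, n_draws, grid = small_grid(),
                              k = 5, seed, observed_auc = NA_real_,
                              train_cohort = names(split$train)[1],
                              selection_cohort = rev(names(split$train))[1]) {
  stopifnot(inherits(split, "split_dataset"))
  pool <- gene_ids(split$train[[1]])
  if (panel_size > length(pool))
    stop_data("panel_size exceeds the filtered gene pool")
  if (n_draws < 1) stop_config("n_draws must be >= 1", field = "n_draws")
  draws <- with_seed(derive_seed(seed, 13), {
    lapply(seq_len(n_draws), function(i) sample(pool, panel_size))
  })
  eval_em <- split$test[[selection_cohort]]
  null_aucs <- rep(NA_real_, n_draws)
  for (i in seq_len(n_draws)) {
    auc_i <- tryCatch({
      ens <- train_ensemble(split$train[[train_cohort]],
                            split$train[[selection_cohort]],
                            new_gene_panel(draws[[i]]),
                            grid = grid, k = k, seed = derive_seed(seed, 17, i))
      roc_auc(predict_proba(ens, eval_em), is_resistant(eval_em))
    }, resistseq_error = function(e) {
      warning(sprintf("null draw %d failed: %s", i, conditionMessage(e)))
      NA_real_
    })
    null_aucs[i] <- auc_i
  }
  done <- !is.na(null_aucs)
  if (sum(done) < n_draws / 2)
    stop_data("fewer than half of the null draws completed")
  empirical_p <- if (is.na(observed_auc)) NA_real_ else
    (1 + sum(null_aucs[done] >= observed_auc)) / (1 + sum(done))
  structure(list(observed_auc = observed_auc, null_aucs = null_aucs[done],
                 empirical_p = empirical_p, panel_size = as.integer(panel_size),
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("<null_comparison> %d random panels of %d genes\n",
              length(x$null_aucs), x$panel_size))
  cat(sprintf("  null AUC: mean %.3f, 90th pct %.3f; observed %.3f; empirical p %.4f\n",
              mean(x$null_aucs), stats::quantile(x$null_aucs, 0.9),
              x$observed_auc, x$empirical_p))
  invisible(x)
}
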