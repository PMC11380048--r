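#' Class-stratified k-fold partition
#'
#' Shuffles each response class with the given seed and deals samples
#' round-robin into `k` folds, so class balance is preserved as closely as
#' integer arithmetic allows. Fold i's holdout is fold i; its fit set is
#' every other fold.
#'
#' @param train An [expression_matrix()] (or a logical vector of
#'   resistant indicators).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(fit = indices, holdout = indices)`.
#' @export
make_folds <- function(train, k = 5, seed) {
  pos <- if (inherits(train, "expr_matrix")) is_resistant(train) else as.logical(train)
  n <- length(pos)
  for (cls in c(TRUE, FALSE)) {
    if (sum(pos == cls) < k)
      stop_data(sprintf("class '%s' has fewer than k = %d samples",
                        if (cls) "resistant" else "sensitive", k))
  }
  assignment <- integer(n)
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(pos == cls))
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(i) {
    list(fit = which(assignment != i), holdout = which(assignment == i))
  })
}

#' Default hyperparameter grid (2160 combinations)
#'
#' Cartesian product of learning rate {0.01, 0.003, 0.001, 0.0003} x hidden
#' layers {1, 2, 3} x hidden units {8, 16, 32, 64, 128} x dropout
#' {0, 0.25, 0.5} x batch size {8, 16, 32} x epochs {25, 50, 100, 200}:
#' 4 * 3 * 5 * 3 * 3 * 4 = 2160 entries. Any axis can be overridden.
#'
#' @param learning_rate,n_hidden_layers,hidden_units,dropout,batch_size,epochs
#'   Numeric vectors, the grid axes.
#' @return A data.frame with one row per combination, in axis order
#'   (learning_rate varying fastest); row order defines the grid index used
#'   for tie-breaking.
#' @export
default_grid <- function(learning_rate = c(0.01, 0.003, 0.001, 0.0003),
                         n_hidden_layers = c(1, 2, 3),
                         hidden_units = c(8, 16, 32, 64, 128),
                         dropout = c(0, 0.25, 0.5),
                         batch_size = c(8, 16, 32),
                         epochs = c(25, 50, 100, 200)) {
  expand.grid(learning_rate = learning_rate,
              n_hidden_layers = n_hidden_layers,
              hidden_units = hidden_units,
              dropout = dropout,
              batch_size = batch_size,
              epochs = epochs,
              KEEP.OUT.ATTRS = FALSE)
}

#' Reduced 12-entry grid for desk-scale runs
#'
#' A small sub-grid (2 learning rates x {1, 2} hidden layers x
#' {16, 32, 64} units, dropout 0.25, batch 16, 50 epochs) for tests, demos
#' and the random-panel null, where the full 2160-entry search is
#' cluster-scale.
#'
#' @return A 12-row hyperparameter data.frame.
#' @export
small_grid <- function() {
  default_grid(learning_rate = c(0.003, 0.001),
               n_hidden_layers = c(1, 2),
               hidden_units = c(16, 32, 64),
               dropout = 0.25, batch_size = 16, epochs = 50)
}

grid_to_list <- function(grid) {
  if (inherits(grid, "hyperparams")) return(list(grid))
  if (is.data.frame(grid)) {
    return(lapply(seq_len(nrow(grid)), function(i) do.call(hyperparams, as.list(grid[i, ]))))
  }
  lapply(grid, function(g) if (inherits(g, "hyperparams")) g else do.call(hyperparams, g))
}

#' Train one ensemble member network
#'
#' Trains the fully connected classifier on an already standardized design
#' matrix with Adam and binary cross-entropy. Deterministic given `seed`
#' (weight initialization, batch shuffling and dropout masks all draw from
#' the seeded stream).
#'
#' @param X Numeric matrix, samples x features, standardized.
#' @param y Binary labels (logical or 0/1), length `nrow(X)`.
#' @param hp A [hyperparams()] object (or list coercible to one).
#' @param seed Integer seed.
#' @return An object of class `mlp_member` carrying the fitted weights,
#'   hyperparameters, final epoch loss and seed.
#' @export
train_member <- function(X, y, hp, seed) {
  if (!inherits(hp, "hyperparams")) hp <- do.call(hyperparams, as.list(hp))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_data("y must be binary (0/1 or logical)")
  if (length(unique(y)) < 2) stop_data("training labels contain a single class")
  if (nrow(X) < hp$batch_size)
    stop_data("fewer training samples than batch_size")
  fit <- with_seed(seed, mlp_train(X, y, hp))
  structure(list(params = fit$params, hyperparams = hp,
                 final_loss = fit$final_loss, seed = as.integer(seed)),
            class = "mlp_member")
}

# Standardize a samples x features matrix with a member's training-fold
# statistics.
standardize_with <- function(member, L_t) {
  sweep(sweep(L_t[, member$feature_order, drop = FALSE], 2, member$center, "-"),
        2, member$scale, "/")
}

# Member-level prediction from a genes x samples TPM matrix.
member_predict <- function(member, tpm) {
  missing <- setdiff(member$feature_order, rownames(tpm))
  if (length(missing) > 0)
    stop_data(paste0("panel gene missing from input: ", missing[1]))
  L_t <- t(log2_tpm(tpm[member$feature_order, , drop = FALSE]))
  mlp_predict_prob(member$params, standardize_with(member, L_t))
}

member_hidden <- function(member, tpm) {
  L_t <- t(log2_tpm(tpm[member$feature_order, , drop = FALSE]))
  mlp_last_hidden(member$params, standardize_with(member, L_t))
}

#' Select the best candidate model on held-aside selection data
#'
#' Scores every candidate on a second cohort's training data (each
#' candidate standardizes the input with its own training-fold statistics)
#' and returns the one maximizing ROC AUC; ties (within 1e-9) are broken by
#' lower selection-set cross-entropy, then by lower grid index.
#'
#' @param candidates Non-empty list of trained members (each carrying
#'   `feature_order`, `center`, `scale`, `grid_index`).
#' @param X_sel Genes x samples TPM matrix of the selection cohort.
#' @param y_sel Binary labels (TRUE/1 = resistant) for the selection samples.
#' @return The winning member, with `selection_score` (AUC) attached.
#' @export
select_member <- function(candidates, X_sel, y_sel) {
  candidates <- Filter(Negate(is.null), candidates)
  if (length(candidates) == 0) stop_data("no candidate models to select from")
  y_sel <- as.numeric(y_sel)
  if (length(unique(y_sel)) < 2)
    stop_data("selection labels contain a single class")
  score <- vapply(candidates, function(cand) {
    p <- member_predict(cand, X_sel)
    c(auc = roc_auc(p, y_sel), ce = mlp_bce(p, y_sel))
  }, c(auc = 0, ce = 0))
  auc <- score["auc", ]; ce <- score["ce", ]
  gi <- vapply(candidates, function(cand) cand$grid_index %||% 0L, 0L)
  best <- order(-round(auc / 1e-9) * 1e-9, ce, gi)[1]
  winner <- candidates[[best]]
  winner$selection_score <- unname(auc[best])
  winner
}

#' Train the fold-wise deep ensemble with cross-cohort model selection
#'
#' Splits the primary cohort's training samples into `k` class-stratified
#' folds. For each fold, trains one network per grid entry on the fold's
#' fit split (inputs are per-gene z-scores of log2(TPM + 1) computed on
#' that fit split) and keeps the entry performing best on the selection
#' cohort's training samples. The ensemble predicts by averaging the k
#' winners' output probabilities; its decision threshold starts at 0.5.
#'
#' @param train_primary [expression_matrix()] used for fitting (the
#'   study's TCGA role).
#' @param train_selection [expression_matrix()] used only to pick each
#'   fold's winner (the study's SNUH role).
#' @param panel A `gene_panel`; `panel$combined` must be present in both
#'   cohorts.
#' @param grid Hyperparameter data.frame (see [default_grid()]) or list of
#'   [hyperparams()].
#' @param k Number of folds.
#' @param seed Integer master seed; folds and every member's training seed
#'   derive from it.
#' @param grid_subsample Optional integer: train on a seeded random subset
#'   of this many grid entries per fold (the desk-scale path through a
#'   large grid).
#' @return An object of class `resist_ensemble`.
#' @export
train_ensemble <- function(train_primary, train_selection, panel,
                           grid = small_grid(), k = 5, seed,
                           grid_subsample = NULL) {
  stopifnot(inherits(train_primary, "expr_matrix"),
            inherits(train_selection, "expr_matrix"))
  features <- panel$combined
  if (length(features) == 0) stop_data("gene panel is empty")
  for (em in list(train_primary, train_selection)) {
    missing <- setdiff(features, gene_ids(em))
    if (length(missing) > 0)
      stop_data(paste0("panel gene missing from cohort: ", missing[1]))
  }
  hps <- grid_to_list(grid)
  grid_idx <- seq_along(hps)
  if (!is.null(grid_subsample) && grid_subsample < length(hps)) {
    pick <- with_seed(derive_seed(seed, 7), sort(sample(length(hps), grid_subsample)))
    hps <- hps[pick]; grid_idx <- grid_idx[pick]
  }
  L <- log2_tpm(train_primary$tpm[features, , drop = FALSE])
  sds <- apply(L, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance panel gene(s)", sum(sds == 0)))
    features <- features[sds > 0]
    if (length(features) == 0) stop_data("all panel genes have zero variance")
    L <- L[features, , drop = FALSE]
  }
  y <- as.numeric(is_resistant(train_primary))
  folds <- make_folds(train_primary, k = k, seed = derive_seed(seed, 1))
  X_sel <- train_selection$tpm
  y_sel <- as.numeric(is_resistant(train_selection))
  members <- vector("list", k)
  for (i in seq_len(k)) {
    fit_idx <- folds[[i]]$fit
    L_fit <- t(L[, fit_idx, drop = FALSE])
    center <- colMeans(L_fit)
    scl <- apply(L_fit, 2, stats::sd)
    if (any(scl == 0)) {
      warning(sprintf("fold %d: %d gene(s) constant within the fit split; left uncentered-scaled", i, sum(scl == 0)))
      scl[scl == 0] <- 1
    }
    Xfit <- sweep(sweep(L_fit, 2, center, "-"), 2, scl, "/")
    candidates <- vector("list", length(hps))
    for (j in seq_along(hps)) {
      mem <- tryCatch(
        train_member(Xfit, y[fit_idx], hps[[j]],
                     seed = derive_seed(seed, i, grid_idx[j])),
        resistseq_training_error = function(e) NULL)
      if (!is.null(mem)) {
        mem$feature_order <- features
        mem$center <- center
        mem$scale <- scl
        mem$fold_index <- i
        mem$grid_index <- grid_idx[j]
        candidates[[j]] <- mem
      }
    }
    if (all(vapply(candidates, is.null, TRUE)))
      stop_training(sprintf("fold %d: no grid entry trained successfully", i))
    members[[i]] <- select_member(candidates, X_sel, y_sel)
  }
  structure(list(members = members, panel = panel, threshold = 0.5,
                 feature_order = features, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "resist_ensemble")
}

#' @export
print.resist_ensemble <- function(x, ...) {
  cat(sprintf("<resist_ensemble> %d members, %d panel genes, threshold %.3f\n",
              length(x$members), length(x$feature_order), x$threshold))
  for (m in x$members) {
    cat(sprintf("  fold %d: %s (selection AUC %.3f)\n",
                m$fold_index, format_hp(m$hyperparams), m$selection_score))
  }
  invisible(x)
}

#' Ensemble resistance score
#'
#' The arithmetic mean of the member networks' sigmoid outputs, each member
#' standardizing the input with its own training-fold statistics. Higher
#' scores mean more chemo-resistant.
#'
#' @param ens A `resist_ensemble`.
#' @param X An [expression_matrix()] or genes x samples TPM matrix
#'   containing every panel gene.
#' @return Numeric vector of per-sample scores in \[0, 1\].
#' @export
predict_proba <- function(ens, X) {
  tpm <- if (inherits(X, "expr_matrix")) X$tpm else X
  preds <- vapply(ens$members, member_predict, numeric(ncol(tpm)), tpm = tpm)
  if (ncol(tpm) == 1) preds <- matrix(preds, nrow = 1)
  out <- rowMeans(preds)
  names(out) <- colnames(tpm)
  out
}

#' Concatenated last-hidden-layer embedding
#'
#' The representation the ensemble holds just before its output units:
#' each member's final hidden-layer activations, concatenated columnwise
#' (D = sum of members' hidden widths). Useful for visualizing what the
#' model has learned across cohorts.
#'
#' @inheritParams predict_proba
#' @return Numeric matrix, samples x D; rows follow the sample order of `X`.
#' @export
last_layer_embedding <- function(ens, X) {
  tpm <- if (inherits(X, "expr_matrix")) X$tpm else X
  missing <- setdiff(ens$feature_order, rownames(tpm))
  if (length(missing) > 0)
    stop_data(paste0("panel gene missing from input: ", missing[1]))
  emb <- do.call(cbind, lapply(ens$members, member_hidden, tpm = tpm))
  rownames(emb) <- colnames(tpm)
  emb
}
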