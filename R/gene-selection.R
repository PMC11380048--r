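#' Tier-1 selection: cross-cohort t-test intersection
#'
#' For each cohort, runs a two-sided pooled-variance Student's t-test per
#' gene on log2(TPM + 1) values (resistant vs sensitive, training samples)
#' and keeps genes with p < `alpha`; the result is the intersection of the
#' per-cohort significant sets, lexicographically sorted. Captures the most
#' concordant resistance signal across cohorts.
#'
#' @param train A [multi_cohort()] of training samples; every cohort must
#'   contain both classes.
#' @param alpha Per-gene significance level.
#' @param log_transform Run tests on log2(TPM + 1) (default) or raw TPM.
#' @return Character vector of gene IDs (possibly empty).
#' @export
tier1_select <- function(train, alpha = 0.05, log_transform = TRUE) {
  stopifnot(inherits(train, "multi_cohort"))
  sets <- lapply(names(train), function(nm) {
    m <- train[[nm]]
    pos <- is_resistant(m)
    if (!any(pos) || all(pos))
      stop_data(sprintf("cohort '%s' lacks one response class", nm))
    v <- if (log_transform) log2_tpm(m$tpm) else m$tpm
    p <- row_t_pvalues(v[, pos, drop = FALSE], v[, !pos, drop = FALSE])
    n_skip <- sum(is.na(p))
    if (n_skip > 0)
      warning(sprintf("cohort '%s': %d gene(s) with zero pooled variance skipped",
                      nm, n_skip))
    gene_ids(m)[!is.na(p) & p < alpha]
  })
  out <- sort(Reduce(intersect, sets))
  if (length(out) == 0)
    message("tier1_select: empty cross-cohort intersection")
  out
}

#' Tier-2 selection: balanced bagging with a Mann-Whitney frequency filter
#'
#' Runs `n_trials` bagging rounds on one cohort's training samples. Each
#' round draws `m = min(n_resistant, n_sensitive)` samples per class (with
#' replacement by default, so classes are balanced regardless of the
#' cohort's imbalance) and tests every gene with a two-sided Mann-Whitney U
#' test on log2(TPM + 1). A gene is selected when significant
#' (p < `alpha`) in strictly more than `min_trials` rounds.
#'
#' @param cohort_train An [expression_matrix()] with both classes present.
#' @param n_trials Number of bagging rounds.
#' @param alpha Per-round significance level.
#' @param min_trials Selection requires a significance count strictly
#'   greater than this.
#' @param seed Integer seed; counts are reproducible given it.
#' @param replace Resample with replacement (bootstrap, default) or without.
#' @param log_transform Test on log2(TPM + 1) (default) or raw TPM.
#' @return List with `genes` (sorted character vector) and `record`, a
#'   `bagging_record` carrying the per-gene significance `counts`,
#'   `n_trials`, `alpha` and `seed`.
#' @export
tier2_select <- function(cohort_train, n_trials = 100, alpha = 0.05,
                         min_trials = 80, seed, replace = TRUE,
                         log_transform = TRUE) {
  stopifnot(inherits(cohort_train, "expr_matrix"))
  if (!is_count(n_trials) || n_trials < 1)
    stop_config("n_trials must be a positive count", field = "n_trials")
  if (!is_count(min_trials) || min_trials > n_trials)
    stop_config("min_trials must be a count in [0, n_trials]", field = "min_trials")
  pos <- which(is_resistant(cohort_train))
  neg <- which(!is_resistant(cohort_train))
  if (length(pos) == 0 || length(neg) == 0)
    stop_data("tier2_select needs both response classes")
  m <- min(length(pos), length(neg))
  v <- if (log_transform) log2_tpm(cohort_train$tpm) else cohort_train$tpm
  counts <- integer(nrow(v))
  names(counts) <- gene_ids(cohort_train)
  with_seed(seed, {
    for (i in seq_len(n_trials)) {
      px <- sample(pos, m, replace = replace)
      nx <- sample(neg, m, replace = replace)
      p <- row_mw_pvalues(v[, px, drop = FALSE], v[, nx, drop = FALSE])
      counts <- counts + (!is.na(p) & p < alpha)
    }
  })
  record <- structure(list(counts = counts, n_trials = as.integer(n_trials),
                           alpha = alpha, seed = as.integer(seed)),
                      class = "bagging_record")
  list(genes = sort(names(counts)[counts > min_trials]), record = record)
}

#' @export
print.bagging_record <- function(x, ...) {
  cat(sprintf("<bagging_record> %d genes, %d trials, alpha = %g, seed = %d\n",
              length(x$counts), x$n_trials, x$alpha, x$seed))
  cat(sprintf("  max count: %d; genes at count > 80: %d\n",
              max(x$counts), sum(x$counts > 80)))
  invisible(x)
}

#' Combine tier-1 and tier-2 lists into the predictive gene panel
#'
#' `combined` is the deduplicated union in stable order: tier-1 genes
#' first, then each cohort's tier-2 genes in cohort order, lexicographic
#' within each group.
#'
#' @param tier1 Character vector of cross-cohort genes.
#' @param tier2 Named list of per-cohort gene vectors.
#' @return An object of class `gene_panel` with `tier1`, `tier2`, `combined`.
#' @export
combine_panel <- function(tier1, tier2 = list()) {
  tier1 <- sort(unique(as.character(tier1)))
  tier2 <- lapply(tier2, function(g) sort(unique(as.character(g))))
  combined <- tier1
  for (g in tier2) combined <- c(combined, setdiff(g, combined))
  structure(list(tier1 = tier1, tier2 = tier2, combined = combined),
            class = "gene_panel")
}

# Internal: a panel made of an arbitrary gene list (used for random-panel
# null draws).
new_gene_panel <- function(genes) {
  structure(list(tier1 = character(0), tier2 = list(),
                 combined = as.character(genes)), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d genes (tier1: %d; tier2: %s)\n",
              length(x$combined), length(x$tier1),
              if (length(x$tier2) == 0) "none" else
                paste(sprintf("%s %d", names(x$tier2),
                              lengths(x$tier2)), collapse = ", ")))
  invisible(x)
}

#' Run both selection tiers on a training dataset
#'
#' Convenience wrapper: [tier1_select()] on all cohorts, [tier2_select()]
#' per cohort (seed offset per cohort), then [combine_panel()].
#'
#' @inheritParams tier1_select
#' @inheritParams tier2_select
#' @return List with `panel` (a `gene_panel`) and `records` (per-cohort
#'   `bagging_record`s).
#' @export
select_panel <- function(train, alpha = 0.05, n_trials = 100, min_trials = 80,
                         seed, replace = TRUE, log_transform = TRUE) {
  tier1 <- tier1_select(train, alpha = alpha, log_transform = log_transform)
  tier2 <- list(); records <- list()
  for (i in seq_along(train)) {
    nm <- names(train)[i]
    res <- tier2_select(train[[nm]], n_trials = n_trials, alpha = alpha,
                        min_trials = min_trials,
                        seed = derive_seed(seed, i), replace = replace,
                        log_transform = log_transform)
    tier2[[nm]] <- res$genes
    records[[nm]] <- res$record
  }
  list(panel = combine_panel(tier1, tier2), records = records)
}
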