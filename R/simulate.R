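#' Configuration for the multi-cohort TPM simulator
#'
#' Describes a synthetic study of several HGSOC-like cohorts with known
#' (planted) differential genes. Expression is generated on the
#' log2(TPM + 1) scale as Gaussian noise around a cohort- and class-specific
#' mean, truncated below at 0, then back-transformed to TPM.
#'
#' The default cohorts mirror the class counts of the three study cohorts
#' this simulator stands in for: 149/59 (TCGA-like), 24/16 (Patch-like) and
#' 14/72 (SNUH-like) chemo-resistant / chemo-sensitive samples, with a
#' cohort-constant batch shift on the log scale standing in for cohort
#' composition differences.
#'
#' @param cohorts List of cohort descriptors, each a list with `name`,
#'   `n_resistant`, `n_sensitive` and `batch_shift` (log2-units added to all
#'   genes of that cohort).
#' @param n_genes Total number of simulated genes.
#' @param shared_de_genes Number of genes differentially expressed
#'   (resistant vs sensitive) in every cohort - tier-1 ground truth.
#' @param specific_de_genes_per_cohort Number of genes differentially
#'   expressed in exactly one cohort - tier-2 ground truth, per cohort.
#' @param effect_size Log2-fold-change added to resistant samples for
#'   planted genes.
#' @param base_mean Baseline log2(TPM + 1) location.
#' @param noise_sd Gaussian noise standard deviation, log2-units; must be
#'   positive.
#' @param seed Integer seed; identical configs produce bit-identical data.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(cohorts = list(
                                list(name = "TCGA", n_resistant = 149,
                                     n_sensitive = 59, batch_shift = 0),
                                list(name = "Patch", n_resistant = 24,
                                     n_sensitive = 16, batch_shift = 0.8),
                                list(name = "SNUH", n_resistant = 14,
                                     n_sensitive = 72, batch_shift = -0.8)),
                              n_genes = 2000,
                              shared_de_genes = 5,
                              specific_de_genes_per_cohort = 5,
                              effect_size = 2,
                              base_mean = 4,
                              noise_sd = 1,
                              seed = 1L) {
  if (!is.list(cohorts) || length(cohorts) < 1)
    stop_config("cohorts must be a non-empty list", field = "cohorts")
  nms <- vapply(cohorts, function(co) as.character(co$name %||% ""), "")
  if (any(nms == "") || anyDuplicated(nms))
    stop_config("every cohort needs a unique name", field = "cohorts")
  for (co in cohorts) {
    if (!is_count(co$n_resistant) || !is_count(co$n_sensitive))
      stop_config(sprintf("cohort '%s': n_resistant and n_sensitive must be counts >= 0",
                          co$name), field = "cohorts")
    if (!is.numeric(co$batch_shift %||% NA) || !is.finite(co$batch_shift))
      stop_config(sprintf("cohort '%s': batch_shift must be finite", co$name),
                  field = "cohorts")
  }
  for (f in c("n_genes", "shared_de_genes", "specific_de_genes_per_cohort")) {
    if (!is_count(get(f))) stop_config(paste(f, "must be a count >= 0"), field = f)
  }
  if (!is.numeric(noise_sd) || !is.finite(noise_sd) || noise_sd <= 0)
    stop_config("noise_sd must be > 0", field = "noise_sd")
  if (!is.numeric(effect_size) || !is.finite(effect_size))
    stop_config("effect_size must be finite", field = "effect_size")
  if (!is.numeric(base_mean) || !is.finite(base_mean))
    stop_config("base_mean must be finite", field = "base_mean")
  n_planted <- shared_de_genes + specific_de_genes_per_cohort * length(cohorts)
  if (n_planted > n_genes)
    stop_config("shared_de_genes + per-cohort specific genes exceed n_genes",
                field = "n_genes")
  if (!is_count(abs(seed))) stop_config("seed must be an integer", field = "seed")
  structure(list(cohorts = cohorts, n_genes = as.integer(n_genes),
                 shared_de_genes = as.integer(shared_de_genes),
                 specific_de_genes_per_cohort =
                   as.integer(specific_de_genes_per_cohort),
                 effect_size = effect_size, base_mean = base_mean,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-cohort TPM dataset with planted differential genes
#'
#' For cohort c and gene g, log2(TPM + 1) is drawn from
#' Normal(base_mean + batch_shift_c + delta_g * 1\[resistant\], noise_sd),
#' truncated below at 0, and TPM = 2^value - 1. `delta_g` equals
#' `effect_size` for shared planted genes in every cohort and for
#' cohort-specific planted genes in their own cohort, else 0. A single RNG
#' stream is consumed in (cohort, sample, gene) order, so output is
#' bit-identical for identical configs regardless of platform parallelism.
#'
#' Planted roles occupy deterministic, disjoint leading blocks of the gene
#' index: first the shared genes, then one block per cohort.
#'
#' @param config A [simulation_config()].
#' @return A list with `dataset` (a [multi_cohort()]) and `truth`, the
#'   ground-truth gene lists: `shared_genes` and `specific_genes` (a named
#'   list, one entry per cohort).
#' @examples
#' sim <- simulate_multicohort(simulation_config(n_genes = 200, seed = 7))
#' sim$dataset
#' @export
simulate_multicohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_config("config must be created by simulation_config()", field = "config")
  g_ids <- sprintf("ENSG%011d", seq_len(config$n_genes))
  n_shared <- config$shared_de_genes
  n_spec <- config$specific_de_genes_per_cohort
  shared <- g_ids[seq_len(n_shared)]
  specific <- list()
  offset <- n_shared
  for (co in config$cohorts) {
    specific[[co$name]] <- g_ids[seq_len(n_spec) + offset]
    offset <- offset + n_spec
  }
  cohorts <- list()
  with_seed(config$seed, {
    for (co in config$cohorts) {
      n <- co$n_resistant + co$n_sensitive
      resistant <- c(rep(TRUE, co$n_resistant), rep(FALSE, co$n_sensitive))
      delta <- numeric(config$n_genes)
      delta[g_ids %in% c(shared, specific[[co$name]])] <- config$effect_size
      mu <- matrix(config$base_mean + co$batch_shift, config$n_genes, n)
      mu[, resistant] <- mu[, resistant] + delta
      # matrix() fills column-major: gene index varies fastest within sample
      v <- mu + matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
                       config$n_genes, n)
      v <- pmax(v, 0)
      tpm <- 2^v - 1
      rownames(tpm) <- g_ids
      colnames(tpm) <- paste0(co$name, "_", ifelse(resistant, "R", "S"),
                              c(seq_len(co$n_resistant), seq_len(co$n_sensitive)))
      cohorts[[co$name]] <- expression_matrix(
        tpm, cohort = rep(co$name, n),
        response = ifelse(resistant, "resistant", "sensitive"))
    }
  })
  truth <- list(shared_genes = shared, specific_genes = specific)
  list(dataset = multi_cohort(cohorts), truth = truth)
}
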