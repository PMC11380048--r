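# End-to-end orchestration: simulate (or load) -> preprocess -> select ->
# train -> evaluate (-> random-panel null), with per-stage seeds derived
# from one master seed and a manifest of output digests.

check_keys <- function(block, allowed, path) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown) > 0)
    stop_config(sprintf("unknown config key '%s.%s'", path, unknown[1]),
                field = paste0(path, ".", unknown[1]))
}

#' Load and validate a pipeline configuration
#'
#' @param config Path to a YAML file or an equivalent nested list. Top-level
#'   blocks: `seed` (required), one of `simulate`/`data`, and optional
#'   `preprocess`, `select`, `train`, `evaluate`, `null`.
#' @return The validated config list.
#' @export
load_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop_config("config must be a YAML mapping", field = "")
  check_keys(cfg, c("seed", "simulate", "data", "preprocess", "select",
                    "train", "evaluate", "null"), "config")
  if (is.null(cfg$seed)) stop_config("config.seed is required", field = "seed")
  if (is.null(cfg$simulate) && is.null(cfg$data))
    stop_config("config needs a 'simulate' or 'data' block", field = "simulate")
  if (!is.null(cfg$simulate))
    check_keys(cfg$simulate, c("cohorts", "n_genes", "shared_de_genes",
                               "specific_de_genes_per_cohort", "effect_size",
                               "base_mean", "noise_sd"), "simulate")
  if (!is.null(cfg$data))
    check_keys(cfg$data, c("matrices", "annotation", "strip_gene_version"), "data")
  if (!is.null(cfg$preprocess))
    check_keys(cfg$preprocess, c("min_tpm", "min_fraction", "test_fraction"),
               "preprocess")
  if (!is.null(cfg$select))
    check_keys(cfg$select, c("alpha", "n_trials", "min_trials"), "select")
  if (!is.null(cfg$train))
    check_keys(cfg$train, c("grid", "grid_subsample", "k", "train_cohort",
                            "selection_cohort"), "train")
  if (!is.null(cfg$evaluate))
    check_keys(cfg$evaluate, c("sens_floor"), "evaluate")
  if (!is.null(cfg[["null"]]))
    check_keys(cfg[["null"]], c("n_draws", "grid", "k"), "null")
  cfg
}

resolve_grid <- function(spec) {
  if (is.null(spec) || identical(spec, "small")) return(small_grid())
  if (identical(spec, "default")) return(default_grid())
  if (is.list(spec)) return(do.call(default_grid, spec))
  stop_config("train.grid must be 'small', 'default' or a list of axes",
              field = "train.grid")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  path
}

#' Serialize a trained ensemble to a directory
#'
#' Writes a JSON manifest (panel, threshold, seeds, per-member
#' hyperparameters and standardization) plus one JSON weight file per
#' member. Everything is plain text; [load_ensemble()] round-trips it.
#'
#' @param ens A `resist_ensemble`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    class = "resist_ensemble", k = ens$k, seed = ens$seed,
    threshold = ens$threshold, feature_order = ens$feature_order,
    panel = ens$panel[c("tier1", "tier2", "combined")],
    members = lapply(ens$members, function(m) {
      list(fold_index = m$fold_index, grid_index = m$grid_index,
           seed = m$seed, selection_score = m$selection_score,
           final_loss = m$final_loss, hyperparams = unclass(m$hyperparams),
           center = as.list(m$center), scale = as.list(m$scale))
    }))
  write_json_file(manifest, file.path(dir, "ensemble.json"))
  for (i in seq_along(ens$members)) {
    m <- ens$members[[i]]
    write_json_file(list(W = lapply(m$params$W, identity),
                         b = lapply(m$params$b, identity)),
                    file.path(dir, sprintf("member_%02d.json", i)))
  }
  invisible(dir)
}

#' Load an ensemble saved by [save_ensemble()]
#'
#' @param dir Directory written by [save_ensemble()].
#' @return A `resist_ensemble`.
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                                  simplifyVector = TRUE)
  members <- lapply(seq_along(manifest$members$fold_index), function(i) {
    w <- jsonlite::read_json(file.path(dir, sprintf("member_%02d.json", i)),
                             simplifyVector = TRUE)
    hp <- do.call(hyperparams, as.list(manifest$members$hyperparams[i, ]))
    structure(list(
      params = list(W = lapply(w$W, as.matrix), b = lapply(w$b, as.numeric)),
      hyperparams = hp,
      final_loss = manifest$members$final_loss[i],
      seed = manifest$members$seed[i],
      feature_order = manifest$feature_order,
      center = unlist(manifest$members$center[i, , drop = TRUE]),
      scale = unlist(manifest$members$scale[i, , drop = TRUE]),
      fold_index = manifest$members$fold_index[i],
      grid_index = manifest$members$grid_index[i],
      selection_score = manifest$members$selection_score[i]),
      class = "mlp_member")
  })
  panel <- combine_panel(manifest$panel$tier1, as.list(manifest$panel$tier2))
  if (!identical(panel$combined, manifest$panel$combined))
    panel <- new_gene_panel(manifest$panel$combined)
  structure(list(members = members, panel = panel,
                 threshold = manifest$threshold,
                 feature_order = manifest$feature_order,
                 k = manifest$k, seed = manifest$seed),
            class = "resist_ensemble")
}

#' Run the whole discovery-and-prediction workflow from one config
#'
#' Executes, in order: data simulation (or loading), cohort merge and
#' low-expression filter, stratified 2:1 split, two-tier gene selection on
#' the training split, fold-wise ensemble training with cross-cohort model
#' selection, sensitivity-prioritized evaluation on the test split, and
#' (optionally) the random-panel null. Writes `panel.json`, `model/`,
#' `report.json` and `manifest.json` under `out_dir`.
#'
#' @param config Path to a YAML config or an equivalent list; see
#'   [load_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return A `run_manifest` (invisibly): stage seeds, output digests,
#'   package version, timestamps, and the in-memory stage results in
#'   `$results`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- list(simulate = derive_seed(cfg$seed, 101),
                split = derive_seed(cfg$seed, 102),
                select = derive_seed(cfg$seed, 103),
                train = derive_seed(cfg$seed, 104),
                null = derive_seed(cfg$seed, 105))
  t0 <- Sys.time()

  # --- data ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim_cfg <- do.call(simulation_config,
                       c(cfg$simulate, list(seed = seeds$simulate)))
    sim <- simulate_multicohort(sim_cfg)
    ds <- sim$dataset
    truth <- sim$truth
    write_json_file(truth, file.path(out_dir, "ground_truth.json"))
    say("simulate: %d cohorts, %d genes", length(ds), nrow(ds[[1]]$tpm))
  } else {
    mats <- lapply(cfg$data$matrices, load_expression,
                   annotation_path = cfg$data$annotation,
                   strip_gene_version = isTRUE(cfg$data$strip_gene_version))
    ds <- merge_cohorts(mats)
    say("load: %d cohorts, %d common genes", length(ds), nrow(ds[[1]]$tpm))
  }

  # --- preprocess ---------------------------------------------------------
  pp <- cfg$preprocess %||% list()
  if (length(ds) > 1) ds <- merge_cohorts(unclass(ds))
  ds <- filter_low_expression(ds, min_tpm = pp$min_tpm %||% 1.0,
                              min_fraction = pp$min_fraction %||% 0.2)
  split <- stratified_split(ds, test_fraction = pp$test_fraction %||% (1 / 3),
                            seed = seeds$split)
  say("preprocess: %d genes pass the low-expression filter", nrow(ds[[1]]$tpm))

  # --- gene selection -----------------------------------------------------
  sl <- cfg$select %||% list()
  sel <- select_panel(split$train, alpha = sl$alpha %||% 0.05,
                      n_trials = sl$n_trials %||% 100,
                      min_trials = sl$min_trials %||% 80, seed = seeds$select)
  panel <- sel$panel
  write_json_file(list(tier1 = panel$tier1, tier2 = panel$tier2,
                       combined = panel$combined,
                       bagging = lapply(sel$records, function(r)
                         list(n_trials = r$n_trials, alpha = r$alpha,
                              seed = r$seed, counts = as.list(r$counts)))),
                  file.path(out_dir, "panel.json"))
  say("select: %d tier-1 + %s tier-2 genes -> %d-gene panel",
      length(panel$tier1),
      paste(lengths(panel$tier2), collapse = "+"), length(panel$combined))
  if (length(panel$combined) == 0)
    stop_data("gene selection produced an empty panel; nothing to train on")

  # --- ensemble training --------------------------------------------------
  tr <- cfg$train %||% list()
  train_cohort <- tr$train_cohort %||% names(split$train)[1]
  selection_cohort <- tr$selection_cohort %||% rev(names(split$train))[1]
  ens <- train_ensemble(split$train[[train_cohort]],
                        split$train[[selection_cohort]], panel,
                        grid = resolve_grid(tr$grid), k = tr$k %||% 5,
                        seed = seeds$train,
                        grid_subsample = tr$grid_subsample)
  say("train: %d members selected on cohort '%s'", length(ens$members),
      selection_cohort)

  # --- evaluation ---------------------------------------------------------
  sens_floor <- (cfg$evaluate %||% list())$sens_floor %||% 1.0
  sel_test <- split$test[[selection_cohort]]
  sel_scores <- predict_proba(ens, sel_test)
  ens$threshold <- threshold_max_spec_at_sens(sel_scores,
                                              is_resistant(sel_test),
                                              sens_floor = sens_floor)
  save_ensemble(ens, file.path(out_dir, "model"))
  metrics <- do.call(rbind, lapply(names(split$test), function(nm)
    evaluate_cohort(ens, split$test[[nm]], threshold = ens$threshold)))
  say("evaluate: AUC %s on test splits (threshold %.3f)",
      paste(sprintf("%s=%.3f", metrics$cohort, metrics$auc), collapse = ", "),
      ens$threshold)

  # --- random-panel null --------------------------------------------------
  null_cmp <- NULL
  if (!is.null(cfg[["null"]])) {
    nl <- cfg[["null"]]
    observed <- metrics$auc[metrics$cohort == selection_cohort]
    null_cmp <- random_panel_null(split, panel_size = length(ens$feature_order),
                                  n_draws = nl$n_draws %||% 20,
                                  grid = resolve_grid(nl$grid),
                                  k = nl$k %||% (tr$k %||% 5),
                                  seed = seeds$null, observed_auc = observed,
                                  train_cohort = train_cohort,
                                  selection_cohort = selection_cohort)
    say("null: observed AUC %.3f vs null mean %.3f (empirical p %.4f)",
        observed, mean(null_cmp$null_aucs), null_cmp$empirical_p)
  }

  report <- list(metrics = metrics, sens_floor = sens_floor,
                 threshold = ens$threshold,
                 train_cohort = train_cohort,
                 selection_cohort = selection_cohort,
                 null_comparison = if (!is.null(null_cmp))
                   unclass(null_cmp) else NULL)
  write_json_file(report, file.path(out_dir, "report.json"))

  # --- manifest -----------------------------------------------------------
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  outputs <- c("panel.json", "report.json", "ground_truth.json",
               file.path("model", "ensemble.json"))
  outputs <- outputs[file.exists(file.path(out_dir, outputs))]
  digests <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(digests) <- outputs
  manifest <- structure(list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seeds = seeds,
    package_version = as.character(utils::packageVersion("resistseq")),
    outputs = digests,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
  write_json_file(unclass(manifest), file.path(out_dir, "manifest.json"))
  unlink(cfg_file)
  manifest$results <- list(dataset = ds, split = split, panel = panel,
                           records = sel$records, ensemble = ens,
                           metrics = metrics, null_comparison = null_cmp,
                           truth = truth)
  invisible(manifest)
}
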