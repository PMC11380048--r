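test_that("roc_auc matches hand-counted concordant pairs and limits", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(1, 0), 4)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "resistseq_data_error")
})

test_that("roc_auc is rank-based and complements under score negation", {
  withr::with_seed(61, {
    for (i in 1:20) {
      sc <- rnorm(40); y <- rbinom(40, 1, 0.4)
      if (sum(y) == 0 || sum(y) == 40) next
      a <- roc_auc(sc, y)
      expect_equal(roc_auc(exp(sc), y), a)          # strictly increasing map
      expect_equal(roc_auc(-sc, y), 1 - a)          # tie-free complement
    }
  })
})

test_that("roc_auc agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  withr::with_seed(62, {
    for (i in 1:10) {
      sc <- round(rnorm(60), 1)  # include ties
      y <- rbinom(60, 1, 0.5)
      if (length(unique(y)) < 2) next
      ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                            direction = "<")))
      expect_equal(roc_auc(sc, y), ref, tolerance = 1e-12)
    }
  })
})

test_that("sensitivity and specificity follow the >= threshold convention", {
  sc <- c(0.9, 0.6, 0.7, 0.2); y <- c(1, 1, 0, 0)
  expect_equal(sens_spec_at(sc, y, 2),
               c(sensitivity = 0, specificity = 1))
  expect_equal(sens_spec_at(sc, y, 0.1),
               c(sensitivity = 1, specificity = 0))
  expect_equal(sens_spec_at(sc, y, 0.6),
               c(sensitivity = 1, specificity = 0.5))
})

test_that("sensitivity-prioritized threshold maximizes specificity", {
  sc <- c(0.9, 0.6, 0.7, 0.2); y <- c(1, 1, 0, 0)
  th <- threshold_max_spec_at_sens(sc, y, sens_floor = 1.0)
  expect_equal(th, 0.6)  # the minimum positive score at floor 1
  expect_equal(unname(sens_spec_at(sc, y, th)), c(1, 0.5))
  # separable scores: full specificity attainable
  sc2 <- c(0.8, 0.7, 0.3, 0.1); y2 <- c(1, 1, 0, 0)
  th2 <- threshold_max_spec_at_sens(sc2, y2, 1.0)
  expect_equal(unname(sens_spec_at(sc2, y2, th2)), c(1, 1))
})

test_that("the selected threshold always satisfies its sensitivity floor", {
  withr::with_seed(63, {
    for (i in 1:1000) {
      n <- sample(4:30, 1)
      sc <- round(rnorm(n), sample(c(1, 2, 8), 1))
      y <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (length(unique(y)) < 2) next
      floor_i <- runif(1, 0.05, 1)
      th <- threshold_max_spec_at_sens(sc, y, floor_i)
      ss <- sens_spec_at(sc, y, th)
      expect_gte(ss[["sensitivity"]], floor_i)
    }
  })
})

test_that("the random-panel null follows the add-one empirical-p rule", {
  sim <- simulate_multicohort(simulation_config(
    cohorts = list(
      list(name = "A", n_resistant = 20, n_sensitive = 20, batch_shift = 0),
      list(name = "B", n_resistant = 16, n_sensitive = 16, batch_shift = 0)),
    n_genes = 40, shared_de_genes = 2, specific_de_genes_per_cohort = 0,
    effect_size = 2, seed = 3))
  split <- stratified_split(sim$dataset, seed = 4)
  grid1 <- default_grid(learning_rate = 0.01, n_hidden_layers = 1,
                        hidden_units = 8, dropout = 0, batch_size = 8,
                        epochs = 20)
  run_null <- function(observed) {
    random_panel_null(split, panel_size = 4, n_draws = 4, grid = grid1,
                      k = 2, seed = 11, observed_auc = observed)
  }
  lo <- run_null(-1)   # observed below every null AUC
  expect_equal(lo$empirical_p, 1.0)
  hi <- run_null(2)    # observed above every null AUC
  expect_equal(hi$empirical_p, 1 / (1 + length(hi$null_aucs)))
  mid <- run_null(0.5)
  expect_equal(mid$empirical_p,
               (1 + sum(mid$null_aucs >= 0.5)) / (1 + length(mid$null_aucs)))
  # same seed, same draws
  expect_equal(run_null(0.5)$null_aucs, mid$null_aucs)
})

test_that("on pure noise the null AUC distribution centres near one half", {
  grid1 <- default_grid(learning_rate = 0.01, n_hidden_layers = 1,
                        hidden_units = 8, dropout = 0, batch_size = 8,
                        epochs = 20)
  for (s in 1:3) {
    sim <- simulate_multicohort(simulation_config(
      cohorts = list(
        list(name = "A", n_resistant = 25, n_sensitive = 25, batch_shift = 0),
        list(name = "B", n_resistant = 25, n_sensitive = 25, batch_shift = 0)),
      n_genes = 60, shared_de_genes = 0, specific_de_genes_per_cohort = 0,
      effect_size = 0, seed = 70 + s))
    split <- stratified_split(sim$dataset, seed = s)
    null <- random_panel_null(split, panel_size = 5, n_draws = 20,
                              grid = grid1, k = 2, seed = 80 + s)
    expect_gte(mean(null$null_aucs), 0.4)
    expect_lte(mean(null$null_aucs), 0.6)
  }
})

test_that("evaluate_cohort packages metrics at the chosen threshold", {
  fit_em <- random_expr(10, n_res = 15, n_sens = 15, seed = 91, effect = 4,
                        de_genes = 1:3)
  sel_em <- random_expr(10, n_res = 8, n_sens = 8, cohort = "B", seed = 92,
                        effect = 4, de_genes = 1:3)
  ens <- train_ensemble(fit_em, sel_em, combine_panel(rownames(fit_em$tpm)[1:5]),
                        grid = default_grid(learning_rate = 0.01,
                                            n_hidden_layers = 1,
                                            hidden_units = 8, dropout = 0,
                                            batch_size = 8, epochs = 20),
                        k = 2, seed = 1)
  rep <- evaluate_cohort(ens, sel_em)
  expect_equal(rep$n_resistant, 8)
  expect_equal(rep$n_sensitive, 8)
  sc <- predict_proba(ens, sel_em)
  expect_equal(rep$auc, roc_auc(sc, sel_em$response == "resistant"))
})
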