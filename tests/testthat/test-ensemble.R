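test_that("folds are stratified, exhaustive, disjoint and reproducible", {
  em <- random_expr(5, n_res = 10, n_sens = 10, seed = 2)
  folds <- make_folds(em, k = 5, seed = 1)
  pos <- em$response == "resistant"
  for (f in folds) {
    expect_equal(sum(pos[f$holdout]), 2)
    expect_equal(sum(!pos[f$holdout]), 2)
    expect_setequal(c(f$fit, f$holdout), 1:20)
  }
  all_holdouts <- unlist(lapply(folds, `[[`, "holdout"))
  expect_setequal(all_holdouts, 1:20)
  expect_false(anyDuplicated(all_holdouts) > 0)
  expect_identical(folds, make_folds(em, k = 5, seed = 1))
  expect_error(make_folds(random_expr(5, 3, 10, seed = 1), k = 5, seed = 1),
               class = "resistseq_data_error")
})

test_that("the default hyperparameter grid has 2160 unique entries", {
  g <- default_grid()
  expect_equal(nrow(g), 2160)
  expect_equal(nrow(unique(g)), 2160)
  expect_equal(nrow(default_grid(learning_rate = 0.1, n_hidden_layers = 1,
                                 hidden_units = 4, dropout = 0,
                                 batch_size = 2, epochs = 5)), 1)
  expect_equal(nrow(small_grid()), 12)
})

test_that("a member fits linearly separable data to training accuracy 1", {
  toy <- separable_toy(10, seed = 3)
  hp <- hyperparams(0.01, 1, 16, 0, 4, 50)
  m <- train_member(toy$X, toy$y, hp, seed = 1)
  pred <- resistseq:::mlp_predict_prob(m$params, toy$X)
  expect_equal(mean((pred >= 0.5) == toy$y), 1.0)
})

test_that("training validates its inputs", {
  toy <- separable_toy(6, seed = 4)
  hp <- hyperparams(0.01, 1, 8, 0, 4, 5)
  expect_error(train_member(toy$X, rep(1, 12), hp, seed = 1),
               "single class")
  expect_error(train_member(toy$X[c(1, 2, 7), ], toy$y[c(1, 2, 7)], hp,
                            seed = 1), "batch_size")
})

test_that("training is deterministic given data, hyperparameters and seed", {
  toy <- separable_toy(8, seed = 5)
  hp <- hyperparams(0.003, 2, 8, 0.25, 4, 20)
  a <- train_member(toy$X, toy$y, hp, seed = 9)
  b <- train_member(toy$X, toy$y, hp, seed = 9)
  expect_equal(a$final_loss, b$final_loss, tolerance = 1e-6)
  expect_equal(a$params, b$params)
  c_ <- train_member(toy$X, toy$y, hp, seed = 10)
  expect_false(isTRUE(all.equal(a$params, c_$params)))
})

make_tiny_ensemble <- function(seed = 2, grid = default_grid(
                                 learning_rate = 0.01, n_hidden_layers = 1,
                                 hidden_units = 8, dropout = 0,
                                 batch_size = 8, epochs = 30), k = 2) {
  primary <- random_expr(12, n_res = 20, n_sens = 20, seed = 31, effect = 4,
                         de_genes = 1:4)
  selection <- random_expr(12, n_res = 10, n_sens = 10, cohort = "B",
                           seed = 32, effect = 4, de_genes = 1:4)
  panel <- combine_panel(rownames(primary$tpm)[1:8], list())
  list(ens = train_ensemble(primary, selection, panel, grid = grid, k = k,
                            seed = seed),
       primary = primary, selection = selection, panel = panel)
}

test_that("a 1-entry grid, 2-fold ensemble solves a separable problem", {
  fit <- make_tiny_ensemble()
  expect_length(fit$ens$members, 2)
  for (m in fit$ens$members) expect_equal(m$selection_score, 1.0)
})

test_that("the ensemble score is the member mean and is order-invariant", {
  fit <- make_tiny_ensemble()
  ens <- fit$ens
  sc <- predict_proba(ens, fit$selection)
  member_scores <- vapply(ens$members, resistseq:::member_predict,
                          numeric(ncol(fit$selection$tpm)),
                          tpm = fit$selection$tpm)
  expect_lt(max(abs(sc - rowMeans(member_scores))), 1e-9)
  perm <- ens
  perm$members <- rev(perm$members)
  expect_equal(unname(predict_proba(perm, fit$selection)), unname(sc))
})

test_that("per-sample scores have no cross-sample coupling", {
  fit <- make_tiny_ensemble()
  tpm <- fit$selection$tpm
  dup <- cbind(tpm, dup1 = tpm[, 3])
  sc <- predict_proba(fit$ens, dup)
  expect_equal(unname(sc["dup1"]), unname(sc[3]))
  single <- predict_proba(fit$ens, tpm[, 3, drop = FALSE])
  expect_equal(unname(single), unname(sc[3]))
})

test_that("full ensemble training is reproducible for a fixed seed", {
  a <- make_tiny_ensemble(seed = 4)
  b <- make_tiny_ensemble(seed = 4)
  sa <- predict_proba(a$ens, a$selection)
  sb <- predict_proba(b$ens, b$selection)
  expect_equal(sa, sb, tolerance = 1e-6)
})

test_that("prediction demands every panel gene", {
  fit <- make_tiny_ensemble()
  short <- fit$selection$tpm[-1, ]
  expect_error(predict_proba(fit$ens, short), "g0001",
               class = "resistseq_data_error")
})

test_that("the last-layer embedding has the contracted shape and locality", {
  fit <- make_tiny_ensemble()
  emb <- last_layer_embedding(fit$ens, fit$selection)
  widths <- vapply(fit$ens$members, function(m) m$hyperparams$hidden_units, 0L)
  expect_equal(dim(emb), c(ncol(fit$selection$tpm), sum(widths)))
  tpm <- fit$selection$tpm
  tpm[, 2] <- tpm[, 1]
  emb2 <- last_layer_embedding(fit$ens, tpm)
  expect_equal(unname(emb2[1, ]), unname(emb2[2, ]))
})

test_that("select_member maximizes AUC with deterministic tie-breaking", {
  fit <- make_tiny_ensemble()
  cands <- fit$ens$members
  # single candidate returns unchanged (modulo the attached score)
  one <- select_member(cands[1], fit$selection$tpm,
                       fit$selection$response == "resistant")
  expect_equal(one$params, cands[[1]]$params)
  # identical predictions -> lower grid index wins
  c1 <- cands[[1]]; c2 <- cands[[1]]
  c1$grid_index <- 5L; c2$grid_index <- 3L
  win <- select_member(list(c1, c2), fit$selection$tpm,
                       fit$selection$response == "resistant")
  expect_equal(win$grid_index, 3L)
  # a dominated candidate loses: flip one candidate's output layer sign
  bad <- cands[[1]]
  bad$params$W[[length(bad$params$W)]] <- -bad$params$W[[length(bad$params$W)]]
  bad$grid_index <- 1L
  good <- cands[[2]]; good$grid_index <- 2L
  win2 <- select_member(list(bad, good), fit$selection$tpm,
                        fit$selection$response == "resistant")
  expect_equal(win2$grid_index, 2L)
})

test_that("a saved ensemble reloads with identical predictions", {
  fit <- make_tiny_ensemble()
  dir <- withr::local_tempdir()
  save_ensemble(fit$ens, dir)
  back <- load_ensemble(dir)
  expect_equal(predict_proba(back, fit$selection),
               predict_proba(fit$ens, fit$selection), tolerance = 1e-12)
  expect_equal(back$threshold, fit$ens$threshold)
  expect_equal(back$feature_order, fit$ens$feature_order)
})
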