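test_that("a matrix round-trips through write and read", {
  em <- toy_expr(matrix(c(1.5, 0, 2.25, 7), 2, 2))
  mat_file <- withr::local_tempfile(fileext = ".tsv")
  ann_file <- withr::local_tempfile(fileext = ".tsv")
  write_expression(em, mat_file, ann_file)
  back <- load_expression(mat_file, ann_file)
  expect_equal(back$tpm, em$tpm)
  expect_equal(back$response, em$response)
  expect_equal(back$cohort, em$cohort)
})

test_that("invalid input files are rejected with informative data errors", {
  mat_file <- withr::local_tempfile(fileext = ".tsv")
  ann_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1.0\t-1.0", "gB\t2\t3"), mat_file)
  writeLines(c("sample_id\tcohort\tresponse",
               "s1\tA\tresistant", "s2\tA\tsensitive"), ann_file)
  expect_error(load_expression(mat_file, ann_file), "negative TPM",
               class = "resistseq_data_error")

  writeLines(c("gene_id\ts1\ts2", "gA\t1.0\t2.0", "gA\t2\t3"), mat_file)
  expect_error(load_expression(mat_file, ann_file), "duplicated gene ID: gA")

  writeLines(c("gene_id\ts1\ts2", "gA\t1.0\t2.0", "gB\t2\t3"), mat_file)
  writeLines(c("sample_id\tcohort\tresponse", "s1\tA\tresistant"), ann_file)
  expect_error(load_expression(mat_file, ann_file), "s2",
               class = "resistseq_data_error")
})

test_that("merge keeps the sorted intersection of gene sets", {
  mk <- function(genes, cohort) {
    tpm <- matrix(seq_len(2 * length(genes)), length(genes), 2,
                  dimnames = list(genes, paste0(cohort, 1:2)))
    toy_expr(tpm, cohort = cohort)
  }
  same <- merge_cohorts(list(A = mk(letters[1:5], "A"), B = mk(letters[1:5], "B")))
  expect_equal(rownames(same[[1]]$tpm), letters[1:5])

  ds <- merge_cohorts(list(A = mk(c("A", "B", "C"), "A"),
                           B = mk(c("B", "C", "D"), "B")))
  expect_equal(rownames(ds[[1]]$tpm), c("B", "C"))
  expect_equal(rownames(ds[[2]]$tpm), c("B", "C"))

  expect_error(merge_cohorts(list(A = mk(c("A", "B"), "A"),
                                  B = mk(c("C", "D"), "B"))),
               "no common genes")
})

test_that("merging an already-merged dataset changes nothing", {
  sim <- simulate_multicohort(simulation_config(n_genes = 30, seed = 2))
  once <- merge_cohorts(unclass(sim$dataset))
  twice <- merge_cohorts(unclass(once))
  expect_identical(lapply(unclass(twice), `[[`, "tpm"),
                   lapply(unclass(once), `[[`, "tpm"))
})

test_that("low-expression filter applies an inclusive pooled-fraction rule", {
  # 1 cohort, 10 samples: gene a all zero, gene b expressed everywhere,
  # gene c >= 1 TPM in exactly 2 of 10 samples
  tpm <- rbind(a = rep(0, 10), b = rep(5, 10), c = c(1, 1, rep(0.2, 8)))
  colnames(tpm) <- paste0("s", 1:10)
  ds <- multi_cohort(list(A = toy_expr(tpm)))
  kept <- filter_low_expression(ds, min_tpm = 1, min_fraction = 0.2)
  expect_equal(rownames(kept[[1]]$tpm), c("b", "c"))  # boundary 2/10 kept
  expect_error(filter_low_expression(ds, min_tpm = 10, min_fraction = 1),
               "every gene")
})

test_that("raising either filter knob never adds genes", {
  sim <- simulate_multicohort(simulation_config(n_genes = 300, base_mean = 1,
                                                noise_sd = 2, seed = 9))
  base <- rownames(filter_low_expression(sim$dataset, 1, 0.2)[[1]]$tpm)
  for (args in list(c(2, 0.2), c(1, 0.5), c(4, 0.8))) {
    tighter <- tryCatch(
      rownames(filter_low_expression(sim$dataset, args[1], args[2])[[1]]$tpm),
      resistseq_data_error = function(e) character(0))
    expect_true(all(tighter %in% base))
  }
})

test_that("stratified split honors exact thirds and the minimum-1 rule", {
  em <- random_expr(5, n_res = 6, n_sens = 3, seed = 4)
  sp <- stratified_split(multi_cohort(list(A = em)), test_fraction = 1 / 3,
                         seed = 1)
  expect_equal(sum(sp$train[[1]]$response == "resistant"), 4)
  expect_equal(sum(sp$train[[1]]$response == "sensitive"), 2)
  expect_equal(sum(sp$test[[1]]$response == "resistant"), 2)
  expect_equal(sum(sp$test[[1]]$response == "sensitive"), 1)

  # n = 2 stratum: floor(2/3) = 0 overridden to 1 test sample
  em2 <- random_expr(5, n_res = 2, n_sens = 6, seed = 4)
  sp2 <- stratified_split(multi_cohort(list(A = em2)), seed = 1)
  expect_equal(sum(sp2$test[[1]]$response == "resistant"), 1)

  # singleton stratum goes to train with a warning
  em1 <- random_expr(5, n_res = 1, n_sens = 6, seed = 4)
  expect_warning(sp1 <- stratified_split(multi_cohort(list(A = em1)), seed = 1),
                 "single")
  expect_equal(sum(sp1$train[[1]]$response == "resistant"), 1)
})

test_that("the split is deterministic given the seed and conserves samples", {
  sim <- simulate_multicohort(simulation_config(n_genes = 20, seed = 6))
  a <- stratified_split(sim$dataset, seed = 42)
  b <- stratified_split(sim$dataset, seed = 42)
  test_ids <- function(sp) lapply(unclass(sp$test), function(m) colnames(m$tpm))
  expect_identical(test_ids(a), test_ids(b))
  for (nm in names(sim$dataset)) {
    ids_in <- colnames(sim$dataset[[nm]]$tpm)
    ids_out <- c(colnames(a$train[[nm]]$tpm), colnames(a$test[[nm]]$tpm))
    expect_setequal(ids_out, ids_in)
    expect_false(anyDuplicated(ids_out) > 0)
  }
  c_ <- stratified_split(sim$dataset, seed = 43)
  expect_false(identical(test_ids(a), test_ids(c_)))
})
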