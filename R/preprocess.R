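#' Read a TPM matrix and its sample annotation
#'
#' The matrix file is TSV or CSV (sniffed from the extension, `.csv` =
#' comma) with a header row of sample IDs and gene IDs in the first column.
#' The annotation file is TSV/CSV with columns `sample_id`, `cohort`,
#' `response` and must cover every sample in the matrix.
#'
#' @param path Matrix file.
#' @param annotation_path Annotation file.
#' @param strip_gene_version Drop trailing ".N" Ensembl version suffixes
#'   from gene IDs before validation. Off by default to avoid silent ID
#'   collisions.
#' @return An [expression_matrix()]; gene (row) order is preserved.
#' @export
load_expression <- function(path, annotation_path, strip_gene_version = FALSE) {
  sep <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep(path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  gid <- as.character(raw[[1]])
  if (strip_gene_version) gid <- sub("\\.\\d+$", "", gid)
  if (anyDuplicated(gid))
    stop_data(paste0("duplicated gene ID: ", gid[duplicated(gid)][1]))
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop_data(sprintf("non-numeric TPM for gene %s, sample %s",
                      gid[bad[1, 1]], colnames(raw)[-1][bad[1, 2]]))
  }
  rownames(m) <- gid
  neg <- which(m < 0, arr.ind = TRUE)
  if (length(neg) > 0)
    stop_data(sprintf("negative TPM for gene %s, sample %s",
                      gid[neg[1, 1]], colnames(m)[neg[1, 2]]))
  ann <- utils::read.table(annotation_path, header = TRUE, sep = sep(annotation_path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "cohort", "response")
  if (!all(need %in% names(ann)))
    stop_data("annotation must have columns sample_id, cohort, response")
  missing <- setdiff(colnames(m), ann$sample_id)
  if (length(missing) > 0)
    stop_data(paste0("sample missing annotation: ", missing[1]))
  idx <- match(colnames(m), ann$sample_id)
  expression_matrix(m, cohort = ann$cohort[idx], response = ann$response[idx])
}

#' Write an expression matrix (and optionally its annotation) to TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output TSV for the TPM matrix (first column `gene_id`).
#' @param annotation_path Optional output TSV for sample annotation.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, path, annotation_path = NULL) {
  df <- data.frame(gene_id = gene_ids(x), x$tpm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- data.frame(sample_id = sample_ids(x), cohort = x$cohort,
                      response = x$response)
    utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Merge cohorts on their common gene set
#'
#' Keeps the intersection of the input gene sets (the shared-identifier
#' merge used when pooling cohorts quantified against the same annotation),
#' sorted lexicographically, and row-subsets every cohort accordingly.
#'
#' @param matrices List of [expression_matrix()] objects; names become
#'   cohort names (default: the dominant `cohort` label of each matrix).
#' @return A [multi_cohort()].
#' @export
merge_cohorts <- function(matrices) {
  if (length(matrices) < 2) stop_data("merge_cohorts needs >= 2 matrices")
  if (is.null(names(matrices)))
    names(matrices) <- vapply(matrices, function(m) m$cohort[1], "")
  common <- Reduce(intersect, lapply(matrices, gene_ids))
  if (length(common) == 0) stop_data("no common genes across cohorts")
  common <- sort(common)
  multi_cohort(lapply(matrices, subset_genes, genes = common))
}

#' Remove lowly expressed genes
#'
#' Keeps gene g iff TPM >= `min_tpm` in at least `min_fraction` of all
#' samples pooled across cohorts (both bounds inclusive). Gene order is
#' preserved.
#'
#' @param ds A [multi_cohort()].
#' @param min_tpm TPM threshold a sample must reach to count as expressing.
#' @param min_fraction Minimum fraction of pooled samples expressing.
#' @return Filtered [multi_cohort()].
#' @export
filter_low_expression <- function(ds, min_tpm = 1.0, min_fraction = 0.2) {
  stopifnot(inherits(ds, "multi_cohort"))
  if (min_fraction < 0 || min_fraction > 1)
    stop_config("min_fraction must be in [0, 1]", field = "min_fraction")
  pooled <- do.call(cbind, lapply(unclass(ds), function(m) m$tpm >= min_tpm))
  keep <- rowMeans(pooled) >= min_fraction
  if (!any(keep)) stop_data("low-expression filter removed every gene")
  multi_cohort(lapply(unclass(ds), function(m)
    expression_matrix(m$tpm[keep, , drop = FALSE], m$cohort, m$response)))
}

#' Stratified train/test split
#'
#' Within each (cohort, class) stratum, `floor(n * test_fraction)` samples
#' (at least 1 when the stratum has >= 2) are assigned to the test set by a
#' seeded shuffle; the default reproduces the study's 2:1 split. Strata of
#' size 1 go to training with a warning.
#'
#' @param ds A [multi_cohort()].
#' @param test_fraction Fraction of each stratum held out for testing.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return An object of class `split_dataset` with elements `train`, `test`
#'   (both [multi_cohort()]), `test_fraction`, `seed`.
#' @export
stratified_split <- function(ds, test_fraction = 1 / 3, seed) {
  stopifnot(inherits(ds, "multi_cohort"))
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_config("test_fraction must be in (0, 1)", field = "test_fraction")
  train <- list(); test <- list()
  with_seed(seed, {
    for (nm in names(ds)) {
      m <- ds[[nm]]
      test_idx <- integer(0)
      for (cls in c("resistant", "sensitive")) {
        idx <- which(m$response == cls)
        n <- length(idx)
        if (n == 0) next
        n_test <- floor(n * test_fraction)
        if (n >= 2 && n_test == 0) n_test <- 1L
        if (n == 1) {
          warning(sprintf("cohort '%s' has a single %s sample; assigned to train",
                          nm, cls))
          n_test <- 0L
        }
        test_idx <- c(test_idx, sample(idx)[seq_len(n_test)])
      }
      test_idx <- sort(test_idx)
      train_idx <- setdiff(seq_along(m$response), test_idx)
      train[[nm]] <- subset_samples(m, train_idx)
      test[[nm]] <- subset_samples(m, test_idx)
    }
  })
  structure(list(train = multi_cohort(train), test = multi_cohort(test),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("<split_dataset> test_fraction = %.4f, seed = %d\n",
              x$test_fraction, x$seed))
  cat("train:\n"); print(x$train)
  cat("test:\n"); print(x$test)
  invisible(x)
}
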