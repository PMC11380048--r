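#' Expression matrix with cohort and response annotation
#'
#' Container for a TPM gene-by-sample matrix plus per-sample metadata. The
#' positive ("resistant") class is a platinum chemo-resistant tumour, the
#' negative class chemo-sensitive; values are transcripts per million (TPM),
#' non-negative and finite.
#'
#' @param tpm Numeric matrix, genes in rows (unique rownames = gene IDs),
#'   samples in columns (unique colnames = sample IDs).
#' @param cohort Character vector, one cohort name per sample.
#' @param response Character vector, one of `"resistant"`/`"sensitive"` per
#'   sample.
#' @return An object of class `expr_matrix`: a list with elements `tpm`,
#'   `cohort`, `response`.
#' @export
expression_matrix <- function(tpm, cohort, response) {
  if (!is.matrix(tpm) || !is.numeric(tpm))
    stop_data("tpm must be a numeric matrix (genes x samples)")
  if (is.null(rownames(tpm)) || anyDuplicated(rownames(tpm)))
    stop_data("duplicated or missing gene IDs in tpm rownames")
  if (is.null(colnames(tpm)) || anyDuplicated(colnames(tpm)))
    stop_data("duplicated or missing sample IDs in tpm colnames")
  bad <- which(!is.finite(tpm) | tpm < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_data(sprintf(
      "negative TPM or non-finite value for gene %s, sample %s",
      rownames(tpm)[bad[1, 1]], colnames(tpm)[bad[1, 2]]))
  }
  cohort <- as.character(cohort)
  response <- as.character(response)
  if (length(cohort) != ncol(tpm) || length(response) != ncol(tpm))
    stop_data("cohort and response must have one entry per sample")
  if (!all(response %in% c("resistant", "sensitive")))
    stop_data("response labels must be 'resistant' or 'sensitive'")
  structure(list(tpm = tpm, cohort = cohort, response = response),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%s)\n",
              nrow(x$tpm), ncol(x$tpm),
              paste(unique(x$cohort), collapse = ", ")))
  tab <- table(factor(x$response, levels = c("resistant", "sensitive")))
  cat(sprintf("  resistant: %d, sensitive: %d\n", tab[[1]], tab[[2]]))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$tpm)

gene_ids <- function(x) rownames(x$tpm)
sample_ids <- function(x) colnames(x$tpm)

# Logical vector: TRUE where the sample is chemo-resistant (positive class).
is_resistant <- function(x) x$response == "resistant"

subset_samples <- function(x, idx) {
  expression_matrix(x$tpm[, idx, drop = FALSE], x$cohort[idx], x$response[idx])
}

subset_genes <- function(x, genes) {
  missing <- setdiff(genes, gene_ids(x))
  if (length(missing) > 0)
    stop_data(paste0("gene not present in matrix: ", missing[1]))
  expression_matrix(x$tpm[genes, , drop = FALSE], x$cohort, x$response)
}

#' Bundle per-cohort expression matrices over one shared gene set
#'
#' @param cohorts Named list of [expression_matrix()] objects with identical
#'   `rownames` in identical order.
#' @return An object of class `multi_cohort`.
#' @export
multi_cohort <- function(cohorts) {
  if (length(cohorts) < 1) stop_data("need at least one cohort")
  if (is.null(names(cohorts)) || anyDuplicated(names(cohorts)))
    stop_data("cohorts must be a uniquely named list")
  ref <- gene_ids(cohorts[[1]])
  for (nm in names(cohorts)) {
    if (!identical(gene_ids(cohorts[[nm]]), ref))
      stop_data(sprintf("cohort '%s' gene IDs differ from the shared gene set", nm))
  }
  structure(cohorts, class = "multi_cohort")
}

#' @export
print.multi_cohort <- function(x, ...) {
  cat(sprintf("<multi_cohort> %d cohorts, %d shared genes\n",
              length(x), nrow(x[[1]]$tpm)))
  for (nm in names(x)) {
    tab <- table(factor(x[[nm]]$response, levels = c("resistant", "sensitive")))
    cat(sprintf("  %s: %d samples (%d resistant / %d sensitive)\n",
                nm, ncol(x[[nm]]$tpm), tab[[1]], tab[[2]]))
  }
  invisible(x)
}
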