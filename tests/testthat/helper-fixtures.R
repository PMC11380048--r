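# Shared fixtures: tiny expression objects and an independent brute-force
# Mann-Whitney oracle. Everything is built in code at test time.

# A small expression matrix with explicit values.
toy_expr <- function(tpm, cohort = "A",
                     response = rep(c("resistant", "sensitive"),
                                    length.out = ncol(tpm))) {
  if (is.null(rownames(tpm))) rownames(tpm) <- paste0("g", seq_len(nrow(tpm)))
  if (is.null(colnames(tpm))) colnames(tpm) <- paste0("s", seq_len(ncol(tpm)))
  expression_matrix(tpm, cohort = rep(cohort, ncol(tpm)), response = response)
}

# Random non-negative TPM matrix with labelled samples.
random_expr <- function(n_genes, n_res, n_sens, cohort = "A", seed = 1,
                        effect = 0, de_genes = integer(0)) {
  withr::with_seed(seed, {
    n <- n_res + n_sens
    v <- matrix(rnorm(n_genes * n, 4, 1), n_genes, n)
    if (length(de_genes) > 0 && effect != 0)
      v[de_genes, seq_len(n_res)] <- v[de_genes, seq_len(n_res)] + effect
    tpm <- 2^pmax(v, 0) - 1
    rownames(tpm) <- sprintf("g%04d", seq_len(n_genes))
    colnames(tpm) <- paste0(cohort, "_s", seq_len(n))
    expression_matrix(tpm, cohort = rep(cohort, n),
                      response = rep(c("resistant", "sensitive"),
                                     c(n_res, n_sens)))
  })
}

# Brute-force two-sided Mann-Whitney p-value by enumerating every way the
# pooled ranks could be assigned to group x (tie-free inputs only).
# Independent of the package implementation: counts subsets directly.
mw_enumeration_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  stopifnot(!any(duplicated(c(x, y))))
  pooled_ranks <- rank(c(x, y))
  u_obs <- sum(pooled_ranks[seq_len(m)]) - m * (m + 1) / 2
  subsets <- utils::combn(m + n, m)
  all_ranks <- seq_len(m + n)
  u_all <- apply(subsets, 2, function(s) sum(all_ranks[s]) - m * (m + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Linearly separable two-feature toy problem (margin ~3 sd).
separable_toy <- function(n_per_class = 10, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * 2, 3, 1), n_per_class),
               matrix(rnorm(n_per_class * 2, -3, 1), n_per_class))
    list(X = scale(X), y = rep(c(1, 0), each = n_per_class))
  })
}
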