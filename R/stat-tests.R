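# Two-sample tests used by gene selection. Scalar front-ends implement the
# documented contracts; row-wise variants apply the same rules across a
# gene-by-sample matrix, which is what makes 100-trial bagging over
# thousands of genes affordable.

#' Two-sided pooled-variance Student's t-test p-value
#'
#' The classic equal-variance two-sample t. Returns `NA` with a warning for
#' degenerate input (zero pooled variance), in which case callers skip the
#' gene.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return Two-sided p-value in \[0, 1\], or `NA` if the pooled variance is 0.
#' @examples
#' student_t_pvalue(c(1, 2), c(3, 4)) # ~0.1056
#' @export
student_t_pvalue <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop_data("student_t_pvalue needs >= 2 observations per group")
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (!is.finite(sp2) || sp2 <= 0) {
    warning("zero pooled variance; p-value undefined")
    return(NA_real_)
  }
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(-abs(tstat), df = nx + ny - 2)
}

# Row-wise pooled-variance t p-values: X, Y numeric matrices with equal
# rownames, samples in columns. Rows with zero pooled variance give NA.
row_t_pvalues <- function(X, Y) {
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2); vy <- rowSums((Y - my)^2)
  sp2 <- (vx + vy) / (nx + ny - 2)
  tstat <- (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * stats::pt(-abs(tstat), df = nx + ny - 2)
  p[!is.finite(sp2) | sp2 <= 0] <- NA_real_
  p
}

#' Two-sided Mann-Whitney U test p-value
#'
#' Uses the exact null distribution of U when the pooled sample size is at
#' most 12 and there are no ties; otherwise the normal approximation with
#' tie correction and continuity correction. Always defined.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return Two-sided p-value in \[0, 1\].
#' @examples
#' mann_whitney_pvalue(c(1, 2, 3), c(4, 5, 6)) # exact, 0.1
#' @export
mann_whitney_pvalue <- function(x, y) {
  if (length(x) < 1 || length(y) < 1)
    stop_data("mann_whitney_pvalue needs non-empty groups")
  m <- length(x); n <- length(y)
  v <- c(x, y)
  r <- rank(v)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(v)
  has_ties <- any(ties > 1)
  if (m + n <= 12 && !has_ties) {
    p <- if (U > m * n / 2) {
      2 * stats::pwilcox(U - 1, m, n, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, m, n)
    }
    return(min(1, p))
  }
  mu <- m * n / 2
  tie_term <- sum(ties^3 - ties) / ((m + n) * (m + n - 1))
  sigma <- sqrt(m * n / 12 * (m + n + 1 - tie_term))
  if (sigma == 0) return(1)  # all values identical: no evidence either way
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sigma  # continuity correction toward the mean
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Row-wise Mann-Whitney p-values under the same exact/approximate switching
# rule. X, Y matrices with samples in columns; returns one p per row.
#
# All rows are ranked with a single order() call by lifting each row into
# its own disjoint value range (an additive per-row offset larger than the
# data range). Midranks and the tie-correction term are computed
# vectorized from runs of equal values in the sorted stream; ties are
# common here because bagging resamples columns with replacement.
row_mw_pvalues <- function(X, Y) {
  m <- ncol(X); n <- ncol(Y)
  M <- cbind(X, Y)
  N <- m + n
  G <- nrow(M)
  step <- diff(range(M)) + 1
  v <- as.vector(t(M)) + rep.int(seq_len(G) - 1, rep.int(N, G)) * step
  o <- order(v)
  vs <- v[o]
  # runs of equal values never cross a row boundary (offsets >= 1 apart)
  run_start <- which(c(TRUE, diff(vs) != 0))
  run_len <- diff(c(run_start, G * N + 1))
  pos_in_row <- rep.int(seq_len(N), G)            # sequential sorted position
  midrank <- rep.int(pos_in_row[run_start] + (run_len - 1) / 2, run_len)
  r <- numeric(G * N)
  r[o] <- midrank
  R <- matrix(r, G, N, byrow = TRUE)
  tie_term <- numeric(G)
  tied <- run_len > 1
  if (any(tied)) {
    contrib <- rowsum(run_len[tied]^3 - run_len[tied],
                      (run_start[tied] - 1) %/% N + 1)
    tie_term[as.integer(rownames(contrib))] <- contrib
  }
  any_tie <- tie_term > 0
  U <- rowSums(R[, seq_len(m), drop = FALSE]) - m * (m + 1) / 2
  p <- numeric(G)
  exact <- (N <= 12) & !any_tie
  if (any(exact)) {
    u <- U[exact]
    hi <- u > m * n / 2
    pe <- numeric(length(u))
    pe[hi] <- 2 * stats::pwilcox(u[hi] - 1, m, n, lower.tail = FALSE)
    pe[!hi] <- 2 * stats::pwilcox(u[!hi], m, n)
    p[exact] <- pmin(1, pe)
  }
  if (any(!exact)) {
    idx <- which(!exact)
    sigma <- sqrt(m * n / 12 * (N + 1 - tie_term[idx] / (N * (N - 1))))
    z <- U[idx] - m * n / 2
    z <- (z - sign(z) * 0.5) / sigma
    pa <- 2 * stats::pnorm(-abs(z))
    pa[sigma == 0] <- 1
    p[idx] <- pmin(1, pa)
  }
  names(p) <- rownames(M)
  p
}
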