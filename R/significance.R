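#' Resampling null distribution of association scores
#'
#' Generates a per-pair null distribution of PLS association scores by
#' decoupled resampling: in each iteration the sample rows of the miRNA
#' matrix and of the mRNA matrix are resampled with replacement
#' independently of each other, destroying any miRNA-mRNA pairing (and any
#' shared-condition alignment) while preserving each matrix's marginal
#' structure; the association scores are then recomputed from scratch on
#' the resampled data. This is the exchangeability null used to calibrate
#' empirical p-values.
#'
#' Degenerate resamples in which a matrix collapses to a single distinct
#' sample row (zero variance everywhere) are redrawn; all draws consume the
#' seeded random stream, so results are reproducible.
#'
#' @param X samples x miRNAs matrix.
#' @param Y samples x mRNAs matrix.
#' @param candidates candidate pair set (data frame with `mirna_id`,
#'   `mrna_id`); null scores are recorded for these pairs only.
#' @param n_boot number of resampling iterations (default 1000; fewer than
#'   100 gives unstable p-values at the 0.01 level and triggers a warning).
#' @param ncomp latent components for the PLS score (default 3).
#' @param seed integer seed.
#' @param paired if TRUE, resample rows keeping the X-Y pairing intact
#'   (case bootstrap, used for stability-based significance) instead of
#'   decoupling the two matrices.
#' @return n_boot x n_pairs numeric matrix of null (or bootstrap) scores;
#'   columns named "mirna_id|mrna_id".
#' @export
resample_null <- function(X, Y, candidates, n_boot = 1000, ncomp = 3,
                          seed = 1L, paired = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  candidates <- as_candidate_pairs(candidates)
  if (n_boot < 100)
    warning("n_boot < 100 gives unstable p-values at the 0.01 level")
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  idx <- cbind(match(candidates$mrna_id, colnames(Y)),
               match(candidates$mirna_id, colnames(X)))
  if (anyNA(idx)) stop("candidate ids missing from the expression matrices")
  out <- matrix(NA_real_, n_boot, nrow(candidates))
  colnames(out) <- paste(candidates$mirna_id, candidates$mrna_id, sep = "|")
  set.seed(as.integer(seed))
  for (b in seq_len(n_boot)) {
    ix <- .resample_rows(X, n)
    iy <- if (paired) ix else .resample_rows(Y, n)
    sc <- .autoscale(X[ix, , drop = FALSE], Y[iy, , drop = FALSE], TRUE)
    S <- .assoc_krylov(sc$Xs, sc$Ys, ncomp)
    out[b, ] <- S[idx]
  }
  out
}

# draw a bootstrap row index whose resampled matrix keeps variance in
# every column (continuous data: requires >= 2 distinct rows)
.resample_rows <- function(M, n, max_tries = 1000L) {
  for (k in seq_len(max_tries)) {
    ix <- sample.int(n, n, replace = TRUE)
    if (length(unique(ix)) < 2L) next
    sub <- M[ix, , drop = FALSE]
    if (all(.col_sds(sub) > 0)) return(ix)
  }
  stop("could not draw a non-degenerate resample")
}

# column sds without extra dependencies
.col_sds <- function(M) {
  mu <- colMeans(M)
  sqrt(colSums(sweep(M, 2L, mu)^2) / (nrow(M) - 1))
}

#' Empirical p-value from a null sample
#'
#' Two-sided add-one estimator: p = (1 + #\{|null| >= |observed|\}) /
#' (1 + n), never exactly zero, with resolution 1/(n+1).
#'
#' @param observed observed association score.
#' @param null_samples numeric vector of null scores for the same pair.
#' @return p-value in (0, 1].
#' @export
empirical_p <- function(observed, null_samples) {
  null_samples <- null_samples[!is.na(null_samples)]
  if (length(null_samples) == 0L) stop("null_samples must be non-empty")
  (1 + sum(abs(null_samples) >= abs(observed))) / (1 + length(null_samples))
}

#' Significance of candidate miRNA-mRNA associations
#'
#' Computes the association score of every candidate pair and attaches a
#' resampling p-value and a Benjamini-Hochberg FDR (computed over the
#' candidate pairs only). Two resampling modes are available:
#'
#' \describe{
#'   \item{`"bootstrap"` (default)}{Case bootstrap: sample rows are
#'     resampled with replacement keeping the miRNA-mRNA pairing; the
#'     two-sided p-value is the sign-crossing rate of the bootstrap score
#'     distribution, p = min(1, 2 (1 + #\{sign(S*) != sign(S)\}) /
#'     (1 + n_boot)). This measures the stability of the observed
#'     association under resampling of the biological replicates and
#'     retains resolution 2/(n_boot+1) even at very small N.}
#'   \item{`"decoupled"`}{Exchangeability null: rows of X and Y resampled
#'     independently (see [resample_null()]); p is the two-sided empirical
#'     tail probability of |S| under that null ([empirical_p()]). Well
#'     calibrated, but at very small sample sizes the chance-alignment
#'     tail of the null limits power.}
#' }
#'
#' @param X samples x miRNAs matrix.
#' @param Y samples x mRNAs matrix.
#' @param candidates candidate pair set.
#' @param n_boot resampling iterations (default 1000).
#' @param ncomp latent components (default 3).
#' @param seed integer seed.
#' @param method `"bootstrap"` or `"decoupled"`, see above.
#' @param b_threshold,p_threshold,fdr_threshold thresholds used to set the
#'   `significant` flag: |score| > b_threshold, p < p_threshold and
#'   FDR < fdr_threshold must all hold.
#' @return data frame of class `pair_significance` with columns `mirna_id`,
#'   `mrna_id`, `score`, `b` (= |score|), `p_value`, `fdr`, `significant`.
#' @export
pair_significance <- function(X, Y, candidates, n_boot = 1000, ncomp = 3,
                              seed = 1L,
                              method = c("bootstrap", "decoupled"),
                              b_threshold = 0.8, p_threshold = 0.01,
                              fdr_threshold = 0.05) {
  method <- match.arg(method)
  X <- as.matrix(X); Y <- as.matrix(Y)
  candidates <- as_candidate_pairs(candidates)
  S <- association_scores(X, Y, ncomp = ncomp)
  obs <- score_candidate_pairs(S, candidates)
  res <- resample_null(X, Y, candidates, n_boot = n_boot, ncomp = ncomp,
                       seed = seed, paired = (method == "bootstrap"))
  if (method == "bootstrap") {
    flips <- colSums(sign(res) != rep(sign(obs$score), each = nrow(res)))
    p <- pmin(1, 2 * (1 + flips) / (1 + nrow(res)))
  } else {
    p <- vapply(seq_len(ncol(res)),
                function(k) empirical_p(obs$score[k], res[, k]),
                numeric(1))
  }
  out <- data.frame(mirna_id = obs$mirna_id, mrna_id = obs$mrna_id,
                    score = obs$score, b = abs(obs$score),
                    p_value = p, fdr = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out$significant <- out$b > b_threshold & out$p_value < p_threshold &
    out$fdr < fdr_threshold
  class(out) <- c("pair_significance", "data.frame")
  out
}

#' Filter pairs by the triple significance threshold
#'
#' Keeps the pairs with |score| above `b_threshold`, resampling p-value
#' below `p_threshold` and FDR below `fdr_threshold`, sorted by decreasing
#' |score|. Optionally restricts to negative (repression-sign) scores.
#'
#' @param pairs a [pair_significance()] data frame (columns `score`, `b`,
#'   `p_value`, `fdr`).
#' @param b_threshold minimum |score| for an edge (default 0.8).
#' @param p_threshold maximum p-value (default 0.01).
#' @param fdr_threshold maximum FDR (default 0.05).
#' @param negative_only if TRUE, additionally require score < 0
#'   (repression-only filter).
#' @return the significant subset, sorted by `b` descending.
#' @export
call_significant <- function(pairs, b_threshold = 0.8, p_threshold = 0.01,
                             fdr_threshold = 0.05, negative_only = FALSE) {
  stopifnot(all(c("score", "b", "p_value", "fdr") %in% names(pairs)))
  keep <- pairs$b > b_threshold & pairs$p_value < p_threshold &
    pairs$fdr < fdr_threshold
  if (negative_only) keep <- keep & pairs$score < 0
  out <- pairs[keep, , drop = FALSE]
  out <- out[order(-out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
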