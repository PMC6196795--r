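#' Background correction by floored subtraction
#'
#' Subtracts a background estimate from raw (non-log) intensities, floors
#' the result at a small positive value to avoid non-positive intensities,
#' and adds a stabilizing offset: corrected = max(value - background,
#' floor) + offset. This is a deliberately simple, monotone substitute for
#' model-based background correction of scanner intensities; the defaults
#' (floor 0.5, offset 16) are the values conventionally used when
#' preparing intensities for log transformation.
#'
#' @param values numeric matrix of raw intensities (>= 0).
#' @param background background estimate, a scalar or a matrix conformable
#'   with `values`.
#' @param floor lower bound applied after subtraction (must be >= 0).
#' @param offset constant added after flooring.
#' @return corrected matrix, same shape as `values`.
#' @examples
#' background_correct(matrix(100), background = 30)  # 70 + 16 = 86
#' @export
background_correct <- function(values, background = 0, floor = 0.5,
                               offset = 16) {
  if (floor < 0) stop("floor must be >= 0")
  values <- as.matrix(values)
  if (any(values < 0)) stop("raw intensities must be >= 0")
  pmax(values - background, floor) + offset
}

#' Quantile normalization
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the vector of cross-column means of the order statistics. Ties are
#' resolved by averaging tied ranks. A single-column matrix is returned
#' unchanged. Delegates to `limma::normalizeQuantiles`.
#'
#' @param values numeric matrix, features x samples, no missing values.
#' @return normalized matrix, same shape and dimnames.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing values are not allowed")
  if (ncol(values) <= 1L) return(values)
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Moderated two-sample t-test with empirical-Bayes variance shrinkage
#'
#' Per-feature two-sample t-statistics in which the residual variance is
#' shrunk towards a pooled prior. The prior is a scaled inverse-chi-square
#' with parameters (d0, s0^2) estimated from all features by the method of
#' moments on the log sample variances: with z_g = log s_g^2 and d residual
#' degrees of freedom per feature, E z = log s0^2 + digamma(d/2) -
#' digamma(d0/2) + log(d0/d) and Var z = trigamma(d/2) + trigamma(d0/2),
#' so d0 solves trigamma(d0/2) = var(z) - trigamma(d/2) (d0 = Inf, full
#' pooling, when the right-hand side is non-positive). The moderated
#' variance is s~_g^2 = (d0 s0^2 + d s_g^2) / (d0 + d) and the statistic is
#' referred to a t distribution with d + d0 degrees of freedom.
#'
#' @param values numeric matrix (log2 intensities), features x samples.
#' @param condition factor/character of length ncol(values) with exactly
#'   two levels; the second level (or `"treated"` if present) is the
#'   treatment. At least two samples per condition are required.
#' @param prior_df optional override of the prior degrees of freedom d0
#'   (0 = classical unmoderated t; Inf = fully pooled variance).
#' @return data frame with columns `feature_id`, `log2_fc` (treated minus
#'   control mean), `t_stat`, `p_value`, `adj_p` (Benjamini-Hochberg over
#'   all features), `direction` (`"up"`/`"down"`).
#' @export
moderated_t_test <- function(values, condition, prior_df = NULL) {
  values <- as.matrix(values)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("condition must have exactly two levels")
  lv <- levels(condition)
  treated_level <- if ("treated" %in% lv) "treated" else lv[2]
  g2 <- condition == treated_level
  g1 <- !g2
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 replicates per condition")
  if (anyNA(values)) stop("missing values are not allowed")

  m1 <- rowMeans(values[, g1, drop = FALSE])
  m2 <- rowMeans(values[, g2, drop = FALSE])
  v1 <- apply(values[, g1, drop = FALSE], 1L, stats::var)
  v2 <- apply(values[, g2, drop = FALSE], 1L, stats::var)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d  # pooled within-group variance

  if (all(s2 == 0)) {
    warning("zero within-group variance for all features; ",
            "falling back to unmoderated t")
    d0 <- 0; s02 <- 0
  } else if (!is.null(prior_df)) {
    d0 <- prior_df
    s02 <- if (d0 > 0) exp(mean(log(s2[s2 > 0]))) else 0
  } else {
    pr <- .fit_variance_prior(s2[s2 > 0], d)
    d0 <- pr$d0; s02 <- pr$s02
  }

  if (is.infinite(d0)) {
    s2_mod <- rep(s02, length(s2)); df_total <- Inf
  } else if (d0 == 0) {
    s2_mod <- s2; df_total <- d
  } else {
    s2_mod <- (d0 * s02 + d * s2) / (d0 + d); df_total <- d + d0
  }
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  lfc <- m2 - m1
  t_stat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_stat)) else
    2 * stats::pt(-abs(t_stat), df = df_total)
  p[t_stat == 0] <- 1

  ids <- rownames(values)
  if (is.null(ids)) ids <- sprintf("feature%04d", seq_len(nrow(values)))
  data.frame(feature_id = ids, log2_fc = lfc, t_stat = t_stat,
             p_value = p, adj_p = bh_adjust(p),
             direction = ifelse(lfc >= 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# method-of-moments fit of the scaled inverse-chi-square variance prior
# on log sample variances (d residual df per feature)
.fit_variance_prior <- function(s2, d) {
  z <- log(s2)
  ez <- mean(z)
  vz <- stats::var(z)
  if (length(z) < 2L || !is.finite(vz)) return(list(d0 = Inf, s02 = exp(ez)))
  rhs <- vz - trigamma(d / 2)
  if (rhs <= 0) {
    d0 <- Inf
    s02 <- exp(ez - digamma(d / 2) + log(d / 2))
  } else {
    d0 <- 2 * .trigamma_inverse(rhs)
    s02 <- exp(ez + digamma(d0 / 2) - digamma(d / 2) - log(d0 / d))
  }
  list(d0 = d0, s02 = s02)
}

# Newton inversion of trigamma on (0, Inf)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sorted p-values are scaled by m/rank and made
#' monotone from the largest down, capped at 1. Input is validated to lie
#' in \[0, 1\]; the adjustment itself is `stats::p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select differentially expressed features
#'
#' Features with adjusted p-value below `alpha`, partitioned by direction
#' of change.
#'
#' @param results data frame from [moderated_t_test()].
#' @param alpha adjusted-p threshold (default 0.05).
#' @return list with components `up`, `down` (feature ids by direction)
#'   and `all` (their union, in the input order).
#' @export
select_de <- function(results, alpha = 0.05) {
  stopifnot(all(c("feature_id", "adj_p", "direction") %in% names(results)))
  sig <- results[results$adj_p < alpha, , drop = FALSE]
  list(up = sig$feature_id[sig$direction == "up"],
       down = sig$feature_id[sig$direction == "down"],
       all = sig$feature_id)
}
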