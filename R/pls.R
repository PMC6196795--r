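#' Partial least squares regression of mRNA profiles on miRNA profiles
#'
#' Fits, for every response (mRNA), a PLS regression of its expression
#' profile on the full set of miRNA expression profiles across samples,
#' using the NIPALS deflation algorithm. Latent components are extracted
#' per response: component l of response i is t_i^(l) = X_(l) w, with
#' w proportional to the covariance of the (deflated) predictors with the
#' response, and the component coefficient is the ordinary least-squares
#' regression of the response on that score, beta_il = t'y / t't. After
#' each component the predictor matrix is deflated by the extracted score
#' direction, which makes the scores of one response mutually orthogonal.
#'
#' Both matrices are oriented samples x features (N rows). Columns are
#' mean-centered and, by default, scaled to unit standard deviation
#' (autoscaling), so that derived coefficients are standardized and
#' comparable across gene pairs. The algorithm is deterministic: for a
#' single response NIPALS requires no iteration and no starting value.
#'
#' @param X numeric matrix, N samples x p miRNAs (predictors).
#' @param Y numeric matrix (or vector), N samples x m mRNAs (responses).
#' @param ncomp number of latent components v; must satisfy v < N.
#' @param scale logical; autoscale columns to unit variance (default TRUE).
#' @param tol relative tolerance below which a deflated direction is
#'   treated as numerically zero and extraction stops early.
#' @return An object of class `pls_fit`:
#'   \describe{
#'     \item{scores}{N x v x m array; `scores[, l, i]` is t_i^(l).}
#'     \item{weights, loadings}{p x v x m arrays of predictor weights and
#'       loadings per response.}
#'     \item{y_coefficients}{m x v matrix of component coefficients
#'       beta_il.}
#'     \item{coefficients}{p x m matrix of per-response coefficients mapped
#'       back to predictor space (standardized scale when `scale = TRUE`).}
#'     \item{residuals}{N x m matrix e_i on the centered/scaled scale.}
#'     \item{ncomp_used}{integer vector: components actually extracted per
#'       response (less than v only for degenerate responses).}
#'   }
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(NULL, paste0("miR", 1:3)))
#' y <- X[, 1] - X[, 2] + rnorm(6, sd = 0.1)
#' fit <- fit_pls(X, y, ncomp = 2)
#' crossprod(fit$scores[, , 1])  # diagonal: per-response scores orthogonal
#' @export
fit_pls <- function(X, Y, ncomp = 3, scale = TRUE, tol = 1e-10) {
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows (samples)")
  if (ncomp >= n) stop("ncomp must be smaller than the number of samples N")
  if (ncomp < 1) stop("ncomp must be at least 1")
  if (anyNA(X) || anyNA(Y)) stop("missing values are not allowed")
  sc <- .autoscale(X, Y, scale)
  Xs <- sc$Xs; Ys <- sc$Ys
  p <- ncol(Xs); m <- ncol(Ys)

  scores <- array(0, c(n, ncomp, m))
  weights <- array(0, c(p, ncomp, m))
  loadings <- array(0, c(p, ncomp, m))
  beta <- matrix(0, m, ncomp)
  B <- matrix(0, p, m)
  resid <- matrix(0, n, m)
  used <- integer(m)

  for (i in seq_len(m)) {
    y <- Ys[, i]
    Xd <- Xs; yd <- y
    w0 <- sqrt(sum(crossprod(Xs, y)^2))
    li <- 0L
    for (l in seq_len(ncomp)) {
      w <- crossprod(Xd, yd)
      nw <- sqrt(sum(w^2))
      if (nw <= tol * max(w0, 1)) break
      w <- w / nw
      tt <- drop(Xd %*% w)
      ss <- sum(tt^2)
      if (ss <= tol^2) break
      bl <- sum(tt * yd) / ss
      pl <- drop(crossprod(Xd, tt)) / ss
      Xd <- Xd - tcrossprod(tt, pl)
      yd <- yd - bl * tt
      scores[, l, i] <- tt
      weights[, l, i] <- w
      loadings[, l, i] <- pl
      beta[i, l] <- bl
      li <- l
    }
    used[i] <- li
    if (li > 0L) {
      Wi <- weights[, seq_len(li), i, drop = TRUE]
      Pi <- loadings[, seq_len(li), i, drop = TRUE]
      Wi <- matrix(Wi, p, li); Pi <- matrix(Pi, p, li)
      B[, i] <- Wi %*% solve(crossprod(Pi, Wi), beta[i, seq_len(li)])
    }
    resid[, i] <- yd
  }
  structure(list(
    scores = scores, weights = weights, loadings = loadings,
    y_coefficients = beta, coefficients = B, residuals = resid,
    ncomp = ncomp, ncomp_used = used,
    x_mean = sc$x_mean, y_mean = sc$y_mean, x_sd = sc$x_sd, y_sd = sc$y_sd,
    scaled = scale, x_names = colnames(X), y_names = colnames(Y)
  ), class = "pls_fit")
}

.autoscale <- function(X, Y, scale) {
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  x_sd <- apply(X, 2L, stats::sd); y_sd <- apply(Y, 2L, stats::sd)
  if (any(x_sd == 0))
    stop("zero_variance_column: predictor column(s) ",
         paste(which(x_sd == 0), collapse = ", "), " have zero variance")
  if (any(y_sd == 0))
    stop("zero_variance_column: response column(s) ",
         paste(which(y_sd == 0), collapse = ", "), " have zero variance")
  Xs <- sweep(X, 2L, x_mean); Ys <- sweep(Y, 2L, y_mean)
  if (scale) {
    Xs <- sweep(Xs, 2L, x_sd, "/"); Ys <- sweep(Ys, 2L, y_sd, "/")
  }
  list(Xs = Xs, Ys = Ys, x_mean = x_mean, y_mean = y_mean,
       x_sd = x_sd, y_sd = y_sd)
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("Per-response PLS fit:", length(x$x_sd), "predictors,",
      length(x$y_sd), "responses,", x$ncomp, "components\n")
  invisible(x)
}

#' Association score matrix between miRNAs and mRNAs
#'
#' Computes the PLS association score for every (mRNA i, miRNA j) pair.
#' On autoscaled data the score of pair (i, j) aggregates the component
#' coefficients of response i weighted by the loading of miRNA j on each of
#' response i's latent components,
#' S_ij = sum_l beta_il p_ijl ||t_i^(l)||^2 / (N - 1),
#' which equals the sample correlation of x_j and y_i computed inside the
#' v-dimensional PLS latent space of response i (the projection of their
#' standardized profiles onto span of the latent scores). Scores are
#' unit-free on the correlation scale; the sign is preserved, negative
#' scores indicating putative repression. For a single predictor and a
#' single component the score is exactly the Pearson correlation.
#'
#' The fast path (matrix input) exploits the Krylov-space characterization
#' of PLS1: the latent space of response i is
#' span\{Gy_i, G^2 y_i, ..., G^v y_i\} with G = XX', which allows all
#' responses to be scored with a handful of matrix products. It agrees with
#' the component-wise formula evaluated on a [fit_pls()] object.
#'
#' @param X samples x miRNAs matrix, or a fitted `pls_fit` object.
#' @param Y samples x mRNAs matrix (ignored when `X` is a fit).
#' @param ncomp number of latent components (default 3).
#' @return m x p numeric matrix (rows mRNAs, columns miRNAs) of scores,
#'   with attributes `sd_x` and `sd_y` (per-feature sample sds). Scores are
#'   always defined on autoscaled data; a `pls_fit` must have been fitted
#'   with `scale = TRUE`.
#' @export
association_scores <- function(X, Y = NULL, ncomp = 3) {
  if (inherits(X, "pls_fit")) return(.assoc_from_fit(X))
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows (samples)")
  if (ncomp >= n) stop("ncomp must be smaller than the number of samples N")
  sc <- .autoscale(X, Y, scale = TRUE)  # scores are defined on autoscaled data
  S <- .assoc_krylov(sc$Xs, sc$Ys, ncomp)
  dimnames(S) <- list(colnames(Y), colnames(X))
  attr(S, "sd_x") <- sc$x_sd
  attr(S, "sd_y") <- sc$y_sd
  S
}

# Latent-projection association via the Krylov basis of G = XX',
# vectorized over responses with a blockwise Gram-Schmidt.
.assoc_krylov <- function(Xs, Ys, ncomp, gs_tol = 1e-8) {
  n <- nrow(Xs); m <- ncol(Ys)
  G <- tcrossprod(Xs)
  Q <- vector("list", ncomp)
  V <- Ys
  for (l in seq_len(ncomp)) {
    V <- G %*% V
    # rescale for conditioning (span is scale-free)
    nv <- sqrt(colSums(V^2))
    V <- sweep(V, 2L, pmax(nv, 1e-300), "/")
    R <- V
    for (k in seq_len(l - 1L)) {
      R <- R - sweep(Q[[k]], 2L, colSums(Q[[k]] * R), "*")
    }
    nr <- sqrt(colSums(R^2))
    keep <- nr > gs_tol
    R <- sweep(R, 2L, pmax(nr, 1e-300), "/")
    R[, !keep] <- 0  # Krylov space exhausted for these responses
    Q[[l]] <- R
  }
  S <- matrix(0, m, ncol(Xs))
  for (l in seq_len(ncomp)) {
    a <- colSums(Ys * Q[[l]])              # y_i' q_il
    S <- S + a * crossprod(Q[[l]], Xs)     # + a_i (q_il' x_j)
  }
  S / (n - 1)
}

# Component-wise evaluation of the same score from a stored fit.
.assoc_from_fit <- function(fit) {
  if (!fit$scaled)
    stop("association scores are defined on autoscaled data; ",
         "refit with scale = TRUE")
  n <- nrow(fit$residuals)
  m <- length(fit$y_sd); p <- length(fit$x_sd)
  S <- matrix(0, m, p)
  for (i in seq_len(m)) {
    li <- fit$ncomp_used[i]
    if (li == 0L) next
    for (l in seq_len(li)) {
      ss <- sum(fit$scores[, l, i]^2)
      S[i, ] <- S[i, ] + fit$y_coefficients[i, l] * fit$loadings[, l, i] * ss
    }
  }
  S <- S / (n - 1)
  dimnames(S) <- list(fit$y_names, fit$x_names)
  attr(S, "sd_x") <- fit$x_sd
  attr(S, "sd_y") <- fit$y_sd
  S
}

#' Attach association scores to sequence-supported candidate pairs
#'
#' Only candidate pairs (sequence-supported miRNA-mRNA pairs) may become
#' network edges; this restricts the full score matrix to those pairs.
#'
#' @param assoc m x p association score matrix from [association_scores()]
#'   (rows mRNAs, columns miRNAs).
#' @param candidates candidate pair set: a data frame with columns
#'   `mirna_id`, `mrna_id` (see [candidate_pairs()]).
#' @return data frame with columns `mirna_id`, `mrna_id`, `score`.
#' @export
score_candidate_pairs <- function(assoc, candidates) {
  candidates <- as_candidate_pairs(candidates)
  if (nrow(candidates) == 0L) {
    return(data.frame(mirna_id = character(), mrna_id = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  bad_mirna <- setdiff(candidates$mirna_id, colnames(assoc))
  bad_mrna <- setdiff(candidates$mrna_id, rownames(assoc))
  if (length(bad_mirna) || length(bad_mrna)) {
    stop("unknown ids in candidate set: ",
         paste(c(bad_mirna, bad_mrna), collapse = ", "))
  }
  idx <- cbind(match(candidates$mrna_id, rownames(assoc)),
               match(candidates$mirna_id, colnames(assoc)))
  data.frame(mirna_id = candidates$mirna_id,
             mrna_id = candidates$mrna_id,
             score = assoc[idx],
             stringsAsFactors = FALSE)
}
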