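#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive-class value exceeds a randomly chosen negative-class value,
#' ties counted half, AUC = (#\{pos > neg\} + 0.5 #\{pos = neg\}) /
#' (n_pos n_neg). Computed via ranks in O(n log n).
#'
#' @param values numeric vector (e.g. expression of one miRNA across
#'   samples).
#' @param labels logical/binary vector, TRUE (or 1, or the level
#'   `"treated"`) marking the positive class; both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(values, labels) {
  lab <- .as_binary_labels(labels)
  if (length(values) != length(lab)) stop("values and labels differ in length")
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L)
    stop("single_class: both classes must be present")
  r <- rank(values, ties.method = "average")
  (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  labels <- as.character(labels)
  u <- sort(unique(labels))
  if (length(u) > 2L) stop("labels must be binary")
  pos <- if ("treated" %in% u) "treated" else u[length(u)]
  labels == pos
}

#' ROC metrics at the optimal cutoff
#'
#' Sweeps all midpoint cutoffs between adjacent distinct values (plus the
#' two open ends), classifying a sample as positive when its value exceeds
#' the cutoff (or falls below it, when the positive class runs low:
#' direction is chosen so that the ROC curve lies above the diagonal,
#' i.e. by the sign of AUC - 0.5). The reported cutoff maximizes Youden's
#' J = sensitivity + specificity - 1; ties are broken towards higher
#' specificity. Accuracy is (TP + TN) / n at that cutoff.
#'
#' @inheritParams auc
#' @return list of class `roc_metrics`: `auc`, `sensitivity`,
#'   `specificity`, `accuracy`, `cutoff`, `direction` (`">"` when high
#'   values predict the positive class).
#' @export
roc_metrics <- function(values, labels) {
  lab <- .as_binary_labels(labels)
  a <- auc(values, lab)
  direction <- if (a >= 0.5) ">" else "<"
  v <- sort(unique(values))
  cuts <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + 1)
  n_pos <- sum(lab); n_neg <- sum(!lab)
  best <- NULL
  for (cut in cuts) {
    pred <- if (direction == ">") values > cut else values < cut
    sens <- sum(pred & lab) / n_pos
    spec <- sum(!pred & !lab) / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
      best <- list(j = j, sens = sens, spec = spec, cut = cut,
                   acc = (sum(pred & lab) + sum(!pred & !lab)) /
                     length(lab))
    }
  }
  structure(list(auc = a, sensitivity = best$sens, specificity = best$spec,
                 accuracy = best$acc, cutoff = best$cut,
                 direction = direction),
            class = "roc_metrics")
}

#' @export
print.roc_metrics <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f | sens %.3f spec %.3f acc %.3f at cutoff %.4g (%s)\n",
    x$auc, x$sensitivity, x$specificity, x$accuracy, x$cutoff,
    x$direction))
  invisible(x)
}

#' Load the packaged per-miRNA ROC metrics table
#'
#' The packaged table of per-miRNA ROC metrics (AUC, sensitivity,
#' specificity, accuracy) for the 13 drought-responsive miRNAs, as
#' printed.
#'
#' @return data frame with columns `mirna`, `auc`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
load_table2_fixture <- function() {
  path <- .fixture_path("table2_roc_metrics.tsv",
                        "b02107acd1d928870705912fd223af1d")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Column summaries of a per-feature ROC metrics table
#'
#' Minimum, maximum and mean of each metric column.
#'
#' @param table2 data frame as returned by [load_table2_fixture()] (numeric
#'   metric columns besides the first id column).
#' @return data frame with one row per metric and columns `metric`, `min`,
#'   `max`, `mean`.
#' @export
summarize_fixture <- function(table2 = load_table2_fixture()) {
  num <- table2[vapply(table2, is.numeric, logical(1))]
  data.frame(metric = names(num),
             min = vapply(num, min, numeric(1)),
             max = vapply(num, max, numeric(1)),
             mean = vapply(num, mean, numeric(1)),
             row.names = NULL)
}

#' Hierarchical clustering of expression features
#'
#' Agglomerative clustering of the rows (features) of an expression
#' matrix, by default with centered Pearson correlation distance (1 - r)
#' and average linkage; uncentered (cosine-like) correlation and Euclidean
#' distance are available. Leaf order is made deterministic by seriating
#' ties by feature id.
#'
#' @param values numeric matrix, features x samples (>= 2 features).
#' @param metric `"pearson"`, `"uncentered"`, or `"euclidean"`.
#' @param linkage agglomeration method passed to `stats::hclust`
#'   (default `"average"`).
#' @return an object of class `hclust` (merge heights, topology and leaf
#'   `order`; labels are the feature ids).
#' @export
hierarchical_cluster <- function(values,
                                 metric = c("pearson", "uncentered",
                                            "euclidean"),
                                 linkage = "average") {
  metric <- match.arg(metric)
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("need >= 2 features to cluster")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("feature%04d", seq_len(nrow(values)))
  if (metric %in% c("pearson", "uncentered")) {
    if (metric == "pearson") {
      sds <- apply(values, 1L, stats::sd)
      if (any(sds == 0))
        stop("zero_variance_feature: ",
             paste(rownames(values)[sds == 0], collapse = ", "))
      d <- stats::as.dist(1 - stats::cor(t(values)))
    } else {
      norms <- sqrt(rowSums(values^2))
      if (any(norms == 0))
        stop("zero_variance_feature: ",
             paste(rownames(values)[norms == 0], collapse = ", "))
      sim <- tcrossprod(values / norms)
      d <- stats::as.dist(1 - sim)
    }
  } else {
    d <- stats::dist(values)
  }
  # order rows by id first so that tie-breaks inside hclust are
  # reproducible regardless of input order
  ord <- order(rownames(values))
  if (metric == "euclidean") {
    d <- stats::dist(values[ord, , drop = FALSE])
  } else {
    m <- as.matrix(d)[ord, ord]
    d <- stats::as.dist(m)
  }
  stats::hclust(d, method = linkage)
}

#' Write a dendrogram in Newick format
#'
#' Exports an `hclust` tree (e.g. from [hierarchical_cluster()]) as a
#' Newick string, with branch lengths derived from the merge heights
#' (via `ape::as.phylo`).
#'
#' @param hc an `hclust` object.
#' @param path optional file path; when omitted the string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
cluster_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  nw <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(path)) {
    writeLines(nw, path)
    return(invisible(nw))
  }
  nw
}
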