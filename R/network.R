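#' Build a bipartite miRNA-mRNA regulatory network
#'
#' Constructs the bipartite regulatory network from significance-filtered
#' miRNA-mRNA pairs: one node set of miRNAs, one of mRNAs, and a directed
#' edge miRNA -> mRNA per retained pair. Duplicate pairs collapse to a
#' single edge; an identifier appearing on both sides is rejected.
#'
#' @param pairs data frame with columns `mirna_id`, `mrna_id` and
#'   optionally `score` and `direction` (per-miRNA response, up/down).
#' @return object of class `reg_network`: list with `edges` (data frame),
#'   `mirnas`, `mrnas` (node id vectors) and per-miRNA `direction` (named
#'   vector, possibly NA).
#' @export
build_network <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("mirna_id", "mrna_id") %in% names(pairs)))
  both <- intersect(unique(pairs$mirna_id), unique(pairs$mrna_id))
  if (length(both))
    stop("id(s) appear as both miRNA and mRNA: ",
         paste(both, collapse = ", "))
  key <- paste(pairs$mirna_id, pairs$mrna_id, sep = "\r")
  edges <- pairs[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  direction <- rep(NA_character_, length(unique(edges$mirna_id)))
  names(direction) <- unique(edges$mirna_id)
  if ("direction" %in% names(edges)) {
    dd <- tapply(as.character(edges$direction), edges$mirna_id,
                 function(v) v[1])
    direction[names(dd)] <- dd
  }
  structure(list(edges = edges,
                 mirnas = unique(edges$mirna_id),
                 mrnas = unique(edges$mrna_id),
                 direction = direction),
            class = "reg_network")
}

#' @export
print.reg_network <- function(x, ...) {
  cat("Bipartite regulatory network:", length(x$mirnas), "miRNAs,",
      length(x$mrnas), "mRNAs,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Out- and in-degrees of a regulatory network
#'
#' @param net a [build_network()] object.
#' @return list with `out_degree` (targets per miRNA, named) and
#'   `in_degree` (regulators per mRNA, named).
#' @export
degree_summary <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  out_degree <- table(factor(net$edges$mirna_id, levels = net$mirnas))
  in_degree <- table(factor(net$edges$mrna_id, levels = net$mrnas))
  list(out_degree = stats::setNames(as.integer(out_degree),
                                    names(out_degree)),
       in_degree = stats::setNames(as.integer(in_degree),
                                   names(in_degree)))
}

#' Fit a power-law or exponential model to a degree distribution
#'
#' Tabulates the frequency of each degree value (zero-frequency degrees
#' are dropped, raw counts are used) and fits by ordinary least squares on
#' the linearizing transform: log10(freq) ~ log10(degree) for the power
#' law, log10(freq) ~ degree for the exponential. The slope/exponent and
#' the R-squared of that same regression are returned.
#'
#' @param degrees integer vector of node degrees (one entry per node).
#' @param model `"power_law"` or `"exponential"`.
#' @return list of class `degree_fit`: `model`, `slope` (power-law slope or
#'   exponential rate, both on the log10 scale of the regression),
#'   `r_squared`, and `points` (data frame degree/frequency used).
#' @export
fit_degree_distribution <- function(degrees,
                                    model = c("power_law", "exponential")) {
  model <- match.arg(model)
  degrees <- as.integer(degrees)
  tab <- table(degrees[degrees > 0])
  deg <- as.numeric(names(tab))
  freq <- as.numeric(tab)
  if (length(deg) < 3L)
    stop("need >= 3 distinct degree values to fit a distribution")
  xx <- if (model == "power_law") log10(deg) else deg
  fit <- stats::lm(log10(freq) ~ xx)
  # summary() warns on numerically perfect fits; the R^2 is still exact
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(model = model,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 points = data.frame(degree = deg, frequency = freq)),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("%s fit: slope %.4f, R^2 %.4f (%d degree values)\n",
              x$model, x$slope, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Find miRNA coregulatory modules
#'
#' Projects the bipartite network onto its miRNA side: two miRNAs are
#' linked when they share at least one target mRNA. Modules are the
#' connected components of that projection with at least two miRNAs
#' (singletons are not modules); each module reports the mRNAs targeted by
#' two or more of its miRNAs (the shared targets through which the module
#' is held together).
#'
#' @param net a [build_network()] object.
#' @return list of class `module_set`; each element has `mirna_ids` and
#'   `shared_mrna_ids`. Modules are ordered by decreasing size then by
#'   first miRNA id; empty list when no targets are shared.
#' @export
find_modules <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  e <- net$edges
  if (nrow(e) == 0L) return(structure(list(), class = "module_set"))
  # miRNA-miRNA projection edges via shared targets
  by_target <- split(e$mirna_id, e$mrna_id)
  proj <- unique(do.call(rbind, lapply(by_target, function(ms) {
    ms <- unique(ms)
    if (length(ms) < 2L) return(NULL)
    t(utils::combn(sort(ms), 2L))
  })))
  if (is.null(proj) || nrow(proj) == 0L)
    return(structure(list(), class = "module_set"))
  g <- igraph::graph_from_edgelist(proj, directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- Filter(function(v) length(v) >= 2L, groups)
  shared <- names(Filter(function(ms) length(unique(ms)) >= 2L, by_target))
  mods <- lapply(groups, function(ms) {
    tgt <- sort(intersect(shared,
                          unique(e$mrna_id[e$mirna_id %in% ms])))
    list(mirna_ids = sort(ms), shared_mrna_ids = tgt)
  })
  ord <- order(-vapply(mods, function(m) length(m$mirna_ids), integer(1)),
               vapply(mods, function(m) m$mirna_ids[1], character(1)))
  structure(unname(mods[ord]), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(length(x), "coregulatory module(s)\n")
  for (i in seq_along(x)) {
    cat(sprintf("  %d. {%s} via {%s}\n", i,
                paste(x[[i]]$mirna_ids, collapse = ", "),
                paste(x[[i]]$shared_mrna_ids, collapse = ", ")))
  }
  invisible(x)
}

#' Fraction of coregulated mRNAs
#'
#' The fraction of mRNA nodes regulated by two or more miRNAs (in-degree
#' at least 2), a summary of target multiplicity in the network.
#'
#' @param net a [build_network()] object.
#' @return scalar in \[0, 1\].
#' @export
coregulated_fraction <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  if (nrow(net$edges) == 0L) stop("empty network")
  deg <- degree_summary(net)$in_degree
  mean(deg >= 2L)
}

.fixture_path <- function(file, md5) {
  path <- system.file("extdata", file, package = "plsmirnet")
  if (path == "") path <- file.path("inst", "extdata", file)
  if (!file.exists(path)) stop("fixture not found: ", file)
  got <- unname(tools::md5sum(path))
  if (!identical(got, md5))
    stop("fixture checksum mismatch for ", file, ": ", got)
  path
}

#' Load the packaged drought miRNA-target network table
#'
#' Returns the packaged table of 13 drought-responsive rice miRNAs with
#' their per-miRNA response direction and predicted target lists, as
#' printed, together with the regulatory network induced by the listed
#' targets.
#'
#' Known transcription quirks of the printed table are preserved, not
#' repaired: the `target_no` column totals 67 while the listed names total
#' 66 (the osa-miR396g row lists 8 names against a stated 9), and the
#' prose total of 69 regulations among 58 mRNAs differs from both (the
#' listed names contain 57 unique targets). All counts computed by the
#' package derive from the listed names.
#'
#' @return list with `table` (the printed rows: mirna, family, response,
#'   target_no, targets) and `network` (a [build_network()] object with
#'   one edge per listed miRNA-target name).
#' @export
load_table1_fixture <- function() {
  path <- .fixture_path("table1_mirna_targets.tsv",
                        "19286004c24eb889dc89d8627eac2b96")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  target_list <- strsplit(tab$targets, ",\\s*")
  edges <- data.frame(
    mirna_id = rep(tab$mirna, lengths(target_list)),
    mrna_id = unlist(target_list),
    direction = rep(tolower(tab$response), lengths(target_list)),
    stringsAsFactors = FALSE)
  list(table = tab, network = build_network(edges))
}

#' Export a network as a SIF file
#'
#' Simple interaction format (one `source relation target` line per edge)
#' accepted by common network-visualization tools.
#'
#' @param net a [build_network()] object.
#' @param path output file path.
#' @param relation edge label (default `"represses"`).
#' @return invisibly, the path.
#' @export
write_sif <- function(net, path, relation = "represses") {
  stopifnot(inherits(net, "reg_network"))
  lines <- paste(net$edges$mirna_id, relation, net$edges$mrna_id,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Convert a regulatory network to an igraph object
#'
#' Bipartite igraph graph with a logical `type` vertex attribute (TRUE for
#' mRNAs) and any edge score carried over; usable for layout or GraphML
#' export via `igraph::write_graph`.
#'
#' @param net a [build_network()] object.
#' @return an igraph graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("mirna_id", "mrna_id"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = c(net$mirnas, net$mrnas),
                          type = rep(c(FALSE, TRUE),
                                     c(length(net$mirnas),
                                       length(net$mrnas)))))
  if ("score" %in% names(net$edges))
    igraph::E(g)$score <- net$edges$score
  g
}
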