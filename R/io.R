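#' Read and write expression matrices as TSV
#'
#' Expression matrices travel as UTF-8 TSV with a header row of sample ids
#' and the feature id in the first column (`feature_id`). Values are
#' written with full double precision (17 significant digits), so a
#' write/read round trip is bit-exact.
#'
#' @param values numeric matrix, features x samples, with dimnames.
#' @param path file path.
#' @return `read_expression_tsv` returns the numeric matrix with feature
#'   ids as rownames; `write_expression_tsv` returns the path invisibly.
#' @export
write_expression_tsv <- function(values, path) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("expression matrix must have feature ids as rownames")
  df <- data.frame(feature_id = rownames(values),
                   apply(values, 2L, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id")
    stop("parse error in ", path, ": first column must be feature_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("parse error in ", path, ": non-numeric values")
  rownames(m) <- df$feature_id
  if (anyDuplicated(rownames(m)))
    stop("parse error in ", path, ": duplicate feature ids")
  if (anyNA(m)) stop("parse error in ", path, ": missing values")
  m
}

#' Read and write sample condition maps
#'
#' Two-column TSV (`sample_id`, `condition`) pairing each sample with its
#' condition label (control/treated).
#'
#' @param condition factor or character vector named by sample id, or (for
#'   writing) unnamed with `sample_ids` given.
#' @param sample_ids sample ids (defaults to names of `condition`).
#' @param path file path.
#' @return `read_condition_tsv` returns a factor named by sample id.
#' @export
write_condition_tsv <- function(condition, path, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- names(condition)
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%d", seq_along(condition))
  utils::write.table(
    data.frame(sample_id = sample_ids,
               condition = as.character(condition)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_condition_tsv
#' @export
read_condition_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(df)))
    stop("parse error in ", path,
         ": need columns sample_id and condition")
  stats::setNames(factor(df$condition), df$sample_id)
}

#' Read and write candidate pair sets as TSV
#'
#' @param pairs a [candidate_pairs()] data frame.
#' @param path file path.
#' @return `read_candidate_tsv` returns a [candidate_pairs()] set.
#' @export
write_candidate_tsv <- function(pairs, path) {
  pairs <- as_candidate_pairs(pairs)
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidate_tsv
#' @export
read_candidate_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "mrna_id") %in% names(df)))
    stop("parse error in ", path,
         ": need columns mirna_id and mrna_id")
  as_candidate_pairs(df)
}

#' Read and write RNA sequences as FASTA
#'
#' Thin wrappers over Biostrings; sequences are handled as plain named
#' character vectors over A/C/G/U elsewhere in the package.
#'
#' @param seqs named character vector of RNA sequences.
#' @param path file path.
#' @return `read_fasta_rna` returns a named character vector.
#' @export
write_fasta_rna <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta_rna
#' @export
read_fasta_rna <- function(path) {
  x <- Biostrings::readRNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write simulated ground truth as JSON
#'
#' @param truth the `truth` element of a [simulate_dataset()] result.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
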