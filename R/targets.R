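#' Candidate miRNA-mRNA pair sets
#'
#' A candidate pair set records sequence-supported miRNA-mRNA pairs together
#' with the predictor(s) that proposed them. Pairs are unique; `source`
#' carries the provenance tag(s), with multiple predictors joined by `+`.
#'
#' @param mirna_id,mrna_id character vectors of equal length.
#' @param source provenance tag per pair (recycled).
#' @return data frame of class `candidate_pairs` with columns `mirna_id`,
#'   `mrna_id`, `source`, one row per unique pair.
#' @export
candidate_pairs <- function(mirna_id, mrna_id, source = "unknown") {
  df <- data.frame(mirna_id = as.character(mirna_id),
                   mrna_id = as.character(mrna_id),
                   source = rep_len(as.character(source),
                                    length(mirna_id)),
                   stringsAsFactors = FALSE)
  key <- paste(df$mirna_id, df$mrna_id, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("candidate_pairs", "data.frame")
  df
}

as_candidate_pairs <- function(x) {
  if (inherits(x, "candidate_pairs")) return(x)
  if (!is.data.frame(x) || !all(c("mirna_id", "mrna_id") %in% names(x)))
    stop("candidate pairs need columns mirna_id and mrna_id")
  candidate_pairs(x$mirna_id, x$mrna_id,
                  if ("source" %in% names(x)) x$source else "unknown")
}

.pair_key <- function(x) paste(x$mirna_id, x$mrna_id, sep = "\r")

#' Expectation penalty of a miRNA/target-site duplex
#'
#' Scores the complementarity between a miRNA (5'->3') and a same-length
#' target site on the transcript (5'->3'), pairing the two strands
#' antiparallel: miRNA position k pairs with site position L-k+1. Each
#' position contributes a penalty: 0 for a Watson-Crick pair, `gu` for a
#' G:U wobble, `mismatch` otherwise; the penalty is multiplied by
#' `core_multiplier` for miRNA positions within `core` (counted from the
#' miRNA 5' end), the region where plant miRNA-target pairing is most
#' constrained. The expectation is the total penalty; lower means a better
#' site, 0 means perfect complementarity.
#'
#' This scheme is a reconstruction of the expectation scoring used by
#' plant target-prediction servers; all penalties are configurable.
#'
#' @param mirna_seq miRNA sequence, 5'->3', over A/C/G/U (length 19-24).
#' @param site_seq candidate site on the transcript, 5'->3', same length.
#' @param mismatch,gu,gap penalties per mismatch, G:U wobble, and gap
#'   symbol (`-`).
#' @param core integer positions (miRNA 5'-based) whose penalty is doubled.
#' @param core_multiplier multiplier applied within `core`.
#' @return List of class `duplex_score`: `expectation`, and `alignment`, a
#'   string over `|` (match), `o` (G:U), `x` (mismatch), `-` (gap), ordered
#'   along the miRNA 5'->3'.
#' @examples
#' duplex_expectation("UGGAAGGGGCAUGCAGGGGAG",
#'                    "CUCCCCUGCAUGCCCCUUCCA")$expectation  # 0: perfect
#' @export
duplex_expectation <- function(mirna_seq, site_seq, mismatch = 1, gu = 0.5,
                               gap = 2, core = 2:13, core_multiplier = 2) {
  mir <- .check_rna(mirna_seq, "mirna_seq", gaps = FALSE)
  site <- .check_rna(site_seq, "site_seq", gaps = TRUE)
  L <- length(mir)
  if (L < 19L || L > 24L) stop("miRNA length must be 19-24 nt")
  if (length(site) != L)
    stop("site length must equal miRNA length (ungapped duplex)")
  partner <- rev(site)  # miRNA position k pairs with site position L-k+1
  pen <- numeric(L); sym <- character(L)
  wc <- .rna_comp
  for (k in seq_len(L)) {
    a <- mir[k]; b <- partner[k]
    if (b == "-") {
      pen[k] <- gap; sym[k] <- "-"
    } else if (wc[[a]] == b) {
      pen[k] <- 0; sym[k] <- "|"
    } else if ((a == "G" && b == "U") || (a == "U" && b == "G")) {
      pen[k] <- gu; sym[k] <- "o"
    } else {
      pen[k] <- mismatch; sym[k] <- "x"
    }
    if (k %in% core) pen[k] <- pen[k] * core_multiplier
  }
  structure(list(expectation = sum(pen),
                 alignment = paste(sym, collapse = ""),
                 penalties = pen),
            class = "duplex_score")
}

.check_rna <- function(seq, what, gaps = FALSE) {
  x <- strsplit(toupper(gsub("T", "U", as.character(seq)[1])), "")[[1]]
  ok <- c("A", "C", "G", "U", if (gaps) "-")
  if (!all(x %in% ok))
    stop("non-RNA characters in ", what, ": ",
         paste(unique(setdiff(x, ok)), collapse = ", "))
  x
}

#' Scan a transcript for miRNA target sites
#'
#' Slides the miRNA along the transcript (ungapped windows of miRNA length)
#' and scores every window with [duplex_expectation()], returning the
#' windows whose expectation penalty does not exceed `cutoff`. Coordinates
#' are 0-based half-open on the transcript, given strand only.
#'
#' @param mirna_seq miRNA sequence, 5'->3'.
#' @param transcript_seq transcript sequence, 5'->3' (length >= miRNA).
#' @param cutoff maximum expectation retained (default 2.5, the stringency
#'   commonly used to limit non-authentic plant targets).
#' @param ... penalty parameters passed to [duplex_expectation()].
#' @return data frame with columns `start`, `end` (0-based half-open),
#'   `expectation`, `alignment`, sorted by expectation then position.
#' @export
scan_transcript <- function(mirna_seq, transcript_seq, cutoff = 2.5, ...) {
  mir <- .check_rna(mirna_seq, "mirna_seq")
  tx <- .check_rna(transcript_seq, "transcript_seq")
  L <- length(mir)
  if (length(tx) < L) stop("transcript shorter than miRNA")
  n_win <- length(tx) - L + 1L
  res <- vector("list", n_win)
  mirna_chr <- paste(mir, collapse = "")
  for (s in seq_len(n_win)) {
    win <- paste(tx[s:(s + L - 1L)], collapse = "")
    d <- duplex_expectation(mirna_chr, win, ...)
    if (d$expectation <= cutoff) {
      res[[s]] <- data.frame(start = s - 1L, end = s - 1L + L,
                             expectation = d$expectation,
                             alignment = d$alignment,
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      expectation = numeric(), alignment = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$expectation, out$start), , drop = FALSE]
}

#' Scan many miRNAs against many transcripts
#'
#' Applies [scan_transcript()] to every miRNA/transcript combination and
#' collects the per-site hits and the induced candidate pair set.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param cutoff maximum expectation retained.
#' @param source provenance tag for the resulting pair set.
#' @param ... penalty parameters passed on.
#' @return List with `sites` (data frame: mirna_id, transcript_id, start,
#'   end, expectation) and `pairs` (a [candidate_pairs()] set).
#' @export
scan_all <- function(mirnas, transcripts, cutoff = 2.5,
                     source = "expectation_scan", ...) {
  hits <- list()
  for (mi in names(mirnas)) {
    for (tx in names(transcripts)) {
      h <- scan_transcript(mirnas[[mi]], transcripts[[tx]], cutoff, ...)
      if (nrow(h) > 0) {
        h$mirna_id <- mi; h$transcript_id <- tx
        hits[[length(hits) + 1L]] <- h
      }
    }
  }
  sites <- if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(), end = integer(), expectation = numeric(),
               alignment = character(), mirna_id = character(),
               transcript_id = character(), stringsAsFactors = FALSE)
  sites <- sites[, c("mirna_id", "transcript_id", "start", "end",
                     "expectation", "alignment")]
  rownames(sites) <- NULL
  pairs <- if (nrow(sites)) candidate_pairs(sites$mirna_id,
                                            sites$transcript_id, source)
           else candidate_pairs(character(), character())
  list(sites = sites, pairs = pairs)
}

#' Intersect two candidate pair sets
#'
#' Keeps only the pairs proposed by both predictors, a standard device to
#' curb sequence-prediction false positives; provenance records both
#' sources.
#'
#' @param a,b candidate pair sets (data frames with `mirna_id`, `mrna_id`).
#' @return A [candidate_pairs()] set with joined provenance tags.
#' @export
intersect_candidates <- function(a, b) {
  a <- as_candidate_pairs(a); b <- as_candidate_pairs(b)
  ka <- .pair_key(a); kb <- .pair_key(b)
  keep <- ka %in% kb
  out <- a[keep, , drop = FALSE]
  out$source <- paste(a$source[keep], b$source[match(ka[keep], kb)],
                      sep = "+")
  rownames(out) <- NULL
  class(out) <- c("candidate_pairs", "data.frame")
  out
}

#' Restrict candidate pairs to differentially expressed endpoints
#'
#' Keeps the pairs whose miRNA and mRNA are both in the corresponding
#' differential-expression lists.
#'
#' @param pairs candidate pair set.
#' @param de_mirnas,de_mrnas character vectors of DE feature ids.
#' @return Filtered [candidate_pairs()] set.
#' @export
restrict_to_de <- function(pairs, de_mirnas, de_mrnas) {
  pairs <- as_candidate_pairs(pairs)
  out <- pairs[pairs$mirna_id %in% de_mirnas &
               pairs$mrna_id %in% de_mrnas, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_pairs", "data.frame")
  out
}
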