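#' Configuration for the synthetic paired miRNA/mRNA data generator
#'
#' Bundles and validates the parameters of the synthetic-data model. The
#' generator emulates a two-condition (control vs. treated) microarray
#' design with replicated samples, differential expression of a subset of
#' features, and a set of planted negative miRNA->mRNA regulations that the
#' pipeline should recover.
#'
#' Expression model (log2 intensity scale): each feature draws a baseline
#' level from Normal(8, 1). Differentially expressed (DE) features receive a
#' +/- `effect_size` shift in the treated condition. Each unregulated
#' feature additionally varies from replicate to replicate with biological
#' standard deviation `bio_sd`, and every measurement adds independent
#' Normal(0, `noise_sd`) technical noise. A planted regulation (j, i) makes
#' mRNA i a decreasing function of its regulator: y_i = baseline_i -
#' `regulation_strength` x (x_j - mean(x_j)) + technical noise, so planted
#' targets are anticorrelated with their miRNA, their biological variation
#' propagates from the regulator, and they inherit its differential
#' expression.
#'
#' @param n_mirna,n_mrna number of miRNA / mRNA features.
#' @param n_reps_per_condition biological replicates per condition (3 by
#'   default, a typical microarray design).
#' @param n_planted_edges number of planted negative regulations.
#' @param effect_size mean absolute log2 shift of DE features between
#'   conditions.
#' @param regulation_strength magnitude in \[0, 1\] of the planted negative
#'   coupling.
#' @param bio_sd per-replicate biological variation (log2-intensity units);
#'   the within-condition spread of a feature across biological replicates
#'   beyond technical noise.
#' @param noise_sd standard deviation of the technical measurement noise
#'   (log2-intensity units).
#' @param candidate_fpr probability that a non-regulating pair is still
#'   listed in the sequence-candidate set (decoy rate), in \[0, 1).
#' @param frac_mirna_de,frac_mrna_de fraction of miRNAs / mRNAs carrying a
#'   condition effect. Planted regulators are drawn from the DE miRNAs and
#'   planted targets count towards the DE mRNAs.
#' @param prop_mirna_up proportion of DE miRNAs shifted upwards (the rest
#'   are downregulated; drought studies typically observe a strong
#'   down-skew).
#' @param seed integer seed making the dataset reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_mirna = 30, n_mrna = 329, n_reps_per_condition = 3,
                       n_planted_edges = 50, effect_size = 1,
                       regulation_strength = 0.9, bio_sd = 1, noise_sd = 0.3,
                       candidate_fpr = 0.02,
                       frac_mirna_de = 1, frac_mrna_de = 1,
                       prop_mirna_up = 0.12, seed = 1L) {
  cfg <- list(n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
              n_reps_per_condition = as.integer(n_reps_per_condition),
              n_planted_edges = as.integer(n_planted_edges),
              effect_size = effect_size,
              regulation_strength = regulation_strength,
              bio_sd = bio_sd,
              noise_sd = noise_sd, candidate_fpr = candidate_fpr,
              frac_mirna_de = frac_mirna_de, frac_mrna_de = frac_mrna_de,
              prop_mirna_up = prop_mirna_up, seed = as.integer(seed))
  counts <- cfg[c("n_mirna", "n_mrna", "n_reps_per_condition")]
  if (any(vapply(counts, function(x) x < 1L, logical(1))))
    stop("all counts must be >= 1")
  if (cfg$n_planted_edges < 0L) stop("n_planted_edges must be >= 0")
  if (cfg$n_planted_edges > cfg$n_mirna * cfg$n_mrna)
    stop("n_planted_edges exceeds the number of miRNA x mRNA pairs")
  if (cfg$regulation_strength < 0 || cfg$regulation_strength > 1)
    stop("regulation_strength must lie in [0, 1]")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$bio_sd < 0) stop("bio_sd must be >= 0")
  if (cfg$candidate_fpr < 0 || cfg$candidate_fpr >= 1)
    stop("candidate_fpr must lie in [0, 1)")
  if (cfg$frac_mirna_de < 0 || cfg$frac_mirna_de > 1 ||
      cfg$frac_mrna_de < 0 || cfg$frac_mrna_de > 1)
    stop("DE fractions must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic paired miRNA/mRNA dataset with planted regulations
#'
#' Draws matched miRNA and mRNA expression matrices (features x samples)
#' under the model described in [sim_config()], together with a
#' sequence-candidate pair set (all planted edges plus uniform decoys at
#' rate `candidate_fpr`) and the ground truth needed to benchmark recovery.
#' Identical seeds produce identical output.
#'
#' @param config a [sim_config()] object.
#' @return List of class `sim_data` with elements
#'   \describe{
#'     \item{mirna}{n_mirna x 2R matrix of log2 intensities.}
#'     \item{mrna}{n_mrna x 2R matrix of log2 intensities.}
#'     \item{condition}{factor of length 2R with levels control, treated.}
#'     \item{candidates}{candidate pair data frame (mirna_id, mrna_id, source).}
#'     \item{truth}{list: `planted_edges` data frame (mirna_id, mrna_id,
#'       sign = "negative"), `de_mirnas`, `de_mrnas` id vectors.}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_samp <- 2L * config$n_reps_per_condition
  condition <- factor(rep(c("control", "treated"),
                          each = config$n_reps_per_condition),
                      levels = c("control", "treated"))
  treated <- condition == "treated"
  mirna_ids <- sprintf("miR%03d", seq_len(config$n_mirna))
  mrna_ids <- sprintf("gene%04d", seq_len(config$n_mrna))

  # --- DE assignment ------------------------------------------------------
  n_de_mir <- round(config$frac_mirna_de * config$n_mirna)
  de_mir_idx <- if (n_de_mir > 0)
    sort(sample.int(config$n_mirna, n_de_mir)) else integer()
  n_up <- round(config$prop_mirna_up * n_de_mir)
  mir_shift <- numeric(config$n_mirna)
  if (n_de_mir > 0) {
    signs <- rep(-1, n_de_mir)
    if (n_up > 0) signs[sample.int(n_de_mir, n_up)] <- 1
    mir_shift[de_mir_idx] <- signs * config$effect_size
  }

  # --- miRNA matrix -------------------------------------------------------
  mir_base <- stats::rnorm(config$n_mirna, 8, 1)
  X <- matrix(mir_base, config$n_mirna, n_samp) +
    outer(mir_shift, as.numeric(treated)) +
    matrix(stats::rnorm(config$n_mirna * n_samp, 0, config$bio_sd),
           config$n_mirna, n_samp) +
    matrix(stats::rnorm(config$n_mirna * n_samp, 0, config$noise_sd),
           config$n_mirna, n_samp)
  dimnames(X) <- list(mirna_ids, sprintf("S%d", seq_len(n_samp)))

  # --- planted edges: regulators among DE miRNAs, distinct targets --------
  n_edge <- config$n_planted_edges
  reg_pool <- if (n_de_mir > 0) de_mir_idx else seq_len(config$n_mirna)
  if (n_edge > 0) {
    tgt_idx <- sample.int(config$n_mrna, min(n_edge, config$n_mrna))
    reg_idx <- sample(reg_pool, n_edge, replace = TRUE)
    if (n_edge > config$n_mrna) {  # more edges than mRNAs: allow reuse
      tgt_idx <- c(tgt_idx, sample.int(config$n_mrna, n_edge - config$n_mrna,
                                       replace = TRUE))
    }
    planted <- unique(data.frame(mirna = reg_idx, mrna = tgt_idx))
  } else {
    planted <- data.frame(mirna = integer(), mrna = integer())
  }

  # --- mRNA DE assignment (planted targets inherit DE from regulator) -----
  n_de_mrna <- round(config$frac_mrna_de * config$n_mrna)
  extra_pool <- setdiff(seq_len(config$n_mrna), planted$mrna)
  n_extra <- max(0L, n_de_mrna - length(unique(planted$mrna)))
  de_mrna_idx <- sort(c(unique(planted$mrna),
                        if (n_extra > 0 && length(extra_pool) > 0)
                          sample(extra_pool, min(n_extra, length(extra_pool)))
                        else integer()))
  mrna_shift <- numeric(config$n_mrna)
  indep_de <- setdiff(de_mrna_idx, planted$mrna)
  if (length(indep_de) > 0) {
    mrna_shift[indep_de] <- sample(c(-1, 1), length(indep_de),
                                   replace = TRUE, prob = c(0.5, 0.5)) *
      config$effect_size
  }

  # --- mRNA matrix --------------------------------------------------------
  mrna_base <- stats::rnorm(config$n_mrna, 8, 1)
  Y <- matrix(mrna_base, config$n_mrna, n_samp) +
    outer(mrna_shift, as.numeric(treated)) +
    matrix(stats::rnorm(config$n_mrna * n_samp, 0, config$bio_sd),
           config$n_mrna, n_samp) +
    matrix(stats::rnorm(config$n_mrna * n_samp, 0, config$noise_sd),
           config$n_mrna, n_samp)
  if (nrow(planted) > 0) {
    for (k in seq_len(nrow(planted))) {
      j <- planted$mirna[k]; i <- planted$mrna[k]
      xc <- X[j, ] - mean(X[j, ])
      Y[i, ] <- mrna_base[i] - config$regulation_strength * xc +
        stats::rnorm(n_samp, 0, config$noise_sd)
    }
  }
  dimnames(Y) <- list(mrna_ids, sprintf("S%d", seq_len(n_samp)))

  # --- candidate pair set: planted edges + uniform decoys -----------------
  planted_keys <- paste(planted$mirna, planted$mrna)
  n_pairs <- config$n_mirna * config$n_mrna
  decoy <- which(stats::runif(n_pairs) < config$candidate_fpr)
  decoy_mir <- ((decoy - 1L) %% config$n_mirna) + 1L
  decoy_mrna <- ((decoy - 1L) %/% config$n_mirna) + 1L
  keep <- !(paste(decoy_mir, decoy_mrna) %in% planted_keys)
  candidates <- data.frame(
    mirna_id = c(mirna_ids[planted$mirna], mirna_ids[decoy_mir[keep]]),
    mrna_id = c(mrna_ids[planted$mrna], mrna_ids[decoy_mrna[keep]]),
    source = rep(c("planted", "decoy"),
                 c(nrow(planted), sum(keep))),
    stringsAsFactors = FALSE)
  candidates <- candidate_pairs(candidates$mirna_id, candidates$mrna_id,
                                source = candidates$source)

  truth <- list(
    planted_edges = data.frame(mirna_id = mirna_ids[planted$mirna],
                               mrna_id = mrna_ids[planted$mrna],
                               sign = rep("negative", nrow(planted)),
                               stringsAsFactors = FALSE),
    de_mirnas = mirna_ids[de_mir_idx],
    de_mrnas = mrna_ids[de_mrna_idx])

  structure(list(mirna = X, mrna = Y, condition = condition,
                 candidates = candidates, truth = truth, config = config),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat("Synthetic paired expression dataset\n")
  cat("  miRNAs:", nrow(x$mirna), " mRNAs:", nrow(x$mrna),
      " samples:", ncol(x$mirna), "\n")
  cat("  planted edges:", nrow(x$truth$planted_edges),
      " candidate pairs:", nrow(x$candidates), "\n")
  invisible(x)
}

# RNA complement / wobble lookup used by the duplex generator
.rna_comp <- c(A = "U", U = "A", C = "G", G = "C")

#' Generate synthetic miRNA and transcript sequences with planted target sites
#'
#' Emits 21-nt miRNA sequences and longer transcripts, each transcript
#' carrying one planted (near-)complementary target site. Sites cycle
#' through a fixed panel of lesion patterns (perfect complement, one
#' seed-region mismatch, one non-seed G:U wobble, one seed G:U plus one
#' non-seed mismatch), so that the intended expectation penalty of every
#' site is known in advance.
#'
#' @param n_sites number of miRNA/transcript pairs to generate.
#' @param seed integer seed.
#' @param transcript_length length of each transcript (>= 21 + 2).
#' @return List with `mirna` (named character vector of RNA sequences,
#'   5'->3'), `transcripts` (named character vector), and `site_truth`
#'   (data frame: mirna_id, transcript_id, start 0-based, expectation).
#' @export
simulate_duplex_sequences <- function(n_sites, seed = 1L,
                                      transcript_length = 120L) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (transcript_length < 23L) stop("transcript_length too short")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "U")
  L <- 21L
  # lesion panel: list of (miRNA position, type); expectation from the
  # default penalty scheme (mismatch 1, G:U 0.5, x2 within positions 2-13)
  panel <- list(
    list(pos = integer(), type = character(), expectation = 0),
    list(pos = 5L, type = "mismatch", expectation = 2),
    list(pos = 20L, type = "wobble", expectation = 0.5),
    list(pos = 3L, type = "wobble", expectation = 1),
    list(pos = c(7L, 18L), type = c("mismatch", "mismatch"), expectation = 3)
  )
  mirna <- character(n_sites); trans <- character(n_sites)
  truth <- vector("list", n_sites)
  for (k in seq_len(n_sites)) {
    mir <- sample(bases, L, replace = TRUE)
    les <- panel[[(k - 1L) %% length(panel) + 1L]]
    # a G:U wobble at miRNA position q needs mir[q] in {G, U}
    for (q in seq_along(les$pos)) {
      if (les$type[q] == "wobble" && !(mir[les$pos[q]] %in% c("G", "U")))
        mir[les$pos[q]] <- sample(c("G", "U"), 1L)
    }
    # build the site: reverse complement of the miRNA, then apply lesions
    site <- rev(unname(.rna_comp[mir]))  # site 5'->3'; mir pos k <-> site pos L-k+1
    for (q in seq_along(les$pos)) {
      sp <- L - les$pos[q] + 1L
      mb <- mir[les$pos[q]]
      if (les$type[q] == "wobble") {
        site[sp] <- if (mb == "G") "U" else "G"
      } else {
        bad <- setdiff(bases, c(.rna_comp[mb],
                                if (mb == "G") "U" else if (mb == "U") "G"))
        site[sp] <- sample(bad, 1L)
      }
    }
    start <- sample.int(transcript_length - L + 1L, 1L) - 1L  # 0-based
    tr <- sample(bases, transcript_length, replace = TRUE)
    tr[(start + 1L):(start + L)] <- site
    mirna[k] <- paste(mir, collapse = "")
    trans[k] <- paste(tr, collapse = "")
    truth[[k]] <- data.frame(mirna_id = sprintf("mir_s%03d", k),
                             transcript_id = sprintf("tx_s%03d", k),
                             start = start, expectation = les$expectation,
                             stringsAsFactors = FALSE)
  }
  names(mirna) <- sprintf("mir_s%03d", seq_len(n_sites))
  names(trans) <- sprintf("tx_s%03d", seq_len(n_sites))
  list(mirna = mirna, transcripts = trans,
       site_truth = do.call(rbind, truth))
}
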