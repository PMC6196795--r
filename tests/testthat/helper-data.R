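# Shared fixtures built in code.

# small paired dataset for fast association tests
small_sim <- function(seed = 1, ...) {
  simulate_dataset(sim_config(n_mirna = 8, n_mrna = 30,
                              n_planted_edges = 6, seed = seed, ...))
}

# random standardized toy matrices (samples x features)
toy_xy <- function(n = 6, p = 3, m = 4, seed = 42) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("miR", seq_len(p)))),
       Y = matrix(rnorm(n * m), n, m,
                  dimnames = list(NULL, paste0("g", seq_len(m)))))
}

# brute-force BH step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force AUC by pair enumeration
auc_oracle <- function(values, labels) {
  pos <- values[labels]; neg <- values[!labels]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# union-find oracle for miRNA modules
modules_oracle <- function(edges) {
  mirnas <- unique(edges$mirna_id)
  parent <- stats::setNames(mirnas, mirnas)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (tgt in unique(edges$mrna_id)) {
    ms <- unique(edges$mirna_id[edges$mrna_id == tgt])
    if (length(ms) > 1)
      for (k in 2:length(ms))
        parent[[find(ms[1])]] <- find(ms[k])
  }
  roots <- vapply(mirnas, find, character(1))
  groups <- split(mirnas, roots)
  groups <- Filter(function(v) length(v) >= 2, groups)
  lapply(unname(groups), sort)
}
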