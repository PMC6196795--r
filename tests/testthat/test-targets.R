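rc <- function(s) {
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

test_that("duplex expectation scores the canonical cases", {
  mir <- "UGGAAGGGGCAUGCAGGGGAG"  # 21 nt
  expect_equal(duplex_expectation(mir, rc(mir))$expectation, 0)
  # single mismatch at miRNA position 5 (inside the doubled core): 1 * 2
  site <- strsplit(rc(mir), "")[[1]]
  site[21 - 5 + 1] <- "C"  # miRNA pos 5 is A; A:C is a mismatch
  expect_equal(duplex_expectation(mir, paste(site, collapse = ""))$expectation, 2)
  # single G:U wobble at position 20 (outside the core): 0.5
  site <- strsplit(rc(mir), "")[[1]]
  expect_equal(substr(mir, 20, 20), "A")
  mir2 <- mir; substr(mir2, 20, 20) <- "G"   # miRNA pos 20 now G
  site2 <- strsplit(rc(mir2), "")[[1]]
  site2[21 - 20 + 1] <- "U"                  # G:U wobble
  expect_equal(duplex_expectation(mir2, paste(site2, collapse = ""))$expectation,
               0.5)
  expect_error(duplex_expectation("UGGAXGGGGCAUGCAGGGGAG", rc(mir)),
               "non-RNA")
})

test_that("expectation is the sum of per-position penalties", {
  set.seed(8)
  bases <- c("A", "C", "G", "U")
  for (k in 1:20) {
    mir <- paste(sample(bases, 21, TRUE), collapse = "")
    site <- paste(sample(bases, 21, TRUE), collapse = "")
    d <- duplex_expectation(mir, site)
    # independent per-position oracle
    mirv <- strsplit(mir, "")[[1]]
    sitev <- rev(strsplit(site, "")[[1]])
    comp <- c(A = "U", U = "A", C = "G", G = "C")
    pen <- vapply(1:21, function(q) {
      a <- mirv[q]; b <- sitev[q]
      base <- if (comp[[a]] == b) 0
      else if ((a == "G" && b == "U") || (a == "U" && b == "G")) 0.5
      else 1
      if (q >= 2 && q <= 13) base * 2 else base
    }, numeric(1))
    expect_equal(d$expectation, sum(pen))
    expect_equal(d$penalties, pen)
  }
})

test_that("expectation is symmetric in the two strands of the duplex", {
  # reading the same duplex from the other strand (site as the 5'->3'
  # query, miRNA as its target) pairs the same bases, so with the
  # position-dependent core weighting disabled the score is unchanged
  set.seed(9)
  bases <- c("A", "C", "G", "U")
  for (k in 1:10) {
    mir <- paste(sample(bases, 21, TRUE), collapse = "")
    site <- paste(sample(bases, 21, TRUE), collapse = "")
    a <- duplex_expectation(mir, site, core = integer(0))
    b <- duplex_expectation(site, mir, core = integer(0))
    expect_equal(a$expectation, b$expectation)
  }
})

test_that("transcript scan finds planted sites and respects the cutoff", {
  set.seed(12)
  bases <- c("A", "C", "G", "U")
  mir <- paste(sample(bases, 21, TRUE), collapse = "")
  flank1 <- paste(sample(bases, 40, TRUE), collapse = "")
  flank2 <- paste(sample(bases, 40, TRUE), collapse = "")
  tx <- paste0(flank1, rc(mir), flank2)
  hits <- scan_transcript(mir, tx, cutoff = 0)
  expect_equal(hits$start, 40)
  expect_equal(hits$expectation, 0)
  # monotonicity: lower cutoff never yields more sites
  h1 <- scan_transcript(mir, tx, cutoff = 6)
  h2 <- scan_transcript(mir, tx, cutoff = 3)
  expect_gte(nrow(h1), nrow(h2))
  expect_error(scan_transcript(mir, "ACGU"), "shorter")
})

test_that("scan recovers all generator-planted sites within the cutoff", {
  dx <- simulate_duplex_sequences(10, seed = 21)
  res <- scan_all(dx$mirna, dx$transcripts, cutoff = 2.5)
  keep <- dx$site_truth[dx$site_truth$expectation <= 2.5, ]
  for (k in seq_len(nrow(keep))) {
    hit <- res$sites[res$sites$mirna_id == keep$mirna_id[k] &
                     res$sites$transcript_id == keep$transcript_id[k] &
                     res$sites$start == keep$start[k], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$expectation, keep$expectation[k])
  }
})

test_that("candidate set algebra: intersection and DE restriction", {
  a <- candidate_pairs(c("m1", "m1", "m2", "m3"),
                       c("g1", "g2", "g1", "g3"), source = "A")
  b <- candidate_pairs(c("m1", "m2", "m4"), c("g2", "g1", "g4"),
                       source = "B")
  ab <- intersect_candidates(a, b)
  expect_equal(nrow(ab), 2)
  expect_setequal(paste(ab$mirna_id, ab$mrna_id), c("m1 g2", "m2 g1"))
  expect_true(all(ab$source == "A+B"))
  # disjoint -> empty; subset identity
  expect_equal(nrow(intersect_candidates(a, candidate_pairs("x", "y"))), 0)
  sub <- candidate_pairs("m1", "g2", source = "A")
  expect_equal(nrow(intersect_candidates(sub, a)), 1)
  # brute-force oracle on random 20-pair sets
  set.seed(30)
  for (k in 1:5) {
    p1 <- candidate_pairs(sample(paste0("m", 1:6), 20, TRUE),
                          sample(paste0("g", 1:6), 20, TRUE))
    p2 <- candidate_pairs(sample(paste0("m", 1:6), 20, TRUE),
                          sample(paste0("g", 1:6), 20, TRUE))
    got <- nrow(intersect_candidates(p1, p2))
    want <- 0
    for (i in seq_len(nrow(p1)))
      for (j in seq_len(nrow(p2)))
        if (p1$mirna_id[i] == p2$mirna_id[j] &&
            p1$mrna_id[i] == p2$mrna_id[j]) {
          want <- want + 1; break
        }
    expect_equal(got, want)
  }
  # DE restriction
  pr <- candidate_pairs(c("m1", "m2", "m3", "m1", "m2"),
                        c("g1", "g2", "g3", "g3", "g1"))
  kept <- restrict_to_de(pr, c("m1", "m2"), c("g1", "g3"))
  expect_setequal(paste(kept$mirna_id, kept$mrna_id),
                  c("m1 g1", "m1 g3", "m2 g1"))
  expect_equal(nrow(restrict_to_de(pr, character(), character())), 0)
  expect_equal(nrow(restrict_to_de(pr, paste0("m", 1:3), paste0("g", 1:3))),
               nrow(pr))
})
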