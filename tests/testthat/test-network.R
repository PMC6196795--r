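test_that("network construction deduplicates and validates sides", {
  e <- data.frame(mirna_id = c("m1", "m1", "m2"),
                  mrna_id = c("g1", "g1", "g2"))
  net <- build_network(e)
  expect_equal(nrow(net$edges), 2)
  expect_error(build_network(data.frame(mirna_id = c("m1", "g1"),
                                        mrna_id = c("g1", "g2"))),
               "both miRNA and mRNA")
  empty <- build_network(e[0, ])
  expect_equal(nrow(empty$edges), 0)
  expect_length(find_modules(empty), 0)
})

test_that("degree summaries satisfy the bipartite handshake", {
  set.seed(50)
  e <- unique(data.frame(mirna_id = sample(paste0("m", 1:6), 30, TRUE),
                         mrna_id = sample(paste0("g", 1:12), 30, TRUE)))
  net <- build_network(e)
  deg <- degree_summary(net)
  expect_equal(sum(deg$out_degree), nrow(net$edges))
  expect_equal(sum(deg$in_degree), nrow(net$edges))
  # star graph
  star <- build_network(data.frame(mirna_id = "hub",
                                   mrna_id = paste0("g", 1:7)))
  sdeg <- degree_summary(star)
  expect_equal(unname(sdeg$out_degree), 7)
  expect_true(all(sdeg$in_degree == 1))
})

test_that("degree fits recover noiseless power-law and exponential data", {
  # counts 8,4,2,1 at degrees 1,2,4,8: freq = 8 * degree^-1 exactly
  degrees <- rep(c(1, 2, 4, 8), times = c(8, 4, 2, 1))
  fit <- fit_degree_distribution(degrees, "power_law")
  expect_equal(fit$slope, -1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # counts 100,10,1 at degrees 2,4,6: log10 freq = 3 - 0.5 degree exactly
  degrees <- rep(c(2, 4, 6), times = c(100, 10, 1))
  fit <- fit_degree_distribution(degrees, "exponential")
  expect_equal(fit$slope, -0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_degree_distribution(c(1, 1, 2, 2)), ">= 3 distinct")
})

test_that("degree-fit slope equals the closed-form OLS oracle", {
  set.seed(51)
  degrees <- sample(1:6, 60, TRUE)
  fit <- fit_degree_distribution(degrees, "power_law")
  tab <- table(degrees)
  x <- log10(as.numeric(names(tab))); y <- log10(as.numeric(tab))
  slope <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
  expect_equal(fit$slope, slope, tolerance = 1e-9)
  r2 <- slope^2 * (mean(x^2) - mean(x)^2) / (mean(y^2) - mean(y)^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-9)
})

test_that("module detection equals the union-find oracle", {
  set.seed(52)
  for (k in 1:10) {
    e <- unique(data.frame(
      mirna_id = sample(paste0("m", 1:8), 25, TRUE),
      mrna_id = sample(paste0("g", 1:10), 25, TRUE),
      stringsAsFactors = FALSE))
    mods <- find_modules(build_network(e))
    got <- lapply(mods, function(m) m$mirna_ids)
    want <- modules_oracle(e)
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
  }
  # no shared targets anywhere -> no modules
  solo <- build_network(data.frame(mirna_id = c("m1", "m2"),
                                   mrna_id = c("g1", "g2")))
  expect_length(find_modules(solo), 0)
})

test_that("coregulated fraction counts multiply-regulated mRNAs", {
  # all in-degree one
  net1 <- build_network(data.frame(mirna_id = c("m1", "m2"),
                                   mrna_id = c("g1", "g2")))
  expect_equal(coregulated_fraction(net1), 0)
  # complete bipartite 2x3
  full <- build_network(expand.grid(mirna_id = c("m1", "m2"),
                                    mrna_id = c("g1", "g2", "g3"),
                                    stringsAsFactors = FALSE))
  expect_equal(coregulated_fraction(full), 1)
  # 8 coregulated of 58 mRNAs -> 0.138 to 3 s.f.
  e <- rbind(data.frame(mirna_id = "mA", mrna_id = paste0("g", 1:58)),
             data.frame(mirna_id = "mB", mrna_id = paste0("g", 1:8)))
  expect_equal(round(coregulated_fraction(build_network(e)), 3), 0.138)
  expect_error(coregulated_fraction(build_network(e[0, ])), "empty")
})

test_that("the drought network fixture reproduces the printed structure", {
  fx <- load_table1_fixture()
  net <- fx$network
  expect_length(net$mirnas, 13)
  deg <- degree_summary(net)
  expect_equal(max(deg$out_degree), 11)
  expect_equal(names(deg$out_degree)[which.max(deg$out_degree)],
               "osa-miR156b-3p")
  expect_equal(deg$in_degree[["49D11.4"]], 3)
  expect_equal(sum(fx$table$response == "Up"), 2)
  expect_equal(sum(fx$table$response == "Down"), 11)
  # osa-miR1430 row as printed
  expect_setequal(net$edges$mrna_id[net$edges$mirna_id == "osa-miR1430"],
                  c("MYB30", "NFYA", "UGE-4"))
  mods <- find_modules(net)
  expect_length(mods, 4)
  # miR528-3p and miR812q share DWARF-3 in one module
  m528 <- Filter(function(m) "osa-miR528-3p" %in% m$mirna_ids, mods)
  expect_length(m528, 1)
  expect_true("osa-miR812q" %in% m528[[1]]$mirna_ids)
  expect_true("DWARF-3" %in% m528[[1]]$shared_mrna_ids)
})

test_that("network exports round-trip through SIF and igraph", {
  fx <- load_table1_fixture()
  path <- tempfile(fileext = ".sif")
  write_sif(fx$network, path)
  lines <- readLines(path)
  expect_length(lines, nrow(fx$network$edges))
  g <- as_igraph(fx$network)
  expect_equal(igraph::vcount(g), 13 + 57)
  expect_equal(igraph::ecount(g), nrow(fx$network$edges))
  expect_true(igraph::is_bipartite(g))
})
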