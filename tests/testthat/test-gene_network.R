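# Anchor-centred networks, signatures, cross-state congruence,
# differential ranking.

random_expr <- function(n_genes = 20, n_samples = 15, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

test_that("network coefficients: anchor at 1, affine copies at 1", {
  e <- random_expr(seed = 2)
  e["G002", ] <- 3 * e["G001", ] + 5
  net <- build_network(e, "G001")
  expect_equal(unname(net$coefficients["G001"]), 1)
  expect_equal(unname(net$coefficients["G002"]), 1, tolerance = 1e-12)
  expect_true(all(net$coefficients >= -1 & net$coefficients <= 1))
})

test_that("anchor-wise networks equal rows of the all-pairs matrix", {
  e <- random_expr(n_genes = 50, seed = 3)
  full <- full_correlation_matrix(e)
  expect_equal(full, t(full), tolerance = 1e-12)  # symmetry
  for (anchor in c("G001", "G025", "G050")) {
    net <- build_network(e, anchor)
    expect_equal(net$coefficients[colnames(full)], full[anchor, ],
                 tolerance = 1e-12)
  }
})

test_that("networks are invariant to sample order and drop constant genes", {
  e <- random_expr(seed = 4)
  e["G003", ] <- 7
  set.seed(9)
  n1 <- build_network(e, "G001")
  n2 <- build_network(e[, sample(ncol(e))], "G001")
  expect_equal(n1$coefficients, n2$coefficients, tolerance = 1e-12)
  expect_true("G003" %in% n1$dropped$gene)
  expect_false("G003" %in% names(n1$coefficients))

  e["G001", ] <- 0
  expect_error(build_network(e, "G001"), "constant",
               class = "codepnet_validation_error")
})

test_that("planted anchor block is recovered at large n", {
  genes <- sprintf("G%03d", 1:30)
  nt <- network_truth(genes, block_a = c(rep(1, 5), rep(0, 25)),
                      rho_a = c("1" = 0.9), anchors = "G001")
  e <- gen_cohort_expression(nt, "A", 1000, seed = 12)
  net <- build_network(e, "G001", cohort = "A")
  expect_true(all(net$coefficients[sprintf("G%03d", 2:5)] > 0.8))
})

test_that("signature membership is strict, intersective, anchor-free", {
  fake_net <- function(coefs, anchor, cohort = "A") {
    structure(list(anchor = anchor, cohort = cohort, method = "pearson",
                   coefficients = c(setNames(1, anchor), coefs),
                   dropped = data.frame(gene = character(0),
                                        reason = character(0))),
              class = "gene_network")
  }
  n1 <- fake_net(c(G1 = 0.71, G2 = 0.70, G3 = 0.69), "A1")
  sig <- extract_signature(list(n1), 0.7)
  expect_identical(sig$members, "G1")  # 0.70 is NOT above 0.7

  n2 <- fake_net(c(G1 = 0.9, G2 = 0.95, G3 = 0.2), "A2")
  sig2 <- extract_signature(list(n1, n2), 0.7)
  expect_identical(sig2$members, "G1")

  expect_error(extract_signature(list(n1), 1.5),
               class = "codepnet_validation_error")
  expect_error(
    extract_signature(list(n1, fake_net(c(G1 = 1), "A3", cohort = "B"))),
    "same cohort", class = "codepnet_validation_error")
})

test_that("signatures shrink as the cutoff rises (random instances)", {
  for (s in 1:25) {
    e <- random_expr(n_genes = 30, n_samples = 10, seed = 100 + s)
    net <- build_network(e, "G001", cohort = "A")
    lo <- extract_signature(list(net), 0.3)
    mid <- extract_signature(list(net), 0.7)
    hi <- extract_signature(list(net), 0.9)
    expect_true(all(hi$members %in% mid$members))
    expect_true(all(mid$members %in% lo$members))
    expect_true(all(abs(net$coefficients) <= 1 + 1e-12))
  }
})

test_that("cross-state assessment: identical cohorts are fully congruent", {
  e <- random_expr(n_genes = 40, n_samples = 20, seed = 7)
  e[2:6, ] <- e[rep(1, 5), ] + 0.1 * matrix(rnorm(100), 5)
  net <- build_network(e, "G001", cohort = "A")
  sig <- extract_signature(list(net), 0.7)
  expect_gt(length(sig$members), 0)
  other <- net
  other$cohort <- "B"
  res <- cross_state_assessment(sig, list(other))
  expect_equal(res$fraction_below, 0)
})

test_that("cross-state fraction and five-number summary match enumeration", {
  sig <- structure(list(anchors = "A1", cohort = "A", cutoff = 0.7,
                        members = c("G1", "G2", "G3", "G4")),
                   class = "network_signature")
  other <- structure(list(anchor = "A1", cohort = "B", method = "pearson",
                          coefficients = c(A1 = 1, G1 = 0.8, G2 = 0.6,
                                           G3 = 0.5, G4 = 0.71),
                          dropped = NULL),
                     class = "gene_network")
  res <- cross_state_assessment(sig, list(other))
  expect_equal(res$fraction_below, 0.5)
  expect_equal(res$min, 0.5)
  expect_equal(res$max, 0.8)
  expect_equal(res$median, 0.655)
})

test_that("differential profile: identity, extremes and bounds", {
  e <- random_expr(n_genes = 25, n_samples = 12, seed = 8)
  net_a <- build_network(e, "G001", cohort = "A")
  net_b <- net_a
  net_b$cohort <- "B"
  prof <- differential_profile(net_b, net_a)
  expect_true(all(prof$delta == 0))
  expect_equal(attr(prof, "n_common"), 24)

  net_b$coefficients["G010"] <- 0.9
  net_a$coefficients["G010"] <- -0.9
  prof2 <- differential_profile(net_b, net_a)
  expect_equal(prof2$delta[1], 1.8)
  expect_equal(prof2$gene[1], "G010")
  expect_equal(prof2$rank[1], 1)
  expect_true(all(prof2$delta >= -2 & prof2$delta <= 2))

  net_x <- net_a
  net_x$anchor <- "G002"
  expect_error(differential_profile(net_b, net_x), "anchor",
               class = "codepnet_validation_error")
})

test_that("block present only in cohort B tops the differential ranking", {
  # well-powered design: 33 samples per cohort so the sampling noise of the
  # anchor correlations does not swamp the planted 0.9 effect
  genes <- sprintf("G%03d", 1:150)
  nt <- network_truth(genes,
                      block_a = 0L,
                      block_b = c(rep(1, 6), rep(0, 144)),
                      rho_b = c("1" = 0.9), anchors = "G001")
  hits <- vapply(1:40, function(s) {
    ea <- gen_cohort_expression(nt, "A", 33, seed = s)
    eb <- gen_cohort_expression(nt, "B", 33, seed = 4000 + s)
    prof <- differential_profile(build_network(eb, "G001", cohort = "B"),
                                 build_network(ea, "G001", cohort = "A"))
    top_decile <- prof$gene[seq_len(ceiling(nrow(prof) / 10))]
    all(sprintf("G%03d", 2:6) %in% top_decile)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("annotate_extremes counts set members in both tails", {
  prof <- structure(
    data.frame(gene = sprintf("G%02d", 1:10), r_b = 0, r_a = 0,
               delta = 10:1, rank = 1:10, stringsAsFactors = FALSE),
    class = c("differential_profile", "data.frame"))
  res <- annotate_extremes(prof, c("G01", "G10"), top_n = 3)
  expect_equal(res$count_top, 1)
  expect_equal(res$count_bottom, 1)
  expect_identical(res$members_top, "G01")
  expect_identical(res$members_bottom, "G10")

  none <- annotate_extremes(prof, c("ZZZ"), top_n = 3)
  expect_equal(none$count_top, 0)
  expect_equal(none$count_bottom, 0)

  expect_error(annotate_extremes(prof, "G01", top_n = 6),
               class = "codepnet_validation_error")
})

test_that("extreme counts match the hypergeometric null expectation", {
  N <- 200
  prof <- structure(
    data.frame(gene = sprintf("G%03d", 1:N), r_b = 0, r_a = 0,
               delta = seq(2, -2, length.out = N), rank = 1:N,
               stringsAsFactors = FALSE),
    class = c("differential_profile", "data.frame"))
  set.seed(17)
  top_n <- 20
  set_size <- 15
  counts <- vapply(seq_len(1000), function(i) {
    annotate_extremes(prof, sample(prof$gene, set_size),
                      top_n = top_n)$count_top
  }, 0)
  expected <- set_size * top_n / N
  sd_one <- sqrt(expected * (1 - top_n / N))
  expect_lt(abs(mean(counts) - expected), 3 * sd_one / sqrt(1000))
})
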