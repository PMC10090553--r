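# Anchored co-dependency screen and candidate funnel.

test_that("pearson_with_p matches hand-computed cases", {
  x <- c(1, 2, 3, 5)
  expect_equal(pearson_with_p(x, x)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_with_p(c(1, 2, 3), c(3, 2, 1))$r, -1, tolerance = 1e-12)
  # centred cross-product 4 over sqrt(5 * 5)
  res <- pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  expect_equal(res$n, 4)
  # p from t = r sqrt((n-2)/(1-r^2)) on n-2 df
  t <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(res$p_two_sided, 2 * pt(t, 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("spearman_with_p is rank-invariant and matches ranks-as-values", {
  res <- spearman_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$rho, 0.8, tolerance = 1e-12)
  mono <- spearman_with_p(c(1, 2, 3), c(10, 100, 1000))
  expect_equal(mono$rho, 1, tolerance = 1e-12)
  expect_lt(pearson_with_p(c(1, 2, 3), c(10, 100, 1000))$r, 1)
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "constant",
               class = "codepnet_validation_error")
  expect_error(pearson_with_p(c(1, 2), c(1, 2)), "complete pairs",
               class = "codepnet_validation_error")
  expect_error(pearson_with_p(c(1, 2, NA, NA), c(1, 2, 3, 4)),
               class = "codepnet_validation_error")
})

test_that("correlation estimators match from-definition oracles to 1e-12", {
  set.seed(101)
  for (i in seq_len(300)) {
    n <- sample(4:50, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    expect_equal(pearson_with_p(x, y)$r, oracle_pearson(x, y),
                 tolerance = 1e-12)
    expect_equal(spearman_with_p(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  # with ties in the data, midranks still agree
  for (i in seq_len(50)) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:5, 12, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(spearman_with_p(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
})

make_screen_fixture <- function(n_planted = 5, n_null = 495, n_hi = 46,
                                seed = 11, rho = 0.9) {
  genes <- c(sprintf("P%02d", seq_len(n_planted)),
             sprintf("Z%03d", seq_len(n_null)))
  tr <- dependency_truth("ANCH", genes,
                         rho_hi = c(rep(rho, n_planted), rep(0, n_null)))
  ann <- gen_scn_annotation(n_hi, 5, 2, 0, 0.2, seed = seed)
  dep <- gen_dependency_matrix(tr, ann, seed = seed)
  list(dep = dep, hi = ann$cell_line[ann$truth_group == "HI"])
}

test_that("screen recovers planted co-dependencies at the top ranks", {
  fx <- make_screen_fixture()
  tab <- screen_codependency(fx$dep, "ANCH", fx$hi)
  planted <- tab$rank_positive[match(sprintf("P%02d", 1:5), tab$gene)]
  expect_true(all(planted <= 10))
  expect_false("ANCH" %in% tab$gene)  # anchor excluded from its own screen
  expect_true(all(tab$n_used == 46))
  # ranks are a permutation of 1..K over significant positive rows
  ranked <- tab$rank_positive[!is.na(tab$rank_positive)]
  expect_setequal(ranked, seq_along(ranked))
})

test_that("screen is invariant to cell-line order", {
  fx <- make_screen_fixture(seed = 21)
  t1 <- screen_codependency(fx$dep, "ANCH", fx$hi)
  t2 <- screen_codependency(fx$dep[, sample(colnames(fx$dep))], "ANCH",
                            sample(fx$hi))
  expect_equal(t1[order(t1$gene), ], t2[order(t2$gene), ],
               ignore_attr = TRUE)
})

test_that("constant genes and low-n genes are excluded with reasons", {
  fx <- make_screen_fixture(n_planted = 2, n_null = 8, seed = 5)
  dep <- fx$dep
  dep["Z001", ] <- 3.14
  dep["Z002", fx$hi[-(1:4)]] <- NA
  tab <- screen_codependency(dep, "ANCH", fx$hi, min_n = 10)
  excl <- attr(tab, "excluded")
  expect_equal(excl$reason[excl$gene == "Z001"], "constant_profile")
  expect_equal(excl$reason[excl$gene == "Z002"], "n_below_min")
  expect_false(any(c("Z001", "Z002") %in% tab$gene))

  all_const <- dep
  all_const[] <- 1
  all_const["ANCH", ] <- dep["ANCH", ]
  tab0 <- screen_codependency(all_const, "ANCH", fx$hi)
  expect_equal(nrow(tab0), 0)
  expect_equal(nrow(attr(tab0, "excluded")), nrow(dep) - 1)
})

test_that("screen null calibration holds at alpha = 0.05", {
  # no planted signal: fraction of genes with p < alpha ~ alpha
  fracs <- vapply(seq_len(30), function(s) {
    tr <- dependency_truth("ANCH", sprintf("Z%03d", 1:200))
    ann <- gen_scn_annotation(46, 2, 2, 0, 0.2, seed = s)
    dep <- gen_dependency_matrix(tr, ann, seed = 5000 + s)
    tab <- screen_codependency(dep, "ANCH",
                               ann$cell_line[ann$truth_group == "HI"])
    mean(tab$pearson_p < 0.05)
  }, 0)
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("candidate funnel reproduces the 6-minus-3 exclusion pattern", {
  tfs <- sprintf("TF%02d", 1:6)
  genes <- c(tfs, sprintf("Z%03d", 1:294))
  tr <- dependency_truth("ANCH", genes,
                         rho_hi = c(rep(0.7, 6), rep(0, 294)),
                         rho_lo = c(rep(0.7, 3), rep(0, 297)),
                         tf = c(rep(TRUE, 6), rep(FALSE, 294)))
  ann <- gen_scn_annotation(46, 445, 2, 0, 0.2, seed = 31)
  dep <- gen_dependency_matrix(tr, ann, seed = 31)
  part <- classify_scn(ann, 1.1)
  hi <- screen_codependency(dep, "ANCH", part$hi)
  lo <- screen_codependency(dep, "ANCH", part$lo)
  rep_ <- candidate_filter(hi, lo, tfs, top_k = 100, alpha = 0.05)
  expect_setequal(rep_$candidates, sprintf("TF%02d", 4:6))
  expect_setequal(
    rep_$provenance$gene[rep_$provenance$stage == "excluded_lo_codependency"],
    sprintf("TF%02d", 1:3))
})

test_that("funnel boundary conditions behave as documented", {
  fx <- make_screen_fixture(n_planted = 3, n_null = 100, seed = 41)
  hi <- screen_codependency(fx$dep, "ANCH", fx$hi)
  lo <- hi
  lo$pearson_p <- 1  # nothing significant in LO

  # tf list disjoint from significant genes -> no candidates
  rep0 <- candidate_filter(hi, lo, c("NOPE1", "NOPE2"))
  expect_length(rep0$candidates, 0)

  # a significant gene ranked just past top_k is excluded at the rank stage
  g2 <- hi$gene[match(2, hi$rank_positive)]
  rep1 <- candidate_filter(hi, lo, g2, top_k = 1)
  expect_length(rep1$candidates, 0)
  expect_equal(rep1$provenance$stage[rep1$provenance$gene == g2],
               "failed_rank")

  expect_error(candidate_filter(hi, lo, character(0)),
               class = "codepnet_validation_error")
})

test_that("concordance across screen technologies reports sign agreement", {
  fx <- make_screen_fixture(seed = 51)
  tab <- screen_codependency(fx$dep, "ANCH", fx$hi)
  same <- codependency_concordance(tab, tab, "P01")
  expect_true(same$agree_sign)
  expect_equal(same$r_a, same$r_b)

  flipped <- tab
  flipped$pearson_r <- -flipped$pearson_r
  expect_false(codependency_concordance(tab, flipped, "P01")$agree_sign)
  expect_error(codependency_concordance(tab, tab, "ABSENT"),
               class = "codepnet_validation_error")
})

test_that("independent screens of the same planted effect agree in sign", {
  tr <- dependency_truth("ANCH", "G1", rho_hi = 0.4)
  ann <- gen_scn_annotation(46, 2, 2, 0, 0.2, seed = 5)
  hi <- ann$cell_line[ann$truth_group == "HI"]
  agree <- vapply(seq_len(100), function(s) {
    a <- screen_codependency(gen_dependency_matrix(tr, ann, seed = s),
                             "ANCH", hi, min_n = 3)
    b <- screen_codependency(gen_dependency_matrix(tr, ann, seed = 7000 + s),
                             "ANCH", hi, min_n = 3)
    codependency_concordance(a, b, "G1")$agree_sign
  }, TRUE)
  expect_gte(mean(agree), 0.95)
})
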