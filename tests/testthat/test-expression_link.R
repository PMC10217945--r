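sim_joined <- function(n = 300L, gamma = 0.6, seed = 81L) {
  cfg <- sim_config(
    n_genes = n, bias_strength = c(0, 0.9),
    expression_coupling = gamma, seed = seed
  )
  counts <- simulate_codon_counts(cfg)
  expr <- simulate_expression(cfg, counts$truth)
  list(
    cfg = cfg, counts = counts$counts, truth = counts$truth,
    profiles = profile_genes(counts$counts),
    expression = expr$expression, expr_truth = expr$truth
  )
}

test_that("tier assignment respects the RPKM boundaries exactly", {
  expr <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    t1 = c(20, 10, 1, 0.5, 0),
    t2 = c(20, 10, 1, 0.5, 0)
  )
  profiles <- data.frame(gene = c("a", "b", "c", "d", "e"), ENC = c(40, 45, 50, 55, 60))
  tiers <- assign_tiers(expr, profiles)
  got <- stats::setNames(tiers$tier, tiers$gene_id)
  expect_equal(unname(got["a"]), "high") # > 10
  expect_equal(unname(got["b"]), "medium") # 10 exactly
  expect_equal(unname(got["c"]), "low") # 1 exactly
  expect_equal(unname(got["d"]), "low")
  expect_equal(unname(got["e"]), "excluded") # 0
  # a partition: each joined gene in exactly one tier
  expect_equal(sort(table(tiers$tier, useNA = "ifany")["excluded"]), c(excluded = 1L))
  expect_false(anyNA(tiers$tier))
})

test_that("median ENC split halves a tier with distinct ENC values", {
  expr <- data.frame(gene_id = sprintf("g%02d", 1:10), t1 = rep(50, 10))
  profiles <- data.frame(gene = sprintf("g%02d", 1:10), ENC = seq(31, 58, length.out = 10))
  tiers <- assign_tiers(expr, profiles)
  expect_equal(sum(tiers$enc_group == "strong_bias"), 5L)
  expect_equal(sum(tiers$enc_group == "weak_bias"), 5L)
  expect_true(all(tiers$ENC[tiers$enc_group == "strong_bias"] <
    tiers$ENC[tiers$enc_group == "weak_bias"][1]))
  # fixed-threshold mode
  tiers50 <- assign_tiers(expr, profiles, enc_split = 50)
  expect_equal(
    tiers50$enc_group,
    ifelse(tiers50$ENC <= 50, "strong_bias", "weak_bias")
  )
  expect_error(assign_tiers(expr, data.frame(gene = "none", ENC = 40)), "no genes shared")
})

test_that("welch_t matches the textbook formulas, t.test, and its guards", {
  x <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1, 19.6)
  y <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9, 22.1)
  w <- welch_t(x, y)
  o <- oracle_welch(x, y)
  expect_equal(w$t, unname(o["t"]), tolerance = 1e-10)
  expect_equal(w$df, unname(o["df"]), tolerance = 1e-10)
  expect_equal(w$p_value, unname(o["p"]), tolerance = 1e-10)
  tt <- t.test(x, y)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w$p_value, tt$p.value, tolerance = 1e-10)

  # identity: t = 0, p = 1
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # clear separation with the mean(x) - mean(y) sign convention
  shift <- welch_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$t, 0)
  expect_lt(shift$p_value, 0.01)
  # antisymmetry under swapping
  ab <- welch_t(x, y)
  ba <- welch_t(y, x)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p_value, ba$p_value)
  # degenerate variance
  flat <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(flat$t, 0)
  expect_equal(flat$p_value, 1)
  expect_error(welch_t(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("sequence-level test recovers planted positive coupling", {
  s <- sim_joined(n = 1200L, gamma = 0.8, seed = 91L)
  tiers <- assign_tiers(s$expression, s$profiles)
  res <- sequence_level_test(tiers)
  high <- res[res$tier == "high", ]
  expect_false(high$untestable)
  expect_gt(high$t, 0) # strong-bias genes more highly expressed
  expect_lt(high$p_value, 0.05)
  # a tiny tier is reported untestable, not an error
  few <- tiers[c(which(tiers$tier == "high")[1:4], which(tiers$tier == "medium")), ]
  few$tier[1:4] <- "high"
  few$enc_group[1:4] <- c("strong_bias", "weak_bias", "strong_bias", "weak_bias")
  res2 <- sequence_level_test(few)
  expect_true(res2$untestable[res2$tier == "high"])
})

test_that("identical strong/weak RPKM gives t = 0, p = 1", {
  tiers <- data.frame(
    gene_id = sprintf("g%d", 1:12),
    summary_rpkm = rep(c(12, 15, 20), 4),
    ENC = rep(c(40, 55), each = 6),
    tier = "high",
    enc_group = rep(c("strong_bias", "weak_bias"), each = 6)
  )
  res <- sequence_level_test(tiers)
  high <- res[res$tier == "high", ]
  expect_equal(high$t, 0)
  expect_equal(high$p_value, 1)
})

test_that("codon-level dominant base uses argmax with T > A > G > C ties", {
  profiles <- data.frame(
    gene = c("ga", "tie", "gg"),
    A3 = c(10, 5, 2), T3 = c(3, 5, 1), G3 = c(2, 1, 9), C3 = c(1, 0, 3)
  )
  expr <- data.frame(gene_id = c("ga", "tie", "gg"), t1 = c(1, 2, 3))
  res <- codon_level_groups(profiles, expr)
  g <- stats::setNames(res$groups$dominant_base, res$groups$gene_id)
  expect_equal(unname(g["ga"]), "A")
  expect_equal(unname(g["tie"]), "T") # A3 = T3 tie resolved to T
  expect_equal(unname(g["gg"]), "G")
  expect_true(res$groups$tied[res$groups$gene_id == "tie"])
  expect_equal(nrow(res$tests), 7L) # 6 pairwise + GC vs AT
})

test_that("planted G/C-expression advantage is detected at the codon level", {
  # construct genes dominated by each base, with G/C genes boosted
  set.seed(101)
  n_per <- 40L
  mk <- function(base, boost) {
    counts <- count_codons(rep(switch(base,
      A = "GCA", T = "GCT", G = "GCG", C = "GCC"
    ), 30))
    list(counts = counts, rpkm = 10^rnorm(n_per, 1 + boost, 0.2))
  }
  profiles <- do.call(rbind, lapply(c("A", "T", "G", "C"), function(b) {
    tb <- synonymous_third_base(mk(b, 0)$counts)
    data.frame(
      gene = sprintf("%s_%02d", b, 1:n_per),
      A3 = tb[["A3"]], T3 = tb[["T3"]], G3 = tb[["G3"]], C3 = tb[["C3"]]
    )
  }))
  expr <- data.frame(
    gene_id = profiles$gene,
    t1 = c(
      10^rnorm(2 * n_per, 1, 0.2), # A, T genes
      10^rnorm(2 * n_per, 1.6, 0.2) # G, C genes boosted
    )
  )
  res <- codon_level_groups(profiles, expr)
  gcat <- res$tests[res$tests$comparison == "GC3 vs AT3", ]
  expect_lt(gcat$p_value, 0.01)
  expect_gt(gcat$mean1, gcat$mean2) # G/C group higher
})

test_that("amino-acid level grouping follows the within-family count argmax", {
  counts <- rbind(
    aaa_pref = count_codons(c(rep("AAA", 5), "AAG", rep("GCT", 3))),
    aag_pref = count_codons(c("AAA", rep("AAG", 5), rep("GCT", 3))),
    tied = count_codons(c(rep("AAA", 3), rep("AAG", 3)))
  )
  expr <- data.frame(gene_id = rownames(counts), t1 = c(1, 100, 10))
  res <- amino_acid_level_groups(counts, expr)
  expect_equal(unname(res$preferred["aaa_pref", "K"]), "AAA")
  expect_equal(unname(res$preferred["aag_pref", "K"]), "AAG")
  expect_true(is.na(res$preferred["tied", "K"]))
  lys <- res$summary[res$summary$aa == "K", ]
  expect_equal(lys$n_tied, 1L)
  # family partition: 9 two-fold, 1 three-fold, 5 four-fold, 3 six-fold
  expect_equal(
    as.vector(table(factor(res$summary$family_size, levels = c(2, 3, 4, 6)))),
    c(9L, 1L, 5L, 3L)
  )
})

test_that("planted AAG-expression advantage is detected for Lys", {
  set.seed(111)
  n_per <- 50L
  counts <- rbind(
    t(replicate(n_per, count_codons(c(rep("AAA", 8), rep("AAG", 2), rep("GGT", 5))))),
    t(replicate(n_per, count_codons(c(rep("AAA", 2), rep("AAG", 8), rep("GGT", 5)))))
  )
  rownames(counts) <- sprintf("g%03d", seq_len(2 * n_per))
  expr <- data.frame(
    gene_id = rownames(counts),
    t1 = c(10^rnorm(n_per, 0.8, 0.2), 10^rnorm(n_per, 1.5, 0.2))
  )
  res <- amino_acid_level_groups(counts, expr)
  lys <- res$summary[res$summary$aa == "K", ]
  expect_false(lys$untestable)
  expect_lt(lys$p_value, 0.01)
  expect_gt(lys$mean1, lys$mean2) # G-ending (AAG) group higher
})
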