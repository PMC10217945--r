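test_that("genetic code table partitions codons as expected", {
  gc <- genetic_code_table()
  expect_equal(nrow(gc), 64L)
  expect_equal(sum(gc$is_stop), 3L)
  expect_equal(sum(!gc$is_stop), 61L)
  expect_equal(sum(gc$is_synonymous), 59L)
  cls <- degeneracy_classes()
  expect_equal(lengths(cls), c(`2` = 9L, `3` = 1L, `4` = 5L, `6` = 3L))
  expect_setequal(cls[["2"]], c("F", "Y", "H", "Q", "N", "K", "D", "E", "C"))
  expect_equal(cls[["3"]], "I")
  expect_setequal(cls[["6"]], c("L", "S", "R"))
  # sum(class size * degeneracy) + Met + Trp = 61 sense codons
  expect_equal(sum(as.integer(names(cls)) * lengths(cls)) + 2L, 61L)
})

test_that("count_codons tabulates and pools additively", {
  cnt <- count_codons(c("ATG", "GCT", "GCT", "TAA"))
  expect_equal(unname(cnt["ATG"]), 1L)
  expect_equal(unname(cnt["GCT"]), 2L)
  expect_equal(unname(cnt["TAA"]), 1L)
  expect_equal(sum(cnt), 4)
  expect_error(count_codons(character(0)), "empty")

  a <- count_codons(c("ATG", "GCT"))
  b <- count_codons(c("GCT", "AAA", "TTT"))
  expect_equal(pool_counts(rbind(a, b)), a + b)
})

test_that("RSCU matches hand-computed cases", {
  cnt <- count_codons(c(rep("TTT", 3), "TTC"))
  r <- rscu(cnt)
  expect_equal(unname(r["TTT"]), 1.5)
  expect_equal(unname(r["TTC"]), 0.5)

  # all-equal usage within a family gives RSCU 1
  cnt2 <- count_codons(c("GGT", "GGC", "GGA", "GGG"))
  expect_equal(unname(rscu(cnt2)[c("GGT", "GGC", "GGA", "GGG")]), rep(1, 4))

  # single codon of a 4-fold family takes the full weight
  cnt3 <- count_codons(rep("GCA", 4))
  r3 <- rscu(cnt3)
  expect_equal(unname(r3["GCA"]), 4)
  expect_equal(unname(r3[c("GCC", "GCG", "GCT")]), rep(0, 3))
  # absent amino acids are masked
  expect_true(is.na(r3["AAA"]))
})

test_that("RSCU sums to family degeneracy for random tables", {
  set.seed(101)
  gc <- genetic_code_table()
  fams <- split(gc$codon[gc$is_synonymous], gc$aa[gc$is_synonymous])
  for (i in 1:200) {
    cnt <- random_count_table()
    if (sum(cnt[gc$codon[!gc$is_stop]]) == 0) next
    r <- rscu(cnt)
    for (aa in names(fams)) {
      vals <- r[fams[[aa]]]
      if (all(is.na(vals))) next
      expect_equal(sum(vals), length(fams[[aa]]), tolerance = 1e-9)
      expect_true(all(vals >= 0))
    }
  }
})

test_that("ENC reproduces the homozygosity arithmetic and range endpoints", {
  # two-codon amino acid with counts (2,2): F = (4 * 0.5 - 1) / 3 = 1/3
  cnt <- count_codons(c("TTT", "TTT", "TTC", "TTC"))
  p <- c(0.5, 0.5)
  f <- (4 * sum(p^2) - 1) / 3
  expect_equal(f, 1 / 3)
  # make ENC defined by adding one amino acid per remaining class
  cnt <- cnt + count_codons(c(
    rep("ATT", 2), rep("GGG", 2), rep("CTA", 2)
  ))
  # all added families use one codon (F = 1); 2-fold class mean is 1/3
  expect_equal(enc_wright(cnt), 2 + 9 / (1 / 3) + 1 / 1 + 5 / 1 + 3 / 1)

  # extreme usage endpoints
  one_per_aa <- count_codons(rep(unname(default_preferred_codons()), each = 5))
  expect_identical(enc_wright(one_per_aa), 20)
  uniform <- count_codons(rep(synonymous_codons(), each = 10))
  expect_identical(enc_wright(uniform), 61)
})

test_that("ENC handles missing classes: Ile imputed, others fatal", {
  pref <- default_preferred_codons()
  no_ile <- pref[setdiff(names(pref), "I")]
  cnt <- count_codons(rep(unname(no_ile), each = 5))
  expect_equal(enc_wright(cnt), 20) # F3 imputed from (F2 + F4) / 2 = 1
  # drop every 6-fold amino acid -> undefined
  no6 <- pref[setdiff(names(pref), c("L", "S", "R"))]
  expect_true(is.na(enc_wright(count_codons(rep(unname(no6), each = 5)))))
})

test_that("RSCU and ENC agree with brute-force oracles on random genes", {
  set.seed(202)
  for (i in 1:50) {
    cnt <- random_count_table()
    if (sum(cnt) == 0) next
    r_pkg <- rscu(cnt)
    r_orc <- oracle_rscu(cnt)
    expect_equal(r_pkg[sort(names(r_pkg))], r_orc, tolerance = 1e-9)
    e_pkg <- enc_wright(cnt)
    e_orc <- oracle_enc(cnt)
    if (is.na(e_pkg)) expect_true(is.na(e_orc)) else {
      expect_equal(e_pkg, e_orc, tolerance = 1e-9)
    }
  }
})

test_that("RSCU agrees with seqinr on a random coding sequence", {
  set.seed(77)
  sim <- simulate_cds(sim_config(n_genes = 1L, seed = 77L))
  codons <- tokenize(sim$cds$seq[1])
  r <- rscu(count_codons(codons))
  u <- seqinr::uco(tolower(unlist(strsplit(sim$cds$seq[1], ""))), index = "rscu")
  names(u) <- toupper(names(u))
  syn <- synonymous_codons()
  expect_equal(unname(r[syn]), unname(u[syn]), tolerance = 1e-9)
})

test_that("positional GC and GC3s match direct counts", {
  gcc <- positional_gc(rep("GCC", 10))
  expect_equal(unname(gcc[c("GC1", "GC2", "GC3", "GC")]), rep(1, 4))
  gat <- positional_gc(rep("GAT", 5))
  expect_equal(unname(gat["GC1"]), 1)
  expect_equal(unname(gat["GC2"]), 0)
  expect_equal(unname(gat["GC3"]), 0)
  expect_equal(unname(gat["GC12"]), 0.5)
  # GC is always the mean of the three positions
  set.seed(3)
  for (i in 1:20) {
    cnt <- random_count_table()
    if (sum(cnt[genetic_code_table()$codon[!genetic_code_table()$is_stop]]) == 0) next
    g <- positional_gc(cnt)
    expect_equal(unname(g["GC"]), mean(g[c("GC1", "GC2", "GC3")]))
    expect_equal(unname(g["GC12"]), mean(g[c("GC1", "GC2")]))
  }

  tb <- synonymous_third_base(c("GCA", "GCT", "GCG", "GCC"))
  expect_equal(unname(tb[c("A3", "T3", "G3", "C3")]), rep(1, 4))
  expect_equal(unname(tb["GC3s"]), 0.5)
  expect_equal(unname(synonymous_third_base(c("AAA", "AAG"))["GC3s"]), 0.5)
  # Met/Trp-only input has no synonymous codons
  expect_true(all(is.na(synonymous_third_base(c("ATG", "TGG")))))
  # third-base counts partition the synonymous codons
  tb2 <- synonymous_third_base(c("GCA", "GCT", "ATG", "TAA", "AAA"))
  expect_equal(sum(tb2[c("A3", "T3", "G3", "C3")]), 3)
})

test_that("profiles compose the indices consistently", {
  set.seed(9)
  sim <- simulate_codon_counts(sim_config(n_genes = 40L, seed = 9L))
  p <- profile_genes(sim$counts, genome = "sim")
  expect_equal(nrow(p), 40L)
  expect_false(anyNA(p$GC))
  expect_equal(p$GC12, (p$GC1 + p$GC2) / 2)
  expect_equal(p$A3 + p$T3 + p$G3 + p$C3,
    vapply(seq_len(40), function(i) {
      sum(sim$counts[i, synonymous_codons()])
    }, numeric(1)),
    ignore_attr = TRUE
  )
  expect_true(all(p$ENC >= 20 & p$ENC <= 61, na.rm = TRUE))
})

test_that("pooled RSCU equals RSCU of summed counts", {
  set.seed(13)
  sim <- simulate_codon_counts(sim_config(n_genes = 15L, seed = 13L))
  pooled <- pool_counts(sim$counts)
  by_sum <- rscu(pooled)
  manual <- rscu(Reduce(`+`, lapply(seq_len(15), function(i) sim$counts[i, ])))
  expect_identical(by_sum, manual)
  tab <- pooled_rscu_table(pooled)
  expect_equal(nrow(tab), 59L)
  expect_true(all(tab$representation %in% c("over", "under", "normal", NA)))
})
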