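test_that("configs validate their domains", {
  expect_error(sim_config(length_codons = c(50L, 200L)), ">= 100")
  expect_error(sim_config(bias_strength = 1), "< 1")
  expect_error(sim_config(aa_freqs = c(A = 0.5, C = 0.4)), "sum to 1")
  expect_error(sim_config(preferred_codons = c(A = "AAA")), "does not encode")
  expect_s3_class(sim_config(seed = 1L), "cub_sim_config")
})

test_that("the generator is reproducible and the fast path matches the model", {
  cfg <- sim_config(n_genes = 15L, seed = 171L)
  a <- simulate_cds(cfg)
  b <- simulate_cds(cfg)
  expect_identical(a$cds$seq, b$cds$seq)
  expect_identical(a$truth, b$truth)
  # fast (grouped) and slow (per-gene) sampling paths draw from the same
  # distribution: compare pooled RSCU of large panels
  cfg_fast <- sim_config(n_genes = 150L, bias_strength = 0.5, seed = 181L)
  cfg_slow <- sim_config(
    n_genes = 150L, bias_strength = c(0.4999, 0.5001), seed = 181L
  ) # forces the per-gene path
  r_fast <- rscu(pool_counts(simulate_codon_counts(cfg_fast)$counts))
  slow <- simulate_codon_counts(cfg_slow)
  expect_gt(length(unique(slow$truth$beta)), 32L)
  r_slow <- rscu(pool_counts(slow$counts))
  expect_equal(r_fast, r_slow, tolerance = 0.08)
})

test_that("generated CDS are well-formed and pass QC untouched", {
  sim <- simulate_cds(sim_config(n_genes = 25L, seed = 191L))
  expect_true(all(startsWith(sim$cds$seq, "ATG")))
  ends <- substr(sim$cds$seq, nchar(sim$cds$seq) - 2, nchar(sim$cds$seq))
  expect_true(all(ends %in% c("TAA", "TAG", "TGA")))
  expect_true(all(nchar(sim$cds$seq) >= 300))
  expect_true(all(nchar(sim$cds$seq) %% 3 == 0))
  res <- qc_filter(sim$cds)
  expect_equal(res$report$n_removed_short, 0L)
  expect_equal(res$report$n_trimmed_frame, 0L)
  expect_equal(res$report$n_with_internal_stop, 0L)
})

test_that("bias strength drives RSCU and ENC as the mixture model predicts", {
  p0 <- profile_genes(simulate_codon_counts(
    sim_config(n_genes = 200L, bias_strength = 0, seed = 201L)
  )$counts)
  expect_gt(mean(p0$ENC, na.rm = TRUE), 55)

  strong <- simulate_codon_counts(
    sim_config(n_genes = 200L, bias_strength = 0.9, seed = 211L)
  )
  p9 <- profile_genes(strong$counts)
  expect_lt(mean(p9$ENC, na.rm = TRUE), 40)
  r <- rscu(pool_counts(strong$counts))
  pref <- default_preferred_codons()
  expect_true(all(r[unname(pref)] > 1))
})

test_that("mean ENC decreases monotonically along a bias grid", {
  grid <- c(0, 0.2, 0.45, 0.7, 0.9)
  means <- vapply(seq_along(grid), function(i) {
    p <- profile_genes(simulate_codon_counts(
      sim_config(n_genes = 200L, bias_strength = grid[i], seed = 220L + i)
    )$counts)
    mean(p$ENC, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("pooled GC3s is monotone in the G/C-ending share of preferred codons", {
  pref <- default_preferred_codons() # all A/T-ending
  gc_alternatives <- c(
    A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
    H = "CAC", I = "ATC", K = "AAG", L = "CTG", N = "AAC", P = "CCG",
    Q = "CAG", R = "CGC", S = "TCG", T = "ACC", V = "GTG", Y = "TAC"
  )
  shares <- c(0, 9, 18) # how many amino acids get a G/C-ending preference
  gc3s <- vapply(seq_along(shares), function(i) {
    m <- pref
    if (shares[i] > 0) {
      swap <- names(pref)[seq_len(shares[i])]
      m[swap] <- gc_alternatives[swap]
    }
    counts <- simulate_codon_counts(sim_config(
      n_genes = 80L, bias_strength = 0.7, preferred_codons = m, seed = 230L + i
    ))$counts
    unname(synonymous_third_base(pool_counts(counts))["GC3s"])
  }, numeric(1))
  expect_true(all(diff(gc3s) > 0))
})

test_that("expression coupling plants a detectable bias-RPKM correlation", {
  cfg <- sim_config(
    n_genes = 1000L, bias_strength = c(0, 0.9),
    expression_coupling = 0.8, seed = 241L
  )
  counts <- simulate_codon_counts(cfg)
  expr <- simulate_expression(cfg, counts$truth)
  e <- summarize_rpkm(expr$expression)
  nz <- e$summary_rpkm > 0
  ct <- suppressWarnings(cor.test(counts$truth$beta[nz], e$summary_rpkm[nz],
    method = "spearman"
  ))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)

  # null generator: no correlation
  cfg0 <- sim_config(
    n_genes = 1000L, bias_strength = c(0, 0.9),
    expression_coupling = 0, seed = 251L
  )
  c0 <- simulate_codon_counts(cfg0)
  e0 <- summarize_rpkm(simulate_expression(cfg0, c0$truth)$expression)
  ct0 <- suppressWarnings(cor.test(c0$truth$beta, e0$summary_rpkm, method = "spearman"))
  expect_gt(ct0$p.value, 0.01)

  # degenerate noise: expression exactly determined by tier and beta
  cfgd <- sim_config(
    n_genes = 50L, bias_strength = 0.5, sigma_gene = 0,
    sigma_tissue = 0, zero_fraction = 0, seed = 261L
  )
  cd <- simulate_codon_counts(cfgd)
  ed <- simulate_expression(cfgd, cd$truth)
  expect_equal(log10(ed$expression$root), ed$truth$mu_log_rpkm)
})

test_that("expression tiers are populated on all three levels", {
  cfg <- sim_config(n_genes = 600L, seed = 271L)
  counts <- simulate_codon_counts(cfg)
  expr <- simulate_expression(cfg, counts$truth)
  tiers <- assign_tiers(expr$expression, profile_genes(counts$counts))
  tab <- table(tiers$tier)
  expect_true(all(c("high", "medium", "low") %in% names(tab)))
  expect_true(all(tab[c("high", "medium", "low")] > 50))
})

test_that("genome panels encode divergence in RSCU distance", {
  clones <- simulate_genome_panel(
    n_genomes = 4L, divergence = 0,
    cfg = sim_config(n_genes = 60L, bias_strength = 0.6, seed = 281L)
  )
  d0 <- euclidean_distance_matrix(build_feature_matrix(clones$pooled))
  split_panel <- simulate_genome_panel(
    n_genomes = 4L, divergence = 0.7,
    cfg = sim_config(n_genes = 60L, bias_strength = 0.6, seed = 281L)
  )
  d1 <- euclidean_distance_matrix(build_feature_matrix(split_panel$pooled))
  # between-group distances dwarf the sampling noise of clones
  between <- d1["genome01", "genome02"]
  expect_gt(between, max(d0))
  expect_equal(unname(split_panel$group), rep(c(1L, 2L), 2))
})
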