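# Synthetic CDS panels and expression matrices with known codon-bias ground
# truth, so every analysis stage can be checked against the generator.

#' Default preferred-codon map
#'
#' One preferred codon per degenerate amino acid, all A/T-ending — the
#' pattern typical of plant nuclear and chloroplast coding sequences, whose
#' high-frequency codons favour A/U third bases.
#'
#' @return Named character vector (names = one-letter amino-acid codes).
#' @export
default_preferred_codons <- function() {
  c(
    A = "GCA", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
    H = "CAT", I = "ATT", K = "AAA", L = "TTA", N = "AAT", P = "CCT",
    Q = "CAA", R = "AGA", S = "TCT", T = "ACA", V = "GTT", Y = "TAT"
  )
}

#' Default amino-acid frequencies
#'
#' A flat profile over the 18 degenerate amino acids with Met and Trp at
#' roughly proteome-like low frequencies. Deliberately simple: the
#' generator's purpose is tractable ground truth, not proteome realism.
#'
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
default_aa_freqs <- function() {
  deg <- names(.syn_families)
  f <- stats::setNames(rep((1 - 0.034) / length(deg), length(deg)), deg)
  c(f, M = 0.022, W = 0.012)
}

# mean GC fraction at codon positions 1-2 for each amino acid's codons
.aa_gc12 <- vapply(
  split(( .gc1 + .gc2 ) / 2, .codon_aa)[setdiff(unique(.codon_aa), "*")],
  mean, numeric(1)
)

#' Simulation configuration
#'
#' Parameters of the codon-usage generator. Per amino acid, each codon is
#' drawn from the mixture `(1 - beta) * background + beta * point mass` on
#' the amino acid's preferred codon, so `bias_strength` (beta) moves genes
#' continuously from uniform usage (ENC near 61) to single-codon usage
#' (ENC near 20). Expression is drawn per gene as
#' `log10(RPKM) ~ Normal(mu_tier + expression_coupling * beta, sigma_gene)`
#' with tissues as noisy replicates.
#'
#' @param n_genes Number of genes.
#' @param length_codons Length range in sense codons, `c(min, max)`; the
#'   minimum must be >= 100 so every simulated CDS passes the 300-bp QC
#'   filter.
#' @param bias_strength Beta in [0, 1): a single value (all genes) or a
#'   range `c(lo, hi)` sampled uniformly per gene.
#' @param preferred_codons Named map amino acid -> preferred codon;
#'   `NA` entries leave that amino acid unbiased. See
#'   [default_preferred_codons()].
#' @param aa_freqs Amino-acid frequencies (sum to 1).
#' @param gc3_coupling Lambda in [0, 1]: strength with which a gene's
#'   amino-acid composition (hence GC1/GC2) tracks its third-base GC
#'   propensity. 0 disables the coupling (and the per-gene third-base
#'   propensity).
#' @param gc3_range Range of the per-gene third-base GC propensity used
#'   when `gc3_coupling > 0`.
#' @param expression_coupling Gamma: effect of per-gene beta on mean
#'   log10-RPKM (0 = null generator).
#' @param tissue_names Tissue column labels for the expression matrix.
#' @param tier_probs,tier_means Mixture weights and mean log10-RPKM of the
#'   planted low/medium/high expression tiers.
#' @param sigma_gene,sigma_tissue Gene-level and tissue-replicate
#'   log10-RPKM standard deviations.
#' @param zero_fraction Fraction of genes with RPKM fixed at 0 (excluded
#'   tier).
#' @param seed Integer seed; every simulation is reproducible given it.
#' @return A validated `cub_sim_config` list.
#' @export
sim_config <- function(n_genes = 200L,
                       length_codons = c(100L, 400L),
                       bias_strength = 0.5,
                       preferred_codons = default_preferred_codons(),
                       aa_freqs = default_aa_freqs(),
                       gc3_coupling = 0,
                       gc3_range = c(0.25, 0.75),
                       expression_coupling = 0.5,
                       tissue_names = c("root", "stem", "leaf", "seed"),
                       tier_probs = c(low = 0.3, medium = 0.4, high = 0.3),
                       tier_means = c(low = -0.7, medium = 0.5, high = 1.6),
                       sigma_gene = 0.3,
                       sigma_tissue = 0.1,
                       zero_fraction = 0.02,
                       seed = NULL) {
  stopifnot(
    n_genes >= 1L,
    length(length_codons) == 2L, length_codons[1L] >= 100L,
    length_codons[2L] >= length_codons[1L],
    length(bias_strength) %in% 1:2,
    all(bias_strength >= 0), all(bias_strength < 1),
    gc3_coupling >= 0, gc3_coupling <= 1,
    length(gc3_range) == 2L, all(gc3_range >= 0), all(gc3_range <= 1),
    length(tier_probs) == 3L, length(tier_means) == 3L,
    sigma_gene >= 0, sigma_tissue >= 0,
    zero_fraction >= 0, zero_fraction < 1
  )
  if (abs(sum(aa_freqs) - 1) > 1e-6) stop("amino-acid frequencies must sum to 1")
  if (any(aa_freqs < 0)) stop("amino-acid frequencies must be non-negative")
  if (!all(names(aa_freqs) %in% c(names(.syn_families), "M", "W"))) {
    stop("aa_freqs must be named by one-letter amino-acid codes")
  }
  for (aa in names(preferred_codons)) {
    pc <- preferred_codons[[aa]]
    if (!is.na(pc) && !(pc %in% .syn_families[[aa]])) {
      stop("preferred codon ", pc, " does not encode amino acid ", aa)
    }
  }
  out <- list(
    n_genes = as.integer(n_genes), length_codons = as.integer(length_codons),
    bias_strength = bias_strength, preferred_codons = preferred_codons,
    aa_freqs = aa_freqs, gc3_coupling = gc3_coupling, gc3_range = gc3_range,
    expression_coupling = expression_coupling, tissue_names = tissue_names,
    tier_probs = tier_probs, tier_means = tier_means,
    sigma_gene = sigma_gene, sigma_tissue = sigma_tissue,
    zero_fraction = zero_fraction, seed = seed
  )
  class(out) <- "cub_sim_config"
  out
}

#' @export
print.cub_sim_config <- function(x, ...) {
  b <- paste(signif(x$bias_strength, 3), collapse = "-")
  cat(
    "Codon-usage simulation config:", x$n_genes, "genes,",
    x$length_codons[1L], "-", x$length_codons[2L], "codons, beta", b,
    ", lambda", x$gc3_coupling, ", gamma", x$expression_coupling,
    ", seed", if (is.null(x$seed)) "unset" else x$seed, "\n"
  )
  invisible(x)
}

#' Genome-style simulation presets
#'
#' Convenience configurations emulating the broad look of real panels:
#' `"nuclear"` draws per-gene bias strength on (0.05, 0.45), giving a mean
#' ENC near 52 and mean GC near 0.42; `"chloroplast"` draws on (0.1, 0.55),
#' giving mean ENC near 50 and a lower GC. Both inherit the A/T-ending
#' preferred-codon map. The targets are qualitative — the generator aims at
#' plausible index ranges, not at reproducing any particular genome.
#'
#' @param preset `"nuclear"` or `"chloroplast"`.
#' @param ... Overrides passed to [sim_config()].
#' @return A `cub_sim_config`.
#' @export
sim_preset <- function(preset = c("nuclear", "chloroplast"), ...) {
  preset <- match.arg(preset)
  beta <- switch(preset,
    nuclear = c(0.05, 0.45),
    chloroplast = c(0.10, 0.55)
  )
  args <- list(...)
  if (is.null(args$bias_strength)) args$bias_strength <- beta
  do.call(sim_config, args)
}

.mixture_weights <- function(fam, preferred, beta, base_w = NULL) {
  k <- length(fam)
  if (is.null(base_w)) base_w <- rep(1 / k, k)
  if (is.na(preferred)) return(base_w)
  w <- (1 - beta) * base_w
  j <- match(preferred, fam)
  w[j] <- w[j] + beta
  w
}

#' Simulate per-gene codon counts
#'
#' The count-level core of the generator (string-free, fast): per gene,
#' amino-acid occurrences are drawn from `aa_freqs` and each amino acid's
#' codons from the bias mixture. Sense codons only; start/stop codons are
#' added when sequences are realized by [simulate_cds()].
#'
#' @param cfg A `cub_sim_config`.
#' @return List: `counts` (genes x 64 integer matrix, row names = gene
#'   ids), `truth` (data.frame `gene_id`, `beta`, `length_codons`, `g3`),
#'   `config`.
#' @export
simulate_codon_counts <- function(cfg) {
  stopifnot(inherits(cfg, "cub_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  beta <- if (length(cfg$bias_strength) == 1L) {
    rep(cfg$bias_strength, n)
  } else {
    stats::runif(n, cfg$bias_strength[1L], cfg$bias_strength[2L])
  }
  len <- sample(seq(cfg$length_codons[1L], cfg$length_codons[2L]), n, replace = TRUE)
  g3 <- if (cfg$gc3_coupling > 0) {
    stats::runif(n, cfg$gc3_range[1L], cfg$gc3_range[2L])
  } else {
    rep(NA_real_, n)
  }

  counts <- matrix(0L, n, 64L, dimnames = list(ids, CODONS))
  aa_names <- names(cfg$aa_freqs)
  pref <- cfg$preferred_codons

  slow <- cfg$gc3_coupling > 0 || length(unique(beta)) > 32L
  if (!slow) {
    # draws are iid given the amino acid and the gene's beta group, so one
    # big sample per (amino acid, beta group) can be dealt back to genes
    gene_of <- rep(seq_len(n), len)
    aas <- sample(aa_names, sum(len), replace = TRUE, prob = cfg$aa_freqs)
    bg <- match(beta, unique(beta))
    for (aa in aa_names) {
      sel <- which(aas == aa)
      if (length(sel) == 0L) next
      if (aa %in% names(SINGLE_CODON_AA)) {
        col <- match(SINGLE_CODON_AA[[aa]], CODONS)
        counts[, col] <- counts[, col] + tabulate(gene_of[sel], nbins = n)
        next
      }
      fam <- .syn_families[[aa]]
      cols <- match(fam, CODONS)
      pc <- if (aa %in% names(pref)) pref[[aa]] else NA_character_
      for (b in unique(bg)) {
        sb <- sel[bg[gene_of[sel]] == b]
        if (length(sb) == 0L) next
        w <- .mixture_weights(fam, pc, unique(beta)[b])
        draw <- sample.int(length(fam), length(sb), replace = TRUE, prob = w)
        g <- gene_of[sb]
        for (j in seq_along(fam)) {
          counts[, cols[j]] <- counts[, cols[j]] + tabulate(g[draw == j], nbins = n)
        }
      }
    }
  } else {
    for (i in seq_len(n)) {
      fr <- cfg$aa_freqs
      if (cfg$gc3_coupling > 0) {
        # tilt amino-acid composition with the gene's third-base propensity
        eta <- cfg$gc3_coupling * 6 * (g3[i] - 0.5)
        fr <- fr * exp(eta * (2 * .aa_gc12[names(fr)] - 1))
        fr <- fr / sum(fr)
      }
      n_aa <- as.vector(stats::rmultinom(1L, len[i], fr))
      names(n_aa) <- names(fr)
      for (aa in names(fr)) {
        if (n_aa[[aa]] == 0L) next
        if (aa %in% names(SINGLE_CODON_AA)) {
          col <- match(SINGLE_CODON_AA[[aa]], CODONS)
          counts[i, col] <- counts[i, col] + n_aa[[aa]]
          next
        }
        fam <- .syn_families[[aa]]
        base_w <- if (cfg$gc3_coupling > 0) {
          w0 <- ifelse(substr(fam, 3L, 3L) %in% c("G", "C"), g3[i], 1 - g3[i])
          w0 / sum(w0)
        } else {
          NULL
        }
        pc <- if (aa %in% names(pref)) pref[[aa]] else NA_character_
        w <- .mixture_weights(fam, pc, beta[i], base_w)
        counts[i, match(fam, CODONS)] <- counts[i, match(fam, CODONS)] +
          as.vector(stats::rmultinom(1L, n_aa[[aa]], w))
      }
    }
  }

  truth <- data.frame(
    gene_id = ids, beta = beta, length_codons = len, g3 = g3,
    stringsAsFactors = FALSE
  )
  list(counts = counts, truth = truth, config = cfg)
}

#' Simulate a CDS panel
#'
#' Realizes the counts of [simulate_codon_counts()] as nucleotide
#' sequences: codons in random order, an ATG start prepended and a stop
#' codon appended, so every CDS starts with ATG, ends with a stop, has no
#' internal stop, and is at least 306 bp.
#'
#' @param cfg A `cub_sim_config`.
#' @param genome Genome label for the returned `cds_set`.
#' @return List: `cds` (a `cds_set`), `truth`, `counts`, `config`.
#' @export
simulate_cds <- function(cfg, genome = "synthetic") {
  res <- simulate_codon_counts(cfg)
  n <- nrow(res$counts)
  stops <- sample(STOP_CODONS, n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    body <- rep(CODONS, res$counts[i, ])
    paste0(c("ATG", sample(body), stops[i]), collapse = "")
  }, character(1))
  cds <- data.frame(
    id = res$truth$gene_id,
    genome = genome,
    seq = seqs,
    description = res$truth$gene_id,
    stringsAsFactors = FALSE
  )
  class(cds) <- c("cds_set", "data.frame")
  list(cds = cds, truth = res$truth, counts = res$counts, config = cfg)
}

#' Simulate an expression matrix coupled to bias strength
#'
#' Per gene, `log10(RPKM) ~ Normal(mu_tier + gamma * beta, sigma_gene)`
#' with the tier drawn from `tier_probs`; tissues are noisy replicates
#' (`sigma_tissue`), and a `zero_fraction` of genes is set to 0 across all
#' tissues (the excluded tier). With `expression_coupling = 0` this is the
#' null generator: expression carries no information about codon bias.
#'
#' @param cfg A `cub_sim_config`.
#' @param truth Truth table from [simulate_codon_counts()] /
#'   [simulate_cds()] (per-gene beta).
#' @param seed Seed for the expression draw; defaults to `cfg$seed + 500009`
#'   so sequence and expression draws are independent yet jointly
#'   reproducible.
#' @return List: `expression` (data.frame `gene_id` + one column per
#'   tissue), `truth` (per-gene tier, expected and realized log10-RPKM).
#' @export
simulate_expression <- function(cfg, truth, seed = NULL) {
  stopifnot(inherits(cfg, "cub_sim_config"), is.data.frame(truth))
  if (is.null(seed) && !is.null(cfg$seed)) seed <- (cfg$seed %% 2100000000L) + 500009L
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  tiers <- names(cfg$tier_probs)
  tier <- sample(tiers, n, replace = TRUE, prob = cfg$tier_probs)
  mu <- unname(cfg$tier_means[tier]) + cfg$expression_coupling * truth$beta
  x <- stats::rnorm(n, mu, cfg$sigma_gene)
  zero <- stats::runif(n) < cfg$zero_fraction
  tis <- lapply(cfg$tissue_names, function(t) {
    v <- 10^(x + stats::rnorm(n, 0, cfg$sigma_tissue))
    v[zero] <- 0
    v
  })
  names(tis) <- cfg$tissue_names
  expression <- cbind(
    data.frame(gene_id = truth$gene_id, stringsAsFactors = FALSE),
    as.data.frame(tis)
  )
  truth_out <- data.frame(
    gene_id = truth$gene_id, beta = truth$beta, tier_true = tier,
    mu_log_rpkm = mu, log_rpkm = x, zeroed = zero,
    stringsAsFactors = FALSE
  )
  list(expression = expression, truth = truth_out)
}

#' Simulate a profile panel with a known neutrality slope
#'
#' Profile-level generator for the neutrality regression: GC3 uniform on
#' `gc3_range` and `GC12 = intercept + slope * GC3 + Normal(0, sigma)`.
#' This gives exact ground truth for the regression slope (the
#' sequence-level generator's `gc3_coupling` produces a monotone but
#' uncalibrated coupling).
#'
#' @param n Number of genes.
#' @param slope True regression slope (1 = fully mutation-coupled, 0 =
#'   decoupled).
#' @param intercept Intercept; default `0.45 * (1 - slope)` keeps GC12 in a
#'   plant-like range for any slope.
#' @param sigma Gaussian noise sd on GC12.
#' @param gc3_range Range of GC3.
#' @param seed Optional seed.
#' @return data.frame `gene`, `GC3`, `GC12` (consumable by
#'   [neutrality_fit()]).
#' @export
simulate_neutrality_panel <- function(n = 2000L, slope = 0.3, intercept = NULL,
                                      sigma = 0.02, gc3_range = c(0.2, 0.8),
                                      seed = NULL) {
  stopifnot(n >= 3L, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(intercept)) intercept <- 0.45 * (1 - slope)
  gc3 <- stats::runif(n, gc3_range[1L], gc3_range[2L])
  gc12 <- intercept + slope * gc3 + stats::rnorm(n, 0, sigma)
  data.frame(
    gene = sprintf("g%05d", seq_len(n)),
    GC3 = gc3,
    GC12 = pmin(pmax(gc12, 0), 1),
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-genome panel with planted group structure
#'
#' Generates `n_genomes` genomes whose preferred-codon maps are perturbed
#' versions of the base map: genomes are assigned round-robin to
#' `n_groups` groups, and each group's map reassigns the preferred codon of
#' `round(divergence * 18)` amino acids to a different synonymous codon.
#' Divergence therefore controls inter-group RSCU distance; genomes within
#' a group differ only by sampling noise.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param divergence Fraction of amino acids whose preferred codon is
#'   reassigned per group, in [0, 1].
#' @param cfg Per-genome `cub_sim_config` (its `n_genes` applies to every
#'   genome; its seed seeds the whole panel).
#' @param n_groups Number of planted groups.
#' @return List: `pooled` (named list of pooled 64-codon count vectors, one
#'   per genome), `group` (named integer vector, the planted partition),
#'   `maps` (per-group preferred-codon maps), `config`.
#' @export
simulate_genome_panel <- function(n_genomes = 6L, divergence = 0.5,
                                  cfg = sim_config(n_genes = 50L, seed = 1L),
                                  n_groups = 2L) {
  stopifnot(n_genomes >= 2L, divergence >= 0, divergence <= 1, n_groups >= 1L)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  base_map <- cfg$preferred_codons
  n_swap <- round(divergence * length(.syn_families))
  maps <- lapply(seq_len(n_groups), function(g) {
    m <- base_map
    if (n_swap > 0L) {
      swap_aa <- sample(names(.syn_families), n_swap)
      for (aa in swap_aa) {
        alts <- setdiff(.syn_families[[aa]], m[[aa]])
        m[[aa]] <- if (length(alts) == 1L) alts else sample(alts, 1L)
      }
    }
    m
  })
  group <- rep(seq_len(n_groups), length.out = n_genomes)
  labels <- sprintf("genome%02d", seq_len(n_genomes))
  names(group) <- labels
  pooled <- vector("list", n_genomes)
  names(pooled) <- labels
  for (i in seq_len(n_genomes)) {
    cfg_i <- cfg
    cfg_i$preferred_codons <- maps[[group[i]]]
    cfg_i$seed <- NULL # continue the panel-level stream
    pooled[[i]] <- pool_counts(simulate_codon_counts(cfg_i)$counts)
  }
  list(pooled = pooled, group = group, maps = maps, config = cfg)
}
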