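# End-to-end orchestration: QC -> indices -> diagnostics -> optimal codons
# -> expression association -> RSCU clustering, with every table written as
# TSV and a run log.

.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}

.pkg_version <- function() {
  as.character(utils::packageVersion("cubtools"))
}

#' Run the full codon-usage-bias pipeline
#'
#' Executes the analysis stages in order over one or more CDS FASTA files
#' (one per genome): QC filtering, per-gene usage profiles, pooled RSCU,
#' ENC-plot / PR2 / neutrality diagnostics, optimal-codon determination,
#' the three-level expression association (when an expression table is
#' given), and RSCU-based genome clustering (when >= 2 genomes are given).
#' Every output is a TSV (or Newick) file under `out_dir`; with identical
#' inputs and settings the outputs are bitwise reproducible.
#'
#' @param cds_files Character vector of CDS FASTA paths; names, if set, are
#'   the genome labels.
#' @param expression_file Optional RPKM TSV (see [read_expression_tsv()]);
#'   genes are matched to profiles by id across all genomes.
#' @param out_dir Output directory (created if missing).
#' @param min_len QC length threshold in bp.
#' @param fraction ENC-extreme tail fraction for optimal codons.
#' @param delta_min,rscu_min,over,under Optimal-codon and representation
#'   thresholds.
#' @param tier_thresholds RPKM tier cutoffs `c(high, low)`.
#' @param enc_split `"median"` or a fixed ENC value for the within-tier
#'   bias split.
#' @param linkage Clustering linkage.
#' @param k Optional flat-cluster count for the genome dendrogram.
#' @param ref_tree Optional Newick file for a Robinson-Foulds comparison
#'   against the RSCU dendrogram.
#' @param plots Also write SVG diagnostic plots.
#' @param strict Strict QC (reject frame/internal-stop sequences).
#' @return Invisibly, a named list of the written file paths plus the main
#'   in-memory results.
#' @export
run_cub_pipeline <- function(cds_files,
                             expression_file = NULL,
                             out_dir = "cub_results",
                             min_len = 300L,
                             fraction = 0.05,
                             delta_min = 0.08,
                             rscu_min = 1,
                             over = 1.6,
                             under = 0.6,
                             tier_thresholds = c(10, 1),
                             enc_split = "median",
                             linkage = "average",
                             k = NULL,
                             ref_tree = NULL,
                             plots = FALSE,
                             strict = FALSE) {
  stopifnot(length(cds_files) >= 1L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c(
    paste0("cubtools ", .pkg_version()),
    paste0("genomes: ", length(cds_files))
  )
  say <- function(...) log_lines <<- c(log_lines, paste0(...))
  ver <- paste0("cubtools ", .pkg_version())
  outputs <- list()

  labels <- names(cds_files)
  if (is.null(labels)) {
    labels <- sub("\\.(fa|fasta|fna|ffn)$", "", basename(cds_files), ignore.case = TRUE)
  }

  # stage 1: read + QC, per genome
  qc_flags <- list()
  counts_by_genome <- list()
  profiles <- list()
  pooled <- list()
  for (i in seq_along(cds_files)) {
    g <- labels[i]
    cds <- read_cds_fasta(cds_files[i], genome_label = g)
    qcr <- qc_filter(cds, min_len = min_len, strict = strict)
    say(
      "qc[", g, "]: input ", qcr$report$n_input, ", kept ", qcr$report$n_kept,
      ", removed_short ", qcr$report$n_removed_short,
      ", trimmed ", qcr$report$n_trimmed_frame,
      ", internal_stop ", qcr$report$n_with_internal_stop
    )
    if (nrow(qcr$kept) == 0L) stop("stage qc: no sequences kept for genome ", g)
    qc_flags[[g]] <- qcr$report$flags
    cm <- codon_count_matrix(tokenize_cds(qcr$kept))
    counts_by_genome[[g]] <- cm
    profiles[[g]] <- profile_genes(cm, genome = g)
    pooled[[g]] <- pool_counts(cm)
  }
  prof <- do.call(rbind, profiles)
  rownames(prof) <- NULL
  outputs$qc_report <- .write_tsv(
    do.call(rbind, qc_flags), file.path(out_dir, "qc_report.tsv"),
    paste0(ver, " | per-sequence QC flags (min_len=", min_len, ")")
  )
  outputs$profiles <- .write_tsv(
    prof, file.path(out_dir, "profiles.tsv"),
    paste0(ver, " | per-gene codon usage indices")
  )

  # stage 2: pooled RSCU per genome
  rscu_tabs <- lapply(labels, function(g) {
    cbind(genome = g, pooled_rscu_table(pooled[[g]], over = over, under = under))
  })
  outputs$pooled_rscu <- .write_tsv(
    do.call(rbind, rscu_tabs), file.path(out_dir, "pooled_rscu.tsv"),
    paste0(ver, " | pooled RSCU per genome (over>", over, ", under<", under, ")")
  )

  # stage 3: diagnostics per genome (pooled across genomes would mix scales)
  enc_tabs <- list()
  pr2_tabs <- list()
  neut_rows <- list()
  for (g in labels) {
    p <- profiles[[g]]
    enc_tabs[[g]] <- cbind(genome = g, enc_plot_table(p))
    pr2_tabs[[g]] <- cbind(genome = g, pr2_table(p))
    nf <- tryCatch(neutrality_fit(p), error = function(e) NULL)
    if (is.null(nf)) {
      say("neutrality[", g, "]: not fit (", nrow(p), " genes)")
    } else {
      neut_rows[[g]] <- data.frame(
        genome = g, n_genes = nf$n_genes, slope = nf$slope,
        intercept = nf$intercept, pearson_r = nf$pearson_r,
        p_value = nf$p_value,
        gc12_min = nf$gc12_range[1L], gc12_max = nf$gc12_range[2L],
        gc3_min = nf$gc3_range[1L], gc3_max = nf$gc3_range[2L],
        stringsAsFactors = FALSE
      )
    }
  }
  outputs$enc_plot <- .write_tsv(
    do.call(rbind, enc_tabs), file.path(out_dir, "enc_plot.tsv"),
    paste0(ver, " | ENC-plot points; deviation = ENC_exp - ENC_obs")
  )
  outputs$pr2 <- .write_tsv(
    do.call(rbind, pr2_tabs), file.path(out_dir, "pr2.tsv"),
    paste0(ver, " | PR2 coordinates over synonymous third bases")
  )
  if (length(neut_rows) > 0L) {
    outputs$neutrality <- .write_tsv(
      do.call(rbind, neut_rows), file.path(out_dir, "neutrality.tsv"),
      paste0(ver, " | neutrality regression GC12 ~ GC3 per genome")
    )
  }

  # stage 4: optimal codons per genome
  opt_tabs <- list()
  for (g in labels) {
    oc <- tryCatch(
      find_optimal_codons(counts_by_genome[[g]], profiles[[g]],
        fraction = fraction, delta_min = delta_min, rscu_min = rscu_min,
        over = over, under = under
      ),
      error = function(e) {
        say("optimal[", g, "]: skipped (", conditionMessage(e), ")")
        NULL
      }
    )
    if (!is.null(oc)) {
      s <- ending_base_summary(oc)
      say(
        "optimal[", g, "]: ", s[["n_optimal"]], " optimal codons (A:", s[["A"]],
        ", U:", s[["U"]], ", G:", s[["G"]], ", C:", s[["C"]], ")"
      )
      opt_tabs[[g]] <- cbind(genome = g, as.data.frame(oc))
    }
  }
  if (length(opt_tabs) > 0L) {
    outputs$optimal_codons <- .write_tsv(
      do.call(rbind, opt_tabs), file.path(out_dir, "optimal_codons.tsv"),
      paste0(
        ver, " | delta-RSCU optimal codon calls (tails=", fraction,
        ", delta>", delta_min, ", RSCU>", rscu_min, ")"
      )
    )
  }

  # stage 5: expression association
  expr_results <- NULL
  if (!is.null(expression_file)) {
    expr <- summarize_rpkm(read_expression_tsv(expression_file))
    all_counts <- do.call(rbind, counts_by_genome)
    tiers <- assign_tiers(expr, prof,
      enc_split = enc_split,
      tier_thresholds = tier_thresholds
    )
    say("expression: ", nrow(tiers), " genes joined; tiers ", paste(
      names(table(tiers$tier)), as.integer(table(tiers$tier)),
      sep = "=", collapse = ", "
    ))
    seq_tests <- sequence_level_test(tiers)
    cod <- codon_level_groups(prof, expr)
    aal <- amino_acid_level_groups(all_counts, expr)
    outputs$tiers <- .write_tsv(
      tiers, file.path(out_dir, "expression_tiers.tsv"),
      paste0(ver, " | tier and within-tier ENC group per gene")
    )
    std_cols <- c(
      "comparison", "n1", "n2", "mean1", "mean2", "t", "df",
      "p_value", "p_adj", "untestable"
    )
    aa_block <- aal$summary
    names(aa_block)[names(aa_block) == "n_gc"] <- "n1"
    names(aa_block)[names(aa_block) == "n_at"] <- "n2"
    test_summary <- rbind(
      cbind(level = "sequence", detail = seq_tests$tier, seq_tests[std_cols]),
      cbind(level = "codon", detail = cod$tests$comparison, cod$tests[std_cols]),
      cbind(level = "amino_acid", detail = aa_block$aa3, aa_block[std_cols])
    )
    test_summary$significant <- !test_summary$untestable &
      !is.na(test_summary$p_value) & test_summary$p_value < 0.05
    outputs$expression_tests <- .write_tsv(
      test_summary, file.path(out_dir, "expression_tests.tsv"),
      paste0(ver, " | Welch tests on log10(RPKM+1) at three levels")
    )
    expr_results <- list(tiers = tiers, sequence = seq_tests, codon = cod, amino_acid = aal)
  }

  # stage 6: clustering (>= 2 genomes)
  cluster_results <- NULL
  if (length(labels) >= 2L) {
    fm <- build_feature_matrix(pooled)
    dm <- euclidean_distance_matrix(fm)
    hc <- agglomerate(dm, linkage = linkage)
    outputs$distance_matrix <- .write_tsv(
      data.frame(genome = rownames(dm), dm, check.names = FALSE),
      file.path(out_dir, "rscu_distance.tsv"),
      paste0(ver, " | Euclidean distances over 59 pooled RSCU values")
    )
    outputs$dendrogram <- write_newick(hc, file.path(out_dir, "rscu_dendrogram.nwk"))
    if (!is.null(k)) {
      cl <- cut_clusters(hc, k)
      outputs$clusters <- .write_tsv(
        data.frame(genome = names(cl), cluster = unname(cl)),
        file.path(out_dir, "rscu_clusters.tsv"),
        paste0(ver, " | flat clusters at k=", k)
      )
    }
    rf <- NULL
    if (!is.null(ref_tree)) {
      rf <- compare_topology(hc, ref_tree)
      say(
        "topology vs reference: RF = ", rf$rf, " / ", rf$max_rf,
        " over ", rf$n_taxa, " taxa"
      )
    }
    cluster_results <- list(features = fm, dist = dm, hclust = hc, rf = rf)
  }

  if (plots) {
    grDevices::svg(file.path(out_dir, "enc_plot.svg"), width = 6, height = 5)
    plot_enc(do.call(rbind, enc_tabs), main = "ENC plot")
    grDevices::dev.off()
    grDevices::svg(file.path(out_dir, "pr2_plot.svg"), width = 5, height = 5)
    plot_pr2(do.call(rbind, pr2_tabs), main = "PR2 plot")
    grDevices::dev.off()
    outputs$plots <- file.path(out_dir, c("enc_plot.svg", "pr2_plot.svg"))
  }

  outputs$log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, outputs$log)

  invisible(list(
    outputs = outputs, profiles = prof, pooled = pooled,
    expression = expr_results, clustering = cluster_results,
    log = log_lines
  ))
}
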