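# Expression-bias association at three levels (sequence, codon, amino acid),
# with Welch t-tests throughout.

.log_rpkm <- function(x, log_transform = TRUE) {
  if (log_transform) log10(x + 1) else x
}

.tissue_cols <- function(expr) {
  stopifnot(is.data.frame(expr), "gene_id" %in% names(expr))
  setdiff(names(expr), c("gene_id", "summary_rpkm"))
}

#' Summarize per-tissue RPKM
#'
#' Adds a `summary_rpkm` column: by default the mean across tissue columns
#' (single-tissue selection via `tissue`).
#'
#' @param expr Expression data.frame from [read_expression_tsv()].
#' @param tissue Optional single tissue column name to use instead of the
#'   cross-tissue mean.
#' @return `expr` with a `summary_rpkm` column appended.
#' @export
summarize_rpkm <- function(expr, tissue = NULL) {
  tc <- .tissue_cols(expr)
  if (length(tc) == 0L) stop("no tissue columns in expression table")
  if (is.null(tissue)) {
    expr$summary_rpkm <- rowMeans(as.matrix(expr[tc]))
  } else {
    stopifnot(tissue %in% tc)
    expr$summary_rpkm <- expr[[tissue]]
  }
  expr
}

#' Welch's two-sample t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom and a two-sided
#' p-value, with the sign convention `t = (mean(x) - mean(y)) / se`. Guards
#' the degenerate cases the analysis can produce: both samples constant with
#' equal means gives t = 0, p = 1; constant samples with different means
#' give an infinite t and p = 0.
#'
#' @param x,y Numeric samples (each n >= 3).
#' @param labels Length-2 character vector naming the groups.
#' @return A `welch_test` list: `labels`, `n1`, `n2`, `mean1`, `mean2`,
#'   `t`, `df`, `p_value`, `significant` (p < 0.05).
#' @export
welch_t <- function(x, y, labels = c("x", "y")) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) stop("each sample needs n >= 3")
  n1 <- length(x)
  n2 <- length(y)
  m1 <- mean(x)
  m2 <- mean(y)
  v1 <- stats::var(x)
  v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    tt <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    df <- n1 + n2 - 2
    p <- if (m1 == m2) 1 else 0
  } else {
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tt), df = df)
  }
  out <- list(
    labels = labels, n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
    t = tt, df = df, p_value = p, significant = is.finite(p) && p < 0.05
  )
  class(out) <- "welch_test"
  out
}

#' @export
print.welch_test <- function(x, digits = 4, ...) {
  cat(
    "Welch t-test:", x$labels[1L], "(n =", paste0(x$n1, ")"), "vs",
    x$labels[2L], "(n =", paste0(x$n2, ")\n")
  )
  cat(
    "  means:", signif(x$mean1, digits), "vs", signif(x$mean2, digits),
    " t =", signif(x$t, digits), " df =", signif(x$df, digits),
    " p =", format.pval(x$p_value, digits = digits), "\n"
  )
  invisible(x)
}

.welch_row <- function(x, y, comparison, log_transform = TRUE) {
  if (sum(!is.na(x)) < 3L || sum(!is.na(y)) < 3L) {
    return(data.frame(
      comparison = comparison, n1 = sum(!is.na(x)), n2 = sum(!is.na(y)),
      mean1 = NA_real_, mean2 = NA_real_, t = NA_real_, df = NA_real_,
      p_value = NA_real_, untestable = TRUE, stringsAsFactors = FALSE
    ))
  }
  w <- welch_t(.log_rpkm(x, log_transform), .log_rpkm(y, log_transform))
  data.frame(
    comparison = comparison, n1 = w$n1, n2 = w$n2,
    mean1 = w$mean1, mean2 = w$mean2, t = w$t, df = w$df,
    p_value = w$p_value, untestable = FALSE, stringsAsFactors = FALSE
  )
}

#' Assign expression tiers and within-tier bias groups
#'
#' Joins expression with codon-usage profiles (inner join on gene id;
#' unmatched genes are counted) and assigns each gene an expression tier —
#' high (RPKM > 10), medium (1 < RPKM <= 10), low (0 < RPKM <= 1); genes
#' with RPKM = 0 are excluded — plus, within each tier, a codon-bias group:
#' strong_bias (ENC <= split point) or weak_bias (ENC > split point). The
#' split point is the within-tier median ENC by default, or a fixed ENC
#' value.
#'
#' @param expr Expression data.frame (a `summary_rpkm` column is added via
#'   [summarize_rpkm()] if absent).
#' @param profiles Profile data.frame with `gene` and `ENC`.
#' @param enc_split `"median"` or a fixed numeric ENC threshold.
#' @param tier_thresholds Length-2 numeric `c(high, low)` RPKM cutoffs
#'   (default `c(10, 1)`).
#' @return data.frame `gene_id`, `summary_rpkm`, `ENC`, `tier`,
#'   `enc_group`, with attribute `n_unmatched`.
#' @export
assign_tiers <- function(expr, profiles, enc_split = "median",
                         tier_thresholds = c(10, 1)) {
  stopifnot(is.data.frame(profiles), all(c("gene", "ENC") %in% names(profiles)))
  if (!"summary_rpkm" %in% names(expr)) expr <- summarize_rpkm(expr)
  d <- merge(
    expr[c("gene_id", "summary_rpkm")],
    data.frame(
      gene_id = profiles$gene, ENC = profiles$ENC,
      stringsAsFactors = FALSE
    ),
    by = "gene_id"
  )
  if (nrow(d) == 0L) stop("no genes shared between expression table and profiles")
  n_unmatched <- (nrow(expr) - nrow(d)) + (nrow(profiles) - nrow(d))
  hi <- tier_thresholds[1L]
  lo <- tier_thresholds[2L]
  r <- d$summary_rpkm
  d$tier <- ifelse(r == 0, "excluded",
    ifelse(r > hi, "high", ifelse(r > lo, "medium", "low"))
  )
  d$enc_group <- NA_character_
  for (tier in c("high", "medium", "low")) {
    i <- which(d$tier == tier & !is.na(d$ENC))
    if (length(i) == 0L) next
    split_at <- if (identical(enc_split, "median")) {
      stats::median(d$ENC[i])
    } else {
      as.numeric(enc_split)
    }
    d$enc_group[i] <- ifelse(d$ENC[i] <= split_at, "strong_bias", "weak_bias")
  }
  rownames(d) <- NULL
  attr(d, "n_unmatched") <- n_unmatched
  d
}

#' Sequence-level expression test
#'
#' Within each expression tier, Welch-tests summary RPKM (log10(x + 1) by
#' default) between the strong-bias and weak-bias ENC groups. Positive t
#' means the strongly biased genes are the more highly expressed. Tiers
#' where either group has fewer than 3 genes are reported untestable.
#'
#' @param assignments Output of [assign_tiers()].
#' @param log_transform Test on log10(RPKM + 1) (default) or raw RPKM.
#' @return data.frame with one row per tier: `tier`, `comparison`, `n1`
#'   (strong), `n2` (weak), group means, `t`, `df`, `p_value`, `p_adj`
#'   (Benjamini-Hochberg across tiers), `significant` (raw p < 0.05),
#'   `untestable`.
#' @export
sequence_level_test <- function(assignments, log_transform = TRUE) {
  stopifnot(all(c("tier", "enc_group", "summary_rpkm") %in% names(assignments)))
  rows <- lapply(c("high", "medium", "low"), function(tier) {
    d <- assignments[assignments$tier == tier & !is.na(assignments$enc_group), ]
    r <- .welch_row(
      d$summary_rpkm[d$enc_group == "strong_bias"],
      d$summary_rpkm[d$enc_group == "weak_bias"],
      "strong_bias vs weak_bias", log_transform
    )
    cbind(data.frame(tier = tier, stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !out$untestable & out$p_value < 0.05
  rownames(out) <- NULL
  out
}

#' Codon-level third-base groups and expression tests
#'
#' Assigns every gene its dominant third base over synonymous codons (the
#' base with the maximal count; ties broken by the fixed order T > A > G >
#' C) and Welch-tests summary RPKM between all 6 base-group pairs plus the
#' combined G/C-ending versus A/T-ending comparison.
#'
#' @param profiles Profile data.frame with `A3`, `T3`, `G3`, `C3`.
#' @param expr Expression data.frame (summary added if absent).
#' @param log_transform Test on log10(RPKM + 1) (default).
#' @return List with `groups` (data.frame `gene_id`, `dominant_base`,
#'   `summary_rpkm`, `tied`) and `tests` (data.frame of 7 Welch rows with
#'   BH-adjusted p-values).
#' @export
codon_level_groups <- function(profiles, expr, log_transform = TRUE) {
  stopifnot(all(c("gene", "A3", "T3", "G3", "C3") %in% names(profiles)))
  if (!"summary_rpkm" %in% names(expr)) expr <- summarize_rpkm(expr)
  d <- merge(
    data.frame(
      gene_id = profiles$gene,
      A3 = profiles$A3, T3 = profiles$T3, G3 = profiles$G3, C3 = profiles$C3,
      stringsAsFactors = FALSE
    ),
    expr[c("gene_id", "summary_rpkm")],
    by = "gene_id"
  )
  if (nrow(d) == 0L) stop("no genes shared between profiles and expression table")
  cnt <- as.matrix(d[c("T3", "A3", "G3", "C3")]) # tie order T > A > G > C
  base_order <- c("T", "A", "G", "C")
  best <- apply(cnt, 1L, which.max) # which.max takes the first maximum
  mx <- cnt[cbind(seq_len(nrow(cnt)), best)]
  tied <- rowSums(cnt == mx) > 1L
  groups <- data.frame(
    gene_id = d$gene_id,
    dominant_base = base_order[best],
    summary_rpkm = d$summary_rpkm,
    tied = tied,
    stringsAsFactors = FALSE
  )
  rpkm_of <- function(bases) groups$summary_rpkm[groups$dominant_base %in% bases]
  pairs <- utils::combn(c("A", "T", "G", "C"), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    b1 <- pairs[1L, j]
    b2 <- pairs[2L, j]
    .welch_row(rpkm_of(b1), rpkm_of(b2), paste0(b1, "3 vs ", b2, "3"), log_transform)
  })
  rows <- c(rows, list(
    .welch_row(rpkm_of(c("G", "C")), rpkm_of(c("A", "T")), "GC3 vs AT3", log_transform)
  ))
  tests <- do.call(rbind, rows)
  tests$p_adj <- stats::p.adjust(tests$p_value, method = "BH")
  tests$significant <- !tests$untestable & tests$p_value < 0.05
  rownames(tests) <- NULL
  list(groups = groups, tests = tests)
}

#' Amino-acid-level preferred-codon groups and expression tests
#'
#' For each of the 18 degenerate amino acids, genes are grouped by the
#' synonymous codon attaining the gene's maximal RSCU for that amino acid
#' (within one amino acid this is the maximal count; genes with a tie are
#' excluded for that amino acid and counted). Genes preferring a G/C-ending
#' codon are then Welch-tested against genes preferring an A/T-ending codon
#' on summary RPKM. Amino-acid families are reported as two-codon (9),
#' three-codon (Ile), four-codon (5), and six-codon (3) groups.
#'
#' @param counts_matrix Genes x 64 codon count matrix (row names = gene ids).
#' @param expr Expression data.frame (summary added if absent).
#' @param log_transform Test on log10(RPKM + 1) (default).
#' @return List with `summary` (one row per amino acid: `aa`, `aa3`,
#'   `family_size`, `n_gc`, `n_at`, `n_tied`, means, `t`, `df`, `p_value`,
#'   `p_adj`, `significant`, `untestable`) and `preferred` (genes x 18
#'   character matrix of preferred codons, `NA` = tied or absent).
#' @export
amino_acid_level_groups <- function(counts_matrix, expr, log_transform = TRUE) {
  stopifnot(is.matrix(counts_matrix), !is.null(rownames(counts_matrix)))
  if (!"summary_rpkm" %in% names(expr)) expr <- summarize_rpkm(expr)
  common <- intersect(rownames(counts_matrix), expr$gene_id)
  if (length(common) == 0L) stop("no genes shared between counts and expression table")
  m <- counts_matrix[common, , drop = FALSE]
  rpkm <- expr$summary_rpkm[match(common, expr$gene_id)]

  preferred <- matrix(NA_character_,
    nrow = length(common), ncol = length(.syn_families),
    dimnames = list(common, names(.syn_families))
  )
  rows <- lapply(names(.syn_families), function(aa) {
    fam <- .syn_families[[aa]]
    sub <- m[, fam, drop = FALSE]
    tot <- rowSums(sub)
    mx <- apply(sub, 1L, max)
    n_best <- rowSums(sub == mx)
    usable <- tot > 0 & n_best == 1L
    pref <- rep(NA_character_, length(common))
    pref[usable] <- fam[apply(sub[usable, , drop = FALSE], 1L, which.max)]
    preferred[, aa] <<- pref
    ends_gc <- substr(pref, 3L, 3L) %in% c("G", "C")
    x <- rpkm[usable & ends_gc]
    y <- rpkm[usable & !ends_gc]
    r <- .welch_row(x, y, "GC-ending vs AT-ending", log_transform)
    cbind(
      data.frame(
        aa = aa, aa3 = .aa3[[aa]], family_size = length(fam),
        n_tied = sum(tot > 0 & n_best > 1L), stringsAsFactors = FALSE
      ),
      r
    )
  })
  summary <- do.call(rbind, rows)
  names(summary)[names(summary) == "n1"] <- "n_gc"
  names(summary)[names(summary) == "n2"] <- "n_at"
  summary$p_adj <- stats::p.adjust(summary$p_value, method = "BH")
  summary$significant <- !summary$untestable & !is.na(summary$p_value) &
    summary$p_value < 0.05
  rownames(summary) <- NULL
  list(summary = summary, preferred = preferred)
}
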