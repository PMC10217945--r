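# Optimal-codon determination: ENC-extreme gene groups, per-codon delta-RSCU
# between the pooled groups, and the RSCU > 1 & delta > 0.08 call.

#' Select ENC-extreme gene groups
#'
#' Sorts genes by ENC and takes the lowest-ENC fraction as the high-bias
#' group and the highest-ENC fraction as the low-bias group (ENC is
#' inversely related to bias strength). Group size is
#' `ceiling(fraction * n)`; ties at either cutoff are broken by gene id
#' (lexicographic), so the selection is deterministic.
#'
#' @param profiles Profile data.frame with `gene` and `ENC` columns.
#' @param fraction Tail fraction (default 0.05, each tail).
#' @return An `extreme_groups` list: `high_bias_ids`, `low_bias_ids`,
#'   `fraction`, `size`, `n_genes`.
#' @export
select_extreme_groups <- function(profiles, fraction = 0.05) {
  stopifnot(
    is.data.frame(profiles), all(c("gene", "ENC") %in% names(profiles)),
    fraction > 0, fraction <= 0.5
  )
  ok <- !is.na(profiles$ENC)
  gene <- as.character(profiles$gene[ok])
  enc <- profiles$ENC[ok]
  n <- length(enc)
  size <- as.integer(ceiling(fraction * n))
  if (size < 2L || 2L * size > n) {
    stop(
      "too few genes with defined ENC (", n, ") for tail fraction ", fraction,
      ": each tail needs >= 2 genes and the tails must be disjoint"
    )
  }
  lo <- order(enc, gene) # ascending ENC = strongest bias first
  hi <- order(-enc, gene) # descending ENC = weakest bias first
  out <- list(
    high_bias_ids = gene[lo[seq_len(size)]],
    low_bias_ids = gene[hi[seq_len(size)]],
    fraction = fraction,
    size = size,
    n_genes = n
  )
  class(out) <- "extreme_groups"
  out
}

#' @export
print.extreme_groups <- function(x, ...) {
  cat(
    "ENC-extreme groups:", x$size, "genes per tail (fraction", x$fraction,
    "of", x$n_genes, "genes)\n"
  )
  invisible(x)
}

#' Per-codon RSCU difference between pooled gene groups
#'
#' RSCU is computed on the pooled codon counts of each group and differenced
#' as `delta = rscu_high - rscu_low` (high-bias minus low-bias; the sign
#' convention matters — a positive delta marks codons enriched in the
#' strongly biased genes). Codons of an amino acid absent from either pool
#' are `NA`.
#'
#' @param high_counts,low_counts Pooled 64-codon count vectors for the
#'   high-bias (low-ENC) and low-bias (high-ENC) groups.
#' @return data.frame with one row per synonymous codon: `codon`, `aa`,
#'   `third_base`, `rscu_high`, `rscu_low`, `delta`.
#' @export
delta_rscu <- function(high_counts, low_counts) {
  high_counts <- .check_counts(high_counts)
  low_counts <- .check_counts(low_counts)
  if (n_sense_codons(high_counts) < 1) stop("empty high-bias pool")
  if (n_sense_codons(low_counts) < 1) stop("empty low-bias pool")
  rh <- rscu(high_counts)
  rl <- rscu(low_counts)
  idx <- match(SYN_CODONS, CODONS)
  out <- data.frame(
    codon = SYN_CODONS,
    aa = .codon_aa[idx],
    third_base = .base3[idx],
    rscu_high = unname(rh),
    rscu_low = unname(rl),
    delta = unname(rh - rl),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Call optimal codons
#'
#' A codon is optimal when it is both highly used in the high-bias pool
#' (RSCU > 1, strict) and enriched there relative to the low-bias pool
#' (delta-RSCU > 0.08, strict). When a whole-dataset pooled RSCU is
#' supplied, codons are additionally flagged over-represented (RSCU > 1.6)
#' or under-represented (RSCU < 0.6) on that pooled usage.
#'
#' @param dr delta-RSCU table from [delta_rscu()].
#' @param rscu_all Optional 59-long pooled RSCU vector (whole dataset) for
#'   the representation flag.
#' @param delta_min,rscu_min Optimality thresholds (defaults 0.08 and 1).
#' @param over,under Representation thresholds (defaults 1.6 and 0.6).
#' @return An `optimal_codon_calls` data.frame: the `dr` columns plus
#'   `is_high_frequency`, `is_optimal`, `rscu_pooled`, `representation`.
#' @export
call_optimal <- function(dr, rscu_all = NULL, delta_min = 0.08, rscu_min = 1,
                         over = 1.6, under = 0.6) {
  stopifnot(
    is.data.frame(dr),
    all(c("codon", "aa", "rscu_high", "rscu_low", "delta") %in% names(dr))
  )
  if (all(is.na(dr$delta))) stop("delta-RSCU undefined for every codon")
  out <- dr
  out$is_high_frequency <- !is.na(out$rscu_high) & out$rscu_high > rscu_min
  out$is_optimal <- out$is_high_frequency & !is.na(out$delta) & out$delta > delta_min
  if (!is.null(rscu_all)) {
    rp <- rscu_all[out$codon]
    out$rscu_pooled <- unname(rp)
    out$representation <- ifelse(is.na(rp), NA_character_,
      ifelse(rp > over, "over", ifelse(rp < under, "under", "normal"))
    )
  } else {
    out$rscu_pooled <- NA_real_
    out$representation <- NA_character_
  }
  class(out) <- c("optimal_codon_calls", "data.frame")
  out
}

#' Summarize optimal-codon calls by ending base
#'
#' @param calls An `optimal_codon_calls` data.frame.
#' @return Named integer vector `c(n_optimal, A, U, G, C)` counting optimal
#'   codons by third base (T reported as U, RNA-style).
#' @export
ending_base_summary <- function(calls) {
  opt <- calls[calls$is_optimal, , drop = FALSE]
  tb <- factor(opt$third_base, levels = c("A", "T", "G", "C"))
  n <- table(tb)
  c(
    n_optimal = nrow(opt),
    A = unname(n[["A"]]), U = unname(n[["T"]]),
    G = unname(n[["G"]]), C = unname(n[["C"]])
  )
}

#' @export
print.optimal_codon_calls <- function(x, ...) {
  s <- ending_base_summary(x)
  cat(
    "Optimal codons:", s[["n_optimal"]],
    sprintf("(A:%d, U:%d, G:%d, C:%d)\n", s[["A"]], s[["U"]], s[["G"]], s[["C"]])
  )
  opt <- x[x$is_optimal, c("codon", "aa", "rscu_high", "rscu_low", "delta")]
  if (nrow(opt) > 0L) print.data.frame(opt, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Optimal codons from per-gene counts and profiles
#'
#' Convenience wrapper: selects the ENC-extreme groups, pools their codon
#' counts, computes delta-RSCU, and calls optimal codons. The
#' representation flag uses the RSCU of all genes pooled.
#'
#' @param counts_matrix Genes x 64 codon count matrix (row names = gene
#'   ids, as from [codon_count_matrix()]).
#' @param profiles Matching profile data.frame (for ENC).
#' @param fraction Tail fraction for [select_extreme_groups()].
#' @param ... Thresholds passed to [call_optimal()].
#' @return An `optimal_codon_calls` data.frame with the `extreme_groups`
#'   attached as attribute `groups`.
#' @export
find_optimal_codons <- function(counts_matrix, profiles, fraction = 0.05, ...) {
  stopifnot(is.matrix(counts_matrix), !is.null(rownames(counts_matrix)))
  groups <- select_extreme_groups(profiles, fraction)
  miss <- setdiff(c(groups$high_bias_ids, groups$low_bias_ids), rownames(counts_matrix))
  if (length(miss) > 0L) {
    stop("genes missing from count matrix: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  high <- pool_counts(counts_matrix[groups$high_bias_ids, , drop = FALSE])
  low <- pool_counts(counts_matrix[groups$low_bias_ids, , drop = FALSE])
  all_pool <- pool_counts(counts_matrix)
  calls <- call_optimal(delta_rscu(high, low), rscu_all = rscu(all_pool), ...)
  attr(calls, "groups") <- groups
  calls
}
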