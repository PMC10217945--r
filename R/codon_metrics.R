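# Per-gene and pooled codon-usage indices: codon counts, RSCU, Wright's ENC,
# positional GC content, and synonymous third-base composition.

#' Count codons
#'
#' Tabulates a codon vector into the fixed 64-codon table (alphabetical
#' order). Pooling genes is elementwise addition of their count vectors.
#'
#' @param codons Character vector of codons (e.g. from [tokenize()]).
#' @return Named integer vector of length 64.
#' @export
count_codons <- function(codons) {
  if (length(codons) == 0L) stop("empty codon list")
  idx <- match(codons, CODONS)
  if (anyNA(idx)) {
    stop("invalid codon(s): ", paste(utils::head(unique(codons[is.na(idx)]), 5L),
      collapse = ", "
    ))
  }
  counts <- tabulate(idx, nbins = 64L)
  names(counts) <- CODONS
  counts
}

#' Per-gene codon count matrix
#'
#' @param codon_list Named list of codon vectors (from [tokenize_cds()]).
#' @return Integer matrix, genes x 64 codons.
#' @export
codon_count_matrix <- function(codon_list) {
  stopifnot(is.list(codon_list), length(codon_list) >= 1L)
  m <- t(vapply(codon_list, count_codons, integer(64L)))
  colnames(m) <- CODONS
  m
}

#' Pool codon counts
#'
#' @param counts A genes x 64 count matrix, or a list of 64-long count
#'   vectors.
#' @return Named numeric vector of length 64 (elementwise sum).
#' @export
pool_counts <- function(counts) {
  if (is.list(counts)) counts <- do.call(rbind, counts)
  if (is.null(dim(counts))) return(.check_counts(counts))
  stopifnot(ncol(counts) == 64L)
  out <- colSums(counts)
  names(out) <- CODONS
  out
}

.check_counts <- function(counts) {
  if (length(counts) != 64L || is.null(names(counts)) ||
    !identical(names(counts), CODONS)) {
    if (!is.null(names(counts)) && setequal(names(counts), CODONS)) {
      counts <- counts[CODONS]
    } else {
      stop("expected a 64-codon count vector named by codon")
    }
  }
  if (any(counts < 0)) stop("negative codon count")
  counts
}

n_sense_codons <- function(counts) sum(counts[.is_sense])

#' Relative synonymous codon usage (RSCU)
#'
#' For amino acid i with synonymous-family degeneracy n_i and codon counts
#' X_ij, RSCU_ij = X_ij / ((1/n_i) * sum_j X_ij): the observed count divided
#' by the count expected were all synonymous codons of that amino acid used
#' equally. Values above 1 mark preferred codons. Met, Trp and stop codons
#' carry no synonymous choice and are excluded; amino acids absent from the
#' input get `NA` for all their codons.
#'
#' @param counts A 64-codon count vector (gene-level or pooled).
#' @return Named numeric vector over the 59 synonymous codons.
#' @export
rscu <- function(counts) {
  counts <- .check_counts(counts)
  if (n_sense_codons(counts) < 1) stop("count table has no sense codons")
  out <- stats::setNames(rep(NA_real_, length(SYN_CODONS)), SYN_CODONS)
  for (fam in .syn_family_idx) {
    x <- counts[fam]
    n_aa <- sum(x)
    if (n_aa > 0) out[CODONS[fam]] <- x / (n_aa / length(fam))
  }
  out
}

#' Wright's effective number of codons (ENC)
#'
#' Summarizes how far a gene's synonymous codon usage departs from uniform:
#' 20 means one codon per amino acid, 61 uniform usage of all synonymous
#' codons. For each degenerate amino acid with occurrence count n >= 2 the
#' codon homozygosity is estimated as F = (n * sum(p^2) - 1) / (n - 1) with
#' p the within-family codon proportions; amino acids with F <= 0 or n < 2
#' are excluded. F is averaged within each degeneracy class and
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6. A missing three-fold mean (Ile
#' absent) is imputed as (F2 + F4)/2; a missing two-, four- or six-fold mean
#' makes ENC `NA`. Estimates above 61 are capped at 61.
#'
#' @param counts A 64-codon count vector for one gene.
#' @return ENC in [20, 61], or `NA` when undefined.
#' @references Wright F (1990) The 'effective number of codons' used in a
#'   gene. Gene 87:23-29.
#' @export
enc_wright <- function(counts) {
  counts <- .check_counts(counts)
  fhat <- rep(NA_real_, length(.syn_family_idx))
  deg <- .syn_degeneracy
  for (k in seq_along(.syn_family_idx)) {
    x <- counts[.syn_family_idx[[k]]]
    n_aa <- sum(x)
    if (n_aa < 2) next
    p <- x / n_aa
    f <- (n_aa * sum(p * p) - 1) / (n_aa - 1)
    if (f > 0) fhat[k] <- f
  }
  fbar <- function(d) {
    v <- fhat[deg == d & !is.na(fhat)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  f2 <- fbar(2L)
  f3 <- fbar(3L)
  f4 <- fbar(4L)
  f6 <- fbar(6L)
  if (is.na(f2) || is.na(f4) || is.na(f6)) return(NA_real_)
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  enc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(enc, 61)
}

#' Positional GC content
#'
#' GC fraction at each codon position over all sense codons, plus GC (mean
#' of the three positions) and GC12 (mean of positions 1 and 2, the
#' dependent variable of the neutrality plot).
#'
#' @param x Codon vector or 64-codon count vector.
#' @return Named numeric vector `GC`, `GC1`, `GC2`, `GC3`, `GC12`.
#' @export
positional_gc <- function(x) {
  counts <- if (is.character(x)) count_codons(x) else .check_counts(x)
  n <- n_sense_codons(counts)
  if (n < 1) stop("no sense codons")
  w <- counts[.is_sense] / n
  gc1 <- sum(w[.gc1[.is_sense]])
  gc2 <- sum(w[.gc2[.is_sense]])
  gc3 <- sum(w[.gc3[.is_sense]])
  c(
    GC = (gc1 + gc2 + gc3) / 3, GC1 = gc1, GC2 = gc2, GC3 = gc3,
    GC12 = (gc1 + gc2) / 2
  )
}

#' Third-base composition over synonymous codons
#'
#' Counts of A/T/G/C at the third position of the 59 synonymous codons
#' (Met, Trp and stops excluded) and GC3s = (G3 + C3) / (A3 + T3 + G3 + C3).
#' With no synonymous codons present all values are `NA`.
#'
#' @param x Codon vector or 64-codon count vector.
#' @return Named numeric vector `A3`, `T3`, `G3`, `C3`, `GC3s`.
#' @export
synonymous_third_base <- function(x) {
  counts <- if (is.character(x)) count_codons(x) else .check_counts(x)
  syn <- counts[.is_syn]
  tot <- sum(syn)
  if (tot < 1) {
    return(c(A3 = NA_real_, T3 = NA_real_, G3 = NA_real_, C3 = NA_real_, GC3s = NA_real_))
  }
  b3 <- .base3[.is_syn]
  a3 <- sum(syn[b3 == "A"])
  t3 <- sum(syn[b3 == "T"])
  g3 <- sum(syn[b3 == "G"])
  c3 <- sum(syn[b3 == "C"])
  c(A3 = a3, T3 = t3, G3 = g3, C3 = c3, GC3s = (g3 + c3) / tot)
}

.profile_from_counts <- function(counts, gene_id, genome = NA_character_,
                                 length_codons = sum(counts)) {
  gc <- positional_gc(counts)
  tb <- synonymous_third_base(counts)
  data.frame(
    gene = gene_id,
    genome = genome,
    length_codons = as.integer(length_codons),
    n_sense = as.integer(n_sense_codons(counts)),
    ENC = enc_wright(counts),
    GC = gc[["GC"]], GC1 = gc[["GC1"]], GC2 = gc[["GC2"]], GC3 = gc[["GC3"]],
    GC12 = gc[["GC12"]], GC3s = tb[["GC3s"]],
    A3 = tb[["A3"]], T3 = tb[["T3"]], G3 = tb[["G3"]], C3 = tb[["C3"]],
    stringsAsFactors = FALSE
  )
}

#' Codon-usage profile of one gene
#'
#' Bundles all per-gene indices (ENC, positional GC, GC3s, third-base
#' counts) into a one-row data.frame.
#'
#' @param codons Codon vector for the gene.
#' @param gene_id,genome Identifiers carried into the output.
#' @return One-row data.frame with columns `gene`, `genome`,
#'   `length_codons`, `n_sense`, `ENC`, `GC`, `GC1`, `GC2`, `GC3`, `GC12`,
#'   `GC3s`, `A3`, `T3`, `G3`, `C3`.
#' @export
profile_gene <- function(codons, gene_id = "gene", genome = NA_character_) {
  counts <- count_codons(codons)
  .profile_from_counts(counts, gene_id, genome, length_codons = length(codons))
}

#' Codon-usage profiles for a gene collection
#'
#' @param codon_list Named list of codon vectors, or a genes x 64 count
#'   matrix with gene ids as row names.
#' @param genome Genome label stored with every profile.
#' @return data.frame, one row per gene (see [profile_gene()]).
#' @export
profile_genes <- function(codon_list, genome = NA_character_) {
  if (is.matrix(codon_list)) {
    m <- codon_list
    ids <- rownames(m)
    if (is.null(ids)) ids <- sprintf("g%04d", seq_len(nrow(m)))
    rows <- lapply(seq_len(nrow(m)), function(i) {
      .profile_from_counts(m[i, ], ids[i], genome)
    })
  } else {
    ids <- names(codon_list)
    if (is.null(ids)) ids <- sprintf("g%04d", seq_along(codon_list))
    rows <- mapply(profile_gene, codon_list, ids,
      MoreArgs = list(genome = genome), SIMPLIFY = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled RSCU table
#'
#' RSCU of a pooled codon count vector, one row per synonymous codon, with
#' over-/under-representation flags at the conventional 1.6 / 0.6 cutoffs.
#'
#' @param counts Pooled 64-codon count vector.
#' @param over,under RSCU cutoffs for the representation flag.
#' @return data.frame with columns `codon`, `aa`, `aa3`, `third_base`,
#'   `count`, `rscu`, `representation` (over/under/normal), ordered by amino
#'   acid then codon.
#' @export
pooled_rscu_table <- function(counts, over = 1.6, under = 0.6) {
  counts <- .check_counts(counts)
  r <- rscu(counts)
  idx <- match(SYN_CODONS, CODONS)
  out <- data.frame(
    codon = SYN_CODONS,
    aa = .codon_aa[idx],
    aa3 = .aa3[.codon_aa[idx]],
    third_base = .base3[idx],
    count = as.integer(counts[idx]),
    rscu = unname(r),
    stringsAsFactors = FALSE
  )
  out$representation <- ifelse(is.na(out$rscu), NA_character_,
    ifelse(out$rscu > over, "over", ifelse(out$rscu < under, "under", "normal"))
  )
  out[order(out$aa, out$codon), , drop = FALSE]
}
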