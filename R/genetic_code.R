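# Standard genetic code (DNA alphabet), codon order fixed alphabetically so that
# every table and file this package writes is byte-reproducible.

.standard_code <- c(
  AAA = "K", AAC = "N", AAG = "K", AAT = "N",
  ACA = "T", ACC = "T", ACG = "T", ACT = "T",
  AGA = "R", AGC = "S", AGG = "R", AGT = "S",
  ATA = "I", ATC = "I", ATG = "M", ATT = "I",
  CAA = "Q", CAC = "H", CAG = "Q", CAT = "H",
  CCA = "P", CCC = "P", CCG = "P", CCT = "P",
  CGA = "R", CGC = "R", CGG = "R", CGT = "R",
  CTA = "L", CTC = "L", CTG = "L", CTT = "L",
  GAA = "E", GAC = "D", GAG = "E", GAT = "D",
  GCA = "A", GCC = "A", GCG = "A", GCT = "A",
  GGA = "G", GGC = "G", GGG = "G", GGT = "G",
  GTA = "V", GTC = "V", GTG = "V", GTT = "V",
  TAA = "*", TAC = "Y", TAG = "*", TAT = "Y",
  TCA = "S", TCC = "S", TCG = "S", TCT = "S",
  TGA = "*", TGC = "C", TGG = "W", TGT = "C",
  TTA = "L", TTC = "F", TTG = "L", TTT = "F"
)

CODONS <- names(.standard_code)
STOP_CODONS <- CODONS[.standard_code == "*"]
SENSE_CODONS <- CODONS[.standard_code != "*"]
# single-codon amino acids: Met (ATG), Trp (TGG) carry no synonymous choice
SINGLE_CODON_AA <- c(M = "ATG", W = "TGG")
SYN_CODONS <- setdiff(SENSE_CODONS, SINGLE_CODON_AA)

.aa3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln", E = "Glu",
  G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys", M = "Met", F = "Phe",
  P = "Pro", S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val"
)

# synonymous families: 18 degenerate amino acids -> their codons (alphabetical)
.syn_aa <- sort(setdiff(unique(.standard_code), c("*", "M", "W")))
.syn_families <- lapply(.syn_aa, function(a) CODONS[.standard_code == a])
names(.syn_families) <- .syn_aa
.syn_family_idx <- lapply(.syn_families, function(cod) match(cod, CODONS))
.syn_degeneracy <- vapply(.syn_families, length, integer(1))

# per-codon helper indicators, aligned with CODONS
.codon_aa <- unname(.standard_code)
.is_sense <- .codon_aa != "*"
.is_syn <- CODONS %in% SYN_CODONS
.base1 <- substr(CODONS, 1L, 1L)
.base2 <- substr(CODONS, 2L, 2L)
.base3 <- substr(CODONS, 3L, 3L)
.gc1 <- .base1 %in% c("G", "C")
.gc2 <- .base2 %in% c("G", "C")
.gc3 <- .base3 %in% c("G", "C")

#' The standard genetic code as a table
#'
#' One row per codon (DNA alphabet, alphabetical order) with its amino acid,
#' synonymous-family degeneracy, and the roles used throughout the package:
#' stop codons and the two single-codon amino acids (Met, Trp) are excluded
#' from all synonymous-usage statistics, leaving the 59 synonymous codons.
#'
#' @return A data.frame with columns `codon`, `aa` (one-letter), `aa3`
#'   (three-letter), `degeneracy` (1 for Met/Trp, NA for stops),
#'   `is_stop`, `is_synonymous`, `third_base`.
#' @examples
#' gc <- genetic_code_table()
#' sum(gc$is_synonymous)  # 59
#' @export
genetic_code_table <- function() {
  deg <- ifelse(.codon_aa == "*", NA_integer_,
    ifelse(.codon_aa %in% names(SINGLE_CODON_AA), 1L,
      .syn_degeneracy[.codon_aa]
    )
  )
  data.frame(
    codon = CODONS,
    aa = .codon_aa,
    aa3 = ifelse(.codon_aa == "*", "Stp", .aa3[.codon_aa]),
    degeneracy = as.integer(deg),
    is_stop = !.is_sense,
    is_synonymous = .is_syn,
    third_base = .base3,
    stringsAsFactors = FALSE
  )
}

#' The 59 synonymous codons
#'
#' @return Character vector of the 59 codons with a synonymous alternative
#'   (61 sense codons minus ATG and TGG), alphabetical.
#' @export
synonymous_codons <- function() SYN_CODONS

#' Degeneracy classes of the degenerate amino acids
#'
#' The 18 amino acids with synonymous choice, partitioned by family size as
#' used in Wright's effective-number-of-codons statistic: 9 two-fold, 1
#' three-fold (Ile), 5 four-fold, 3 six-fold (Leu, Ser, Arg).
#'
#' @return Named list with elements `"2"`, `"3"`, `"4"`, `"6"`, each a
#'   character vector of one-letter amino-acid codes.
#' @export
degeneracy_classes <- function() {
  split(names(.syn_degeneracy), .syn_degeneracy)
}
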