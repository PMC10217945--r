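# CDS FASTA / expression-table input, QC filtering, codon tokenization.

#' Read a CDS FASTA file
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file of protein-coding
#' sequences. Sequences are upper-cased and RNA-style `U` is normalized to
#' `T`, so both DNA and mRNA alphabets are accepted; otherwise sequences are
#' stored exactly as read. The record id is the header token up to the first
#' whitespace; the full header is kept as `description`.
#'
#' @param path Path to a FASTA file.
#' @param genome_label Label attached to every record (one CDS file per
#'   genome is the expected layout). Defaults to the file name without
#'   extension.
#' @return A `cds_set`: data.frame with columns `id`, `genome`, `seq`,
#'   `description`, one row per FASTA record, input order preserved.
#' @seealso [qc_filter()], [write_cds_fasta()]
#' @export
read_cds_fasta <- function(path, genome_label = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  # fail with a line number if sequence data precedes the first header
  con <- file(path, "r")
  on.exit(close(con))
  lineno <- 0L
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L) stop("empty FASTA file: ", path)
    lineno <- lineno + 1L
    if (nzchar(trimws(ln))) break
  }
  if (!startsWith(trimws(ln), ">")) {
    stop(
      "malformed FASTA (", path, "): sequence data before first header at line ",
      lineno
    )
  }
  close(con)
  on.exit()

  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("malformed FASTA (", path, "): empty record id")
  if (anyDuplicated(ids)) {
    stop(
      "duplicate sequence id(s) in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  seqs <- chartr("U", "T", toupper(as.character(x)))
  if (is.null(genome_label)) {
    genome_label <- sub("\\.(fa|fasta|fna|ffn)$", "", basename(path),
      ignore.case = TRUE
    )
  }
  out <- data.frame(
    id = unname(ids),
    genome = genome_label,
    seq = unname(seqs),
    description = unname(headers),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cds_set", "data.frame")
  out
}

#' Write a CDS collection as FASTA
#'
#' @param cds A `cds_set` (or any data.frame with `id` and `seq` columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  stopifnot(is.data.frame(cds), all(c("id", "seq") %in% names(cds)))
  x <- Biostrings::BStringSet(cds$seq)
  names(x) <- cds$id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Quality-control filter for CDS sequences
#'
#' Removes sequences shorter than `min_len` (strictly; a sequence of exactly
#' `min_len` bp is kept). The length test applies to the raw sequence, before
#' any frame trimming. Kept sequences whose length is not a multiple of three
#' have the trailing 1-2 bases trimmed and are flagged; sequences containing
#' an in-frame internal stop codon are flagged. Under the default policy
#' flagged sequences are retained (stop codons are excluded from all codon
#' statistics downstream); with `strict = TRUE` they are rejected instead.
#'
#' @param cds A `cds_set` from [read_cds_fasta()].
#' @param min_len Minimum raw length in bp (default 300, >= 3).
#' @param strict Reject (rather than flag) frame-trimmed and internal-stop
#'   sequences.
#' @return A `qc_result` list with elements `kept` (filtered `cds_set`,
#'   trimmed in frame) and `report` (counts `n_input`, `n_kept`,
#'   `n_removed_short`, `n_trimmed_frame`, `n_with_internal_stop`, plus a
#'   per-sequence `flags` data.frame).
#' @export
qc_filter <- function(cds, min_len = 300L, strict = FALSE) {
  stopifnot(is.data.frame(cds), all(c("id", "seq") %in% names(cds)))
  if (nrow(cds) == 0L) stop("no sequences")
  if (min_len < 3L) stop("min_len must be >= 3")

  len <- nchar(cds$seq)
  removed_short <- len < min_len
  trimmed_len <- (len %/% 3L) * 3L
  trimmed <- !removed_short & trimmed_len < len

  seq_trim <- substr(cds$seq, 1L, trimmed_len)
  internal_stop <- rep(FALSE, nrow(cds))
  keep_idx <- which(!removed_short)
  for (i in keep_idx) {
    cod <- .split_codons(seq_trim[i])
    body <- cod[-length(cod)] # the terminal codon may legitimately be a stop
    internal_stop[i] <- any(body %in% STOP_CODONS)
  }

  keep <- !removed_short
  if (strict) keep <- keep & !trimmed & !internal_stop
  kept <- cds[keep, , drop = FALSE]
  kept$seq <- seq_trim[keep]
  rownames(kept) <- NULL
  class(kept) <- c("cds_set", "data.frame")

  n_trim <- sum(trimmed)
  if (n_trim > 0L && !strict) {
    warning(n_trim, " sequence(s) not a multiple of 3 bp; trailing bases trimmed")
  }

  flags <- data.frame(
    id = cds$id,
    genome = if ("genome" %in% names(cds)) cds$genome else NA_character_,
    length_bp = len,
    removed_short = removed_short,
    trimmed_frame = trimmed & !removed_short,
    internal_stop = internal_stop,
    stringsAsFactors = FALSE
  )
  report <- list(
    n_input = nrow(cds),
    n_kept = nrow(kept),
    n_removed_short = sum(removed_short),
    n_trimmed_frame = sum(trimmed),
    n_with_internal_stop = sum(internal_stop),
    min_len = as.integer(min_len),
    strict = strict,
    flags = flags
  )
  out <- list(kept = kept, report = report)
  class(out) <- "qc_result"
  out
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat("CDS quality control (min length ", r$min_len, " bp",
    if (r$strict) ", strict", ")\n",
    sep = ""
  )
  cat(
    "  input:", r$n_input, " kept:", r$n_kept,
    " removed (<", r$min_len, "bp):", r$n_removed_short, "\n"
  )
  cat(
    "  frame-trimmed:", r$n_trimmed_frame,
    " internal stop:", r$n_with_internal_stop, "\n"
  )
  invisible(x)
}

.split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Tokenize a CDS into codons
#'
#' Splits a sequence into non-overlapping 3-mers from position 1. Codons
#' containing any symbol outside A/C/G/T (ambiguity codes, gaps) are skipped
#' and counted in the `n_skipped_ambiguous` attribute. A trailing partial
#' codon (sequence length not a multiple of 3) is ignored.
#'
#' @param seq A single nucleotide string (>= 3 bases), or a one-row
#'   `cds_set`.
#' @return Character vector of codons with attribute `n_skipped_ambiguous`.
#' @export
tokenize <- function(seq) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L, "seq" %in% names(seq))
    seq <- seq$seq
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  cod <- .split_codons(seq)
  ok <- !grepl("[^ACGT]", cod)
  out <- cod[ok]
  attr(out, "n_skipped_ambiguous") <- sum(!ok)
  out
}

#' Tokenize every sequence of a CDS collection
#'
#' @param cds A `cds_set`.
#' @return Named list (by sequence id) of codon vectors, each as returned by
#'   [tokenize()].
#' @export
tokenize_cds <- function(cds) {
  stopifnot(is.data.frame(cds), all(c("id", "seq") %in% names(cds)))
  out <- lapply(cds$seq, tokenize)
  names(out) <- cds$id
  out
}

#' Read a gene-expression table (RPKM)
#'
#' Tab-separated, header row required; first column gene id, remaining
#' columns numeric RPKM values (one per tissue). Duplicate gene ids and
#' negative values are rejected.
#'
#' @param path Path to a TSV file.
#' @return data.frame with column `gene_id` followed by one numeric column
#'   per tissue.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (ncol(df) < 2L) stop("expression table needs a gene-id column and >= 1 tissue column")
  # a header of numbers means the first data row was consumed as the header
  hdr <- colnames(df)[-1L]
  if (all(!is.na(suppressWarnings(as.numeric(hdr))))) {
    stop("expression table appears to have no header row: ", path)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop(
      "duplicate gene id(s) in expression table: ",
      paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", ")
    )
  }
  vals <- df[-1L]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) stop("non-numeric RPKM value in column '", names(vals)[j], "'")
    if (any(v < 0)) stop("negative RPKM value in column '", names(vals)[j], "'")
    vals[[j]] <- v
  }
  out <- cbind(data.frame(gene_id = ids, stringsAsFactors = FALSE), vals)
  rownames(out) <- NULL
  out
}
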