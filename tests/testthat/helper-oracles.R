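# Brute-force oracles, independent of the package's table-indexed
# implementations: plain loops over codons and the genetic code.

oracle_code <- local({
  gc <- genetic_code_table()
  stats::setNames(gc$aa, gc$codon)
})

# RSCU by looping over every synonymous codon of every amino acid
oracle_rscu <- function(counts) {
  aas <- setdiff(unique(oracle_code), c("*", "M", "W"))
  out <- numeric(0)
  for (aa in aas) {
    cods <- names(oracle_code)[oracle_code == aa]
    total <- 0
    for (cd in cods) total <- total + counts[[cd]]
    for (cd in cods) {
      out[cd] <- if (total > 0) counts[[cd] ] / (total / length(cods)) else NA_real_
    }
  }
  out[sort(names(out))]
}

# Wright's ENC with explicit per-amino-acid loops
oracle_enc <- function(counts) {
  aas <- setdiff(unique(oracle_code), c("*", "M", "W"))
  fh <- list()
  for (aa in aas) {
    cods <- names(oracle_code)[oracle_code == aa]
    n <- 0
    for (cd in cods) n <- n + counts[[cd]]
    if (n < 2) next
    s <- 0
    for (cd in cods) s <- s + (counts[[cd]] / n)^2
    f <- (n * s - 1) / (n - 1)
    if (f > 0) fh[[aa]] <- c(f = f, k = length(cods))
  }
  if (length(fh) == 0) return(NA_real_)
  m <- do.call(rbind, fh)
  avg <- function(k) {
    v <- m[m[, "k"] == k, "f"]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  f2 <- avg(2); f3 <- avg(3); f4 <- avg(4); f6 <- avg(6)
  if (is.na(f2) || is.na(f4) || is.na(f6)) return(NA_real_)
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

# closed-form simple linear regression
oracle_ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(
    intercept = my - slope * mx, slope = slope,
    r = sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  )
}

# Welch statistic straight from the textbook formulas
oracle_welch <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  c(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# O(n^3) average-linkage agglomeration on a distance matrix; returns sorted
# merge heights
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# random 64-codon count table (named, alphabetical order)
random_count_table <- function(max_count = 50L, p_present = 0.9) {
  cods <- genetic_code_table()$codon
  counts <- rpois(64L, lambda = runif(1, 2, max_count / 2))
  counts[runif(64) > p_present] <- 0L
  stats::setNames(as.integer(counts), cods)
}

write_fasta_lines <- function(lines, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".fasta")
  writeLines(lines, path)
  path
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
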