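# Genome clustering on pooled RSCU vectors: Euclidean distances, average-
# linkage agglomeration, Newick export, flat cuts, and an optional
# Robinson-Foulds comparison against a reference tree.

#' Build the genome x codon RSCU feature matrix
#'
#' @param rscu_list Named list (one element per genome) of 59-long pooled
#'   RSCU vectors (from [rscu()]), or of 64-codon pooled count vectors
#'   (RSCU computed on the fly). At least two genomes; every RSCU value must
#'   be defined (a pooled genome lacking an amino acid entirely is refused,
#'   naming the genome and amino acid).
#' @return Numeric matrix, genomes (input order) x 59 synonymous codons
#'   (alphabetical).
#' @export
build_feature_matrix <- function(rscu_list) {
  stopifnot(is.list(rscu_list))
  if (length(rscu_list) < 2L) stop("need >= 2 genomes to build a feature matrix")
  labels <- names(rscu_list)
  if (is.null(labels)) labels <- sprintf("genome%02d", seq_along(rscu_list))
  rows <- lapply(seq_along(rscu_list), function(i) {
    v <- rscu_list[[i]]
    if (length(v) == 64L) v <- rscu(v)
    if (length(v) != length(SYN_CODONS) || is.null(names(v))) {
      stop("genome '", labels[i], "': expected a 59-long named RSCU vector")
    }
    v <- v[SYN_CODONS]
    if (anyNA(v)) {
      bad <- SYN_CODONS[which(is.na(v))[1L]]
      stop(
        "genome '", labels[i], "': RSCU undefined for amino acid ",
        .aa3[[.standard_code[[bad]]]], " (codon ", bad, ")"
      )
    }
    v
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(labels, SYN_CODONS)
  m
}

#' Euclidean distance matrix between genomes
#'
#' @param m Feature matrix from [build_feature_matrix()].
#' @return Symmetric numeric matrix of pairwise Euclidean distances over
#'   the 59 RSCU coordinates.
#' @export
euclidean_distance_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  as.matrix(stats::dist(m, method = "euclidean"))
}

.linkage_method <- function(linkage) {
  switch(linkage,
    average = "average",
    single = "single",
    complete = "complete",
    ward = "ward.D2",
    stop("unknown linkage: ", linkage)
  )
}

#' Agglomerative clustering of genomes
#'
#' Hierarchical agglomeration of a genome distance matrix (average linkage
#' by default, i.e. UPGMA-style; `single`, `complete` and `ward` are also
#' accepted).
#'
#' @param d Symmetric distance matrix or `dist` object.
#' @param linkage Linkage rule (default `"average"`).
#' @return An `hclust` object with the linkage stored in `$method`.
#' @export
agglomerate <- function(d, linkage = "average") {
  if (is.matrix(d)) d <- stats::as.dist(d)
  stopifnot(inherits(d, "dist"), attr(d, "Size") >= 2L)
  stats::hclust(d, method = .linkage_method(linkage))
}

#' Cut a dendrogram into k flat clusters
#'
#' Cutting above the k-1 highest merges yields exactly k clusters.
#'
#' @param hc `hclust` object from [agglomerate()].
#' @param k Number of clusters, 1 <= k <= number of genomes.
#' @return Named integer vector of cluster labels (a partition).
#' @export
cut_clusters <- function(hc, k) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels)
  if (k < 1L || k > n) stop("k must lie in [1, ", n, "]")
  stats::cutree(hc, k = k)
}

#' Dendrogram as a Newick string
#'
#' Converts the merge tree to a phylogram with branch lengths equal to half
#' the merge heights (so two genomes merging at height h sit at distance h
#' along the tree) and serializes it as Newick.
#'
#' @param hc `hclust` object.
#' @return Newick string (single line, semicolon-terminated).
#' @export
as_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Write a dendrogram to a Newick file
#'
#' @param hc `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  writeLines(as_newick(hc), path)
  invisible(path)
}

#' Robinson-Foulds distance to a reference tree
#'
#' Comparison aid for setting an RSCU-based dendrogram against an
#' independently built phylogeny (e.g. an alignment-based tree supplied as
#' Newick): reports the Robinson-Foulds topological distance on the shared
#' taxa. Branch lengths are ignored.
#'
#' @param hc `hclust` object from [agglomerate()].
#' @param ref A `phylo` object or path to a Newick file.
#' @return List `rf` (Robinson-Foulds distance), `max_rf` (its maximum for
#'   the taxon set), `normalized` (rf / max_rf), `n_taxa`.
#' @export
compare_topology <- function(hc, ref) {
  t1 <- ape::as.phylo(hc)
  t2 <- if (inherits(ref, "phylo")) ref else ape::read.tree(ref)
  common <- intersect(t1$tip.label, t2$tip.label)
  if (length(common) < 4L) stop("need >= 4 shared taxa for a Robinson-Foulds comparison")
  t1 <- ape::keep.tip(t1, common)
  t2 <- ape::keep.tip(t2, common)
  rf <- phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))
  max_rf <- 2L * (length(common) - 3L)
  list(rf = rf, max_rf = max_rf, normalized = rf / max_rf, n_taxa = length(common))
}
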