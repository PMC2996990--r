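# Genome context analysis: chromosomal gene clusters (candidate operons),
# co-clustering and co-occurrence coupling scores, and gap-filling
# candidates for pathway roles missing from a reconstruction.

#' Call chromosomal gene clusters (candidate operons)
#'
#' Partitions the genes of a genome into maximal runs of neighbors whose
#' intergenic distance does not exceed `max_gap` (overlapping genes count
#' as distance 0) and, optionally, that share a strand. Singletons are
#' legitimate clusters. On a circular replicon the run may wrap the origin.
#'
#' @param genes data frame with `gene_id`, `replicon`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param max_gap maximum intergenic distance within a cluster (bp).
#' @param require_same_strand split clusters at strand flips.
#' @param circular treat each replicon as circular (requires
#'   `replicon_length`).
#' @param replicon_length named vector of replicon lengths (circular only).
#' @return the input genes with a `cluster_id` column
#'   (`<replicon>:c<k>`), ordered by replicon and start.
#' @export
call_clusters <- function(genes, max_gap = 200L, require_same_strand = TRUE,
                          circular = FALSE, replicon_length = NULL) {
  if (max_gap < 0) stopf("max_gap must be >= 0")
  if (!nrow(genes)) {
    genes$cluster_id <- character(0)
    return(genes)
  }
  if (any(genes$end < genes$start) || any(genes$start < 0))
    stopf("malformed coordinates")
  genes <- genes[order(genes$replicon, genes$start, genes$gene_id), ,
                 drop = FALSE]
  out <- list()
  for (rep_id in unique(genes$replicon)) {
    g <- genes[genes$replicon == rep_id, , drop = FALSE]
    n <- nrow(g)
    newc <- logical(n)
    newc[1] <- TRUE
    if (n > 1) for (i in 2:n) {
      gap <- max(0L, g$start[i] - g$end[i - 1])
      newc[i] <- gap > max_gap ||
        (require_same_strand && g$strand[i] != g$strand[i - 1])
    }
    cid <- cumsum(newc)
    if (circular && n > 1 && max(cid) > 1) {
      if (is.null(replicon_length) || is.na(replicon_length[rep_id]))
        stopf("circular clustering needs replicon_length for %s", rep_id)
      wrap_gap <- max(0L, replicon_length[[rep_id]] - g$end[n] + g$start[1])
      strand_ok <- !require_same_strand || g$strand[1] == g$strand[n]
      if (wrap_gap <= max_gap && strand_ok)
        cid[cid == max(cid)] <- 1L  # merge last run into the first
    }
    g$cluster_id <- sprintf("%s:c%d", rep_id, cid)
    out[[rep_id]] <- g
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of co-present genomes where two families co-cluster
#'
#' Over the genomes where both families have members, the fraction in
#' which some member of each shares a cluster.
#'
#' @param familyA,familyB family ids.
#' @param membership data frame with `genome`, `gene_id`, `family_id`
#'   (e.g. role assignments or truth).
#' @param clusters data frame with `genome`, `gene_id`, `cluster_id`
#'   (from [call_clusters()] run per genome).
#' @return fraction in \[0, 1\], or NA when no genome has both.
#' @export
co_clustering_fraction <- function(familyA, familyB, membership, clusters) {
  cl <- setNames(clusters$cluster_id,
                 paste(clusters$genome, clusters$gene_id))
  genomes <- intersect(membership$genome[membership$family_id == familyA],
                       membership$genome[membership$family_id == familyB])
  if (!length(genomes)) return(NA_real_)
  hit <- vapply(genomes, function(gn) {
    ca <- cl[paste(gn, membership$gene_id[membership$genome == gn &
                                            membership$family_id == familyA])]
    cb <- cl[paste(gn, membership$gene_id[membership$genome == gn &
                                            membership$family_id == familyB])]
    any(ca %in% cb)
  }, logical(1))
  mean(hit)
}

#' Jaccard co-occurrence of two phyletic profiles
#'
#' @param profileA,profileB logical vectors of equal length (presence per
#'   genome).
#' @return `|A & B| / |A | B|`, or NA when both profiles are empty.
#' @export
cooccurrence_score <- function(profileA, profileB) {
  if (length(profileA) != length(profileB))
    stopf("profiles must have equal length")
  un <- sum(profileA | profileB)
  if (un == 0) return(NA_real_)
  sum(profileA & profileB) / un
}

#' Propose gap-filling candidates for a missing pathway role
#'
#' Candidates are genes without a family assignment in the genome that
#' share a chromosomal cluster and/or a regulon with at least one gene
#' already assigned to the pathway. Ranking: cluster-and-regulon evidence
#' first, then cluster only, then regulon only; ties break by distance (bp)
#' to the nearest assigned pathway gene, then by gene id.
#'
#' @param genome_alias genome to search.
#' @param pathway_id pathway with the gap.
#' @param assignments data frame with `genome`, `gene_id`, `family_id`,
#'   `pathway_id` for assigned genes.
#' @param clusters cluster calls with `genome`, `gene_id`, `cluster_id`.
#' @param genes gene table with `genome`, `gene_id`, `start`, `end`.
#' @param regulon_members optional data frame `genome`, `gene_id` of
#'   regulon members attributed to the pathway's regulator.
#' @return data frame of ranked candidates: `gene_id`, `evidence`
#'   (`both`/`cluster`/`regulon`), `distance`.
#' @export
propose_gap_fillers <- function(genome_alias, pathway_id, assignments,
                                clusters, genes,
                                regulon_members = NULL) {
  empty <- data.frame(gene_id = character(), evidence = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  anchors <- assignments[assignments$genome == genome_alias &
                           assignments$pathway_id %in% pathway_id, ,
                         drop = FALSE]
  if (!nrow(anchors)) return(empty)
  cl <- clusters[clusters$genome == genome_alias, , drop = FALSE]
  gg <- genes[genes$genome == genome_alias, , drop = FALSE]
  assigned_ids <- unique(
    assignments$gene_id[assignments$genome == genome_alias])
  anchor_clusters <- unique(cl$cluster_id[cl$gene_id %in% anchors$gene_id])
  in_cluster <- cl$gene_id[cl$cluster_id %in% anchor_clusters]
  in_regulon <- if (is.null(regulon_members)) character(0) else
    regulon_members$gene_id[regulon_members$genome == genome_alias]
  cand <- setdiff(union(in_cluster, in_regulon), assigned_ids)
  if (!length(cand)) return(empty)
  ev <- ifelse(cand %in% in_cluster & cand %in% in_regulon, "both",
               ifelse(cand %in% in_cluster, "cluster", "regulon"))
  mid <- function(ids) {
    m <- gg[match(ids, gg$gene_id), , drop = FALSE]
    (m$start + m$end) / 2
  }
  am <- mid(anchors$gene_id)
  dist <- vapply(mid(cand), function(x) min(abs(x - am)), numeric(1))
  rank_ev <- match(ev, c("both", "cluster", "regulon"))
  o <- order(rank_ev, dist, cand)
  data.frame(gene_id = cand[o], evidence = ev[o], distance = dist[o],
             stringsAsFactors = FALSE)
}
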