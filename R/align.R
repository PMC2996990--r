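# Family-based homology scanning: Smith-Waterman local alignment with
# affine gaps (C++ core), family scans with thresholds, bidirectional
# best-hit orthology and phyletic presence/absence profiles.

.sc_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' Cached copy of the BLOSUM62 matrix shipped with Biostrings, restricted
#' to the 20 standard residues.
#' @return 20 x 20 numeric matrix.
#' @export
blosum62 <- function() {
  if (is.null(.sc_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .sc_env$blosum62 <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  .sc_env$blosum62
}

encode_seq <- function(x, alphabet) {
  v <- strsplit(x, "")[[1]]
  code <- match(v, alphabet)
  if (anyNA(code))
    stopf("invalid residue '%s' in sequence", v[which(is.na(code))[1]])
  as.integer(code)
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment score under the convention that a gap run of
#' length k costs `gap_open + k * gap_extend`. Scores are floored at zero;
#' an empty input aligns with score 0. Percent identity is computed over
#' all alignment columns (matches / columns, gaps included), as in BLAST
#' output.
#'
#' @param a,b protein sequences (strings over the 20-letter amino-acid
#'   alphabet, or DNA when `matrix` has ACGT dimnames).
#' @param matrix substitution matrix with residue dimnames.
#' @param gap_open,gap_extend affine gap penalties (positive numbers).
#' @return list: `score`, `identity` (percent, NA when nothing aligns),
#'   `aln_length` (alignment columns), `matches`.
#' @examples
#' local_align("ACDE", "ACDE")$score  # 24 on the BLOSUM62 diagonal
#' @export
local_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                        gap_extend = 1) {
  alph <- rownames(matrix)
  if (!nzchar(a) || !nzchar(b))
    return(list(score = 0, identity = NA_real_, aln_length = 0L,
                matches = 0L))
  res <- .sw_align(encode_seq(a, alph), encode_seq(b, alph), matrix,
                   gap_open, gap_extend)
  list(score = res$score,
       identity = if (res$columns > 0) 100 * res$matches / res$columns
                  else NA_real_,
       aln_length = res$columns, matches = res$matches)
}

# score-only fast path on pre-encoded sequences
sw_score_enc <- function(a, b, matrix, gap_open, gap_extend) {
  .sw_score(a, b, matrix, gap_open, gap_extend)
}

# Shared 4-mer prefilter: TRUE when the pair shares at least one exact
# k-mer, a necessary condition for any alignment containing an exact
# k-residue match. Pairs failing it cannot reach meaningful identity at
# the scales scanned here; the filter is off in oracle tests.
kmer_sets <- function(seqs, k = 4L) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
}

#' Scan a proteome with family query sequences
#'
#' Aligns every family representative against every protein and keeps hits
#' satisfying both thresholds. Output is sorted by family, then descending
#' score, ties broken by gene id (deterministic).
#'
#' @param proteome named character vector of protein sequences (names are
#'   gene ids).
#' @param families named character vector of family representative
#'   sequences (names are family ids), or a data frame with `family_id`
#'   and `consensus` columns.
#' @param min_score minimum alignment score.
#' @param min_identity minimum percent identity.
#' @param matrix,gap_open,gap_extend alignment parameters.
#' @param prefilter skip pairs sharing no exact 4-mer (lossless for any
#'   pair whose optimal alignment contains an exact 4-mer run).
#' @return data frame: `family_id`, `gene_id`, `score`, `identity`,
#'   `aln_len`.
#' @export
scan_families <- function(proteome, families, min_score = 50,
                          min_identity = 30, matrix = blosum62(),
                          gap_open = 11, gap_extend = 1, prefilter = TRUE) {
  if (min_score < 0 || min_identity < 0) stopf("thresholds must be >= 0")
  if (is.data.frame(families))
    families <- setNames(families$consensus, families$family_id)
  if (!length(proteome) || !length(families))
    return(data.frame(family_id = character(), gene_id = character(),
                      score = numeric(), identity = numeric(),
                      aln_len = integer(), stringsAsFactors = FALSE))
  alph <- rownames(matrix)
  enc_p <- lapply(proteome, encode_seq, alphabet = alph)
  km_p <- if (prefilter) kmer_sets(proteome) else NULL
  rows <- list()
  for (f in sort(names(families))) {
    fq <- families[[f]]
    enc_f <- encode_seq(fq, alph)
    km_f <- if (prefilter) kmer_sets(list(fq))[[1]] else NULL
    for (g in names(proteome)) {
      if (prefilter && !any(km_p[[g]] %in% km_f)) next
      res <- .sw_align(enc_f, enc_p[[g]], matrix, gap_open, gap_extend)
      if (res$columns == 0) next
      ident <- 100 * res$matches / res$columns
      if (res$score >= min_score && ident >= min_identity)
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = f, gene_id = g, score = res$score, identity = ident,
          aln_len = res$columns, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(family_id = character(), gene_id = character(),
                      score = numeric(), identity = numeric(),
                      aln_len = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$family_id, -out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a whole panel with family queries
#'
#' Convenience wrapper running [scan_families()] per genome.
#'
#' @param genomes list of `sc_genome` objects.
#' @param families as in [scan_families()].
#' @param ... passed to [scan_families()].
#' @return data frame of hits with a `genome` column.
#' @export
scan_panel <- function(genomes, families, ...) {
  out <- lapply(genomes, function(g) {
    h <- scan_families(g$proteins, families, ...)
    if (nrow(h)) h$genome <- g$alias
    h
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out))
    return(data.frame(family_id = character(), gene_id = character(),
                      score = numeric(), identity = numeric(),
                      aln_len = integer(), genome = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bidirectional best-hit orthologs between two proteomes
#'
#' A pair (a, b) is reported when b is a's best hit in B and a is b's best
#' hit in A, both above thresholds. Best hits are made unique
#' deterministically: ties on score break by identity, then by
#' lexicographic gene id.
#'
#' @param proteomeA,proteomeB named character vectors of protein sequences.
#' @param matrix,gap_open,gap_extend alignment parameters.
#' @param min_score,min_identity hit thresholds.
#' @return data frame: `gene_a`, `gene_b`, `score_ab`, `score_ba`.
#' @export
bbh_orthologs <- function(proteomeA, proteomeB, matrix = blosum62(),
                          gap_open = 11, gap_extend = 1, min_score = 50,
                          min_identity = 30) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      score_ab = numeric(), score_ba = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(proteomeA) || !length(proteomeB)) return(empty)
  alph <- rownames(matrix)
  idsA <- sort(names(proteomeA)); idsB <- sort(names(proteomeB))
  encA <- lapply(proteomeA[idsA], encode_seq, alphabet = alph)
  encB <- lapply(proteomeB[idsB], encode_seq, alphabet = alph)
  S <- matrix(0, length(idsA), length(idsB), dimnames = list(idsA, idsB))
  I <- S
  for (i in seq_along(idsA)) for (j in seq_along(idsB)) {
    r <- .sw_align(encA[[i]], encB[[j]], matrix, gap_open, gap_extend)
    S[i, j] <- r$score
    I[i, j] <- if (r$columns > 0) 100 * r$matches / r$columns else 0
  }
  ok <- S >= min_score & I >= min_identity
  best_of <- function(scores, idents, ids, keep) {
    if (!any(keep)) return(NA_character_)
    o <- order(-scores, -idents, ids)
    o <- o[keep[o]]
    ids[o[1]]
  }
  bestA <- vapply(seq_along(idsA), function(i)
    best_of(S[i, ], I[i, ], idsB, ok[i, ]), character(1))
  bestB <- vapply(seq_along(idsB), function(j)
    best_of(S[, j], I[, j], idsA, ok[, j]), character(1))
  rows <- list()
  for (i in seq_along(idsA)) {
    b <- bestA[i]
    if (is.na(b)) next
    j <- match(b, idsB)
    if (identical(bestB[j], idsA[i]))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = idsA[i], gene_b = b, score_ab = S[i, j],
        score_ba = S[i, j], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phyletic presence/absence profile of families across a panel
#'
#' @param hits panel hit table from [scan_panel()] (already thresholded).
#' @param genomes character vector of genome aliases enumerating the panel.
#' @param families character vector of family ids (default: those in
#'   `hits`).
#' @return logical matrix families x genomes; TRUE when the family has at
#'   least one hit in that genome.
#' @export
build_phyletic_profile <- function(hits, genomes,
                                   families = sort(unique(hits$family_id))) {
  prof <- matrix(FALSE, nrow = length(families), ncol = length(genomes),
                 dimnames = list(families, genomes))
  if (nrow(hits)) {
    keep <- hits$family_id %in% families & hits$genome %in% genomes
    h <- hits[keep, ]
    prof[cbind(h$family_id, h$genome)] <- TRUE
  }
  prof
}
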