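# Regulon inference: upstream region extraction, position-weight-matrix
# construction and scoring, iterative one-occurrence-per-sequence motif
# discovery, genome scanning at the minimum-training-score threshold, and
# the cross-genome conservation filter.

#' Extract upstream regions for all genes of a genome
#'
#' For a '+' gene `[s, e)` the window is `[s - window_up, s + window_down)`;
#' for a '-' gene `[e - window_down, e + window_up)`, reverse-complemented
#' so the sequence reads toward the gene start. Windows are clipped to the
#' replicon and, optionally, truncated at the nearest upstream neighbor.
#' Genes whose window collapses to zero length are dropped with a warning;
#' the pipeline continues.
#'
#' @param genome an `sc_genome`.
#' @param window_up,window_down window extents (bp) upstream of /
#'   downstream into the gene start.
#' @param truncate_at_neighbor clip at the boundary of the adjacent gene.
#' @return data frame: `gene_id`, `genome`, `replicon`, `start`, `end`
#'   (replicon coordinates of the window, 0-based half-open), `strand`,
#'   `seq` (reading toward the gene).
#' @export
extract_upstream <- function(genome, window_up = 300L, window_down = 20L,
                             truncate_at_neighbor = TRUE) {
  g <- genome$genes
  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    repl <- genome$replicons[[g$replicon[i]]]
    rl <- nchar(repl)
    others <- g[g$replicon == g$replicon[i] & g$gene_id != g$gene_id[i], ,
                drop = FALSE]
    if (g$strand[i] == "+") {
      ws <- max(0L, g$start[i] - window_up)
      we <- min(rl, g$start[i] + window_down)
      if (truncate_at_neighbor && nrow(others)) {
        ne <- others$end[others$end <= g$start[i]]
        if (length(ne)) ws <- max(ws, max(ne))
      }
    } else {
      ws <- max(0L, g$end[i] - window_down)
      we <- min(rl, g$end[i] + window_up)
      if (truncate_at_neighbor && nrow(others)) {
        ns <- others$start[others$start >= g$end[i]]
        if (length(ns)) we <- min(we, min(ns))
      }
    }
    if (we <= ws) {
      warning(sprintf("zero-length upstream region for gene %s; skipped",
                      g$gene_id[i]), call. = FALSE)
      next
    }
    s <- substr(repl, ws + 1L, we)
    if (g$strand[i] == "-") s <- revcomp(s)
    out[[i]] <- data.frame(gene_id = g$gene_id[i], genome = genome$alias,
                           replicon = g$replicon[i], start = ws, end = we,
                           strand = g$strand[i], seq = s,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), genome = character(),
                      replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      seq = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Build a position weight matrix from aligned sites
#'
#' Counts bases per column and derives log-odds weights
#' `w(b, k) = ln((n(b, k) + pseudocount) / ((N + 4 * pseudocount) * background(b)))`
#' where `N` is the number of contributing sites. The palindromic option
#' symmetrizes the count matrix with its reverse complement (for dyad
#' motifs bound by LacI/GntR-style dimers).
#'
#' @param sites character vector of equal-length ACGT words (>= 2).
#' @param pseudocount per-base pseudocount.
#' @param background per-base background probabilities (A, C, G, T),
#'   summing to 1.
#' @param palindromic average counts with their reverse complement.
#' @return an `sc_pwm`: list with `counts` (4 x L), `n_sites`,
#'   `pseudocount`, `background`, `palindromic`, `weights` (4 x L
#'   log-odds), `length`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5,
                      background = c(A = 0.25, C = 0.25, G = 0.25,
                                     T = 0.25),
                      palindromic = FALSE) {
  if (length(sites) < 2) stopf("need at least 2 sites to build a PWM")
  L <- unique(nchar(sites))
  if (length(L) != 1) stopf("sites must have equal length")
  if (abs(sum(background) - 1) > 1e-9) stopf("background must sum to 1")
  mat <- do.call(rbind, strsplit(sites, ""))
  if (!all(mat %in% DNA_BASES)) stopf("sites must be over ACGT")
  counts <- vapply(seq_len(L), function(k)
    tabulate(match(mat[, k], DNA_BASES), 4L), integer(4))
  dimnames(counts) <- list(DNA_BASES, NULL)
  counts <- counts + 0  # numeric
  if (palindromic) {
    rc <- counts[4:1, L:1, drop = FALSE]
    dimnames(rc) <- dimnames(counts)
    counts <- (counts + rc) / 2
  }
  new_pwm(counts, n_sites = length(sites), pseudocount = pseudocount,
          background = background, palindromic = palindromic)
}

new_pwm <- function(counts, n_sites, pseudocount, background, palindromic) {
  bg <- setNames(as.numeric(background), DNA_BASES)
  denom <- (n_sites + 4 * pseudocount) * bg
  weights <- log((counts + pseudocount) / denom)
  structure(list(counts = counts, n_sites = n_sites,
                 pseudocount = pseudocount, background = bg,
                 palindromic = palindromic, weights = weights,
                 length = ncol(counts)),
            class = "sc_pwm")
}

#' @export
print.sc_pwm <- function(x, ...) {
  ic <- information_content(x)
  cat(sprintf("<sc_pwm> length %d, %d sites, total IC %.2f bits%s\n",
              x$length, x$n_sites, ic$total,
              if (x$palindromic) ", palindromic" else ""))
  invisible(x)
}

#' Score a word against a PWM
#'
#' Additive log-odds score: the sum over positions of the weight of the
#' observed base.
#'
#' @param pwm an `sc_pwm`.
#' @param word ACGT word of the PWM's length.
#' @return numeric score.
#' @export
site_score <- function(pwm, word) {
  enc <- encode_seq(word, DNA_BASES)
  if (length(enc) != pwm$length)
    stopf("word length %d != PWM length %d", length(enc), pwm$length)
  sum(pwm$weights[cbind(enc, seq_len(pwm$length))])
}

# All window scores of an encoded sequence against weight matrix W (4 x L).
score_windows_enc <- function(enc, W) {
  L <- ncol(W)
  n <- length(enc) - L + 1L
  if (n <= 0L) return(numeric(0))
  s <- numeric(n)
  for (k in seq_len(L)) s <- s + W[cbind(enc[k:(k + n - 1L)], k)]
  s
}

#' Per-column and total information content of a PWM
#'
#' Column IC in bits, `2 + sum_b p(b) log2 p(b)`, with `p` taken from the
#' pseudocounted frequencies; each column lies in \[0, 2\].
#'
#' @param pwm an `sc_pwm`.
#' @return list with `per_column` (numeric vector) and `total`.
#' @export
information_content <- function(pwm) {
  p <- (pwm$counts + pwm$pseudocount) /
    (pwm$n_sites + 4 * pwm$pseudocount)
  percol <- apply(p, 2, function(col) {
    nz <- col[col > 0]
    2 + sum(nz * log2(nz))
  })
  list(per_column = percol, total = sum(percol))
}

#' Site-search threshold from a training set
#'
#' The threshold is the lowest score observed among the training sites, so
#' scanning the training material at this threshold recovers every
#' training gene by construction.
#'
#' @param pwm an `sc_pwm`.
#' @param sites training sites: a data frame with a `score` column, a
#'   numeric vector of scores, or a character vector of words to score.
#' @return numeric threshold.
#' @export
training_threshold <- function(pwm, sites) {
  scores <- if (is.data.frame(sites)) sites$score
            else if (is.character(sites))
              vapply(sites, site_score, numeric(1), pwm = pwm)
            else sites
  if (!length(scores)) stopf("empty training set")
  min(scores)
}

# Best single window per region under OOPS; ties prefer leftmost forward
# offset, then '+' strand. enc/renc: encoded forward and revcomp sequence.
best_window <- function(enc, renc, W, both_strands) {
  L <- ncol(W)
  M <- length(enc)
  sp <- score_windows_enc(enc, W)
  if (!length(sp)) return(NULL)
  cand <- data.frame(offset = seq_along(sp) - 1L, strand = "+", score = sp,
                     stringsAsFactors = FALSE)
  if (both_strands) {
    sm <- score_windows_enc(renc, W)
    # revcomp offset o (0-based) maps to forward offset M - L - o
    cand <- rbind(cand, data.frame(offset = M - L - (seq_along(sm) - 1L),
                                   strand = "-", score = sm,
                                   stringsAsFactors = FALSE))
  }
  cand <- cand[order(-cand$score, cand$offset, cand$strand), , drop = FALSE]
  cand[1, ]
}

#' Iterative one-occurrence-per-sequence motif discovery
#'
#' Greedy PWM refinement: starting from a seed word, the current matrix
#' picks the best-scoring window in every training region (both strands if
#' enabled), the matrix is rebuilt from those words, and the cycle repeats
#' until the site set is stable, the total information content would
#' decrease, or `max_iter` is reached. Seeds are drawn from the training
#' regions themselves (every window of a reference region plus `n_seeds`
#' random windows); the run with the highest final total information
#' content wins. Deterministic under `seed`.
#'
#' @param regions data frame from [extract_upstream()] (needs `gene_id`,
#'   `seq`), or a character vector of sequences.
#' @param L motif length (config input per regulator; no automatic length
#'   search).
#' @param n_seeds number of random seed windows beyond the reference
#'   region's exhaustive seeds.
#' @param both_strands scan both strands.
#' @param palindromic symmetrize the PWM at each rebuild.
#' @param seed integer seed.
#' @param max_iter iteration cap per seed.
#' @param pseudocount,background PWM parameters.
#' @return list: `pwm`, `sites` (data frame `gene_id`, `offset`, `strand`,
#'   `word`, `score` w.r.t. the final PWM), `total_ic`, `ic_trace`.
#' @export
discover_motif <- function(regions, L, n_seeds = 10L, both_strands = TRUE,
                           palindromic = FALSE, seed = 1L, max_iter = 100L,
                           pseudocount = 0.5,
                           background = c(A = 0.25, C = 0.25, G = 0.25,
                                          T = 0.25)) {
  if (is.character(regions))
    regions <- data.frame(gene_id = paste0("r", seq_along(regions)),
                          seq = regions, stringsAsFactors = FALSE)
  short <- nchar(regions$seq) < L
  if (any(short)) {
    warning(sprintf("%d region(s) shorter than L = %d excluded",
                    sum(short), L), call. = FALSE)
    regions <- regions[!short, , drop = FALSE]
  }
  if (nrow(regions) < 4)
    stopf("need at least 4 training regions of length >= %d", L)
  with_seed(seed, discover_motif_(regions, L, n_seeds, both_strands,
                                  palindromic, max_iter, pseudocount,
                                  background))
}

discover_motif_ <- function(regions, L, n_seeds, both_strands, palindromic,
                            max_iter, pseudocount, background) {
  enc <- lapply(regions$seq, encode_seq, alphabet = DNA_BASES)
  renc <- lapply(regions$seq, function(s) encode_seq(revcomp(s),
                                                     alphabet = DNA_BASES))
  n <- length(enc)
  rebuild <- function(words)
    build_pwm(words, pseudocount = pseudocount, background = background,
              palindromic = palindromic)
  harvest <- function(W) {
    picks <- lapply(seq_len(n), function(i)
      best_window(enc[[i]], renc[[i]], W, both_strands))
    do.call(rbind, picks)
  }
  word_at <- function(i, offset, strand) {
    s <- substr(regions$seq[i], offset + 1L, offset + L)
    if (strand == "-") revcomp(s) else s
  }
  one_pass <- function(seed_word) {
    # initial matrix from the single seed word, heavier pseudocount so the
    # first scan is not an exact-word match
    cnt <- matrix(0, 4, L, dimnames = list(DNA_BASES, NULL))
    se <- encode_seq(seed_word, DNA_BASES)
    cnt[cbind(se, seq_len(L))] <- 1
    W0 <- new_pwm(cnt, n_sites = 1L, pseudocount = pseudocount,
                  background = background,
                  palindromic = palindromic)$weights
    picks <- harvest(W0)
    words <- vapply(seq_len(n), function(i)
      word_at(i, picks$offset[i], picks$strand[i]), character(1))
    list(words = words, picks = picks)
  }
  refine <- function(words, picks) {
    pwm <- rebuild(words)
    ic <- information_content(pwm)$total
    trace <- ic
    for (it in seq_len(max_iter)) {
      new_picks <- harvest(pwm$weights)
      new_words <- vapply(seq_len(n), function(i)
        word_at(i, new_picks$offset[i], new_picks$strand[i]), character(1))
      if (identical(new_words, words) &&
          identical(new_picks$offset, picks$offset)) break
      new_pwm_ <- rebuild(new_words)
      new_ic <- information_content(new_pwm_)$total
      if (new_ic < ic - 1e-9) break  # keep monotone objective
      words <- new_words; picks <- new_picks; pwm <- new_pwm_; ic <- new_ic
      trace <- c(trace, ic)
    }
    list(pwm = pwm, picks = picks, words = words, ic = ic, trace = trace)
  }
  # seed pool: every window of the reference region + random windows
  ref <- which.max(nchar(regions$seq))
  seeds <- character(0)
  nref <- nchar(regions$seq[ref]) - L + 1L
  seeds <- substring(regions$seq[ref], seq_len(nref), seq_len(nref) + L - 1L)
  for (k in seq_len(n_seeds)) {
    i <- sample.int(n, 1L)
    o <- sample.int(nchar(regions$seq[i]) - L + 1L, 1L) - 1L
    seeds <- c(seeds, word_at(i, o, "+"))
  }
  seeds <- unique(seeds)
  # phase 1: one refinement pass per seed, rank by IC
  phase1 <- lapply(seeds, function(sw) {
    st <- one_pass(sw)
    ic <- information_content(rebuild(st$words))$total
    list(state = st, ic = ic)
  })
  keep <- order(vapply(phase1, `[[`, numeric(1), "ic"),
                decreasing = TRUE)[seq_len(min(5L, length(phase1)))]
  # phase 2: full refinement of the best few
  best <- NULL
  for (i in keep) {
    st <- phase1[[i]]$state
    res <- refine(st$words, st$picks)
    if (is.null(best) || res$ic > best$ic) best <- res
  }
  scores <- vapply(best$words, site_score, numeric(1), pwm = best$pwm,
                   USE.NAMES = FALSE)
  sites <- data.frame(gene_id = regions$gene_id, offset = best$picks$offset,
                      strand = best$picks$strand, word = best$words,
                      score = scores, stringsAsFactors = FALSE)
  list(pwm = best$pwm, sites = sites, total_ic = best$ic,
       ic_trace = best$trace)
}

#' Scan regions with a PWM at a threshold
#'
#' Reports every window (both strands if enabled) scoring at or above the
#' threshold; overlapping hits within a region are collapsed to the
#' best-scoring one (ties: leftmost forward offset, then '+' strand).
#'
#' @param pwm an `sc_pwm`.
#' @param threshold finite score threshold (use [training_threshold()]).
#' @param regions data frame from [extract_upstream()] or character
#'   vector.
#' @param both_strands scan both strands.
#' @param tol numeric guard subtracted from the threshold so that a site
#'   whose score defines the threshold is never lost to floating-point
#'   summation order.
#' @return data frame: `gene_id`, `genome` (if present in `regions`),
#'   `offset`, `strand`, `word`, `score`.
#' @export
scan_regions <- function(pwm, threshold, regions, both_strands = TRUE,
                         tol = 1e-9) {
  if (is.na(threshold) || identical(threshold, -Inf))
    stopf("threshold must be finite or +Inf")
  if (is.character(regions))
    regions <- data.frame(gene_id = paste0("r", seq_along(regions)),
                          seq = regions, stringsAsFactors = FALSE)
  L <- pwm$length
  W <- pwm$weights
  out <- list()
  for (i in seq_len(nrow(regions))) {
    s <- regions$seq[i]
    M <- nchar(s)
    if (M < L) next
    enc <- encode_seq(s, DNA_BASES)
    cand <- data.frame(offset = seq_len(M - L + 1L) - 1L, strand = "+",
                       score = score_windows_enc(enc, W),
                       stringsAsFactors = FALSE)
    if (both_strands) {
      renc <- encode_seq(revcomp(s), DNA_BASES)
      sm <- score_windows_enc(renc, W)
      cand <- rbind(cand,
                    data.frame(offset = M - L - (seq_along(sm) - 1L),
                               strand = "-", score = sm,
                               stringsAsFactors = FALSE))
    }
    cand <- cand[cand$score >= threshold - tol, , drop = FALSE]
    if (!nrow(cand)) next
    # collapse overlap groups: hits whose [offset, offset + L) intervals
    # chain-overlap form one group; keep the best per group
    cand <- cand[order(cand$offset, cand$strand), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      cand$offset[-1] >= head(cand$offset, -1) + L)))
    kept <- do.call(rbind, lapply(split(cand, grp), function(gr) {
      gr <- gr[order(-gr$score, gr$offset, gr$strand), , drop = FALSE]
      gr[1, ]
    }))
    kept$gene_id <- regions$gene_id[i]
    if ("genome" %in% names(regions)) kept$genome <- regions$genome[i]
    word <- substr(rep(regions$seq[i], nrow(kept)), kept$offset + 1L,
                   kept$offset + L)
    kept$word <- ifelse(kept$strand == "-", revcomp(word), word)
    out[[length(out) + 1L]] <- kept
  }
  if (!length(out))
    return(data.frame(gene_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      word = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-genome conservation filter for regulon candidates
#'
#' A candidate regulon member is retained when orthologs in at least
#' `min_other_genomes` other genomes also carry a candidate site, or when
#' its family is functionally related to the pathway under study (the
#' whitelist). Raising `min_other_genomes` can only shrink the retained
#' set.
#'
#' @param candidates data frame with `genome`, `gene_id` and (for the
#'   whitelist route) `family_id`; one row per candidate gene.
#' @param orthology data frame mapping `gene_id` to an ortholog `group`.
#' @param min_other_genomes required number of other genomes with a
#'   conserved candidate site.
#' @param functional_whitelist character vector of family ids always
#'   retained.
#' @return the retained subset of `candidates`, with a `support` column
#'   (number of other genomes with conserved sites).
#' @export
conservation_filter <- function(candidates, orthology,
                                min_other_genomes = 2L,
                                functional_whitelist = character(0)) {
  if (!nrow(candidates)) {
    candidates$support <- integer(0)
    return(candidates)
  }
  grp <- orthology$group[match(candidates$gene_id, orthology$gene_id)]
  support <- vapply(seq_len(nrow(candidates)), function(i) {
    if (is.na(grp[i])) return(0L)
    peers <- grp == grp[i] & !is.na(grp) &
      candidates$genome != candidates$genome[i]
    length(unique(candidates$genome[peers]))
  }, integer(1))
  whitelisted <- if ("family_id" %in% names(candidates))
    candidates$family_id %in% functional_whitelist else
      rep(FALSE, nrow(candidates))
  keep <- support >= min_other_genomes | whitelisted
  out <- candidates[keep, , drop = FALSE]
  out$support <- support[keep]
  rownames(out) <- NULL
  out
}
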