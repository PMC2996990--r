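# Independent oracles and small builders shared across the suite.

# Reference Smith-Waterman (full matrices, written independently of the
# C++ rolling-row implementation). Score only.
ref_sw <- function(a, b, mat = blosum62(), go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  if (n == 0 || m == 0) return(0)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
    F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# Exhaustive local-alignment oracle: enumerates every increasing matching
# between positions of a and b (a column either pairs two residues, scored
# by the matrix, or is a gap; gap runs of length k between consecutive
# pairs cost go + k * ge, charged per sequence). Feasible for lengths <= 5.
enum_sw <- function(a, b, mat = blosum62(), go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  best <- 0
  gap_cost <- function(k) if (k > 0) go + k * ge else 0
  # recursively extend a matching; (i, j) = last matched pair
  recurse <- function(i, j, score) {
    best <<- max(best, score)
    if (i >= n || j >= m) return()
    for (ii in seq(i + 1, n)) for (jj in seq(j + 1, m)) {
      s <- score - gap_cost(ii - i - 1) - gap_cost(jj - j - 1) +
        mat[A[ii], B[jj]]
      recurse(ii, jj, s)
    }
  }
  if (n >= 1 && m >= 1)
    for (i in 1:n) for (j in 1:m) recurse(i, j, mat[A[i], B[j]])
  best
}

# Memoized recursion over (i, j, state) - an independent route to the same
# optimum, feasible for lengths <= 8. state: 1 = last column paired,
# 2 = gap run in a, 3 = gap run in b. Scores the best alignment ENDING at
# (i, j) in that state, floored per local alignment.
memo_sw <- function(a, b, mat = blosum62(), go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  if (n == 0 || m == 0) return(0)
  memo <- array(NA_real_, c(n + 1, m + 1, 3))
  f <- function(i, j, s) {
    if (i == 0 || j == 0) return(if (s == 1) 0 else -Inf)
    if (!is.na(memo[i + 1, j + 1, s])) return(memo[i + 1, j + 1, s])
    v <- if (s == 1) {
      max(0, max(f(i - 1, j - 1, 1), f(i - 1, j - 1, 2),
                 f(i - 1, j - 1, 3))) + mat[A[i], B[j]]
    } else if (s == 2) {  # gap in a, consumes B[j]
      max(f(i, j - 1, 1) - go - ge, f(i, j - 1, 2) - ge)
    } else {              # gap in b, consumes A[i]
      max(f(i - 1, j, 1) - go - ge, f(i - 1, j, 3) - ge)
    }
    memo[i + 1, j + 1, s] <<- v
    v
  }
  best <- 0
  for (i in 1:n) for (j in 1:m) best <- max(best, f(i, j, 1))
  best
}

# O(n^2) brute-force cluster oracle: successor pairs found by pairwise
# comparison, then union-find over qualifying links.
brute_clusters <- function(genes, max_gap, same_strand = TRUE) {
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (genes$replicon[i] != genes$replicon[j]) next
    if (genes$start[j] < genes$start[i]) next
    between <- any(genes$replicon == genes$replicon[i] &
                     genes$start > genes$start[i] &
                     genes$start < genes$start[j] &
                     seq_len(n) != i & seq_len(n) != j)
    if (between) next
    if (i != j && genes$start[j] == genes$start[i] && j < i) next
    gap <- max(0L, genes$start[j] - genes$end[i])
    if (gap > max_gap) next
    if (same_strand && genes$strand[i] != genes$strand[j]) next
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  comp <- vapply(seq_len(n), find, integer(1))
  split(genes$gene_id, comp)
}

# random gene layout on one replicon for cluster tests
random_gene_layout <- function(n, seed) {
  with_seed(seed, {
    starts <- sort(sample.int(20000L, n))
    lens <- sample(200:600, n, replace = TRUE)
    data.frame(gene_id = sprintf("g%02d", seq_len(n)),
               replicon = "chr", start = starts, end = starts + lens,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

# training regions with one planted site each; returns regions + truth
planted_region_set <- function(n_regions = 16, region_len = 300, L = 16,
                               ic = 1.2, seed = 1) {
  with_seed(seed, {
    pwm <- make_truth_pwm(paste(sample(c("A", "C", "G", "T"), L,
                                       replace = TRUE), collapse = ""), ic)
    offs <- integer(n_regions); strands <- character(n_regions)
    words <- character(n_regions); seqs <- character(n_regions)
    for (i in seq_len(n_regions)) {
      bg <- sugarcat:::random_dna(region_len)
      o <- sample.int(region_len - L + 1L, 1L) - 1L
      w <- sugarcat:::sample_pwm_word(pwm$probs)
      s <- sample(c("+", "-"), 1L)
      on_plus <- if (s == "+") w else sugarcat:::revcomp(w)
      substr(bg, o + 1L, o + L) <- on_plus
      offs[i] <- o; strands[i] <- s; words[i] <- w; seqs[i] <- bg
    }
    list(regions = data.frame(gene_id = sprintf("r%02d", seq_len(n_regions)),
                              seq = seqs, stringsAsFactors = FALSE),
         offsets = offs, strands = strands, words = words, pwm = pwm)
  })
}

# small panel config used by several tests
tiny_panel_config <- function(seed, n_genomes = 3, identity = 1.0,
                              n_pathways = 2, protein_length = 120,
                              scenario = NULL, plan = NULL, decoys = 2) {
  fams <- synthetic_families(pathways = paste0("P", seq_len(n_pathways)),
                             roles_per_pathway = 4,
                             protein_length = protein_length,
                             seed = seed + 5077)
  make_panel_config(n_genomes = n_genomes, families = fams,
                    pathway_scenario = scenario,
                    identity_target = identity, n_decoys = decoys,
                    pseudogene_plan = plan, seed = seed)
}
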