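# regulon inference: upstream extraction, PWM arithmetic, discovery,
# thresholding, scanning and the conservation filter

mk_genome <- function(replicon, genes) {
  structure(list(alias = "G", replicons = c(chr = replicon),
                 genes = genes, proteins = character(0)),
            class = "sc_genome")
}

test_that("extract_upstream window arithmetic on both strands", {
  repl <- with_seed(1, sugarcat:::random_dna(3000))
  genes <- data.frame(gene_id = c("plus", "minus"), replicon = "chr",
                      start = c(1000, 1000), end = c(2000, 2000),
                      strand = c("+", "-"), pseudo = FALSE,
                      stringsAsFactors = FALSE)
  # genes overlap; disable neighbor truncation to test the raw windows
  up <- extract_upstream(mk_genome(repl, genes), 300, 20,
                         truncate_at_neighbor = FALSE)
  p <- up[up$gene_id == "plus", ]
  expect_equal(c(p$start, p$end), c(700, 1020))
  expect_identical(p$seq, substr(repl, 701, 1020))
  m <- up[up$gene_id == "minus", ]
  expect_equal(c(m$start, m$end), c(1980, 2300))
  expect_identical(m$seq, sugarcat:::revcomp(substr(repl, 1981, 2300)))
})

test_that("extract_upstream clips at replicon bounds and neighbors", {
  repl <- with_seed(2, sugarcat:::random_dna(1000))
  g1 <- data.frame(gene_id = "g", replicon = "chr", start = 50, end = 400,
                   strand = "+", pseudo = FALSE)
  up <- extract_upstream(mk_genome(repl, g1), 300, 20)
  expect_equal(c(up$start, up$end), c(0, 70))
  # neighbor truncation
  g2 <- rbind(g1, data.frame(gene_id = "up", replicon = "chr", start = 0,
                             end = 30, strand = "+", pseudo = FALSE))
  up2 <- extract_upstream(mk_genome(repl, g2), 300, 20)
  expect_equal(up2$start[up2$gene_id == "g"], 30)
  # zero-length window warns and skips, pipeline continues
  g3 <- rbind(g1, data.frame(gene_id = "tight", replicon = "chr",
                             start = 400, end = 500, strand = "+",
                             pseudo = FALSE))
  expect_warning(up3 <- extract_upstream(mk_genome(repl, g3), 300, 0),
                 "zero-length")
  expect_false("tight" %in% up3$gene_id)
})

test_that("build_pwm implements the stated log-odds formula", {
  pwm <- build_pwm(c("ACGT", "ACGA"), pseudocount = 0.5)
  # w(b,k) = ln((n + 0.5) / ((2 + 4*0.5) * 0.25)); denominator = 1
  expect_equal(unname(pwm$weights["A", 1]), log(2.5), tolerance = 1e-12)
  expect_equal(unname(pwm$weights["C", 1]), log(0.5), tolerance = 1e-12)
  expect_equal(unname(pwm$weights["T", 4]), log(1.5), tolerance = 1e-12)
  expect_equal(site_score(pwm, "ACGT"), 3 * log(2.5) + log(1.5),
               tolerance = 1e-12)
  # degenerate and error cases
  expect_error(build_pwm("ACGT"), "at least 2")
  expect_error(build_pwm(c("ACGT", "ACG")), "equal length")
  ident <- build_pwm(c("ACGT", "ACGT", "ACGT"), pseudocount = 0)
  p <- (ident$counts) / ident$n_sites
  expect_equal(unname(p["A", 1]), 1)
  expect_equal(information_content(ident)$per_column, rep(2, 4))
})

test_that("uniform PWM scores every word zero; invalid bases error", {
  pwm <- build_pwm(c("ACGT", "CAGT", "GCAT", "TGCA"), pseudocount = 0)
  # columns not uniform here; build a truly uniform matrix instead
  uni <- build_pwm(c("AAAA", "CCCC", "GGGG", "TTTT"), pseudocount = 0)
  for (w in c("ACGT", "AAAA", "GTCA"))
    expect_equal(site_score(uni, w), 0, tolerance = 1e-12)
  expect_error(site_score(pwm, "ACGN"), "invalid residue")
  expect_error(site_score(pwm, "ACGTA"), "length")
})

test_that("palindromic PWMs score reverse complements identically", {
  sites <- c("ATGCAATTGGCA", "ATGCCATTGGCA", "TTGCAATTGCCA",
             "ATGCAAATGGCA")
  pwm <- build_pwm(sites, palindromic = TRUE)
  for (w in c("ATGCAATTGGCA", "GGGCAATTGGCA", "ACGTACGTACGT"))
    expect_equal(site_score(pwm, w),
                 site_score(pwm, sugarcat:::revcomp(w)),
                 tolerance = 1e-12)
})

test_that("information_content frozen values", {
  cnt <- function(...) {
    m <- matrix(c(...), nrow = 4, dimnames = list(c("A", "C", "G", "T"),
                                                  NULL))
    sugarcat:::new_pwm(m, n_sites = sum(m[, 1]), pseudocount = 0,
                       background = c(A = .25, C = .25, G = .25, T = .25),
                       palindromic = FALSE)
  }
  expect_equal(information_content(cnt(c(2, 0, 0, 0)))$per_column, 2)
  expect_equal(information_content(cnt(c(1, 1, 1, 1)))$per_column, 0)
  expect_equal(information_content(cnt(c(3, 1, 0, 0)))$per_column,
               2 + 0.75 * log2(0.75) + 0.25 * log2(0.25),
               tolerance = 1e-12)
})

test_that("training_threshold is the minimum training score", {
  pwm <- build_pwm(c("ACGT", "ACGA"))
  expect_equal(training_threshold(pwm, c(4.31, 3.79, 5.02)), 3.79)
  expect_equal(training_threshold(pwm, 2.5), 2.5)
  expect_error(training_threshold(pwm, numeric(0)), "empty")
  # at least one training site attains the threshold exactly
  words <- c("ACGT", "ACGA", "ACGA")
  scores <- vapply(words, site_score, numeric(1), pwm = pwm)
  thr <- training_threshold(pwm, words)
  expect_true(any(abs(scores - thr) < 1e-12))
})

test_that("scanning training regions at the threshold recovers all genes", {
  for (seed in 1:10) {
    ps <- planted_region_set(n_regions = 8, region_len = 120, L = 10,
                             ic = 1.4, seed = seed)
    disc <- discover_motif(ps$regions, L = 10, n_seeds = 3, seed = seed)
    thr <- training_threshold(disc$pwm, disc$sites)
    hits <- scan_regions(disc$pwm, thr, ps$regions)
    expect_setequal(unique(hits$gene_id), ps$regions$gene_id)
  }
})

test_that("scan_regions: +Inf threshold, overlap collapse, minus strand", {
  pwm <- build_pwm(c("AAAAAA", "AAAAAA", "AAAAAT"))
  regions <- data.frame(gene_id = "r1",
                        seq = paste0(strrep("C", 20), strrep("A", 12),
                                     strrep("C", 20)))
  expect_equal(nrow(scan_regions(pwm, Inf, regions)), 0)
  hits <- scan_regions(pwm, training_threshold(pwm, "AAAAAA"), regions,
                       both_strands = FALSE)
  # 7 overlapping perfect windows collapse to the leftmost best one
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 20)
  # a site planted on the minus strand is found when scanning both strands
  s <- paste0(strrep("A", 15), "GGGTTTCCC", strrep("A", 15))
  pwm2 <- build_pwm(c("GGGAAACCC", "GGGAAACCC", "GGGAAACCT"))
  h2 <- scan_regions(pwm2, 5, data.frame(gene_id = "r", seq = s))
  expect_true(any(h2$strand == "-"))
  expect_error(scan_regions(pwm2, NA, data.frame(gene_id = "r", seq = s)),
               "threshold")
})

test_that("discover_motif: degenerate certainty and monotone objective", {
  w <- "ACGTTGCACG"
  regions <- rep(paste(rep(w, 3), collapse = ""), 5)
  disc <- discover_motif(regions, L = nchar(w), n_seeds = 2, seed = 1,
                         both_strands = FALSE)
  cons <- paste(rownames(disc$pwm$counts)[apply(disc$pwm$counts, 2,
                                                which.max)],
                collapse = "")
  expect_equal(cons, w)
  expect_equal(nrow(disc$sites), 5)
  expect_false(is.unsorted(disc$ic_trace))
  # input validation
  expect_error(discover_motif(regions[1:3], L = 10), "at least 4")
  expect_warning(discover_motif(c(regions, "ACG"), L = 10, n_seeds = 2,
                                seed = 1), "excluded")
})

test_that("discover_motif recovers a planted motif (single panel)", {
  ps <- planted_region_set(n_regions = 16, region_len = 300, L = 16,
                           ic = 1.4, seed = 5)
  disc <- discover_motif(ps$regions, L = 16, n_seeds = 10, seed = 5)
  found <- abs(disc$sites$offset - ps$offsets) <= 1
  expect_gte(mean(found), 0.8)
})

test_that("conservation_filter applies the >=2-other-genomes rule", {
  cand <- data.frame(genome = c("G1", "G2", "G3", "G4", "G5"),
                     gene_id = paste0("g", 1:5),
                     family_id = c("fX", "fX", "fX", "fY", "whitelisted"),
                     stringsAsFactors = FALSE)
  ortho <- data.frame(gene_id = paste0("g", 1:5),
                      group = c("o1", "o1", "o1", "o2", "o3"))
  kept <- conservation_filter(cand, ortho, min_other_genomes = 2)
  # g1..g3 are a 3-genome conserved set; g4/g5 have no support
  expect_setequal(kept$gene_id, c("g1", "g2", "g3"))
  # one other genome only, family not whitelisted -> dropped
  kept1 <- conservation_filter(cand[1:2, ], ortho, min_other_genomes = 2)
  expect_equal(nrow(kept1), 0)
  # whitelist rescues regardless of support
  keptw <- conservation_filter(cand, ortho, min_other_genomes = 2,
                               functional_whitelist = "whitelisted")
  expect_true("g5" %in% keptw$gene_id)
  # empty input
  expect_equal(nrow(conservation_filter(cand[0, ], ortho)), 0)
})

test_that("raising min_other_genomes never enlarges the retained set", {
  with_seed(31, {
    for (k in 1:10) {
      n <- sample(5:25, 1)
      cand <- data.frame(genome = sample(paste0("G", 1:6), n, TRUE),
                         gene_id = paste0("g", 1:n),
                         family_id = sample(c("fA", "fB"), n, TRUE),
                         stringsAsFactors = FALSE)
      ortho <- data.frame(gene_id = cand$gene_id,
                          group = sample(c("o1", "o2", "o3"), n, TRUE))
      prev <- conservation_filter(cand, ortho, 0)$gene_id
      for (m in 1:4) {
        cur <- conservation_filter(cand, ortho, m)$gene_id
        expect_true(all(cur %in% prev))
        prev <- cur
      }
    }
  })
})
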