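# synthetic panel generator: divergence control, planting, lesions,
# determinism and on-disk round trips

pct_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  mean(va == vb)
}

test_that("mutate_protein hits the identity target", {
  cons <- with_seed(11, sugarcat:::random_protein(200))
  expect_identical(mutate_protein(cons, 1.0, seed = 3), cons)
  m <- mutate_protein(cons, 0.6, seed = 7)
  expect_gte(pct_identity(cons, m), 0.57)
  expect_lte(pct_identity(cons, m), 0.63)
  # deterministic under a fixed seed
  expect_identical(m, mutate_protein(cons, 0.6, seed = 7))
  expect_false(identical(m, mutate_protein(cons, 0.6, seed = 8)))
  # +/- 3 percentage points across targets and lengths >= 100
  for (tg in c(0.5, 0.75, 0.9)) for (len in c(100, 350)) {
    cc <- with_seed(len, sugarcat:::random_protein(len))
    mm <- mutate_protein(cc, tg, seed = 2)
    expect_lte(abs(pct_identity(cc, mm) - tg), 0.03)
  }
  expect_error(mutate_protein("", 0.5), "empty")
  expect_error(mutate_protein("ACDE", 0), "identity_target")
})

test_that("plant_operon does the coordinate arithmetic", {
  co <- plant_operon(1000, c(300, 300, 300), gaps = c(50, 80),
                     strand = "+")
  expect_equal(co$start, c(1000, 1350, 1730))
  expect_equal(co$end, c(1300, 1650, 2030))
  expect_equal(unique(co$strand), "+")
  one <- plant_operon(10, 500, strand = "-")
  expect_equal(nrow(one), 1)
  expect_equal(one$end, 510)
  expect_error(plant_operon(0, c(100, 100), gaps = integer(0)), "gaps")
  expect_error(plant_operon(0, c(100, 100), gaps = 50,
                            replicon_length = 200), "overflow")
})

test_that("plant_sites: counts, determinism of invariants, errors", {
  pwm <- make_truth_pwm("ACGTACGTACGTACGT", ic_per_column = 2)
  wins <- data.frame(gene_id = sprintf("g%02d", 1:16),
                     start = seq(0, by = 400, length.out = 16),
                     end = seq(0, by = 400, length.out = 16) + 300,
                     strand = "+")
  sites <- with_seed(4, plant_sites(pwm, wins))
  expect_equal(nrow(sites), 16)
  # 2 bits/column => deterministic columns: every planted word = consensus
  expect_true(all(sites$word == "ACGTACGTACGTACGT"))
  expect_true(all(sites$start >= wins$start & sites$end <= wins$end))
  short <- data.frame(gene_id = "g", start = 0, end = 15, strand = "+")
  expect_error(plant_sites(make_truth_pwm(strrep("A", 18), 1.5), short),
               "shorter than motif")
})

test_that("make_truth_pwm solves the per-column information content", {
  for (ic in c(0.8, 1.2, 1.9)) {
    pwm <- make_truth_pwm("ACGT", ic)
    p <- pwm$probs[, 1]
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(2 + sum(p * log2(p)), ic, tolerance = 1e-6)
  }
})

test_that("inject_pseudogene lesions behave as defined", {
  prot <- with_seed(5, sugarcat:::random_protein(299))
  nt <- sugarcat:::reverse_translate(prot)  # 900 bp with stop
  g <- list(gene_id = "g1", nt = nt, pseudo = FALSE, protein = prot)
  expect_equal(nchar(nt), 900)
  fs <- inject_pseudogene(g, "frameshift", seed = 2)
  expect_equal(nchar(fs$nt), 899)
  expect_true(fs$pseudo)
  # translation truncated/garbled downstream of the lesion
  expect_lt(nchar(fs$protein), nchar(prot))
  expect_identical(substr(fs$protein, 1, 100), substr(prot, 1, 100))
  ie <- inject_pseudogene(g, "insertion_element", seed = 2)
  expect_equal(nchar(ie$nt), 900 + 1000)
  expect_true(ie$pseudo)
  expect_error(inject_pseudogene(fs, "frameshift"), "already")
})

test_that("simulate_panel respects the scenario and the seed", {
  scen <- list(P1 = c(1, 2, 4), P2 = c(2, 3))
  cfg <- tiny_panel_config(seed = 21, n_genomes = 4, identity = 1.0,
                           scenario = scen)
  p <- simulate_panel(cfg)
  expect_equal(unname(colSums(t(p$truth$presence))),
               unname(vapply(scen, length, integer(1))))
  expect_equal(which(p$truth$presence["P1", ]), c(G01 = 1, G02 = 2,
                                                  G04 = 4))
  # identity 1.0: every planted protein equals its family consensus
  tg <- p$truth$genes
  planted <- tg[!is.na(tg$family_id), ]
  for (i in seq_len(nrow(planted))) {
    cons <- cfg$families$consensus[cfg$families$family_id ==
                                     planted$family_id[i]]
    prot <- p$genomes[[planted$genome[i]]]$proteins[[planted$gene_id[i]]]
    expect_identical(prot, cons)
  }
  # determinism: identical config -> identical object and identical bytes
  p2 <- simulate_panel(cfg)
  expect_identical(p, p2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_panel(p, d1); write_panel(p2, d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})

test_that("planted site truth matches the emitted replicon sequence", {
  cfg <- tiny_panel_config(seed = 33, n_genomes = 4, identity = 0.8)
  p <- simulate_panel(cfg)
  s <- p$truth$sites
  expect_gt(nrow(s), 0)
  for (i in seq_len(nrow(s))) {
    repl <- p$genomes[[s$genome[i]]]$replicons[[1]]
    on_plus <- substr(repl, s$start[i] + 1, s$end[i])
    expect_identical(if (s$strand[i] == "+") on_plus
                     else sugarcat:::revcomp(on_plus), s$word[i])
  }
})

test_that("emitted GFF3+FASTA round-trips the gene set exactly", {
  cfg <- tiny_panel_config(seed = 8, n_genomes = 3, identity = 0.7,
    plan = data.frame(genome = "G02", family_id = "P1_tpt",
                      mode = "frameshift"))
  p <- simulate_panel(cfg)
  d <- withr::local_tempdir()
  write_panel(p, d)
  back <- read_panel(d)
  expect_setequal(names(back), names(p$genomes))
  for (al in names(back)) {
    a <- back[[al]]; b <- p$genomes[[al]]
    expect_identical(a$replicons, b$replicons)
    expect_identical(a$proteins, b$proteins)
    expect_equal(a$genes[c("gene_id", "start", "end", "strand", "pseudo")],
                 b$genes[c("gene_id", "start", "end", "strand", "pseudo")])
  }
  # pseudo attribute survives
  expect_true(any(back[["G02"]]$genes$pseudo))
  # independent GFF3 reader agrees on coordinates
  gr <- rtracklayer::import(file.path(d, "G01.gff3"))
  g1 <- p$genomes[["G01"]]$genes
  expect_equal(BiocGenerics::start(gr), g1$start + 1L)
  expect_equal(BiocGenerics::end(gr), g1$end)
  expect_equal(as.character(BiocGenerics::strand(gr)), g1$strand)
})

test_that("infeasible packing is an error", {
  cfg <- tiny_panel_config(seed = 2, n_genomes = 2)
  cfg$replicon_length <- 1000L
  expect_error(simulate_panel(cfg), "infeasible packing")
})
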