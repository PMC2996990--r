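# pathway reconstruction: role assignment, status calling, audits

def_of <- function(id, slots) {
  structure(list(pathway_id = id, required_roles = slots),
            class = "sc_pathway_def")
}

mk_ass <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(genome = r[[1]], gene_id = r[[2]], family_id = r[[3]],
               pseudo = as.logical(r[[4]]),
               pathway_id = if (length(r) > 4) r[[5]] else NA_character_,
               stringsAsFactors = FALSE)))
}

test_that("assign_roles keeps the best family per gene", {
  hits <- data.frame(family_id = c("fA", "fB", "fC"),
                     gene_id = c("g1", "g1", "g2"),
                     score = c(120, 80, 60), identity = c(50, 70, 40),
                     genome = "G1", stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("g1", "g2"), pseudo = c(FALSE, TRUE))
  ass <- assign_roles(hits, genes)
  expect_equal(ass$family_id[ass$gene_id == "g1"], "fA")  # 120 > 80
  expect_true(ass$pseudo[ass$gene_id == "g2"])
  # score tie resolves by identity, then family id
  tie <- data.frame(family_id = c("fB", "fA"), gene_id = "g1",
                    score = 100, identity = c(50, 50), genome = "G1")
  expect_equal(assign_roles(tie, genes)$family_id, "fA")
})

test_that("assignments equal truth at identity 1.0", {
  cfg <- tiny_panel_config(seed = 61, n_genomes = 2, identity = 1.0)
  p <- simulate_panel(cfg)
  genes <- do.call(rbind, lapply(p$genomes, function(g) g$genes))
  ass <- assign_roles(scan_panel(p$genomes, cfg$families), genes)
  tg <- p$truth$genes[!is.na(p$truth$genes$family_id), ]
  expect_equal(ass$family_id[match(tg$gene_id, ass$gene_id)],
               tg$family_id)
  # no decoy picked up any assignment
  decoys <- p$truth$genes$gene_id[is.na(p$truth$genes$family_id)]
  expect_false(any(decoys %in% ass$gene_id))
})

test_that("call_pathway status logic: present / impaired / absent", {
  def <- def_of("Mal", list("glcP_Mal", "susA"))
  ok <- mk_ass(list("G", "g1", "glcP_Mal", FALSE),
               list("G", "g2", "susA", FALSE))
  expect_equal(call_pathway("G", def, ok)$status, "present")
  # role covered only by a frameshifted gene -> impaired
  fs <- mk_ass(list("G", "g1", "glcP_Mal", TRUE),
               list("G", "g2", "susA", FALSE))
  cl <- call_pathway("G", def, fs)
  expect_equal(cl$status, "impaired")
  expect_equal(cl$disrupted_roles, "glcP_Mal")
  # a second intact paralog rescues presence
  rescue <- rbind(fs, mk_ass(list("G", "g3", "glcP_Mal", FALSE)))
  expect_equal(call_pathway("G", def, rescue)$status, "present")
  # whole cluster lost -> absent with the full missing list
  none <- mk_ass(list("G", "g9", "unrelated", FALSE))
  cl2 <- call_pathway("G", def, none)
  expect_equal(cl2$status, "absent")
  expect_setequal(cl2$missing_roles, c("glcP_Mal", "susA"))
  # alternative fillers within one role slot
  alt <- def_of("Glc", list(c("glcP_Bgl", "glcP_Mal"), "glk_II"))
  a <- mk_ass(list("G", "g1", "glcP_Bgl", FALSE),
              list("G", "g2", "glk_II", FALSE))
  expect_equal(call_pathway("G", alt, a)$status, "present")
})

test_that("adding assignments never demotes a present call", {
  def <- def_of("P", list("fT", "fE"))
  base <- mk_ass(list("G", "g1", "fT", FALSE), list("G", "g2", "fE", FALSE))
  expect_equal(call_pathway("G", def, base)$status, "present")
  with_seed(13, {
    for (k in 1:10) {
      extra <- mk_ass(list("G", paste0("x", k),
                           sample(c("fT", "fE", "fZ"), 1),
                           sample(c(TRUE, FALSE), 1)))
      expect_equal(call_pathway("G", def, rbind(base, extra))$status,
                   "present")
    }
  })
})

test_that("every genome x pathway cell gets exactly one status", {
  cfg <- tiny_panel_config(seed = 71, n_genomes = 3, identity = 0.7)
  p <- simulate_panel(cfg)
  genes <- do.call(rbind, lapply(p$genomes, function(g) {
    gg <- g$genes; gg$genome <- g$alias; gg
  }))
  ass <- assign_roles(scan_panel(p$genomes, cfg$families), genes,
                      registry = cfg$families)
  defs <- sugarcat:::panel_definitions(cfg$families)
  calls <- call_pathways(names(p$genomes), defs, ass)
  expect_false(any(is.na(calls$status)))
  expect_true(all(calls$status %in% c("present", "impaired", "absent")))
  expect_equal(dim(calls$status), c(length(defs), 3))
})

test_that("missing-gene audit lists gaps, not wholly absent pathways", {
  def <- def_of("P", list("f1", "f2", "f3", "f4", "f5"))
  four <- mk_ass(list("G", "g1", "f1", FALSE), list("G", "g2", "f2", FALSE),
                 list("G", "g3", "f3", FALSE), list("G", "g4", "f4", FALSE))
  cl <- call_pathway("G", def, four)
  mg <- list_missing_genes(list(cl))
  expect_equal(nrow(mg), 1)
  expect_equal(mg$role, "f5")
  # wholly absent pathway contributes no triples
  cl2 <- call_pathway("G2", def, four[0, ])
  expect_equal(nrow(list_missing_genes(list(cl2))), 0)
})

test_that("clean panels audit clean: no gaps, no disconnected genes", {
  cfg <- tiny_panel_config(seed = 81, n_genomes = 3, identity = 1.0)
  p <- simulate_panel(cfg)
  genes <- do.call(rbind, lapply(p$genomes, function(g) {
    gg <- g$genes; gg$genome <- g$alias; gg
  }))
  ass <- assign_roles(scan_panel(p$genomes, cfg$families), genes,
                      registry = cfg$families)
  defs <- sugarcat:::panel_definitions(cfg$families)
  calls <- call_pathways(names(p$genomes), defs, ass)
  clusters <- call_clusters(genes, max_gap = 200)
  expect_equal(nrow(list_missing_genes(calls$calls)), 0)
  expect_equal(nrow(list_disconnected_genes(ass, calls$calls, clusters)),
               0)
})

test_that("a stray homolog outside any cluster is disconnected", {
  def <- def_of("P", list("fT", "fE"))
  # genome lacks fE entirely; the lone fT gene sits isolated
  ass <- mk_ass(list("G", "g1", "fT", FALSE, "P"))
  cl <- call_pathway("G", def, ass)
  clusters <- data.frame(genome = "G", gene_id = "g1",
                         cluster_id = "chr:c1")
  disc <- list_disconnected_genes(ass, list(cl), clusters)
  expect_equal(disc$gene_id, "g1")
  # genes of a present pathway are never disconnected
  ass2 <- mk_ass(list("G", "g1", "fT", FALSE, "P"),
                 list("G", "g2", "fE", FALSE, "P"))
  cl2 <- call_pathway("G", def, ass2)
  clusters2 <- data.frame(genome = "G", gene_id = c("g1", "g2"),
                          cluster_id = c("chr:c1", "chr:c2"))
  expect_equal(nrow(list_disconnected_genes(ass2, list(cl2), clusters2)),
               0)
})
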