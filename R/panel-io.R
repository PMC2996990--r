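# On-disk representation of a panel: nucleotide FASTA (one record per
# replicon), protein FASTA (one per gene), GFF3 gene features (1-based
# inclusive, pseudo attribute), truth JSON and a site BED (0-based
# half-open). Writing is deterministic: identical panels give byte-identical
# files.

#' Write a simulated panel to a directory
#'
#' @param panel an `sc_panel` from [simulate_panel()].
#' @param dir output directory (created if needed).
#' @param truth also write `truth.json` and `sites.bed`.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir, truth = TRUE) {
  stopifnot(inherits(panel, "sc_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in panel$genomes) {
    nt <- Biostrings::DNAStringSet(g$replicons)
    Biostrings::writeXStringSet(nt, file.path(dir, paste0(g$alias, ".fna")))
    aa <- Biostrings::AAStringSet(g$proteins)
    Biostrings::writeXStringSet(aa, file.path(dir, paste0(g$alias, ".faa")))
    write_gff3(g, file.path(dir, paste0(g$alias, ".gff3")))
  }
  if (truth) {
    tr <- panel$truth
    jsonlite::write_json(
      list(genes = tr$genes,
           presence = as.data.frame(tr$presence),
           pwms = lapply(tr$pwms, function(p)
             list(consensus = p$consensus,
                  probs = unname(apply(p$probs, 2, as.numeric,
                                       simplify = FALSE))))),
      file.path(dir, "truth.json"), digits = 10)
    if (!is.null(tr$sites)) {
      bed <- data.frame(chrom = paste0(tr$sites$genome, "_chr"),
                        start = tr$sites$start, end = tr$sites$end,
                        name = tr$sites$gene_id, score = 0L,
                        strand = tr$sites$strand)
      write.table(bed, file.path(dir, "sites.bed"), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

# GFF3 emission; internal 0-based half-open coordinates become 1-based
# inclusive on disk, per the format.
write_gff3 <- function(genome, path) {
  g <- genome$genes
  attrs <- sprintf("ID=%s;locus_tag=%s%s", g$gene_id, g$gene_id,
                   ifelse(g$pseudo, ";pseudo=true", ""))
  lines <- sprintf("%s\tsugarcat\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   g$replicon, g$start + 1L, g$end, g$strand, attrs)
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", names(genome$replicons),
                       nchar(genome$replicons)),
               lines), path)
  invisible(path)
}

#' Read a panel back from a directory
#'
#' Reconstructs `sc_genome` objects from the emitted FASTA and GFF3 files.
#' Truth is not reloaded; this models analyzing genomes "from sequence".
#'
#' @param dir directory written by [write_panel()].
#' @return list of `sc_genome` objects, named by alias.
#' @export
read_panel <- function(dir) {
  gffs <- sort(list.files(dir, pattern = "\\.gff3$", full.names = TRUE))
  if (!length(gffs)) stopf("no GFF3 files in %s", dir)
  genomes <- list()
  for (gf in gffs) {
    alias <- sub("\\.gff3$", "", basename(gf))
    nt <- Biostrings::readDNAStringSet(file.path(dir, paste0(alias, ".fna")))
    aa <- Biostrings::readAAStringSet(file.path(dir, paste0(alias, ".faa")))
    tab <- read.delim(gf, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE,
                      col.names = c("seqid", "source", "type", "start",
                                    "end", "score", "strand", "phase",
                                    "attributes"))
    ids <- sub(".*ID=([^;]+).*", "\\1", tab$attributes)
    genes <- data.frame(gene_id = ids, replicon = tab$seqid,
                        start = tab$start - 1L, end = tab$end,
                        strand = tab$strand,
                        pseudo = grepl("pseudo=true", tab$attributes),
                        stringsAsFactors = FALSE)
    if (any(genes$end > nchar(as.character(nt[genes$replicon]))))
      stopf("malformed coordinates in %s", gf)
    genomes[[alias]] <- structure(
      list(alias = alias,
           replicons = setNames(as.character(nt), names(nt)),
           genes = genes,
           proteins = setNames(as.character(aa), names(aa))),
      class = "sc_genome")
  }
  genomes
}
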