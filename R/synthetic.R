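# Seeded synthetic genome panels with planted homolog families, operons,
# transcription-factor binding sites, mosaic pathway presence and pseudogene
# lesions, plus a machine-readable truth table. The generator states the
# conditions the downstream modules are tested against; it is first-class,
# tested code rather than a throwaway fixture.

#' Mutate a consensus protein to a target percent identity
#'
#' Substitution-only divergence: a fixed number of positions
#' (`round((1 - identity_target) * length)`) is substituted, so the realized
#' identity to the consensus is exact up to rounding. Replacement residues
#' are drawn with probability proportional to `exp(BLOSUM62 score / 2)`
#' against the original residue (excluding the residue itself), which keeps
#' distant homologs detectable by score-based alignment, mimicking natural
#' divergence better than uniform replacement.
#'
#' @param consensus amino-acid string (20-letter alphabet).
#' @param identity_target fraction in (0, 1].
#' @param seed integer seed; the operation is deterministic given the seed.
#' @return mutated amino-acid string.
#' @export
mutate_protein <- function(consensus, identity_target, seed = 1L) {
  if (!nzchar(consensus)) stopf("empty consensus protein")
  if (identity_target <= 0 || identity_target > 1)
    stopf("identity_target must be in (0, 1]")
  with_seed(seed, mutate_protein_(consensus, identity_target))
}

# RNG-using core, called inside an established seed scope.
mutate_protein_ <- function(consensus, identity_target) {
  aa <- strsplit(consensus, "")[[1]]
  L <- length(aa)
  n_mut <- round((1 - identity_target) * L)
  if (n_mut == 0) return(consensus)
  pos <- sample.int(L, n_mut)
  mat <- blosum62()
  for (i in pos) {
    from <- aa[i]
    others <- setdiff(AA_ALPHABET, from)
    w <- exp(mat[from, others] / 2)
    aa[i] <- sample(others, 1L, prob = w)
  }
  paste(aa, collapse = "")
}

#' Lay out an operon on a replicon
#'
#' Pure coordinate arithmetic: places genes contiguously in the given order
#' on a shared strand, separated by the supplied intergenic gaps. All
#' coordinates are 0-based half-open.
#'
#' @param offset start coordinate of the first gene.
#' @param gene_lengths integer vector of gene lengths (bp).
#' @param gaps intergenic gaps (bp), length `length(gene_lengths) - 1`.
#' @param strand "+" or "-".
#' @param replicon_length total replicon length; overflow is an error.
#' @return data frame with `start`, `end`, `strand`.
#' @export
plant_operon <- function(offset, gene_lengths, gaps = integer(0),
                         strand = "+", replicon_length = Inf) {
  n <- length(gene_lengths)
  if (n == 0) stopf("no genes to place")
  if (length(gaps) != n - 1)
    stopf("need %d intergenic gaps for %d genes, got %d", n - 1, n,
          length(gaps))
  if (any(gaps < 0)) stopf("negative intergenic gap")
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  starts <- integer(n)
  starts[1] <- offset
  if (n > 1)
    for (i in 2:n) starts[i] <- starts[i - 1] + gene_lengths[i - 1] + gaps[i - 1]
  ends <- starts + gene_lengths
  if (offset < 0 || ends[n] > replicon_length)
    stopf("operon overflows replicon (end %d > length %s)", ends[n],
          format(replicon_length))
  data.frame(start = starts, end = ends, strand = strand,
             stringsAsFactors = FALSE)
}

#' Ground-truth PWM at a controlled information content
#'
#' Builds a per-column probability matrix that puts probability `p` on the
#' consensus base and `(1 - p) / 3` elsewhere, with `p` solved so each
#' column carries `ic_per_column` bits.
#'
#' @param consensus DNA consensus word.
#' @param ic_per_column bits per column in (0, 2].
#' @return list with `probs` (4 x L matrix, rows ACGT), `consensus`,
#'   `length`.
#' @export
make_truth_pwm <- function(consensus, ic_per_column = 1.2) {
  if (ic_per_column <= 0 || ic_per_column > 2)
    stopf("ic_per_column must be in (0, 2]")
  bases <- strsplit(consensus, "")[[1]]
  if (!all(bases %in% DNA_BASES)) stopf("consensus must be over ACGT")
  p <- if (ic_per_column == 2) 1 else
    uniroot(function(p) 2 + p * log2(p) + (1 - p) * log2((1 - p) / 3) -
              ic_per_column,
            interval = c(0.2500001, 1 - 1e-12), tol = 1e-10)$root
  L <- length(bases)
  probs <- matrix((1 - p) / 3, nrow = 4, ncol = L,
                  dimnames = list(DNA_BASES, NULL))
  probs[cbind(match(bases, DNA_BASES), seq_len(L))] <- p
  list(probs = probs, consensus = consensus, length = L)
}

# Sample one word from a truth PWM probability matrix.
sample_pwm_word <- function(probs) {
  paste(apply(probs, 2, function(col) sample(DNA_BASES, 1L, prob = col)),
        collapse = "")
}

#' Plant transcription-factor binding sites in upstream windows
#'
#' One site per regulated gene (the one-occurrence-per-sequence model used
#' by the motif discovery stage): a word is sampled from the truth PWM and
#' placed at a uniform offset inside the gene's upstream window.
#'
#' @param pwm_truth result of [make_truth_pwm()].
#' @param windows data frame with one row per regulated gene: `gene_id`,
#'   `start`, `end` (0-based half-open window on the replicon), `strand`
#'   of the gene.
#' @param both_strands if TRUE the planted strand is sampled; otherwise all
#'   sites go on the window's forward reading direction.
#' @return data frame of site records: `gene_id`, `start`, `end`, `strand`,
#'   `word` (word as read on the planted strand).
#' @export
plant_sites <- function(pwm_truth, windows, both_strands = TRUE) {
  L <- pwm_truth$length
  too_short <- windows$end - windows$start < L
  if (any(too_short))
    stopf("upstream window shorter than motif (%d bp) for gene %s", L,
          windows$gene_id[which(too_short)[1]])
  n <- nrow(windows)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    wlen <- windows$end[i] - windows$start[i]
    off <- sample.int(wlen - L + 1L, 1L) - 1L
    strand <- if (both_strands) sample(c("+", "-"), 1L) else "+"
    word <- sample_pwm_word(pwm_truth$probs)
    out[[i]] <- data.frame(gene_id = windows$gene_id[i],
                           start = windows$start[i] + off,
                           end = windows$start[i] + off + L,
                           strand = strand, word = word,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Disrupt a gene into a pseudogene
#'
#' `frameshift` deletes one nucleotide at the midpoint of the coding
#' sequence; `insertion_element` inserts a 1 kb cassette there. Either way
#' the downstream translation is garbled or truncated and the gene is
#' flagged `pseudo`.
#'
#' @param gene a list with at least `nt` (coding nucleotide string, as
#'   transcribed) and `pseudo` (logical).
#' @param mode `"frameshift"` or `"insertion_element"`.
#' @param seed integer seed (used to draw the cassette sequence).
#' @return the modified gene list, with `pseudo = TRUE`, updated `nt`, and
#'   `protein` re-derived from the lesioned sequence.
#' @export
inject_pseudogene <- function(gene, mode = c("frameshift",
                                             "insertion_element"),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (isTRUE(gene$pseudo)) stopf("gene %s is already a pseudogene",
                                 gene$gene_id %||% "?")
  nt <- gene$nt
  mid <- nchar(nt) %/% 2L
  if (mode == "frameshift") {
    gene$nt <- paste0(substr(nt, 1L, mid - 1L),
                      substr(nt, mid + 1L, nchar(nt)))
  } else {
    cassette <- with_seed(seed, random_dna(1000L))
    gene$nt <- paste0(substr(nt, 1L, mid), cassette,
                      substr(nt, mid + 1L, nchar(nt)))
  }
  gene$pseudo <- TRUE
  gene$protein <- translate_nt(gene$nt)
  gene
}

#' Synthetic family set for a panel
#'
#' One pathway is a transporter, `roles_per_pathway - 2` enzymes and a
#' transcriptional regulator; consensus proteins are drawn from background
#' amino-acid frequencies.
#'
#' @param pathways character vector of synthetic pathway ids.
#' @param roles_per_pathway genes per pathway including the regulator
#'   (minimum 3).
#' @param protein_length consensus protein length (residues).
#' @param seed integer seed.
#' @return data frame: `family_id`, `pathway_id`, `role_class`,
#'   `consensus`.
#' @export
synthetic_families <- function(pathways = paste0("P", 1:4),
                               roles_per_pathway = 4L,
                               protein_length = 200L, seed = 1L) {
  stopifnot(roles_per_pathway >= 3L)
  with_seed(seed, {
    rows <- list()
    for (p in pathways) {
      roles <- c("tpt", paste0("enz", seq_len(roles_per_pathway - 2L)),
                 "reg")
      cls <- c("transport", rep("enzyme", roles_per_pathway - 2L),
               "regulation")
      for (i in seq_along(roles)) {
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = paste0(p, "_", roles[i]), pathway_id = p,
          role_class = cls[i], consensus = random_protein(protein_length),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Panel generator configuration
#'
#' Collects the stated world of a synthetic panel: the genome count, the
#' family set, which genomes carry which pathway, the divergence level, the
#' regulatory motif truth and the pseudogene plan.
#'
#' @param n_genomes number of genomes.
#' @param families family table from [synthetic_families()] (or compatible).
#' @param pathway_scenario named list: pathway id -> integer vector of
#'   genome indices carrying the pathway. Default: each pathway present in
#'   each genome with probability 0.7, drawn once under `seed`.
#' @param identity_target per-gene protein identity to the family consensus,
#'   fraction in (0, 1].
#' @param upstream_window upstream bp reserved (and scanned) ahead of each
#'   transcription unit.
#' @param motif_length planted motif length (nt).
#' @param motif_ic planted information content, bits per column.
#' @param operon_gap_range intergenic gaps inside operons are drawn
#'   uniformly from this range (bp).
#' @param n_decoys unrelated background genes per genome.
#' @param pseudogene_plan data frame (`genome`, `family_id`, `mode`) of
#'   lesions to apply, or NULL.
#' @param replicon_length replicon size (bp); NULL = computed to fit with
#'   margin. Too-small values make packing infeasible and raise an error.
#' @param seed integer seed controlling every random draw.
#' @return an `sc_panel_config` list.
#' @export
make_panel_config <- function(n_genomes = 10L,
                              families = synthetic_families(seed = seed +
                                                              5077L),
                              pathway_scenario = NULL,
                              identity_target = 0.6,
                              upstream_window = 300L,
                              motif_length = 16L,
                              motif_ic = 1.2,
                              operon_gap_range = c(20L, 120L),
                              n_decoys = 5L,
                              pseudogene_plan = NULL,
                              replicon_length = NULL,
                              seed = 1L) {
  if (identity_target <= 0 || identity_target > 1)
    stopf("identity_target must be in (0, 1]")
  pathways <- unique(families$pathway_id)
  if (is.null(pathway_scenario)) {
    pathway_scenario <- with_seed(seed + 101L, {
      s <- lapply(pathways, function(p)
        which(runif(n_genomes) < 0.7))
      setNames(s, pathways)
    })
  }
  bad <- vapply(pathway_scenario, function(g)
    length(g) && (max(g) > n_genomes || min(g) < 1), logical(1))
  if (any(bad)) stopf("pathway_scenario indexes genomes outside 1..%d",
                      n_genomes)
  structure(list(n_genomes = as.integer(n_genomes), families = families,
                 pathway_scenario = pathway_scenario,
                 identity_target = identity_target,
                 upstream_window = as.integer(upstream_window),
                 motif_length = as.integer(motif_length),
                 motif_ic = motif_ic,
                 operon_gap_range = as.integer(operon_gap_range),
                 n_decoys = as.integer(n_decoys),
                 pseudogene_plan = pseudogene_plan,
                 replicon_length = replicon_length,
                 seed = as.integer(seed)),
            class = "sc_panel_config")
}

#' Simulate a genome panel with planted truth
#'
#' Builds `n_genomes` single-replicon genomes. For every pathway present in
#' a genome, the pathway's non-regulator genes are planted as one compact
#' same-strand operon, the regulator as a separate transcription unit, and
#' one binding site sampled from the pathway's truth PWM is embedded in the
#' upstream window of the operon's lead gene. Decoy genes unrelated to any
#' family are interspersed. Pseudogene lesions from the plan are applied
#' before final assembly, so emitted coordinates are consistent with the
#' lesioned sequences. Identical configurations (including seed) give
#' byte-identical emitted files.
#'
#' @param config an `sc_panel_config` from [make_panel_config()].
#' @return an `sc_panel`: list with `genomes` (list of `sc_genome`:
#'   `alias`, `replicons`, `genes`, `proteins`), `truth` (gene/family
#'   membership, site coordinates, per-pathway presence, truth PWMs) and
#'   `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sc_panel_config"))
  with_seed(config$seed, simulate_panel_(config))
}

simulate_panel_ <- function(cfg) {
  fams <- cfg$families
  pathways <- unique(fams$pathway_id)
  # truth PWMs, one per pathway with a regulator
  pwms <- list()
  for (p in pathways) {
    if (any(fams$pathway_id == p & fams$role_class == "regulation")) {
      cons <- random_dna(cfg$motif_length)
      pwms[[p]] <- make_truth_pwm(cons, cfg$motif_ic)
    }
  }
  aliases <- sprintf("G%02d", seq_len(cfg$n_genomes))
  genomes <- list()
  truth_genes <- list()
  truth_sites <- list()
  presence <- matrix(FALSE, nrow = length(pathways), ncol = cfg$n_genomes,
                     dimnames = list(pathways, aliases))
  plan <- cfg$pseudogene_plan
  spacer <- max(400L, cfg$upstream_window + 100L)

  for (gi in seq_len(cfg$n_genomes)) {
    alias <- aliases[gi]
    units <- list()  # transcription units: list(genes=df rows, strand)
    for (p in pathways) {
      if (!(gi %in% cfg$pathway_scenario[[p]])) next
      presence[p, gi] <- TRUE
      pf <- fams[fams$pathway_id == p, ]
      operon <- pf[pf$role_class != "regulation", ]
      regr <- pf[pf$role_class == "regulation", ]
      units[[length(units) + 1L]] <-
        list(fams = operon, strand = sample(c("+", "-"), 1L),
             pathway = p, lead_site = !is.null(pwms[[p]]))
      if (nrow(regr))
        units[[length(units) + 1L]] <-
          list(fams = regr, strand = sample(c("+", "-"), 1L),
               pathway = p, lead_site = FALSE)
    }
    for (d in seq_len(cfg$n_decoys)) {
      units[[length(units) + 1L]] <-
        list(fams = data.frame(family_id = NA_character_,
                               pathway_id = NA_character_,
                               role_class = "decoy",
                               consensus = random_protein(
                                 nchar(fams$consensus[1])),
                               stringsAsFactors = FALSE),
             strand = sample(c("+", "-"), 1L), pathway = NA_character_,
             lead_site = FALSE)
    }
    units <- units[sample.int(length(units))]  # shuffle layout order

    # realize genes
    gene_counter <- 0L
    segs <- list()     # sequence segments in replicon order
    pos <- 0L
    genes_rows <- list()
    sites_rows <- list()
    for (u in units) {
      n <- nrow(u$fams)
      gaps <- if (n > 1)
        sample(seq(cfg$operon_gap_range[1], cfg$operon_gap_range[2]), n - 1,
               replace = TRUE) else integer(0)
      # per-gene sequences (divergence from consensus, lesions)
      prot <- character(n); nt <- character(n); pseudo <- logical(n)
      for (k in seq_len(n)) {
        p0 <- if (is.na(u$fams$family_id[k])) u$fams$consensus[k]
              else mutate_protein_(u$fams$consensus[k], cfg$identity_target)
        g <- list(gene_id = NA, nt = reverse_translate(p0), pseudo = FALSE,
                  protein = p0)
        if (!is.null(plan) && !is.na(u$fams$family_id[k])) {
          hit <- plan$genome == alias & plan$family_id == u$fams$family_id[k]
          if (any(hit))
            g <- inject_pseudogene(g, plan$mode[which(hit)[1]],
                                   seed = cfg$seed + 997L * gi + k)
        }
        prot[k] <- g$protein; nt[k] <- g$nt; pseudo[k] <- g$pseudo
      }
      # transcription order k = 1..n; on '-' the unit is laid right-to-left
      ord <- if (u$strand == "+") seq_len(n) else rev(seq_len(n))
      # upstream window precedes the lead gene in transcription direction
      lead_first <- u$strand == "+"
      segs[[length(segs) + 1L]] <- list(type = "bg", len = spacer)
      pos <- pos + spacer
      win <- NULL
      if (lead_first) {
        win <- c(pos - cfg$upstream_window, pos)
      }
      unit_starts <- integer(n); unit_ends <- integer(n)
      for (j in seq_along(ord)) {
        k <- ord[j]
        glen <- nchar(nt[k])
        seq_on_plus <- if (u$strand == "+") nt[k] else revcomp(nt[k])
        segs[[length(segs) + 1L]] <- list(type = "gene", seq = seq_on_plus)
        unit_starts[k] <- pos; unit_ends[k] <- pos + glen
        pos <- pos + glen
        if (j < n) {
          gp <- gaps[j]
          segs[[length(segs) + 1L]] <- list(type = "bg", len = gp)
          pos <- pos + gp
        }
      }
      if (!lead_first) {
        segs[[length(segs) + 1L]] <- list(type = "bg",
                                          len = cfg$upstream_window)
        win <- c(pos, pos + cfg$upstream_window)
        pos <- pos + cfg$upstream_window
      }
      gene_ids <- character(n)
      for (k in seq_len(n)) {
        gene_counter <- gene_counter + 1L
        gene_ids[k] <- sprintf("%s_%04d", alias, gene_counter)
      }
      # fix ids to follow coordinate order for readability
      ido <- order(unit_starts)
      gene_ids <- gene_ids[order(ido)]
      genes_rows[[length(genes_rows) + 1L]] <- data.frame(
        gene_id = gene_ids, genome = alias,
        replicon = paste0(alias, "_chr"),
        start = unit_starts, end = unit_ends, strand = u$strand,
        pseudo = pseudo, family_id = u$fams$family_id,
        pathway_id = u$fams$pathway_id, role_class = u$fams$role_class,
        protein = prot, stringsAsFactors = FALSE)
      if (u$lead_site) {
        lead <- 1L  # first gene in transcription order
        pw <- pwms[[u$pathway]]
        site <- plant_sites(pw, data.frame(gene_id = gene_ids[lead],
                                           start = win[1], end = win[2],
                                           strand = u$strand))
        site$genome <- alias
        site$pathway_id <- u$pathway
        sites_rows[[length(sites_rows) + 1L]] <- site
      }
    }
    segs[[length(segs) + 1L]] <- list(type = "bg", len = spacer)
    pos <- pos + spacer
    total_len <- cfg$replicon_length %||% pos
    if (pos > total_len)
      stopf("infeasible packing: need %d bp, replicon_length %d", pos,
            total_len)
    extra <- total_len - pos
    if (extra > 0) segs[[length(segs) + 1L]] <- list(type = "bg",
                                                     len = extra)
    # assemble replicon
    pieces <- vapply(segs, function(s)
      if (s$type == "bg") random_dna(s$len) else s$seq, character(1))
    repl <- paste(pieces, collapse = "")
    # embed planted sites (windows are background, so overwrite in place)
    gsites <- if (length(sites_rows)) do.call(rbind, sites_rows) else NULL
    if (!is.null(gsites)) {
      for (r in seq_len(nrow(gsites))) {
        w <- gsites$word[r]
        on_plus <- if (gsites$strand[r] == "+") w else revcomp(w)
        substr(repl, gsites$start[r] + 1L, gsites$end[r]) <- on_plus
      }
    }
    genes <- do.call(rbind, genes_rows)
    genes <- genes[order(genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    proteins <- setNames(genes$protein, genes$gene_id)
    genomes[[alias]] <- structure(
      list(alias = alias,
           replicons = setNames(repl, paste0(alias, "_chr")),
           genes = genes[, c("gene_id", "replicon", "start", "end",
                             "strand", "pseudo")],
           proteins = proteins),
      class = "sc_genome")
    truth_genes[[alias]] <- genes[, c("gene_id", "genome", "replicon",
                                      "start", "end", "strand", "pseudo",
                                      "family_id", "pathway_id",
                                      "role_class")]
    if (!is.null(gsites)) truth_sites[[alias]] <- gsites
  }
  truth <- list(
    genes = do.call(rbind, c(truth_genes, list(make.row.names = FALSE))),
    sites = if (length(truth_sites))
      do.call(rbind, c(truth_sites, list(make.row.names = FALSE))) else NULL,
    presence = presence,
    pwms = pwms)
  structure(list(genomes = genomes, truth = truth, config = cfg),
            class = "sc_panel")
}

#' @export
print.sc_panel <- function(x, ...) {
  cat(sprintf("<sc_panel> %d genomes, %d planted genes, %d planted sites\n",
              length(x$genomes), nrow(x$truth$genes),
              if (is.null(x$truth$sites)) 0L else nrow(x$truth$sites)))
  invisible(x)
}
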