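# End-to-end pipeline: simulate -> scan -> context -> regulon -> pathways
# -> phenotype -> report, with one seeded configuration and deterministic
# TSV/JSON outputs per stage.

#' Default pipeline configuration
#'
#' @param outdir output directory for stage artifacts.
#' @param seed integer seed propagated to every stochastic stage.
#' @param panel `sc_panel_config` for the simulation stage (default: a
#'   10-genome panel at 60% identity).
#' @param min_score,min_identity homology-scan thresholds.
#' @param max_gap,require_same_strand operon-clustering parameters.
#' @param window_up,window_down upstream-region window (bp).
#' @param n_seeds,both_strands,palindromic motif-discovery parameters.
#' @param min_other_genomes conservation-filter requirement.
#' @param stages character vector of stages to run, in pipeline order.
#' @return an `sc_pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("sugarcat_run_"),
                            seed = 1L,
                            panel = make_panel_config(seed = seed),
                            min_score = 50, min_identity = 30,
                            max_gap = 200L, require_same_strand = TRUE,
                            window_up = 300L, window_down = 20L,
                            n_seeds = 10L, both_strands = TRUE,
                            palindromic = FALSE, min_other_genomes = 2L,
                            stages = c("simulate", "scan", "context",
                                       "regulon", "pathways", "phenotype",
                                       "report")) {
  structure(list(outdir = outdir, seed = as.integer(seed), panel = panel,
                 min_score = min_score, min_identity = min_identity,
                 max_gap = as.integer(max_gap),
                 require_same_strand = require_same_strand,
                 window_up = as.integer(window_up),
                 window_down = as.integer(window_down),
                 n_seeds = as.integer(n_seeds),
                 both_strands = both_strands, palindromic = palindromic,
                 min_other_genomes = as.integer(min_other_genomes),
                 stages = stages),
            class = "sc_pipeline_config")
}

# required-role definitions for a synthetic family table: transport +
# enzyme roles; regulators are informative but not required for presence.
panel_definitions <- function(families) {
  defs <- list()
  for (p in unique(families$pathway_id)) {
    req <- families$family_id[families$pathway_id == p &
                                families$role_class %in%
                                c("transport", "enzyme")]
    if (!length(req)) next
    defs[[p]] <- structure(list(pathway_id = p,
                                required_roles = as.list(req)),
                           class = "sc_pathway_def")
  }
  defs
}

log_msg <- function(level, fmt, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

#' Run the reconstruction pipeline on a synthetic panel
#'
#' Executes the configured stages in order; each stage's outputs feed the
#' next and are also written under `outdir` as TSV/JSON. Re-running with
#' the same configuration and seed reproduces byte-identical outputs.
#'
#' @param config an `sc_pipeline_config` (see [pipeline_config()]), or a
#'   path to a JSON file with a subset of its scalar fields.
#' @param quiet suppress progress logging.
#' @return (invisibly) a list with the panel, hits, clusters, regulons,
#'   pathway calls, concordance and the summary list written to
#'   `summary.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "sc_pipeline_config"))
  say <- function(...) if (!quiet) log_msg("INFO", ...)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  res <- list(config = config)

  say("stage simulate: %d genomes", config$panel$n_genomes)
  panel <- simulate_panel(config$panel)
  res$panel <- panel
  if ("simulate" %in% st) write_panel(panel, file.path(outdir, "panel"))
  genomes <- panel$genomes
  fams <- config$panel$families
  all_genes <- do.call(rbind, lapply(genomes, function(g) {
    gg <- g$genes; gg$genome <- g$alias; gg
  }))
  rownames(all_genes) <- NULL

  hits <- NULL
  if (any(c("scan", "regulon", "pathways", "phenotype", "report") %in% st)) {
    say("stage scan: %d families", length(unique(fams$family_id)))
    hits <- scan_panel(genomes, fams, min_score = config$min_score,
                       min_identity = config$min_identity)
    res$hits <- hits
    write_tsv(hits, file.path(outdir, "hits.tsv"))
    prof <- build_phyletic_profile(hits, names(genomes))
    write_tsv(data.frame(family_id = rownames(prof), prof + 0L,
                         check.names = FALSE),
              file.path(outdir, "profiles.tsv"))
  }

  clusters <- NULL
  if (any(c("context", "pathways", "phenotype", "report") %in% st)) {
    say("stage context: clustering (max_gap %d)", config$max_gap)
    clusters <- call_clusters(all_genes, max_gap = config$max_gap,
                              require_same_strand =
                                config$require_same_strand)
    res$clusters <- clusters
    write_tsv(clusters[, c("genome", "gene_id", "replicon", "start", "end",
                           "strand", "cluster_id")],
              file.path(outdir, "clusters.tsv"))
  }

  assignments <- assign_roles(hits, all_genes, registry = fams)
  res$assignments <- assignments

  regulons <- list()
  regulon_members <- NULL
  if ("regulon" %in% st) {
    upstream <- do.call(rbind, lapply(genomes, extract_upstream,
                                      window_up = config$window_up,
                                      window_down = config$window_down))
    rownames(upstream) <- NULL
    for (p in names(panel$truth$pwms)) {
      tpt_fams <- fams$family_id[fams$pathway_id == p &
                                   fams$role_class == "transport"]
      lead_genes <- assignments$gene_id[assignments$family_id %in% tpt_fams]
      train <- upstream[upstream$gene_id %in% lead_genes, , drop = FALSE]
      if (nrow(train) < 4) {
        say("stage regulon: %s skipped (%d training regions)", p,
            nrow(train))
        next
      }
      say("stage regulon: %s (%d training regions)", p, nrow(train))
      disc <- discover_motif(train, L = config$panel$motif_length,
                             n_seeds = config$n_seeds,
                             both_strands = config$both_strands,
                             palindromic = config$palindromic,
                             seed = config$seed)
      thr <- training_threshold(disc$pwm, disc$sites)
      reg_fams <- fams$family_id[fams$pathway_id == p &
                                   fams$role_class == "regulation"]
      tf_genomes <- unique(
        assignments$genome[assignments$family_id %in% reg_fams])
      scanned <- scan_regions(disc$pwm, thr,
                              upstream[upstream$genome %in% tf_genomes, ,
                                       drop = FALSE],
                              both_strands = config$both_strands)
      cand <- unique(scanned[, c("gene_id", "genome")])
      cand$family_id <- assignments$family_id[match(cand$gene_id,
                                                    assignments$gene_id)]
      ortho <- data.frame(gene_id = assignments$gene_id,
                          group = assignments$family_id,
                          stringsAsFactors = FALSE)
      wl <- fams$family_id[fams$pathway_id == p]
      members <- conservation_filter(cand, ortho,
                                     config$min_other_genomes, wl)
      regulons[[p]] <- list(pathway_id = p, pwm = disc$pwm,
                            threshold = thr, training_sites = disc$sites,
                            sites = scanned, members = members)
      if (nrow(members)) {
        members$pathway_id <- p
        regulon_members <- rbind(regulon_members,
                                 members[, c("genome", "gene_id",
                                             "pathway_id")])
      }
    }
    res$regulons <- regulons
    write_regulons(regulons, outdir)
  }

  calls <- NULL
  if (any(c("pathways", "phenotype", "report") %in% st)) {
    say("stage pathways: calling %d pathways",
        length(unique(fams$pathway_id)))
    defs <- panel_definitions(fams)
    calls <- call_pathways(names(genomes), defs, assignments)
    res$calls <- calls
    status_df <- data.frame(pathway_id = rownames(calls$status),
                            calls$status, check.names = FALSE)
    write_tsv(status_df, file.path(outdir, "pathway_status.tsv"))
    audit <- list(missing = list_missing_genes(calls$calls),
                  disconnected = list_disconnected_genes(
                    assignments, calls$calls, clusters, regulon_members))
    res$audit <- audit
    jsonlite::write_json(audit, file.path(outdir, "audit.json"),
                         dataframe = "rows")
  }

  conc <- NULL
  if (any(c("phenotype", "report") %in% st)) {
    say("stage phenotype: truth-derived observations")
    truth_status <- truth_status_matrix(panel)
    smap <- setNames(rownames(calls$status), rownames(calls$status))
    pred <- predict_growth(calls$status, smap)
    obs_mat <- ifelse(truth_status == "present", "p", "n")
    cells <- data.frame(
      strain = rep(colnames(pred), each = nrow(pred)),
      substrate = rep(rownames(pred), times = ncol(pred)),
      predicted = as.vector(pred),
      observed = as.vector(obs_mat[rownames(pred), colnames(pred)]),
      stringsAsFactors = FALSE)
    conc <- score_concordance(cells)
    res$concordance <- conc
    jsonlite::write_json(list(counts = as.list(conc$counts),
                              discordant = conc$discordant),
                         file.path(outdir, "concordance.json"),
                         dataframe = "rows")
  }

  if ("report" %in% st) {
    summary <- list(
      seed = config$seed,
      n_genomes = length(genomes),
      n_genes = nrow(all_genes),
      n_hits = if (is.null(hits)) 0L else nrow(hits),
      n_clusters = if (is.null(clusters)) 0L else
        length(unique(clusters$cluster_id)),
      regulons = lapply(regulons, function(r)
        list(threshold = r$threshold,
             total_ic = information_content(r$pwm)$total,
             n_members = nrow(r$members))),
      pathway_status = if (is.null(calls)) NULL else
        as.data.frame(calls$status),
      concordance = if (is.null(conc)) NULL else as.list(conc$counts))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    res$summary <- summary
  }
  say("done: %s", outdir)
  invisible(res)
}

# truth pathway status of a panel: present / impaired / absent per cell,
# derived from the planted scenario and pseudogene lesions.
truth_status_matrix <- function(panel) {
  tr <- panel$truth
  status <- ifelse(tr$presence, "present", "absent")
  tg <- tr$genes
  req <- tg[!is.na(tg$family_id) & tg$role_class != "regulation", ,
            drop = FALSE]
  for (p in rownames(status)) for (g in colnames(status)) {
    if (status[p, g] != "present") next
    pg <- req[req$pathway_id == p & req$genome == g, , drop = FALSE]
    by_fam <- split(pg$pseudo, pg$family_id)
    if (length(by_fam) && any(vapply(by_fam, all, logical(1))))
      status[p, g] <- "impaired"
  }
  status
}

write_regulons <- function(regulons, outdir) {
  for (p in names(regulons)) {
    r <- regulons[[p]]
    pwm_df <- data.frame(position = seq_len(r$pwm$length),
                         t(r$pwm$counts), check.names = FALSE)
    hdr <- sprintf("# sugarcat-pwm v1 pathway=%s pseudocount=%g palindromic=%s threshold=%.6f",
                   p, r$pwm$pseudocount, r$pwm$palindromic, r$threshold)
    path <- file.path(outdir, sprintf("pwm_%s.tsv", p))
    writeLines(hdr, path)
    suppressWarnings(write.table(pwm_df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    if (nrow(r$sites))
      write_tsv(r$sites[, c("genome", "gene_id", "offset", "strand",
                            "score", "word")],
                file.path(outdir, sprintf("sites_%s.tsv", p)))
    if (nrow(r$members))
      write_tsv(r$members, file.path(outdir, sprintf("regulon_%s.tsv", p)))
  }
}

load_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- as.integer(raw$seed %||% 1L)
  panel_args <- raw$panel %||% list()
  panel_args$seed <- panel_args$seed %||% seed
  panel <- do.call(make_panel_config, panel_args)
  args <- raw[setdiff(names(raw), c("panel"))]
  args$panel <- panel
  args$seed <- seed
  do.call(pipeline_config, args)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `scan`, `context`, `regulon`, `pathways`,
#' `phenotype`, `report`, `run-all`. Each subcommand runs the pipeline up
#' to and including the named stage. Flags: `--config` (JSON), `--seed`,
#' `--outdir`, `--log-level`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status: 0 ok, 1 validation error, 2 runtime error.
#' @export
sugarcat_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  all_stages <- c("simulate", "scan", "context", "regulon", "pathways",
                  "phenotype", "report")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat("usage: sugarcat <subcommand> [--config F] [--seed N] [--outdir D] [--log-level L]\n",
        "subcommands:", paste(c(all_stages, "run-all"), collapse = " "),
        "\n")
    return(0L)
  }
  sub <- args[1]
  if (!sub %in% c(all_stages, "run-all")) {
    message("unknown subcommand: ", sub)
    return(1L)
  }
  opt <- list(config = NULL, seed = 1L, outdir = "sugarcat_run",
              log_level = "info")
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opt)) {
      message("unknown flag: ", rest[i]); return(1L)
    }
    if (i + 1L > length(rest)) { message("missing value for ", rest[i]);
      return(1L) }
    opt[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  tryCatch({
    if (!is.null(opt$config) && !file.exists(opt$config)) {
      message("config file not found: ", opt$config)
      return(1L)
    }
    cfg <- if (!is.null(opt$config)) load_pipeline_config(opt$config)
           else pipeline_config(seed = as.integer(opt$seed),
                                panel = make_panel_config(
                                  seed = as.integer(opt$seed)))
    cfg$outdir <- opt$outdir
    cfg$seed <- as.integer(opt$seed)
    stages <- if (sub == "run-all") all_stages
              else all_stages[seq_len(match(sub, all_stages))]
    cfg$stages <- stages
    run_pipeline(cfg, quiet = identical(opt$log_level, "quiet"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
}
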