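# Reference-table registry: isofunctional protein families (FIGfam-style),
# pathway definitions, genome panel properties and the growth-phenotype
# matrix, packaged as versioned TSV fixtures.

ROLE_CLASSES <- c("transport", "regulation", "enzyme", "auxiliary",
                  "upstream", "ccm")

PATHWAY_IDS <- c("Nag", "Grt", "Bgl", "Scr", "Mal", "Ara", "Gal", "Gnt",
                 "Aga", "Man", "Tre", "Xlt", "Rbs", "Nan", "Alg", "Mtl",
                 "Glc", "CCM", "Unassigned")

OBSERVED_STATES <- c("p", "n", "w", "nd")

sc_file <- function(name) {
  system.file("extdata", name, package = "sugarcat", mustWork = TRUE)
}

#' Load the sugar-catabolome family registry
#'
#' Reads the packaged (or a user-supplied) family registry and pathway table
#' and validates them against the closed role-class and pathway vocabularies.
#' The packaged fixture transcribes the published pathway inventory of a
#' 19-genome sugar catabolome: 170 isofunctional protein families spanning
#' 16 peripheral pathways, central carbon metabolism (CCM) and a block of
#' unassigned families, with 62 families flagged as novel functional
#' assignments.
#'
#' @param registry_path path to the family TSV (`family_id`, `role_name`,
#'   `role_class`, `pathway_id`, `novel`, `count`). Defaults to the packaged
#'   fixture.
#' @param pathway_path path to the pathway TSV (`pathway_id`,
#'   `pathway_name`, `n_genomes`, `n_genes`). Defaults to the packaged
#'   fixture.
#' @return an object of class `sc_registry`: a list with data frames
#'   `families` and `pathways`.
#' @examples
#' reg <- load_registry()
#' summarize_registry(reg)
#' @export
load_registry <- function(registry_path = sc_file("registry.tsv"),
                          pathway_path = sc_file("pathways.tsv")) {
  if (!file.exists(registry_path)) stopf("no such file: %s", registry_path)
  fams <- read_tsv(registry_path)
  if (nrow(fams) == 0) {
    fams <- data.frame(family_id = character(), role_name = character(),
                       role_class = character(), pathway_id = character(),
                       novel = logical(), count = integer(),
                       stringsAsFactors = FALSE)
  }
  need <- c("family_id", "role_class", "pathway_id", "novel", "count")
  miss <- setdiff(need, names(fams))
  if (length(miss))
    stopf("registry parse error: missing column(s) %s",
          paste(miss, collapse = ", "))
  bad <- which(!fams$role_class %in% ROLE_CLASSES)
  if (length(bad))
    stopf("registry validation error at row %d: unknown role_class '%s'",
          bad[1], fams$role_class[bad[1]])
  bad <- which(!fams$pathway_id %in% PATHWAY_IDS)
  if (length(bad))
    stopf("registry validation error at row %d: unknown pathway_id '%s'",
          bad[1], fams$pathway_id[bad[1]])
  dup <- fams$family_id[duplicated(fams$family_id)]
  if (length(dup))
    stopf("registry validation error: duplicate family_id '%s'", dup[1])
  if (nrow(fams) && any(fams$count < 1))
    stopf("registry validation error: count < 1 at row %d",
          which(fams$count < 1)[1])
  fams$novel <- as.logical(fams$novel)

  pw <- NULL
  if (!is.null(pathway_path)) {
    pw <- read_tsv(pathway_path)
    if (nrow(pw)) {
      bad <- which(!pw$pathway_id %in% PATHWAY_IDS)
      if (length(bad))
        stopf("pathway validation error: unknown pathway_id '%s'",
              pw$pathway_id[bad[1]])
      if (anyDuplicated(pw$pathway_id))
        stopf("pathway validation error: duplicate pathway_id")
    }
  }
  structure(list(families = fams, pathways = pw), class = "sc_registry")
}

#' Summarize a family registry
#'
#' Pure counting arithmetic over a validated registry: total families,
#' families assigned to a specific pathway, unassigned families, CCM
#' families, peripheral families (total minus CCM minus unassigned), and
#' novel families broken down by role class.
#'
#' @param registry an `sc_registry` from [load_registry()].
#' @return a list with components `total`, `assigned`, `unassigned`, `ccm`,
#'   `peripheral`, `novel_total` and `novel_by_class` (named integer
#'   vector over role classes).
#' @export
summarize_registry <- function(registry) {
  stopifnot(inherits(registry, "sc_registry"))
  f <- registry$families
  n <- function(idx) as.integer(sum(f$count[idx]))
  total <- n(rep(TRUE, nrow(f)))
  unassigned <- n(f$pathway_id == "Unassigned")
  ccm <- n(f$pathway_id == "CCM")
  novel_by_class <- vapply(ROLE_CLASSES, function(cl)
    n(f$novel & f$role_class == cl), integer(1))
  list(total = total,
       assigned = total - unassigned,
       unassigned = unassigned,
       ccm = ccm,
       peripheral = total - ccm - unassigned,
       novel_total = as.integer(sum(novel_by_class)),
       novel_by_class = novel_by_class)
}

#' Collection expansion contributed by novel families
#'
#' Percentage expansion of a pre-existing family collection by the newly
#' assigned families of a reconstruction.
#'
#' @param n_novel number of novel families (default: from the registry).
#' @param base_collection size of the original query collection.
#' @return percentage (0-100 scale).
#' @export
expansion_percent <- function(n_novel, base_collection = 480) {
  if (base_collection <= 0) stopf("base_collection must be positive")
  100 * n_novel / base_collection
}

#' Load the packaged genome panel table
#'
#' @param path TSV path; defaults to the packaged 19-genome fixture.
#' @return data frame with `alias`, `full_name`, `total_genes`,
#'   `sugar_genes`, `sugar_pathways`.
#' @export
load_genome_table <- function(path = sc_file("genomes.tsv")) {
  g <- read_tsv(path)
  if (anyDuplicated(g$alias)) stopf("genome table: duplicate alias")
  ints <- c("total_genes", "sugar_genes", "sugar_pathways")
  if (any(as.matrix(g[ints]) < 0)) stopf("genome table: negative count")
  g
}

#' Load a predicted/observed growth-phenotype matrix
#'
#' The packaged fixture transcribes a 14-strain by 12-substrate matrix of
#' predicted (`plus`/`minus`) and observed (`p` growth, `n` no growth, `w`
#' weak growth, `nd` not determined) phenotypes, with three cells flagged
#' as inconsistent in the source.
#'
#' @param path TSV path (`strain`, `substrate`, `predicted`, `observed`,
#'   `flagged`); defaults to the packaged fixture.
#' @param complete require a complete strain-by-substrate grid.
#' @return an `sc_phenotypes` data frame.
#' @export
load_phenotype_matrix <- function(path = sc_file("phenotypes.tsv"),
                                  complete = TRUE) {
  pm <- read_tsv(path)
  need <- c("strain", "substrate", "predicted", "observed", "flagged")
  miss <- setdiff(need, names(pm))
  if (length(miss))
    stopf("phenotype parse error: missing column(s) %s",
          paste(miss, collapse = ", "))
  bad <- which(!pm$observed %in% OBSERVED_STATES)
  if (length(bad))
    stopf("phenotype validation error: observed state '%s' at row %d",
          pm$observed[bad[1]], bad[1])
  if (any(!pm$predicted %in% c("plus", "minus")))
    stopf("phenotype validation error: predicted must be plus/minus")
  pm$flagged <- as.logical(pm$flagged)
  if (complete) {
    grid <- table(pm$strain, pm$substrate)
    if (any(grid != 1L))
      stopf("phenotype validation error: missing or duplicated cell (%s, %s)",
            rownames(grid)[which(grid != 1, arr.ind = TRUE)[1, 1]],
            colnames(grid)[which(grid != 1, arr.ind = TRUE)[1, 2]])
  }
  class(pm) <- c("sc_phenotypes", "data.frame")
  pm
}

#' Pathway definitions from a registry
#'
#' Builds the required-role sets used for pathway presence calling. The
#' required roles of each pathway are its transport and enzyme families;
#' regulators, upstream hydrolases and auxiliary components are informative
#' but not required for presence. A glucose (Glc) definition is synthesized
#' when the registry carries glucose-permease and glucokinase families:
#' it requires a glucose permease (either paralogous locus variant
#' satisfies the role) plus the glucokinase.
#'
#' @param registry an `sc_registry`.
#' @param pathways which pathway ids to define; default: all peripheral
#'   pathways in the registry plus CCM (and Glc when derivable).
#' @return named list of `sc_pathway_def` objects, each with `pathway_id`
#'   and `required_roles` (a list of character vectors; each vector is a
#'   role slot whose alternatives are interchangeable fillers).
#' @export
pathway_definitions <- function(registry, pathways = NULL) {
  stopifnot(inherits(registry, "sc_registry"))
  f <- registry$families
  ids <- setdiff(unique(f$pathway_id), "Unassigned")
  if (!is.null(pathways)) ids <- intersect(pathways, c(ids, "Glc"))
  defs <- list()
  for (p in setdiff(ids, "Glc")) {
    cls <- if (p == "CCM") "ccm" else c("transport", "enzyme")
    req <- f$family_id[f$pathway_id == p & f$role_class %in% cls]
    if (!length(req)) next
    defs[[p]] <- structure(
      list(pathway_id = p, required_roles = as.list(req)),
      class = "sc_pathway_def")
  }
  glc_perm <- intersect(c("glcP_Bgl", "glcP_Mal"), f$family_id)
  if (("Glc" %in% c(ids, pathways %||% "Glc")) && length(glc_perm) &&
      "glk_II" %in% f$family_id) {
    defs[["Glc"]] <- structure(
      list(pathway_id = "Glc",
           required_roles = list(glc_perm, "glk_II")),
      class = "sc_pathway_def")
  }
  defs
}
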