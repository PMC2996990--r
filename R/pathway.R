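# Pathway reconstruction: role assignment from homology hits, per-genome
# pathway status calling (present / impaired / absent) with pseudogene-aware
# impairment, and reconstruction audits (missing genes, disconnected genes).

#' Assign genes to functional roles from homology hits
#'
#' Each gene receives its highest-scoring family among its hits; ties break
#' by identity, then lexicographic family id. Genes without hits stay
#' unassigned (absent from the result). The pseudo flag is inherited from
#' the gene table.
#'
#' @param hits hit table from [scan_panel()] (`family_id`, `gene_id`,
#'   `score`, `identity`, `genome`).
#' @param genes gene table with `gene_id`, `pseudo` (and optionally
#'   `genome`); typically the concatenated `genes` of the panel's genomes.
#' @param registry optional `sc_registry` or family data frame used to
#'   attach `pathway_id` per family.
#' @return data frame: `genome`, `gene_id`, `family_id`, `score`,
#'   `identity`, `pseudo`, and `pathway_id` when a registry is given.
#' @export
assign_roles <- function(hits, genes, registry = NULL) {
  empty <- data.frame(genome = character(), gene_id = character(),
                      family_id = character(), score = numeric(),
                      identity = numeric(), pseudo = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  h <- hits[order(hits$gene_id, -hits$score, -hits$identity,
                  hits$family_id), , drop = FALSE]
  h <- h[!duplicated(h$gene_id), , drop = FALSE]
  h$pseudo <- genes$pseudo[match(h$gene_id, genes$gene_id)]
  h$pseudo[is.na(h$pseudo)] <- FALSE
  fams <- if (inherits(registry, "sc_registry")) registry$families
          else registry
  if (!is.null(fams))
    h$pathway_id <- fams$pathway_id[match(h$family_id, fams$family_id)]
  out <- h[, intersect(c("genome", "gene_id", "family_id", "score",
                         "identity", "pseudo", "pathway_id"), names(h))]
  rownames(out) <- NULL
  out
}

#' Call pathway status in one genome
#'
#' A pathway is `present` when every required role slot is covered by at
#' least one intact (non-pseudo) assigned gene; `impaired` when every slot
#' is covered but at least one slot is covered only by pseudogenes (an
#' insertion element or frameshift makes the pathway nonfunctional);
#' `absent` otherwise, with the uncovered slots listed.
#'
#' @param genome_alias genome to call.
#' @param definition an `sc_pathway_def` (see [pathway_definitions()]);
#'   `required_roles` is a list of role slots, each a character vector of
#'   interchangeable family ids.
#' @param assignments role assignments from [assign_roles()].
#' @return an `sc_pathway_call`: list with `genome`, `pathway_id`,
#'   `status`, `missing_roles`, `disrupted_roles`, `found_roles`.
#' @export
call_pathway <- function(genome_alias, definition, assignments) {
  stopifnot(inherits(definition, "sc_pathway_def"))
  req <- definition$required_roles
  if (!length(req)) stopf("pathway definition has no required roles")
  a <- assignments[assignments$genome == genome_alias, , drop = FALSE]
  slot_name <- vapply(req, function(r) r[1], character(1))
  missing_roles <- character(0)
  disrupted_roles <- character(0)
  found_roles <- character(0)
  for (i in seq_along(req)) {
    covering <- a[a$family_id %in% req[[i]], , drop = FALSE]
    if (!nrow(covering)) {
      missing_roles <- c(missing_roles, slot_name[i])
    } else {
      found_roles <- c(found_roles, slot_name[i])
      if (all(covering$pseudo))
        disrupted_roles <- c(disrupted_roles, slot_name[i])
    }
  }
  status <- if (length(missing_roles)) "absent"
            else if (length(disrupted_roles)) "impaired"
            else "present"
  structure(list(genome = genome_alias,
                 pathway_id = definition$pathway_id, status = status,
                 missing_roles = missing_roles,
                 disrupted_roles = disrupted_roles,
                 found_roles = found_roles),
            class = "sc_pathway_call")
}

#' Call all pathways across a panel
#'
#' @param genome_aliases character vector of genomes.
#' @param definitions named list of `sc_pathway_def`.
#' @param assignments role assignments from [assign_roles()].
#' @return list with `calls` (list of `sc_pathway_call`) and `status`
#'   (pathways x genomes character matrix of `present`/`impaired`/
#'   `absent`).
#' @export
call_pathways <- function(genome_aliases, definitions, assignments) {
  calls <- list()
  status <- matrix(NA_character_, nrow = length(definitions),
                   ncol = length(genome_aliases),
                   dimnames = list(names(definitions), genome_aliases))
  for (p in names(definitions)) for (g in genome_aliases) {
    cl <- call_pathway(g, definitions[[p]], assignments)
    calls[[length(calls) + 1L]] <- cl
    status[p, g] <- cl$status
  }
  list(calls = calls, status = status)
}

#' List missing genes (true reconstruction gaps)
#'
#' The missing roles of pathways that are absent but partially present
#' (at least one required role found): genuine gaps required by functional
#' context, as opposed to wholly absent pathways.
#'
#' @param calls list of `sc_pathway_call` (e.g. `call_pathways()$calls`).
#' @return data frame of (`genome`, `pathway_id`, `role`) triples.
#' @export
list_missing_genes <- function(calls) {
  rows <- list()
  for (cl in calls) {
    if (cl$status == "absent" && length(cl$found_roles) &&
        length(cl$missing_roles)) {
      rows[[length(rows) + 1L]] <- data.frame(
        genome = cl$genome, pathway_id = cl$pathway_id,
        role = cl$missing_roles, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(genome = character(), pathway_id = character(),
                      role = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' List disconnected genes (assignments without functional context)
#'
#' Genes assigned to a pathway whose call is absent in their genome and
#' that share neither a chromosomal cluster nor a regulon with any other
#' gene of the same pathway: functionally assigned but out of context.
#'
#' @param assignments role assignments with `pathway_id`.
#' @param calls list of `sc_pathway_call`.
#' @param clusters cluster calls (`genome`, `gene_id`, `cluster_id`).
#' @param regulon_members optional (`genome`, `gene_id`, `pathway_id`)
#'   regulon membership.
#' @return data frame: `genome`, `gene_id`, `family_id`, `pathway_id`.
#' @export
list_disconnected_genes <- function(assignments, calls, clusters,
                                    regulon_members = NULL) {
  status <- list()
  for (cl in calls) status[[paste(cl$genome, cl$pathway_id)]] <- cl$status
  rows <- list()
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    if (is.na(a$pathway_id) ||
        a$pathway_id %in% c("Unassigned", NA)) next
    st <- status[[paste(a$genome, a$pathway_id)]]
    if (is.null(st) || st != "absent") next
    mates <- assignments$gene_id[assignments$genome == a$genome &
                                   !is.na(assignments$pathway_id) &
                                   assignments$pathway_id == a$pathway_id &
                                   assignments$gene_id != a$gene_id]
    cl_g <- clusters[clusters$genome == a$genome, , drop = FALSE]
    own <- cl_g$cluster_id[cl_g$gene_id == a$gene_id]
    mate_cl <- cl_g$cluster_id[cl_g$gene_id %in% mates]
    shares_cluster <- length(own) && any(own %in% mate_cl)
    shares_regulon <- FALSE
    if (!is.null(regulon_members)) {
      rm_g <- regulon_members[regulon_members$genome == a$genome, ,
                              drop = FALSE]
      shares_regulon <- a$gene_id %in% rm_g$gene_id &&
        any(mates %in% rm_g$gene_id)
    }
    if (!shares_cluster && !shares_regulon)
      rows[[length(rows) + 1L]] <- a[, c("genome", "gene_id", "family_id",
                                         "pathway_id")]
  }
  if (!length(rows))
    return(data.frame(genome = character(), gene_id = character(),
                      family_id = character(), pathway_id = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
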