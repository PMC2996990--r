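# Growth-phenotype concordance: translate pathway status into growth
# predictions on diagnostic substrates and score them against observed
# growth calls.

#' Default substrate-to-pathway map for the 12 diagnostic substrates
#'
#' Each substrate is diagnosed by one pathway; on this panel the mapping
#' is the identity on pathway abbreviations.
#'
#' @return named character vector substrate -> pathway id.
#' @export
default_substrate_map <- function() {
  s <- c("Glc", "Nag", "Grt", "Bgl", "Scr", "Mal", "Ara", "Gal", "Gnt",
         "Aga", "Tre", "Mtl")
  setNames(s, s)
}

#' Predict growth phenotypes from pathway status
#'
#' A strain is predicted to grow (`plus`) on a substrate exactly when the
#' mapped pathway is `present`; both `impaired` (nonfunctional due to
#' frameshift / insertion element) and `absent` predict `minus`.
#'
#' @param status pathways x genomes character matrix from
#'   [call_pathways()].
#' @param substrate_map named character vector substrate -> pathway id;
#'   every requested substrate must be mapped.
#' @param substrates substrates to predict (default: all mapped).
#' @return character matrix substrates x genomes with `plus`/`minus`.
#' @export
predict_growth <- function(status, substrate_map = default_substrate_map(),
                           substrates = names(substrate_map)) {
  unmapped <- setdiff(substrates, names(substrate_map))
  if (length(unmapped))
    stopf("unmapped substrate(s): %s", paste(unmapped, collapse = ", "))
  missing_pw <- setdiff(unname(substrate_map[substrates]), rownames(status))
  if (length(missing_pw))
    stopf("no pathway status for: %s", paste(missing_pw, collapse = ", "))
  pred <- ifelse(status[substrate_map[substrates], , drop = FALSE] ==
                   "present", "plus", "minus")
  rownames(pred) <- substrates
  pred
}

#' Score predicted against observed growth phenotypes
#'
#' Cells with observed `nd` are `untested`; weak growth (`w`) counts as
#' growth-positive. A cell is `concordant` when `plus` meets `p` or `w`,
#' or `minus` meets `n`; otherwise `discordant`.
#'
#' @param phenotypes an `sc_phenotypes` data frame
#'   ([load_phenotype_matrix()]) or any data frame with `strain`,
#'   `substrate`, `predicted` (`plus`/`minus`) and `observed`
#'   (`p`/`n`/`w`/`nd`).
#' @return an `sc_concordance`: list with `cells` (the input plus a
#'   `class` column), `counts` (concordant / discordant / untested),
#'   `discordant` (data frame of discordant cells).
#' @export
score_concordance <- function(phenotypes) {
  pm <- as.data.frame(phenotypes)
  cls <- ifelse(pm$observed == "nd", "untested",
         ifelse((pm$predicted == "plus" & pm$observed %in% c("p", "w")) |
                  (pm$predicted == "minus" & pm$observed == "n"),
                "concordant", "discordant"))
  pm$class <- cls
  counts <- c(concordant = sum(cls == "concordant"),
              discordant = sum(cls == "discordant"),
              untested = sum(cls == "untested"))
  structure(list(cells = pm, counts = counts,
                 discordant = pm[cls == "discordant", , drop = FALSE]),
            class = "sc_concordance")
}

#' @export
print.sc_concordance <- function(x, ...) {
  cat(sprintf("<sc_concordance> %d concordant, %d discordant, %d untested\n",
              x$counts["concordant"], x$counts["discordant"],
              x$counts["untested"]))
  if (nrow(x$discordant)) {
    cat("discordant cells:\n")
    print(x$discordant[, c("strain", "substrate", "predicted", "observed")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Growth-positive strain counts per substrate
#'
#' Number of strains observed to grow (`p` or weak `w`) on each substrate.
#'
#' @param phenotypes data frame with `substrate` and `observed`.
#' @param substrates substrates to count (default: all present).
#' @return named integer vector.
#' @export
substrate_growth_counts <- function(phenotypes,
                                    substrates =
                                      sort(unique(phenotypes$substrate))) {
  vapply(substrates, function(s)
    sum(phenotypes$substrate == s &
          phenotypes$observed %in% c("p", "w")), integer(1))
}
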