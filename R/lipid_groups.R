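## Lipid bead groups: named selections over (lipid_species, bead_class).
## The eight canonical groups mirror the index groups used for PH domain
## contact analysis: one headgroup group per phospholipid species, all
## cholesterol particles, the combined PIP headgroups, and all lipid tails.

#' Define a lipid bead group
#'
#' @param name Group label used in outputs.
#' @param species Character vector of lipid species selected (subset of
#'   POPC, POPE, POPS, POP2, POP3, CHOL).
#' @param classes Character vector of bead classes selected (subset of
#'   lipid_headgroup, lipid_tail, lipid_PO4).
#' @return An object of class `lipid_group`.
#' @export
lipid_group <- function(name, species, classes) {
  bad <- setdiff(species, LIPID_SPECIES)
  if (length(bad)) stop_validation("unknown species: ",
                                   paste(bad, collapse = ", "))
  bad <- setdiff(classes, c("lipid_headgroup", "lipid_tail", "lipid_PO4"))
  if (length(bad)) stop_validation("unknown lipid bead class: ",
                                   paste(bad, collapse = ", "))
  structure(list(name = as.character(name), species = species,
                 classes = classes), class = "lipid_group")
}

#' @export
print.lipid_group <- function(x, ...) {
  cat("lipid_group '", x$name, "': species {",
      paste(x$species, collapse = ", "), "}, classes {",
      paste(x$classes, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' The eight canonical lipid groups for PH domain contact analysis
#'
#' Five per-species headgroup groups, all cholesterol particles, POP2 and
#' POP3 headgroups combined (the PIP group used for binding-site
#' fingerprints), and all lipid tails.
#'
#' @return Named list of [lipid_group()] objects.
#' @export
canonical_lipid_groups <- function() {
  phl <- c("POPC", "POPE", "POPS", "POP2", "POP3")
  groups <- lapply(phl, function(sp)
    lipid_group(paste0(sp, "_head"), sp, "lipid_headgroup"))
  names(groups) <- paste0(phl, "_head")
  groups$CHOL <- lipid_group("CHOL", "CHOL",
                             c("lipid_headgroup", "lipid_tail"))
  groups$PIP_head <- lipid_group("PIP_head", c("POP2", "POP3"),
                                 "lipid_headgroup")
  groups$tails <- lipid_group("tails", LIPID_SPECIES, "lipid_tail")
  groups
}

## 1-based bead row indices selected by a group
group_bead_indices <- function(topology, group) {
  stopifnot(inherits(group, "lipid_group"))
  which(topology$entity == "lipid" &
          topology$lipid_species %in% group$species &
          topology$bead_class %in% group$classes)
}
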