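## Topology: bead-level description of the system. Stored as a data.frame
## with one row per bead and explicit classification of every bead; nothing
## is inferred silently from names at analysis time.

TOPOLOGY_COLUMNS <- c("bead_id", "bead_name", "entity", "residue_index",
                      "residue_name", "lipid_species", "bead_class")

LIPID_SPECIES <- c("POPC", "POPE", "POPS", "POP2", "POP3", "CHOL")

BEAD_CLASSES <- c("protein_backbone", "protein_sidechain",
                  "lipid_headgroup", "lipid_tail", "lipid_PO4")

#' Construct and validate a bead topology
#'
#' A topology maps every bead of a coarse-grained system to a protein residue
#' or a lipid molecule, with an explicit species and bead-class label. All
#' distance-based analyses in the package take their bead selections from
#' this table, mirroring the role of index groups in GROMACS-based workflows.
#'
#' @param beads data.frame with columns `bead_id` (0-based, contiguous),
#'   `bead_name`, `entity` (`"protein"` or `"lipid"`), `residue_index`
#'   (1-based residue or lipid molecule index, numbered per entity),
#'   `residue_name` (3-letter amino-acid code or lipid species name),
#'   `lipid_species` (one of POPC, POPE, POPS, POP2, POP3, CHOL, or `"none"`
#'   for protein beads) and `bead_class` (protein_backbone,
#'   protein_sidechain, lipid_headgroup, lipid_tail, lipid_PO4).
#' @return An object of class `cg_topology` (a validated data.frame).
#' @details Validation enforces: unique contiguous `bead_id` starting at 0;
#'   protein beads have `lipid_species == "none"`; lipid beads have
#'   `residue_name` equal to their species; every POP2/POP3 molecule carries
#'   exactly one `lipid_PO4` bead (the linker phosphate used for PIP
#'   association counting).
#' @export
cg_topology <- function(beads) {
  if (!is.data.frame(beads))
    stop_validation("beads must be a data.frame")
  missing_cols <- setdiff(TOPOLOGY_COLUMNS, names(beads))
  if (length(missing_cols))
    stop_validation("topology missing columns: ",
                    paste(missing_cols, collapse = ", "))
  beads <- beads[TOPOLOGY_COLUMNS]
  beads$bead_id <- as.integer(beads$bead_id)
  beads$residue_index <- as.integer(beads$residue_index)
  for (col in c("bead_name", "entity", "residue_name", "lipid_species",
                "bead_class"))
    beads[[col]] <- as.character(beads[[col]])

  n <- nrow(beads)
  if (n == 0L) stop_validation("topology has no beads")
  if (anyDuplicated(beads$bead_id))
    stop_validation("duplicate bead_id: ",
                    paste(unique(beads$bead_id[duplicated(beads$bead_id)]),
                          collapse = ", "))
  if (!identical(sort(beads$bead_id), 0:(n - 1L)))
    stop_validation("bead_ids must be contiguous from 0")
  beads <- beads[order(beads$bead_id), , drop = FALSE]
  rownames(beads) <- NULL

  bad_entity <- !beads$entity %in% c("protein", "lipid")
  if (any(bad_entity))
    stop_validation("unknown entity: ",
                    paste(unique(beads$entity[bad_entity]), collapse = ", "))
  bad_class <- !beads$bead_class %in% BEAD_CLASSES
  if (any(bad_class))
    stop_validation("unknown bead_class: ",
                    paste(unique(beads$bead_class[bad_class]), collapse = ", "))

  is_prot <- beads$entity == "protein"
  if (any(is_prot & beads$lipid_species != "none"))
    stop_validation("protein beads must have lipid_species 'none'")
  if (any(is_prot & !beads$bead_class %in%
            c("protein_backbone", "protein_sidechain")))
    stop_validation("protein beads must have a protein bead_class")
  is_lip <- !is_prot
  bad_sp <- is_lip & !beads$lipid_species %in% LIPID_SPECIES
  if (any(bad_sp))
    stop_validation("unknown lipid_species: ",
                    paste(unique(beads$lipid_species[bad_sp]), collapse = ", "))
  if (any(is_lip & beads$residue_name != beads$lipid_species))
    stop_validation("lipid residue_name must match lipid_species")
  if (any(is_lip & beads$bead_class %in%
            c("protein_backbone", "protein_sidechain")))
    stop_validation("lipid beads must have a lipid bead_class")
  if (any(!is_lip & beads$bead_class == "lipid_PO4"))
    stop_validation("lipid_PO4 bead_class on a protein bead")

  ## every PIP molecule has exactly one PO4 linker bead
  pip <- beads[is_lip & beads$lipid_species %in% c("POP2", "POP3"), ]
  if (nrow(pip)) {
    po4_per_mol <- tapply(pip$bead_class == "lipid_PO4",
                          paste(pip$lipid_species, pip$residue_index), sum)
    if (any(po4_per_mol != 1L))
      stop_validation("every POP2/POP3 molecule must have exactly one ",
                      "lipid_PO4 bead")
  }

  class(beads) <- c("cg_topology", "data.frame")
  beads
}

#' @export
print.cg_topology <- function(x, ...) {
  n_prot <- sum(x$entity == "protein")
  lip <- x[x$entity == "lipid", ]
  n_mol <- if (nrow(lip))
    nrow(unique(lip[c("lipid_species", "residue_index")])) else 0L
  cat("cg_topology:", nrow(x), "beads |", n_prot, "protein beads in",
      length(unique(x$residue_index[x$entity == "protein"])), "residues |",
      n_mol, "lipid molecules\n")
  invisible(x)
}

n_beads <- function(topology) nrow(topology)

protein_residue_indices <- function(topology) {
  sort(unique(topology$residue_index[topology$entity == "protein"]))
}

#' Read a bead topology from file
#'
#' @param path File path.
#' @param dialect `"tsv"` for the native sidecar table (one row per bead,
#'   the columns of [cg_topology()]); `"gro_annotated"` for a single-frame
#'   GRO file whose residue names are lipid species or amino-acid codes and
#'   whose bead names are classified through the packaged Martini-style
#'   name table (unknown names are an error, never guessed).
#' @return A validated `cg_topology`.
#' @export
read_topology <- function(path, dialect = c("tsv", "gro_annotated")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_parse("file not found: ", path)
  if (dialect == "tsv") {
    beads <- tryCatch(
      read.delim(path, stringsAsFactors = FALSE, colClasses = "character"),
      error = function(e) stop_parse("cannot parse topology TSV ", path, ": ",
                                     conditionMessage(e)))
    missing_cols <- setdiff(TOPOLOGY_COLUMNS, names(beads))
    if (length(missing_cols))
      stop_parse("topology TSV ", path, " missing columns: ",
                 paste(missing_cols, collapse = ", "))
    ids <- suppressWarnings(as.integer(beads$bead_id))
    res <- suppressWarnings(as.integer(beads$residue_index))
    if (anyNA(ids) || anyNA(res)) {
      bad <- which(is.na(ids) | is.na(res))[1L]
      stop_parse("malformed topology row at line ", bad + 1L, " of ", path)
    }
    beads$bead_id <- ids
    beads$residue_index <- res
    cg_topology(beads)
  } else {
    topology_from_gro(path)
  }
}

#' Write a bead topology as a TSV sidecar
#'
#' @param topology A `cg_topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "cg_topology"))
  write_tsv(as.data.frame(topology), path)
}

## Martini-style bead name -> class table used by the gro_annotated dialect.
## Deliberately explicit: an unlisted name is an error, not a guess.
GRO_BEAD_CLASS <- c(
  BB = "protein_backbone",
  SC1 = "protein_sidechain", SC2 = "protein_sidechain",
  SC3 = "protein_sidechain", SC4 = "protein_sidechain",
  NC3 = "lipid_headgroup", NH3 = "lipid_headgroup", CNO = "lipid_headgroup",
  GL1 = "lipid_tail", GL2 = "lipid_tail",
  C1A = "lipid_tail", C2A = "lipid_tail", C3A = "lipid_tail",
  C4A = "lipid_tail", C1B = "lipid_tail", C2B = "lipid_tail",
  C3B = "lipid_tail", C4B = "lipid_tail", D2A = "lipid_tail",
  D2B = "lipid_tail", ROH = "lipid_headgroup", R1 = "lipid_tail",
  R2 = "lipid_tail", R3 = "lipid_tail", R4 = "lipid_tail",
  R5 = "lipid_tail", C1 = "lipid_tail", C2 = "lipid_tail",
  HEAD = "lipid_headgroup", TAIL = "lipid_tail"
)

topology_from_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop_parse("GRO file too short: ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(natoms)) stop_parse("bad atom count at line 2 of ", path)
  if (length(lines) < 2L + natoms)
    stop_parse("GRO file truncated: ", path)
  at <- lines[3:(2L + natoms)]
  resname <- toupper(trimws(substr(at, 6L, 10L)))
  beadname <- toupper(trimws(substr(at, 11L, 15L)))
  resid <- suppressWarnings(as.integer(substr(at, 1L, 5L)))
  if (anyNA(resid)) stop_parse("malformed GRO atom line in ", path)

  is_lip <- resname %in% LIPID_SPECIES
  bead_class <- character(natoms)
  for (i in seq_len(natoms)) {
    nm <- beadname[i]
    if (is_lip[i]) {
      if (nm == "PO4") {
        ## PO4 is the linker phosphate on PIPs; on other phospholipids it is
        ## part of the headgroup
        bead_class[i] <- if (resname[i] %in% c("POP2", "POP3"))
          "lipid_PO4" else "lipid_headgroup"
      } else if (nm %in% names(GRO_BEAD_CLASS)) {
        cls <- GRO_BEAD_CLASS[[nm]]
        if (cls %in% c("protein_backbone", "protein_sidechain"))
          stop_parse("protein bead name ", nm, " on lipid residue ",
                     resname[i], " at atom ", i, " of ", path)
        bead_class[i] <- cls
      } else {
        stop_parse("unknown lipid bead name '", nm, "' at atom ", i, " of ",
                   path, "; extend the name table or use the tsv dialect")
      }
    } else {
      if (!nm %in% names(GRO_BEAD_CLASS) ||
          !GRO_BEAD_CLASS[[nm]] %in% c("protein_backbone", "protein_sidechain"))
        stop_parse("unknown protein bead name '", nm, "' at atom ", i, " of ",
                   path, "; extend the name table or use the tsv dialect")
      bead_class[i] <- GRO_BEAD_CLASS[[nm]]
    }
  }

  ## renumber residue/molecule indices per entity (GRO numbering is global
  ## and wraps at 100000)
  key <- paste(is_lip, cumsum(c(TRUE, diff(resid) != 0L | diff(as.integer(
    factor(resname))) != 0L)))
  residue_index <- integer(natoms)
  for (ent in c(FALSE, TRUE)) {
    sel <- is_lip == ent
    if (!any(sel)) next
    residue_index[sel] <- as.integer(factor(key[sel], levels = unique(key[sel])))
  }

  cg_topology(data.frame(
    bead_id = 0:(natoms - 1L),
    bead_name = beadname,
    entity = ifelse(is_lip, "lipid", "protein"),
    residue_index = residue_index,
    residue_name = resname,
    lipid_species = ifelse(is_lip, resname, "none"),
    bead_class = bead_class,
    stringsAsFactors = FALSE))
}
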