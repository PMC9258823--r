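## STRIDE-format secondary structure records. Only ASG (per-residue
## assignment) lines are consumed; everything else is passed over, as when
## reading real STRIDE output.

#' Read per-residue secondary structure from a STRIDE file
#'
#' Parses `ASG` records and returns one row per residue with the one-letter
#' secondary-structure state (E strand, H/G/I helix, C/T coil and turn, ...).
#'
#' @param path Path to a STRIDE-format file.
#' @return data.frame with columns `residue_index` (ordinal, 1-based),
#'   `residue_name`, `chain`, `pdb_number`, `state`.
#' @export
read_stride <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  lines <- grep("^ASG ", readLines(path), value = TRUE)
  if (!length(lines)) stop_parse("no ASG records in ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) < 6L)
  if (length(bad)) stop_parse("malformed ASG record (line ", bad[1L], " of ",
                              "ASG block) in ", path)
  df <- data.frame(
    residue_name = vapply(parts, `[[`, character(1), 2L),
    chain = vapply(parts, `[[`, character(1), 3L),
    pdb_number = suppressWarnings(
      as.integer(vapply(parts, `[[`, character(1), 4L))),
    residue_index = suppressWarnings(
      as.integer(vapply(parts, `[[`, character(1), 5L))),
    state = toupper(vapply(parts, `[[`, character(1), 6L)),
    stringsAsFactors = FALSE)
  if (anyNA(df$residue_index))
    stop_parse("non-numeric ordinal residue number in ASG records of ", path)
  df[order(df$residue_index),
     c("residue_index", "residue_name", "chain", "pdb_number", "state")]
}

#' Write per-residue secondary structure as STRIDE ASG records
#'
#' @param residue_names Character vector of 3-letter residue codes.
#' @param states Character vector of one-letter states (same length).
#' @param path Output path.
#' @param chain Chain identifier written on every record.
#' @return `path`, invisibly.
#' @export
write_stride <- function(residue_names, states, path, chain = "A") {
  n <- length(residue_names)
  if (length(states) != n)
    stop_validation("residue_names and states must have equal length")
  state_names <- c(E = "Strand", H = "AlphaHelix", G = "310Helix",
                   I = "PiHelix", C = "Coil", T = "Turn", B = "Bridge")
  full <- state_names[toupper(states)]
  full[is.na(full)] <- "Coil"
  lines <- c(
    "REM  --------------- Secondary structure summary -------------------",
    sprintf("ASG  %-3s %s %4d %4d    %s   %-11s   %7.2f   %7.2f   %7.1f",
            toupper(substr(residue_names, 1L, 3L)), chain, seq_len(n),
            seq_len(n), toupper(states), full, 0, 0, 0))
  writeLines(lines, path)
  invisible(path)
}
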