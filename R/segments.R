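## Assignment of residues to the 14 conserved PH-domain structural segments
## (beta1..beta7, the six inter-strand loops, and the C-terminal helix) and
## the family-wide contact statistics built on it.

#' Assign residues to the 14 conserved PH-domain segments
#'
#' From a STRIDE-format secondary structure record: the seven longest
#' strand (state E) runs, in sequence order, become beta1..beta7; residues
#' between consecutive strands become the connecting loop; unstructured
#' N-terminal residues before the first strand are assigned to beta1 and
#' everything after beta7 (including the C-terminal helix) to alpha-C.
#' Short structured insertions that are not among the seven strand runs are
#' thereby folded into the surrounding loop. Declarative overrides are
#' applied last and recorded in an audit log.
#'
#' @param stride A data.frame from [read_stride()], or a path to a
#'   STRIDE-format file.
#' @param overrides Optional list of edits, each
#'   `list(residues = <indices>, segment = <label>)`, applied after
#'   automatic assignment.
#' @param min_strand_length Minimum E-run length counted as a strand
#'   (default 2; single-residue strands merge into the adjacent loop).
#' @return A `segment_assignment`: character vector of canonical labels,
#'   one per residue, named by residue index, with attributes `strands`
#'   (the detected runs) and `audit` (override log).
#' @export
assign_segments <- function(stride, overrides = NULL,
                            min_strand_length = 2L) {
  if (is.character(stride) && length(stride) == 1L)
    stride <- read_stride(stride)
  if (!is.data.frame(stride) || !all(c("residue_index", "state") %in%
                                       names(stride)))
    stop_validation("stride must be a STRIDE data.frame or file path")
  stride <- stride[order(stride$residue_index), ]
  n <- nrow(stride)
  if (!identical(stride$residue_index, seq_len(n)))
    stop_validation("STRIDE records must cover residues 1..n contiguously")

  is_e <- stride$state == "E"
  runs <- rle(is_e)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  strand_runs <- data.frame(start = starts[runs$values],
                            end = ends[runs$values])
  strand_runs <- strand_runs[
    strand_runs$end - strand_runs$start + 1L >= min_strand_length, ,
    drop = FALSE]

  if (nrow(strand_runs) < 7L && is.null(overrides)) {
    msg <- if (nrow(strand_runs))
      paste(sprintf("%d-%d", strand_runs$start, strand_runs$end),
            collapse = ", ") else "none"
    stop_validation("only ", nrow(strand_runs), " strand runs detected ",
                    "(need 7): ", msg,
                    "; supply overrides or exclude this domain")
  }
  if (nrow(strand_runs) > 7L) {
    len <- strand_runs$end - strand_runs$start + 1L
    keep <- order(len, -strand_runs$start, decreasing = TRUE)[1:7]
    strand_runs <- strand_runs[sort(keep), , drop = FALSE]
  }
  strand_runs <- strand_runs[order(strand_runs$start), , drop = FALSE]

  labels <- rep(NA_character_, n)
  if (nrow(strand_runs) == 7L) {
    for (k in 1:7)
      labels[strand_runs$start[k]:strand_runs$end[k]] <- paste0("beta", k)
    labels[seq_len(strand_runs$start[1L] - 1L)] <- "beta1"
    for (k in 1:6) {
      gap <- (strand_runs$end[k] + 1L):(strand_runs$start[k + 1L] - 1L)
      if (strand_runs$end[k] + 1L <= strand_runs$start[k + 1L] - 1L)
        labels[gap] <- paste0("beta", k, "-beta", k + 1L)
    }
    if (strand_runs$end[7L] < n)
      labels[(strand_runs$end[7L] + 1L):n] <- "alpha-C"
  }

  audit <- character(0)
  for (ov in overrides) {
    if (!all(c("residues", "segment") %in% names(ov)))
      stop_validation("each override needs $residues and $segment")
    if (!ov$segment %in% SEGMENT_LABELS)
      stop_validation("unknown segment label in override: ", ov$segment)
    res <- as.integer(ov$residues)
    if (any(res < 1L | res > n))
      stop_validation("override residues outside 1..", n)
    audit <- c(audit, sprintf("residues %s: %s -> %s",
                              paste(res, collapse = ","),
                              paste(unique(labels[res]), collapse = "/"),
                              ov$segment))
    labels[res] <- ov$segment
  }
  if (anyNA(labels))
    stop_validation("assignment incomplete; residues ",
                    paste(which(is.na(labels)), collapse = ", "),
                    " unlabelled (supply overrides)")

  structure(setNames(labels, seq_len(n)),
            strands = strand_runs, audit = audit,
            class = "segment_assignment")
}

#' @export
print.segment_assignment <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = SEGMENT_LABELS))
  cat("segment_assignment:", length(x), "residues\n")
  print(tab)
  if (length(attr(x, "audit")))
    cat("overrides:\n ", paste(attr(x, "audit"), collapse = "\n  "), "\n")
  invisible(x)
}

## counts vector for one lipid group out of a contact matrix
group_counts <- function(contacts, group) {
  stopifnot(inherits(contacts, "contact_matrix"))
  if (!group %in% colnames(contacts$counts))
    stop_validation("no lipid group '", group, "' in contact matrix")
  contacts$counts[, group]
}

#' Family-wide contact frequency per structural segment
#'
#' Sums the contacts of every residue assigned to each segment over all
#' domains (and their replicates, already totalled in the input matrices)
#' and divides by the total number of residues assigned to that segment, so
#' segments are comparable despite different lengths.
#'
#' @param contacts A `contact_matrix` or list of them (one per domain,
#'   summed over replicates).
#' @param assignments Matching `segment_assignment` or list of them.
#' @param group Lipid group column to analyse (default the combined PIP
#'   headgroups).
#' @return data.frame with `segment` (canonical order), `total_contacts`,
#'   `n_residues`, `frequency`.
#' @export
segment_contact_frequency <- function(contacts, assignments,
                                      group = "PIP_head") {
  if (inherits(contacts, "contact_matrix")) contacts <- list(contacts)
  if (inherits(assignments, "segment_assignment"))
    assignments <- list(assignments)
  if (length(contacts) != length(assignments))
    stop_validation("contacts and assignments must pair up per domain")
  totals <- setNames(numeric(length(SEGMENT_LABELS)), SEGMENT_LABELS)
  nres <- totals
  for (i in seq_along(contacts)) {
    cm <- contacts[[i]]
    seg <- assignments[[i]]
    counts <- group_counts(cm, group)
    lab <- unclass(seg)[as.character(cm$residue_index)]
    if (anyNA(lab))
      stop_validation("domain ", i, ": residues without a segment label")
    for (s in SEGMENT_LABELS) {
      sel <- lab == s
      totals[s] <- totals[s] + sum(counts[sel])
      nres[s] <- nres[s] + sum(sel)
    }
  }
  data.frame(segment = SEGMENT_LABELS,
             total_contacts = as.numeric(totals),
             n_residues = as.integer(nres),
             frequency = ifelse(nres > 0, totals / nres, NA_real_),
             row.names = NULL)
}

#' Family-wide contact frequency per amino-acid type
#'
#' Sums contacts over every occurrence of each amino acid across all
#' domains and divides by the number of occurrences. Types absent from all
#' sequences are reported as `NA`, not zero.
#'
#' @param contacts A `contact_matrix` or list of them (one per domain).
#' @param group Lipid group column to analyse.
#' @return data.frame with `residue_name`, `total_contacts`,
#'   `n_occurrences`, `frequency`.
#' @export
aminoacid_contact_frequency <- function(contacts, group = "PIP_head") {
  if (inherits(contacts, "contact_matrix")) contacts <- list(contacts)
  totals <- setNames(numeric(length(AA3)), AA3)
  nocc <- totals
  for (cm in contacts) {
    counts <- group_counts(cm, group)
    bad <- setdiff(unique(cm$residue_name), AA3)
    if (length(bad))
      stop_validation("unknown residue code(s): ",
                      paste(bad, collapse = ", "))
    for (aa in unique(cm$residue_name)) {
      sel <- cm$residue_name == aa
      totals[aa] <- totals[aa] + sum(counts[sel])
      nocc[aa] <- nocc[aa] + sum(sel)
    }
  }
  data.frame(residue_name = AA3,
             total_contacts = as.numeric(totals),
             n_occurrences = as.integer(nocc),
             frequency = ifelse(nocc > 0, totals / nocc, NA_real_),
             row.names = NULL)
}

#' Threshold table of segments with substantial PIP contacts
#'
#' For every domain and each of the 14 segments, marks TRUE when the
#' segment contains a residue whose normalized contact value for the chosen
#' group meets the threshold (default 0.8, applied as `>= 0.8`; the
#' normalization guarantees the top-contact residue always qualifies, so
#' the segment holding the primary site is always marked).
#'
#' @param normalized A `normalized_contacts` or list of them (one per
#'   domain).
#' @param assignments Matching `segment_assignment`(s).
#' @param threshold Value in (0, 1\] (default 0.8).
#' @param group Lipid group column (default combined PIP headgroups).
#' @param domain_names Optional row labels.
#' @return A `threshold_table`: logical domains x 14 matrix plus a
#'   `summary` attribute with `primary_beta12_fraction` (fraction of
#'   domains with TRUE in any of beta1, beta1-beta2, beta2) and
#'   `supplementary_fraction` (among those, fraction with TRUE in at least
#'   one other segment).
#' @export
threshold_table <- function(normalized, assignments, threshold = 0.8,
                            group = "PIP_head", domain_names = NULL) {
  if (inherits(normalized, "normalized_contacts")) normalized <- list(normalized)
  if (inherits(assignments, "segment_assignment"))
    assignments <- list(assignments)
  if (length(normalized) != length(assignments))
    stop_validation("normalized and assignments must pair up per domain")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop_validation("threshold must lie in (0, 1]")
  n_dom <- length(normalized)
  tab <- matrix(FALSE, n_dom, length(SEGMENT_LABELS),
                dimnames = list(domain_names %||% paste0("domain_",
                                                         seq_len(n_dom)),
                                SEGMENT_LABELS))
  for (i in seq_len(n_dom)) {
    nc <- normalized[[i]]
    if (!group %in% colnames(nc$values))
      stop_validation("no lipid group '", group, "' in domain ", i)
    vals <- nc$values[, group]
    lab <- unclass(assignments[[i]])[as.character(nc$residue_index)]
    if (anyNA(lab))
      stop_validation("domain ", i, ": residues without a segment label")
    hit <- unique(lab[vals >= threshold])
    tab[i, hit] <- TRUE
  }
  beta12 <- c("beta1", "beta1-beta2", "beta2")
  primary <- rowSums(tab[, beta12, drop = FALSE]) > 0
  others <- rowSums(tab[, setdiff(SEGMENT_LABELS, beta12),
                        drop = FALSE]) > 0
  summary <- list(
    primary_beta12_fraction = mean(primary),
    supplementary_fraction = if (any(primary)) mean(others[primary])
                             else NA_real_,
    n_domains = n_dom)
  structure(tab, threshold = threshold, summary = summary,
            class = c("threshold_table", "matrix"))
}

#' @export
print.threshold_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat("threshold_table:", nrow(x), "domains x", ncol(x),
      "segments, threshold", attr(x, "threshold"), "\n")
  cat(sprintf("  beta1/beta1-beta2/beta2 primary site: %.1f%% of domains\n",
              100 * s$primary_beta12_fraction))
  if (!is.na(s$supplementary_fraction))
    cat(sprintf("  of those, with a supplementary segment: %.1f%%\n",
                100 * s$supplementary_fraction))
  invisible(x)
}

#' Write a threshold table as TSV
#'
#' @param table A `threshold_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_table <- function(table, path) {
  stopifnot(inherits(table, "threshold_table"))
  df <- data.frame(domain = rownames(table),
                   as.data.frame(unclass(table)[, , drop = FALSE]),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Render a threshold table as a boolean heat map
#'
#' @param table A `threshold_table`.
#' @param ... Passed to [graphics::image()].
#' @export
plot_threshold_table <- function(table, ...) {
  stopifnot(inherits(table, "threshold_table"))
  m <- t(unclass(table))[, rev(seq_len(nrow(table))), drop = FALSE]
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m * 1,
                  col = c("white", "darkgreen"), axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(ncol(m)), labels = colnames(m), las = 1,
                 cex.axis = 0.6)
  graphics::box()
  invisible(table)
}
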