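## Per-residue protein-lipid contact counting, normalization, replicate
## aggregation and convergence analysis.
##
## A contact is binary per (residue, lipid group, frame): one contact is
## counted at a residue for every frame in which any bead of the group lies
## within the cutoff distance (default 0.55 nm, minimum image) of any bead
## of that residue. Multiple lipids simultaneously inside the cutoff still
## count once.

#' Count per-residue contacts with lipid bead groups
#'
#' @param frames List of [cg_frame()] objects (one replicate trajectory).
#' @param topology Matching `cg_topology`.
#' @param groups Named list of [lipid_group()]s; defaults to the eight
#'   canonical groups of [canonical_lipid_groups()].
#' @param cutoff Contact cutoff in nm (default 0.55, i.e. 5.5 Angstrom).
#' @param window Integer vector of frame indices to analyse (1-based), or
#'   `NULL` for the default final-window fraction.
#' @param window_fraction Fraction of trailing frames analysed when `window`
#'   is `NULL` (default 0.2, the final fifth of the run — e.g. the last
#'   200 ns of a 1 us trajectory).
#' @param replicate_id Identifier stored on the result.
#' @return A `contact_matrix`: residue x group integer counts with
#'   attributes `n_frames_analyzed`, `window`, `cutoff`, `replicate_id`,
#'   `residue_index`, `residue_name`.
#' @details Distances use a cell-list neighbour search that is exactly
#'   equivalent to an all-pairs sweep (the brute-force oracle is part of the
#'   test suite). A group that selects zero beads yields a column of zeros
#'   with a warning.
#' @export
residue_group_contacts <- function(frames, topology,
                                   groups = canonical_lipid_groups(),
                                   cutoff = 0.55, window = NULL,
                                   window_fraction = 0.2,
                                   replicate_id = 1L) {
  stopifnot(inherits(topology, "cg_topology"))
  assert_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  nf <- length(frames)
  if (!nf) stop_validation("no frames supplied")
  if (is.null(window)) window <- final_window(nf, window_fraction)
  window <- as.integer(window)
  if (!length(window)) stop_validation("empty analysis window")
  if (any(window < 1L | window > nf))
    stop_validation("window indices outside trajectory (1..", nf, ")")

  if (inherits(groups, "lipid_group")) groups <- list(groups)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- vapply(groups, `[[`, character(1), "name")
  n_groups <- length(groups)
  if (n_groups > 30L)
    stop_validation("at most 30 lipid groups per call")

  prot <- which(topology$entity == "protein")
  if (!length(prot)) stop_validation("topology has no protein beads")
  res_idx <- protein_residue_indices(topology)
  res_slot <- match(topology$residue_index[prot], res_idx) - 1L

  ## bead -> group-membership bitmask
  sel <- lapply(groups, function(g) group_bead_indices(topology, g))
  empty <- vapply(sel, length, integer(1)) == 0L
  if (any(empty))
    warning("lipid group(s) selecting zero beads: ",
            paste(names(groups)[empty], collapse = ", "))
  lipid_beads <- sort(unique(unlist(sel)))
  mask <- integer(length(lipid_beads))
  for (g in seq_len(n_groups))
    mask[match(sel[[g]], lipid_beads)] <-
      bitwOr(mask[match(sel[[g]], lipid_beads)], bitwShiftL(1L, g - 1L))

  nb <- n_beads(topology)
  coord_list <- vector("list", length(window))
  boxes <- matrix(0, length(window), 3L)
  for (i in seq_along(window)) {
    f <- frames[[window[i]]]
    if (nrow(f$coordinates) != nb)
      stop_validation("frame ", window[i], " bead count != topology")
    coord_list[[i]] <- f$coordinates
    boxes[i, ] <- f$box
  }

  counts <- cpp_contact_counts(coord_list, boxes, prot - 1L, res_slot,
                               lipid_beads - 1L, mask,
                               length(res_idx), n_groups, cutoff)
  dimnames(counts) <- list(as.character(res_idx), names(groups))

  res_name <- topology$residue_name[prot][match(res_idx,
                                                topology$residue_index[prot])]
  structure(list(counts = counts,
                 n_frames_analyzed = length(window),
                 window = c(min(window), max(window)),
                 cutoff = cutoff,
                 replicate_id = replicate_id,
                 residue_index = res_idx,
                 residue_name = res_name),
            class = "contact_matrix")
}

final_window <- function(n_frames, fraction = 0.2) {
  if (fraction <= 0 || fraction > 1)
    stop_validation("window fraction must be in (0, 1]")
  start <- n_frames - max(1L, floor(n_frames * fraction)) + 1L
  start:n_frames
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", nrow(x$counts), "residues x", ncol(x$counts),
      "groups,", x$n_frames_analyzed, "frames analysed (window ",
      x$window[1], "-", x$window[2], "), cutoff", x$cutoff, "nm\n")
  invisible(x)
}

#' Sum contact matrices over simulation replicates
#'
#' Contact counts at each residue are totalled across replicates before
#' normalization; frame counts add likewise.
#'
#' @param matrices List of `contact_matrix` objects sharing residue and
#'   group axes, cutoff and window placement.
#' @return A single summed `contact_matrix` (`replicate_id = NA`).
#' @export
aggregate_replicates <- function(matrices) {
  if (inherits(matrices, "contact_matrix")) matrices <- list(matrices)
  if (!length(matrices)) stop_validation("no contact matrices supplied")
  ref <- matrices[[1L]]
  for (m in matrices[-1L]) {
    if (!identical(dimnames(m$counts), dimnames(ref$counts)))
      stop_validation("contact matrices have mismatched residue/group axes")
    if (!isTRUE(all.equal(m$cutoff, ref$cutoff)))
      stop_validation("contact matrices have mismatched cutoffs")
  }
  total <- Reduce(`+`, lapply(matrices, `[[`, "counts"))
  structure(list(counts = total,
                 n_frames_analyzed = sum(vapply(matrices, `[[`, numeric(1),
                                                "n_frames_analyzed")),
                 window = ref$window,
                 cutoff = ref$cutoff,
                 replicate_id = NA_integer_,
                 residue_index = ref$residue_index,
                 residue_name = ref$residue_name),
            class = "contact_matrix")
}

#' Normalize contact counts per lipid group
#'
#' Divides the total contacts at each residue by the contacts of the residue
#' with the most contacts with that lipid group, so the top residue has the
#' value 1 and all others are relative to it.
#'
#' @param total A `contact_matrix` (typically summed over replicates).
#' @return A `normalized_contacts` object: `values` in \[0, 1\] plus the
#'   per-group `normalizer` (the raw maximum; 0 flags an all-zero group,
#'   whose column is reported as all zeros).
#' @export
normalize_contacts <- function(total) {
  stopifnot(inherits(total, "contact_matrix"))
  counts <- total$counts
  if (any(counts < 0)) stop_validation("negative contact counts")
  normalizer <- apply(counts, 2L, max)
  values <- counts
  for (g in seq_len(ncol(counts)))
    values[, g] <- if (normalizer[g] > 0) counts[, g] / normalizer[g] else 0
  structure(list(values = values, normalizer = normalizer,
                 residue_index = total$residue_index,
                 residue_name = total$residue_name),
            class = "normalized_contacts")
}

#' @export
print.normalized_contacts <- function(x, ...) {
  cat("normalized_contacts:", nrow(x$values), "residues x", ncol(x$values),
      "groups; group maxima:",
      paste(sprintf("%s=%g", colnames(x$values), x$normalizer),
            collapse = ", "), "\n")
  invisible(x)
}

#' Convergence of contact profiles with replicate subset size
#'
#' For each subset size k, repeatedly samples two disjoint k-subsets of
#' replicates, computes the normalized contact profile of a lipid group for
#' each subset, and records the Pearson correlation between the two
#' profiles. Increasing mean correlation with k indicates the aggregated
#' profile has converged.
#'
#' @param matrices List of per-replicate `contact_matrix` objects.
#' @param group Column name (or index) of the lipid group to profile.
#' @param subset_sizes Integer vector of subset sizes; each must be at most
#'   `floor(n_replicates / 2)` so disjoint draws exist.
#' @param n_draws Draws per subset size.
#' @param seed Integer seed for the draw sequence.
#' @return data.frame with columns `k`, `draw`, `correlation`, plus a
#'   summary attribute `summary` (mean and sd per k).
#' @export
convergence_profile <- function(matrices, group = "PIP_head",
                                subset_sizes = 1:5, n_draws = 20L,
                                seed = 1L) {
  n_rep <- length(matrices)
  if (n_rep < 2L) stop_validation("need at least 2 replicates")
  subset_sizes <- as.integer(subset_sizes)
  if (any(subset_sizes < 1L) || any(subset_sizes > n_rep %/% 2L))
    stop_validation("subset sizes must lie in 1..floor(n_replicates/2)")
  profile_of <- function(idx) {
    total <- aggregate_replicates(matrices[idx])
    normalize_contacts(total)$values[, group]
  }
  out <- list()
  set.seed(as.integer(seed))
  for (k in subset_sizes) {
    corr <- numeric(n_draws)
    for (d in seq_len(n_draws)) {
      picks <- sample.int(n_rep, 2L * k)
      p1 <- profile_of(picks[1:k])
      p2 <- profile_of(picks[(k + 1L):(2L * k)])
      corr[d] <- if (sd(p1) == 0 || sd(p2) == 0) {
        if (isTRUE(all.equal(p1, p2))) 1 else 0
      } else cor(p1, p2)
    }
    out[[length(out) + 1L]] <-
      data.frame(k = k, draw = seq_len(n_draws), correlation = corr)
  }
  res <- do.call(rbind, out)
  summ <- do.call(rbind, lapply(split(res$correlation, res$k), function(v)
    data.frame(mean = mean(v), sd = sd(v))))
  summ <- data.frame(k = as.integer(rownames(summ)), summ, row.names = NULL)
  attr(res, "summary") <- summ
  res
}

#' Export a contact table as TSV
#'
#' One row per residue and group, with raw and normalized counts.
#'
#' @param total Summed `contact_matrix`.
#' @param normalized Matching `normalized_contacts` (computed if missing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(total, normalized = NULL, path) {
  stopifnot(inherits(total, "contact_matrix"))
  if (is.null(normalized)) normalized <- normalize_contacts(total)
  groups <- colnames(total$counts)
  df <- do.call(rbind, lapply(groups, function(g)
    data.frame(residue_index = total$residue_index,
               residue_name = total$residue_name,
               group = g,
               raw = total$counts[, g],
               normalized = sprintf("%.6f", normalized$values[, g]))))
  write_tsv(df, path)
}

#' Write normalized contacts into the B-factor column of a PDB file
#'
#' Renders a per-residue contact fingerprint as structure colouring: each
#' protein bead is written as a pseudo-atom whose temperature factor is the
#' residue's normalized contact value for the chosen group (scaled to
#' 0-99.99).
#'
#' @param frame A `cg_frame` supplying coordinates (nm; written as Angstrom).
#' @param topology Matching `cg_topology`.
#' @param normalized A `normalized_contacts` object.
#' @param group Group column to render.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bfactor_pdb <- function(frame, topology, normalized,
                              group = "PIP_head", path) {
  stopifnot(inherits(frame, "cg_frame"), inherits(topology, "cg_topology"),
            inherits(normalized, "normalized_contacts"))
  prot <- which(topology$entity == "protein")
  vals <- normalized$values[, group]
  b <- vals[match(topology$residue_index[prot], normalized$residue_index)]
  xyz <- frame$coordinates[prot, , drop = FALSE] * 10  # nm -> Angstrom
  lines <- sprintf(
    "ATOM  %5d %-4s%-4sA%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_along(prot) %% 100000L,
    substr(topology$bead_name[prot], 1L, 4L),
    substr(topology$residue_name[prot], 1L, 3L),
    topology$residue_index[prot] %% 10000L,
    xyz[, 1], xyz[, 2], xyz[, 3], 1, pmin(99.99, b * 99.99))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
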