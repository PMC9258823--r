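# shared fixtures and independent oracles for the test suite

# minimal hand-built topology: one 2-bead protein residue plus lipids placed
# by the caller
tiny_topology <- function(lipids = data.frame(
                            lipid_species = "CHOL",
                            bead_class = "lipid_headgroup")) {
  prot <- data.frame(bead_id = 0:1, bead_name = c("BB", "SC1"),
                     entity = "protein", residue_index = 1L,
                     residue_name = "LYS", lipid_species = "none",
                     bead_class = c("protein_backbone", "protein_sidechain"))
  lip <- data.frame(bead_id = 2:(1 + nrow(lipids)),
                    bead_name = "L",
                    entity = "lipid",
                    residue_index = seq_len(nrow(lipids)),
                    residue_name = lipids$lipid_species,
                    lipid_species = lipids$lipid_species,
                    bead_class = lipids$bead_class)
  cg_topology(rbind(prot, lip))
}

# independent O(N^2) all-pairs contact oracle (no cell list, no C++)
brute_contact_counts <- function(frames, topology, groups, cutoff, window) {
  res_idx <- sort(unique(topology$residue_index[topology$entity == "protein"]))
  counts <- matrix(0L, length(res_idx), length(groups),
                   dimnames = list(as.character(res_idx), names(groups)))
  sel <- lapply(groups, function(g)
    which(topology$entity == "lipid" &
            topology$lipid_species %in% g$species &
            topology$bead_class %in% g$classes))
  res_beads <- lapply(res_idx, function(r)
    which(topology$entity == "protein" & topology$residue_index == r))
  for (fi in window) {
    f <- frames[[fi]]
    bx <- matrix(f$box, 1, 3)
    for (ri in seq_along(res_idx)) {
      for (gi in seq_along(groups)) {
        lb <- sel[[gi]]
        if (!length(lb)) next
        hit <- FALSE
        for (p in res_beads[[ri]]) {
          d <- f$coordinates[lb, , drop = FALSE] -
            matrix(f$coordinates[p, ], length(lb), 3, byrow = TRUE)
          b <- matrix(f$box, length(lb), 3, byrow = TRUE)
          d <- d - b * round(d / b)
          if (any(rowSums(d * d) <= cutoff^2)) { hit <- TRUE; break }
        }
        if (hit) counts[ri, gi] <- counts[ri, gi] + 1L
      }
    }
  }
  counts
}

# random mixed protein/lipid system with valid topology and random frames;
# coordinates deliberately spill outside the box to exercise wrapping
random_system <- function(n_res = 20, n_lip = 60, n_frames = 5, seed = 1) {
  set.seed(seed)
  rows <- list(); id <- 0L
  for (r in seq_len(n_res)) {
    nb <- sample(1:2, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      bead_id = id:(id + nb - 1L),
      bead_name = c("BB", "SC1")[seq_len(nb)], entity = "protein",
      residue_index = r,
      residue_name = sample(c("ALA", "LYS", "ARG", "SER"), 1),
      lipid_species = "none",
      bead_class = c("protein_backbone", "protein_sidechain")[seq_len(nb)])
    id <- id + nb
  }
  species <- sample(c("POPC", "POPE", "POPS", "POP2", "POP3", "CHOL"),
                    n_lip, replace = TRUE)
  for (m in seq_len(n_lip)) {
    sp <- species[m]
    layout <- switch(sp,
      POP2 = , POP3 = data.frame(
        bead_name = c("HEAD", "PO4", "C1A"),
        bead_class = c("lipid_headgroup", "lipid_PO4", "lipid_tail")),
      CHOL = data.frame(bead_name = "ROH", bead_class = "lipid_headgroup"),
      data.frame(bead_name = c("NC3", "C1A"),
                 bead_class = c("lipid_headgroup", "lipid_tail")))
    rows[[length(rows) + 1L]] <- data.frame(
      bead_id = id:(id + nrow(layout) - 1L), bead_name = layout$bead_name,
      entity = "lipid", residue_index = m, residue_name = sp,
      lipid_species = sp, bead_class = layout$bead_class)
    id <- id + nrow(layout)
  }
  topology <- cg_topology(do.call(rbind, rows))
  n <- nrow(topology)
  frames <- lapply(seq_len(n_frames), function(i) {
    box <- runif(3, 2.5, 9)
    cg_frame(cbind(runif(n, -box[1], 2 * box[1]),
                   runif(n, -box[2], 2 * box[2]),
                   runif(n, -box[3], 2 * box[3])),
             box, time = (i - 1) * 100)
  })
  list(topology = topology, frames = frames)
}

# small planted synthetic setup shared by module tests
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_replicates = 3L, n_frames = 150L,
                   protein_residue_count = 56L,
                   bilayer_dimensions = c(8, 8), box_height = 14)
  defaults[names(args)] <- args
  if (is.null(defaults$truth))
    defaults$truth <- planted_truth(
      bound_from_frame = max(1L, defaults$n_frames %/% 5L), seed = 5L)
  do.call(synthetic_run_spec, defaults)
}

# 180-degree rotation about an in-plane axis through the box centre: the
# physical leaflet-swap operation (a rigid motion, unlike a z reflection)
flip_leaflets <- function(frames) {
  lapply(frames, function(f)
    cg_frame(cbind(f$coordinates[, 1],
                   f$box[2] - f$coordinates[, 2],
                   f$box[3] - f$coordinates[, 3]),
             f$box, f$time))
}
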