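## Multivalent PIP association and lipid clustering: per-frame counts of
## PIP PO4 linker phosphates close to the protein, and lateral radial
## distribution functions of lipid species about the bound protein.

#' Per-frame count of PIP PO4 particles near the protein
#'
#' Counts, at every frame, the distinct POP2/POP3 molecules whose PO4
#' linker-phosphate bead lies within the cutoff (minimum image) of any
#' protein bead. Each PIP carries exactly one PO4 bead, so molecule and
#' bead counts coincide. The cutoff (default 0.65 nm) is larger than the
#' 0.55 nm contact cutoff because the linker phosphate sits below the
#' headgroup phosphates.
#'
#' @param frames List of `cg_frame`s (one replicate).
#' @param topology Matching `cg_topology`.
#' @param cutoff Cutoff in nm (default 0.65).
#' @return data.frame with columns `frame`, `time`, `count`.
#' @export
pip_association_count <- function(frames, topology, cutoff = 0.65) {
  stopifnot(inherits(topology, "cg_topology"))
  assert_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  po4 <- which(topology$bead_class == "lipid_PO4" &
                 topology$lipid_species %in% c("POP2", "POP3"))
  if (!length(po4))
    stop_validation("topology contains no POP2/POP3 lipid_PO4 beads")
  prot <- which(topology$entity == "protein")
  nb <- n_beads(topology)
  coord_list <- lapply(frames, function(f) {
    if (nrow(f$coordinates) != nb)
      stop_validation("frame bead count does not match topology")
    f$coordinates
  })
  boxes <- do.call(rbind, lapply(frames, `[[`, "box"))
  counts <- cpp_within_counts(coord_list, boxes, prot - 1L, po4 - 1L, cutoff)
  data.frame(frame = seq_along(frames),
             time = vapply(frames, `[[`, numeric(1), "time"),
             count = counts)
}

#' Replicate mean and SD of PIP association counts
#'
#' @param series List of per-replicate data.frames from
#'   [pip_association_count()], sharing the same time grid.
#' @return data.frame of class `association_series` with columns `frame`,
#'   `time`, `mean`, `sd`, and the per-replicate count matrix as attribute
#'   `counts`.
#' @export
association_series <- function(series) {
  if (is.data.frame(series)) series <- list(series)
  if (!length(series)) stop_validation("no association series supplied")
  t0 <- series[[1L]]$time
  for (s in series[-1L])
    if (!isTRUE(all.equal(s$time, t0)))
      stop_validation("replicates do not share a time grid")
  m <- vapply(series, `[[`, numeric(length(t0)), "count")
  m <- matrix(m, nrow = length(t0))
  structure(data.frame(frame = series[[1L]]$frame, time = t0,
                       mean = rowMeans(m),
                       sd = apply(m, 1L, sd)),
            counts = m,
            class = c("association_series", "data.frame"))
}

#' Lateral radial distribution function of a lipid species about the protein
#'
#' For frames where the protein is membrane-bound, computes the 2D
#' (xy-plane) radial distribution of the species' headgroup beads
#' (cholesterol: its single bead) in the bound leaflet around the protein's
#' lateral geometric centre. Normalization is by the species' mean areal
#' density in the leaflet, so uniform placement gives g(r) ~ 1. A 3D
#' spherical mode about the protein centre is provided for comparison.
#'
#' @param frames List of `cg_frame`s.
#' @param topology Matching `cg_topology`.
#' @param species Lipid species name (POPC, POPE, POPS, POP2, POP3, CHOL).
#' @param r_max Maximum radius in nm (default 6; must not exceed half the
#'   smaller lateral box length).
#' @param dr Bin width in nm (default 0.25).
#' @param window Frame indices to analyse, or `NULL` for the final
#'   `window_fraction` of frames.
#' @param window_fraction Trailing fraction analysed when `window` is NULL.
#' @param binding_distance Frames with |z-distance| below this (nm) count
#'   as membrane-bound (default 4.5).
#' @param mode `"lateral"` (default) or `"spherical"`.
#' @return data.frame of class `rdf_profile` with columns `r` (bin centre)
#'   and `g`, and attributes `species`, `n_frames_used`, `n_observations`,
#'   `mode`.
#' @export
lipid_rdf <- function(frames, topology, species, r_max = 6, dr = 0.25,
                      window = NULL, window_fraction = 0.2,
                      binding_distance = 4.5,
                      mode = c("lateral", "spherical")) {
  mode <- match.arg(mode)
  stopifnot(inherits(topology, "cg_topology"))
  assert_scalar_number(dr, "dr", positive = TRUE)
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  nf <- length(frames)
  if (is.null(window)) window <- final_window(nf, window_fraction)
  if (!length(window)) stop_validation("empty analysis window")
  if (!species %in% LIPID_SPECIES)
    stop_validation("unknown species: ", species)
  sel <- which(topology$lipid_species == species &
                 topology$bead_class == "lipid_headgroup")
  if (!length(sel))
    stop_validation("no headgroup beads for species ", species,
                    " (composition fraction 0?)")
  prot <- which(topology$entity == "protein")

  box_xy <- frames[[window[1L]]]$box[1:2]
  if (r_max > min(box_xy) / 2 && mode == "lateral")
    stop_validation("r_max must not exceed half the lateral box length")
  edges <- seq(0, r_max, by = dr)
  if (tail(edges, 1L) < r_max) edges <- c(edges, tail(edges, 1L) + dr)
  counts <- numeric(length(edges) - 1L)
  n_used <- 0L
  n_obs <- 0
  density_acc <- 0

  for (i in window) {
    f <- frames[[i]]
    zd <- z_distance(f, topology)
    if (abs(zd) >= binding_distance) next
    n_used <- n_used + 1L
    pc <- colMeans(f$coordinates[prot, , drop = FALSE])
    if (mode == "lateral") {
      memb_z <- mean(f$coordinates[topology$entity == "lipid", 3L])
      leaf_side <- sign(zd)
      bead_side <- sign(f$coordinates[sel, 3L] - memb_z)
      beads <- sel[bead_side == leaf_side]
      dx <- f$coordinates[beads, 1L] - pc[1L]
      dy <- f$coordinates[beads, 2L] - pc[2L]
      dx <- dx - f$box[1L] * round(dx / f$box[1L])
      dy <- dy - f$box[2L] * round(dy / f$box[2L])
      r <- sqrt(dx^2 + dy^2)
      density_acc <- density_acc + length(beads) / prod(f$box[1:2])
    } else {
      disp <- minimum_image_displacement(
        f$coordinates[sel, , drop = FALSE],
        matrix(pc, length(sel), 3L, byrow = TRUE), f$box)
      r <- sqrt(rowSums(disp^2))
      density_acc <- density_acc + length(sel) / prod(f$box)
    }
    inside <- r <= r_max
    n_obs <- n_obs + sum(inside)
    bi <- findInterval(r[inside], edges, rightmost.closed = TRUE)
    for (b in bi) counts[b] <- counts[b] + 1
  }
  if (n_used == 0L)
    stop_validation("no membrane-bound frames in window (binding criterion",
                    ": |z-distance| < ", binding_distance, " nm)")
  rho <- density_acc / n_used
  lo <- head(edges, -1L); hi <- tail(edges, -1L)
  shell <- if (mode == "lateral") pi * (hi^2 - lo^2) else
    4 / 3 * pi * (hi^3 - lo^3)
  g <- counts / n_used / (shell * rho)
  structure(data.frame(r = (lo + hi) / 2, g = g),
            species = species, n_frames_used = n_used,
            n_observations = n_obs, mode = mode, rho = rho,
            class = c("rdf_profile", "data.frame"))
}

#' Write per-species RDF profiles as a single TSV
#'
#' @param profiles List of `rdf_profile` data.frames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rdf_tsv <- function(profiles, path) {
  if (inherits(profiles, "rdf_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(species = attr(p, "species"), r = p$r,
               g = sprintf("%.6f", p$g))))
  write_tsv(df, path)
}
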