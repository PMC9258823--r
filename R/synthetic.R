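## Synthetic coarse-grained trajectory generator with planted ground truth.
##
## The generator emulates the statistical structure the analysis stack
## assumes — an approach phase with the protein detached and tumbling,
## followed by a bound phase with a planted orientation, planted per-residue
## contact hotspots and planted PIP enrichment around the protein — without
## integrating any dynamics. Lipids are resampled every frame from a known
## spatial distribution (quasi-static equilibrium snapshots), which keeps
## the planted truth analytic and every downstream stage verifiable.

## canonical ordered labels of the 14 conserved PH-domain segments:
## seven strands, six inter-strand loops, C-terminal helix
SEGMENT_LABELS <- c("beta1", "beta1-beta2", "beta2", "beta2-beta3", "beta3",
                    "beta3-beta4", "beta4", "beta4-beta5", "beta5",
                    "beta5-beta6", "beta6", "beta6-beta7", "beta7", "alpha-C")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

## membrane geometry constants (nm, offsets from the bilayer mid-plane)
MEMBRANE_Z <- list(head = 2.0, po4 = 1.7, tail1 = 1.0, tail2 = 0.5,
                   chol = 1.2)

#' Bilayer composition by species mole fraction
#'
#' Defaults to the PIP-rich model bilayer used throughout the package:
#' 10% POPC, 40% POPE, 15% POPS, 7% PIP2, 3% PIP3 and 25% cholesterol,
#' identical in both leaflets.
#'
#' @param POPC,POPE,POPS,POP2,POP3,CHOL Mole fractions, summing to 1.
#' @return Named numeric vector of class `membrane_composition`.
#' @export
membrane_composition <- function(POPC = 0.10, POPE = 0.40, POPS = 0.15,
                                 POP2 = 0.07, POP3 = 0.03, CHOL = 0.25) {
  x <- c(POPC = POPC, POPE = POPE, POPS = POPS, POP2 = POP2, POP3 = POP3,
         CHOL = CHOL)
  if (any(x < 0) || any(x > 1))
    stop_validation("composition fractions must lie in [0, 1]")
  if (abs(sum(x) - 1) > 1e-9)
    stop_validation("composition fractions must sum to 1 (got ", sum(x), ")")
  structure(x, class = "membrane_composition")
}

## largest-remainder rounding of composition fractions to integer counts
species_counts <- function(composition, n) {
  raw <- unclass(composition) * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  as.integer(counts) |> setNames(names(raw))
}

#' Planted ground truth for a synthetic run
#'
#' @param hotspot_residues Integer residue indices of the planted contact
#'   hotspots, or `NULL` to use the residues of `hotspot_segment`.
#' @param hotspot_segment Segment label whose residues become hotspots when
#'   `hotspot_residues` is `NULL` (default the beta1-beta2 loop, the
#'   canonical PIP-binding loop).
#' @param hotspot_bias Multiplier (>= 1) on lipid placement probability
#'   within reach of hotspot residues; 1 disables the hotspot.
#' @param bound_Rzz Planted Rzz (cosine of the tilt from the reference
#'   orientation) during the bound phase, in \[-1, 1\].
#' @param orientation_noise Angular standard deviation (radians) of the
#'   per-frame tilt noise in the bound phase.
#' @param pip_enrichment_radius Radius (nm) of PIP enrichment around the
#'   bound protein's lateral centre.
#' @param pip_enrichment_factor Multiplier (>= 1) on POP2/POP3 placement
#'   probability inside the enrichment radius; 1 disables enrichment.
#' @param bound_from_frame 0-based frame index at which the protein becomes
#'   membrane-bound; earlier frames are the detached approach phase.
#' @param replicate_tilt_jitter Standard deviation (radians) of the
#'   per-replicate jitter in the tilt azimuth of the bound pose. Each
#'   replicate settles into a slightly different pose, so which non-hotspot
#'   residues graze the bilayer varies across replicates — the
#'   heterogeneity that convergence analysis averages out.
#' @param binding_distance z-distance (nm) below which a frame counts as
#'   membrane-associated in the planted truth (default 4.5 nm: membrane
#'   half-thickness plus protein radius).
#' @param seed Integer root seed; replicate r uses `seed + r`.
#' @return Object of class `planted_truth`.
#' @export
planted_truth <- function(hotspot_residues = NULL,
                          hotspot_segment = "beta1-beta2",
                          hotspot_bias = 10, bound_Rzz = 0.9,
                          orientation_noise = 0.1,
                          pip_enrichment_radius = 1.5,
                          pip_enrichment_factor = 3,
                          bound_from_frame = 200L,
                          replicate_tilt_jitter = 0.25,
                          binding_distance = 4.5, seed = 42L) {
  if (hotspot_bias < 1) stop_validation("hotspot_bias must be >= 1")
  if (pip_enrichment_factor < 1)
    stop_validation("pip_enrichment_factor must be >= 1")
  if (abs(bound_Rzz) > 1) stop_validation("bound_Rzz must lie in [-1, 1]")
  if (!is.null(hotspot_segment) &&
      !hotspot_segment %in% SEGMENT_LABELS)
    stop_validation("unknown hotspot_segment: ", hotspot_segment)
  structure(list(hotspot_residues = hotspot_residues,
                 hotspot_segment = hotspot_segment,
                 hotspot_bias = hotspot_bias,
                 bound_Rzz = bound_Rzz,
                 orientation_noise = orientation_noise,
                 pip_enrichment_radius = pip_enrichment_radius,
                 pip_enrichment_factor = pip_enrichment_factor,
                 bound_from_frame = as.integer(bound_from_frame),
                 replicate_tilt_jitter = replicate_tilt_jitter,
                 binding_distance = binding_distance,
                 seed = as.integer(seed)),
            class = "planted_truth")
}

#' Specification of a synthetic replicate set
#'
#' Defaults mirror the production design emulated by the generator: 20
#' replicate trajectories of a ~120-residue bead protein over a
#' 16.5 x 16.5 nm bilayer, 1000 frames per replicate at 1 ns spacing
#' (a nominal 1 us run), with the approach phase covering the first fifth.
#'
#' @param n_replicates Number of replicate trajectories (default 20).
#' @param n_frames Frames per replicate (default 1000).
#' @param frame_spacing Time between frames in ps (default 1000).
#' @param protein_residue_count Residues in the toy protein (default 120).
#' @param bilayer_dimensions Lateral box lengths (nm), default 16.5 x 16.5.
#' @param box_height Box height (nm), default 20.5.
#' @param apl Area per lipid (nm^2) setting the leaflet packing density
#'   (default 0.64).
#' @param composition A [membrane_composition()].
#' @param truth A [planted_truth()].
#' @return Object of class `synthetic_run_spec`.
#' @export
synthetic_run_spec <- function(n_replicates = 20L, n_frames = 1000L,
                               frame_spacing = 1000,
                               protein_residue_count = 120L,
                               bilayer_dimensions = c(16.5, 16.5),
                               box_height = 20.5, apl = 0.64,
                               composition = membrane_composition(),
                               truth = planted_truth()) {
  if (n_replicates < 1L) stop_validation("n_replicates must be >= 1")
  if (n_frames < 1L) stop_validation("n_frames must be >= 1")
  if (truth$bound_from_frame >= n_frames)
    stop_validation("bound_from_frame must be < n_frames")
  if (length(bilayer_dimensions) != 2L || any(bilayer_dimensions <= 0))
    stop_validation("bilayer_dimensions must be two positive lengths")
  assert_scalar_number(apl, "apl", positive = TRUE)
  stopifnot(inherits(composition, "membrane_composition"),
            inherits(truth, "planted_truth"))
  structure(list(n_replicates = as.integer(n_replicates),
                 n_frames = as.integer(n_frames),
                 frame_spacing = frame_spacing,
                 protein_residue_count = as.integer(protein_residue_count),
                 bilayer_dimensions = bilayer_dimensions,
                 box_height = box_height, apl = apl,
                 composition = composition, truth = truth),
            class = "synthetic_run_spec")
}

## ---- toy protein ----------------------------------------------------------

## split n residues over the 14 segments: floor(n/14) each, remainder dealt
## out in canonical order
segment_partition <- function(residue_count) {
  if (residue_count < 2L * length(SEGMENT_LABELS))
    stop_validation("residue_count must be >= ", 2L * length(SEGMENT_LABELS),
                    " (two residues per segment)")
  base <- residue_count %/% 14L
  lens <- rep(base, 14L)
  rem <- residue_count - 14L * base
  if (rem > 0) lens[seq_len(rem)] <- lens[seq_len(rem)] + 1L
  setNames(lens, SEGMENT_LABELS)
}

#' Build a rigid toy PH-like bead protein
#'
#' Places one backbone bead per residue (plus a sidechain bead on non-GLY
#' residues) on a barrel-like scaffold: seven antiparallel strands on a
#' cylinder, connecting loops bulging at the rims, and a C-terminal helix
#' capping the top. The scaffold's internal frame is well defined (barrel
#' axis along z, beta1-beta2 loop at the bottom rim), so a true orientation
#' is computable for any rotation applied to it. This is a geometric
#' stand-in for a CG PH domain, not a folded structure.
#'
#' @param residue_count Number of residues (>= 28).
#' @param seed Integer seed (controls the generated sequence).
#' @return Object of class `toy_protein`: `$topology` (protein-only
#'   `cg_topology`), `$coordinates` (reference orientation, centred),
#'   `$segments` (per-residue canonical segment label), `$states`
#'   (per-residue STRIDE one-letter state), `$sequence` (3-letter codes).
#' @export
build_toy_protein <- function(residue_count = 120L, seed = 1L) {
  lens <- segment_partition(residue_count)
  segments <- rep(names(lens), lens)

  set.seed(as.integer(seed))
  sequence <- sample(AA3, residue_count, replace = TRUE)

  radius <- 1.0
  strand_ids <- paste0("beta", 1:7)
  ## strand k sits at azimuth 2*pi*(k-1)/7; odd strands run top->bottom so
  ## that beta1-beta2 (and the other odd loops) bulge at the bottom rim
  strand_phi <- 2 * pi * (0:6) / 7
  height <- 0.35 * (max(lens[strand_ids]) - 1L)
  half <- height / 2

  phi <- numeric(residue_count)
  zz <- numeric(residue_count)
  rr <- rep(radius, residue_count)
  pos <- 1L
  for (s in seq_along(SEGMENT_LABELS)) {
    lab <- SEGMENT_LABELS[s]
    len <- lens[[lab]]
    idx <- pos:(pos + len - 1L)
    if (lab %in% strand_ids) {
      k <- match(lab, strand_ids)
      down <- (k %% 2L) == 1L
      t <- if (len > 1L) seq(0, 1, length.out = len) else 0.5
      zz[idx] <- if (down) half - height * t else -half + height * t
      phi[idx] <- strand_phi[k]
    } else if (lab == "alpha-C") {
      ## helix capping the top of the barrel
      t <- seq_along(idx) - 1L
      phi[idx] <- strand_phi[7L] + 0.6 * t
      rr[idx] <- 0.45
      zz[idx] <- half + 0.5 + 0.12 * t
    } else {
      ## loop between strands k and k+1, bulging past the rim
      k <- match(sub("-.*", "", lab), strand_ids)
      bottom <- (k %% 2L) == 1L
      t <- seq_len(len) / (len + 1L)
      phi[idx] <- strand_phi[k] + t * (2 * pi / 7)
      zz[idx] <- (if (bottom) -1 else 1) * (half + 0.3 * sin(pi * t))
    }
    pos <- pos + len
  }

  bb <- cbind(rr * cos(phi), rr * sin(phi), zz)
  has_sc <- sequence != "GLY"
  sc <- cbind((rr + 0.25) * cos(phi), (rr + 0.25) * sin(phi),
              zz)[has_sc, , drop = FALSE]

  n_bb <- residue_count
  coords <- rbind(bb, sc)
  res_of_bead <- c(seq_len(n_bb), which(has_sc))
  bead_name <- c(rep("BB", n_bb), rep("SC1", sum(has_sc)))
  ord <- order(res_of_bead, bead_name)
  coords <- coords[ord, , drop = FALSE]
  res_of_bead <- res_of_bead[ord]
  bead_name <- bead_name[ord]
  coords <- sweep(coords, 2L, colMeans(coords))  # centre internal frame

  topology <- cg_topology(data.frame(
    bead_id = seq_along(res_of_bead) - 1L,
    bead_name = bead_name,
    entity = "protein",
    residue_index = res_of_bead,
    residue_name = sequence[res_of_bead],
    lipid_species = "none",
    bead_class = ifelse(bead_name == "BB", "protein_backbone",
                        "protein_sidechain"),
    stringsAsFactors = FALSE))

  ## STRIDE states: strands E, loops C, helix H; long terminal segments get
  ## unstructured tails (re-absorbed into beta1 / alpha-C on parsing)
  states <- rep("C", residue_count)
  states[segments %in% strand_ids] <- "E"
  states[segments == "alpha-C"] <- "H"
  b1 <- which(segments == "beta1")
  if (length(b1) >= 4L) states[b1[1:2]] <- "C"
  ac <- which(segments == "alpha-C")
  if (length(ac) >= 4L) states[tail(ac, 2L)] <- "C"

  structure(list(topology = topology, coordinates = coords,
                 segments = segments, states = states, sequence = sequence),
            class = "toy_protein")
}

## ---- bilayer --------------------------------------------------------------

## per-species bead layout: (bead_name, bead_class, |z| offset) per bead
lipid_bead_layout <- function(species) {
  head_name <- c(POPC = "NC3", POPE = "NH3", POPS = "CNO",
                 POP2 = "HEAD", POP3 = "HEAD")
  switch(species,
    POPC = , POPE = , POPS = data.frame(
      bead_name = c(head_name[[species]], "C1A", "C1B"),
      bead_class = c("lipid_headgroup", "lipid_tail", "lipid_tail"),
      z = c(MEMBRANE_Z$head, MEMBRANE_Z$tail1, MEMBRANE_Z$tail2)),
    POP2 = , POP3 = data.frame(
      bead_name = c("HEAD", "PO4", "C1A", "C1B"),
      bead_class = c("lipid_headgroup", "lipid_PO4", "lipid_tail",
                     "lipid_tail"),
      z = c(MEMBRANE_Z$head, MEMBRANE_Z$po4, MEMBRANE_Z$tail1,
            MEMBRANE_Z$tail2)),
    CHOL = data.frame(bead_name = "ROH", bead_class = "lipid_headgroup",
                      z = MEMBRANE_Z$chol))
}

#' Build a symmetric planar bilayer of bead lipids
#'
#' Two leaflets mirrored in z about the bilayer mid-plane; per-species
#' counts per leaflet are the largest-remainder rounding of the composition
#' fractions. Phospholipids carry a headgroup bead and two tail beads at
#' fixed z offsets (PIPs additionally the PO4 linker phosphate);
#' cholesterol is a single bead.
#'
#' @param dimensions Lateral dimensions c(Lx, Ly) in nm.
#' @param composition A [membrane_composition()].
#' @param apl Area per lipid in nm^2 (default 0.64).
#' @param seed Integer seed for the initial lateral positions.
#' @return List: `$topology` (lipid-only topology rows, bead_id from 0),
#'   `$coordinates` (z relative to the bilayer mid-plane), `$leaflet`
#'   (+1/-1 per bead), `$molecule` (molecule index per bead),
#'   `$counts_per_leaflet` (named species counts).
#' @export
build_bilayer <- function(dimensions = c(16.5, 16.5),
                          composition = membrane_composition(),
                          apl = 0.64, seed = 1L) {
  stopifnot(inherits(composition, "membrane_composition"))
  if (length(dimensions) != 2L || any(dimensions <= 0))
    stop_validation("dimensions must be two positive lengths")
  assert_scalar_number(apl, "apl", positive = TRUE)
  n_leaflet <- max(1L, round(prod(dimensions) / apl))
  counts <- species_counts(composition, n_leaflet)

  rows <- list(); mol <- 0L
  molecule <- integer(0); leaflet <- integer(0); zoff <- numeric(0)
  for (side in c(1L, -1L)) {
    for (sp in names(counts)) {
      layout <- lipid_bead_layout(sp)
      for (i in seq_len(counts[[sp]])) {
        mol <- mol + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          bead_name = layout$bead_name, entity = "lipid",
          residue_index = mol, residue_name = sp, lipid_species = sp,
          bead_class = layout$bead_class, stringsAsFactors = FALSE)
        molecule <- c(molecule, rep(mol, nrow(layout)))
        leaflet <- c(leaflet, rep(side, nrow(layout)))
        zoff <- c(zoff, side * layout$z)
      }
    }
  }
  beads <- do.call(rbind, rows)
  beads <- cbind(bead_id = seq_len(nrow(beads)) - 1L, beads)

  set.seed(as.integer(seed))
  xy_mol <- cbind(runif(mol, 0, dimensions[1]), runif(mol, 0, dimensions[2]))
  coords <- cbind(xy_mol[molecule, 1L], xy_mol[molecule, 2L], zoff)

  list(topology = beads, coordinates = coords, leaflet = leaflet,
       molecule = molecule, counts_per_leaflet = counts)
}

## ---- rotation helpers -----------------------------------------------------

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3L, 3L)
}

rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3L, 3L)
}

## uniform random rotation from a normalized quaternion
random_rotation <- function() {
  q <- rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L)
}

## ---- system assembly and frame generation ---------------------------------

#' Assemble the static synthetic system for a run specification
#'
#' Builds the toy protein and bilayer once, resolves the planted hotspot
#' residues, and precomputes everything frame generation needs. Protein
#' beads come first in the combined topology, then lipid beads.
#'
#' @param spec A [synthetic_run_spec()].
#' @param protein_seed Seed for the toy protein build (sequence identity);
#'   defaults to the truth seed so a spec fully determines the system.
#' @return Object of class `synthetic_system`.
#' @export
synthetic_system <- function(spec, protein_seed = spec$truth$seed) {
  stopifnot(inherits(spec, "synthetic_run_spec"))
  protein <- build_toy_protein(spec$protein_residue_count, protein_seed)
  bilayer <- build_bilayer(spec$bilayer_dimensions, spec$composition,
                           spec$apl, protein_seed)

  np <- nrow(protein$topology)
  lip <- bilayer$topology
  lip$bead_id <- lip$bead_id + np
  topology <- cg_topology(rbind(as.data.frame(protein$topology), lip))

  truth <- spec$truth
  if (is.null(truth$hotspot_residues)) {
    truth$hotspot_residues <-
      which(protein$segments == (truth$hotspot_segment %||% "beta1-beta2"))
  }
  bad <- setdiff(truth$hotspot_residues,
                 seq_len(spec$protein_residue_count))
  if (length(bad))
    stop_validation("hotspot residues outside protein: ",
                    paste(bad, collapse = ", "))

  box <- c(spec$bilayer_dimensions, spec$box_height)
  structure(list(spec = spec, truth = truth, protein = protein,
                 bilayer = bilayer, topology = topology,
                 box = box, membrane_z = spec$box_height / 2,
                 hotspot_beads = which(protein$topology$residue_index %in%
                                         truth$hotspot_residues)),
            class = "synthetic_system")
}

#' @export
print.synthetic_system <- function(x, ...) {
  cat("synthetic_system:", nrow(x$protein$topology), "protein beads (",
      x$spec$protein_residue_count, "residues ),",
      nrow(x$bilayer$topology), "lipid beads;",
      length(x$truth$hotspot_residues), "hotspot residues in",
      x$truth$hotspot_segment %||% "custom set", "\n")
  invisible(x)
}

## sample n lateral positions from the planted mixture:
## uniform background + hotspot discs (all species) + enrichment disc
## (PIP species only); density ratios are hotspot_bias and
## pip_enrichment_factor relative to the background
sample_lateral <- function(n, box_xy, attractors, r_hot, bias,
                           center, r_enrich, factor) {
  area <- prod(box_xy)
  n_att <- if (is.null(attractors)) 0L else nrow(attractors)
  a_hot <- n_att * pi * r_hot^2
  a_enr <- if (factor > 1) pi * r_enrich^2 else 0
  d <- area + (bias - 1) * a_hot + (factor - 1) * a_enr
  p_hot <- (bias - 1) * a_hot / d
  p_enr <- (factor - 1) * a_enr / d

  u <- runif(n)
  comp <- ifelse(u < p_hot, 1L, ifelse(u < p_hot + p_enr, 2L, 3L))
  x <- numeric(n); y <- numeric(n)
  k1 <- comp == 1L
  if (any(k1)) {
    pick <- sample.int(n_att, sum(k1), replace = TRUE)
    r <- r_hot * sqrt(runif(sum(k1)))
    th <- runif(sum(k1), 0, 2 * pi)
    x[k1] <- attractors[pick, 1L] + r * cos(th)
    y[k1] <- attractors[pick, 2L] + r * sin(th)
  }
  k2 <- comp == 2L
  if (any(k2)) {
    r <- r_enrich * sqrt(runif(sum(k2)))
    th <- runif(sum(k2), 0, 2 * pi)
    x[k2] <- center[1L] + r * cos(th)
    y[k2] <- center[2L] + r * sin(th)
  }
  k3 <- comp == 3L
  if (any(k3)) {
    x[k3] <- runif(sum(k3), 0, box_xy[1L])
    y[k3] <- runif(sum(k3), 0, box_xy[2L])
  }
  cbind(x %% box_xy[1L], y %% box_xy[2L])
}

#' Generate one synthetic replicate trajectory
#'
#' Frames `0 .. bound_from_frame - 1` place the protein detached (z-distance
#' >= 6 nm from the bilayer mid-plane, fresh random orientation each frame);
#' later frames place it at membrane contact in the planted pose: tilt
#' drawn around `acos(bound_Rzz)` with `orientation_noise`, the hotspot
#' loop facing the bilayer, and a per-replicate azimuthal spin (membrane
#' binding does not constrain spin, so replicates differ in which
#' non-hotspot residues graze the surface). Lipid lateral positions are
#' resampled each frame; in the bound leaflet, placement probability is
#' multiplied by `hotspot_bias` within reach of hotspot residues and by
#' `pip_enrichment_factor` for PIPs within the enrichment radius.
#'
#' @param system A [synthetic_system()].
#' @param replicate 1-based replicate index; the RNG is seeded with
#'   `truth$seed + replicate`, so replicates are independent and each is
#'   individually reproducible.
#' @return List of [cg_frame()]s of length `spec$n_frames`.
#' @export
generate_replicate <- function(system, replicate = 1L) {
  stopifnot(inherits(system, "synthetic_system"))
  spec <- system$spec
  truth <- system$truth
  set.seed(replicate_seed(truth$seed, replicate))

  box <- system$box
  box_xy <- box[1:2]
  memb_z <- system$membrane_z
  z_head <- memb_z + MEMBRANE_Z$head
  ref <- system$protein$coordinates
  n_prot <- nrow(ref)
  hot_beads <- system$hotspot_beads

  ## tilt azimuth aligning the hotspot centroid with the down-tipping side
  hot_centroid <- colMeans(ref[hot_beads, , drop = FALSE])
  phi_hot <- atan2(hot_centroid[2L], hot_centroid[1L])
  spin_rep <- runif(1L, 0, 2 * pi)
  null_hotspot <- truth$hotspot_bias <= 1
  ## bound-pose tilt azimuth: towards the hotspot loop (with per-replicate
  ## jitter) when one is planted, otherwise uniform across replicates
  tilt_phi <- if (null_hotspot) runif(1L, 0, 2 * pi) else
    phi_hot + rnorm(1L, 0, truth$replicate_tilt_jitter %||% 0)
  theta0 <- acos(truth$bound_Rzz)

  lip <- system$bilayer
  mol_leaflet <- lip$leaflet[!duplicated(lip$molecule)]
  mol_species <- lip$topology$lipid_species[!duplicated(lip$molecule)]
  n_mol <- length(mol_leaflet)
  zoff <- lip$coordinates[, 3L]
  bead_mol <- lip$molecule
  is_pip_mol <- mol_species %in% c("POP2", "POP3")

  center_xy <- box_xy / 2
  frames <- vector("list", spec$n_frames)

  for (f in seq_len(spec$n_frames)) {
    frame0 <- f - 1L  # 0-based index, matching bound_from_frame
    bound <- frame0 >= truth$bound_from_frame

    if (bound) {
      theta <- theta0 + rnorm(1L, 0, truth$orientation_noise)
      rot <- rot_z(spin_rep + rnorm(1L, 0, 0.05)) %*% rot_y(theta) %*%
        rot_z(-tilt_phi)
      prot <- ref %*% t(rot)
      ## anchor the binding interface just above the headgroup plane: the
      ## hotspot loop when one is planted, otherwise whatever shell of
      ## beads ends up lowest (null model: no residue is special)
      anchor <- if (null_hotspot) {
        lo <- prot[, 3L] - min(prot[, 3L])
        mean(prot[lo < 0.3, 3L])
      } else mean(prot[hot_beads, 3L])
      dz <- z_head + 0.25 - anchor + rnorm(1L, 0, 0.03)
      prot[, 3L] <- prot[, 3L] + dz
    } else {
      rot <- random_rotation()
      prot <- ref %*% t(rot)
      prot[, 3L] <- prot[, 3L] + memb_z + runif(1L, 6.0, 6.6)
    }
    prot[, 1L] <- prot[, 1L] + center_xy[1L]
    prot[, 2L] <- prot[, 2L] + center_xy[2L]

    ## lateral attractors: hotspot beads within vertical reach of the
    ## bound-leaflet headgroup plane
    attractors <- NULL
    if (bound && truth$hotspot_bias > 1) {
      reach <- abs(prot[hot_beads, 3L] - z_head) <= 0.45
      if (any(reach))
        attractors <- prot[hot_beads[reach], 1:2, drop = FALSE]
    }

    mol_xy <- matrix(0, n_mol, 2L)
    top <- mol_leaflet == 1L
    if (bound) {
      sel <- top & is_pip_mol
      if (any(sel))
        mol_xy[sel, ] <- sample_lateral(sum(sel), box_xy, attractors, 0.5,
                                        truth$hotspot_bias, center_xy,
                                        truth$pip_enrichment_radius,
                                        truth$pip_enrichment_factor)
      sel <- top & !is_pip_mol
      if (any(sel))
        mol_xy[sel, ] <- sample_lateral(sum(sel), box_xy, attractors, 0.5,
                                        truth$hotspot_bias, center_xy,
                                        truth$pip_enrichment_radius, 1)
    } else {
      mol_xy[top, ] <- cbind(runif(sum(top), 0, box_xy[1L]),
                             runif(sum(top), 0, box_xy[2L]))
    }
    bot <- !top
    mol_xy[bot, ] <- cbind(runif(sum(bot), 0, box_xy[1L]),
                           runif(sum(bot), 0, box_xy[2L]))

    coords <- rbind(prot,
                    cbind(mol_xy[bead_mol, 1L], mol_xy[bead_mol, 2L],
                          memb_z + zoff))
    frames[[f]] <- cg_frame(coords, box, time = frame0 * spec$frame_spacing)
  }
  frames
}

#' Generate a full replicate set, optionally writing it to disk
#'
#' @param system A [synthetic_system()] (or a [synthetic_run_spec()], which
#'   is assembled first).
#' @param output_dir If non-NULL, writes `topology.tsv`, one
#'   `replicate_XX.gro` multi-frame trajectory per replicate, the
#'   STRIDE-format `segments.stride` file, `truth.json` and `manifest.json`
#'   into this directory.
#' @param keep_frames Return the frame lists (default TRUE when not
#'   writing; set FALSE to generate-and-write without holding all
#'   replicates in memory).
#' @return Invisibly, a list with `$system`, `$replicates` (list of frame
#'   lists or NULL), and `$files` (written paths, if any).
#' @export
generate_replicates <- function(system, output_dir = NULL,
                                keep_frames = is.null(output_dir)) {
  if (inherits(system, "synthetic_run_spec"))
    system <- synthetic_system(system)
  stopifnot(inherits(system, "synthetic_system"))
  spec <- system$spec
  files <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    files["topology"] <- write_topology(system$topology,
                                        file.path(output_dir, "topology.tsv"))
    files["stride"] <- write_stride(system$protein$sequence,
                                    system$protein$states,
                                    file.path(output_dir, "segments.stride"))
    files["truth"] <- write_truth_json(system,
                                       file.path(output_dir, "truth.json"))
  }
  replicates <- if (keep_frames) vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    frames <- generate_replicate(system, r)
    if (!is.null(output_dir)) {
      path <- file.path(output_dir, sprintf("replicate_%02d.gro", r))
      write_frames(frames, system$topology, path, "gro_multiframe")
      files[sprintf("replicate_%02d", r)] <- path
    }
    if (keep_frames) replicates[[r]] <- frames
  }
  if (!is.null(output_dir)) {
    manifest <- list(
      n_replicates = spec$n_replicates, n_frames = spec$n_frames,
      frame_spacing_ps = spec$frame_spacing,
      seed = system$truth$seed,
      replicate_seeds = vapply(seq_len(spec$n_replicates), function(r)
        replicate_seed(system$truth$seed, r), integer(1)),
      files = as.list(setNames(basename(files), names(files))))
    mp <- file.path(output_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
    files["manifest"] <- mp
  }
  invisible(list(system = system, replicates = replicates, files = files))
}

#' Generate a synthetic family of domains with planted site fractions
#'
#' Builds one [synthetic_system()] per family member, planting the primary
#' hotspot in `primary_segment` for a fixed fraction of members (the
#' remainder get their primary site in `secondary_segment` instead —
#' atypical binders); among the primary-site members, a fixed fraction
#' additionally carries a supplementary hotspot in `secondary_segment`.
#' Planted memberships are deterministic counts (rounded fractions), so the
#' family-statistic recovery is a test of the analysis, not of membership
#' sampling.
#'
#' @param n_domains Number of family members.
#' @param spec Per-domain [synthetic_run_spec()] template; each member gets
#'   its own derived seed (`seed + 1000 * domain_index`).
#' @param primary_fraction Fraction of members whose hotspots sit in
#'   `primary_segment` (default 0.85).
#' @param secondary_fraction Among primary-site members, fraction that also
#'   carries hotspots in `secondary_segment` (default 0.89).
#' @param primary_segment,secondary_segment Canonical segment labels.
#' @param seed Family root seed.
#' @return List of `synthetic_system`s with attribute `family_truth`, a
#'   data.frame of the planted membership per domain.
#' @export
synthetic_family <- function(n_domains = 10L, spec = synthetic_run_spec(),
                             primary_fraction = 0.85,
                             secondary_fraction = 0.89,
                             primary_segment = "beta1-beta2",
                             secondary_segment = "beta3-beta4",
                             seed = 1L) {
  n_domains <- as.integer(n_domains)
  if (n_domains < 1L) stop_validation("n_domains must be >= 1")
  n_primary <- round(primary_fraction * n_domains)
  n_secondary <- round(secondary_fraction * n_primary)
  is_primary <- seq_len(n_domains) <= n_primary
  has_secondary <- seq_len(n_domains) <= n_secondary

  systems <- vector("list", n_domains)
  for (d in seq_len(n_domains)) {
    truth <- spec$truth
    truth$seed <- as.integer(seed + 1000L * d)
    truth$hotspot_residues <- NULL
    truth$hotspot_segment <- if (is_primary[d]) primary_segment
                             else secondary_segment
    sp <- spec
    sp$truth <- truth
    sys <- synthetic_system(sp)
    if (is_primary[d] && has_secondary[d]) {
      extra <- which(sys$protein$segments == secondary_segment)
      sys$truth$hotspot_residues <-
        sort(unique(c(sys$truth$hotspot_residues, extra)))
      sys$hotspot_beads <-
        which(sys$protein$topology$residue_index %in%
                sys$truth$hotspot_residues)
    }
    systems[[d]] <- sys
  }
  attr(systems, "family_truth") <- data.frame(
    domain = seq_len(n_domains), primary_site = is_primary,
    supplementary_site = is_primary & has_secondary)
  systems
}

write_truth_json <- function(system, path) {
  truth <- system$truth
  jsonlite::write_json(
    list(hotspot_residues = truth$hotspot_residues,
         hotspot_segment = truth$hotspot_segment,
         hotspot_bias = truth$hotspot_bias,
         bound_Rzz = truth$bound_Rzz,
         orientation_noise = truth$orientation_noise,
         pip_enrichment_radius = truth$pip_enrichment_radius,
         pip_enrichment_factor = truth$pip_enrichment_factor,
         bound_from_frame = truth$bound_from_frame,
         replicate_tilt_jitter = truth$replicate_tilt_jitter,
         binding_distance = truth$binding_distance,
         seed = truth$seed),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}
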