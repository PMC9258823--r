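## Protein-membrane orientation analysis: signed z-distance, least-squares
## rotation fit against a reference orientation, and the symmetry-corrected
## distance-rotation density matrix.

#' Signed z-distance between protein and membrane centres
#'
#' z-component of (protein geometric centre - membrane geometric centre),
#' minimum-image corrected along z. Assumes each entity is whole (not split
#' across the periodic boundary), as after centring the protein in the
#' trajectory.
#'
#' @param frame A `cg_frame`.
#' @param topology Matching `cg_topology`.
#' @return Signed distance in nm.
#' @export
z_distance <- function(frame, topology) {
  stopifnot(inherits(frame, "cg_frame"), inherits(topology, "cg_topology"))
  prot <- topology$entity == "protein"
  if (!any(prot) || all(prot))
    stop_validation("need at least one protein and one lipid bead")
  dz <- mean(frame$coordinates[prot, 3L]) -
    mean(frame$coordinates[!prot, 3L])
  bz <- frame$box[3L]
  dz - bz * round(dz / bz)
}

#' Least-squares rotation between a reference and a frame configuration
#'
#' Kabsch superposition: centres both bead sets, and returns the proper
#' rotation R (det +1, orthonormal) minimizing the squared deviation of
#' `R %*% reference` from the frame configuration. The (3,3) element is the
#' Rzz orientation proxy: the cosine between the reference frame's z-axis
#' and its image, i.e. protein tilt relative to the membrane normal when
#' the reference is membrane-bound.
#'
#' @param frame_coords N x 3 matrix of bead positions at the frame.
#' @param reference_coords N x 3 matrix of the reference orientation (same
#'   beads, same order).
#' @return 3 x 3 rotation matrix.
#' @export
fit_rotation <- function(frame_coords, reference_coords) {
  frame_coords <- as.matrix(frame_coords)
  reference_coords <- as.matrix(reference_coords)
  if (!identical(dim(frame_coords), dim(reference_coords)))
    stop_validation("frame and reference must have identical dimensions")
  if (nrow(frame_coords) < 3L)
    stop_validation("need at least 3 beads to fit a rotation")
  x <- sweep(reference_coords, 2L, colMeans(reference_coords))
  y <- sweep(frame_coords, 2L, colMeans(frame_coords))
  h <- crossprod(x, y)  # 3x3 covariance
  s <- svd(h)
  ## degenerate (collinear) configurations leave the rotation about the
  ## line undetermined
  if (s$d[2L] < 1e-10 * max(s$d[1L], 1e-300))
    stop_validation("degenerate (collinear) configuration; ",
                    "rotation is not determined")
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Per-frame orientation records for a trajectory
#'
#' For every frame: the signed z-distance, the Rzz element of the rotation
#' fit of the protein backbone beads against the reference, and the
#' symmetry-corrected Rzz (multiplied by -1 when the z-distance is
#' negative, because binding to either leaflet of a symmetric bilayer is
#' physically equivalent).
#'
#' @param frames List of `cg_frame`s.
#' @param topology Matching `cg_topology`.
#' @param reference Reference backbone coordinates (M x 3 matrix, one row
#'   per protein_backbone bead in topology order), or a `cg_frame` from
#'   which they are extracted. By convention the reference is the end frame
#'   of the first replicate of a set; an explicit reference structure may
#'   be supplied instead.
#' @return data.frame of class `orientation_records` with columns `frame`,
#'   `time`, `z_distance`, `Rzz`, `corrected_Rzz`.
#' @export
orientation_records <- function(frames, topology, reference) {
  stopifnot(inherits(topology, "cg_topology"))
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  bb <- which(topology$bead_class == "protein_backbone")
  if (length(bb) < 3L)
    stop_validation("need at least 3 backbone beads")
  if (inherits(reference, "cg_frame"))
    reference <- reference$coordinates[bb, , drop = FALSE]
  reference <- as.matrix(reference)
  if (nrow(reference) != length(bb))
    stop_validation("reference must have one row per backbone bead")
  n <- length(frames)
  zd <- numeric(n); rzz <- numeric(n); tm <- numeric(n)
  for (i in seq_len(n)) {
    f <- frames[[i]]
    zd[i] <- z_distance(f, topology)
    rot <- fit_rotation(f$coordinates[bb, , drop = FALSE], reference)
    rzz[i] <- rot[3L, 3L]
    tm[i] <- f$time
  }
  structure(data.frame(frame = seq_len(n), time = tm, z_distance = zd,
                       Rzz = rzz,
                       corrected_Rzz = rzz * ifelse(zd < 0, -1, 1)),
            class = c("orientation_records", "data.frame"))
}

#' Distance-rotation density matrix
#'
#' 2D histogram of absolute z-distance versus symmetry-corrected Rzz over a
#' set of orientation records (the sign of the z-distance has already been
#' consumed by the Rzz correction). Records outside the bin ranges are
#' counted in the clamped edge bins and reported via a message.
#'
#' @param records An `orientation_records` data.frame (rows from several
#'   replicates may be concatenated).
#' @param z_bins Strictly increasing bin edges for |z-distance| (nm);
#'   default 50 bins over 0..8 nm.
#' @param r_bins Strictly increasing bin edges for corrected Rzz; default
#'   50 bins over -1..1.
#' @param normalize Divide counts by the total so densities sum to 1.
#' @return Object of class `density_matrix`: `$counts` (z bins x Rzz
#'   bins), `$z_edges`, `$r_edges`, `$normalized`, `$n_records`.
#' @export
orientation_density <- function(records,
                                z_bins = seq(0, 8, length.out = 51L),
                                r_bins = seq(-1, 1, length.out = 51L),
                                normalize = FALSE) {
  if (!nrow(records)) stop_validation("no orientation records")
  if (is.unsorted(z_bins, strictly = TRUE) ||
      is.unsorted(r_bins, strictly = TRUE))
    stop_validation("bin edges must be strictly increasing")
  z <- abs(records$z_distance)
  r <- records$corrected_Rzz
  out_of_range <- sum(z < z_bins[1L] | z > z_bins[length(z_bins)] |
                        r < r_bins[1L] | r > r_bins[length(r_bins)])
  if (out_of_range > 0)
    message(out_of_range, " record(s) outside bin range; ",
            "counted in edge bins")
  zi <- pmin(pmax(findInterval(z, z_bins, rightmost.closed = TRUE), 1L),
             length(z_bins) - 1L)
  ri <- pmin(pmax(findInterval(r, r_bins, rightmost.closed = TRUE), 1L),
             length(r_bins) - 1L)
  counts <- matrix(0, length(z_bins) - 1L, length(r_bins) - 1L)
  for (k in seq_along(zi))
    counts[zi[k], ri[k]] <- counts[zi[k], ri[k]] + 1
  if (normalize) counts <- counts / sum(counts)
  structure(list(counts = counts, z_edges = z_bins, r_edges = r_bins,
                 normalized = normalize, n_records = nrow(records)),
            class = "density_matrix")
}

#' @export
print.density_matrix <- function(x, ...) {
  m <- density_mode(x)
  cat(sprintf(paste0("density_matrix: %d x %d bins over %d records; mode ",
                     "bin |z| in [%.2f, %.2f] nm, Rzz in [%.2f, %.2f]\n"),
              nrow(x$counts), ncol(x$counts), x$n_records,
              m$z_interval[1], m$z_interval[2], m$r_interval[1],
              m$r_interval[2]))
  invisible(x)
}

#' Mode bin of a density matrix
#'
#' @param density A `density_matrix`.
#' @return List with `z_interval` and `r_interval` (bin edges of the
#'   highest-count bin) and `count`.
#' @export
density_mode <- function(density) {
  stopifnot(inherits(density, "density_matrix"))
  idx <- arrayInd(which.max(density$counts), dim(density$counts))
  list(z_interval = density$z_edges[idx[1L] + 0:1],
       r_interval = density$r_edges[idx[2L] + 0:1],
       count = density$counts[idx[1L], idx[2L]])
}

#' Write orientation records or a density matrix as TSV
#'
#' @param x An `orientation_records` data.frame or a `density_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orientation_tsv <- function(x, path) {
  if (inherits(x, "density_matrix")) {
    nz <- nrow(x$counts); nr <- ncol(x$counts)
    df <- data.frame(
      z_lo = rep(x$z_edges[seq_len(nz)], nr),
      z_hi = rep(x$z_edges[seq_len(nz) + 1L], nr),
      rzz_lo = rep(x$r_edges[seq_len(nr)], each = nz),
      rzz_hi = rep(x$r_edges[seq_len(nr) + 1L], each = nz),
      count = as.vector(x$counts))
    write_tsv(df, path)
  } else {
    df <- as.data.frame(x)
    for (col in c("z_distance", "Rzz", "corrected_Rzz"))
      df[[col]] <- sprintf("%.6f", df[[col]])
    write_tsv(df, path)
  }
}

#' Render a density matrix as a heat map
#'
#' @param density A `density_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot_orientation_density <- function(density, ...) {
  stopifnot(inherits(density, "density_matrix"))
  zc <- (head(density$z_edges, -1L) + tail(density$z_edges, -1L)) / 2
  rc <- (head(density$r_edges, -1L) + tail(density$r_edges, -1L)) / 2
  graphics::image(zc, rc, density$counts,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "|z-distance| (nm)", ylab = "corrected Rzz", ...)
  invisible(density)
}
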