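## Configuration-driven orchestration: synthesize -> analyze -> report,
## with a JSON manifest (resolved parameters, file hashes) for audit.

#' Build and validate a run configuration
#'
#' A single configuration object drives the pipeline; all randomness flows
#' from one root seed (replicate r of the generator uses `seed + r`).
#'
#' @param mode `"synthesize"` (generate and write a replicate set),
#'   `"analyze"` (analyse existing files) or `"full"` (generate in memory
#'   and analyse).
#' @param output_dir Output directory (created if needed).
#' @param topology,trajectories,stride_file Input paths (analyze mode):
#'   topology TSV, character vector of trajectory files, STRIDE file.
#' @param spec A [synthetic_run_spec()] (synthesize/full modes); its truth
#'   seed is overridden by `seed`.
#' @param contact_cutoff Contact cutoff in nm (default 0.55).
#' @param association_cutoff PIP PO4 association cutoff in nm (default
#'   0.65).
#' @param window_fraction Trailing fraction of frames analysed (default
#'   0.2).
#' @param threshold Normalized-contact threshold for the segment table
#'   (default 0.8).
#' @param binding_distance Membrane-association z-distance criterion in nm
#'   (default 4.5).
#' @param rdf_r_max,rdf_dr RDF extent and bin width in nm.
#' @param z_bins,r_bins Bin counts of the orientation density matrix.
#' @param seed Root integer seed.
#' @param stages Analysis stages to run (subset of `"contacts"`,
#'   `"segments"`, `"orient"`, `"cluster"`; `"segments"` implies
#'   `"contacts"`). Default: all.
#' @param write_plots Also render PNG figures (default FALSE).
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("full", "synthesize", "analyze"),
                       output_dir,
                       topology = NULL, trajectories = NULL,
                       stride_file = NULL,
                       spec = synthetic_run_spec(),
                       contact_cutoff = 0.55, association_cutoff = 0.65,
                       window_fraction = 0.2, threshold = 0.8,
                       binding_distance = 4.5,
                       rdf_r_max = 6, rdf_dr = 0.25,
                       z_bins = 50L, r_bins = 50L,
                       seed = 1L,
                       stages = c("contacts", "segments", "orient",
                                  "cluster"),
                       write_plots = FALSE) {
  mode <- match.arg(mode)
  bad <- setdiff(stages, c("contacts", "segments", "orient", "cluster"))
  if (length(bad) || !length(stages))
    stop_validation("unknown stage(s): ", paste(bad, collapse = ", "))
  if ("segments" %in% stages) stages <- union(stages, "contacts")
  for (v in c(contact_cutoff, association_cutoff, binding_distance,
              rdf_r_max, rdf_dr))
    if (!is.numeric(v) || v <= 0)
      stop_validation("all cutoffs and bin widths must be > 0")
  if (window_fraction <= 0 || window_fraction > 1)
    stop_validation("window_fraction must lie in (0, 1]")
  if (threshold <= 0 || threshold > 1)
    stop_validation("threshold must lie in (0, 1]")
  if (mode == "analyze") {
    for (p in c(topology, trajectories, stride_file))
      if (!is.null(p) && !file.exists(p))
        stop_validation("input path does not exist: ", p)
    if (is.null(topology) || is.null(trajectories))
      stop_validation("analyze mode needs topology and trajectories")
  } else {
    stopifnot(inherits(spec, "synthetic_run_spec"))
    spec$truth$seed <- as.integer(seed)
  }
  structure(list(mode = mode, output_dir = output_dir,
                 topology = topology, trajectories = trajectories,
                 stride_file = stride_file, spec = spec,
                 contact_cutoff = contact_cutoff,
                 association_cutoff = association_cutoff,
                 window_fraction = window_fraction, threshold = threshold,
                 binding_distance = binding_distance,
                 rdf_r_max = rdf_r_max, rdf_dr = rdf_dr,
                 z_bins = as.integer(z_bins), r_bins = as.integer(r_bins),
                 seed = as.integer(seed), stages = stages,
                 write_plots = write_plots),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `spec` block
#' (with optional `truth` sub-block) mirrors [synthetic_run_spec()] and
#' [planted_truth()].
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$spec)) {
    sp <- raw$spec
    truth <- do.call(planted_truth, sp$truth %||% list())
    sp$truth <- NULL
    if (!is.null(sp$composition))
      sp$composition <- do.call(membrane_composition, sp$composition)
    raw$spec <- do.call(synthetic_run_spec, c(sp, list(truth = truth)))
  }
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(run_config, raw)
}

#' Run the pipeline described by a configuration
#'
#' `synthesize` writes a replicate set (topology, GRO trajectories, STRIDE
#' segments, planted truth). `analyze` reads existing files and writes the
#' analysis outputs: per-residue contact table, per-residue B-factor PDB,
#' segment frequencies, threshold-table row, orientation records and
#' density matrix, PIP association series and per-species RDFs. `full`
#' generates in memory and analyses. All outputs are listed in
#' `manifest.json` with MD5 hashes and the resolved parameter set;
#' identical configuration and seed reproduce identical hashes.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)

  if (config$mode == "synthesize") {
    gen <- generate_replicates(synthetic_system(config$spec),
                               output_dir = config$output_dir,
                               keep_frames = FALSE)
    outputs <- gen$files
    return(invisible(write_manifest(config, outputs)))
  }

  if (config$mode == "full") {
    system <- synthetic_system(config$spec)
    topology <- system$topology
    segments <- structure(
      setNames(system$protein$segments,
               seq_along(system$protein$segments)),
      class = "segment_assignment")
    outputs["stride"] <- write_stride(
      system$protein$sequence, system$protein$states,
      file.path(config$output_dir, "segments.stride"))
    outputs["topology"] <- write_topology(
      topology, file.path(config$output_dir, "topology.tsv"))
    outputs["truth"] <- write_truth_json(
      system, file.path(config$output_dir, "truth.json"))
    load_replicate <- function(r) generate_replicate(system, r)
    n_rep <- config$spec$n_replicates
  } else {
    topology <- read_topology(config$topology, "tsv")
    segments <- if (!is.null(config$stride_file))
      assign_segments(config$stride_file)
    load_replicate <- function(r)
      read_frames(config$trajectories[r], "gro_multiframe")
    n_rep <- length(config$trajectories)
  }

  stages <- config$stages
  groups <- canonical_lipid_groups()
  matrices <- vector("list", n_rep)
  assoc <- vector("list", n_rep)
  records <- vector("list", n_rep)
  reference <- NULL
  last_frame <- NULL
  all_frames_last <- NULL
  for (r in seq_len(n_rep)) {
    frames <- load_replicate(r)
    if (is.null(reference)) {
      ## reference orientation: end frame of the first replicate
      bb <- which(topology$bead_class == "protein_backbone")
      reference <- frames[[length(frames)]]$coordinates[bb, , drop = FALSE]
    }
    if ("contacts" %in% stages)
      matrices[[r]] <- residue_group_contacts(
        frames, topology, groups, cutoff = config$contact_cutoff,
        window_fraction = config$window_fraction, replicate_id = r)
    if ("cluster" %in% stages)
      assoc[[r]] <- pip_association_count(frames, topology,
                                          config$association_cutoff)
    if ("orient" %in% stages)
      records[[r]] <- orientation_records(frames, topology, reference)
    last_frame <- frames[[length(frames)]]
    if (r == n_rep) all_frames_last <- frames
  }

  normalized <- NULL
  if ("contacts" %in% stages) {
    total <- aggregate_replicates(matrices)
    normalized <- normalize_contacts(total)
    outputs["contacts"] <- write_contact_table(
      total, normalized, file.path(config$output_dir, "contacts.tsv"))
    outputs["bfactor_pdb"] <- write_bfactor_pdb(
      last_frame, topology, normalized, "PIP_head",
      file.path(config$output_dir, "contacts_pip.pdb"))
  }

  if ("segments" %in% stages && !is.null(segments)) {
    freq <- segment_contact_frequency(total, segments)
    outputs["segment_frequency"] <- write_tsv(
      transform(freq, frequency = sprintf("%.6f", frequency)),
      file.path(config$output_dir, "segment_frequency.tsv"))
    tab <- threshold_table(normalized, segments,
                           threshold = config$threshold)
    outputs["threshold_table"] <- write_threshold_table(
      tab, file.path(config$output_dir, "threshold_table.tsv"))
  }

  density <- NULL
  if ("orient" %in% stages) {
    all_records <- do.call(rbind, records)
    density <- orientation_density(
      all_records,
      z_bins = seq(0, 8, length.out = config$z_bins + 1L),
      r_bins = seq(-1, 1, length.out = config$r_bins + 1L))
    outputs["orientation"] <- write_orientation_tsv(
      all_records, file.path(config$output_dir, "orientation.tsv"))
    outputs["density_matrix"] <- write_orientation_tsv(
      density, file.path(config$output_dir, "density_matrix.tsv"))
  }

  if ("cluster" %in% stages) {
    assoc_summary <- association_series(assoc)
    df <- transform(as.data.frame(assoc_summary),
                    mean = sprintf("%.6f", mean), sd = sprintf("%.6f", sd))
    outputs["association"] <- write_tsv(
      df, file.path(config$output_dir, "pip_association.tsv"))

    present <- intersect(LIPID_SPECIES, unique(topology$lipid_species))
    box_xy <- all_frames_last[[1L]]$box[1:2]
    r_max <- min(config$rdf_r_max, min(box_xy) / 2)
    rdfs <- lapply(present, function(sp)
      lipid_rdf(all_frames_last, topology, sp, r_max = r_max,
                dr = config$rdf_dr,
                window_fraction = config$window_fraction,
                binding_distance = config$binding_distance))
    outputs["rdf"] <- write_rdf_tsv(
      rdfs, file.path(config$output_dir, "rdf.tsv"))
  }

  if (isTRUE(config$write_plots) && !is.null(density)) {
    png_path <- file.path(config$output_dir, "density_matrix.png")
    grDevices::png(png_path, width = 800, height = 600)
    plot_orientation_density(density)
    grDevices::dev.off()
    outputs["density_plot"] <- png_path
  }

  invisible(write_manifest(config, outputs))
}

write_manifest <- function(config, outputs) {
  params <- config[c("mode", "stages", "contact_cutoff",
                     "association_cutoff", "window_fraction", "threshold",
                     "binding_distance", "rdf_r_max", "rdf_dr", "z_bins",
                     "r_bins", "seed")]
  inputs <- c(config$topology, config$trajectories, config$stride_file)
  manifest <- list(
    parameters = params,
    inputs = if (length(inputs))
      as.list(setNames(unname(tools::md5sum(inputs)), inputs)),
    outputs = as.list(setNames(unname(tools::md5sum(unname(outputs))),
                               basename(unname(outputs)))))
  path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  manifest
}
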