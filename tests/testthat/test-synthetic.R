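test_that("toy protein partitions residues over the 14 segments", {
  p <- build_toy_protein(28, seed = 1)
  expect_equal(as.vector(table(factor(p$segments,
                                      levels = unique(p$segments)))),
               rep(2L, 14L))
  expect_equal(length(p$sequence), 28L)
  expect_error(build_toy_protein(27), "residue_count")

  # determinism
  p2 <- build_toy_protein(28, seed = 1)
  expect_identical(p$coordinates, p2$coordinates)
  expect_identical(p$sequence, p2$sequence)
})

test_that("generated STRIDE files reproduce the generator's segment map", {
  for (n in c(28L, 70L, 120L)) {
    p <- build_toy_protein(n, seed = n)
    path <- withr::local_tempfile(fileext = ".stride")
    write_stride(p$sequence, p$states, path)
    assigned <- assign_segments(path)
    expect_identical(as.character(assigned), p$segments)
  }
})

test_that("bilayer counts follow the composition by largest remainder", {
  # 8 x 8 nm at 0.64 nm^2/lipid -> exactly 100 lipids per leaflet
  b <- build_bilayer(c(8, 8), membrane_composition(), apl = 0.64, seed = 2)
  expect_equal(unname(b$counts_per_leaflet),
               c(10L, 40L, 15L, 7L, 3L, 25L))
  # bookkeeping: total beads = sum over species of count x beads/lipid
  beads_per <- c(POPC = 3, POPE = 3, POPS = 3, POP2 = 4, POP3 = 4, CHOL = 1)
  expect_equal(nrow(b$topology),
               2L * sum(b$counts_per_leaflet * beads_per))
  # leaflet symmetry: species/class/|z| multisets match between leaflets
  key <- function(side) sort(paste(b$topology$lipid_species[b$leaflet == side],
                                   b$topology$bead_class[b$leaflet == side],
                                   abs(b$coordinates[b$leaflet == side, 3])))
  expect_identical(key(1L), key(-1L))
  expect_error(
    build_bilayer(c(8, 8), structure(c(POPC = 0.5, POPE = 0.1, POPS = 0.1,
                                       POP2 = 0.1, POP3 = 0.1, CHOL = 0.2),
                                     class = "membrane_composition")),
    NA)  # valid sums pass
  expect_error(membrane_composition(POPC = 0.5), "sum to 1")
})

test_that("replicate generation is deterministic and byte-stable", {
  sys <- synthetic_system(small_spec())
  f1 <- generate_replicate(sys, 1)
  f2 <- generate_replicate(sys, 1)
  expect_identical(f1, f2)
  f3 <- generate_replicate(sys, 2)
  expect_false(identical(f1[[1]]$coordinates, f3[[1]]$coordinates))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- small_spec(n_replicates = 2L, n_frames = 20L)
  generate_replicates(synthetic_system(spec), output_dir = d1,
                      keep_frames = FALSE)
  generate_replicates(synthetic_system(spec), output_dir = d2,
                      keep_frames = FALSE)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("bound-phase fraction matches the planted binding frame", {
  spec <- small_spec(n_frames = 200L,
                     truth = planted_truth(bound_from_frame = 80L, seed = 3))
  sys <- synthetic_system(spec)
  frames <- generate_replicate(sys, 1)
  zd <- vapply(frames, z_distance, numeric(1), topology = sys$topology)
  bound <- abs(zd) < sys$truth$binding_distance
  expect_equal(mean(bound), (200 - 80) / 200)
  # approach phase respects the detachment distance
  expect_true(all(abs(zd[!bound]) >= 6))
})

test_that("the null generator plants no per-residue structure", {
  vals <- lapply(c(11L, 23L, 37L), function(s) {
    spec <- small_spec(
      n_replicates = 3L, n_frames = 120L,
      truth = planted_truth(hotspot_bias = 1, pip_enrichment_factor = 1,
                            bound_from_frame = 24L, seed = s))
    sys <- synthetic_system(spec)
    mats <- lapply(1:3, function(r)
      residue_group_contacts(generate_replicate(sys, r), sys$topology,
                             replicate_id = r))
    normalize_contacts(aggregate_replicates(mats))$values[, "PIP_head"]
  })
  # no residue is persistently the top contact across independent runs
  argmaxes <- vapply(vals, which.max, integer(1))
  expect_gt(length(unique(argmaxes)), 1L)
  # and the planted-recovery signature (a tight >=0.8 set with everything
  # else below 0.5) is absent: many residues sit in the mid range
  for (v in vals)
    expect_gt(mean(v >= 0.5 & v < 0.8) + mean(v >= 0.8), 0.05)
})

test_that("a written replicate set reads back consistently", {
  spec <- small_spec(n_replicates = 2L, n_frames = 15L)
  dir <- withr::local_tempdir()
  gen <- generate_replicates(synthetic_system(spec), output_dir = dir,
                             keep_frames = TRUE)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "^replicate_.*gro$"), 2L)

  top <- read_topology(file.path(dir, "topology.tsv"), "tsv")
  frames <- read_frames(file.path(dir, "replicate_01.gro"), "gro_multiframe")
  expect_length(frames, 15L)
  expect_equal(nrow(frames[[1]]$coordinates), nrow(top))
  # GRO precision: 0.001 nm
  expect_equal(frames[[3]]$coordinates,
               gen$replicates[[1]][[3]]$coordinates, tolerance = 6e-4,
               ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(truth$hotspot_residues),
               gen$system$truth$hotspot_residues)
})
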