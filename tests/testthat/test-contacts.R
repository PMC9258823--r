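test_that("a single lipid bead is counted inside but not outside the cutoff", {
  top <- cg_topology(rbind(
    data.frame(bead_id = 0:1, bead_name = c("BB", "SC1"),
               entity = "protein", residue_index = 1L,
               residue_name = "LYS", lipid_species = "none",
               bead_class = c("protein_backbone", "protein_sidechain")),
    data.frame(bead_id = 2:3, bead_name = c("HEAD", "PO4"),
               entity = "lipid", residue_index = 1L, residue_name = "POP2",
               lipid_species = "POP2",
               bead_class = c("lipid_headgroup", "lipid_PO4"))))
  groups <- list(PIP_head = lipid_group("PIP_head", c("POP2", "POP3"),
                                        "lipid_headgroup"))
  make <- function(d) cg_frame(rbind(c(5, 5, 5), c(5, 5, 5.3),
                                     c(5 + d, 5, 5), c(9, 9, 9)),
                               c(10, 10, 10))
  inside <- residue_group_contacts(list(make(0.50)), top, groups,
                                   window = 1L)
  expect_equal(unname(inside$counts[1, 1]), 1L)
  outside <- residue_group_contacts(list(make(0.56)), top, groups,
                                    window = 1L)
  expect_equal(unname(outside$counts[1, 1]), 0L)
  # binary per frame: a second bead inside the cutoff adds nothing
  two <- cg_topology(rbind(as.data.frame(top), data.frame(
    bead_id = 4L, bead_name = "HEAD", entity = "lipid", residue_index = 2L,
    residue_name = "POP3", lipid_species = "POP3",
    bead_class = "lipid_headgroup"), data.frame(
    bead_id = 5L, bead_name = "PO4", entity = "lipid", residue_index = 2L,
    residue_name = "POP3", lipid_species = "POP3",
    bead_class = "lipid_PO4")))
  fr <- cg_frame(rbind(c(5, 5, 5), c(5, 5, 5.3), c(5.4, 5, 5), c(9, 9, 9),
                       c(5, 5.4, 5), c(9, 9, 8)), c(10, 10, 10))
  both <- residue_group_contacts(list(fr), two, groups, window = 1L)
  expect_equal(unname(both$counts[1, 1]), 1L)
})

test_that("cell-list contact counts equal the all-pairs brute force", {
  sys <- random_system(n_res = 15, n_lip = 50, n_frames = 6, seed = 7)
  groups <- canonical_lipid_groups()
  for (cutoff in c(0.4, 0.8, 1.5)) {
    got <- suppressWarnings(
      residue_group_contacts(sys$frames, sys$topology, groups,
                             cutoff = cutoff, window = 1:6))
    want <- brute_contact_counts(sys$frames, sys$topology, groups,
                                 cutoff, 1:6)
    expect_identical(unname(got$counts), unname(want),
                     label = paste("cutoff", cutoff))
  }
})

test_that("contact counts are monotone in the cutoff", {
  sys <- random_system(n_res = 10, n_lip = 40, n_frames = 4, seed = 3)
  groups <- canonical_lipid_groups()
  cuts <- c(0.3, 0.55, 0.9, 1.4)
  mats <- lapply(cuts, function(cc) suppressWarnings(
    residue_group_contacts(sys$frames, sys$topology, groups, cutoff = cc,
                           window = 1:4))$counts)
  for (i in seq_along(cuts)[-1])
    expect_true(all(mats[[i]] >= mats[[i - 1]]))
})

test_that("contact matrix bounds and window handling hold", {
  sys <- random_system(n_res = 6, n_lip = 20, n_frames = 10, seed = 11)
  cm <- suppressWarnings(
    residue_group_contacts(sys$frames, sys$topology,
                           window_fraction = 0.2))
  expect_equal(cm$n_frames_analyzed, 2L)   # final 20% of 10 frames
  expect_true(all(cm$counts <= cm$n_frames_analyzed))
  expect_error(residue_group_contacts(sys$frames, sys$topology,
                                      window = integer(0)), "window")
  expect_error(residue_group_contacts(sys$frames, sys$topology,
                                      window = 11L), "window")
  # a group selecting zero beads warns and yields zeros
  g0 <- list(none = lipid_group("none", "POPC", "lipid_PO4"))
  expect_warning(cm0 <- residue_group_contacts(sys$frames, sys$topology,
                                               g0, window = 1:2),
                 "zero beads")
  expect_true(all(cm0$counts == 0L))
})

test_that("normalization divides by the per-group maximum", {
  cm <- structure(list(
    counts = matrix(c(10L, 5L, 0L, 0L, 0L, 0L), 3, 2,
                    dimnames = list(1:3, c("a", "b"))),
    n_frames_analyzed = 10L, window = c(1L, 10L), cutoff = 0.55,
    replicate_id = 1L, residue_index = 1:3,
    residue_name = c("ALA", "LYS", "SER")), class = "contact_matrix")
  nc <- normalize_contacts(cm)
  expect_equal(unname(nc$values[, "a"]), c(1, 0.5, 0))
  expect_equal(unname(nc$values[, "b"]), c(0, 0, 0))
  expect_equal(unname(nc$normalizer), c(10, 0))
  # scale invariance
  cm2 <- cm; cm2$counts <- cm$counts * 7L
  expect_equal(normalize_contacts(cm2)$values, nc$values)
})

test_that("replicate aggregation is a sum equal to concatenated counting", {
  sys <- random_system(n_res = 8, n_lip = 30, n_frames = 8, seed = 5)
  groups <- canonical_lipid_groups()
  m1 <- suppressWarnings(residue_group_contacts(sys$frames, sys$topology,
                                                groups, window = 1:4))
  m2 <- suppressWarnings(residue_group_contacts(sys$frames, sys$topology,
                                                groups, window = 5:8))
  tot <- aggregate_replicates(list(m1, m2))
  whole <- suppressWarnings(residue_group_contacts(sys$frames, sys$topology,
                                                   groups, window = 1:8))
  expect_equal(tot$counts, whole$counts)
  expect_equal(tot$n_frames_analyzed, 8L)
  # commutativity and doubling
  expect_equal(aggregate_replicates(list(m2, m1))$counts, tot$counts)
  expect_equal(aggregate_replicates(list(m1, m1))$counts, m1$counts * 2L)
  # axis mismatch rejected
  other <- suppressWarnings(residue_group_contacts(
    random_system(n_res = 8, n_lip = 30, seed = 6)$frames,
    random_system(n_res = 8, n_lip = 30, seed = 6)$topology,
    groups[1:2], window = 1:2))
  expect_error(aggregate_replicates(list(m1, other)), "mismatch")
})

test_that("convergence profile is exact for identical replicates and seeded", {
  sys <- random_system(n_res = 10, n_lip = 40, n_frames = 4, seed = 9)
  m <- suppressWarnings(residue_group_contacts(sys$frames, sys$topology,
                                               window = 1:4))
  mats <- rep(list(m), 6)
  cp <- convergence_profile(mats, "PIP_head", subset_sizes = 1:3,
                            n_draws = 5, seed = 2)
  expect_true(all(abs(cp$correlation - 1) < 1e-12))
  cp2 <- convergence_profile(mats, "PIP_head", subset_sizes = 1:3,
                             n_draws = 5, seed = 2)
  expect_identical(cp, cp2)
  expect_error(convergence_profile(mats[1], subset_sizes = 1), "replicates")
  expect_error(convergence_profile(mats, subset_sizes = 4), "subset sizes")
})

test_that("contact tables and B-factor PDB render per-residue values", {
  sys <- synthetic_system(small_spec(n_replicates = 1L, n_frames = 40L))
  frames <- generate_replicate(sys, 1)
  cm <- residue_group_contacts(frames, sys$topology)
  nc <- normalize_contacts(cm)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_contact_table(cm, nc, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), nrow(cm$counts) * ncol(cm$counts))
  expect_true(all(tab$normalized >= 0 & tab$normalized <= 1))

  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_bfactor_pdb(frames[[length(frames)]], sys$topology, nc,
                    "PIP_head", pdb)
  lines <- grep("^ATOM", readLines(pdb), value = TRUE)
  expect_equal(length(lines), sum(sys$topology$entity == "protein"))
  b <- as.numeric(substr(lines, 61, 66))
  expect_equal(max(b), 99.99, tolerance = 1e-6)
})
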