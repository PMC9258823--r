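# topology with n PIP molecules (PO4 + head) and one 2-bead protein residue
pip_topology <- function(n_pip) {
  prot <- data.frame(bead_id = 0:1, bead_name = c("BB", "SC1"),
                     entity = "protein", residue_index = 1L,
                     residue_name = "LYS", lipid_species = "none",
                     bead_class = c("protein_backbone", "protein_sidechain"))
  lip <- do.call(rbind, lapply(seq_len(n_pip), function(m)
    data.frame(bead_id = 2L * m:(m) + c(0L, 1L),
               bead_name = c("HEAD", "PO4"), entity = "lipid",
               residue_index = m, residue_name = "POP2",
               lipid_species = "POP2",
               bead_class = c("lipid_headgroup", "lipid_PO4"))))
  lip$bead_id <- 2L + seq_len(nrow(lip)) - 1L
  cg_topology(rbind(prot, lip))
}

test_that("constructed PO4 placements give exact association counts", {
  top <- pip_topology(6)
  coords <- matrix(0, nrow(top), 3)
  coords[1, ] <- c(5, 5, 5); coords[2, ] <- c(5, 5, 5.3)
  po4_rows <- which(top$bead_class == "lipid_PO4")
  head_rows <- which(top$bead_class == "lipid_headgroup")
  coords[head_rows, ] <- matrix(c(8, 8, 8), length(head_rows), 3,
                                byrow = TRUE)
  # exactly 4 PO4 beads at 0.6 nm, the other two >= 2 nm away
  coords[po4_rows[1:4], ] <- matrix(c(5.6, 5, 5), 4, 3, byrow = TRUE)
  coords[po4_rows[5:6], ] <- matrix(c(5, 5, 8), 2, 3, byrow = TRUE)
  f <- cg_frame(coords, c(10, 10, 10))
  ac <- pip_association_count(list(f), top, cutoff = 0.65)
  expect_equal(ac$count, 4L)
  # monotone in cutoff
  wide <- pip_association_count(list(f), top, cutoff = 3.5)
  expect_gte(wide$count, ac$count)
  narrow <- pip_association_count(list(f), top, cutoff = 0.5)
  expect_lte(narrow$count, ac$count)
})

test_that("association counts match a brute-force evaluation", {
  sys <- random_system(n_res = 12, n_lip = 50, n_frames = 8, seed = 21)
  ac <- pip_association_count(sys$frames, sys$topology, cutoff = 0.9)
  po4 <- which(sys$topology$bead_class == "lipid_PO4" &
                 sys$topology$lipid_species %in% c("POP2", "POP3"))
  prot <- which(sys$topology$entity == "protein")
  want <- vapply(sys$frames, function(f) {
    n <- 0L
    for (t in po4) {
      d <- f$coordinates[prot, , drop = FALSE] -
        matrix(f$coordinates[t, ], length(prot), 3, byrow = TRUE)
      b <- matrix(f$box, length(prot), 3, byrow = TRUE)
      d <- d - b * round(d / b)
      if (any(rowSums(d * d) <= 0.9^2)) n <- n + 1L
    }
    n
  }, integer(1))
  expect_identical(ac$count, want)
})

test_that("unbound approach frames have zero association", {
  spec <- small_spec(n_replicates = 1L, n_frames = 60L,
                     truth = planted_truth(bound_from_frame = 40L, seed = 2))
  sys <- synthetic_system(spec)
  frames <- generate_replicate(sys, 1)
  ac <- pip_association_count(frames, sys$topology)
  expect_true(all(ac$count[1:40] == 0L))
  expect_gt(mean(ac$count[41:60]), 0)
})

test_that("association series aggregates replicates on a shared grid", {
  s1 <- data.frame(frame = 1:4, time = c(0, 10, 20, 30),
                   count = c(0L, 1L, 2L, 3L))
  s2 <- data.frame(frame = 1:4, time = c(0, 10, 20, 30),
                   count = c(2L, 1L, 0L, 5L))
  as <- association_series(list(s1, s2))
  expect_equal(as$mean, c(1, 1, 1, 4))
  expect_equal(as$sd, apply(cbind(s1$count, s2$count), 1, sd))
  bad <- s2; bad$time <- bad$time + 5
  expect_error(association_series(list(s1, bad)), "time grid")
  # missing PO4 beads are a validation error
  top <- tiny_topology()
  f <- cg_frame(matrix(1, 3, 3), c(5, 5, 5))
  expect_error(pip_association_count(list(f), top), "PO4")
})

test_that("uniformly placed lipids give a flat lateral RDF", {
  spec <- small_spec(
    n_replicates = 1L, n_frames = 120L,
    bilayer_dimensions = c(14, 14), box_height = 16,
    truth = planted_truth(hotspot_bias = 1, pip_enrichment_factor = 1,
                          bound_from_frame = 20L, seed = 19))
  sys <- synthetic_system(spec)
  frames <- generate_replicate(sys, 1)
  rdf <- lipid_rdf(frames, sys$topology, "POPE", r_max = 6.5, dr = 0.5,
                   window = 21:120)
  expect_gte(attr(rdf, "n_observations"), 5000)
  mid <- rdf$g[rdf$r >= 2 & rdf$r <= 6]
  expect_lt(mean(abs(mid - 1)), 0.08)
  expect_true(all(rdf$g >= 0))
})

test_that("RDF normalization recovers the observed molecule count", {
  spec <- small_spec(n_replicates = 1L, n_frames = 60L,
                     truth = planted_truth(hotspot_bias = 1,
                                           pip_enrichment_factor = 1,
                                           bound_from_frame = 10L,
                                           seed = 23))
  sys <- synthetic_system(spec)
  frames <- generate_replicate(sys, 1)
  rdf <- lipid_rdf(frames, sys$topology, "POPE", r_max = 3.5, dr = 0.25,
                   window = 11:60)
  rho <- attr(rdf, "rho")
  lo <- rdf$r - 0.125; hi <- rdf$r + 0.125
  integral <- sum(rdf$g * rho * pi * (hi^2 - lo^2))
  mean_inside <- attr(rdf, "n_observations") / attr(rdf, "n_frames_used")
  expect_equal(integral, mean_inside, tolerance = 1e-9)
})

test_that("planted PIP enrichment appears in the short-range RDF", {
  spec <- small_spec(
    n_replicates = 1L, n_frames = 150L,
    bilayer_dimensions = c(12, 12), box_height = 16,
    truth = planted_truth(hotspot_bias = 1, pip_enrichment_factor = 3,
                          pip_enrichment_radius = 1.5,
                          bound_from_frame = 30L, seed = 29))
  sys <- synthetic_system(spec)
  frames <- generate_replicate(sys, 1)
  g_pip <- lipid_rdf(frames, sys$topology, "POP2", r_max = 5, dr = 0.5,
                     window = 31:150)
  g_pc <- lipid_rdf(frames, sys$topology, "POPC", r_max = 5, dr = 0.5,
                    window = 31:150)
  short_pip <- mean(g_pip$g[g_pip$r < 1.5])
  short_pc <- mean(g_pc$g[g_pc$r < 1.5])
  expect_gt(short_pip, 1)
  expect_gt(short_pip, short_pc)
})

test_that("RDF input validation names the binding criterion", {
  sys <- synthetic_system(small_spec(n_replicates = 1L, n_frames = 30L,
                                     truth = planted_truth(
                                       bound_from_frame = 29L, seed = 3)))
  frames <- generate_replicate(sys, 1)
  # window entirely in the approach phase: no bound frames
  expect_error(lipid_rdf(frames, sys$topology, "POPE", r_max = 3.5,
                         window = 1:20),
               "binding criterion")
  comp <- membrane_composition(POPC = 0.2, POPE = 0.5, POPS = 0.15,
                               POP2 = 0.07, POP3 = 0.03, CHOL = 0.05)
  spec2 <- small_spec(n_replicates = 1L, n_frames = 20L,
                      composition = comp,
                      truth = planted_truth(bound_from_frame = 5L, seed = 4))
  sys2 <- synthetic_system(spec2)
  expect_error(lipid_rdf(generate_replicate(sys2, 1), sys$topology,
                         "PIPX"), "unknown species")
})
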