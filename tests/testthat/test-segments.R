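# hand-build a STRIDE record with a given state string
stride_df <- function(states) {
  data.frame(residue_index = seq_along(states),
             residue_name = "ALA", chain = "A",
             pdb_number = seq_along(states), state = states)
}

test_that("strand runs map to the canonical 14-segment partition", {
  states <- c("C", "C",                 # N-terminal coil -> beta1
              rep("E", 4),              # beta1
              "C", "C",                 # beta1-beta2
              rep("E", 4),              # beta2
              "T",                      # beta2-beta3
              rep("E", 3),              # beta3
              "C", "H", "H", "C",       # short helix inside beta3-beta4 gap
              rep("E", 3),              # beta4
              "C",
              rep("E", 3),              # beta5
              "C",
              rep("E", 3),              # beta6
              "C",
              rep("E", 3),              # beta7
              "C", rep("H", 4), "C")    # alpha-C (helix + C-terminal coil)
  a <- assign_segments(stride_df(states))
  lab <- as.character(a)
  expect_equal(lab[1:6], rep("beta1", 6))
  expect_equal(lab[7:8], rep("beta1-beta2", 2))
  expect_equal(lab[13], "beta2-beta3")
  # the short helix inserted between beta3 and beta4 joins the loop
  expect_equal(lab[17:20], rep("beta3-beta4", 4))
  expect_equal(tail(lab, 6), rep("alpha-C", 6))
  # partition is exhaustive and in canonical order
  expect_false(anyNA(lab))
  expect_true(!is.unsorted(match(unique(lab),
                                 c("beta1", "beta1-beta2", "beta2",
                                   "beta2-beta3", "beta3", "beta3-beta4",
                                   "beta4", "beta4-beta5", "beta5",
                                   "beta5-beta6", "beta6", "beta6-beta7",
                                   "beta7", "alpha-C"))))
})

test_that("undetectable strand patterns error and overrides are audited", {
  few <- stride_df(c("C", "E", "E", "C", rep("C", 10)))
  expect_error(assign_segments(few), "strand runs")

  states <- c(rep(c("E", "E", "C"), 7), "H", "H")
  a <- assign_segments(stride_df(states))
  ov <- assign_segments(stride_df(states),
                        overrides = list(list(residues = 6L,
                                              segment = "beta5")))
  expect_equal(as.character(ov)[6], "beta5")
  expect_match(attr(ov, "audit"), "beta5")
  expect_error(assign_segments(stride_df(states),
                               overrides = list(list(residues = 6L,
                                                     segment = "beta9"))),
               "unknown segment")
})

test_that("segment frequencies are uniform for uniform counts and linear", {
  p <- build_toy_protein(56, seed = 4)
  assign <- structure(setNames(p$segments, seq_along(p$segments)),
                      class = "segment_assignment")
  cm <- structure(list(
    counts = matrix(5L, 56, 1, dimnames = list(1:56, "PIP_head")),
    n_frames_analyzed = 10L, window = c(1L, 10L), cutoff = 0.55,
    replicate_id = 1L, residue_index = 1:56, residue_name = p$sequence),
    class = "contact_matrix")
  f <- segment_contact_frequency(cm, assign)
  expect_true(all(f$frequency == 5))
  cm2 <- cm; cm2$counts <- cm$counts * 2L
  f2 <- segment_contact_frequency(cm2, assign)
  expect_equal(f2$frequency, f$frequency * 2)
})

test_that("amino-acid frequencies divide by occurrences, absent types are NA", {
  cm <- structure(list(
    counts = matrix(c(5L, 4L, 0L), 3, 1,
                    dimnames = list(1:3, "PIP_head")),
    n_frames_analyzed = 10L, window = c(1L, 10L), cutoff = 0.55,
    replicate_id = 1L, residue_index = 1:3,
    residue_name = c("TRP", "LYS", "LYS")), class = "contact_matrix")
  f <- aminoacid_contact_frequency(cm)
  expect_equal(f$frequency[f$residue_name == "TRP"], 5)
  expect_equal(f$frequency[f$residue_name == "LYS"], 2)
  expect_true(is.na(f$frequency[f$residue_name == "ALA"]))
  bad <- cm; bad$residue_name <- c("XXX", "LYS", "LYS")
  expect_error(aminoacid_contact_frequency(bad), "unknown residue")
})

test_that("threshold table marks the argmax segment and is antitone", {
  p <- build_toy_protein(56, seed = 8)
  assign <- structure(setNames(p$segments, seq_along(p$segments)),
                      class = "segment_assignment")
  set.seed(31)
  vals <- runif(56, 0, 0.7)
  vals[which(p$segments == "beta1-beta2")[1]] <- 1.0   # primary site
  nc <- structure(list(
    values = matrix(vals, 56, 1, dimnames = list(1:56, "PIP_head")),
    normalizer = c(PIP_head = 100), residue_index = 1:56,
    residue_name = p$sequence), class = "normalized_contacts")
  tab <- threshold_table(nc, assign)
  expect_true(tab[1, "beta1-beta2"])
  s <- attr(tab, "summary")
  expect_equal(s$primary_beta12_fraction, 1)

  # threshold exactly 1: only max-tied residues qualify
  tab1 <- threshold_table(nc, assign, threshold = 1.0)
  expect_equal(sum(tab1), 1L)
  expect_error(threshold_table(nc, assign, threshold = 1.0 + 1e-9),
               "threshold")
  # antitone: raising the threshold never flips FALSE -> TRUE
  for (th in c(0.5, 0.8, 0.9)) {
    lo <- threshold_table(nc, assign, threshold = th)
    hi <- threshold_table(nc, assign, threshold = th + 0.05)
    expect_true(all(lo | !hi))
  }

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_threshold_table(tab, tsv)
  back <- read.delim(tsv, check.names = FALSE)
  expect_equal(ncol(back), 15L)
  expect_equal(sum(unlist(back[-1])), sum(tab))
})
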