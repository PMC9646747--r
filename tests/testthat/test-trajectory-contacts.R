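make_fixed_traj <- function(frames_list, meta = NULL) {
  n <- nrow(frames_list[[1]])
  coords <- array(NA_real_, c(length(frames_list), n, 3))
  for (f in seq_along(frames_list)) coords[f, , ] <- frames_list[[f]]
  if (is.null(meta)) {
    meta <- data.frame(name = "CA", resid = seq_len(n), resname = "BEA",
                       chain = "A", is_ligand = FALSE, heavy = TRUE,
                       stringsAsFactors = FALSE)
  }
  trajectory_ensemble(coords, meta)
}

test_that("multi-model PDB parsing is strict about frame structure", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "MODEL        2",
    "ENDMDL"), f)
  expect_error(read_ensemble(f), "line 3")

  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       1.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       0.100   0.000   0.000  1.00  0.00           C",
    "ENDMDL"), f)
  expect_error(read_ensemble(f), "frame 2")

  writeLines("REMARK nothing here", f)
  expect_error(read_ensemble(f), "no frames")
})

test_that("a 2-model 5-atom PDB reads as 2 frames x 5 nodes", {
  bm <- make_bead_model(5, "chain")
  tr <- sample_trajectory(bm, 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(tr, f)
  back <- read_ensemble(f)
  expect_equal(dim(back$coords), c(2, 5, 3))
  expect_equal(nrow(node_table(back)), 5)
})

test_that("pdb writer/reader agree with bio3d on coordinates", {
  skip_if_not_installed("bio3d")
  bm <- make_bead_model(6, "ring")
  tr <- sample_trajectory(bm, 3, seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(tr, f)
  ref <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  ours <- read_ensemble(f)
  for (fr in 1:3) {
    expect_equal(matrix(ref$xyz[fr, ], ncol = 3, byrow = TRUE),
                 ours$coords[fr, , ], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("superposition removes rigid-body contamination exactly", {
  bm <- make_bead_model(10, "ring")
  clean <- sample_trajectory(bm, 300, amplitude = 0.4, seed = 3)
  dirty <- sample_trajectory(bm, 300, amplitude = 0.4, rigid_body = TRUE,
                             seed = 3)
  v_clean <- colMeans(fluctuation_series(node_positions(superpose(clean)))^2)
  v_dirty <- colMeans(fluctuation_series(node_positions(superpose(dirty)))^2)
  expect_true(all(abs(v_dirty / v_clean - 1) < 0.10))
})

test_that("superposition is idempotent and kills pure translations", {
  bm <- make_bead_model(8, "ring")
  tr <- sample_trajectory(bm, 50, amplitude = 0.3, rigid_body = TRUE,
                          seed = 6)
  s1 <- superpose(tr)
  s2 <- superpose(s1)
  expect_equal(s1$coords, s2$coords, tolerance = 1e-10)

  base <- bm$positions
  shifted <- lapply(1:5, function(i) base + matrix(i, nrow(base), 3))
  tr2 <- make_fixed_traj(shifted)
  fitted <- superpose(tr2, reference = 1)
  expect_lt(max(fluctuation_series(node_positions(fitted))), 1e-8)
})

test_that("collinear frames are rejected as degenerate", {
  line <- cbind(1:4, 0, 0)
  tr <- make_fixed_traj(list(line, line + 0.5))
  expect_error(superpose(tr), "degenerate|collinear")
})

test_that("contact occupancy follows the strict >75% rule", {
  # beads 1-2 fixed at 4.9 A: always a contact
  near <- cbind(c(0, 4.9), 0, 0)
  tr <- make_fixed_traj(rep(list(near), 10))
  cm <- contact_map(tr)
  expect_true(cm$mask[1, 2])

  # 7 of 10 frames below 5 A: occupancy 0.70 <= 0.75, no edge
  frames <- c(rep(list(cbind(c(0, 4.0), 0, 0)), 7),
              rep(list(cbind(c(0, 6.0), 0, 0)), 3))
  cm2 <- contact_map(make_fixed_traj(frames))
  expect_equal(cm2$occupancy[1, 2], 0.7)
  expect_false(cm2$mask[1, 2])

  # exactly 75% also fails the strict rule
  frames3 <- c(rep(list(cbind(c(0, 4.0), 0, 0)), 3),
               list(cbind(c(0, 6.0), 0, 0)))
  expect_false(contact_map(make_fixed_traj(frames3))$mask[1, 2])
  expect_error(contact_map(tr, cutoff = -1), "cutoff")
})

test_that("contact maps are symmetric, hollow, and monotone in cutoff", {
  bm <- make_bead_model(10, "two_branch")
  tr <- sample_trajectory(bm, 200, amplitude = 0.6, seed = 11)
  cm5 <- contact_map(tr, cutoff = 5)
  cm8 <- contact_map(tr, cutoff = 8)
  cm5_low <- contact_map(tr, cutoff = 5, occupancy = 0.5)
  expect_equal(cm5$mask, t(cm5$mask))
  expect_true(all(!diag(cm5$mask)))
  expect_true(all(cm8$mask[cm5$mask]))       # larger cutoff keeps edges
  expect_true(all(cm5_low$mask[cm5$mask]))   # lower occupancy keeps edges
})

test_that("ligand contact probability averages copies then replicas", {
  # 1 residue bead + 4 ligand copies; residue within 6 A of exactly one
  # copy in every frame
  pos <- rbind(c(0, 0, 0),      # residue
               c(3, 0, 0),      # ligand copy 1 (contact)
               c(20, 0, 0), c(40, 0, 0), c(60, 0, 0))
  meta <- data.frame(name = c("CA", "L1", "L1", "L1", "L1"),
                     resid = 1:5,
                     resname = c("BEA", rep("LIG", 4)),
                     chain = c("A", "W", "X", "Y", "Z"),
                     is_ligand = c(FALSE, rep(TRUE, 4)),
                     heavy = TRUE, stringsAsFactors = FALSE)
  tr <- make_fixed_traj(rep(list(pos), 5), meta)
  prof <- ligand_contact_probability(tr)
  expect_equal(prof$probability, 0.25)

  # replica where the residue contacts no copy: mean over replicas
  pos2 <- pos; pos2[1, 1] <- -10
  tr2 <- make_fixed_traj(rep(list(pos2), 5), meta)
  prof2 <- ligand_contact_probability(tr, replicas = list(tr2))
  expect_equal(prof2$probability, 0.125)

  # all four copies in contact -> probability 1
  pos3 <- pos; pos3[3:5, 1] <- c(4, 5, 5.5)
  prof3 <- ligand_contact_probability(make_fixed_traj(rep(list(pos3), 5),
                                                      meta))
  expect_equal(prof3$probability, 1)

  no_lig <- make_fixed_traj(rep(list(pos), 5))
  expect_error(ligand_contact_probability(no_lig), "no ligand")
})
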