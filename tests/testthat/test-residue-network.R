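test_that("node positions honor the representative-atom convention", {
  # 2-atom residue in centroid mode -> midpoint
  meta <- data.frame(name = c("CB", "CG"), resid = 1, resname = "XXX",
                     chain = "A", is_ligand = FALSE, heavy = TRUE,
                     stringsAsFactors = FALSE)
  coords <- array(0, c(2, 2, 3))
  coords[, 2, 1] <- 2
  tr <- trajectory_ensemble(coords, meta)
  pos <- node_positions(tr, "centroid")
  expect_equal(pos[1, 1, ], c(1, 0, 0))
  expect_error(node_positions(tr, "c_alpha"), "CA")

  # bead models pass through unchanged
  bm <- make_bead_model(4, "chain")
  tb <- sample_trajectory(bm, 10, seed = 1)
  expect_equal(node_positions(tb)[3, , ], tb$coords[3, , ],
               ignore_attr = TRUE)
})

test_that("correlation matrix is a normalized correlation", {
  bm <- make_bead_model(5, "ring")
  tr <- sample_trajectory(bm, 500, seed = 4)
  pos <- node_positions(tr)
  # duplicated node has correlation exactly 1
  pos2 <- array(NA_real_, c(dim(pos)[1], 6, 3))
  pos2[, 1:5, ] <- pos
  pos2[, 6, ] <- pos[, 1, ]
  C <- correlation_matrix(pos2)
  expect_equal(C[1, 6], 1)
  expect_equal(diag(C), rep(1, 6))
  expect_true(all(abs(C) <= 1 + 1e-12))
  expect_equal(C, t(C))

  # zero-variance node is rejected by name
  pos3 <- pos
  pos3[, 2, ] <- 5
  expect_error(correlation_matrix(pos3), "zero-variance")
})

test_that("independent nodes decorrelate at large frame counts", {
  set.seed(77)
  pos <- array(rnorm(5000 * 4 * 3), c(5000, 4, 3))
  C <- correlation_matrix(pos)
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
})

test_that("GMM entropy matches closed-form Gaussian entropy and scaling", {
  set.seed(101)
  x <- rnorm(2e4)
  h <- as.numeric(entropy_gmm(x))
  expect_lt(abs(h - 0.5 * log(2 * pi * exp(1))), 0.05)
  # change of variables: scaling by a shifts entropy by log|a|
  h3 <- as.numeric(entropy_gmm(3 * x))
  expect_lt(abs((h3 - h) - log(3)), 0.05)
  expect_error(entropy_gmm(rep(1, 100)), "degenerate")
  expect_error(entropy_gmm(rnorm(10)), "50")
})

test_that("GMM entropy handles non-Gaussian mixtures", {
  set.seed(55)
  x <- c(rnorm(8000, -4, 0.5), rnorm(8000, 4, 0.5))
  h <- entropy_gmm(x, max_components = 5)
  expect_gte(attr(h, "G"), 2)
  # oracle: entropy of a well-separated symmetric 2-component mixture is
  # the component entropy plus one bit
  h_true <- 0.5 * log(2 * pi * exp(1) * 0.25) + log(2)
  expect_lt(abs(as.numeric(h) - h_true), 0.05)
})

test_that("mutual information separates dependence from independence", {
  set.seed(9)
  fl <- cbind(abs(rnorm(800)), abs(rnorm(800)))
  colnames(fl) <- c("a", "b")
  M <- mutual_information_matrix(fl, max_components = 3)
  expect_lt(M[1, 2], 0.05)                 # independent ~ 0 after clamp

  fl2 <- cbind(fl[, 1], fl[, 1])           # perfectly dependent
  M2 <- mutual_information_matrix(fl2, max_components = 3)
  expect_gt(M2[1, 2], 1)

  expect_equal(M, t(M))
  expect_true(all(M >= 0))
})

test_that("MI ranking on a GNM fixture follows the analytic correlation", {
  bm <- make_bead_model(6, "chain")
  Ca <- analytic_gnm_correlation(bm)
  tr <- sample_trajectory(bm, 4000, seed = 31)
  fl <- fluctuation_series(node_positions(tr))
  M <- mutual_information_matrix(fl, max_components = 3)
  off <- which(upper.tri(Ca), arr.ind = TRUE)
  hi <- off[which.max(abs(Ca[off])), ]
  lo <- off[which.min(abs(Ca[off])), ]
  expect_gt(M[hi[1], hi[2]], M[lo[1], lo[2]])
})

test_that("path network weights are -log|C| on contact edges only", {
  C <- matrix(c(1, 0.5, 0.9,
                0.5, 1, 0,
                0.9, 0, 1), 3, 3)
  mask <- matrix(FALSE, 3, 3)
  mask[1, 2] <- mask[2, 1] <- TRUE
  mask[2, 3] <- mask[3, 2] <- TRUE
  pn <- build_path_network(C, mask)
  expect_equal(pn$weights[1, 2], log(2))       # |C| = 0.5
  expect_equal(pn$weights[2, 3], Inf)          # contact but C = 0
  expect_equal(pn$weights[1, 3], Inf)          # high C but no contact
  # |C| = 1 -> zero-length edge
  C2 <- C; C2[1, 2] <- C2[2, 1] <- 1
  expect_equal(build_path_network(C2, mask)$weights[1, 2], 0)
})

test_that("flow network is the contact-masked mutual information", {
  M <- matrix(c(0, 0.3, 0.8,
                0.3, 0, 0.2,
                0.8, 0.2, 0), 3, 3)
  mask <- matrix(FALSE, 3, 3)
  mask[1, 2] <- mask[2, 1] <- TRUE
  A <- build_flow_network(M, mask)
  expect_equal(A[1, 2], 0.3)   # contact with M = m -> m
  expect_equal(A[1, 3], 0)     # no contact -> 0 regardless of M
  expect_equal(A[2, 3], 0)
  mask2 <- mask; mask2[2, 3] <- mask2[3, 2] <- TRUE
  M2 <- M; M2[2, 3] <- M2[3, 2] <- 0
  expect_equal(build_flow_network(M2, mask2)[2, 3], 0)  # contact, M = 0
})

test_that("edge tables round-trip the network to CSV", {
  bm <- make_bead_model(10, "two_branch")
  tr <- sample_trajectory(bm, 150, amplitude = 0.5, seed = 2)
  cm <- contact_map(tr)
  C <- correlation_matrix(node_positions(tr))
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- network_edge_table(cm, C, path = f)
  back <- read.csv(f)
  expect_equal(nrow(back), sum(cm$mask) / 2)
  expect_equal(back$w, -log(abs(back$C)))
})
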