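#' Elastic bead models with analytically known fluctuation covariance
#'
#' A bead model is a Gaussian network model (GNM): beads connected by
#' harmonic springs, summarised by the Kirchhoff (connectivity) matrix
#' \eqn{\Gamma}, with \eqn{\Gamma_{ij} = -k_{ij}} for a spring between
#' beads i and j and \eqn{\Gamma_{ii} = \sum_j k_{ij}}. The equilibrium
#' fluctuation covariance of such a network is proportional to the
#' Moore-Penrose pseudoinverse \eqn{\Gamma^+}, which gives every sampled
#' trajectory an analytic ground truth for correlation and
#' mutual-information estimators downstream.
#'
#' Three topologies are provided. `"chain"` and `"ring"` are the usual
#' linear and cyclic networks. `"two_branch"` connects a source bead to a
#' sink bead through two disjoint chains of beads, emulating the two-branch
#' architecture of sensor-to-pore coupling in a channel (one covalent
#' linker branch, one domain-interface branch); per-branch spring
#' constants let one branch dominate both correlation and flow.
#'
#' @param n_beads integer, number of beads (>= 3).
#' @param topology one of `"chain"`, `"ring"`, `"two_branch"`.
#' @param k spring constant applied to every spring (energy/length^2 in
#'   arbitrary units; only ratios matter for correlations).
#' @param branch_lengths integer length-2, number of interior beads on
#'   each branch for `"two_branch"`. Defaults to an even split of
#'   `n_beads - 2`. Must satisfy `sum(branch_lengths) + 2 == n_beads`.
#' @param branch_k numeric length-2, per-branch spring constants for
#'   `"two_branch"` (overrides `k` on branch springs).
#' @param spacing bead spacing in Angstrom for the equilibrium layout.
#' @return an object of class `bead_model`: list with `positions`
#'   (n x 3 matrix, Angstrom), `springs` (data.frame i, j, k),
#'   `kirchhoff` (n x n), `labels` (data.frame node, resid, subunit).
#' @examples
#' bm <- make_bead_model(3, "chain")
#' bm$kirchhoff
#' @export
make_bead_model <- function(n_beads, topology = c("chain", "ring", "two_branch"),
                            k = 1, branch_lengths = NULL, branch_k = NULL,
                            spacing = 3.8) {
  topology <- match.arg(topology)
  n_beads <- as.integer(n_beads)
  if (n_beads < 3) stop("n_beads must be >= 3")
  if (any(k <= 0)) stop("spring constant must be positive")

  if (topology == "chain") {
    springs <- data.frame(i = seq_len(n_beads - 1), j = 2:n_beads, k = k)
    positions <- cbind(spacing * (seq_len(n_beads) - 1), 0, 0)
    subunit <- rep("A", n_beads)
  } else if (topology == "ring") {
    springs <- data.frame(i = seq_len(n_beads),
                          j = c(2:n_beads, 1L), k = k)
    ang <- 2 * pi * (seq_len(n_beads) - 1) / n_beads
    r <- spacing / (2 * sin(pi / n_beads))
    positions <- cbind(r * cos(ang), r * sin(ang), 0)
    subunit <- rep("A", n_beads)
  } else {
    if (is.null(branch_lengths)) {
      b1 <- (n_beads - 2L) %/% 2L
      branch_lengths <- c(b1, n_beads - 2L - b1)
    }
    branch_lengths <- as.integer(branch_lengths)
    if (length(branch_lengths) != 2L || any(branch_lengths < 1L))
      stop("branch_lengths must be two positive integers")
    if (sum(branch_lengths) + 2L != n_beads)
      stop("sum(branch_lengths) + 2 must equal n_beads")
    if (is.null(branch_k)) branch_k <- c(k, k)
    if (any(branch_k <= 0)) stop("spring constant must be positive")
    src <- 1L
    snk <- n_beads
    a <- seq.int(2L, 1L + branch_lengths[1])          # branch A interior
    b <- seq.int(2L + branch_lengths[1], n_beads - 1L) # branch B interior
    chain_springs <- function(nodes, kk) {
      seqn <- c(src, nodes, snk)
      data.frame(i = seqn[-length(seqn)], j = seqn[-1], k = kk)
    }
    springs <- rbind(chain_springs(a, branch_k[1]), chain_springs(b, branch_k[2]))
    # layout on a circle: source at angle 0, sink at pi, one branch per
    # semicircle, so spring-connected beads sit at ~bond distance while
    # cross-branch beads stay well outside a contact cutoff
    positions <- matrix(0, n_beads, 3)
    arc <- function(nodes, sgn) {
      m <- length(nodes)
      R <- spacing / (2 * sin(pi / (2 * (m + 1))))
      ang <- sgn * pi * seq_len(m) / (m + 1)
      list(R = R, xy = cbind(R * cos(ang), R * sin(ang)))
    }
    arc_a <- arc(a, +1)
    arc_b <- arc(b, -1)
    R0 <- max(arc_a$R, arc_b$R)
    positions[src, ] <- c(R0, 0, 0)
    positions[snk, ] <- c(-R0, 0, 0)
    scale_to <- function(xy, R) xy * R0 / R
    positions[a, 1:2] <- scale_to(arc_a$xy, arc_a$R)
    positions[b, 1:2] <- scale_to(arc_b$xy, arc_b$R)
    subunit <- rep("A", n_beads)
    subunit[a] <- "B1"
    subunit[b] <- "B2"
  }

  kirchhoff <- matrix(0, n_beads, n_beads)
  for (s in seq_len(nrow(springs))) {
    i <- springs$i[s]; j <- springs$j[s]; kk <- springs$k[s]
    kirchhoff[i, j] <- kirchhoff[i, j] - kk
    kirchhoff[j, i] <- kirchhoff[j, i] - kk
  }
  diag(kirchhoff) <- -rowSums(kirchhoff)

  if (!.graph_connected(kirchhoff != 0)) stop("disconnected model")

  structure(list(
    positions = positions,
    springs = springs,
    kirchhoff = kirchhoff,
    labels = data.frame(node = seq_len(n_beads),
                        resid = seq_len(n_beads),
                        subunit = subunit,
                        stringsAsFactors = FALSE),
    topology = topology
  ), class = "bead_model")
}

#' Analytic fluctuation covariance of a bead model
#'
#' Pseudoinverse of the Kirchhoff matrix (the zero mode, a uniform
#' translation, is projected out), scaled by `amplitude^2`. This is the
#' exact node-node covariance of each Cartesian coordinate of
#' [sample_trajectory()] displacements.
#'
#' @param model a `bead_model`.
#' @param amplitude fluctuation scale (Angstrom).
#' @return n x n covariance matrix.
#' @export
bead_covariance <- function(model, amplitude = 1) {
  stopifnot(inherits(model, "bead_model"))
  amplitude^2 * .pseudoinverse(model$kirchhoff)
}

## pseudoinverse via eigendecomposition, dropping (near-)zero modes
.pseudoinverse <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

.graph_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Sample a correlated-fluctuation trajectory from a bead model
#'
#' Draws per-frame displacements from a zero-mean multivariate Gaussian
#' whose node-node covariance is `amplitude^2` times the Kirchhoff
#' pseudoinverse, applied independently and identically to the x, y and z
#' coordinates (isotropic fluctuations). With `rigid_body = TRUE` each
#' frame additionally receives a random global rotation and translation,
#' which downstream superposition must remove. The internal displacement
#' draws are identical for a given `seed` regardless of `rigid_body`, so
#' paired ensembles share their internal dynamics.
#'
#' @param model a `bead_model`.
#' @param n_frames number of frames (>= 10).
#' @param amplitude fluctuation amplitude (Angstrom); must be > 0.
#' @param rigid_body add a random global rotation + translation per frame?
#' @param frame_interval nominal time between frames (ps).
#' @param seed integer RNG seed; identical seeds give identical ensembles.
#' @return a [trajectory_ensemble()].
#' @export
sample_trajectory <- function(model, n_frames, amplitude = 1,
                              rigid_body = FALSE, frame_interval = 50,
                              seed = 1) {
  stopifnot(inherits(model, "bead_model"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (amplitude <= 0) stop("amplitude must be positive")
  n <- nrow(model$positions)

  e <- eigen(model$kirchhoff, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values)
  # columns scaled so B %*% z has covariance amplitude^2 * pinv(kirchhoff)
  B <- e$vectors[, keep, drop = FALSE] %*%
    diag(amplitude / sqrt(e$values[keep]), sum(keep))

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  coords <- array(0, dim = c(n_frames, n, 3))
  for (f in seq_len(n_frames)) {
    z <- matrix(stats::rnorm(ncol(B) * 3), ncol(B), 3)
    coords[f, , ] <- model$positions + B %*% z
  }
  if (rigid_body) {
    for (f in seq_len(n_frames)) {
      R <- .random_rotation()
      tr <- stats::runif(3, -10, 10)
      coords[f, , ] <- coords[f, , ] %*% t(R) +
        matrix(tr, n, 3, byrow = TRUE)
    }
  }

  meta <- data.frame(
    name = "CA",
    resid = model$labels$resid,
    resname = "BEA",
    chain = substr(model$labels$subunit, 1, 1),
    is_ligand = FALSE,
    heavy = TRUE,
    stringsAsFactors = FALSE
  )
  trajectory_ensemble(coords, meta, frame_interval = frame_interval)
}

## uniform random rotation via QR of a Gaussian matrix
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  R <- R %*% diag(sign(d))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
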