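#' Per-frame node coordinates of an ensemble
#'
#' Reduces an atom-level ensemble to one 3-vector per network node per
#' frame. Protein-like nodes use either their C-alpha atom or the
#' centroid of their heavy atoms; ligand nodes always use the heavy-atom
#' centroid. Bead-model ensembles (one atom per node) pass through
#' unchanged under either convention.
#'
#' @param traj a superposed [trajectory_ensemble()].
#' @param node_def `"c_alpha"` or `"centroid"`.
#' @return array frames x nodes x 3 with node ids in `dimnames[[2]]`.
#' @export
node_positions <- function(traj, node_def = c("centroid", "c_alpha")) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  node_def <- match.arg(node_def)
  nt <- node_table(traj)
  pick <- lapply(seq_len(nrow(nt)), function(i) {
    a <- nt$atoms[[i]]
    if (nt$is_ligand[i] || node_def == "centroid") {
      h <- a[traj$meta$heavy[a]]
      if (!length(h)) h <- a
      h
    } else {
      ca <- a[traj$meta$name[a] == "CA"]
      if (!length(ca))
        stop("residue ", nt$node[i], " has no CA atom for c_alpha nodes")
      ca[1]
    }
  })
  nf <- n_frames(traj)
  out <- array(NA_real_, c(nf, nrow(nt), 3),
               dimnames = list(NULL, nt$node, NULL))
  for (f in seq_len(nf)) {
    xyz <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    out[f, , ] <- t(vapply(pick, function(a)
      colMeans(xyz[a, , drop = FALSE]), numeric(3)))
  }
  out
}

#' Normalized dynamic cross-correlation matrix
#'
#' \eqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#' \sqrt{\langle |\Delta r_i|^2 \rangle \langle |\Delta r_j|^2 \rangle}}
#' with \eqn{\Delta r} the deviation of each node from its time-mean
#' position. Normalization bounds \eqn{|C_{ij}| \le 1} so that the path
#' weight \eqn{-\log|C_{ij}|} is always non-negative.
#'
#' @param pos node position array from [node_positions()] (frames x
#'   nodes x 3).
#' @return n x n correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(pos) {
  stopifnot(length(dim(pos)) == 3, dim(pos)[3] == 3)
  if (dim(pos)[1] < 10) stop("need >= 10 frames for correlations")
  mu <- apply(pos, c(2, 3), mean)
  cross <- matrix(0, dim(pos)[2], dim(pos)[2])
  for (k in 1:3) {
    d <- sweep(pos[, , k, drop = TRUE], 2, mu[, k])
    cross <- cross + crossprod(d)
  }
  v <- diag(cross)
  zero <- which(v <= 0 | v < 1e-12 * max(v))
  if (length(zero)) {
    nm <- dimnames(pos)[[2]]
    stop("zero-variance node(s): ",
         paste(if (is.null(nm)) zero else nm[zero], collapse = ", "))
  }
  C <- cross / sqrt(outer(v, v))
  dimnames(C) <- list(dimnames(pos)[[2]], dimnames(pos)[[2]])
  C
}

#' Distance-to-equilibrium fluctuation series
#'
#' The scalar fluctuation variable used for mutual information: for each
#' node and frame, the Euclidean distance of the node from its time-mean
#' (equilibrium) position.
#'
#' @param pos node position array (frames x nodes x 3).
#' @return frames x nodes matrix of non-negative distances (Angstrom).
#' @export
fluctuation_series <- function(pos) {
  stopifnot(length(dim(pos)) == 3, dim(pos)[3] == 3)
  mu <- apply(pos, c(2, 3), mean)
  d2 <- 0
  for (k in 1:3) {
    d2 <- d2 + sweep(pos[, , k, drop = TRUE], 2, mu[, k])^2
  }
  out <- sqrt(d2)
  colnames(out) <- dimnames(pos)[[2]]
  out
}

#' Gaussian-mixture plug-in differential entropy
#'
#' Fits a Gaussian mixture density to 1-D or 2-D samples, selecting the
#' number of components by BIC over `1:max_components`, and returns the
#' plug-in entropy estimate: the sample average of \eqn{-\ln \hat\rho(x)}
#' over the input points themselves (nats). Mixture fitting is
#' deterministic: EM is initialised from model-based hierarchical
#' clustering on an evenly spaced subset of at most 1000 points, so no
#' random seed is consumed.
#'
#' @param samples numeric vector (1-D) or two-column matrix (2-D),
#'   at least 50 points.
#' @param max_components maximum number of mixture components (>= 1).
#' @return entropy in nats, with attributes `G` (components chosen) and
#'   `loglik`.
#' @export
entropy_gmm <- function(samples, max_components = 5) {
  x <- if (is.null(dim(samples))) matrix(samples, ncol = 1) else as.matrix(samples)
  if (ncol(x) > 2) stop("entropy_gmm supports 1-D or 2-D samples only")
  if (nrow(x) < 50) stop("need >= 50 samples")
  if (max_components < 1) stop("max_components must be >= 1")
  spread <- apply(x, 2, stats::sd)
  if (any(spread <= 0) || any(!is.finite(spread)))
    stop("degenerate samples: zero spread")

  sub <- unique(round(seq(1, nrow(x), length.out = min(nrow(x), 1000L))))
  model_names <- if (ncol(x) == 1) c("E", "V") else "VVV"
  fit <- mclust::densityMclust(
    if (ncol(x) == 1) x[, 1] else x,
    G = seq_len(max_components), modelNames = model_names,
    initialization = list(subset = sub),
    verbose = FALSE, plot = FALSE)
  if (is.null(fit)) stop("GMM fit failed")
  dens <- stats::predict(fit, if (ncol(x) == 1) x[, 1] else x)
  h <- mean(-log(pmax(dens, .Machine$double.xmin)))
  attr(h, "G") <- fit$G
  attr(h, "loglik") <- fit$loglik
  h
}

#' Pairwise mutual information matrix of node fluctuations
#'
#' \eqn{M_{ij} = H_i + H_j - H_{ij}} in nats, with marginal entropies
#' from 1-D GMM fits of each node's distance-to-equilibrium series and
#' joint entropies from 2-D GMM fits of the paired series. Negative
#' estimates (possible through estimator noise) are clamped to zero so
#' that the flow network never receives a negative conductance. Each
#' unordered pair is computed once; the diagonal is set to zero (self
#' information is not used by any downstream network).
#'
#' @param fluct frames x nodes matrix from [fluctuation_series()].
#' @param pairs optional n x n logical mask restricting which pairs are
#'   computed (e.g. a contact mask); others are left at 0.
#' @param max_components passed to [entropy_gmm()].
#' @param floor lower clamp for computed pairs (default 0, the plain
#'   non-negativity clamp). A small positive floor (e.g. `1e-4` nats)
#'   keeps weak but genuine edges conductive in the downstream flow
#'   network when estimator noise would otherwise zero them out.
#' @return n x n symmetric matrix (nats).
#' @export
mutual_information_matrix <- function(fluct, pairs = NULL, max_components = 5,
                                      floor = 0) {
  if (floor < 0) stop("floor must be >= 0")
  stopifnot(is.matrix(fluct))
  n <- ncol(fluct)
  if (nrow(fluct) < 50) stop("need >= 50 frames for mutual information")
  if (is.null(pairs)) pairs <- matrix(TRUE, n, n)
  stopifnot(dim(pairs) == c(n, n))

  H1 <- numeric(n)
  need_marginal <- unique(c(which(apply(pairs | t(pairs), 1, any))))
  for (i in need_marginal) {
    H1[i] <- tryCatch(as.numeric(entropy_gmm(fluct[, i], max_components)),
                      error = function(e)
                        stop("entropy failed for node ", i, ": ",
                             conditionMessage(e)))
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!(pairs[i, j] || pairs[j, i])) next
      Hij <- tryCatch(
        as.numeric(entropy_gmm(fluct[, c(i, j)], max_components)),
        error = function(e)
          stop("joint entropy failed for pair (", i, ",", j, "): ",
               conditionMessage(e)))
      M[i, j] <- M[j, i] <- max(floor, H1[i] + H1[j] - Hij)
    }
  }
  dimnames(M) <- list(colnames(fluct), colnames(fluct))
  M
}

# ---------------------------------------------------------------------------

#' Build the coupling-path network
#'
#' Edges are exactly the persistent-contact pairs; each carries weight
#' \eqn{w_{ij} = -\log|C_{ij}|}, so strongly correlated contacts are
#' short. Contact pairs with \eqn{C_{ij} = 0} get no edge (infinite
#' weight).
#'
#' @param C correlation matrix from [correlation_matrix()].
#' @param contacts a [contact_map()] (or bare logical mask).
#' @return object of class `path_network`: list with `weights` (n x n,
#'   `Inf` off-edges, 0 diagonal), `nodes`, and the underlying `C`.
#' @export
build_path_network <- function(C, contacts) {
  mask <- if (inherits(contacts, "contact_map")) contacts$mask else contacts
  stopifnot(is.matrix(C), dim(mask) == dim(C))
  w <- matrix(Inf, nrow(C), ncol(C))
  on <- mask & abs(C) > 0
  w[on] <- -log(abs(C[on]))
  diag(w) <- 0
  nodes <- rownames(C) %||%
    (if (inherits(contacts, "contact_map")) contacts$nodes
     else as.character(seq_len(nrow(C))))
  dimnames(w) <- list(nodes, nodes)
  structure(list(weights = w, nodes = nodes, C = C), class = "path_network")
}

#' Build the information-flow network
#'
#' Elementwise product of the binary contact mask and the mutual
#' information matrix: \eqn{A_{ij} = \mathrm{contact}_{ij} M_{ij}}. The
#' result is the conductance (adjacency) matrix of the flow analysis.
#'
#' @param M mutual information matrix (nats).
#' @param contacts a [contact_map()] or logical mask.
#' @return n x n symmetric adjacency matrix, zero off contact edges.
#' @export
build_flow_network <- function(M, contacts) {
  mask <- if (inherits(contacts, "contact_map")) contacts$mask else contacts
  stopifnot(is.matrix(M), dim(mask) == dim(M))
  A <- M * (mask * 1)
  diag(A) <- 0
  if (!is.null(rownames(M))) dimnames(A) <- dimnames(M)
  A
}

#' Serialize a residue network to an edge-list table
#'
#' One row per unordered node pair that is in contact, with the
#' correlation, path weight, mutual information and flow conductance of
#' the edge.
#'
#' @param contacts a [contact_map()].
#' @param C correlation matrix (optional).
#' @param M mutual information matrix (optional).
#' @param path CSV output path; when `NULL` the data.frame is returned
#'   only.
#' @return data.frame (i, j, contact, C, w, M, A), invisibly when
#'   written.
#' @export
network_edge_table <- function(contacts, C = NULL, M = NULL, path = NULL) {
  stopifnot(inherits(contacts, "contact_map"))
  mask <- contacts$mask
  idx <- which(upper.tri(mask) & mask, arr.ind = TRUE)
  nodes <- contacts$nodes
  cvals <- if (is.null(C)) NA_real_ else C[idx]
  mvals <- if (is.null(M)) NA_real_ else M[idx]
  out <- data.frame(
    i = nodes[idx[, 1]], j = nodes[idx[, 2]],
    contact = 1L,
    C = cvals,
    w = if (is.null(C)) NA_real_ else -log(abs(cvals)),
    M = mvals,
    A = mvals,
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
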