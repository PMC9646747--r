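#' Persistent residue-residue contact map of an ensemble
#'
#' Two residues are in contact in a frame when the minimal distance
#' between any of their non-hydrogen atoms is below `cutoff` (5 Angstrom
#' by default). An edge enters the network only when that holds for
#' strictly more than `occupancy` of the frames (default 0.75), i.e. the
#' contact is persistent rather than transient. Distances are computed
#' per frame without periodic-boundary imaging: inputs are expected to be
#' whole-molecule ensembles.
#'
#' @param traj a [trajectory_ensemble()].
#' @param cutoff contact distance cutoff in Angstrom (> 0).
#' @param occupancy occupancy threshold in (0, 1); the comparison is
#'   strict (`> occupancy`).
#' @param atom_scope `"heavy"` (non-hydrogen atoms, the default) or
#'   `"all"`.
#' @return object of class `contact_map`: list with `mask` (n x n
#'   logical), `occupancy` (n x n fraction of frames in contact),
#'   `nodes` (node ids), `cutoff`, `threshold`.
#' @export
contact_map <- function(traj, cutoff = 5, occupancy = 0.75,
                        atom_scope = c("heavy", "all")) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  atom_scope <- match.arg(atom_scope)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (occupancy <= 0 || occupancy >= 1) stop("occupancy must be in (0, 1)")

  nt <- node_table(traj)
  n <- nrow(nt)
  atoms <- lapply(nt$atoms, function(a) {
    if (atom_scope == "heavy") a[traj$meta$heavy[a]] else a
  })
  if (any(!lengths(atoms)))
    stop("node(s) without atoms in scope: ",
         paste(nt$node[lengths(atoms) == 0], collapse = ", "))

  nf <- n_frames(traj)
  count <- matrix(0L, n, n)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    d <- as.matrix(stats::dist(xyz))
    for (i in seq_len(n - 1)) {
      ai <- atoms[[i]]
      for (j in (i + 1):n) {
        if (min(d[ai, atoms[[j]]]) < cutoff)
          count[i, j] <- count[i, j] + 1L
      }
    }
  }
  occ <- (count + t(count)) / nf
  diag(occ) <- 0
  mask <- occ > occupancy
  structure(list(mask = mask, occupancy = occ, nodes = nt$node,
                 cutoff = cutoff, threshold = occupancy),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", length(x$nodes), " nodes, ",
      sum(x$mask) / 2, " edges (cutoff ", x$cutoff, " A, occupancy > ",
      x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Per-residue ligand contact probability
#'
#' A residue contacts the ligand in a frame when any of its non-hydrogen
#' atoms lies within `cutoff` (6 Angstrom by default) of any ligand heavy
#' atom. The per-frame indicator is averaged over frames, then over
#' ligand copies (e.g. the four copies bound to a tetramer), then as an
#' unweighted mean over replica ensembles — in that order.
#'
#' @param traj a [trajectory_ensemble()] (used as the first replica).
#' @param cutoff Angstrom; the comparison is strict (`< cutoff`).
#' @param replicas optional list of further `trajectory_ensemble`
#'   replicas with the same node layout.
#' @return object of class `ligand_contact_profile`: data.frame `node`,
#'   `probability`, plus attributes `cutoff` and `averaging`.
#' @export
ligand_contact_probability <- function(traj, cutoff = 6, replicas = NULL) {
  ensembles <- c(list(traj), replicas %||% list())
  per_rep <- lapply(ensembles, .ligand_profile_one, cutoff = cutoff)
  prob <- Reduce(`+`, per_rep) / length(per_rep)
  nt <- node_table(traj)
  res <- data.frame(node = nt$node[!nt$is_ligand], probability = prob,
                    stringsAsFactors = FALSE)
  attr(res, "cutoff") <- cutoff
  attr(res, "averaging") <- "frames, then ligand copies, then replicas"
  class(res) <- c("ligand_contact_profile", "data.frame")
  res
}

.ligand_profile_one <- function(traj, cutoff) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  nt <- node_table(traj)
  lig <- which(nt$is_ligand)
  if (!length(lig)) stop("no ligand nodes")
  res <- which(!nt$is_ligand)
  heavy_atoms <- function(i) {
    a <- nt$atoms[[i]]
    a[traj$meta$heavy[a]]
  }
  nf <- n_frames(traj)
  # contact indicator summed over frames: residues x ligand copies
  hits <- matrix(0, length(res), length(lig))
  for (f in seq_len(nf)) {
    xyz <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    d <- as.matrix(stats::dist(xyz))
    for (li in seq_along(lig)) {
      la <- heavy_atoms(lig[li])
      for (ri in seq_along(res)) {
        if (min(d[heavy_atoms(res[ri]), la]) < cutoff)
          hits[ri, li] <- hits[ri, li] + 1
      }
    }
  }
  rowMeans(hits / nf)   # average over frames, then over ligand copies
}

`%||%` <- function(a, b) if (is.null(a)) b else a
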