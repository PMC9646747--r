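#' Conformational ensemble container
#'
#' Holds a frames x atoms x 3 coordinate array (Angstrom) together with
#' per-atom metadata. Atoms are grouped into network nodes (residues or
#' ligand copies) by `(chain, resid)`; for bead models every bead is its
#' own residue and its own heavy atom, so node-level and atom-level views
#' coincide.
#'
#' @param coords numeric array, frames x atoms x 3, all finite.
#' @param meta data.frame with one row per atom: columns `name`, `resid`,
#'   `resname`, `chain`, `is_ligand` (logical), `heavy` (logical).
#' @param frame_interval time between frames (ps); the default matches the
#'   common 50 ps snapshot stride of equilibrium trajectory analysis.
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(coords, meta, frame_interval = 50) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be a frames x atoms x 3 array")
  if (dim(coords)[1] < 1) stop("ensemble has zero frames")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  need <- c("name", "resid", "resname", "chain", "is_ligand", "heavy")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("meta lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(meta) != dim(coords)[2])
    stop("meta rows (", nrow(meta), ") != atom count (", dim(coords)[2], ")")
  structure(list(coords = coords, meta = meta,
                 frame_interval = frame_interval),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("<trajectory_ensemble> ", n_frames(x), " frames x ",
      dim(x$coords)[2], " atoms (", nrow(node_table(x)), " nodes), ",
      x$frame_interval, " ps/frame\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname trajectory_ensemble
#' @param x a `trajectory_ensemble`.
n_frames <- function(x) dim(x$coords)[1]

#' Node (residue/ligand) table of an ensemble
#'
#' One row per network node, in first-appearance order: node id
#' `chain:resid`, residue name, ligand flag, and the atom indices that
#' belong to it.
#'
#' @param traj a `trajectory_ensemble`.
#' @return data.frame with columns `node`, `chain`, `resid`, `resname`,
#'   `is_ligand` and a list-column `atoms`.
#' @export
node_table <- function(traj) {
  m <- traj$meta
  key <- paste(m$chain, m$resid, sep = ":")
  idx <- split(seq_len(nrow(m)), factor(key, levels = unique(key)))
  first <- vapply(idx, `[`, integer(1), 1L)
  data.frame(node = names(idx),
             chain = m$chain[first],
             resid = m$resid[first],
             resname = m$resname[first],
             is_ligand = m$is_ligand[first],
             atoms = I(unname(idx)),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# multi-model PDB and XYZ readers/writers
#
# Both formats are written with one MODEL (or frame block) per snapshot.
# The parser is deliberately strict about MODEL/ENDMDL nesting and frame
# size so that malformed trajectory exports fail loudly with a line or
# frame index rather than silently truncating.

#' Read a conformational ensemble
#'
#' @param path file path.
#' @param format `"pdb"` (multi-model) or `"xyz"`; guessed from the file
#'   extension by default.
#' @return a [trajectory_ensemble()].
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (format == "pdb") .read_pdb_ensemble(path) else .read_xyz_ensemble(path)
}

#' Write a conformational ensemble
#'
#' @param traj a [trajectory_ensemble()].
#' @param path output file path.
#' @param format `"pdb"` or `"xyz"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(traj, path, format = c("auto", "pdb", "xyz")) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (format == "pdb") .write_pdb_ensemble(traj, path)
  else .write_xyz_ensemble(traj, path)
  invisible(path)
}

.write_pdb_ensemble <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  m <- traj$meta
  rec <- ifelse(m$is_ligand, "HETATM", "ATOM  ")
  el <- ifelse(m$heavy, "C", "H")
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, 1, 3)
    lines <- sprintf(
      "%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, seq_len(nrow(m)), substr(m$name, 1, 4), substr(m$resname, 1, 3),
      substr(m$chain, 1, 1), m$resid %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, el)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

.read_pdb_ensemble <- function(path) {
  lines <- readLines(path)
  frames <- list()
  cur <- NULL       # accumulating data for the open MODEL, else NULL
  in_model <- FALSE
  meta <- NULL
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    tag <- substr(line, 1, 6)
    if (startsWith(tag, "MODEL")) {
      if (in_model)
        stop("malformed PDB: MODEL inside open MODEL at line ", ln)
      in_model <- TRUE
      cur <- list(xyz = list(), meta = list())
    } else if (startsWith(tag, "ENDMDL")) {
      if (!in_model)
        stop("malformed PDB: ENDMDL without MODEL at line ", ln)
      in_model <- FALSE
      frames[[length(frames) + 1L]] <- cur
      cur <- NULL
    } else if (tag == "ATOM  " || tag == "HETATM") {
      if (!in_model) {           # single-model file without MODEL records
        in_model <- TRUE
        cur <- list(xyz = list(), meta = list())
      }
      cur$xyz[[length(cur$xyz) + 1L]] <-
        as.numeric(c(substr(line, 31, 38), substr(line, 39, 46),
                     substr(line, 47, 54)))
      cur$meta[[length(cur$meta) + 1L]] <- list(
        name = trimws(substr(line, 13, 16)),
        resname = trimws(substr(line, 18, 21)),
        chain = substr(line, 22, 22),
        resid = as.integer(substr(line, 23, 26)),
        is_ligand = tag == "HETATM",
        element = trimws(substr(line, 77, 78)))
    }
  }
  if (in_model) {   # file truncated without ENDMDL: accept trailing block
    frames[[length(frames) + 1L]] <- cur
  }
  if (!length(frames)) stop("no frames found in ", path)
  natom <- length(frames[[1]]$xyz)
  if (natom == 0) stop("no atoms in first frame of ", path)
  coords <- array(NA_real_, c(length(frames), natom, 3))
  for (f in seq_along(frames)) {
    if (length(frames[[f]]$xyz) != natom)
      stop("frame ", f, " has ", length(frames[[f]]$xyz),
           " atoms, expected ", natom)
    coords[f, , ] <- do.call(rbind, frames[[f]]$xyz)
  }
  m0 <- frames[[1]]$meta
  el <- vapply(m0, function(a) a$element, character(1))
  name <- vapply(m0, function(a) a$name, character(1))
  heavy <- ifelse(el != "", toupper(el) != "H",
                  !grepl("^[0-9]*H", name))
  meta <- data.frame(
    name = name,
    resid = vapply(m0, function(a) a$resid, integer(1)),
    resname = vapply(m0, function(a) a$resname, character(1)),
    chain = vapply(m0, function(a) a$chain, character(1)),
    is_ligand = vapply(m0, function(a) a$is_ligand, logical(1)),
    heavy = heavy,
    stringsAsFactors = FALSE)
  trajectory_ensemble(coords, meta)
}

.write_xyz_ensemble <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  m <- traj$meta
  sym <- ifelse(m$heavy, "C", "H")
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(nrow(m)), con)
    writeLines(sprintf("frame %d", f), con)
    xyz <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, 1, 3)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       sym, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
}

.read_xyz_ensemble <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1)
      stop("malformed XYZ: expected atom count at line ", i)
    if (i + 1L + nat > length(lines))
      stop("malformed XYZ: truncated frame starting at line ", i)
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad))
      stop("malformed XYZ: bad atom line at line ", i + 1L + bad[1])
    sym <- vapply(parts, `[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- list(sym = sym, xyz = xyz)
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames found in ", path)
  natom <- nrow(frames[[1]]$xyz)
  coords <- array(NA_real_, c(length(frames), natom, 3))
  for (f in seq_along(frames)) {
    if (nrow(frames[[f]]$xyz) != natom)
      stop("frame ", f, " has ", nrow(frames[[f]]$xyz),
           " atoms, expected ", natom)
    coords[f, , ] <- frames[[f]]$xyz
  }
  sym <- frames[[1]]$sym
  meta <- data.frame(
    name = sym,
    resid = seq_len(natom),    # synthesized: one node per atom
    resname = "XYZ",
    chain = "A",
    is_ligand = FALSE,
    heavy = toupper(sym) != "H",
    stringsAsFactors = FALSE)
  trajectory_ensemble(coords, meta)
}

# ---------------------------------------------------------------------------

#' Least-squares superposition of an ensemble
#'
#' Removes global rotation and translation from every frame by Kabsch
#' superposition onto a reference. With `reference = "mean"` the frames
#' are first fitted to frame 1, the mean structure is computed, and the
#' fit is repeated onto that mean (two passes), which is the standard
#' fixed-point approximation to the maximum-likelihood mean structure.
#'
#' @param traj a [trajectory_ensemble()].
#' @param reference `"mean"` or an integer frame index.
#' @return a superposed `trajectory_ensemble`.
#' @export
superpose <- function(traj, reference = "mean") {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  if (n_frames(traj) < 2) stop("need >= 2 frames to superpose")
  if (identical(reference, "mean")) {
    pass1 <- .fit_all(traj$coords, traj$coords[1, , ])
    ref <- apply(pass1, c(2, 3), mean)
    coords <- .fit_all(pass1, ref)
  } else {
    f <- as.integer(reference)
    if (f < 1 || f > n_frames(traj)) stop("reference frame out of range")
    coords <- .fit_all(traj$coords, traj$coords[f, , ])
  }
  trajectory_ensemble(coords, traj$meta, traj$frame_interval)
}

.fit_all <- function(coords, ref) {
  out <- coords
  refc <- scale(ref, scale = FALSE)
  for (f in seq_len(dim(coords)[1])) {
    out[f, , ] <- .kabsch(coords[f, , ], refc)
  }
  out
}

## Kabsch: optimal rotation of x onto centred reference refc
.kabsch <- function(x, refc) {
  mx <- colMeans(x)
  xc <- sweep(x, 2, mx)
  s <- svd(crossprod(xc, refc))
  if (s$d[2] < 1e-10 * max(s$d, 1e-30))
    stop("degenerate frame: nodes are collinear, superposition undefined")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t(R %*% t(xc))
}
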