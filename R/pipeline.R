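#' Default pipeline configuration
#'
#' The configuration drives [run_pipeline()] end to end. Defaults follow
#' the standard analysis conventions: 5 Angstrom / 75% occupancy network
#' contacts, 6 Angstrom ligand and vicinity cutoffs, top-20 paths.
#'
#' @param ... overrides for any default key (unknown keys are rejected
#'   at validation).
#' @return named list of class `run_config`.
#' @export
demo_config <- function(...) {
  cfg <- list(
    topology = "two_branch",      # synthetic system
    n_beads = 10L,
    branch_lengths = c(4L, 4L),
    branch_k = c(1, 1),
    n_frames = 2000L,
    amplitude = 0.6,
    rigid_body = FALSE,
    frame_stride = 1L,
    contact_cutoff = 5,
    ligand_cutoff = 6,
    vicinity_cutoff = 6,
    occupancy = 0.75,
    k_paths = 20L,
    source = 1L,
    sink = 10L,
    max_gmm_components = 3L,
    mi_floor = 1e-4,
    node_def = "centroid",
    seed = 1L,
    out_dir = tempfile("allopath_run_")
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "run_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Strict: unknown keys are rejected, cutoffs must be positive, the
#' occupancy threshold must lie in (0, 1), and `k_paths >= 1`.
#'
#' @param cfg a configuration list.
#' @return the validated `run_config`, invisibly usable.
#' @export
validate_config <- function(cfg) {
  known <- c("topology", "n_beads", "branch_lengths", "branch_k",
             "n_frames", "amplitude", "rigid_body", "frame_stride",
             "contact_cutoff", "ligand_cutoff", "vicinity_cutoff",
             "occupancy", "k_paths", "source", "sink",
             "max_gmm_components", "mi_floor", "node_def", "seed",
             "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(known, names(cfg))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  for (k in c("contact_cutoff", "ligand_cutoff", "vicinity_cutoff"))
    if (cfg[[k]] <= 0) stop(k, " must be positive")
  if (cfg$occupancy <= 0 || cfg$occupancy >= 1)
    stop("occupancy must be in (0, 1)")
  if (cfg$k_paths < 1) stop("k_paths must be >= 1")
  if (cfg$frame_stride < 1) stop("frame_stride must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

#' Run the coupling-analysis pipeline end to end
#'
#' Synthesize a bead-model ensemble, compute persistent contacts, build
#' the correlation- and mutual-information-weighted networks, extract
#' the top-k coupling paths and the source-to-sink current flow, and
#' write every stage product plus a reproducibility manifest to
#' `cfg$out_dir`. Deterministic for a fixed config and seed.
#'
#' @param cfg a validated [demo_config()]-style configuration.
#' @param quiet suppress stage logging.
#' @return invisible list with the in-memory stage products and
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg = demo_config(), quiet = FALSE) {
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[allopath] ", ...)

  say("synth: ", cfg$topology, " model, ", cfg$n_beads, " beads, ",
      cfg$n_frames, " frames")
  model <- make_bead_model(cfg$n_beads, cfg$topology,
                           branch_lengths = if (cfg$topology == "two_branch")
                             cfg$branch_lengths else NULL,
                           branch_k = if (cfg$topology == "two_branch")
                             cfg$branch_k else NULL)
  traj <- sample_trajectory(model, cfg$n_frames, cfg$amplitude,
                            rigid_body = cfg$rigid_body, seed = cfg$seed)
  if (cfg$frame_stride > 1) {
    idx <- seq(1, n_frames(traj), by = cfg$frame_stride)
    traj <- trajectory_ensemble(traj$coords[idx, , , drop = FALSE],
                                traj$meta, traj$frame_interval *
                                  cfg$frame_stride)
  }
  write_ensemble(traj, file.path(cfg$out_dir, "trajectory.pdb"))

  say("contacts: cutoff ", cfg$contact_cutoff, " A, occupancy > ",
      cfg$occupancy)
  fitted <- superpose(traj)
  cm <- contact_map(fitted, cutoff = cfg$contact_cutoff,
                    occupancy = cfg$occupancy)
  if (sum(cm$mask) == 0) stop("contacts stage: no persistent contacts")

  say("network: correlations + mutual information (",
      sum(cm$mask) / 2, " edges)")
  pos <- node_positions(fitted, cfg$node_def)
  C <- correlation_matrix(pos)
  fl <- fluctuation_series(pos)
  M <- mutual_information_matrix(fl, pairs = cm$mask,
                                 max_components = cfg$max_gmm_components,
                                 floor = cfg$mi_floor)
  pn <- build_path_network(C, cm)
  A <- build_flow_network(M, cm)
  network_edge_table(cm, C, M, file.path(cfg$out_dir, "network.csv"))

  say("paths: top ", cfg$k_paths, " ", cfg$source, " -> ", cfg$sink)
  ps <- suboptimal_paths(pn, cfg$source, cfg$sink, k = cfg$k_paths)
  path_tab <- data.frame(
    rank = seq_along(ps$paths),
    length = ps$lengths,
    nodes = vapply(ps$paths, function(p)
      paste(ps$nodes[p], collapse = "|"), character(1)))
  utils::write.csv(path_tab, file.path(cfg$out_dir, "paths.csv"),
                   row.names = FALSE)
  utils::write.csv(residue_frequency(ps),
                   file.path(cfg$out_dir, "path_frequency.csv"),
                   row.names = FALSE)

  say("flow: source ", cfg$source, " -> sink ", cfg$sink)
  fr <- solve_flow(A, cfg$source, cfg$sink)
  mean_xyz <- apply(pos, c(2, 3), mean)
  vic <- path_vicinity(mean_xyz, ps, cfg$vicinity_cutoff)
  rep_tab <- flow_report(fr, ps, vic)
  utils::write.csv(rep_tab, file.path(cfg$out_dir, "flow.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "allopath",
    version = as.character(utils::packageVersion("allopath")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    stages = list(
      trajectory = list(frames = n_frames(traj),
                        nodes = nrow(node_table(traj))),
      contacts = list(edges = sum(cm$mask) / 2),
      network = list(edges = nrow(network_edge_table(cm, C, M))),
      paths = list(found = length(ps$paths),
                   optimal_length = ps$lengths[1]),
      flow = list(total_out_of_source =
                    sum(pmax(fr$edge_current[fr$source, ], 0)))
    ))
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  say("done: ", cfg$out_dir)
  invisible(list(model = model, trajectory = traj, contacts = cm,
                 C = C, M = M, path_network = pn, flow_network = A,
                 paths = ps, flow = fr, report = rep_tab,
                 out_dir = cfg$out_dir))
}
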