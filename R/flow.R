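#' Network Laplacian of a flow adjacency
#'
#' \eqn{L = D - A} with \eqn{D_{ii} = \sum_j A_{ij}}. For a symmetric,
#' non-negative adjacency the Laplacian is symmetric positive
#' semidefinite with zero row sums and the constant vector in its null
#' space.
#'
#' @param A symmetric non-negative adjacency (conductance) matrix with
#'   zero diagonal.
#' @return n x n Laplacian matrix.
#' @export
laplacian <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A < 0)) stop("adjacency must be non-negative")
  if (max(abs(A - t(A))) > 1e-12 * max(1, max(abs(A))))
    stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero")
  diag(rowSums(A)) - A
}

#' Current-flow ("information flow") analysis between source and sinks
#'
#' Injects one unit of current at the source node and grounds all sink
#' nodes at potential zero, treating the mutual-information adjacency as
#' an electrical conductance network. Potentials solve
#' \eqn{P = \tilde L^{-1} b} on the reduced Laplacian (sink rows and
#' columns deleted; \eqn{b} is +1 at the source). The per-node flow is
#' \eqn{f_i = \frac{1}{2}\sum_j |P_i - P_j| A_{ij}}: half the total
#' current through node i, which equals the through-current at interior
#' nodes and half of it at the terminals (reported as-is; a
#' `normalized_flow` column with terminals forced to 1 is available from
#' [flow_report()]).
#'
#' @param A flow adjacency from [build_flow_network()] (or any symmetric
#'   non-negative conductance matrix).
#' @param source node id or index.
#' @param sinks one or more node ids or indices (common ground).
#' @return object of class `flow_result`: list with `potentials` (n),
#'   `node_flow` (n), `edge_current` (n x n antisymmetric,
#'   current i -> j), `source`, `sinks`, `nodes`.
#' @export
solve_flow <- function(A, source, sinks) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  n <- nrow(A)
  nodes <- rownames(A) %||% as.character(seq_len(n))
  s <- .node_index(nodes, source)
  tt <- vapply(sinks, function(x) .node_index(nodes, x), integer(1))
  tt <- unique(tt)
  if (s %in% tt) stop("source must not be a sink")

  # source must reach a sink through positive conductances
  comp <- .component_of(A > 0, s)
  if (!any(tt %in% comp)) stop("source is disconnected from all sinks")

  L <- laplacian(A)
  keep <- setdiff(seq_len(n), tt)
  Lr <- L[keep, keep, drop = FALSE]
  b <- numeric(length(keep))
  b[match(s, keep)] <- 1

  # floating subgraphs (no path to any sink) make Lr singular
  ch <- tryCatch(chol(Lr), error = function(e) NULL)
  if (is.null(ch)) {
    stop("singular reduced Laplacian; floating node(s): ",
         paste(nodes[setdiff(keep, comp)], collapse = ", "))
  }
  P <- numeric(n)
  P[keep] <- backsolve(ch, backsolve(ch, b, transpose = TRUE))

  dP <- outer(P, P, `-`)
  edge_current <- dP * A
  f <- 0.5 * rowSums(abs(dP) * A)
  names(P) <- names(f) <- nodes
  structure(list(potentials = P, node_flow = f,
                 edge_current = edge_current,
                 source = s, sinks = tt, nodes = nodes),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat("<flow_result> source ", x$nodes[x$source], " -> sinks ",
      paste(x$nodes[x$sinks], collapse = ","), "\n", sep = "")
  print(utils::head(data.frame(node = x$nodes,
                               potential = x$potentials,
                               flow = x$node_flow), 10))
  invisible(x)
}

.component_of <- function(adj, v) {
  n <- nrow(adj)
  seen <- logical(n); seen[v] <- TRUE
  queue <- v
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nb <- which(adj[u, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  which(seen)
}

#' Per-residue flow report, joined with path statistics
#'
#' Combines the current-flow solution with path membership frequency and
#' (optionally) vicinity flags and user-defined branch groups, enabling
#' the branch-level comparison of coupling routes (e.g. domain-interface
#' branch vs covalent-linker branch).
#'
#' @param flow a [solve_flow()] result.
#' @param pathset optional [suboptimal_paths()] result on the same
#'   nodes.
#' @param vicinity optional [path_vicinity()] result.
#' @param groups optional named list mapping group label -> node
#'   ids/indices; per-group flow sums are attached as attribute
#'   `group_flow`.
#' @return data.frame `node`, `potential`, `flow`, `normalized_flow`,
#'   `path_count`, `within_cutoff`, `group`.
#' @export
flow_report <- function(flow, pathset = NULL, vicinity = NULL,
                        groups = NULL) {
  stopifnot(inherits(flow, "flow_result"))
  n <- length(flow$nodes)
  norm <- flow$node_flow
  norm[c(flow$source, flow$sinks)] <- 1
  out <- data.frame(node = flow$nodes,
                    potential = flow$potentials,
                    flow = flow$node_flow,
                    normalized_flow = norm,
                    path_count = NA_integer_,
                    within_cutoff = NA,
                    group = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(pathset)) {
    rf <- residue_frequency(pathset)
    out$path_count <- rf$count[match(out$node, rf$node)]
  }
  if (!is.null(vicinity)) {
    out$within_cutoff <- vicinity$within_cutoff[match(out$node,
                                                      vicinity$node)]
  }
  if (!is.null(groups)) {
    gf <- numeric(length(groups)); names(gf) <- names(groups)
    for (g in names(groups)) {
      idx <- vapply(groups[[g]], function(x)
        .node_index(flow$nodes, x), integer(1))
      out$group[idx] <- g
      gf[g] <- sum(flow$node_flow[idx])
    }
    attr(out, "group_flow") <- gf
  }
  rownames(out) <- NULL
  out
}
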