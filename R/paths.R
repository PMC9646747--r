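#' All-pairs shortest path distances (Floyd-Warshall)
#'
#' Exact all-pairs shortest distances on the weighted coupling network,
#' with a successor structure for path reconstruction. The coupling
#' length \eqn{D_{ij}} between two residues is the sum of edge weights
#' \eqn{-\log|C|} along the shortest route, so small \eqn{D} means
#' strong dynamic coupling.
#'
#' @param graph a [build_path_network()] result, or a bare weight matrix
#'   (`Inf` for missing edges, 0 diagonal).
#' @return object of class `apsp`: list with `dist` (n x n),
#'   `next_hop` (n x n successor indices, NA when unreachable), `nodes`.
#' @export
all_pairs_shortest <- function(graph) {
  w <- .as_weight_matrix(graph)
  n <- nrow(w)
  if (any(w[is.finite(w)] < 0)) stop("negative edge weight")
  D <- w
  nxt <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(w[i, j])) nxt[i, j] <- j
  }
  diag(nxt) <- seq_len(n)
  for (k in seq_len(n)) {
    via <- outer(D[, k], D[k, ], `+`)
    better <- via < D
    if (any(better)) {
      D[better] <- via[better]
      nxt[better] <- matrix(nxt[, k], n, n)[better]
    }
  }
  structure(list(dist = D, next_hop = nxt,
                 nodes = .graph_nodes(graph, n)), class = "apsp")
}

#' Reconstruct one shortest path from an `apsp` structure
#'
#' @param apsp result of [all_pairs_shortest()].
#' @param from,to node indices or ids.
#' @return integer vector of node indices along the path.
#' @export
shortest_path_from <- function(apsp, from, to) {
  i <- .node_index(apsp$nodes, from)
  j <- .node_index(apsp$nodes, to)
  if (!is.finite(apsp$dist[i, j])) stop("no path: nodes are unreachable")
  path <- i
  while (i != j) {
    i <- apsp$next_hop[i, j]
    path <- c(path, i)
  }
  path
}

#' Optimal and suboptimal source-to-sink coupling paths
#'
#' Returns the `k` loopless (simple) paths of smallest total weight from
#' `source` to `sink`, ranked by non-decreasing length — the optimal
#' coupling route followed by its strongest alternatives. Enumeration is
#' Yen's deviation scheme over a deterministic Dijkstra; ties in length
#' are broken by lexicographic node-sequence order. Fewer than `k` paths
#' are returned when the graph admits fewer simple paths.
#'
#' @param graph [build_path_network()] result or weight matrix.
#' @param source,sink node ids or indices (distinct).
#' @param k number of paths requested (default 20, the conventional
#'   depth for suboptimal-path analysis).
#' @param max_offset optional: discard paths longer than
#'   `optimal + max_offset`.
#' @return object of class `path_set`: list with `paths` (list of
#'   integer index vectors), `lengths`, `source`, `sink`, `k`, `nodes`.
#' @export
suboptimal_paths <- function(graph, source, sink, k = 20, max_offset = Inf) {
  w <- .as_weight_matrix(graph)
  nodes <- .graph_nodes(graph, nrow(w))
  s <- .node_index(nodes, source)
  t <- .node_index(nodes, sink)
  if (s == t) stop("source and sink must differ")
  if (k < 1) stop("k must be >= 1")

  first <- .dijkstra(w, s, t)
  if (is.null(first)) stop("no path: sink unreachable from source")

  A <- list(first)          # accepted paths (each: list(path, len))
  B <- list()               # candidate pool
  while (length(A) < k) {
    prev <- A[[length(A)]]$path
    for (spur_i in seq_len(length(prev) - 1)) {
      root <- prev[seq_len(spur_i)]
      spur <- prev[spur_i]
      wmod <- w
      # remove edges leaving the spur node along any accepted path
      # sharing this root
      for (acc in A) {
        p <- acc$path
        if (length(p) > spur_i && identical(p[seq_len(spur_i)], root)) {
          wmod[p[spur_i], p[spur_i + 1]] <- Inf
          wmod[p[spur_i + 1], p[spur_i]] <- Inf
        }
      }
      # remove root nodes (except the spur) entirely
      if (spur_i > 1) {
        gone <- root[-spur_i]
        wmod[gone, ] <- Inf
        wmod[, gone] <- Inf
      }
      sp <- .dijkstra(wmod, spur, t)
      if (is.null(sp)) next
      cand_path <- c(root[-spur_i], sp$path)
      cand_len <- sp$len +
        if (spur_i > 1) sum(w[cbind(root[-spur_i], root[-1])]) else 0
      key <- paste(cand_path, collapse = "-")
      if (!is.null(B[[key]])) next
      if (any(vapply(A, function(a)
        identical(a$path, cand_path), logical(1)))) next
      B[[key]] <- list(path = cand_path, len = cand_len)
    }
    if (!length(B)) break
    lens <- vapply(B, `[[`, numeric(1), "len")
    best <- which(lens == min(lens))
    if (length(best) > 1) {
      seqs <- lapply(B[best], `[[`, "path")
      best <- best[.lex_order(seqs)[1]]
    }
    A[[length(A) + 1L]] <- B[[best]]
    B[[best]] <- NULL
  }

  lens <- vapply(A, `[[`, numeric(1), "len")
  keep <- lens <= lens[1] + max_offset
  A <- A[keep]; lens <- lens[keep]
  # stable final ordering: length, then lexicographic sequence
  ord <- order(lens)
  runs <- split(ord, lens[ord])
  ord <- unlist(lapply(runs, function(ix) {
    if (length(ix) == 1) return(ix)
    ix[.lex_order(lapply(A[ix], `[[`, "path"))]
  }), use.names = FALSE)
  structure(list(paths = lapply(A[ord], `[[`, "path"),
                 lengths = lens[ord],
                 source = s, sink = t, k = k, nodes = nodes),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat("<path_set> ", length(x$paths), " path(s) ",
      x$nodes[x$source], " -> ", x$nodes[x$sink], "\n", sep = "")
  for (i in seq_along(x$paths)) {
    cat(sprintf("  %2d  L=%.4f  %s\n", i, x$lengths[i],
                paste(x$nodes[x$paths[[i]]], collapse = " - ")))
  }
  invisible(x)
}

#' Residue frequency across a path set
#'
#' How often each node appears among the ranked optimal/suboptimal
#' paths; nodes that recur across many near-optimal routes carry the
#' coupling.
#'
#' @param pathset a [suboptimal_paths()] result.
#' @return data.frame `node`, `count` (0..k), `frequency` (count / number
#'   of paths), all nodes included.
#' @export
residue_frequency <- function(pathset) {
  stopifnot(inherits(pathset, "path_set"))
  n <- length(pathset$nodes)
  count <- integer(n)
  for (p in pathset$paths) count[p] <- count[p] + 1L
  data.frame(node = pathset$nodes, count = count,
             frequency = count / length(pathset$paths),
             stringsAsFactors = FALSE)
}

#' Residues in the vicinity of a path set
#'
#' Flags every node that lies strictly within `cutoff` of any path
#' member node in a representative structure frame (path members
#' themselves are at distance 0 and always flagged).
#'
#' @param frame_xyz n x 3 node coordinate matrix (one structure frame).
#' @param pathset a [suboptimal_paths()] result over the same nodes.
#' @param cutoff Angstrom, strict `<` comparison (default 6).
#' @return data.frame `node`, `on_path`, `min_dist`, `within_cutoff`.
#' @export
path_vicinity <- function(frame_xyz, pathset, cutoff = 6) {
  stopifnot(inherits(pathset, "path_set"))
  frame_xyz <- as.matrix(frame_xyz)
  if (nrow(frame_xyz) != length(pathset$nodes))
    stop("coordinate rows must match path-set nodes")
  members <- sort(unique(unlist(pathset$paths)))
  on_path <- seq_len(nrow(frame_xyz)) %in% members
  d <- apply(frame_xyz, 1, function(p) {
    sqrt(min(colSums((t(frame_xyz[members, , drop = FALSE]) - p)^2)))
  })
  data.frame(node = pathset$nodes, on_path = on_path, min_dist = d,
             within_cutoff = d < cutoff, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# internals

.as_weight_matrix <- function(graph) {
  w <- if (inherits(graph, "path_network")) graph$weights else as.matrix(graph)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (any(w[is.finite(w)] < 0)) stop("negative edge weight")
  w
}

.graph_nodes <- function(graph, n) {
  if (inherits(graph, "path_network")) return(graph$nodes)
  rownames(graph) %||% as.character(seq_len(n))
}

.node_index <- function(nodes, id) {
  if (is.numeric(id)) {
    i <- as.integer(id)
    if (i < 1 || i > length(nodes)) stop("node index out of range: ", id)
    return(i)
  }
  i <- match(as.character(id), nodes)
  if (is.na(i)) stop("unknown node: ", id)
  i
}

## Dijkstra with lexicographic tie-breaking on equal-length paths.
## Returns list(path, len) or NULL when t is unreachable.
.dijkstra <- function(w, s, t) {
  n <- nrow(w)
  dist <- rep(Inf, n); dist[s] <- 0
  done <- logical(n)
  paths <- vector("list", n); paths[[s]] <- s
  repeat {
    u <- NA_integer_; du <- Inf
    for (v in which(!done)) {
      if (dist[v] < du) { du <- dist[v]; u <- v }
    }
    if (is.na(u) || !is.finite(du)) break
    if (u == t) break
    done[u] <- TRUE
    nb <- which(is.finite(w[u, ]) & !done & seq_len(n) != u)
    for (v in nb) {
      nd <- dist[u] + w[u, v]
      if (nd < dist[v] - 1e-15) {
        dist[v] <- nd
        paths[[v]] <- c(paths[[u]], v)
      } else if (abs(nd - dist[v]) <= 1e-15 && !is.null(paths[[v]])) {
        cand <- c(paths[[u]], v)
        if (.lex_less(cand, paths[[v]])) paths[[v]] <- cand
      }
    }
  }
  if (!is.finite(dist[t])) return(NULL)
  list(path = paths[[t]], len = dist[t])
}

## order a list of integer sequences lexicographically
.lex_order <- function(seqs) {
  maxlen <- max(lengths(seqs))
  keys <- vapply(seqs, function(p)
    paste(sprintf("%09d", c(p, rep(0L, maxlen - length(p)))),
          collapse = ","), character(1))
  order(keys)
}

.lex_less <- function(a, b) {
  .lex_order(list(a, b))[1] == 1L
}
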