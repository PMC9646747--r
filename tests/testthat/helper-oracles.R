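# Independent oracles used across the suite.

# exhaustive enumeration of all simple paths s -> t, ranked by
# (length, lexicographic node sequence) -- the reference for the
# k-shortest-path implementation
brute_force_paths <- function(w, s, t) {
  res <- list()
  rec <- function(path, len) {
    v <- path[length(path)]
    if (v == t) {
      res[[length(res) + 1L]] <<- list(path = path, len = len)
      return()
    }
    for (u in which(is.finite(w[v, ]))) {
      if (u == v || u %in% path) next
      rec(c(path, u), len + w[v, u])
    }
  }
  rec(as.integer(s), 0)
  if (!length(res)) return(res)
  lens <- vapply(res, `[[`, numeric(1), "len")
  ord <- order(lens)
  # lexicographic tie-break within equal lengths
  runs <- split(ord, round(lens[ord], 12))
  ord <- unlist(lapply(runs, function(ix) {
    if (length(ix) == 1) return(ix)
    keys <- vapply(res[ix], function(p)
      paste(sprintf("%04d", p$path), collapse = ","), character(1))
    ix[order(keys)]
  }), use.names = FALSE)
  res[ord]
}

# random symmetric weighted graph as a weight matrix (Inf off-edges)
random_weight_graph <- function(n, p_edge = 0.6, wmin = 0.1, wmax = 2) {
  w <- matrix(Inf, n, n)
  diag(w) <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge)
        w[i, j] <- w[j, i] <- stats::runif(1, wmin, wmax)
    }
  }
  w
}

# random conductance network restricted to the component of node 1
random_conductance_graph <- function(n, p_edge = 0.5) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge)
        A[i, j] <- A[j, i] <- stats::runif(1, 0.1, 3)
    }
  }
  comp <- allopath:::.component_of(A > 0, 1)
  A[comp, comp, drop = FALSE]
}

# analytic GNM correlation matrix of a bead model (pseudoinverse of the
# Kirchhoff matrix via eigendecomposition, normalized to correlations)
analytic_gnm_correlation <- function(model) {
  e <- eigen(model$kirchhoff, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values)
  Kp <- e$vectors[, keep] %*% (t(e$vectors[, keep]) / e$values[keep])
  Kp / sqrt(outer(diag(Kp), diag(Kp)))
}

# hand-buildable two-branch weight matrix: source 1, sink n, branch A
# through nodes 2..(1+l1), branch B through the rest
two_branch_weights <- function(l1, l2, wa, wb) {
  n <- l1 + l2 + 2
  w <- matrix(Inf, n, n)
  diag(w) <- 0
  a <- c(1, seq.int(2, 1 + l1), n)
  b <- c(1, seq.int(2 + l1, n - 1), n)
  for (s in seq_len(length(a) - 1)) w[a[s], a[s + 1]] <- w[a[s + 1], a[s]] <- wa
  for (s in seq_len(length(b) - 1)) w[b[s], b[s + 1]] <- w[b[s + 1], b[s]] <- wb
  w
}
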