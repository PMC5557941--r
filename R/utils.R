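# Internal helpers shared across modules.

# Connected components of the graph with an edge (i, j) iff d[i, j] <= threshold.
# NA distances contribute no edge. Components are numbered 1..k in order of
# their first member, so labels are deterministic for a fixed input order.
single_linkage_components <- function(dmat, threshold) {
  n <- nrow(dmat)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        dij <- dmat[i, j]
        if (!is.na(dij) && dij <= threshold) {
          ri <- find(i)
          rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Upper-triangle pair index of a square matrix, as a two-column matrix.
upper_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  t(combn(n, 2L))
}

# Evaluate an expression under a temporary seed when one is given.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(as.integer(seed), expr)
}

stop_integrity <- function(msg) abort(msg, class = "bg_error_integrity")
stop_parameter <- function(msg) abort(msg, class = "bg_error_parameter")
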