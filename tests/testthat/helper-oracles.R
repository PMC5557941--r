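# Independent oracles and small fixture builders used across the suite.
# These deliberately use naive algorithms (character loops, matrix powers,
# pair counting) so they share no code path with the package internals.

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force K2P over two character vectors: explicit site loop
oracle_k2p <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  bases <- c("A", "C", "G", "T")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(a)) {
    if (!(a[i] %in% bases) || !(b[i] %in% bases)) next
    n <- n + 1L
    if (a[i] == b[i]) next
    pur <- c("A", "G")
    if ((a[i] %in% pur) == (b[i] %in% pur)) ts <- ts + 1L else tv <- tv + 1L
  }
  if (n == 0L) return(list(d = NA_real_, sites = 0L))
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    return(list(d = NA_real_, sites = n)) # saturated: correction undefined
  }
  list(d = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q), sites = n)
}

# transitive closure of the d <= t relation via boolean matrix powers
oracle_components <- function(dmat, t) {
  n <- nrow(dmat)
  adj <- !is.na(dmat) & dmat <= t
  diag(adj) <- TRUE
  reach <- adj
  for (i in seq_len(n)) reach <- (reach %*% adj) > 0
  comp <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      nxt <- nxt + 1L
      comp[reach[i, ]] <- nxt
    }
  }
  comp
}

# ARI by explicit pair counting over all specimen pairs
oracle_ari <- function(p1, p2) {
  ids <- p1$specimen_id
  a <- setNames(p1$group, p1$specimen_id)[ids]
  b <- setNames(p2$group, p2$specimen_id)[ids]
  n11 <- n00 <- n10 <- n01 <- 0
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      s1 <- a[i] == a[j]
      s2 <- b[i] == b[j]
      if (s1 && s2) n11 <- n11 + 1
      else if (!s1 && !s2) n00 <- n00 + 1
      else if (s1) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# wrap a bare symmetric matrix as the package's distance container
make_dist <- function(d, ids = NULL) {
  ids <- ids %||% rownames(d) %||% paste0("s", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  sites <- matrix(1L, nrow(d), ncol(d), dimnames = dimnames(d))
  structure(list(ids = ids, d = d, sites = sites,
                 diagnostics = tibble::tibble(id_a = character(0),
                                              id_b = character(0),
                                              type = character(0))),
            class = "k2p_dist")
}

# block distance matrix: within-block wd, between-block bd
block_dist <- function(sizes, wd, bd) {
  n <- sum(sizes)
  grp <- rep.int(seq_along(sizes), sizes)
  d <- matrix(bd, n, n)
  for (g in seq_along(sizes)) d[grp == g, grp == g] <- wd
  diag(d) <- 0
  make_dist(d)
}

# metadata with sites laid out at given along-equator km offsets
make_geo_meta <- function(km, morphospecies = NULL, site_id = NULL,
                          ids = NULL) {
  n <- length(km)
  tibble::tibble(
    specimen_id = ids %||% paste0("s", seq_len(n)),
    site_id = site_id %||% paste0("site", seq_len(n)),
    latitude = rep(0, n),
    longitude = km / 111.1949,
    morphospecies = morphospecies %||% rep("M1", n),
    deformed = rep(FALSE, n),
    characters = rep(list(character(0)), n)
  )
}

random_partition <- function(ids, k) {
  as_partition(setNames(paste0("R", sample.int(k, length(ids), replace = TRUE)),
                        ids))
}

# every group of `fine` lies inside one group of `coarse`
is_refinement <- function(fine, coarse) {
  lk <- setNames(coarse$group, coarse$specimen_id)
  all(tapply(lk[fine$specimen_id], fine$group,
             function(x) length(unique(x)) == 1L))
}

# random related sequences: perturbations of a common random root, with a
# sprinkling of gaps and Ns to exercise pairwise deletion
random_alignment <- function(n, L, sub_rate = 0.08, gap_rate = 0.03) {
  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(root, each = n), nrow = n)
  mut <- matrix(runif(n * L) < sub_rate, nrow = n)
  m[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
  gap <- matrix(runif(n * L) < gap_rate, nrow = n)
  m[gap] <- sample(c("-", "N"), sum(gap), replace = TRUE)
  rownames(m) <- paste0("s", seq_len(n))
  aligned_matrix(m)
}
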