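#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour-joining agglomeration over the K2P distance matrix.
#' Negative branch lengths (a known NJ artefact) are clamped to zero with
#' the deficit transferred to the sister edge, so path lengths through the
#' parent are preserved; the adjustment is reported.
#'
#' @param dm A `k2p_dist` object with at least 3 specimens and no flagged
#'   (NA) distances.
#' @return An unrooted [ape::phylo] tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  if (length(dm$ids) < 3) abort("need at least 3 specimens",
                                class = "bg_error_size")
  if (anyNA(dm$d)) {
    stop_integrity("distance matrix has flagged pairs; cap or resolve first")
  }
  tr <- ape::nj(dm$d)
  neg <- which(tr$edge.length < 0)
  if (length(neg) > 0) {
    for (e in neg) {
      deficit <- tr$edge.length[e]
      parent <- tr$edge[e, 1]
      sisters <- setdiff(which(tr$edge[, 1] == parent), e)
      if (length(sisters) > 0) {
        tr$edge.length[sisters[1]] <- tr$edge.length[sisters[1]] + deficit
      }
      tr$edge.length[e] <- 0
    }
    inform(sprintf("clamped %d negative branch length(s) to zero", length(neg)))
  }
  tr
}

#' Bootstrap support for neighbour-joining clades
#'
#' Resamples alignment columns with replacement, recomputes the K2P + NJ
#' tree per replicate, and reports for each internal node of the reference
#' tree the proportion of replicates containing the same bipartition.
#' Seeded and reproducible.
#'
#' @param alignment An [aligned_matrix()].
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param tree Optional reference tree; defaults to the NJ tree of the full
#'   alignment.
#' @return A `bootstrap_result`: list with `tree` (reference tree, supports
#'   written into `$node.label`), `support` (tibble: `node`, `support`) and
#'   `replicates`.
#' @export
bootstrap_support <- function(alignment, replicates = 1000, seed = NULL,
                              tree = NULL) {
  if (replicates < 1) stop_parameter("`replicates` must be >= 1")
  dm <- distance_matrix(alignment)
  ref <- tree %||% nj_tree(dm)
  L <- ncol(alignment)
  boots <- with_seed_if(seed, {
    purrr::map(seq_len(replicates), function(i) {
      cols <- sample.int(L, L, replace = TRUE)
      # replicate-level clamp messages are noise; the reference tree reports
      suppressMessages(
        nj_tree(distance_matrix(subset_alignment(alignment, sites = cols))))
    })
  })
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / replicates
  ref$node.label <- formatC(support, format = "g")
  structure(list(tree = ref,
                 support = tibble(node = ape::Ntip(ref) + seq_along(support),
                                  support = support),
                 replicates = replicates),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<NJ bootstrap: %d replicates, %d internal nodes>\n",
              x$replicates, nrow(x$support)))
  invisible(x)
}

#' @rdname bootstrap_support
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @export
tidy.bootstrap_result <- function(x, ...) x$support

# Root so that the outgroup forms a clade whenever its split exists. When
# the outgroup's MRCA coincides with the stored (arbitrary) root of the
# unrooted tree, rooting on it leaves the outgroup paraphyletic; rooting on
# the complement then puts the outgroup on one side of the root.
root_on_outgroup <- function(tree, outgroup) {
  is_clade <- function(phy, tips) {
    if (length(tips) == 1L) return(TRUE)
    mrca <- ape::getMRCA(phy, tips)
    setequal(ape::extract.clade(phy, mrca)$tip.label, tips)
  }
  rooted <- tryCatch(ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
                     error = function(e) NULL)
  if (!is.null(rooted) && is_clade(rooted, outgroup)) return(rooted)
  comp <- setdiff(tree$tip.label, outgroup)
  rooted2 <- tryCatch(ape::root(tree, outgroup = comp, resolve.root = TRUE),
                      error = function(e) NULL)
  if (!is.null(rooted2) && is_clade(rooted2, outgroup)) return(rooted2)
  rooted %||% rooted2 %||%
    abort("could not root the tree on the given outgroup",
          class = "bg_error_rooting")
}

# does `tipset` form one side of a split of the (unrooted) tree?
is_split_of <- function(tree, tipset) {
  tips <- tree$tip.label
  if (!all(tipset %in% tips)) return(FALSE)
  if (length(tipset) <= 1L || length(tipset) >= length(tips) - 1L) return(TRUE)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  target <- sort(match(tipset, labs))
  comp <- sort(setdiff(seq_along(labs), target))
  any(vapply(parts, function(p) {
    sp <- sort(p)
    identical(sp, target) || identical(sp, comp)
  }, logical(1)))
}

#' Monophyly assessment of candidate clusters
#'
#' Checks, for every cluster of a partition, whether some node of the rooted
#' tree has exactly that cluster as its descendant leaf set. Unrooted trees
#' must come with an outgroup for rooting. Size-1 clusters are `trivial`;
#' clusters with leaves missing from the tree are `unresolvable` and listed.
#' When bootstrap trees are supplied, each cluster also gets the proportion
#' of replicates in which it forms a split.
#'
#' @param tree An [ape::phylo] tree whose leaves cover the partition
#'   specimens (missing leaves are reported, not dropped silently).
#' @param partition A [as_partition()].
#' @param outgroup Leaf labels used to root an unrooted tree.
#' @param boot_trees Optional list of (bootstrap) trees for per-cluster
#'   support.
#' @return A `monophyly_report` tibble: `group`, `n`, `n_in_tree`, `status`
#'   (`monophyletic`, `non-monophyletic`, `trivial`, `unresolvable`) and
#'   `support` (NA without `boot_trees`).
#' @export
monophyly <- function(tree, partition, outgroup = NULL, boot_trees = NULL) {
  partition <- as_partition_quiet(partition)
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup)) {
      abort("unrooted tree: an outgroup is required for rooting",
            class = "bg_error_rooting")
    }
    if (!all(outgroup %in% tree$tip.label)) {
      stop_integrity("outgroup labels missing from the tree")
    }
    tree <- root_on_outgroup(tree, outgroup)
  }
  groups <- split(partition$specimen_id, partition$group)
  groups <- groups[unique(partition$group)] # deterministic order
  rows <- purrr::imap(groups, function(ids, gname) {
    present <- ids[ids %in% tree$tip.label]
    status <- if (length(present) < length(ids)) {
      "unresolvable"
    } else if (length(ids) == 1L) {
      "trivial"
    } else {
      mrca <- ape::getMRCA(tree, ids)
      clade_tips <- ape::extract.clade(tree, mrca)$tip.label
      if (setequal(clade_tips, ids)) "monophyletic" else "non-monophyletic"
    }
    support <- NA_real_
    if (!is.null(boot_trees) && status %in% c("monophyletic", "non-monophyletic")) {
      support <- mean(vapply(boot_trees, is_split_of, logical(1), tipset = ids))
    }
    tibble(group = gname, n = length(ids), n_in_tree = length(present),
           status = status, support = support)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("monophyly_report", class(out))
  out
}

#' Write a tree as newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
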