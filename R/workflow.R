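#' Run the full integrative delimitation workflow
#'
#' Chains the package end to end: K2P distances with pairwise deletion, the
#' barcode-gap prior scan with plateau-based selection of the molecular
#' candidate partition, population assembly and geographic delimitation at
#' `geo_threshold_km`, a neighbour-joining tree (or an imported tree) with
#' per-cluster monophyly, cluster-wise congruence of the candidate against
#' the geographic (and any extra imported) partitions, morphological
#' character stability/diagnosability, and the three-criterion species
#' validation with cryptic-species flagging.
#'
#' When no outgroup is given and the tree is unrooted, the candidate
#' cluster with the largest mean distance to all other specimens serves as
#' a functional outgroup for rooting.
#'
#' @param alignment An [aligned_matrix()].
#' @param metadata Specimen metadata tibble (see [read_metadata()]).
#' @param geo_threshold_km Geographic threshold for the congruence
#'   partition (default 50 km).
#' @param geo_thresholds_km Thresholds for the geographic scan (default
#'   `c(10, 20, 50, 100, 200, 300, 400, 500)`).
#' @param link_km Population (site-cluster) radius in km (default 5).
#' @param tree Optional imported [ape::phylo] tree; defaults to the NJ tree
#'   of the K2P distances.
#' @param outgroup Optional leaf labels for rooting.
#' @param extra_partitions Optional named list of imported partitions (e.g.
#'   PTP output) added to the congruence comparison.
#' @param stability_floor Passed to [validate_species()] (default 1).
#' @param ... Passed to [prior_scan()] (`p_min`, `p_max`, `n_priors`,
#'   `gap_width`, `window`, `max_rounds`).
#' @return A `delim_result` list: `distances`, `scan` (prior scan),
#'   `candidate` (selected molecular partition), `populations`, `geo`
#'   (geographic scan), `geo_partition`, `tree`, `monophyly`, `congruence`,
#'   `characters`, `validation`, `distance_summary`.
#' @export
delimit_integrative <- function(alignment, metadata,
                                geo_threshold_km = 50,
                                geo_thresholds_km = c(10, 20, 50, 100, 200,
                                                      300, 400, 500),
                                link_km = 5,
                                tree = NULL,
                                outgroup = NULL,
                                extra_partitions = list(),
                                stability_floor = 1,
                                ...) {
  issues <- validate_inputs(alignment = alignment, metadata = metadata)
  if (nrow(issues) > 0) {
    stop_integrity(paste0("alignment/metadata mismatch: ",
                          paste(issues$specimen_id, collapse = ", ")))
  }
  dm <- distance_matrix(alignment)
  scan <- prior_scan(dm, ...)
  candidate <- scan$selected
  pops <- assemble_populations(metadata, link_km = link_km)
  geo <- geo_scan(pops, thresholds_km = geo_thresholds_km)
  geo_partition <- geo_delimit(pops, geo_threshold_km)
  tree <- tree %||% nj_tree(dm)
  if (is.null(outgroup) && !ape::is.rooted(tree)) {
    outgroup <- most_divergent_cluster(dm, candidate)
  }
  mono <- monophyly(tree, candidate, outgroup = outgroup)
  cong <- clusterwise_congruence(candidate,
                                 c(list(geo = geo_partition), extra_partitions))
  chars <- character_report(metadata, candidate)
  validation <- validate_species(candidate, mono, cong, chars,
                                 stability_floor = stability_floor)
  structure(list(distances = dm,
                 scan = scan,
                 candidate = candidate,
                 populations = pops,
                 geo = geo,
                 geo_partition = geo_partition,
                 tree = tree,
                 monophyly = mono,
                 congruence = cong,
                 characters = chars,
                 validation = validation,
                 distance_summary = summarize_distances(dm, candidate)),
            class = "delim_result")
}

# specimens of the candidate cluster with max mean distance to the rest
most_divergent_cluster <- function(dm, partition) {
  grp <- partition_lookup(partition)[dm$ids]
  groups <- unique(grp)
  mean_out <- vapply(groups, function(g) {
    inside <- dm$ids[grp == g]
    outside <- dm$ids[grp != g]
    if (length(outside) == 0) return(0)
    mean(dm$d[inside, outside, drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  dm$ids[grp == groups[which.max(mean_out)]]
}

#' @export
print.delim_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0(
    "<integrative delimitation: %d specimens>\n",
    "  molecular candidate: k = %d (prior scan)\n",
    "  geographic partition: k = %d\n",
    "  congruent clusters: %d | validated: %d, cryptic: %d, unresolved: %d\n"),
    g$n_specimens, g$k_molecular, g$k_geographic, g$n_congruent,
    g$n_validated, g$n_cryptic, g$n_unresolved))
  invisible(x)
}

#' @rdname delimit_integrative
#' @param x,object A `delim_result`.
#' @param ... Unused for the methods.
#' @export
tidy.delim_result <- function(x, ...) {
  dplyr::left_join(x$validation,
                   dplyr::select(x$monophyly, "group", mono_status = "status"),
                   by = "group")
}

#' @rdname delimit_integrative
#' @export
glance.delim_result <- function(x, ...) {
  ds <- x$distance_summary
  tibble(
    n_specimens = length(x$distances$ids),
    k_molecular = partition_k(x$candidate),
    k_geographic = partition_k(x$geo_partition),
    n_congruent = x$congruence$n_congruent,
    n_validated = sum(x$validation$status == "validated_species"),
    n_cryptic = sum(x$validation$status == "cryptic_species"),
    n_unresolved = sum(x$validation$status == "unresolved"),
    intra_mean = ds$mean[ds$type == "intra"],
    intra_min = ds$min[ds$type == "intra"],
    intra_max = ds$max[ds$type == "intra"],
    inter_mean = ds$mean[ds$type == "inter"],
    inter_min = ds$min[ds$type == "inter"],
    inter_max = ds$max[ds$type == "inter"]
  )
}

#' @rdname delimit_integrative
#' @export
autoplot.delim_result <- function(object, ...) {
  autoplot(object$scan)
}
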