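#' Common refinement (meet) of partitions
#'
#' The meet assigns two specimens to the same group only when every input
#' partition does; its groups are the nonempty intersections of one group
#' from each partition. It refines every input and formalises "congruent
#' across methods" as set algebra.
#'
#' @param ... Two or more partitions (or a single list of them), all over
#'   the same specimen set.
#' @return A [as_partition()] labelled `G1..Gk` by first-member order.
#' @export
partition_meet <- function(...) {
  parts <- rlang::list2(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "data.frame")) {
    parts <- parts[[1]]
  }
  if (length(parts) < 2) stop_parameter("need at least two partitions")
  parts <- purrr::map(parts, as_partition_quiet)
  check_same_universe(parts)
  ids <- parts[[1]]$specimen_id
  keys <- purrr::map(parts, ~ partition_lookup(.x)[ids])
  combo <- do.call(paste, c(keys, sep = "\r"))
  p <- as_partition(tibble(specimen_id = ids, group = combo), source = "meet")
  relabel_groups(p)
}

#' Adjusted Rand index between two partitions
#'
#' Standard ARI from the contingency table: agreement of specimen-pair
#' co-assignment, corrected for chance. 1 for identical partitions, about 0
#' for independent ones.
#'
#' @param p1,p2 Partitions over the same specimen set.
#' @return A number in \[-1, 1\].
#' @export
adjusted_rand <- function(p1, p2) {
  p1 <- as_partition_quiet(p1)
  p2 <- as_partition_quiet(p2)
  check_same_universe(list(p1, p2))
  ids <- p1$specimen_id
  a <- partition_lookup(p1)[ids]
  b <- partition_lookup(p2)[ids]
  tab <- table(a, b)
  n <- length(ids)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1) # both trivial partitions
  (sum_ij - expected) / (max_index - expected)
}

#' Cluster-wise congruence of a reference partition
#'
#' A reference cluster is congruent when its exact specimen set is also a
#' cluster of every other partition. This is the operational reading of
#' "congruent across methods" that lets a 22-group molecular partition be
#' congruent cluster-by-cluster with, say, a larger geographic partition;
#' incongruent clusters are listed with the partitions that disagree.
#'
#' @param reference The designated reference partition.
#' @param others A partition or list of partitions over the same specimens.
#' @return A `congruence_report`: list with `clusters` (tibble: `group`,
#'   `n`, `congruent`, `disagrees_with`), `n_congruent`, `ari` (pairwise
#'   adjusted Rand matrix including the reference) and `meet`.
#' @export
clusterwise_congruence <- function(reference, others) {
  reference <- as_partition_quiet(reference)
  if (inherits(others, "data.frame")) others <- list(others)
  others <- purrr::map(others, as_partition_quiet)
  if (length(others) < 1) stop_parameter("need at least one other partition")
  check_same_universe(c(list(reference), others))
  other_names <- names(others) %||% rep("", length(others))
  other_names <- ifelse(nzchar(other_names), other_names,
                        purrr::map_chr(others, partition_source))
  ref_groups <- split(reference$specimen_id, reference$group)
  ref_groups <- ref_groups[unique(reference$group)]
  other_sets <- purrr::map(others, function(p) {
    purrr::map(split(p$specimen_id, p$group), sort)
  })
  rows <- purrr::imap(ref_groups, function(ids, gname) {
    s <- sort(ids)
    miss <- purrr::map_lgl(other_sets, function(sets) {
      !any(purrr::map_lgl(sets, identical, y = s))
    })
    tibble(group = gname, n = length(ids), congruent = !any(miss),
           disagrees_with = paste(other_names[miss], collapse = ";"))
  })
  clusters <- dplyr::bind_rows(rows)
  all_parts <- c(list(reference = reference), setNames(others, other_names))
  k <- length(all_parts)
  ari <- matrix(1, k, k, dimnames = list(names(all_parts), names(all_parts)))
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      ari[i, j] <- ari[j, i] <- adjusted_rand(all_parts[[i]], all_parts[[j]])
    }
  }
  structure(list(clusters = clusters,
                 n_congruent = sum(clusters$congruent),
                 ari = ari,
                 meet = partition_meet(all_parts)),
            class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf("<congruence: %d/%d reference clusters congruent>\n",
              x$n_congruent, nrow(x$clusters)))
  invisible(x)
}

#' @rdname clusterwise_congruence
#' @param x A `congruence_report`.
#' @param ... Unused.
#' @export
tidy.congruence_report <- function(x, ...) x$clusters

#' Character stability and diagnosability per cluster
#'
#' For every cluster and discrete character: the multiset of values among
#' non-deformed members, the modal value, and stability (fraction of
#' non-missing values equal to the mode). For every cluster pair and
#' character: a diagnosability flag, true when both clusters have values and
#' their value sets are disjoint. Deformed specimens contribute to no
#' statistic; values are opaque strings compared only for equality.
#'
#' @param metadata Specimen metadata tibble with a `characters` list-column
#'   and a `deformed` flag (see [read_metadata()]).
#' @param partition A [as_partition()] over (a subset of) the metadata
#'   specimens.
#' @return A `character_report`: list with `stability` (tibble: `group`,
#'   `character`, `n`, `modal`, `stability`) and `diagnosability` (tibble:
#'   `group_a`, `group_b`, `character`, `diagnosable`).
#' @export
character_report <- function(metadata, partition) {
  partition <- as_partition_quiet(partition)
  missing_meta <- setdiff(partition$specimen_id, metadata$specimen_id)
  if (length(missing_meta) > 0) {
    stop_integrity(paste0("no metadata for: ",
                          paste(missing_meta, collapse = ", ")))
  }
  meta <- metadata[match(partition$specimen_id, metadata$specimen_id), ,
                   drop = FALSE]
  grp <- partition$group
  usable <- !meta$deformed
  long <- purrr::map2(meta$characters[usable], grp[usable], function(v, g) {
    if (length(v) == 0) return(NULL)
    tibble(group = g, character = names(v), value = unname(v))
  }) |>
    purrr::compact() |>
    dplyr::bind_rows()
  if (nrow(long) == 0) {
    warn("no morphological characters available; empty report")
    long <- tibble(group = character(0), character = character(0),
                   value = character(0))
  }
  stability <- long |>
    dplyr::group_by(.data$group, .data$character) |>
    dplyr::summarise(
      n = dplyr::n(),
      modal = names(sort(table(.data$value), decreasing = TRUE))[1],
      stability = max(table(.data$value)) / dplyr::n(),
      .groups = "drop")
  groups <- unique(partition$group)
  chars <- unique(long$character)
  value_sets <- long |>
    dplyr::group_by(.data$group, .data$character) |>
    dplyr::summarise(values = list(unique(.data$value)), .groups = "drop")
  diag_rows <- list()
  if (length(groups) >= 2 && length(chars) >= 1) {
    gp <- upper_pairs(length(groups))
    for (r in seq_len(nrow(gp))) {
      ga <- groups[gp[r, 1]]
      gb <- groups[gp[r, 2]]
      for (ch in chars) {
        va <- value_sets$values[value_sets$group == ga &
                                  value_sets$character == ch]
        vb <- value_sets$values[value_sets$group == gb &
                                  value_sets$character == ch]
        ok <- length(va) == 1 && length(vb) == 1 &&
          length(intersect(va[[1]], vb[[1]])) == 0
        diag_rows[[length(diag_rows) + 1L]] <-
          tibble(group_a = ga, group_b = gb, character = ch, diagnosable = ok)
      }
    }
  }
  diagnosability <- if (length(diag_rows) > 0) {
    dplyr::bind_rows(diag_rows)
  } else {
    tibble(group_a = character(0), group_b = character(0),
           character = character(0), diagnosable = logical(0))
  }
  structure(list(stability = stability, diagnosability = diagnosability,
                 groups = groups),
            class = "character_report")
}

#' @export
print.character_report <- function(x, ...) {
  cat(sprintf("<character report: %d groups, %d characters>\n",
              length(x$groups), dplyr::n_distinct(x$stability$character)))
  invisible(x)
}

#' Validate candidate species under the generalized lineage concept
#'
#' Combines three criteria per candidate cluster: (i) monophyly on the
#' phylogeny, (ii) congruence between molecular and geographic
#' delimitations, and (iii) reliable morphological diagnosis — stability at
#' least `stability_floor` on at least one character AND diagnosability
#' against every other cluster on at least one character. A cluster meeting
#' all three is a validated species; one meeting (i) and (ii) but not (iii)
#' shows morphological stasis and is flagged a cryptic species; anything
#' else stays unresolved. Trivial (size-1) monophyly counts as met;
#' unresolvable clusters do not.
#'
#' @param candidate The candidate partition the reports refer to.
#' @param monophyly A `monophyly_report` from [monophyly()].
#' @param congruence A `congruence_report` from [clusterwise_congruence()].
#' @param characters A `character_report` from [character_report()].
#' @param stability_floor Minimum within-cluster stability for a character
#'   to count as reliable (default 1: no intraspecific variation).
#' @return A `species_validation` tibble: `group`, `n`, `monophyletic`,
#'   `congruent`, `diagnosable`, `status` (`validated_species`,
#'   `cryptic_species`, `unresolved`).
#' @export
validate_species <- function(candidate, monophyly, congruence, characters,
                             stability_floor = 1) {
  candidate <- as_partition_quiet(candidate)
  groups <- unique(candidate$group)
  if (!setequal(groups, monophyly$group) ||
      !setequal(groups, congruence$clusters$group)) {
    stop_integrity("reports do not refer to the candidate partition's clusters")
  }
  sizes <- table(candidate$group)
  mono_ok <- setNames(monophyly$status %in% c("monophyletic", "trivial"),
                      monophyly$group)
  cong_ok <- setNames(congruence$clusters$congruent, congruence$clusters$group)
  stab <- characters$stability
  diagn <- characters$diagnosability
  morph_ok <- purrr::map_lgl(groups, function(g) {
    has_stable <- any(stab$group == g & stab$stability >= stability_floor &
                        stab$n > 0)
    if (!has_stable) return(FALSE)
    othergroups <- setdiff(groups, g)
    all(purrr::map_lgl(othergroups, function(o) {
      rows <- diagn[(diagn$group_a == g & diagn$group_b == o) |
                      (diagn$group_a == o & diagn$group_b == g), , drop = FALSE]
      any(rows$diagnosable)
    }))
  })
  morph_ok <- setNames(morph_ok, groups)
  status <- dplyr::case_when(
    mono_ok[groups] & cong_ok[groups] & morph_ok[groups] ~ "validated_species",
    mono_ok[groups] & cong_ok[groups] & !morph_ok[groups] ~ "cryptic_species",
    .default = "unresolved"
  )
  status <- unname(status)
  out <- tibble(group = groups,
                n = as.integer(sizes[groups]),
                monophyletic = unname(mono_ok[groups]),
                congruent = unname(cong_ok[groups]),
                diagnosable = unname(morph_ok[groups]),
                status = status)
  class(out) <- c("species_validation", class(out))
  out
}

#' @rdname validate_species
#' @param x A `species_validation` table.
#' @param ... Unused.
#' @export
glance.species_validation <- function(x, ...) {
  tibble(n_clusters = nrow(x),
         n_validated = sum(x$status == "validated_species"),
         n_cryptic = sum(x$status == "cryptic_species"),
         n_unresolved = sum(x$status == "unresolved"))
}
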