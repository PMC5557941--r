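#' K2P distance between two aligned sequences
#'
#' Computes the Kimura two-parameter distance with pairwise deletion: sites
#' where either sequence has a gap, `N` or other non-base are removed for
#' this pair only. Over the remaining comparable sites, with transition
#' proportion P (A<->G, C<->T) and transversion proportion Q,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param a,b Aligned sequences of equal length (strings or character
#'   vectors of single bases).
#' @return A one-row tibble with columns `distance`, `sites` (comparable
#'   sites used), `p_ts` and `p_tv`.
#' @examples
#' k2p_distance("AAAA", "AGAA")$distance # -log(0.5)/2
#' @export
k2p_distance <- function(a, b) {
  a <- as_base_vector(a)
  b <- as_base_vector(b)
  if (length(a) != length(b)) {
    abort("sequences differ in length", class = "bg_error_shape")
  }
  bases <- c("A", "C", "G", "T")
  ok <- (a %in% bases) & (b %in% bases)
  n <- sum(ok)
  if (n == 0) {
    abort("no comparable sites between the two sequences",
          class = "bg_error_incomparable")
  }
  aa <- a[ok]
  bb <- b[ok]
  diff <- aa != bb
  ts <- diff & ((aa == "A" & bb == "G") | (aa == "G" & bb == "A") |
                  (aa == "C" & bb == "T") | (aa == "T" & bb == "C"))
  p_ts <- sum(ts) / n
  p_tv <- sum(diff & !ts) / n
  w1 <- 1 - 2 * p_ts - p_tv
  w2 <- 1 - 2 * p_tv
  if (w1 <= 0 || w2 <= 0) {
    abort("K2P correction undefined (saturated pair)",
          class = "bg_error_saturation")
  }
  tibble(distance = -0.5 * log(w1) - 0.25 * log(w2),
         sites = n, p_ts = p_ts, p_tv = p_tv)
}

as_base_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1]]
  toupper(as.character(x))
}

#' All-pairs K2P distance matrix
#'
#' Computes every pairwise K2P distance of an alignment (pairwise deletion),
#' plus the per-pair count of comparable sites. Pairs whose correction is
#' undefined (saturation) or that share no comparable site get `NA` with a
#' row in the diagnostics table instead of crashing the run;
#' [cap_saturated()] can replace saturated pairs by the maximum observed
#' distance when the user opts in.
#'
#' @param alignment An [aligned_matrix()] with at least two specimens.
#' @return A `k2p_dist` object: list with `ids`, `d` (symmetric distance
#'   matrix, substitutions/site), `sites` (comparable-site counts) and
#'   `diagnostics` (tibble of problematic pairs).
#' @export
distance_matrix <- function(alignment) {
  if (!inherits(alignment, "aligned_matrix")) alignment <- aligned_matrix(alignment)
  x <- unclass(alignment)
  n <- nrow(x)
  if (n < 2L) abort("need at least 2 specimens", class = "bg_error_size")
  mA <- (x == "A") * 1
  mC <- (x == "C") * 1
  mG <- (x == "G") * 1
  mT <- (x == "T") * 1
  V <- mA + mC + mG + mT
  sites <- tcrossprod(V)
  match_ <- tcrossprod(mA) + tcrossprod(mC) + tcrossprod(mG) + tcrossprod(mT)
  ts <- mA %*% t(mG) + mG %*% t(mA) + mC %*% t(mT) + mT %*% t(mC)
  tv <- sites - match_ - ts
  P <- ts / sites
  Q <- tv / sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- suppressWarnings(-0.5 * log(w1) - 0.25 * log(w2))
  incomparable <- sites == 0
  saturated <- !incomparable & (w1 <= 0 | w2 <= 0)
  d[incomparable | saturated] <- NA_real_
  diag(d) <- 0
  diag(saturated) <- FALSE
  diag(incomparable) <- FALSE
  ids <- rownames(x)
  dimnames(d) <- dimnames(sites) <- list(ids, ids)
  pr <- upper_pairs(n)
  bad <- incomparable[pr] | saturated[pr]
  diagnostics <- tibble(
    id_a = ids[pr[bad, 1]],
    id_b = ids[pr[bad, 2]],
    type = ifelse(incomparable[pr][bad], "incomparable", "saturated")
  )
  structure(list(ids = ids, d = d, sites = sites, diagnostics = diagnostics),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("<K2P distances: %d specimens, %d pairs, %d flagged>\n",
              length(x$ids), choose(length(x$ids), 2), nrow(x$diagnostics)))
  invisible(x)
}

#' @rdname distance_matrix
#' @param dm A `k2p_dist` object.
#' @export
cap_saturated <- function(dm) {
  sat <- dm$diagnostics$type == "saturated"
  if (any(sat)) {
    cap <- max(dm$d, na.rm = TRUE)
    for (i in which(sat)) {
      a <- dm$diagnostics$id_a[i]
      b <- dm$diagnostics$id_b[i]
      dm$d[a, b] <- dm$d[b, a] <- cap
    }
    inform(sprintf("%d saturated pair(s) capped at max observed distance %.4f",
                   sum(sat), cap))
    dm$diagnostics <- dm$diagnostics[!sat, , drop = FALSE]
  }
  dm
}

#' @rdname distance_matrix
#' @export
tidy.k2p_dist <- function(x, ...) {
  pr <- upper_pairs(length(x$ids))
  tibble(id_a = x$ids[pr[, 1]],
         id_b = x$ids[pr[, 2]],
         distance = x$d[pr],
         sites = x$sites[pr])
}

# sorted vector of pairwise distances among a subset of specimens
pairwise_distances <- function(dm, ids = NULL) {
  d <- dm$d
  if (!is.null(ids)) d <- d[ids, ids, drop = FALSE]
  v <- d[upper.tri(d)]
  sort(v, na.last = TRUE)
}

subset_dist <- function(dm, ids) {
  structure(list(ids = ids,
                 d = dm$d[ids, ids, drop = FALSE],
                 sites = dm$sites[ids, ids, drop = FALSE],
                 diagnostics = dm$diagnostics[dm$diagnostics$id_a %in% ids &
                                                dm$diagnostics$id_b %in% ids, ,
                                              drop = FALSE]),
            class = "k2p_dist")
}

#' Pooled intra- and interspecific distance summary
#'
#' Pools all within-group pairs (intraspecific) and all between-group pairs
#' (interspecific) of a partition and reports mean/min/max of each, plus the
#' per-group maximum divergence. Groups of size one contribute no
#' intraspecific pairs; when a side has no pairs its statistics are `NA` and
#' flagged.
#'
#' @param dm A `k2p_dist` object from [distance_matrix()].
#' @param partition A [as_partition()] covering the matrix specimens.
#' @return A tibble with one row per side (`intra`, `inter`): `n_pairs`,
#'   `mean`, `min`, `max` (substitutions/site) and `defined`. Per-group
#'   maxima are attached as attribute `"per_group_max"`.
#' @export
summarize_distances <- function(dm, partition) {
  partition <- as_partition_quiet(partition)
  if (!setequal(partition$specimen_id, dm$ids)) {
    stop_integrity("partition and distance matrix cover different specimens")
  }
  grp <- partition_lookup(partition)[dm$ids]
  pr <- upper_pairs(length(dm$ids))
  dist <- dm$d[pr]
  intra <- grp[pr[, 1]] == grp[pr[, 2]]
  side_stats <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      tibble(n_pairs = 0L, mean = NA_real_, min = NA_real_, max = NA_real_,
             defined = FALSE)
    } else {
      tibble(n_pairs = length(v), mean = mean(v), min = min(v), max = max(v),
             defined = TRUE)
    }
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(side_stats(dist[intra]), type = "intra", .before = 1),
    dplyr::mutate(side_stats(dist[!intra]), type = "inter", .before = 1)
  )
  intra_tbl <- tibble(group = unname(grp[pr[intra, 1]]),
                      distance = dist[intra]) |>
    dplyr::filter(!is.na(.data$distance))
  per_group <- if (nrow(intra_tbl) == 0) {
    tibble(group = character(0), max = numeric(0))
  } else {
    dplyr::summarise(dplyr::group_by(intra_tbl, .data$group),
                     max = max(.data$distance), .groups = "drop")
  }
  attr(out, "per_group_max") <- per_group
  out
}

#' Histogram of pairwise distances
#'
#' Equal-width bins over `[0, max distance]`; counts sum to the number of
#' pairs. The default 40 bins matches the graphic convention for inspecting
#' the barcode gap.
#'
#' @param dm A `k2p_dist` object.
#' @param bins Number of bins (positive integer, default 40).
#' @return A tibble with columns `bin`, `lower`, `upper`, `count`.
#' @export
distance_histogram <- function(dm, bins = 40) {
  if (length(bins) != 1 || is.na(bins) || bins < 1) {
    stop_parameter("`bins` must be a positive integer")
  }
  bins <- as.integer(bins)
  v <- dm$d[upper.tri(dm$d)]
  if (anyNA(v)) {
    warn(sprintf("%d flagged pair(s) omitted from histogram", sum(is.na(v))))
    v <- v[!is.na(v)]
  }
  if (length(v) == 0) abort("no pairs to histogram", class = "bg_error_empty")
  upper <- max(v)
  width <- if (upper > 0) upper / bins else 1
  idx <- pmin(pmax(ceiling(v / width), 1L), bins)
  edges <- seq(0, by = width, length.out = bins + 1L)
  tibble(bin = seq_len(bins),
         lower = edges[-(bins + 1L)],
         upper = edges[-1L],
         count = tabulate(idx, nbins = bins))
}

#' @rdname distance_histogram
#' @param object A `k2p_dist` object.
#' @param ... Passed on (unused).
#' @export
autoplot.k2p_dist <- function(object, bins = 40, ...) {
  h <- distance_histogram(object, bins = bins)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = (h$upper[1] - h$lower[1]) * 0.95) +
    ggplot2::labs(x = "K2P distance (substitutions/site)",
                  y = "specimen pairs",
                  title = "Pairwise distance histogram")
}

#' Write a distance matrix as square TSV
#'
#' @param dm A `k2p_dist` object.
#' @param path Output path (tab-separated, specimen ids as first row/column).
#' @export
write_distance_matrix <- function(dm, path) {
  df <- as.data.frame(dm$d)
  df <- cbind(specimen_id = dm$ids, df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
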