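#' Locate the barcode gap in a sorted distance list
#'
#' Scans the ranked pairwise distances for gaps significantly wider than
#' the local background, starting from the last rank at or below the prior
#' intraspecific divergence. At rank `i` the gap is `g_i = d_(i+1) - d_(i)`
#' and the local reference `r_i` is the mean of up to `window` preceding
#' rank gaps; a rank is significant when `g_i > gap_width * r_i` and
#' `g_i > 0`. The threshold is the midpoint of the *widest* significant gap,
#' `t = (d_(i) + d_(i+1)) / 2` — taking the widest rather than the first
#' significant gap keeps the detected barcode gap stable across priors
#' instead of latching onto sampling noise among low intraspecific ranks.
#' Ranks with no preceding gap carry no reference and are skipped.
#'
#' @param distances Numeric vector of pairwise distances (sorted internally).
#' @param prior Prior maximum intraspecific divergence P.
#' @param gap_width Relative gap width X: a gap must exceed `X` times the
#'   local mean gap to count (default 1).
#' @param window Number of preceding rank gaps averaged into the local
#'   reference (default 10).
#' @return The threshold `t`, or `NA_real_` when no significant gap exists.
#' @examples
#' find_gap_threshold(c(0.005, 0.006, 0.007, 0.10, 0.11), prior = 0.01)
#' @export
find_gap_threshold <- function(distances, prior, gap_width = 1, window = 10) {
  if (length(distances) == 0) {
    abort("no distances to scan", class = "bg_error_empty")
  }
  if (anyNA(distances)) {
    stop_integrity("distances contain NA; resolve or cap flagged pairs first")
  }
  if (gap_width <= 0 || window < 1) {
    stop_parameter("`gap_width` must be > 0 and `window` >= 1")
  }
  d <- sort(distances)
  m <- length(d)
  if (m == 1L) return(NA_real_)
  g <- diff(d)
  i0 <- sum(d <= prior)
  start <- max(i0, 1L)
  if (start > m - 1L) return(NA_real_)
  best <- 0L
  for (i in start:(m - 1L)) {
    if (g[i] <= 0) next
    if (i == 1L) next # no preceding gaps: local reference undefined
    r <- mean(g[seq.int(max(1L, i - window), i - 1L)])
    # strict inequality up to float noise: a gap exactly matching the local
    # reference (uniform ladder) is not a barcode gap
    if (g[i] > gap_width * r * (1 + 1e-9) + 1e-12 &&
        (best == 0L || g[i] > g[best])) {
      best <- i
    }
  }
  if (best == 0L) return(NA_real_)
  (d[best] + d[best + 1L]) / 2
}

#' Partition specimens by a distance threshold
#'
#' Connectivity (single-linkage) clustering: specimens are joined whenever
#' their distance is at most `t`, groups are the connected components, and
#' labels `G1..Gk` follow the order of each group's first member, so results
#' are deterministic for a fixed input order.
#'
#' @param dm A `k2p_dist` object from [distance_matrix()].
#' @param threshold Distance threshold `t >= 0`.
#' @return A [as_partition()] with attribute `threshold`.
#' @export
partition_at_threshold <- function(dm, threshold) {
  if (is.na(threshold) || threshold < 0) {
    stop_parameter("`threshold` must be a non-negative number")
  }
  comp <- single_linkage_components(dm$d, threshold)
  p <- as_partition(tibble(specimen_id = dm$ids, group = paste0("G", comp)),
                    source = sprintf("gapdelim:t=%.5g", threshold))
  attr(p, "threshold") <- threshold
  p
}

#' Primary barcode-gap partition
#'
#' One application of gap detection on the full ranked distance list,
#' followed by connectivity clustering at the detected threshold. When no
#' significant gap exists the prior itself is used as the threshold (the
#' fallback is recorded in the `fallback` attribute), keeping the prior scan
#' total.
#'
#' @inheritParams partition_at_threshold
#' @inheritParams find_gap_threshold
#' @return A [as_partition()] with attributes `threshold`, `fallback`, `prior`.
#' @export
primary_partition <- function(dm, prior, gap_width = 1, window = 10) {
  t <- find_gap_threshold(pairwise_distances(dm), prior,
                          gap_width = gap_width, window = window)
  fallback <- is.na(t)
  if (fallback) t <- prior
  p <- partition_at_threshold(dm, t)
  attr(p, "fallback") <- fallback
  attr(p, "prior") <- prior
  attr(p, "source") <- sprintf("gapdelim:primary:P=%.5g", prior)
  p
}

#' Recursive barcode-gap partition
#'
#' Starts from the primary partition and re-applies gap detection inside
#' every group of three or more specimens, splitting at any within-group gap
#' found, until no group splits or `max_rounds` is reached. The result is
#' always a refinement of the primary partition (recursion only splits).
#'
#' @inheritParams primary_partition
#' @param max_rounds Cap on recursion rounds (default 20).
#' @return A [as_partition()] refining `primary_partition(dm, prior, ...)`.
#' @export
recursive_partition <- function(dm, prior, gap_width = 1, window = 10,
                                max_rounds = 20) {
  if (max_rounds < 1) stop_parameter("`max_rounds` must be >= 1")
  part <- primary_partition(dm, prior, gap_width = gap_width, window = window)
  assign <- partition_lookup(part)
  for (round in seq_len(max_rounds)) {
    changed <- FALSE
    for (gname in unique(assign)) {
      ids <- names(assign)[assign == gname]
      if (length(ids) < 3L) next
      sub <- dm$d[ids, ids, drop = FALSE]
      subd <- sub[upper.tri(sub)]
      t2 <- find_gap_threshold(subd, prior, gap_width = gap_width,
                               window = window)
      if (is.na(t2)) next
      comp <- single_linkage_components(sub, t2)
      if (max(comp) > 1L) {
        assign[ids] <- paste0(gname, ".", comp)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p <- as_partition(tibble(specimen_id = dm$ids, group = unname(assign[dm$ids])),
                    source = sprintf("gapdelim:recursive:P=%.5g", prior))
  p <- relabel_groups(p)
  attr(p, "source") <- sprintf("gapdelim:recursive:P=%.5g", prior)
  attr(p, "prior") <- prior
  p
}

#' Scan barcode-gap partitions over a grid of priors
#'
#' Computes primary and recursive gap partitions at each of `n_priors`
#' log-spaced prior intraspecific divergences between `p_min` and `p_max`,
#' detects plateaus (maximal runs of consecutive priors with equal primary
#' group count), and selects the primary partition of the widest plateau —
#' primary partitions being stable over a wider prior range than recursive
#' ones. Ties go to the plateau at larger priors, and the selected partition
#' is the one at the largest prior of that plateau.
#'
#' @inheritParams primary_partition
#' @param p_min,p_max Prior grid bounds (defaults 0.001 and 0.14).
#' @param n_priors Grid size (default 20, log-spaced).
#' @param max_rounds Recursion cap per prior (default 20).
#' @return A `prior_scan` object: list with `scan` (tibble: `prior`,
#'   `threshold`, `fallback`, `primary_k`, `recursive_k`, `plateau_id`),
#'   `plateaus`, `partitions` (per-prior primary and recursive lists),
#'   `selected` (the chosen partition) and `selected_plateau`.
#' @export
prior_scan <- function(dm, p_min = 0.001, p_max = 0.14, n_priors = 20,
                       gap_width = 1, window = 10, max_rounds = 20) {
  if (!(p_min > 0 && p_min < p_max && p_max < 0.75)) {
    stop_parameter("need 0 < p_min < p_max < 0.75")
  }
  if (n_priors < 2) stop_parameter("`n_priors` must be >= 2")
  priors <- p_min * (p_max / p_min)^((seq_len(n_priors) - 1) / (n_priors - 1))
  primary <- purrr::map(priors, function(p) {
    primary_partition(dm, p, gap_width = gap_width, window = window)
  })
  recursive <- purrr::map(priors, function(p) {
    recursive_partition(dm, p, gap_width = gap_width, window = window,
                        max_rounds = max_rounds)
  })
  scan <- tibble(
    prior = priors,
    threshold = purrr::map_dbl(primary, ~ attr(.x, "threshold")),
    fallback = purrr::map_lgl(primary, ~ attr(.x, "fallback")),
    primary_k = purrr::map_int(primary, partition_k),
    recursive_k = purrr::map_int(recursive, partition_k)
  )
  pl <- plateau_table(scan$primary_k)
  scan$plateau_id <- rep.int(pl$plateau_id, pl$width)
  sel_id <- select_widest_plateau(pl)
  sel_idx <- pl$end[sel_id] # largest prior of the selected plateau
  structure(list(scan = scan,
                 plateaus = pl,
                 partitions = list(primary = primary, recursive = recursive),
                 selected = primary[[sel_idx]],
                 selected_plateau = sel_id,
                 selected_prior = priors[sel_idx]),
            class = "prior_scan")
}

# maximal runs of equal k over the grid; disjoint and covering
plateau_table <- function(k) {
  r <- rle(k)
  end <- cumsum(r$lengths)
  tibble(plateau_id = seq_along(r$values),
         k = r$values,
         start = end - r$lengths + 1L,
         end = end,
         width = r$lengths)
}

# widest plateau; tie -> the plateau at larger priors
select_widest_plateau <- function(pl) {
  w <- pl$width
  max(which(w == max(w)))
}

#' @export
print.prior_scan <- function(x, ...) {
  cat(sprintf("<prior scan: %d priors, selected k = %d (plateau %d, width %d)>\n",
              nrow(x$scan), partition_k(x$selected), x$selected_plateau,
              x$plateaus$width[x$selected_plateau]))
  invisible(x)
}

#' @rdname prior_scan
#' @param x,object A `prior_scan` object.
#' @param ... Unused.
#' @export
tidy.prior_scan <- function(x, ...) x$scan

#' @rdname prior_scan
#' @export
glance.prior_scan <- function(x, ...) {
  tibble(n_priors = nrow(x$scan),
         selected_k = partition_k(x$selected),
         selected_prior = x$selected_prior,
         selected_plateau_width = x$plateaus$width[x$selected_plateau],
         n_plateaus = nrow(x$plateaus))
}

#' @rdname prior_scan
#' @export
autoplot.prior_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(object$scan,
                              c("primary_k", "recursive_k"),
                              names_to = "pass", values_to = "k")
  long$pass <- sub("_k$", "", long$pass)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$prior, y = .data$k,
                                     colour = .data$pass)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = object$selected_prior, linetype = 2) +
    ggplot2::labs(x = "prior intraspecific divergence P",
                  y = "groups (k)",
                  colour = NULL,
                  title = "Barcode-gap partitions across priors")
}
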