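#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorised over
#' coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Decimal-degree coordinates (latitude in
#'   \[-90, 90\], longitude in \[-180, 180\]).
#' @return Distance in kilometres.
#' @examples
#' haversine_km(0, 0, 1, 0) # one degree of latitude, ~111.195 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    abort("coordinates out of range", class = "bg_error_range")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371.0088)
}

#' Assemble populations from collection sites
#'
#' A population is a set of individuals collected from sites connected by
#' chains of links of at most `link_km` kilometres (single linkage; default
#' 5 km). Because delimitation treats populations within one morphospecies,
#' populations are formed per (locality, morphospecies) by default: a
#' locality is a 5 km site cluster, and specimens of different morphospecies
#' co-occurring at a locality fall into different populations. Set
#' `by_morphospecies = FALSE` to get plain localities (mixtures are then
#' reported in the `morphospecies` column as comma-joined labels).
#'
#' @param metadata Specimen metadata tibble (see [read_metadata()]).
#' @param link_km Maximum site-to-site link distance in kilometres
#'   (default 5).
#' @param by_morphospecies Split localities by morphospecies label
#'   (default `TRUE`).
#' @return A `populations` tibble: `population_id`, `locality`,
#'   `morphospecies`, `n_specimens`, `specimen_ids` (list), `sites`
#'   (list of site tibbles). Specimens without coordinates are excluded with
#'   a warning and listed in attribute `"excluded"`.
#' @export
assemble_populations <- function(metadata, link_km = 5,
                                 by_morphospecies = TRUE) {
  if (link_km <= 0) stop_parameter("`link_km` must be positive")
  no_coord <- is.na(metadata$latitude) | is.na(metadata$longitude)
  if (any(no_coord)) {
    warn(paste0("excluding specimens without coordinates: ",
                paste(metadata$specimen_id[no_coord], collapse = ", ")))
  }
  meta <- metadata[!no_coord, , drop = FALSE]
  if (nrow(meta) == 0) abort("no specimens with coordinates",
                             class = "bg_error_empty")
  sites <- dplyr::distinct(meta, .data$site_id, .data$latitude, .data$longitude)
  if (anyDuplicated(sites$site_id)) {
    stop_integrity("a site_id maps to more than one coordinate pair")
  }
  n <- nrow(sites)
  dmat <- matrix(0, n, n)
  if (n > 1) {
    pr <- upper_pairs(n)
    dv <- haversine_km(sites$latitude[pr[, 1]], sites$longitude[pr[, 1]],
                       sites$latitude[pr[, 2]], sites$longitude[pr[, 2]])
    dmat[pr] <- dv
    dmat[pr[, 2:1, drop = FALSE]] <- dv
  }
  sites$locality <- paste0("L", single_linkage_components(dmat, link_km))
  meta <- dplyr::left_join(meta, sites[c("site_id", "locality")], by = "site_id")
  keys <- if (by_morphospecies) c("locality", "morphospecies") else "locality"
  pops <- meta |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_specimens = dplyr::n(),
      specimen_ids = list(.data$specimen_id),
      sites = list(dplyr::distinct(dplyr::pick("site_id", "latitude",
                                               "longitude"))),
      .groups = "drop"
    )
  if (!by_morphospecies) {
    msp <- meta |>
      dplyr::group_by(.data$locality) |>
      dplyr::summarise(
        morphospecies = paste(sort(unique(.data$morphospecies)), collapse = ","),
        .groups = "drop")
    pops <- dplyr::left_join(pops, msp, by = "locality")
  }
  # deterministic ids: order of first member specimen in input order
  first <- purrr::map_int(pops$specimen_ids, ~ min(match(.x, meta$specimen_id)))
  pops <- pops[order(first), , drop = FALSE]
  pops$population_id <- sprintf("P%02d", seq_len(nrow(pops)))
  pops <- dplyr::relocate(pops, "population_id")
  attr(pops, "excluded") <- metadata$specimen_id[no_coord]
  class(pops) <- c("populations", class(pops))
  pops
}

# population x population distance matrix for one set of populations
population_distances <- function(pops, method = c("min", "centroid")) {
  method <- match.arg(method)
  n <- nrow(pops)
  dmat <- matrix(0, n, n)
  if (n < 2) return(dmat)
  coords <- purrr::map(pops$sites, ~ cbind(.x$latitude, .x$longitude))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (method == "min") {
        a <- coords[[i]]
        b <- coords[[j]]
        idx <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
        dij <- min(haversine_km(a[idx$ia, 1], a[idx$ia, 2],
                                b[idx$ib, 1], b[idx$ib, 2]))
      } else {
        dij <- haversine_km(mean(coords[[i]][, 1]), mean(coords[[i]][, 2]),
                            mean(coords[[j]][, 1]), mean(coords[[j]][, 2]))
      }
      dmat[i, j] <- dmat[j, i] <- dij
    }
  }
  dmat
}

#' Geographic species delimitation at a distance threshold
#'
#' Within each morphospecies, populations separated by more than
#' `threshold_km` kilometres are recognised as distinct putative species.
#' With `linkage = "single"` (default) populations chain: two populations
#' farther apart than the threshold still merge through an intermediate
#' population within threshold of both. `linkage = "complete"` instead
#' requires every population pair of a putative species to lie within the
#' threshold. Morphospecies are never merged — geography only refines the
#' morphospecies partition.
#'
#' @param populations A `populations` tibble from [assemble_populations()].
#' @param threshold_km Distance threshold in kilometres.
#' @param linkage `"single"` (chaining, default) or `"complete"`.
#' @param distance Inter-population distance: `"min"` over member-site pairs
#'   (default, conservative merging) or `"centroid"`.
#' @return A [as_partition()] over all member specimens; group labels are
#'   `<morphospecies>_<i>`.
#' @export
geo_delimit <- function(populations, threshold_km,
                        linkage = c("single", "complete"),
                        distance = c("min", "centroid")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  if (threshold_km <= 0) stop_parameter("`threshold_km` must be positive")
  if (anyNA(populations$morphospecies) ||
      any(populations$morphospecies == "")) {
    stop_integrity("every population must carry a morphospecies label")
  }
  rows <- list()
  for (msp in unique(populations$morphospecies)) {
    sub <- populations[populations$morphospecies == msp, , drop = FALSE]
    dmat <- population_distances(sub, method = distance)
    comp <- if (linkage == "single" || nrow(sub) == 1) {
      single_linkage_components(dmat, threshold_km)
    } else {
      hc <- stats::hclust(stats::as.dist(dmat), method = "complete")
      cl <- stats::cutree(hc, h = threshold_km)
      match(cl, unique(cl))
    }
    for (i in seq_len(nrow(sub))) {
      rows[[length(rows) + 1L]] <- tibble(
        specimen_id = sub$specimen_ids[[i]],
        group = sprintf("%s_%d", msp, comp[i])
      )
    }
  }
  as_partition(dplyr::bind_rows(rows),
               source = sprintf("geo:%gkm:%s", threshold_km, linkage))
}

#' Scan geographic delimitation across distance thresholds
#'
#' Applies [geo_delimit()] at each threshold and summarises the number of
#' putative species per threshold, with plateau structure (runs of equal
#' counts). Under single linkage the count is non-increasing in the
#' threshold; a violation (possible only under complete linkage) is
#' reported, not hidden.
#'
#' @inheritParams geo_delimit
#' @param thresholds_km Ascending positive thresholds in kilometres
#'   (default `c(10, 20, 50, 100, 200, 300, 400, 500)`).
#' @return A `geo_scan` object: list with `scan` (tibble: `threshold_km`,
#'   `k`, `plateau_id`), `plateaus` and `partitions`.
#' @export
geo_scan <- function(populations,
                     thresholds_km = c(10, 20, 50, 100, 200, 300, 400, 500),
                     linkage = c("single", "complete"),
                     distance = c("min", "centroid")) {
  if (any(thresholds_km <= 0) || is.unsorted(thresholds_km, strictly = TRUE)) {
    stop_parameter("`thresholds_km` must be positive and strictly ascending")
  }
  parts <- purrr::map(thresholds_km, function(t) {
    geo_delimit(populations, t, linkage = linkage, distance = distance)
  })
  k <- purrr::map_int(parts, partition_k)
  if (any(diff(k) > 0)) {
    warn("putative-species count increased with the threshold (non-monotone)")
  }
  pl <- plateau_table(k)
  structure(list(scan = tibble(threshold_km = thresholds_km, k = k,
                               plateau_id = rep.int(pl$plateau_id, pl$width)),
                 plateaus = pl,
                 partitions = setNames(parts, paste0(thresholds_km, "km"))),
            class = "geo_scan")
}

#' @export
print.geo_scan <- function(x, ...) {
  cat("<geo scan>\n")
  print(x$scan)
  invisible(x)
}

#' @rdname geo_scan
#' @param x,object A `geo_scan` object.
#' @param ... Unused.
#' @export
tidy.geo_scan <- function(x, ...) x$scan

#' @rdname geo_scan
#' @export
autoplot.geo_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(x = .data$threshold_km, y = .data$k)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance threshold (km)", y = "putative species (k)",
                  title = "Geographic delimitation across thresholds")
}
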