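#' Simulate a barcode dataset with planted species truth
#'
#' Generates an aligned barcode matrix, specimen metadata and ground truth
#' under a K80 substitution process with a star genealogy inside each
#' species:
#'
#' 1. a root sequence is drawn uniformly over `{A,C,G,T}^L`;
#' 2. each species ancestor diverges from the root along its own branch,
#'    drawn so that the expected pairwise divergence between individuals of
#'    different species falls inside
#'    `inter_divergence`; the realised barcode gap (max pooled intraspecific
#'    distance < min interspecific distance) is asserted, regenerating up to
#'    `max_attempts` times;
#' 3. each individual adds `Poisson(L * intra_divergence / 2)` K80
#'    substitutions to its species ancestor, so expected within-species
#'    pairwise divergence is about `intra_divergence`;
#' 4. species range centres are placed at least `2 * range_radius_km` apart
#'    (rejection sampling) inside the bounding box, populations are
#'    scattered within the range radius, and widespread species get extra
#'    centres more than 100 km apart; alternatively `locality_map` pins
#'    species to shared localities;
#' 5. every species carries one categorical value per character; cryptic
#'    pairs share all values; morphospecies labels come from the lumping
#'    map; deformed specimens (i.i.d. at `deformed_rate`) get an aberrant,
#'    one-sided variant of the first character.
#'
#' All randomness flows from `seed`; the same seed reproduces the dataset
#' byte for byte.
#'
#' @param n_species Number of true species (default 22).
#' @param n_individuals Total individuals, spread as evenly as possible
#'   across species (default 144).
#' @param seq_length Alignment length L in sites (default 658).
#' @param kappa Transition/transversion rate ratio of the K80 process
#'   (default 4).
#' @param intra_divergence Target expected pooled within-species K2P
#'   distance (default 0.02).
#' @param inter_divergence Range of expected between-ancestor K2P distances
#'   (default `c(0.09, 0.20)`).
#' @param bbox Named vector `lat_min, lat_max, lon_min, lon_max` in decimal
#'   degrees (default a roughly 1000 km continental box).
#' @param range_radius_km Radius of each species' range (default 30).
#' @param pops_per_species Populations per species in default placement
#'   (default 1).
#' @param widespread_species How many species get a second range centre
#'   more than 100 km away (default 0).
#' @param cryptic_pairs Number of species pairs sharing all character
#'   values, or a list of explicit index pairs (default 0).
#' @param morphospecies_lumping Optional named list: morphospecies label ->
#'   integer vector of species indices. Defaults to one morphospecies per
#'   species.
#' @param n_characters Number of discrete characters (default 3).
#' @param deformed_rate Probability a specimen is deformed (default 0.05).
#' @param gap_rate Fraction of alignment cells masked to `-` (default 0).
#' @param two_clade_species How many species split internally into two
#'   subclades with extra divergence, pushing intraspecific distances
#'   towards 4-6% (default 0).
#' @param locality_map Optional list (length `n_species`) of locality
#'   indices per species; localities are shared points placed at least
#'   `locality_min_km` apart, and localities of one species at least 100 km
#'   apart.
#' @param locality_min_km Minimum locality separation used with
#'   `locality_map` (default 60).
#' @param seed Optional integer seed.
#' @param max_attempts Regeneration cap for the barcode-gap assertion and
#'   rejection placements (default 25).
#' @return A `delim_sim` list: `alignment` ([aligned_matrix()]), `metadata`
#'   (tibble as in [read_metadata()]), `truth` (list: `partition`,
#'   `cryptic_pairs`, `widespread`, `centers`, `config`, `attempts`).
#' @export
simulate_dataset <- function(n_species = 22,
                             n_individuals = 144,
                             seq_length = 658,
                             kappa = 4,
                             intra_divergence = 0.02,
                             inter_divergence = c(0.09, 0.20),
                             bbox = c(lat_min = 40, lat_max = 50,
                                      lon_min = 120, lon_max = 132),
                             range_radius_km = 30,
                             pops_per_species = 1,
                             widespread_species = 0,
                             cryptic_pairs = 0,
                             morphospecies_lumping = NULL,
                             n_characters = 3,
                             deformed_rate = 0.05,
                             gap_rate = 0,
                             two_clade_species = 0,
                             locality_map = NULL,
                             locality_min_km = 60,
                             seed = NULL,
                             max_attempts = 25) {
  if (n_species < 1 || n_individuals < n_species) {
    abort("need n_individuals >= n_species >= 1", class = "bg_error_config")
  }
  if (intra_divergence >= inter_divergence[1]) {
    abort("intra_divergence must be below min(inter_divergence)",
          class = "bg_error_config")
  }
  with_seed_if(seed, {
    species <- sprintf("SP%02d", seq_len(n_species))
    sizes <- species_sizes(n_species, n_individuals)
    cpairs <- resolve_cryptic_pairs(cryptic_pairs, n_species)
    seqs <- simulate_sequences(n_species, sizes, seq_length, kappa,
                               intra_divergence, inter_divergence,
                               two_clade_species, max_attempts)
    geo <- if (is.null(locality_map)) {
      place_default_geography(n_species, sizes, bbox, range_radius_km,
                              pops_per_species, widespread_species,
                              max_attempts)
    } else {
      place_locality_geography(sizes, locality_map, bbox, locality_min_km,
                               max_attempts)
    }
    msp <- morphospecies_labels(species, morphospecies_lumping)
    chars <- species_characters(n_species, n_characters, cpairs)
    specimen_species <- rep.int(seq_len(n_species), sizes)
    specimen_id <- unlist(lapply(seq_len(n_species), function(s) {
      sprintf("%s_i%02d", species[s], seq_len(sizes[s]))
    }))
    deformed <- stats::runif(n_individuals) < deformed_rate
    characters <- lapply(seq_len(n_individuals), function(i) {
      v <- chars[[specimen_species[i]]]
      if (deformed[i] && length(v) > 0) {
        v[1] <- paste0(v[1], "|asym") # one-sided aberration
      }
      v
    })
    aln_chr <- seqs$matrix
    if (gap_rate > 0) {
      mask <- stats::runif(length(aln_chr)) < gap_rate
      aln_chr[mask] <- "-"
    }
    rownames(aln_chr) <- specimen_id
    metadata <- tibble(
      specimen_id = specimen_id,
      site_id = geo$site_id,
      latitude = geo$latitude,
      longitude = geo$longitude,
      morphospecies = msp[specimen_species],
      deformed = deformed,
      characters = characters
    )
    truth <- list(
      partition = as_partition(tibble(specimen_id = specimen_id,
                                      group = species[specimen_species]),
                               source = "truth"),
      cryptic_pairs = lapply(cpairs, function(p) species[p]),
      widespread = geo$widespread,
      centers = geo$centers,
      attempts = seqs$attempts,
      config = list(n_species = n_species, n_individuals = n_individuals,
                    seq_length = seq_length, kappa = kappa,
                    intra_divergence = intra_divergence,
                    inter_divergence = inter_divergence,
                    range_radius_km = range_radius_km,
                    deformed_rate = deformed_rate, seed = seed)
    )
    structure(list(alignment = aligned_matrix(aln_chr),
                   metadata = metadata,
                   truth = truth),
              class = "delim_sim")
  })
}

#' @export
print.delim_sim <- function(x, ...) {
  cat(sprintf("<simulated dataset: %d specimens, %d true species, %d localities>\n",
              nrow(x$metadata), partition_k(x$truth$partition),
              dplyr::n_distinct(x$metadata$site_id)))
  invisible(x)
}

species_sizes <- function(n_species, n_individuals) {
  base <- n_individuals %/% n_species
  rem <- n_individuals %% n_species
  c(rep.int(base + 1L, rem), rep.int(base, n_species - rem))
}

resolve_cryptic_pairs <- function(cryptic_pairs, n_species) {
  if (is.list(cryptic_pairs)) {
    lapply(cryptic_pairs, as.integer)
  } else if (cryptic_pairs > 0) {
    if (2 * cryptic_pairs > n_species) {
      abort("too many cryptic pairs for n_species", class = "bg_error_config")
    }
    lapply(seq_len(cryptic_pairs), function(i) c(2L * i - 1L, 2L * i))
  } else {
    list()
  }
}

# K80 substitution events applied in place to an integer-coded sequence
# (1=A, 2=C, 3=G, 4=T); transitions 1<->3, 2<->4 with prob kappa/(kappa+2).
mutate_k80 <- function(seq_int, n_events, kappa) {
  if (n_events == 0) return(seq_int)
  sites <- sample.int(length(seq_int), n_events, replace = TRUE)
  is_ts <- stats::runif(n_events) < kappa / (kappa + 2)
  ts_map <- c(3L, 4L, 1L, 2L)
  for (e in seq_len(n_events)) {
    s <- sites[e]
    cur <- seq_int[s]
    seq_int[s] <- if (is_ts[e]) {
      ts_map[cur]
    } else {
      # one of the two transversion targets, uniformly
      tv <- if (cur %in% c(1L, 3L)) c(2L, 4L) else c(1L, 3L)
      tv[sample.int(2L, 1L)]
    }
  }
  seq_int
}

simulate_sequences <- function(n_species, sizes, L, kappa, intra, inter,
                               two_clade_species, max_attempts) {
  bases <- c("A", "C", "G", "T")
  for (attempt in seq_len(max_attempts)) {
    root <- sample.int(4L, L, replace = TRUE)
    # tip-to-tip divergence between species is ~ b_i + b_j + intra (each tip
    # adds intra/2). The lower branch bound keeps ancestor pairs at or above
    # the configured floor; the upper bound nets out the within-species
    # contribution so tip pairs stay inside the configured range.
    branch <- stats::runif(n_species, inter[1] / 2,
                           max(inter[1], inter[2] - intra) / 2)
    ancestors <- lapply(branch, function(b) {
      mutate_k80(root, stats::rpois(1L, L * b), kappa)
    })
    rows <- list()
    for (s in seq_len(n_species)) {
      anc <- ancestors[[s]]
      sub_anc <- NULL
      if (s <= two_clade_species) {
        sub_anc <- mutate_k80(anc, stats::rpois(1L, L * intra), kappa)
      }
      for (i in seq_len(sizes[s])) {
        start <- if (!is.null(sub_anc) && i > sizes[s] %/% 2L) sub_anc else anc
        rows[[length(rows) + 1L]] <-
          mutate_k80(start, stats::rpois(1L, L * intra / 2), kappa)
      }
    }
    m <- matrix(bases[do.call(rbind, rows)], nrow = length(rows))
    # assert the planted barcode gap on realised distances
    dm <- distance_matrix(structure(
      `rownames<-`(m, sprintf("x%03d", seq_len(nrow(m)))),
      class = c("aligned_matrix", "matrix", "array")))
    grp <- rep.int(seq_len(n_species), sizes)
    pr <- upper_pairs(nrow(m))
    same <- grp[pr[, 1]] == grp[pr[, 2]]
    dv <- dm$d[pr]
    intra_max <- if (any(same)) max(dv[same]) else 0
    inter_min <- if (any(!same)) min(dv[!same]) else Inf
    if (nrow(dm$diagnostics) == 0 && intra_max < inter_min) {
      return(list(matrix = m, attempts = attempt))
    }
  }
  abort("could not realise the planted barcode gap; relax the configuration",
        class = "bg_error_config")
}

km_to_lat <- function(km) km / 111.1949
km_to_lon <- function(km, lat) km / (111.1949 * cos(lat * pi / 180))

# rejection-sample n points in bbox with pairwise separation >= min_km
sample_separated_points <- function(n, bbox, min_km, max_attempts = 200) {
  for (attempt in seq_len(max_attempts)) {
    lat <- stats::runif(n, bbox["lat_min"], bbox["lat_max"])
    lon <- stats::runif(n, bbox["lon_min"], bbox["lon_max"])
    if (n == 1) return(tibble(latitude = lat, longitude = lon))
    pr <- upper_pairs(n)
    dv <- haversine_km(lat[pr[, 1]], lon[pr[, 1]], lat[pr[, 2]], lon[pr[, 2]])
    if (min(dv) >= min_km) return(tibble(latitude = lat, longitude = lon))
  }
  abort("could not place range centres with the required spacing",
        class = "bg_error_config")
}

place_default_geography <- function(n_species, sizes, bbox, radius_km,
                                    pops_per_species, widespread_species,
                                    max_attempts) {
  centers <- sample_separated_points(n_species, bbox, 2 * radius_km,
                                     max_attempts * 8)
  centers$species <- seq_len(n_species)
  widespread <- integer(0)
  extra <- NULL
  if (widespread_species > 0) {
    widespread <- seq_len(min(widespread_species, n_species))
    # a second, distant centre for each widespread species
    for (s in widespread) {
      for (a in seq_len(max_attempts * 8)) {
        lat <- stats::runif(1, bbox["lat_min"], bbox["lat_max"])
        lon <- stats::runif(1, bbox["lon_min"], bbox["lon_max"])
        if (haversine_km(lat, lon, centers$latitude[s],
                         centers$longitude[s]) > 100) {
          extra <- dplyr::bind_rows(extra, tibble(latitude = lat,
                                                  longitude = lon,
                                                  species = s))
          break
        }
      }
    }
  }
  site_id <- character(sum(sizes))
  latitude <- numeric(sum(sizes))
  longitude <- numeric(sum(sizes))
  idx <- 0L
  site_counter <- 0L
  for (s in seq_len(n_species)) {
    cs <- dplyr::bind_rows(centers[centers$species == s, ],
                           if (!is.null(extra)) extra[extra$species == s, ])
    n_pop <- max(pops_per_species, nrow(cs))
    pops <- purrr::map(seq_len(n_pop), function(p) {
      ctr <- cs[((p - 1L) %% nrow(cs)) + 1L, ]
      r <- sqrt(stats::runif(1)) * radius_km
      th <- stats::runif(1, 0, 2 * pi)
      list(lat = ctr$latitude + km_to_lat(r * sin(th)),
           lon = ctr$longitude + km_to_lon(r * cos(th), ctr$latitude))
    })
    for (i in seq_len(sizes[s])) {
      p <- ((i - 1L) %% n_pop) + 1L
      idx <- idx + 1L
      site_id[idx] <- sprintf("site_%02d_%02d", s, p)
      latitude[idx] <- pops[[p]]$lat
      longitude[idx] <- pops[[p]]$lon
    }
    site_counter <- site_counter + n_pop
  }
  list(site_id = site_id, latitude = latitude, longitude = longitude,
       centers = centers, widespread = widespread)
}

place_locality_geography <- function(sizes, locality_map, bbox, min_km,
                                     max_attempts) {
  n_loc <- max(unlist(locality_map))
  multi <- which(lengths(locality_map) > 1L)
  for (a in seq_len(max_attempts * 8)) {
    pts <- sample_separated_points(n_loc, bbox, min_km, max_attempts * 8)
    # localities of one (widespread) species must be > 100 km apart
    ok <- all(vapply(multi, function(s) {
      locs <- locality_map[[s]]
      pr <- upper_pairs(length(locs))
      all(haversine_km(pts$latitude[locs[pr[, 1]]], pts$longitude[locs[pr[, 1]]],
                       pts$latitude[locs[pr[, 2]]], pts$longitude[locs[pr[, 2]]])
          > 100)
    }, logical(1)))
    if (ok) break
    pts <- NULL
  }
  if (is.null(pts)) {
    abort("could not place localities with the required spacing",
          class = "bg_error_config")
  }
  n_species <- length(sizes)
  site_id <- character(sum(sizes))
  latitude <- numeric(sum(sizes))
  longitude <- numeric(sum(sizes))
  idx <- 0L
  for (s in seq_len(n_species)) {
    locs <- locality_map[[s]]
    for (i in seq_len(sizes[s])) {
      loc <- locs[((i - 1L) %% length(locs)) + 1L]
      idx <- idx + 1L
      site_id[idx] <- sprintf("site_L%02d", loc)
      latitude[idx] <- pts$latitude[loc]
      longitude[idx] <- pts$longitude[loc]
    }
  }
  list(site_id = site_id, latitude = latitude, longitude = longitude,
       centers = dplyr::mutate(pts, locality = seq_len(n_loc)),
       widespread = multi)
}

morphospecies_labels <- function(species, lumping) {
  if (is.null(lumping)) return(setNames(species, species)[species])
  out <- character(length(species))
  for (m in names(lumping)) out[lumping[[m]]] <- m
  if (any(out == "")) {
    abort("morphospecies_lumping must cover every species",
          class = "bg_error_config")
  }
  out
}

species_characters <- function(n_species, n_characters, cpairs) {
  if (n_characters == 0) return(rep(list(character(0)), n_species))
  char_names <- c("pso_formula", "vpaso_formula", "th2_chaetae",
                  paste0("char", seq_len(max(0, n_characters - 3))))[
                    seq_len(n_characters)]
  owner <- seq_len(n_species) # cryptic pairs share the first member's values
  for (p in cpairs) owner[p[2]] <- owner[p[1]]
  lapply(seq_len(n_species), function(s) {
    setNames(sprintf("%s_v%02d", char_names, owner[s]), char_names)
  })
}

#' Simulated dataset mirroring the study design
#'
#' Convenience preset: 22 true species and 144 individuals spread over 17
#' shared localities (several species can co-occur at a locality), lumped
#' into 10 morphospecies, with 4 planted cryptic pairs (each inside one
#' morphospecies) and 1 widespread species occupying two localities more
#' than 100 km apart. Same-morphospecies species always sit at different
#' localities, and co-occurring species always differ in morphospecies, so
#' the geographic criterion can in principle recover every lumped species —
#' except the widespread one, whose molecular cluster geography splits.
#'
#' @param seed Optional integer seed.
#' @return A `delim_sim` list; see [simulate_dataset()].
#' @export
emulate_study <- function(seed = NULL) {
  lumping <- list(
    M01 = 1:3, M02 = 4:6, M03 = 7:8, M04 = 9:10, M05 = 11:12,
    M06 = 13:14, M07 = c(15L, 16L), M08 = 17:18, M09 = 19:21, M10 = 22L
  )
  # species 1..15 -> localities 1..15; 16..21 co-occur at 1..6 (always with a
  # different morphospecies); widespread species 22 -> localities 16 and 17
  locality_map <- c(as.list(1:15), as.list(1:6), list(c(16L, 17L)))
  simulate_dataset(
    n_species = 22, n_individuals = 144,
    cryptic_pairs = list(c(1L, 2L), c(4L, 5L), c(9L, 10L), c(17L, 18L)),
    morphospecies_lumping = lumping,
    locality_map = locality_map,
    seed = seed
  )
}
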