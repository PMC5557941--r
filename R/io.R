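#' Aligned nucleotide matrices
#'
#' An aligned matrix holds one aligned sequence per specimen over the
#' alphabet `A C G T - N`. Sequences are stored upper-case; IUPAC ambiguity
#' codes other than `N` are collapsed to `N` with a warning, since pairwise
#' deletion removes them from every distance anyway.
#'
#' @param seqs Named character vector of aligned sequences (names are
#'   specimen ids), or a character matrix with one row per specimen and one
#'   column per site.
#' @return An `aligned_matrix`: a character matrix (specimens x sites) with
#'   specimen ids as row names.
#' @examples
#' aln <- aligned_matrix(c(s1 = "ACGT", s2 = "ACGA"))
#' dim(aln)
#' @export
aligned_matrix <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    seqs <- as.character(seqs) |> setNames(names(seqs))
    if (length(seqs) == 0) abort("no sequences", class = "bg_error_empty")
    if (is.null(names(seqs)) || any(names(seqs) == "")) {
      abort("sequences must be named by specimen id", class = "bg_error_schema")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      abort(paste0("aligned sequences must share one length; saw lengths ",
                   paste(sort(unique(lens)), collapse = ", ")),
            class = "bg_error_shape")
    }
    if (lens[1] == 0) abort("empty sequences", class = "bg_error_empty")
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m))) {
    abort("sequence matrix must have specimen ids as row names",
          class = "bg_error_schema")
  }
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup) > 0) {
    abort(paste0("duplicate specimen ids: ", paste(unique(dup), collapse = ", ")),
          class = "bg_error_duplicate")
  }
  m[] <- toupper(m)
  bad <- !(m %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) {
    warn(sprintf("%d ambiguous/unknown base(s) collapsed to N", sum(bad)))
    m[bad] <- "N"
  }
  structure(m, class = c("aligned_matrix", "matrix", "array"))
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat(sprintf("<aligned matrix: %d specimens x %d sites>\n", nrow(x), ncol(x)))
  invisible(x)
}

specimen_ids <- function(alignment) rownames(alignment)

# subset specimens (and optionally sites), keeping the class
subset_alignment <- function(alignment, ids = NULL, sites = NULL) {
  m <- unclass(alignment)
  if (!is.null(ids)) m <- m[ids, , drop = FALSE]
  if (!is.null(sites)) m <- m[, sites, drop = FALSE]
  structure(m, class = c("aligned_matrix", "matrix", "array"))
}

#' Read an aligned FASTA file
#'
#' @param path Path to a FASTA file of aligned nucleotide sequences.
#' @return An [aligned_matrix()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "bg_error_empty")
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    abort(paste0("could not parse FASTA: ", conditionMessage(e)),
                          class = "bg_error_parse")
                  })
  if (length(set) == 0) abort("empty FASTA file", class = "bg_error_empty")
  w <- Biostrings::width(set)
  if (length(unique(w)) != 1L) {
    abort(paste0("aligned sequences must share one length; saw lengths ",
                 paste(sort(unique(w)), collapse = ", ")),
          class = "bg_error_shape")
  }
  seqs <- as.character(set)
  # FASTA headers may carry descriptions after whitespace; the id is the token
  names(seqs) <- sub("\\s.*$", "", names(set))
  aligned_matrix(seqs)
}

#' Read and write specimen metadata
#'
#' The metadata table carries, per barcoded specimen: collection site and
#' decimal-degree coordinates, an optional morphospecies label, a `deformed`
#' flag (specimens with bilateral asymmetry in key diagnostic features, which
#' are excluded from all character statistics), and optional discrete
#' morphological characters. Characters may come either as a single
#' `characters` column of `name=value` pairs separated by `;`, or as columns
#' prefixed `char_`; values are opaque strings compared only for equality.
#'
#' @param path Path to a CSV or TSV file (by extension; default CSV) with at
#'   least columns `specimen_id`, `site_id`, `latitude`, `longitude`.
#' @return A tibble with columns `specimen_id`, `site_id`, `latitude`,
#'   `longitude`, `morphospecies`, `deformed` and a `characters` list-column
#'   of named character vectors.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "bg_error_empty")
  }
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  x <- reader(path, col_types = readr::cols(.default = readr::col_character()),
              progress = FALSE)
  required <- c("specimen_id", "site_id", "latitude", "longitude")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("metadata is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "bg_error_schema")
  }
  x$latitude <- as.numeric(x$latitude)
  x$longitude <- as.numeric(x$longitude)
  out <- tibble(
    specimen_id = x$specimen_id,
    site_id = x$site_id,
    latitude = x$latitude,
    longitude = x$longitude,
    morphospecies = x[["morphospecies"]] %||% rep("", nrow(x)),
    deformed = parse_flag(x[["deformed"]] %||% rep("false", nrow(x)))
  )
  out$morphospecies[is.na(out$morphospecies)] <- ""
  char_cols <- grep("^char_", names(x), value = TRUE)
  char_field <- x[["characters"]]
  chars <- lapply(seq_len(nrow(x)), function(i) {
    v <- character(0)
    if (!is.null(char_field) && !is.na(char_field[i]) && nzchar(char_field[i])) {
      v <- c(v, parse_character_field(char_field[i]))
    }
    for (cc in char_cols) {
      val <- x[[cc]][i]
      if (!is.na(val) && nzchar(val)) {
        v <- c(v, setNames(val, sub("^char_", "", cc)))
      }
    }
    v
  })
  out$characters <- chars
  validate_metadata(out)
}

validate_metadata <- function(meta) {
  dup <- meta$specimen_id[duplicated(meta$specimen_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate specimen ids: ", paste(unique(dup), collapse = ", ")),
          class = "bg_error_duplicate")
  }
  bad_lat <- !is.na(meta$latitude) & abs(meta$latitude) > 90
  bad_lon <- !is.na(meta$longitude) & abs(meta$longitude) > 180
  if (any(bad_lat) || any(bad_lon)) {
    abort(paste0("coordinates out of range for: ",
                 paste(meta$specimen_id[bad_lat | bad_lon], collapse = ", ")),
          class = "bg_error_range")
  }
  meta
}

parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("true", "t", "1", "yes", "y")
  out[is.na(x) | x == ""] <- FALSE
  out
}

# "a=1;b=2" -> c(a = "1", b = "2")
parse_character_field <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(parts, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) {
    abort(paste0("malformed character field: ", s), class = "bg_error_parse")
  }
  setNames(trimws(vapply(kv, `[`, "", 2L)), trimws(vapply(kv, `[`, "", 1L)))
}

#' @rdname read_metadata
#' @param metadata A metadata tibble as returned by [read_metadata()].
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  if (!is.null(out$characters)) {
    out$characters <- vapply(out$characters, function(v) {
      if (length(v) == 0) "" else paste(names(v), v, sep = "=", collapse = ";")
    }, "")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a newick tree
#'
#' Thin wrapper over [ape::read.tree()] that turns malformed newick into a
#' classed parse error and reports the leaf set for reconciliation against
#' specimen metadata. Internal node labels (e.g. bootstrap or posterior
#' supports on imported ML/BI trees) are preserved in `$node.label`.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "bg_error_empty")
  }
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    abort(paste0("malformed newick in ", path), class = "bg_error_parse")
  }
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup) > 0) {
    abort(paste0("duplicate leaf labels: ", paste(unique(dup), collapse = ", ")),
          class = "bg_error_duplicate")
  }
  tr
}

#' Cross-check alignment, metadata and tree identifiers
#'
#' Lists every identifier mismatch between the inputs; nothing is dropped
#' silently. An empty result means the inputs are mutually consistent.
#'
#' @param alignment An [aligned_matrix()] (optional).
#' @param metadata A metadata tibble (optional).
#' @param tree An [ape::phylo] tree (optional).
#' @return A tibble with columns `issue` and `specimen_id`, one row per
#'   mismatch.
#' @export
validate_inputs <- function(alignment = NULL, metadata = NULL, tree = NULL) {
  issues <- list()
  note <- function(issue, ids) {
    if (length(ids) > 0) tibble(issue = issue, specimen_id = ids) else NULL
  }
  if (!is.null(alignment) && !is.null(metadata)) {
    a <- specimen_ids(alignment)
    m <- metadata$specimen_id
    issues <- c(issues,
                list(note("in alignment, not in metadata", setdiff(a, m)),
                     note("in metadata, not in alignment", setdiff(m, a))))
  }
  if (!is.null(tree) && !is.null(metadata)) {
    issues <- c(issues,
                list(note("tree leaf not in metadata",
                          setdiff(tree$tip.label, metadata$specimen_id))))
  }
  if (!is.null(tree) && !is.null(alignment)) {
    issues <- c(issues,
                list(note("in alignment, not in tree",
                          setdiff(specimen_ids(alignment), tree$tip.label))))
  }
  out <- dplyr::bind_rows(purrr::compact(issues))
  if (nrow(out) == 0) tibble(issue = character(0), specimen_id = character(0)) else out
}
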