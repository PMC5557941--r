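#' Specimen partitions
#'
#' A partition assigns every specimen to exactly one putative-species group.
#' It is the common currency of all delimitation methods in the package:
#' barcode-gap clusters, geographic putative species, morphospecies, and
#' imported partitions (e.g. PTP output) are all represented the same way,
#' as a tibble with columns `specimen_id` and `group` plus a free-text
#' `source` provenance attribute.
#'
#' @param x A data frame with columns `specimen_id` and `group`, or a named
#'   character vector of group labels (names are specimen ids).
#' @param source Free-text provenance tag (e.g. `"gapdelim"`, `"geo:50km"`,
#'   `"morphospecies"`).
#' @return A `delim_partition` tibble with columns `specimen_id` and `group`.
#' @examples
#' p <- as_partition(c(s1 = "A", s2 = "A", s3 = "B"), source = "toy")
#' partition_k(p)
#' @export
as_partition <- function(x, source = "unknown") {
  if (is.character(x) || is.factor(x)) {
    if (is.null(names(x))) {
      stop_parameter("a vector partition must be named by specimen id")
    }
    x <- tibble(specimen_id = names(x), group = as.character(x))
  }
  x <- as_tibble(x)
  if (!all(c("specimen_id", "group") %in% names(x))) {
    abort("a partition needs `specimen_id` and `group` columns",
          class = "bg_error_schema")
  }
  x <- dplyr::select(x, "specimen_id", "group")
  x$specimen_id <- as.character(x$specimen_id)
  x$group <- as.character(x$group)
  dup <- x$specimen_id[duplicated(x$specimen_id)]
  if (length(dup) > 0) {
    conflict <- dplyr::n_distinct(x$group[x$specimen_id %in% dup[1]]) > 1
    if (conflict) {
      abort(paste0("specimen assigned to more than one group: ",
                   paste(unique(dup), collapse = ", ")),
            class = "bg_error_conflict")
    }
    x <- dplyr::distinct(x)
  }
  if (anyNA(x$specimen_id) || anyNA(x$group)) {
    stop_integrity("partition contains missing specimen ids or group labels")
  }
  new_partition(x, source = source)
}

new_partition <- function(x, source = "unknown") {
  structure(as_tibble(x),
            source = source,
            class = c("delim_partition", class(tibble())))
}

#' @rdname as_partition
#' @param partition A `delim_partition` (or coercible data frame).
#' @export
partition_k <- function(partition) {
  dplyr::n_distinct(as_partition_quiet(partition)$group)
}

#' @rdname as_partition
#' @export
partition_source <- function(partition) attr(partition, "source") %||% "unknown"

as_partition_quiet <- function(x) {
  if (inherits(x, "delim_partition")) x else as_partition(x)
}

# specimen_id -> group named vector, in partition row order
partition_lookup <- function(partition) {
  setNames(partition$group, partition$specimen_id)
}

# Relabel groups G1..Gk deterministically by order of first member.
relabel_groups <- function(partition, prefix = "G") {
  first <- match(unique(partition$group), partition$group)
  ord <- partition$group[sort(first)]
  map <- setNames(paste0(prefix, seq_along(ord)), ord)
  partition$group <- unname(map[partition$group])
  partition
}

same_universe <- function(p1, p2) {
  setequal(p1$specimen_id, p2$specimen_id)
}

check_same_universe <- function(partitions) {
  ids <- partitions[[1]]$specimen_id
  ok <- vapply(partitions, function(p) setequal(p$specimen_id, ids), logical(1))
  if (!all(ok)) {
    stop_integrity("partitions are defined over different specimen sets")
  }
  invisible(TRUE)
}

#' Read and write partition tables
#'
#' Partitions are exchanged as two-column TSV files (`specimen_id`, `group`),
#' the carrier used to import external delimitations such as PTP/bPTP output.
#' `read_partition(write_partition(p, f))` restores the assignment exactly.
#'
#' @param path Path to a tab-separated file with columns `specimen_id` and
#'   `group` (a header line is optional).
#' @param source Provenance tag attached to the partition; defaults to
#'   `"import:<filename>"`.
#' @return `read_partition()` returns a [as_partition()] tibble;
#'   `write_partition()` returns `path` invisibly.
#' @export
read_partition <- function(path, source = NULL) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "bg_error_empty")
  }
  first <- readLines(path, n = 1L)
  has_header <- grepl("^specimen_id\\b", first)
  x <- readr::read_tsv(path,
                       col_names = if (has_header) TRUE else c("specimen_id", "group"),
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (nrow(x) == 0) abort("empty partition file", class = "bg_error_empty")
  as_partition(x, source = source %||% paste0("import:", basename(path)))
}

#' @rdname read_partition
#' @param partition A `delim_partition` (or coercible data frame).
#' @export
write_partition <- function(partition, path) {
  partition <- as_partition_quiet(partition)
  readr::write_tsv(as_tibble(partition)[c("specimen_id", "group")], path,
                   progress = FALSE)
  invisible(path)
}

#' @export
print.delim_partition <- function(x, ...) {
  cat(sprintf("<partition: %d specimens, k = %d, source = %s>\n",
              nrow(x), dplyr::n_distinct(x$group), partition_source(x)))
  NextMethod()
}
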