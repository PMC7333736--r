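#' Read a protein-protein interaction edge list
#'
#' Parses a whitespace/tab-delimited edge list (DIP/BioGrid export style). The
#' first two tokens of every non-comment line are protein identifiers; any
#' additional columns are ignored. Lines starting with `#` and blank lines are
#' skipped. Self-loops are dropped and duplicate unordered pairs collapsed,
#' each with an informative message. Protein identifiers are matched by exact,
#' case-sensitive string equality throughout the package.
#'
#' @param path Path to the edge-list file.
#' @return A tibble with columns `protein_a`, `protein_b` (canonical order:
#'   `protein_a < protein_b` within each row, rows sorted), carrying the node
#'   set in `attr(, "proteins")`.
#' @export
read_ppi_edgelist <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) {
    return(new_edge_tbl(character(), character()))
  }
  toks <- strsplit(lines$text, "[ \t]+")
  bad <- which(vapply(toks, length, integer(1)) < 2L)
  if (length(bad) > 0L) {
    stop("PPI edge list parse error: line ", lines$lineno[bad[1]],
         " has fewer than 2 fields", call. = FALSE)
  }
  a <- vapply(toks, `[[`, character(1), 1L)
  b <- vapply(toks, `[[`, character(1), 2L)
  self <- a == b
  if (any(self)) {
    rlang::inform(paste0("read_ppi_edgelist: dropped ", sum(self), " self-loop(s)"))
    a <- a[!self]; b <- b[!self]
  }
  pa <- pmin(a, b); pb <- pmax(a, b)
  key <- paste(pa, pb, sep = "\t")
  dup <- duplicated(key)
  if (any(dup)) {
    rlang::inform(paste0("read_ppi_edgelist: collapsed ", sum(dup), " duplicate pair(s)"))
  }
  new_edge_tbl(pa[!dup], pb[!dup])
}

new_edge_tbl <- function(a, b) {
  out <- tibble::tibble(protein_a = a, protein_b = b)
  out <- dplyr::arrange(out, .data$protein_a, .data$protein_b)
  attr(out, "proteins") <- sort(unique(c(a, b)))
  out
}

# shared line reader: strips comments/blank lines, keeps original line numbers
read_clean_lines <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read '", path, "': no such file", call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(text = trimws(raw[keep]), lineno = which(keep))
}

#' Read a TAP purification score table
#'
#' Each line is `proteinA proteinB score`. Pairs are stored unordered; if the
#' same unordered pair occurs more than once, the maximum score is kept (with
#' a message).
#'
#' @param path Path to the 3-column table.
#' @param source Either `"LCMS"` or `"MALDI"`, recorded on the result.
#' @return A tibble with columns `protein_a`, `protein_b`, `score` and
#'   attributes `source` and `normalized` (`FALSE` for raw tables).
#' @export
read_tap_scores <- function(path, source = c("LCMS", "MALDI")) {
  source <- match.arg(source)
  lines <- read_clean_lines(path)
  if (length(lines$text) == 0L) {
    return(new_tap_tbl(character(), character(), numeric(), source))
  }
  toks <- strsplit(lines$text, "[ \t]+")
  bad <- which(vapply(toks, length, integer(1)) < 3L)
  if (length(bad) > 0L) {
    stop("TAP table parse error: line ", lines$lineno[bad[1]],
         " has fewer than 3 fields", call. = FALSE)
  }
  a <- vapply(toks, `[[`, character(1), 1L)
  b <- vapply(toks, `[[`, character(1), 2L)
  s <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 3L)))
  if (anyNA(s)) {
    stop("TAP table parse error: non-numeric score at line ",
         lines$lineno[which(is.na(s))[1]], call. = FALSE)
  }
  pa <- pmin(a, b); pb <- pmax(a, b)
  tbl <- tibble::tibble(protein_a = pa, protein_b = pb, score = s)
  n0 <- nrow(tbl)
  tbl <- tbl |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
  if (nrow(tbl) < n0) {
    rlang::inform(paste0("read_tap_scores: ", n0 - nrow(tbl),
                         " duplicate pair(s), kept maximum score"))
  }
  new_tap_tbl(tbl$protein_a, tbl$protein_b, tbl$score, source)
}

new_tap_tbl <- function(a, b, s, source, normalized = FALSE) {
  out <- tibble::tibble(protein_a = a, protein_b = b, score = s)
  out <- dplyr::arrange(out, .data$protein_a, .data$protein_b)
  attr(out, "source") <- source
  attr(out, "normalized") <- normalized
  out
}

#' Read a time-course gene-expression matrix
#'
#' Expects a header row of time-point labels and one row per protein
#' (`protein_id value1 ... valueN`, tab/space separated).
#'
#' @param path Path to the matrix file.
#' @return A numeric matrix, rows named by protein, columns by time point.
#' @export
read_ge_matrix <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines$text) < 1L) stop("empty expression file", call. = FALSE)
  toks <- strsplit(lines$text, "[ \t]+")
  header <- toks[[1]]
  n <- length(header)
  rows <- toks[-1]
  if (length(rows) == 0L) stop("expression file has no data rows", call. = FALSE)
  ids <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate protein row '", ids[duplicated(ids)][1], "' in expression file",
         call. = FALSE)
  }
  lens <- vapply(rows, length, integer(1))
  if (any(lens != n + 1L)) {
    bad <- which(lens != n + 1L)[1]
    stop("ragged expression row for protein '", ids[bad], "': expected ", n,
         " values, found ", lens[bad] - 1L, call. = FALSE)
  }
  vals <- suppressWarnings(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  if (anyNA(vals)) stop("non-numeric expression value", call. = FALSE)
  mat <- t(matrix(vals, nrow = n))
  dimnames(mat) <- list(ids, header)
  mat
}

#' Write a gene-expression matrix
#'
#' Inverse of [read_ge_matrix()]: header row of time labels, then one row per
#' protein.
#'
#' @param ge Numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ge_matrix <- function(ge, path) {
  stopifnot(is.matrix(ge), !is.null(rownames(ge)), !is.null(colnames(ge)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(ge), collapse = "\t"), con)
  body <- apply(ge, 1L, function(r) paste(format(r, digits = 15, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(ge), body, sep = "\t"), con)
  invisible(path)
}

#' Read a protein-complex catalog
#'
#' One complex per line, whitespace-separated protein IDs (CYC2008/MIPS
#' style). Empty lines are skipped with a message; duplicate proteins within a
#' complex are removed.
#'
#' @param path Path to the catalog.
#' @return A complex tibble: columns `complex_id`, `proteins` (list-column of
#'   character vectors), `size`.
#' @export
read_complex_set <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*#", raw)]
  blank <- grepl("^\\s*$", raw)
  if (any(blank)) {
    rlang::inform(paste0("read_complex_set: skipped ", sum(blank), " empty line(s)"))
  }
  members <- lapply(strsplit(trimws(raw[!blank]), "[ \t]+"), unique)
  as_complex_tbl(members)
}

#' Build a complex tibble from a list of protein sets
#'
#' @param proteins List of character vectors (one protein set per complex),
#'   or an existing complex tibble (returned unchanged apart from recomputed
#'   ids/sizes).
#' @param origin Optional character vector of provenance labels, recycled.
#' @return A tibble with columns `complex_id`, `proteins`, `size` (and
#'   `origin` if given).
#' @export
as_complex_tbl <- function(proteins, origin = NULL) {
  if (is.data.frame(proteins)) proteins <- proteins$proteins
  proteins <- lapply(proteins, function(p) sort(unique(as.character(p))))
  out <- tibble::tibble(
    complex_id = if (length(proteins)) seq_along(proteins) else integer(),
    proteins = proteins,
    size = lengths(proteins)
  )
  if (!is.null(origin) && nrow(out) > 0L) out$origin <- rep_len(origin, nrow(out))
  out
}

#' Write a protein-complex catalog
#'
#' Deterministic output: complexes are sorted by descending size, then by the
#' lexicographically first member; members within a complex are sorted.
#' `read_complex_set(write_complex_set(x))` is the identity on the set of
#' protein sets.
#'
#' @param complexes A complex tibble (see [as_complex_tbl()]) or a list of
#'   character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complex_set <- function(complexes, path) {
  tbl <- as_complex_tbl(complexes)
  if (nrow(tbl) > 0L) {
    first <- vapply(tbl$proteins, function(p) p[1], character(1))
    ord <- order(-tbl$size, first)
    tbl <- tbl[ord, ]
  }
  writeLines(vapply(tbl$proteins, paste, character(1), collapse = " "), path)
  invisible(path)
}

#' Write / read a weighted PPI edge table
#'
#' Tab-separated with a header: `protein_a protein_b w w_go w_tap alpha_tap`.
#' Edge order is deterministic (sorted on the protein pair).
#'
#' @param net A `weighted_ppi` edge tibble (see [build_weighted_network()]).
#' @param path File path.
#' @return `write_weighted_edges()` returns `path` invisibly;
#'   `read_weighted_edges()` returns a `weighted_ppi` tibble.
#' @export
write_weighted_edges <- function(net, path) {
  cols <- c("protein_a", "protein_b", "w", "w_go", "w_tap", "alpha_tap")
  stopifnot(all(cols %in% names(net)))
  df <- as.data.frame(dplyr::arrange(net[cols], .data$protein_a, .data$protein_b))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weighted_edges
#' @export
read_weighted_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = c(
    protein_a = "character", protein_b = "character"))
  net <- tibble::as_tibble(df)
  attr(net, "proteins") <- sort(unique(c(net$protein_a, net$protein_b)))
  class(net) <- c("weighted_ppi", class(net))
  net
}

#' Write / read a bicluster table
#'
#' Tab-separated: `bicluster_id`, comma-separated protein list, comma-separated
#' time-point list, fitness.
#'
#' @param biclusters A bicluster tibble (see [run_memetic()]).
#' @param path File path.
#' @return `write_biclusters()` returns `path` invisibly; `read_biclusters()`
#'   returns a bicluster tibble.
#' @export
write_biclusters <- function(biclusters, path) {
  lines <- vapply(seq_len(nrow(biclusters)), function(i) {
    paste(biclusters$bicluster_id[i],
          paste(biclusters$proteins[[i]], collapse = ","),
          paste(biclusters$timepoints[[i]], collapse = ","),
          format(biclusters$fitness[i], digits = 15),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_biclusters
#' @export
read_biclusters <- function(path) {
  lines <- read_clean_lines(path)
  toks <- strsplit(lines$text, "\t")
  tibble::tibble(
    bicluster_id = vapply(toks, function(t) as.integer(t[1]), integer(1)),
    proteins = lapply(toks, function(t) strsplit(t[2], ",")[[1]]),
    timepoints = lapply(toks, function(t) strsplit(t[3], ",")[[1]]),
    fitness = vapply(toks, function(t) as.numeric(t[4]), numeric(1))
  )
}

#' Read a precomputed per-aspect GO edge-weight table
#'
#' Alternative to OBO+GAF input: a 4-column TSV `p1 p2 aspect weight`, one row
#' per protein pair per annotated aspect (aspect in BP/CC/MF).
#'
#' @param path Path to the table.
#' @return A tibble `protein_a`, `protein_b`, `aspect`, `weight` (pairs
#'   canonicalised unordered).
#' @export
read_go_weight_table <- function(path) {
  lines <- read_clean_lines(path)
  toks <- strsplit(lines$text, "[ \t]+")
  bad <- which(vapply(toks, length, integer(1)) < 4L)
  if (length(bad) > 0L) {
    stop("GO weight table parse error: line ", lines$lineno[bad[1]],
         " has fewer than 4 fields", call. = FALSE)
  }
  a <- vapply(toks, `[[`, character(1), 1L)
  b <- vapply(toks, `[[`, character(1), 2L)
  aspect <- vapply(toks, `[[`, character(1), 3L)
  w <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 4L)))
  if (anyNA(w)) {
    stop("GO weight table parse error: non-numeric weight at line ",
         lines$lineno[which(is.na(w))[1]], call. = FALSE)
  }
  if (!all(aspect %in% c("BP", "CC", "MF"))) {
    stop("GO weight table parse error: aspect must be BP, CC or MF", call. = FALSE)
  }
  tibble::tibble(protein_a = pmin(a, b), protein_b = pmax(a, b),
                 aspect = aspect, weight = w) |>
    dplyr::arrange(.data$protein_a, .data$protein_b, .data$aspect)
}
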