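#' Read a Gene Ontology OBO file
#'
#' Minimal OBO 1.2/1.4 flat-file parser covering what SimGIC needs: `[Term]`
#' stanzas with `id`, `namespace` and `is_a` lines. Obsolete terms are
#' skipped; only `is_a` edges are kept (`part_of` and other relationships are
#' ignored, see the methods vignette).
#'
#' @param path Path to the `.obo` file.
#' @return An `ontology_dag`: list with `terms` (tibble `term`, `aspect` in
#'   BP/CC/MF) and `parents` (named list term -> character vector of is_a
#'   parents).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- sub("!.*$", "", raw)            # trailing comments
  raw <- trimws(raw)
  stanza_starts <- grep("^\\[", raw)
  term_ids <- character(); aspects <- character(); parents <- list()
  for (k in seq_along(stanza_starts)) {
    if (raw[stanza_starts[k]] != "[Term]") next
    from <- stanza_starts[k] + 1L
    to <- if (k < length(stanza_starts)) stanza_starts[k + 1L] - 1L else length(raw)
    block <- raw[from:to]
    get1 <- function(tag) sub(paste0("^", tag, ":\\s*"), "", grep(paste0("^", tag, ":"), block, value = TRUE))
    id <- get1("id")
    if (length(id) == 0L) next
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    ns <- get1("namespace")
    isa_raw <- trimws(get1("is_a"))
    isa <- vapply(strsplit(isa_raw[nzchar(isa_raw)], "[ \t]+"),
                  `[[`, character(1), 1L)
    term_ids <- c(term_ids, id[1])
    aspects <- c(aspects, if (length(ns)) obo_aspect(ns[1]) else NA_character_)
    parents[[id[1]]] <- isa
  }
  new_ontology_dag(term_ids, aspects, parents)
}

obo_aspect <- function(ns) {
  switch(ns,
         biological_process = "BP",
         cellular_component = "CC",
         molecular_function = "MF",
         stop("unknown OBO namespace '", ns, "'", call. = FALSE))
}

new_ontology_dag <- function(term_ids, aspects, parents) {
  dag <- list(terms = tibble::tibble(term = term_ids, aspect = aspects),
              parents = parents)
  class(dag) <- "ontology_dag"
  # cycle check via iterative ancestor closure (errors on a cycle)
  invisible(term_ancestors(dag))
  dag
}

# ancestors-inclusive closure of every term; memoised bottom-up
term_ancestors <- function(dag) {
  anc <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  walk <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    if (!is.null(visiting[[t]])) stop("cycle detected in ontology at term '", t, "'", call. = FALSE)
    visiting[[t]] <- TRUE
    ps <- dag$parents[[t]]
    ps <- ps[ps %in% dag$terms$term]
    out <- unique(c(t, unlist(lapply(ps, walk), use.names = FALSE)))
    rm(list = t, envir = visiting)
    anc[[t]] <- out
    out
  }
  res <- lapply(dag$terms$term, walk)
  names(res) <- dag$terms$term
  res
}

#' Read a GAF 2.x annotation file
#'
#' Keeps column 2 (protein/gene product ID), column 5 (GO term) and column 9
#' (aspect letter P/C/F, mapped to BP/CC/MF). Header lines starting with `!`
#' are skipped. No evidence-code filtering is applied.
#'
#' @param path Path to the GAF file.
#' @return A tibble `protein`, `term`, `aspect`.
#' @export
read_gaf <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*(!|$)", raw)]
  toks <- strsplit(raw, "\t")
  bad <- which(vapply(toks, length, integer(1)) < 9L)
  if (length(bad) > 0L) {
    stop("GAF parse error: row ", bad[1], " has fewer than 9 columns", call. = FALSE)
  }
  aspect_letter <- vapply(toks, `[[`, character(1), 9L)
  aspect <- c(P = "BP", C = "CC", F = "MF")[aspect_letter]
  if (anyNA(aspect)) stop("GAF parse error: unknown aspect letter", call. = FALSE)
  tibble::tibble(
    protein = vapply(toks, `[[`, character(1), 2L),
    term = vapply(toks, `[[`, character(1), 5L),
    aspect = unname(aspect)
  ) |> dplyr::distinct()
}

#' Build the ancestral closure of direct GO annotations
#'
#' For every protein and aspect, the closure is the union of the
#' ancestors-inclusive sets of its directly annotated terms (is_a edges only).
#'
#' @param dag An `ontology_dag` from [read_obo()].
#' @param direct Tibble `protein`, `term`, `aspect` as from [read_gaf()].
#' @return A `go_annotations` object: list with `direct`, `closure` (named
#'   list aspect -> named list protein -> term vector) and `proteins`.
#' @export
build_closure <- function(dag, direct) {
  unknown <- setdiff(unique(direct$term), dag$terms$term)
  if (length(unknown) > 0L) {
    stop("annotation to unknown term '", unknown[1], "'", call. = FALSE)
  }
  anc <- term_ancestors(dag)
  closure <- lapply(c(BP = "BP", CC = "CC", MF = "MF"), function(a) {
    sub <- direct[direct$aspect == a, ]
    if (nrow(sub) == 0L) return(list())
    by_protein <- split(sub$term, sub$protein)
    lapply(by_protein, function(ts) {
      sort(unique(unlist(anc[ts], use.names = FALSE)))
    })
  })
  out <- list(direct = direct, closure = closure,
              proteins = sort(unique(direct$protein)))
  class(out) <- "go_annotations"
  out
}

#' Corpus information content of GO terms
#'
#' For each term `t`, `p(t)` is the fraction of corpus proteins whose
#' ancestral closure (any aspect) contains `t`; `ic(t) = -ln p(t)` when
#' `p(t) > 0`, else 0 with the term flagged unused. The root of each aspect
#' annotates every protein annotated in that aspect, so its IC is 0.
#'
#' @param dag An `ontology_dag`.
#' @param annotations A `go_annotations` object from [build_closure()].
#' @param corpus Character vector of protein IDs defining the background set;
#'   defaults to all annotated proteins.
#' @return Named numeric vector of IC values (natural-log units) for every
#'   term of the ontology, with unused terms in `attr(, "unused")`.
#' @export
information_content <- function(dag, annotations, corpus = annotations$proteins) {
  corpus <- unique(corpus)
  if (length(corpus) == 0L) stop("corpus must be non-empty", call. = FALSE)
  counts <- integer(nrow(dag$terms))
  names(counts) <- dag$terms$term
  for (a in names(annotations$closure)) {
    cl <- annotations$closure[[a]][intersect(names(annotations$closure[[a]]), corpus)]
    if (length(cl) == 0L) next
    tab <- table(unlist(cl, use.names = FALSE))
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  p <- counts / length(corpus)
  ic <- ifelse(p > 0, -log(p), 0)
  ic <- pmax(ic, 0)  # p == 1 can give -0
  attr(ic, "unused") <- names(ic)[p == 0]
  ic
}

#' SimGIC semantic similarity of two proteins in one GO aspect
#'
#' Graph-information-content similarity: the summed IC of the shared
#' ancestral annotations divided by the summed IC of the combined ancestral
#' annotations. Returns `NA` when either protein is unannotated in the aspect
#' (the "missing aspect" sentinel used by [go_pair_weight()]); returns 0 when
#' the union carries no information (only zero-IC terms).
#'
#' @param p1,p2 Protein IDs.
#' @param aspect One of `"BP"`, `"CC"`, `"MF"`.
#' @param annotations A `go_annotations` object.
#' @param ic Named IC vector from [information_content()].
#' @return Similarity in `[0, 1]`, or `NA_real_` if an annotation is missing.
#' @export
simgic <- function(p1, p2, aspect, annotations, ic) {
  cl <- annotations$closure[[aspect]]
  c1 <- cl[[p1]]; c2 <- cl[[p2]]
  if (is.null(c1) || is.null(c2)) return(NA_real_)
  denom <- sum(ic[union(c1, c2)])
  if (denom <= 0) return(0)
  sum(ic[intersect(c1, c2)]) / denom
}

#' Combined GO weight of a protein pair
#'
#' Mean of the per-aspect SimGIC similarities (BP, CC, MF). Aspects where
#' either protein is unannotated are excluded from the mean; if no aspect is
#' available the weight is 0.
#'
#' @inheritParams simgic
#' @return Weight in `[0, 1]`.
#' @export
go_pair_weight <- function(p1, p2, annotations, ic) {
  ws <- vapply(c("BP", "CC", "MF"), simgic, numeric(1),
               p1 = p1, p2 = p2, annotations = annotations, ic = ic)
  ws <- ws[!is.na(ws)]
  if (length(ws) == 0L) return(0)
  mean(ws)
}

#' GO weights for a set of protein pairs
#'
#' Computes [go_pair_weight()] for every row of an edge table, either from
#' annotations + IC or from a precomputed per-aspect weight table (see
#' [read_go_weight_table()]), in which case the same missing-aspect averaging
#' rule is applied to the aspects present per pair.
#'
#' @param edges Tibble with columns `protein_a`, `protein_b`.
#' @param annotations A `go_annotations` object (with `ic`), or `NULL` when
#'   `weight_table` is given.
#' @param ic Named IC vector, required with `annotations`.
#' @param weight_table Precomputed tibble `protein_a`, `protein_b`, `aspect`,
#'   `weight`.
#' @return The edge tibble with a `w_go` column appended.
#' @export
go_weight_edges <- function(edges, annotations = NULL, ic = NULL,
                            weight_table = NULL) {
  stopifnot(all(c("protein_a", "protein_b") %in% names(edges)))
  if (!is.null(weight_table)) {
    agg <- weight_table |>
      dplyr::group_by(.data$protein_a, .data$protein_b) |>
      dplyr::summarise(w_go = mean(.data$weight), .groups = "drop")
    out <- dplyr::left_join(edges, agg, by = c("protein_a", "protein_b"))
    out$w_go[is.na(out$w_go)] <- 0
    return(out)
  }
  if (is.null(annotations) || is.null(ic)) {
    stop("either annotations+ic or weight_table must be supplied", call. = FALSE)
  }
  edges$w_go <- vapply(seq_len(nrow(edges)), function(i) {
    go_pair_weight(edges$protein_a[i], edges$protein_b[i], annotations, ic)
  }, numeric(1))
  edges
}
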