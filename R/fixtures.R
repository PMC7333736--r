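#' Configuration for the synthetic data generator
#'
#' The generator plants protein complexes (dense subgraphs with coherent GO
#' markers and elevated TAP scores) and expression biclusters (blocks of
#' proteins fully active over a block of time points) inside otherwise random
#' data, so that every pipeline stage can be validated against known truth.
#' Defaults define the package's reference validation conditions; see the
#' methods vignette for the rationale behind each value.
#'
#' @param n_proteins Total number of proteins (default 300).
#' @param n_timepoints Number of expression time points (default 12).
#' @param complex_sizes Sizes of the planted complexes (default
#'   `c(5, 7, 8, 9, 10, 12)`).
#' @param internal_edge_prob Probability of each intra-complex edge (default
#'   1: planted cliques).
#' @param shared_proteins Number of proteins shared by the last two planted
#'   complexes, exercising the aggregation category logic (default 2).
#' @param background_edge_prob Erdos-Renyi probability of background edges
#'   (default 0.02).
#' @param biclusters_per_complexes Number of complexes pooled into each
#'   planted bicluster's protein block (default 2, giving 3 biclusters over
#'   disjoint time-point blocks; with 2 per block the smallest complex is
#'   paired with the largest so the blocks have comparable size).
#' @param p_in Activity probability inside a planted bicluster block
#'   (default 1: the planted bicluster is the fully active block; lower it to
#'   degrade the signal).
#' @param p_out Background activity rate (default 0.05, emulating the sparse
#'   binarized activity of proteins outside their expression module).
#'   Background activations are stratified per time point - each column
#'   receives the same number, at randomly chosen proteins - so that no time
#'   point is accidentally favored by sampling noise.
#' @param epsilon Binarization penalty factor the expression values are
#'   constructed for (default 0.6).
#' @param noise_sd Gaussian noise added to the two-level expression
#'   construction (default 0.05).
#' @param tap_signal,tap_noise Mean raw purification score of co-complex vs
#'   background pairs (defaults 5 and 2, unit SD).
#' @param tap_missing Fraction of PPI edges absent from each TAP source
#'   (default 0.3, independently per source).
#' @param rng_seed Integer seed (default 1).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_proteins = 300, n_timepoints = 12,
                           complex_sizes = c(5, 7, 8, 9, 10, 12),
                           internal_edge_prob = 1, shared_proteins = 2,
                           background_edge_prob = 0.02,
                           biclusters_per_complexes = 2,
                           p_in = 1, p_out = 0.05, epsilon = 0.6,
                           noise_sd = 0.05, tap_signal = 5, tap_noise = 2,
                           tap_missing = 0.3, rng_seed = 1) {
  probs <- c(internal_edge_prob, background_edge_prob, p_in, p_out, tap_missing)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (p_in <= p_out) stop("p_in must exceed p_out", call. = FALSE)
  n_needed <- sum(complex_sizes) - shared_proteins
  if (n_needed > n_proteins) stop("complex sizes exceed the protein universe", call. = FALSE)
  n_bic <- ceiling(length(complex_sizes) / biclusters_per_complexes)
  if (n_bic > n_timepoints) stop("more biclusters than time points", call. = FALSE)
  structure(list(n_proteins = n_proteins, n_timepoints = n_timepoints,
                 complex_sizes = complex_sizes,
                 internal_edge_prob = internal_edge_prob,
                 shared_proteins = shared_proteins,
                 background_edge_prob = background_edge_prob,
                 biclusters_per_complexes = biclusters_per_complexes,
                 p_in = p_in, p_out = p_out, epsilon = epsilon,
                 noise_sd = noise_sd, tap_signal = tap_signal,
                 tap_noise = tap_noise, tap_missing = tap_missing,
                 rng_seed = rng_seed),
            class = "fixture_config")
}

# inactive expression level l (active level is 1) such that the row threshold
# |mu - sigma*eps| separates the two levels with maximal margin
choose_inactive_level <- function(k, n, eps) {
  if (k >= n) return(0)
  d <- (k - eps * sqrt(k * (n - k))) / n
  grid <- seq(-1.5, 0.9, by = 0.01)
  thr <- abs(grid + (1 - grid) * d)
  margin <- pmin(thr - grid, 1 - thr)
  margin[thr <= grid | thr >= 1] <- -Inf
  grid[which.max(margin)]
}

#' Generate a synthetic benchmark bundle
#'
#' Produces an internally consistent set of inputs for the whole pipeline:
#' a PPI edge list (planted dense complexes plus Erdos-Renyi background), two
#' TAP score tables with elevated co-complex scores, a time-course expression
#' matrix whose binarization recovers the planted activity pattern, a toy GO
#' (three aspects; per-complex marker terms plus generic terms) with GAF-style
#' annotations, and the ground-truth complexes and biclusters.
#'
#' @param config A [fixture_config()].
#' @param dir Optional directory: when given, every component is also written
#'   in its flat-file dialect and the paths returned under `$paths`.
#' @return A list bundle: `ppi`, `tap_lcms`, `tap_maldi`, `ge`, `dag`,
#'   `annotations` (direct annotation tibble), `truth_complexes`,
#'   `truth_biclusters`, `nge_truth` (planted 0/1 matrix),
#'   `binarize_agreement` (post-hoc fraction of cells where
#'   `binarize(ge, epsilon)` matches `nge_truth`), `config`, and optionally
#'   `paths`.
#' @export
generate_fixture <- function(config = fixture_config(), dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$rng_seed)
  np <- config$n_proteins; nt <- config$n_timepoints
  proteins <- sprintf("P%03d", seq_len(np))
  timepoints <- sprintf("T%02d", seq_len(nt))

  # --- planted complex membership (last two complexes share proteins) ---
  sizes <- config$complex_sizes
  nc <- length(sizes)
  members <- vector("list", nc)
  cursor <- 0L
  for (c in seq_len(nc)) {
    fresh <- sizes[c]
    reuse <- character()
    if (c == nc && nc >= 2L && config$shared_proteins > 0L) {
      reuse <- utils::tail(members[[c - 1L]], config$shared_proteins)
      fresh <- sizes[c] - length(reuse)
    }
    members[[c]] <- c(reuse, proteins[cursor + seq_len(fresh)])
    cursor <- cursor + fresh
  }
  truth_complexes <- as_complex_tbl(members)

  # --- PPI: intra-complex edges + background ---
  edge_env <- new.env(parent = emptyenv())
  add_edge <- function(a, b) {
    k <- paste(min(a, b), max(a, b), sep = "\t")
    edge_env[[k]] <- TRUE
  }
  co_complex <- new.env(parent = emptyenv())
  for (c in seq_len(nc)) {
    prs <- utils::combn(sort(members[[c]]), 2L)
    for (i in seq_len(ncol(prs))) {
      co_complex[[paste(prs[1, i], prs[2, i], sep = "\t")]] <- TRUE
      if (stats::runif(1) < config$internal_edge_prob) add_edge(prs[1, i], prs[2, i])
    }
  }
  if (config$background_edge_prob > 0) {
    all_pairs <- utils::combn(proteins, 2L)
    keep <- stats::runif(ncol(all_pairs)) < config$background_edge_prob
    for (i in which(keep)) add_edge(all_pairs[1, i], all_pairs[2, i])
  }
  keys <- sort(ls(edge_env))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  ppi <- new_edge_tbl(vapply(parts, `[[`, character(1), 1L),
                      vapply(parts, `[[`, character(1), 2L))

  # --- TAP scores over PPI edges, higher for co-complex pairs ---
  is_co <- vapply(keys, function(k) isTRUE(co_complex[[k]]), logical(1))
  mk_tap <- function(source) {
    raw <- stats::rnorm(length(keys),
                        mean = ifelse(is_co, config$tap_signal, config$tap_noise),
                        sd = 1)
    present <- stats::runif(length(keys)) >= config$tap_missing
    new_tap_tbl(ppi$protein_a[present], ppi$protein_b[present],
                raw[present], source)
  }
  tap_lcms <- mk_tap("LCMS")
  tap_maldi <- mk_tap("MALDI")

  # --- toy GO: per aspect one root, 5 generic terms, one marker per complex ---
  aspects <- c("BP", "CC", "MF")
  term_ids <- character(); term_aspect <- character(); parents <- list()
  root_of <- stats::setNames(sprintf("GO:%s00000", c("10", "20", "30")), aspects)
  for (a in aspects) {
    root <- root_of[[a]]
    term_ids <- c(term_ids, root); term_aspect <- c(term_aspect, a)
    parents[[root]] <- character()
    for (g in 1:5) {
      id <- sprintf("GO:%s0%03d", substr(root_of[[a]], 4, 5), g)
      term_ids <- c(term_ids, id); term_aspect <- c(term_aspect, a)
      parents[[id]] <- root
    }
    for (c in seq_len(nc)) {
      id <- sprintf("GO:%s1%03d", substr(root_of[[a]], 4, 5), c)
      term_ids <- c(term_ids, id); term_aspect <- c(term_aspect, a)
      parents[[id]] <- root
    }
  }
  dag <- new_ontology_dag(term_ids, term_aspect, parents)
  marker <- function(a, c) sprintf("GO:%s1%03d", substr(root_of[[a]], 4, 5), c)
  generic <- function(a, g) sprintf("GO:%s0%03d", substr(root_of[[a]], 4, 5), g)
  complex_of <- stats::setNames(rep(NA_integer_, np), proteins)
  for (c in seq_len(nc)) complex_of[members[[c]]] <- c
  ann <- list()
  for (a in aspects) {
    g1 <- sample.int(5, np, replace = TRUE)
    terms <- lapply(seq_len(np), function(i) {
      t <- generic(a, g1[i])
      if (!is.na(complex_of[i])) t <- c(t, marker(a, complex_of[i]))
      t
    })
    ann[[a]] <- tibble::tibble(protein = rep(proteins, lengths(terms)),
                               term = unlist(terms), aspect = a)
  }
  annotations <- dplyr::bind_rows(ann)

  # --- planted activity pattern and expression matrix ---
  pat <- matrix(0L, nrow = np, ncol = nt, dimnames = list(proteins, timepoints))
  n_bic <- ceiling(nc / config$biclusters_per_complexes)
  # periodic phase assignment: module b is active at every n_bic-th time
  # point, emulating modules that peak once per cycle in a repeated
  # (cell-cycle-like) time course
  tp_block <- split(seq_len(nt), rep_len(seq_len(n_bic), nt))
  # group complexes into bicluster blocks; with 2 per block, pair the
  # smallest with the largest so block sizes stay comparable
  if (config$biclusters_per_complexes == 2L && nc >= 2L) {
    by_size <- order(sizes)
    groups <- lapply(seq_len(n_bic), function(b) {
      unique(c(by_size[b], by_size[nc + 1L - b]))
    })
  } else {
    groups <- split(seq_len(nc),
                    ceiling(seq_len(nc) / config$biclusters_per_complexes))
  }
  bic_proteins <- vector("list", n_bic)
  for (b in seq_len(n_bic)) {
    bic_proteins[[b]] <- sort(unique(unlist(members[groups[[b]]])))
    block <- pat[bic_proteins[[b]], tp_block[[b]], drop = FALSE]
    pat[bic_proteins[[b]], tp_block[[b]]] <-
      matrix(stats::rbinom(length(block), 1L, config$p_in), nrow = nrow(block))
  }
  # stratified background activity: the same number of background
  # activations per time point, at randomly drawn off-module proteins
  block_of_col <- rep(seq_len(n_bic), lengths(tp_block))[order(unlist(tp_block))]
  for (j in seq_len(nt)) {
    eligible <- setdiff(proteins, bic_proteins[[block_of_col[j]]])
    n_act <- round(config$p_out * length(eligible))
    if (n_act > 0L) pat[sample(eligible, n_act), j] <- 1L
  }
  truth_biclusters <- tibble::tibble(
    bicluster_id = seq_len(n_bic),
    proteins = bic_proteins,
    timepoints = lapply(tp_block, function(j) timepoints[j])
  )
  ge <- matrix(0, nrow = np, ncol = nt, dimnames = list(proteins, timepoints))
  for (i in seq_len(np)) {
    k <- sum(pat[i, ])
    l <- choose_inactive_level(k, nt, config$epsilon)
    ge[i, ] <- ifelse(pat[i, ] == 1L, 1, l) + stats::rnorm(nt, sd = config$noise_sd)
  }
  agreement <- mean(binarize(ge, config$epsilon)$nge == pat)

  bundle <- list(ppi = ppi, tap_lcms = tap_lcms, tap_maldi = tap_maldi,
                 ge = ge, dag = dag, annotations = annotations,
                 truth_complexes = truth_complexes,
                 truth_biclusters = truth_biclusters,
                 nge_truth = pat, binarize_agreement = agreement,
                 config = config)
  if (!is.null(dir)) bundle$paths <- write_fixture(bundle, dir)
  bundle
}

# write every bundle component in its external dialect
write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  writeLines(paste(bundle$ppi$protein_a, bundle$ppi$protein_b, sep = "\t"), p("ppi.tsv"))
  for (src in c("lcms", "maldi")) {
    tap <- bundle[[paste0("tap_", src)]]
    writeLines(paste(tap$protein_a, tap$protein_b,
                     format(tap$score, digits = 10, trim = TRUE), sep = "\t"),
               p(paste0("tap_", src, ".tsv")))
  }
  write_ge_matrix(bundle$ge, p("ge.tsv"))
  write_obo(bundle$dag, p("go.obo"))
  write_gaf(bundle$annotations, p("annotations.gaf"))
  write_complex_set(bundle$truth_complexes, p("truth_complexes.txt"))
  write_biclusters(dplyr::mutate(bundle$truth_biclusters, fitness = 1),
                   p("truth_biclusters.tsv"))
  list(ppi = p("ppi.tsv"), tap_lcms = p("tap_lcms.tsv"),
       tap_maldi = p("tap_maldi.tsv"), ge = p("ge.tsv"), obo = p("go.obo"),
       gaf = p("annotations.gaf"), truth_complexes = p("truth_complexes.txt"),
       truth_biclusters = p("truth_biclusters.tsv"))
}

write_obo <- function(dag, path) {
  ns_of <- c(BP = "biological_process", CC = "cellular_component",
             MF = "molecular_function")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms$term[i]
    ps <- dag$parents[[t]]
    writeLines(c("[Term]", paste0("id: ", t),
                 paste0("name: synthetic term ", t),
                 paste0("namespace: ", ns_of[[dag$terms$aspect[i]]]),
                 if (length(ps)) paste0("is_a: ", ps, " ! parent"),
                 ""), con)
  }
  invisible(path)
}

write_gaf <- function(annotations, path) {
  letter <- c(BP = "P", CC = "C", MF = "F")
  lines <- paste("SYN", annotations$protein, annotations$protein, "",
                 annotations$term, "SYN_REF", "IEA", "",
                 letter[annotations$aspect], "", "", "protein",
                 "taxon:4932", "20260101", "SYN", sep = "\t")
  writeLines(c("!gaf-version: 2.1", lines), path)
  invisible(path)
}
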