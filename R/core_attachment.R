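#' Weighted clustering coefficient of a node
#'
#' `wcc(v) = sum of the weights of v's incident edges / (|L| * (|L| - 1))`
#' where `L` is the set of edges incident to `v` in the governing network.
#' Nodes with at most one incident edge carry no clustering evidence and
#' score 0. Note the denominator makes the score fall with degree: within a
#' unit-weight k-clique every node scores `1 / (k - 2)`.
#'
#' @param v Protein ID.
#' @param net A `weighted_ppi` network (edge tibble with `w` and a
#'   `proteins` attribute).
#' @return Non-negative score.
#' @export
wcc_node <- function(v, net) {
  nodes <- attr(net, "proteins") %||% unique(c(net$protein_a, net$protein_b))
  if (!v %in% nodes) stop("protein '", v, "' is not in the network", call. = FALSE)
  inc <- net$protein_a == v | net$protein_b == v
  deg <- sum(inc)
  if (deg <= 1L) return(0)
  sum(net$w[inc]) / (deg * (deg - 1))
}

# per-node degree and incident-weight sums for a whole edge table
node_wcc_table <- function(net, nodes = NULL) {
  nodes <- nodes %||% attr(net, "proteins") %||% unique(c(net$protein_a, net$protein_b))
  deg <- stats::setNames(numeric(length(nodes)), nodes)
  sw <- deg
  if (nrow(net) > 0L) {
    for (col in c("protein_a", "protein_b")) {
      t1 <- tapply(rep(1, nrow(net)), net[[col]], sum)
      w1 <- tapply(net$w, net[[col]], sum)
      t1 <- t1[names(t1) %in% nodes]; w1 <- w1[names(w1) %in% nodes]
      deg[names(t1)] <- deg[names(t1)] + t1
      sw[names(w1)] <- sw[names(w1)] + w1
    }
  }
  wcc <- ifelse(deg <= 1, 0, sw / (deg * pmax(deg - 1, 1)))
  tibble::tibble(protein = nodes, degree = as.numeric(deg), wcc = as.numeric(wcc))
}

#' Weighted clustering coefficient of a protein complex
#'
#' Mean of the node scores over the complex members, with each node's edge
#' set restricted to edges inside the complex: the score rates the complex's
#' own cohesion, not its environment.
#'
#' @param proteins Character vector of complex members.
#' @param net A `weighted_ppi` network providing the edge weights.
#' @return Non-negative score; 0 for an edgeless complex.
#' @export
wcc_complex <- function(proteins, net) {
  proteins <- unique(as.character(proteins))
  if (length(proteins) == 0L) return(0)
  induced <- net[net$protein_a %in% proteins & net$protein_b %in% proteins, ]
  if (nrow(induced) == 0L) return(0)
  mean(node_wcc_table(induced, nodes = proteins)$wcc)
}

#' Detection parameters for core-attachment complex discovery
#'
#' @param alpha_seed Seed-selection quantile in `[0, 1]`: seeds are the
#'   proteins whose node wcc reaches the `alpha_seed` quantile of the nonzero
#'   wcc distribution (0 selects every protein with nonzero wcc). Lower
#'   values yield more seeds.
#' @param beta Attachment threshold in `[0, 1]`: a neighbour joins a core
#'   when its edge count into the core, divided by the core size, reaches
#'   `beta`. Higher values yield smaller complexes.
#' @param redundancy_threshold Jaccard threshold for the redundancy filter
#'   (default 0.8).
#' @return A `detection_params` list.
#' @export
detection_params <- function(alpha_seed = 0.5, beta = 0.5,
                             redundancy_threshold = 0.8) {
  v <- c(alpha_seed = alpha_seed, beta = beta, redundancy_threshold = redundancy_threshold)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("detection_params: all parameters must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(v), class = "detection_params")
}

#' Select complex seeds from a weighted subnetwork
#'
#' Computes the node wcc for every protein and returns those at or above the
#' `alpha_seed` quantile of the nonzero wcc distribution, ordered by wcc
#' descending (ties by protein ID). The quantile rule makes the tuning range
#' scale-free across networks with different weight scales.
#'
#' @param net A `weighted_ppi` network.
#' @param alpha_seed Quantile in `[0, 1]`.
#' @return Character vector of seed proteins.
#' @export
select_seeds <- function(net, alpha_seed = 0.5) {
  tab <- node_wcc_table(net)
  nz <- tab$wcc[tab$wcc > 0]
  if (length(nz) == 0L) return(character())
  thr <- stats::quantile(nz, alpha_seed, names = FALSE, type = 7)
  tab <- tab[tab$wcc > 0 & tab$wcc >= thr, ]
  tab <- tab[order(-tab$wcc, tab$protein), ]
  tab$protein
}

#' Grow a complex core from a seed
#'
#' Greedy growth: starting from the seed, repeatedly add the neighbour of the
#' current core with the largest summed edge weight into the core (ties by
#' protein ID), accepting the addition only while the complex-level wcc does
#' not decrease; growth stops at the first rejection. This acceptance rule is
#' a reconstruction built from the package's own wcc machinery (the original
#' core-growing criterion of the core-attachment literature is not restated
#' here); in practice it stops cores at small dense kernels - e.g. a
#' triangle inside a clique - and the attachment step completes the complex.
#'
#' @param seed Seed protein (must be in the network).
#' @param net A `weighted_ppi` network.
#' @return Character vector of core proteins (always contains the seed).
#' @export
grow_core <- function(seed, net) {
  nodes <- attr(net, "proteins") %||% unique(c(net$protein_a, net$protein_b))
  if (!seed %in% nodes) stop("seed '", seed, "' is not in the network", call. = FALSE)
  core <- seed
  cur <- wcc_complex(core, net)
  repeat {
    inc <- net[(net$protein_a %in% core) != (net$protein_b %in% core), ]
    if (nrow(inc) == 0L) break
    other <- ifelse(inc$protein_a %in% core, inc$protein_b, inc$protein_a)
    sums <- tapply(inc$w, other, sum)
    best <- names(sums)[order(-sums, names(sums))][1]
    cand_wcc <- wcc_complex(c(core, best), net)
    if (cand_wcc < cur) break
    core <- c(core, best)
    cur <- cand_wcc
  }
  sort(core)
}

#' Attach peripheral proteins to a core
#'
#' A protein outside the core becomes an attachment when its number of edges
#' into the core, divided by the core size, reaches `beta`. Attachments are
#' judged against the original core only (not incrementally).
#'
#' @param core Character vector of core proteins (non-empty).
#' @param net A `weighted_ppi` network.
#' @param beta Attachment threshold in `[0, 1]`.
#' @return Character vector: the complex (core plus attachments).
#' @export
add_attachments <- function(core, net, beta = 0.5) {
  stopifnot(length(core) > 0L)
  inc <- net[(net$protein_a %in% core) != (net$protein_b %in% core), ]
  if (nrow(inc) > 0L) {
    other <- ifelse(inc$protein_a %in% core, inc$protein_b, inc$protein_a)
    cnt <- tapply(rep(1, nrow(inc)), other, sum)
    att <- names(cnt)[cnt / length(core) >= beta]
  } else {
    att <- character()
  }
  sort(unique(c(core, att)))
}

#' Remove redundant complexes
#'
#' Greedy pass over the complexes sorted by wcc (descending), then size
#' (descending), then member list: a complex is kept only if its Jaccard
#' similarity with every already-kept complex is below the threshold.
#'
#' @param complexes A complex tibble with a `wcc` column.
#' @param threshold Jaccard redundancy threshold (default 0.8).
#' @return The filtered complex tibble.
#' @export
filter_redundant <- function(complexes, threshold = 0.8) {
  if (nrow(complexes) == 0L) return(complexes)
  key <- vapply(complexes$proteins, paste, character(1), collapse = " ")
  wcc <- complexes$wcc %||% rep(0, nrow(complexes))
  ord <- order(-wcc, -complexes$size, key)
  kept <- list()
  keep_idx <- integer()
  for (i in ord) {
    p <- complexes$proteins[[i]]
    if (all(vapply(kept, function(k) jaccard(p, k), numeric(1)) < threshold)) {
      kept <- c(kept, list(p))
      keep_idx <- c(keep_idx, i)
    }
  }
  complexes[sort(keep_idx), ]
}

#' Detect protein complexes in a weighted subnetwork
#'
#' The four core-attachment steps: seed selection by node wcc quantile, core
#' growth under the non-decreasing complex-wcc rule, attachment of peripheral
#' proteins by edge-count fraction, and Jaccard redundancy filtering. The
#' procedure is fully deterministic.
#'
#' @param net A `weighted_ppi` (sub)network.
#' @param params A [detection_params()] object.
#' @param origin Optional label recorded on each complex (e.g. the
#'   subnetwork/bicluster ID).
#' @return A complex tibble: `complex_id`, `proteins`, `size`, `wcc`, `seed`,
#'   `origin`.
#' @export
detect_complexes <- function(net, params = detection_params(), origin = NA_character_) {
  seeds <- select_seeds(net, params$alpha_seed)
  if (length(seeds) == 0L) {
    out <- as_complex_tbl(list())
    out$wcc <- numeric(); out$seed <- character(); out$origin <- character()
    return(out)
  }
  members <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    core <- grow_core(seeds[k], net)
    members[[k]] <- add_attachments(core, net, params$beta)
  }
  out <- as_complex_tbl(members, origin = origin)
  out$seed <- seeds
  out$wcc <- vapply(out$proteins, wcc_complex, numeric(1), net = net)
  out <- filter_redundant(out, params$redundancy_threshold)
  out$complex_id <- seq_len(nrow(out))
  out
}
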