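#' Jaccard similarity of two protein sets
#'
#' `|intersection| / |union|`; defined as 0 when both sets are empty.
#'
#' @param c1,c2 Character vectors of protein IDs.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(c1, c2) {
  u <- length(union(c1, c2))
  if (u == 0L) return(0)
  length(intersect(c1, c2)) / u
}

complex_key <- function(proteins) {
  vapply(proteins, function(p) paste(sort(unique(p)), collapse = " "), character(1))
}

#' Partition the global complex set by size and similarity
#'
#' Complexes with fewer than 3 proteins are removed; those with 3-5 proteins
#' pass through to the final result untouched; those with 6 or more are
#' categorized greedily (largest first, ties by member list): a complex joins
#' the first category in which its Jaccard similarity with *every* current
#' member exceeds 0.8, otherwise it opens a new category. Every pair inside a
#' category is therefore similar at > 0.8 at categorization time.
#'
#' @param G A complex tibble (the pooled per-subnetwork results).
#' @return List with `passthrough` (complex tibble) and `categories` (list of
#'   lists of protein vectors).
#' @export
partition_global_set <- function(G) {
  sizes <- lengths(G$proteins)
  pass <- G[sizes >= 3L & sizes <= 5L, ]
  big <- G[sizes >= 6L, ]
  cats <- list()
  if (nrow(big) > 0L) {
    ord <- order(-lengths(big$proteins), complex_key(big$proteins))
    for (i in ord) {
      p <- sort(unique(big$proteins[[i]]))
      placed <- FALSE
      for (k in seq_along(cats)) {
        if (all(vapply(cats[[k]], function(m) jaccard(p, m), numeric(1)) > 0.8)) {
          cats[[k]] <- c(cats[[k]], list(p))
          placed <- TRUE
          break
        }
      }
      if (!placed) cats <- c(cats, list(list(p)))
    }
  }
  list(passthrough = pass, categories = cats)
}

#' Common part of a category
#'
#' The intersection of all member complexes; those proteins are removed from
#' every member (the residues).
#'
#' @param members List of protein vectors (non-empty).
#' @return List with `common_part` and `residues` (list of vectors).
#' @export
extract_common_part <- function(members) {
  stopifnot(length(members) > 0L)
  cp <- sort(Reduce(intersect, members))
  list(common_part = cp, residues = lapply(members, setdiff, y = cp))
}

#' Majority augmentation of a common part
#'
#' Every residual protein present in at least half of the category's members
#' is moved into the common part and removed from all members.
#'
#' @param common_part Protein vector from [extract_common_part()].
#' @param residues List of residual protein vectors (one per member).
#' @return List with the augmented `common_part` and the remaining
#'   `residues`.
#' @export
majority_augment <- function(common_part, residues) {
  k <- length(residues)
  tab <- table(unlist(residues, use.names = FALSE))
  promote <- names(tab)[as.integer(tab) >= k / 2]
  list(common_part = sort(union(common_part, promote)),
       residues = lapply(residues, setdiff, y = promote))
}

#' WCC-guarded expansion of a common part
#'
#' Each remaining residual protein (deduplicated, in lexicographic order) is
#' added to a copy of the common part; the candidate complex is emitted only
#' if its weighted clustering coefficient on the governing network strictly
#' exceeds that of the common part. Candidates never accumulate: every
#' residue is tested against the original common part, so the emitted set is
#' order-independent. The wcc is computed on the full weighted network
#' because a category can merge complexes from different subnetworks.
#'
#' @param common_part Protein vector (after [majority_augment()]).
#' @param residues List of residual protein vectors.
#' @param net The full `weighted_ppi` network.
#' @return List of emitted protein vectors (each `common_part + one residue`).
#' @export
wcc_guarded_expansion <- function(common_part, residues, net) {
  pool <- sort(setdiff(unique(unlist(residues, use.names = FALSE)), common_part))
  if (length(pool) == 0L) return(list())
  base <- wcc_complex(common_part, net)
  out <- list()
  for (p in pool) {
    cand <- sort(c(common_part, p))
    if (wcc_complex(cand, net) > base) out <- c(out, list(cand))
  }
  out
}

#' Aggregate per-subnetwork complexes into the final set
#'
#' The post-processing phase: pools all detected complexes, removes those
#' with fewer than 3 proteins, passes 3-5-protein complexes through,
#' categorizes similar large complexes (pairwise Jaccard > 0.8), and per
#' category emits the majority-augmented common part plus any wcc-improving
#' single-residue expansions. With `postprocessing_enabled = FALSE` the pooled
#' set is returned with only exact duplicates removed (the ablation mode).
#' The final set is always deduplicated on exact protein-set equality.
#'
#' @param G A complex tibble pooling all per-subnetwork results.
#' @param net The full `weighted_ppi` network (used by the wcc guard).
#' @param postprocessing_enabled Toggle for the ablation mode.
#' @return A complex tibble (`complex_id`, `proteins`, `size`), with a
#'   per-category audit log in `attr(, "audit")` when post-processing ran.
#' @export
aggregate_complexes <- function(G, net, postprocessing_enabled = TRUE) {
  if (!postprocessing_enabled) {
    keys <- complex_key(G$proteins)
    return(as_complex_tbl(G$proteins[!duplicated(keys)]))
  }
  part <- partition_global_set(G)
  final <- as.list(part$passthrough$proteins)
  audit <- list()
  for (k in seq_along(part$categories)) {
    members <- part$categories[[k]]
    cp <- extract_common_part(members)
    aug <- majority_augment(cp$common_part, cp$residues)
    expansions <- wcc_guarded_expansion(aug$common_part, aug$residues, net)
    final <- c(final, list(aug$common_part), expansions)
    n_res <- length(unique(unlist(aug$residues, use.names = FALSE)))
    audit[[k]] <- tibble::tibble(
      category = k, members = length(members),
      common_part_size = length(aug$common_part),
      residues = n_res, emitted = length(expansions),
      ignored = n_res - length(expansions))
  }
  keys <- complex_key(final)
  out <- as_complex_tbl(final[!duplicated(keys)])
  attr(out, "audit") <- if (length(audit)) dplyr::bind_rows(audit) else
    tibble::tibble(category = integer(), members = integer(),
                   common_part_size = integer(), residues = integer(),
                   emitted = integer(), ignored = integer())
  out
}
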