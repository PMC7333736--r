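#' Min-max normalize a TAP score table
#'
#' Purification scores are normalized per source to `[0, 1]` by
#' `(s - min) / (max - min)`. A degenerate table (all scores equal) maps to
#' 1.0; an empty table is returned unchanged.
#'
#' @param tap A TAP tibble from [read_tap_scores()].
#' @return The same tibble with `score` rescaled and `attr(, "normalized")`
#'   set to `TRUE`.
#' @export
normalize_tap <- function(tap) {
  if (nrow(tap) == 0L) {
    attr(tap, "normalized") <- TRUE
    return(tap)
  }
  lo <- min(tap$score); hi <- max(tap$score)
  tap$score <- if (hi == lo) rep(1, nrow(tap)) else (tap$score - lo) / (hi - lo)
  attr(tap, "normalized") <- TRUE
  tap
}

tap_lookup <- function(tap) {
  if (is.null(tap) || nrow(tap) == 0L) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(tap$score, paste(tap$protein_a, tap$protein_b, sep = "\t"))
}

#' TAP weight of a protein pair
#'
#' Mean of the normalized LCMS and MALDI purification scores when both are
#' present; the available score when only one is; 0.5 (the neutral value)
#' when the pair is absent from both sources.
#'
#' @param p1,p2 Protein IDs.
#' @param lcms,maldi Normalized TAP tibbles (see [normalize_tap()]); `NULL`
#'   for an unavailable source.
#' @return `W_TAP` in `[0, 1]`.
#' @export
tap_weight <- function(p1, p2, lcms = NULL, maldi = NULL) {
  key <- paste(min(p1, p2), max(p1, p2), sep = "\t")
  s1 <- unname(tap_lookup(lcms)[key])
  s2 <- unname(tap_lookup(maldi)[key])
  tap_weight_scalar(s1, s2)
}

tap_weight_scalar <- function(s1, s2) {
  if (is.null(s1) || length(s1) == 0L) s1 <- NA_real_
  if (is.null(s2) || length(s2) == 0L) s2 <- NA_real_
  if (!is.na(s1) && !is.na(s2)) (s1 + s2) / 2
  else if (!is.na(s1)) s1
  else if (!is.na(s2)) s2
  else 0.5
}

#' TAP coefficient of an edge
#'
#' `alpha_tap = 1 + (W_TAP - 0.5) * gamma`, where `gamma` in `[0, 1]` is the
#' impact factor of the TAP data. The coefficient lies in
#' `[1 - gamma/2, 1 + gamma/2]`; a pair absent from both TAP sources
#' (`W_TAP = 0.5`) gives the neutral coefficient 1.
#'
#' @param w_tap Normalized TAP weight(s) in `[0, 1]` (vectorized).
#' @param gamma TAP impact factor in `[0, 1]`.
#' @return `alpha_tap`, same length as `w_tap`.
#' @export
tap_coefficient <- function(w_tap, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    stop("gamma must be a single value in [0, 1]", call. = FALSE)
  }
  1 + (w_tap - 0.5) * gamma
}

#' Fused edge weight
#'
#' The final interaction weight `W = alpha_tap * W_GO`; the TAP coefficient
#' scales the GO similarity up or down by at most `gamma/2`.
#'
#' @param w_go GO weight(s) in `[0, 1]` (vectorized).
#' @param alpha_tap TAP coefficient(s) from [tap_coefficient()].
#' @return Non-negative fused weight(s), at most `(1 + gamma/2)`.
#' @export
fuse_edge_weight <- function(w_go, alpha_tap) {
  alpha_tap * w_go
}

#' Build a TAP-aware weighted PPI network
#'
#' Phase 1: every PPI edge is annotated with its GO weight `w_go`, TAP weight
#' `w_tap` (0.5 when absent from both sources), TAP coefficient `alpha_tap`
#' and fused weight `w = alpha_tap * w_go`. With `tap_enabled = FALSE`
#' (TAP-OFF ablation), `alpha_tap` is identically 1 and `w == w_go`.
#' TAP pairs not present in the PPI edge list never create edges.
#'
#' @param ppi Edge tibble from [read_ppi_edgelist()] (or any tibble with
#'   `protein_a`, `protein_b`).
#' @param go_weights Edge tibble with `w_go` (from [go_weight_edges()]), or a
#'   per-aspect weight table with columns `aspect`, `weight`, which is
#'   averaged per pair. Edges absent from it get `w_go = 0`.
#' @param tap_lcms,tap_maldi Raw TAP tibbles (normalized internally) or
#'   `NULL`.
#' @param gamma TAP impact factor in `[0, 1]`.
#' @param tap_enabled If `FALSE`, ignore TAP entirely (weights from GO only).
#' @return A `weighted_ppi` tibble: `protein_a`, `protein_b`, `w_go`,
#'   `w_lcms`, `w_maldi`, `w_tap`, `alpha_tap`, `w`; node set in
#'   `attr(, "proteins")`, `gamma` and `tap_enabled` as attributes.
#' @export
build_weighted_network <- function(ppi, go_weights, tap_lcms = NULL,
                                   tap_maldi = NULL, gamma = 0.3,
                                   tap_enabled = TRUE) {
  net <- tibble::tibble(protein_a = pmin(ppi$protein_a, ppi$protein_b),
                        protein_b = pmax(ppi$protein_a, ppi$protein_b))
  net <- dplyr::distinct(dplyr::arrange(net, .data$protein_a, .data$protein_b))
  if ("aspect" %in% names(go_weights)) {
    net <- go_weight_edges(net, weight_table = go_weights)
  } else {
    stopifnot("w_go" %in% names(go_weights))
    net <- dplyr::left_join(
      net, go_weights[c("protein_a", "protein_b", "w_go")],
      by = c("protein_a", "protein_b"))
    net$w_go[is.na(net$w_go)] <- 0
  }
  key <- paste(net$protein_a, net$protein_b, sep = "\t")
  lk1 <- tap_lookup(if (!is.null(tap_lcms)) normalize_tap(tap_lcms))
  lk2 <- tap_lookup(if (!is.null(tap_maldi)) normalize_tap(tap_maldi))
  net$w_lcms <- unname(lk1[key])
  net$w_maldi <- unname(lk2[key])
  net$w_tap <- vapply(seq_len(nrow(net)), function(i) {
    tap_weight_scalar(net$w_lcms[i], net$w_maldi[i])
  }, numeric(1))
  if (tap_enabled) {
    net$alpha_tap <- tap_coefficient(net$w_tap, gamma)
  } else {
    net$alpha_tap <- rep(1, nrow(net))
  }
  net$w <- fuse_edge_weight(net$w_go, net$alpha_tap)
  attr(net, "proteins") <- sort(unique(c(net$protein_a, net$protein_b)))
  attr(net, "gamma") <- gamma
  attr(net, "tap_enabled") <- tap_enabled
  class(net) <- c("weighted_ppi", class(net))
  net
}

#' @export
print.weighted_ppi <- function(x, ...) {
  cat("TAP-aware weighted PPI network: ", length(attr(x, "proteins")),
      " proteins, ", nrow(x), " edges (gamma = ", attr(x, "gamma"),
      ", TAP ", if (isTRUE(attr(x, "tap_enabled"))) "on" else "off", ")\n",
      sep = "")
  NextMethod()
}
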