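# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths, plus small fixture builders.

# build a weighted_ppi edge tibble by hand
mk_net <- function(a, b, w, proteins = NULL) {
  net <- tibble::tibble(protein_a = pmin(a, b), protein_b = pmax(a, b), w = w)
  attr(net, "proteins") <- sort(unique(c(a, b, proteins)))
  class(net) <- c("weighted_ppi", class(net))
  net
}

# unit-weight clique edge table
mk_clique <- function(ids, w = 1) {
  prs <- utils::combn(ids, 2L)
  mk_net(prs[1, ], prs[2, ], rep(w, ncol(prs)))
}

# Eq 8 by explicit double loop
oracle_fitness <- function(chrom, nge) {
  m <- nrow(nge); n <- ncol(nge)
  I <- which(chrom[1:m] == 1L); J <- which(chrom[m + (1:n)] == 1L)
  if (length(I) == 0 || length(J) == 0) return(0)
  s <- 0
  for (i in I) for (j in J) s <- s + (nge[i, j] == 1)
  s / (length(I) * length(J))
}

# Eq 9 on explicit sets
oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- unique(c(a, b))
  if (length(u) == 0) return(0)
  sum(a %in% b) / length(u)
}

# Eq 10 by explicit edge scan over an edge data frame
oracle_wcc_node <- function(v, edges) {
  inc <- edges[edges$protein_a == v | edges$protein_b == v, ]
  if (nrow(inc) <= 1) return(0)
  sum(inc$w) / (nrow(inc) * (nrow(inc) - 1))
}

# Eq 11: mean of Eq 10 over members, edges restricted to the complex
oracle_wcc_complex <- function(members, edges) {
  if (length(members) == 0) return(0)
  induced <- edges[edges$protein_a %in% members & edges$protein_b %in% members, ]
  mean(vapply(members, oracle_wcc_node, numeric(1), edges = induced))
}

# ancestors-inclusive closure by fixed-point parent expansion
oracle_closure <- function(terms, parents) {
  out <- terms
  repeat {
    nxt <- unique(c(out, unlist(parents[out], use.names = FALSE)))
    if (length(nxt) == length(out)) return(sort(out))
    out <- nxt
  }
}

# SimGIC from explicit closures
oracle_simgic <- function(t1, t2, parents, ic) {
  c1 <- oracle_closure(t1, parents); c2 <- oracle_closure(t2, parents)
  den <- sum(ic[unique(c(c1, c2))])
  if (den <= 0) return(0)
  sum(ic[c1[c1 %in% c2]]) / den
}

# Eqs 12-14 by explicit double loop
oracle_evaluate <- function(detected, benchmark, th) {
  nd <- length(detected); nb <- length(benchmark)
  dm <- logical(nd); bm <- logical(nb)
  for (i in seq_len(nd)) for (j in seq_len(nb)) {
    if (oracle_jaccard(detected[[i]], benchmark[[j]]) >= th) {
      dm[i] <- TRUE; bm[j] <- TRUE
    }
  }
  p <- if (nd == 0) 0 else mean(dm)
  r <- mean(bm)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

# random 0/1 matrix with dimnames
rand_nge <- function(m, n, p = 0.4) {
  matrix(rbinom(m * n, 1L, p), nrow = m,
         dimnames = list(sprintf("p%02d", 1:m), sprintf("t%02d", 1:n)))
}

# random chromosome for an m x n matrix
rand_chrom <- function(m, n, p = 0.5) as.integer(runif(m + n) < p)

# small shared fixture bundle (cheap enough to rebuild per file)
small_fixture <- function(seed = 1) {
  generate_fixture(fixture_config(
    n_proteins = 60, n_timepoints = 6, complex_sizes = c(5, 6),
    shared_proteins = 0, background_edge_prob = 0.03, rng_seed = seed))
}
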