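#' Binarize a gene-expression matrix into activity calls
#'
#' Per protein (row) `i`, the mean `mu[i]` and population standard deviation
#' `sigma[i]` (divide by `n`) are computed over its time points, and
#' `nge[i, j] = 1` iff `ge[i, j] >= |mu[i] - sigma[i] * epsilon|` (equality is
#' active). `epsilon` is the penalty factor: larger values push the threshold
#' away from the mean, making the activity matrix sparser. Each row is
#' binarized independently of all others.
#'
#' @param ge Numeric matrix (proteins x time points) with dimnames.
#' @param epsilon Penalty factor, `>= 0`. Default 0.6.
#' @param prescale If `TRUE`, min-max rescale each row to `[0, 1]` first,
#'   for parity with pipelines that persist a rescaled matrix. The threshold
#'   is equivariant under positive scaling of a row, so pure rescaling never
#'   changes the calls; the min-max *shift*, however, can flip the sign
#'   inside `|mu - sigma * epsilon|` and alter calls for rows where
#'   `mu < sigma * epsilon`. Off by default; see the methods vignette.
#' @return A `binary_activity` object: list with `nge` (0/1 matrix), `mu`,
#'   `sigma`, `epsilon`.
#' @export
binarize <- function(ge, epsilon = 0.6, prescale = FALSE) {
  stopifnot(is.matrix(ge), is.numeric(ge), epsilon >= 0)
  if (prescale) {
    rng <- apply(ge, 1L, function(r) c(min(r), max(r)))
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1
    ge <- (ge - rng[1, ]) / span
  }
  n <- ncol(ge)
  mu <- rowMeans(ge)
  sigma <- sqrt(rowSums((ge - mu)^2) / n)   # population SD
  thr <- abs(mu - sigma * epsilon)
  nge <- (ge >= thr) * 1L
  structure(list(nge = nge, mu = mu, sigma = sigma, epsilon = epsilon),
            class = "binary_activity")
}

as_nge <- function(x) {
  if (inherits(x, "binary_activity")) x$nge else x
}

# protein part = bits[1:m], time part = bits[m + (1:n)]
chrom_sets <- function(bits, m, n) {
  list(I = which(bits[seq_len(m)] == 1L),
       J = which(bits[m + seq_len(n)] == 1L))
}

#' Bicluster fitness
#'
#' The proportion of active cells in the submatrix selected by the
#' chromosome: `F_b = sum(nge[I, J]) / (|I| * |J|)`, in `[0, 1]`. A
#' degenerate chromosome (empty protein or time-point part) has fitness 0.
#'
#' @param chrom Binary vector of length `m + n` (protein part first).
#' @param nge A `binary_activity` object or 0/1 matrix.
#' @return Fitness in `[0, 1]`.
#' @export
fitness <- function(chrom, nge) {
  nge <- as_nge(nge)
  m <- nrow(nge); n <- ncol(nge)
  stopifnot(length(chrom) == m + n)
  s <- chrom_sets(chrom, m, n)
  if (length(s$I) == 0L || length(s$J) == 0L) return(0)
  sum(nge[s$I, s$J]) / (length(s$I) * length(s$J))
}

#' Binary tournament selection
#'
#' Draws two individuals uniformly without replacement and returns the index
#' of the fitter one (ties go to the first drawn). Two independent
#' tournaments give the two parents.
#'
#' @param fits Numeric vector of population fitness values (length >= 2).
#' @return Integer vector of two parent indices.
#' @export
tournament_select <- function(fits) {
  if (length(fits) < 2L) stop("population must have at least 2 individuals", call. = FALSE)
  one <- function() {
    cand <- sample.int(length(fits), 2L)
    cand[which.max(fits[cand])]   # which.max: first drawn wins ties
  }
  c(one(), one())
}

#' Two-point crossover on the protein part
#'
#' With probability `p_crossover` two distinct cut positions are drawn from
#' `0..m` and the protein-part segment between them is swapped between the
#' parents; the time-point parts are always copied unchanged. Otherwise the
#' children are clones of the parents.
#'
#' @param a,b Parent chromosomes (equal length `m + n`).
#' @param m Number of proteins (length of the protein part).
#' @param p_crossover Crossover probability (default 0.9).
#' @return List of two child chromosomes.
#' @export
two_point_crossover <- function(a, b, m, p_crossover = 0.9) {
  stopifnot(length(a) == length(b), m <= length(a))
  if (stats::runif(1) >= p_crossover) return(list(a, b))
  cuts <- sort(sample.int(m + 1L, 2L) - 1L)    # distinct positions in 0..m
  seg <- if (cuts[2] > cuts[1]) (cuts[1] + 1L):cuts[2] else integer()
  c1 <- a; c2 <- b
  c1[seg] <- b[seg]
  c2[seg] <- a[seg]
  list(c1, c2)
}

#' Bitwise mutation
#'
#' Protein bits flip independently with probability `p_protein` (default
#' 0.001); time-point bits with probability `p_time` (default 0.1). The
#' higher time-point rate compensates for crossover never touching the
#' time-point part.
#'
#' @param chrom Chromosome to mutate.
#' @param m Number of proteins.
#' @param p_protein,p_time Flip probabilities.
#' @return Mutated chromosome.
#' @export
mutate_chromosome <- function(chrom, m, p_protein = 0.001, p_time = 0.1) {
  n <- length(chrom) - m
  flips <- stats::runif(m + n) < c(rep(p_protein, m), rep(p_time, n))
  chrom[flips] <- 1L - chrom[flips]
  chrom
}

#' Lamarckian local search
#'
#' Hill climbing to a local optimum of the bicluster fitness. Each sweep
#' scans the chromosome bits left to right (protein part, then time-point
#' part); each bit is tested with probability `p_bit` and its flip is kept
#' only if the fitness strictly increases. Sweeps repeat until one accepts no
#' flip, so the returned chromosome is locally optimal with respect to the
#' bits that were tested; its fitness never falls below the input fitness.
#' Incremental bookkeeping of the selected submatrix sums makes each test
#' O(1).
#'
#' @param chrom Chromosome.
#' @param nge A `binary_activity` object or 0/1 matrix.
#' @param p_bit Probability of testing each bit within a sweep (default 0.8).
#' @param max_sweeps Safety cap on the number of sweeps (default 100).
#' @return Improved chromosome with its fitness in `attr(, "fitness")`.
#' @export
local_search <- function(chrom, nge, p_bit = 0.8, max_sweeps = 100) {
  nge <- as_nge(nge)
  m <- nrow(nge); n <- ncol(nge)
  stopifnot(length(chrom) == m + n)
  Ib <- chrom[seq_len(m)] == 1L
  Jb <- chrom[m + seq_len(n)] == 1L
  rs <- if (any(Jb)) rowSums(nge[, Jb, drop = FALSE]) else numeric(m)
  cs <- if (any(Ib)) colSums(nge[Ib, , drop = FALSE]) else numeric(n)
  kI <- sum(Ib); kJ <- sum(Jb)
  S <- sum(rs[Ib])
  fit <- if (kI > 0L && kJ > 0L) S / (kI * kJ) else 0
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    test <- stats::runif(m + n) < p_bit
    for (i in seq_len(m)) {
      if (!test[i]) next
      if (Ib[i]) { S2 <- S - rs[i]; kI2 <- kI - 1L } else { S2 <- S + rs[i]; kI2 <- kI + 1L }
      f2 <- if (kI2 > 0L && kJ > 0L) S2 / (kI2 * kJ) else 0
      if (f2 > fit) {
        cs <- cs + (if (Ib[i]) -1 else 1) * nge[i, ]
        Ib[i] <- !Ib[i]; S <- S2; kI <- kI2; fit <- f2
        improved <- TRUE
      }
    }
    for (j in seq_len(n)) {
      if (!test[m + j]) next
      if (Jb[j]) { S2 <- S - cs[j]; kJ2 <- kJ - 1L } else { S2 <- S + cs[j]; kJ2 <- kJ + 1L }
      f2 <- if (kI > 0L && kJ2 > 0L) S2 / (kI * kJ2) else 0
      if (f2 > fit) {
        rs <- rs + (if (Jb[j]) -1 else 1) * nge[, j]
        Jb[j] <- !Jb[j]; S <- S2; kJ <- kJ2; fit <- f2
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  out <- c(as.integer(Ib), as.integer(Jb))
  attr(out, "fitness") <- unname(fit)
  out
}

#' Memetic algorithm configuration
#'
#' Operator probabilities default to the canonical values (crossover 0.9,
#' protein-bit mutation 0.001, time-bit mutation 0.1, local-search bit test
#' 0.8); population size 100 and an iteration budget of 2000 with a fitness
#' goal of 0.95 are package defaults, all overridable.
#'
#' @param population_size Steady-state population size (>= 4).
#' @param max_iterations Iteration budget.
#' @param fitness_goal Stop early once every individual reaches this fitness.
#' @param p_crossover,p_mut_protein,p_mut_time,p_localsearch_bit Operator
#'   probabilities in `[0, 1]`.
#' @param n_biclusters Number of biclusters to return.
#' @param local_search_enabled Disable for the genetic-algorithm ablation
#'   (approximation: no local refinement; consider also equalizing the
#'   mutation rates).
#' @param rng_seed Optional integer seed applied at the start of
#'   [run_memetic()].
#' @return A `memetic_config` list.
#' @export
memetic_config <- function(population_size = 100, max_iterations = 2000,
                           fitness_goal = 0.95, p_crossover = 0.9,
                           p_mut_protein = 0.001, p_mut_time = 0.1,
                           p_localsearch_bit = 0.8, n_biclusters = 10,
                           local_search_enabled = TRUE, rng_seed = NULL) {
  probs <- c(fitness_goal, p_crossover, p_mut_protein, p_mut_time, p_localsearch_bit)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("memetic_config: probabilities and fitness_goal must lie in [0, 1]", call. = FALSE)
  }
  if (population_size < 4) stop("memetic_config: population_size must be >= 4", call. = FALSE)
  if (max_iterations < 1) stop("memetic_config: max_iterations must be >= 1", call. = FALSE)
  if (n_biclusters < 1) stop("memetic_config: n_biclusters must be >= 1", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 fitness_goal = fitness_goal, p_crossover = p_crossover,
                 p_mut_protein = p_mut_protein, p_mut_time = p_mut_time,
                 p_localsearch_bit = p_localsearch_bit,
                 n_biclusters = as.integer(n_biclusters),
                 local_search_enabled = isTRUE(local_search_enabled),
                 rng_seed = rng_seed),
            class = "memetic_config")
}

#' Run the Lamarckian memetic biclustering algorithm
#'
#' Steady-state loop: random initial population; each iteration selects two
#' parents by binary tournament, applies two-point crossover on the protein
#' part, mutates, locally refines both children (the refined individuals are
#' written back into the population - Lamarckian learning), inserts them and
#' removes the two worst individuals. The loop stops at `max_iterations` or
#' once every individual reaches `fitness_goal`. The final population is
#' sorted by fitness (ties: larger bicluster area first, then bit-string) and
#' the top `n_biclusters` distinct, non-degenerate chromosomes are decoded.
#'
#' @param nge A `binary_activity` object or named 0/1 matrix.
#' @param config A [memetic_config()].
#' @return A bicluster tibble: `bicluster_id`, `proteins` (list-column),
#'   `timepoints` (list-column), `n_proteins`, `n_timepoints`, `fitness`;
#'   the per-iteration best-fitness trace is in `attr(, "trace")`.
#' @export
run_memetic <- function(nge, config = memetic_config()) {
  if (!inherits(config, "memetic_config")) stop("config must be a memetic_config", call. = FALSE)
  act <- as_nge(nge)
  m <- nrow(act); n <- ncol(act)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  # random init: protein bits Bernoulli(0.5); time bits Bernoulli(0.9), so
  # that early candidates span most of the time course and the search prunes
  # time points rather than having to rediscover them
  pop <- lapply(seq_len(config$population_size), function(i) {
    as.integer(stats::runif(m + n) < c(rep(0.5, m), rep(0.9, n)))
  })
  fits <- vapply(pop, fitness, numeric(1), nge = act)
  trace <- numeric(config$max_iterations)
  refine <- function(ch) {
    if (config$local_search_enabled) {
      out <- local_search(ch, act, config$p_localsearch_bit)
      list(chrom = as.integer(out), fit = attr(out, "fitness"))
    } else {
      list(chrom = ch, fit = fitness(ch, act))
    }
  }
  iters <- 0L
  for (it in seq_len(config$max_iterations)) {
    iters <- it
    par <- tournament_select(fits)
    kids <- two_point_crossover(pop[[par[1]]], pop[[par[2]]], m, config$p_crossover)
    kids <- lapply(kids, mutate_chromosome, m = m,
                   p_protein = config$p_mut_protein, p_time = config$p_mut_time)
    kids <- lapply(kids, refine)
    pop <- c(pop, list(kids[[1]]$chrom, kids[[2]]$chrom))
    fits <- c(fits, kids[[1]]$fit, kids[[2]]$fit)
    worst <- order(fits)[1:2]
    pop <- pop[-worst]
    fits <- fits[-worst]
    trace[it] <- max(fits)
    if (min(fits) >= config$fitness_goal) break
  }
  ord_key <- vapply(pop, paste, character(1), collapse = "")
  area <- vapply(pop, function(ch) {
    s <- chrom_sets(ch, m, n); length(s$I) * length(s$J)
  }, numeric(1))
  ord <- order(-fits, -area, ord_key)
  pop <- pop[ord]; fits <- fits[ord]; area <- area[ord]; ord_key <- ord_key[ord]
  keep <- !duplicated(ord_key) & area > 0
  pop <- pop[keep]; fits <- fits[keep]
  if (length(pop) < config$n_biclusters) {
    rlang::inform(paste0("run_memetic: only ", length(pop),
                         " distinct non-degenerate biclusters available (",
                         config$n_biclusters, " requested)"))
  }
  take <- seq_len(min(config$n_biclusters, length(pop)))
  pnames <- rownames(act) %||% as.character(seq_len(m))
  tnames <- colnames(act) %||% as.character(seq_len(n))
  out <- tibble::tibble(
    bicluster_id = take,
    proteins = lapply(pop[take], function(ch) pnames[chrom_sets(ch, m, n)$I]),
    timepoints = lapply(pop[take], function(ch) tnames[chrom_sets(ch, m, n)$J]),
    fitness = fits[take]
  )
  out$n_proteins <- lengths(out$proteins)
  out$n_timepoints <- lengths(out$timepoints)
  attr(out, "trace") <- trace[seq_len(iters)]
  class(out) <- c("bicluster_set", class(out))
  out
}

#' Extract the dynamic subnetwork induced by a bicluster
#'
#' The subnetwork contains the bicluster's proteins that are present in the
#' weighted PPI network (isolated nodes retained) and every network edge with
#' both endpoints in that set, keeping all edge weights.
#'
#' @param proteins Character vector of bicluster proteins (or a one-row slice
#'   of a bicluster tibble).
#' @param net A `weighted_ppi` network.
#' @return A `weighted_ppi` subnetwork.
#' @export
extract_subnetwork <- function(proteins, net) {
  if (is.data.frame(proteins)) proteins <- unlist(proteins$proteins)
  proteins <- unique(as.character(proteins))
  nodes <- intersect(attr(net, "proteins"), proteins)
  if (length(nodes) == 0L) {
    rlang::warn("extract_subnetwork: no bicluster protein occurs in the network")
  }
  sub <- net[net$protein_a %in% nodes & net$protein_b %in% nodes, ]
  attr(sub, "proteins") <- sort(nodes)
  attr(sub, "gamma") <- attr(net, "gamma")
  attr(sub, "tap_enabled") <- attr(net, "tap_enabled")
  class(sub) <- unique(c("weighted_ppi", class(sub)))
  sub
}

`%||%` <- function(x, y) if (is.null(x)) y else x
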