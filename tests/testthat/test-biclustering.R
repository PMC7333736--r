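test_that("binarization matches hand-computed thresholds", {
  ge1 <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("A", c("t1", "t2", "t3")))
  act <- binarize(ge1, epsilon = 0)
  expect_equal(unname(act$nge[1, ]), c(0, 1, 1))   # threshold |mu| = 2, equality active
  expect_equal(unname(act$mu), 2)

  ge2 <- matrix(rep(3, 4), nrow = 1, dimnames = list("A", paste0("t", 1:4)))
  expect_equal(unname(binarize(ge2, 0.8)$nge[1, ]), rep(1, 4))  # sigma 0, c >= |c|

  ge3 <- matrix(c(0.1, 0.9, 0.9, 0.1), nrow = 1,
                dimnames = list("A", paste0("t", 1:4)))
  act3 <- binarize(ge3, epsilon = 0.6)
  expect_equal(unname(act3$mu), 0.5)
  expect_equal(unname(act3$sigma), 0.4)            # population SD
  expect_equal(unname(act3$nge[1, ]), c(0, 1, 1, 0))
})

test_that("binarization is row-independent and invariant to positive row scaling", {
  set.seed(21)
  ge <- matrix(rnorm(60), nrow = 10,
               dimnames = list(paste0("p", 1:10), paste0("t", 1:6)))
  whole <- binarize(ge, 0.6)$nge
  for (i in c(1, 5, 10)) {
    solo <- binarize(ge[i, , drop = FALSE], 0.6)$nge
    expect_equal(unname(solo[1, ]), unname(whole[i, ]))
  }
  # |mu - sigma*eps| scales with the row, so the calls do not change
  scaled <- binarize(ge * 3.7, 0.6)$nge
  expect_equal(scaled, whole)
  # prescale = TRUE is exactly binarize() of the min-max rescaled matrix
  mm <- t(apply(ge, 1, function(r) (r - min(r)) / (max(r) - min(r))))
  dimnames(mm) <- dimnames(ge)
  expect_equal(binarize(ge, 0.6, prescale = TRUE)$nge, binarize(mm, 0.6)$nge)
})

test_that("fitness equals the brute-force double loop, with degenerate zero", {
  set.seed(2)
  nge <- rand_nge(8, 5)
  for (k in 1:200) {
    ch <- rand_chrom(8, 5)
    expect_equal(fitness(ch, nge), oracle_fitness(ch, nge))
  }
  expect_equal(fitness(rep(0L, 13), nge), 0)                    # empty I and J
  expect_equal(fitness(c(rep(1L, 8), rep(0L, 5)), nge), 0)      # empty J
  ones <- matrix(1L, 3, 2, dimnames = list(paste0("p", 1:3), paste0("t", 1:2)))
  expect_equal(fitness(rep(1L, 5), ones), 1)
  expect_equal(fitness(rep(1L, 5), matrix(0L, 3, 2)), 0)
  expect_equal(fitness(rep(1L, 4), matrix(c(1L, 1L, 1L, 0L), 2, 2)), 0.75)
})

test_that("binary tournament picks the fitter of two and is uniform under ties", {
  set.seed(4)
  fits <- c(0.9, 0.1)
  picks <- replicate(50, tournament_select(fits))
  expect_true(all(picks == 1L))  # the 0.9 individual always wins its tournament
  expect_error(tournament_select(0.5), "at least 2")
  # all-equal fitness: selection marginals are uniform (chi-squared over 1e4)
  eq <- rep(0.5, 8)
  draws <- as.vector(replicate(5000, tournament_select(eq)))
  p <- stats::chisq.test(table(factor(draws, levels = 1:8)))$p.value
  expect_gt(p, 1e-4)
})

test_that("crossover swaps only a protein segment and conserves positions", {
  set.seed(6)
  m <- 12; n <- 4
  for (k in 1:50) {
    a <- rand_chrom(m, n); b <- rand_chrom(m, n)
    kids <- two_point_crossover(a, b, m, p_crossover = 1)
    # per-position multiset conservation
    for (i in seq_len(m + n)) {
      expect_setequal(c(kids[[1]][i], kids[[2]][i]), c(a[i], b[i]))
    }
    # time parts copied unchanged
    expect_identical(kids[[1]][m + 1:n], a[m + 1:n])
    expect_identical(kids[[2]][m + 1:n], b[m + 1:n])
  }
  a <- rand_chrom(m, n)
  kids <- two_point_crossover(a, a, m, p_crossover = 1)
  expect_identical(kids[[1]], a)    # identical parents -> clones
  b <- rand_chrom(m, n)
  clones <- two_point_crossover(a, b, m, p_crossover = 0)
  expect_identical(clones, list(a, b))
})

test_that("mutation respects the per-part flip probabilities", {
  m <- 50000L
  chrom <- rep(0L, 2L * m)
  expect_identical(mutate_chromosome(chrom, m, 0, 0), chrom)
  expect_identical(mutate_chromosome(chrom, m, 1, 1), rep(1L, 2L * m))
  set.seed(8)
  flipped <- mutate_chromosome(chrom, m)    # defaults 0.001 / 0.1
  prot_flips <- sum(flipped[1:m])
  time_flips <- sum(flipped[(m + 1):(2 * m)])
  expect_lt(abs(prot_flips - m * 0.001), 3 * sqrt(m * 0.001 * 0.999))
  expect_lt(abs(time_flips - m * 0.1), 3 * sqrt(m * 0.1 * 0.9))
})

test_that("local search is monotone, idempotent at the optimum, and prunes", {
  ones <- matrix(1L, 3, 2, dimnames = list(paste0("p", 1:3), paste0("t", 1:2)))
  perfect <- rep(1L, 5)
  out <- local_search(perfect, ones, p_bit = 1)
  expect_identical(as.integer(out), perfect)   # no strict improvement possible
  # an inactive protein alongside an all-active block is cleared
  nge <- rbind(matrix(1L, 3, 4), matrix(0L, 1, 4))
  dimnames(nge) <- list(paste0("p", 1:4), paste0("t", 1:4))
  ch <- rep(1L, 8)
  out <- local_search(ch, nge, p_bit = 1)
  expect_identical(as.integer(out), c(1L, 1L, 1L, 0L, rep(1L, 4)))
  expect_equal(attr(out, "fitness"), 1)
  # monotonicity on 1000 random chromosomes
  set.seed(10)
  nge <- rand_nge(12, 6, 0.3)
  for (k in 1:1000) {
    ch <- rand_chrom(12, 6)
    res <- local_search(ch, nge)
    expect_gte(attr(res, "fitness"), fitness(ch, nge))
    expect_equal(attr(res, "fitness"), fitness(as.integer(res), nge))
  }
})

test_that("memetic run keeps a bounded population, improves monotonically, and is deterministic", {
  set.seed(3)
  nge <- rand_nge(20, 6, 0.35)
  cfg <- memetic_config(population_size = 6, max_iterations = 40,
                        fitness_goal = 1, n_biclusters = 10, rng_seed = 5)
  expect_message(bic <- run_memetic(nge, cfg), "distinct")
  expect_lte(nrow(bic), 6L)       # steady state: never more distinct than the population
  trace <- attr(bic, "trace")
  expect_true(all(diff(trace) >= 0))   # Lamarckian elitist steady state
  expect_true(all(bic$n_proteins > 0 & bic$n_timepoints > 0))
  key <- paste(sapply(bic$proteins, paste, collapse = " "),
               sapply(bic$timepoints, paste, collapse = " "), sep = "|")
  expect_false(any(duplicated(key)))
  bic2 <- run_memetic(nge, cfg)
  expect_identical(bic$proteins, bic2$proteins)   # same seed, same result
  expect_identical(bic$fitness, bic2$fitness)
  expect_error(memetic_config(population_size = 2), "population_size")
  expect_error(memetic_config(p_crossover = 1.2), "\\[0, 1\\]")
})

test_that("planted biclusters are recovered from a small activity matrix", {
  set.seed(12)
  nge <- rand_nge(30, 6, 0.05)
  nge[1:8, 1:3] <- 1L
  nge[9:16, 4:6] <- 1L
  bic <- run_memetic(nge, memetic_config(population_size = 40,
                                         max_iterations = 400,
                                         fitness_goal = 1,
                                         n_biclusters = 6, rng_seed = 7))
  for (block in list(rownames(nge)[1:8], rownames(nge)[9:16])) {
    js <- vapply(bic$proteins, jaccard, numeric(1), c2 = block)
    expect_gte(max(js), 0.9)
  }
})

test_that("subnetwork extraction induces exactly the internal edges", {
  set.seed(14)
  prs <- t(combn(sprintf("n%02d", 1:30), 2))
  keep <- sample(nrow(prs), 120)
  net <- mk_net(prs[keep, 1], prs[keep, 2], runif(120))
  pick <- sample(sprintf("n%02d", 1:30), 12)
  sub <- extract_subnetwork(pick, net)
  brute <- sum(prs[keep, 1] %in% pick & prs[keep, 2] %in% pick)
  expect_equal(nrow(sub), brute)
  expect_setequal(attr(sub, "proteins"), pick)   # isolated nodes retained
  # whole-network bicluster reproduces the network
  all_sub <- extract_subnetwork(attr(net, "proteins"), net)
  expect_equal(nrow(all_sub), nrow(net))
  expect_warning(empty <- extract_subnetwork(c("zz1", "zz2"), net), "no bicluster")
  expect_equal(nrow(empty), 0L)
})
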