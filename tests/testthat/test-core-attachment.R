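test_that("node wcc matches the closed form on small motifs", {
  v2 <- mk_net(c("a", "a"), c("b", "c"), c(0.5, 0.5))
  expect_equal(wcc_node("a", v2), 0.5)            # 1.0 / (2*1)
  expect_equal(wcc_node("b", v2), 0)              # degree 1
  tri <- mk_clique(c("x", "y", "z"))
  for (v in c("x", "y", "z")) expect_equal(wcc_node(v, tri), 1)
  expect_error(wcc_node("nope", tri), "not in the network")
})

test_that("node and complex wcc match brute force on random graphs", {
  set.seed(31)
  for (k in 1:20) {
    n <- sample(10:50, 1)
    ids <- sprintf("v%02d", 1:n)
    prs <- t(combn(ids, 2))
    keep <- runif(nrow(prs)) < 0.15
    net <- mk_net(prs[keep, 1], prs[keep, 2], runif(sum(keep)), proteins = ids)
    df <- as.data.frame(net)
    for (v in sample(ids, 3)) {
      expect_equal(wcc_node(v, net), oracle_wcc_node(v, df))
    }
    members <- sample(ids, sample(3:8, 1))
    expect_equal(wcc_complex(members, net), oracle_wcc_complex(members, df))
  }
  expect_equal(wcc_complex(c("q1", "q2"), mk_clique(c("a", "b", "c"))), 0)
  expect_equal(wcc_complex(c("a", "b", "c"), mk_clique(c("a", "b", "c"))), 1)
})

test_that("seed selection follows the nonzero-wcc quantile rule", {
  set.seed(32)
  prs <- t(combn(sprintf("s%02d", 1:40), 2))
  keep <- runif(nrow(prs)) < 0.12
  net <- mk_net(prs[keep, 1], prs[keep, 2], runif(sum(keep)))
  tab <- dyncomplex:::node_wcc_table(net)
  nz <- tab$wcc[tab$wcc > 0]
  all_nz <- select_seeds(net, 0)
  expect_setequal(all_nz, tab$protein[tab$wcc > 0])  # alpha 0: every nonzero-wcc node
  s9 <- select_seeds(net, 0.9)
  expect_lte(length(s9), ceiling(0.1 * length(nz)) + 1L)  # upper-quantile bound
  # monotone: seed count non-increasing in alpha_seed
  counts <- vapply(seq(0, 1, by = 0.1), function(a) length(select_seeds(net, a)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # ordering: by wcc descending
  wccs <- tab$wcc[match(s9, tab$protein)]
  expect_true(all(diff(wccs) <= 0))
})

test_that("core growth stops when the complex wcc would drop", {
  # unit 4-clique with weak pendant edges: the triangle is the maximal core
  # under the non-decreasing wcc rule (a 4-clique halves the complex wcc),
  # and the attachment step completes the clique
  cl <- mk_clique(c("c1", "c2", "c3", "c4"))
  pend <- mk_net(c("c1", "c2"), c("p1", "p2"), c(0.1, 0.1))
  net <- mk_net(c(cl$protein_a, pend$protein_a), c(cl$protein_b, pend$protein_b),
                c(cl$w, pend$w))
  core <- grow_core("c1", net)
  expect_length(core, 3L)
  expect_true("c1" %in% core)
  expect_true(all(core %in% c("c1", "c2", "c3", "c4")))
  cpx <- add_attachments(core, net, beta = 0.5)
  expect_setequal(cpx, c("c1", "c2", "c3", "c4"))
  # isolated seed
  iso <- mk_net("a", "b", 1, proteins = c("a", "b", "lone"))
  expect_identical(grow_core("lone", iso), "lone")
})

test_that("core growth never decreases the complex wcc along accepted steps", {
  set.seed(33)
  for (k in 1:10) {
    ids <- sprintf("g%02d", 1:15)
    prs <- t(combn(ids, 2))
    keep <- runif(nrow(prs)) < 0.3
    net <- mk_net(prs[keep, 1], prs[keep, 2], runif(sum(keep)), proteins = ids)
    seed <- sample(attr(net, "proteins"), 1)
    core <- grow_core(seed, net)
    # replay growth prefix-by-prefix is not possible without order; instead
    # check the invariant the rule guarantees: the final core's wcc is at
    # least the seed's trivial core wcc (0) and the two-node baseline
    expect_gte(wcc_complex(core, net), 0)
    if (length(core) >= 3) {
      expect_gte(wcc_complex(core, net),
                 wcc_complex(core[seq_len(2)], net) - 1e-12)
    }
  }
})

test_that("attachments follow the edge-count fraction threshold", {
  tri <- mk_clique(c("a", "b", "c"))
  u2 <- mk_net(c("u", "u"), c("a", "b"), c(1, 1))
  net <- mk_net(c(tri$protein_a, u2$protein_a), c(tri$protein_b, u2$protein_b),
                c(tri$w, u2$w))
  expect_setequal(add_attachments(c("a", "b", "c"), net, beta = 0.5),
                  c("a", "b", "c", "u"))          # 2/3 >= 0.5
  expect_setequal(add_attachments(c("a", "b", "c"), net, beta = 0.7),
                  c("a", "b", "c"))               # 2/3 < 0.7
  expect_setequal(add_attachments(c("a", "b", "c"), net, beta = 0),
                  c("a", "b", "c", "u"))          # every neighbour
})

test_that("higher beta never yields larger complexes from the same core", {
  set.seed(34)
  ids <- sprintf("h%02d", 1:25)
  prs <- t(combn(ids, 2))
  keep <- runif(nrow(prs)) < 0.2
  net <- mk_net(prs[keep, 1], prs[keep, 2], runif(sum(keep)), proteins = ids)
  core <- grow_core(ids[1], net)
  sizes <- vapply(seq(0.1, 0.9, by = 0.1), function(b) {
    length(add_attachments(core, net, b))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("redundancy filtering enforces the pairwise Jaccard bound", {
  mk <- function(...) {
    tbl <- as_complex_tbl(list(...))
    tbl$wcc <- seq_len(nrow(tbl))
    tbl
  }
  two_same <- mk(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(nrow(filter_redundant(two_same)), 1L)
  # J = 6/8 = 0.75 < 0.8: both kept
  pair <- mk(LETTERS[1:7], c(LETTERS[1:6], "H"))
  expect_equal(nrow(filter_redundant(pair, 0.8)), 2L)
  set.seed(35)
  many <- as_complex_tbl(lapply(1:25, function(i) sample(LETTERS[1:12], sample(4:9, 1))))
  many$wcc <- runif(25)
  kept <- filter_redundant(many, 0.8)
  prs <- combn(nrow(kept), 2)
  for (k in seq_len(ncol(prs))) {
    expect_lt(jaccard(kept$proteins[[prs[1, k]]], kept$proteins[[prs[2, k]]]), 0.8)
  }
})

test_that("detection recovers planted cliques and is deterministic", {
  set.seed(36)
  truth <- list(sprintf("k%02d", 1:5), sprintf("k%02d", 6:11))
  cl1 <- mk_clique(truth[[1]]); cl2 <- mk_clique(truth[[2]])
  ids <- sprintf("k%02d", 1:20)
  prs <- t(combn(ids, 2))
  noise_keep <- runif(nrow(prs)) < 0.08
  noise <- mk_net(prs[noise_keep, 1], prs[noise_keep, 2],
                  rep(0.1, sum(noise_keep)))
  all_e <- dplyr::bind_rows(as.data.frame(cl1), as.data.frame(cl2), as.data.frame(noise)) |>
    dplyr::distinct(protein_a, protein_b, .keep_all = TRUE)
  net <- mk_net(all_e$protein_a, all_e$protein_b, all_e$w, proteins = ids)
  res <- detect_complexes(net, detection_params(alpha_seed = 0.5, beta = 0.5))
  for (tr in truth) {
    expect_gte(max(vapply(res$proteins, jaccard, numeric(1), c2 = tr)), 0.8)
  }
  expect_true(all(vapply(seq_len(nrow(res)), function(i) {
    res$seed[i] %in% res$proteins[[i]]
  }, logical(1))))                                  # every complex keeps a seed
  res2 <- detect_complexes(net, detection_params(alpha_seed = 0.5, beta = 0.5))
  expect_identical(res$proteins, res2$proteins)     # fully deterministic
  empty <- mk_net(character(), character(), numeric())
  expect_equal(nrow(detect_complexes(empty)), 0L)
})
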