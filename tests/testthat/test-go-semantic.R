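# 4-protein toy used by several cases: t1, t2 are children of one BP root
toy_dag <- function() {
  dyncomplex:::new_ontology_dag(
    c("root", "t1", "t2"), rep("BP", 3),
    list(root = character(), t1 = "root", t2 = "root"))
}
toy_ann <- function(extra = NULL) {
  direct <- tibble::tibble(
    protein = c("P1", "P2", "P3", "P4"),
    term = c("t1", "t1", "t2", "t2"), aspect = "BP")
  if (!is.null(extra)) direct <- dplyr::bind_rows(direct, extra)
  build_closure(toy_dag(), direct)
}

test_that("closure follows is_a chains and is a fixed point at the root", {
  dag <- dyncomplex:::new_ontology_dag(
    c("root", "t1", "t2"), rep("BP", 3),
    list(root = character(), t1 = "root", t2 = "t1"))
  ann <- build_closure(dag, tibble::tibble(protein = "P", term = "t2", aspect = "BP"))
  expect_setequal(ann$closure$BP$P, c("t2", "t1", "root"))
  ann_root <- build_closure(dag, tibble::tibble(protein = "P", term = "root", aspect = "BP"))
  expect_identical(ann_root$closure$BP$P, "root")
  expect_error(
    build_closure(dag, tibble::tibble(protein = "P", term = "ghost", aspect = "BP")),
    "ghost")
})

test_that("closure matches brute-force reachability on a random DAG", {
  set.seed(42)
  ids <- sprintf("n%02d", 1:20)
  parents <- list(n01 = character())
  for (i in 2:20) parents[[ids[i]]] <- sample(ids[1:(i - 1)], sample(1:2, 1))
  dag <- dyncomplex:::new_ontology_dag(ids, rep("BP", 20), parents)
  direct <- tibble::tibble(protein = sprintf("Q%02d", 1:10),
                           term = sample(ids, 10, replace = TRUE), aspect = "BP")
  ann <- build_closure(dag, direct)
  for (i in 1:10) {
    expect_setequal(ann$closure$BP[[direct$protein[i]]],
                    oracle_closure(direct$term[i], parents))
  }
})

test_that("ontology cycles are rejected", {
  expect_error(
    dyncomplex:::new_ontology_dag(c("a", "b"), c("BP", "BP"),
                                  list(a = "b", b = "a")),
    "cycle")
})

test_that("information content matches hand computation", {
  ann <- toy_ann()
  ic <- information_content(toy_dag(), ann)
  expect_equal(unname(ic["root"]), 0)            # annotates everyone
  expect_true(all(ic >= 0))
  # term in 2 of 4 closures
  expect_equal(unname(ic["t1"]), log(2))
  # restricted corpus: t1 in 1 of 2
  ic2 <- information_content(toy_dag(), ann, corpus = c("P1", "P3"))
  expect_equal(unname(ic2["t1"]), log(2), tolerance = 1e-12)
  expect_error(information_content(toy_dag(), ann, corpus = character()), "non-empty")
})

test_that("simgic reproduces the analytic toy values", {
  ann <- toy_ann()
  ic <- information_content(toy_dag(), ann)
  # identical closures with positive IC
  expect_equal(simgic("P1", "P2", "BP", ann, ic), 1)
  # intersection is only the zero-IC root
  expect_equal(simgic("P1", "P3", "BP", ann, ic), 0)
  # adding P5 annotated to both terms: equal ICs make the ratio exactly 1/2
  ann5 <- toy_ann(tibble::tibble(protein = "P5", term = c("t1", "t2"), aspect = "BP"))
  ic5 <- information_content(toy_dag(), ann5)
  expect_equal(simgic("P1", "P5", "BP", ann5, ic5), 0.5)
  # missing annotation sentinel
  expect_true(is.na(simgic("P1", "P9", "BP", ann, ic)))
})

test_that("simgic is symmetric, bounded, self-similar, and matches brute force", {
  set.seed(5)
  ids <- c("r", sprintf("g%02d", 1:12))
  parents <- list(r = character())
  for (i in 2:13) parents[[ids[i]]] <- sample(ids[1:(i - 1)], 1)
  dag <- dyncomplex:::new_ontology_dag(ids, rep("BP", 13), parents)
  prots <- sprintf("P%02d", 1:30)
  direct <- dplyr::bind_rows(lapply(prots, function(p) {
    tibble::tibble(protein = p, term = sample(ids[-1], sample(1:3, 1)), aspect = "BP")
  }))
  ann <- build_closure(dag, direct)
  ic <- information_content(dag, ann)
  by_p <- split(direct$term, direct$protein)
  for (k in 1:60) {
    pq <- sample(prots, 2)
    s1 <- simgic(pq[1], pq[2], "BP", ann, ic)
    expect_equal(s1, simgic(pq[2], pq[1], "BP", ann, ic))
    expect_gte(s1, 0); expect_lte(s1, 1)
    expect_equal(s1, oracle_simgic(by_p[[pq[1]]], by_p[[pq[2]]], parents, ic))
  }
  for (p in sample(prots, 5)) {
    if (sum(ic[ann$closure$BP[[p]]]) > 0) {
      expect_equal(simgic(p, p, "BP", ann, ic), 1)
    }
  }
})

test_that("the IC log base is observationally irrelevant to pair weights", {
  ann <- toy_ann(tibble::tibble(protein = "P5", term = c("t1", "t2"), aspect = "BP"))
  ic <- information_content(toy_dag(), ann)
  ic2 <- ic / log(2)   # base-2 IC is a constant rescaling
  attr(ic2, "unused") <- attr(ic, "unused")
  for (pair in list(c("P1", "P2"), c("P1", "P3"), c("P1", "P5"))) {
    expect_equal(go_pair_weight(pair[1], pair[2], ann, ic),
                 go_pair_weight(pair[1], pair[2], ann, ic2))
  }
})

test_that("pair weight averages only over aspects annotated in both proteins", {
  dag <- dyncomplex:::new_ontology_dag(
    c("rb", "b1", "rc", "c1", "rm", "m1"), c("BP", "BP", "CC", "CC", "MF", "MF"),
    list(rb = character(), b1 = "rb", rc = character(), c1 = "rc",
         rm = character(), m1 = "rm"))
  direct <- tibble::tibble(
    protein = c("X", "X", "X", "Y", "Y", "Z"),
    term = c("b1", "c1", "m1", "b1", "c1", "b1"),
    aspect = c("BP", "CC", "MF", "BP", "CC", "BP"))
  ann <- build_closure(dag, direct)
  ic <- information_content(dag, ann)
  # X vs Z share only BP; CC and MF are missing for Z -> average over BP only
  expect_equal(go_pair_weight("X", "Z", ann, ic), simgic("X", "Z", "BP", ann, ic))
  # unannotated pair -> 0
  expect_equal(go_pair_weight("Q1", "Q2", ann, ic), 0)
})

test_that("OBO and GAF files written by the generator parse back", {
  dir <- withr::local_tempdir()
  fx <- generate_fixture(fixture_config(
    n_proteins = 30, n_timepoints = 6, complex_sizes = c(4, 5),
    shared_proteins = 0, rng_seed = 2), dir = dir)
  dag <- read_obo(fx$paths$obo)
  expect_setequal(dag$terms$term, fx$dag$terms$term)
  expect_identical(dag$parents[fx$dag$terms$term],
                   lapply(fx$dag$parents[fx$dag$terms$term], identity))
  gaf <- read_gaf(fx$paths$gaf)
  expect_setequal(paste(gaf$protein, gaf$term, gaf$aspect),
                  paste(fx$annotations$protein, fx$annotations$term,
                        fx$annotations$aspect))
})

test_that("obsolete terms and unknown namespaces are handled by the OBO parser", {
  f <- withr::local_tempfile(lines = c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "namespace: biological_process", "",
    "[Term]", "id: GO:2", "namespace: biological_process",
    "is_a: GO:1 ! parent", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"))
  dag <- read_obo(f)
  expect_identical(dag$terms$term, "GO:1")
})
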