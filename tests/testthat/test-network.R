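test_that("build_network collects endpoints and attributes", {
  e <- make_edges("A", "B", "r")
  e$source_mz <- 100; e$target_mz <- 116
  net <- build_network(e)
  expect_identical(nrow(net$nodes), 2L)
  expect_identical(nrow(net$arcs), 1L)
  expect_setequal(net$nodes$id, c("A", "B"))
  empty <- build_network(e[0, ])
  expect_identical(nrow(empty$nodes), 0L)
})

test_that("a chain collapses to a single maximal pathway", {
  e <- make_edges(c("A", "B"), c("B", "C"), c("r1", "r2"))
  p <- enumerate_pathways(build_network(e))
  expect_identical(nrow(p), 1L)
  expect_identical(p$nodes, "A;B;C")
  expect_identical(p$rules, "r1;r2")
})

test_that("a diamond yields both branch pathways", {
  e <- make_edges(c("A", "B", "A", "C"), c("B", "D", "C", "D"),
                  c("r", "r", "r", "r"))
  p <- enumerate_pathways(build_network(e))
  expect_identical(nrow(p), 2L)
  expect_setequal(p$nodes, c("A;B;D", "A;C;D"))
})

test_that("parallel arcs with different rules give distinct pathways", {
  e <- make_edges(c("A", "A", "B"), c("B", "B", "C"), c("r1", "r2", "r3"))
  p <- enumerate_pathways(build_network(e))
  expect_setequal(paste(p$nodes, p$rules), c("A;B;C r1;r3", "A;B;C r2;r3"))
})

test_that("pathway enumeration equals brute force on random DAGs", {
  set.seed(31)
  for (rep in 1:30) {
    e <- random_dag_edges(sample(4:12, 1), p = stats::runif(1, 0.15, 0.5))
    p <- enumerate_pathways(build_network(e))
    expect_identical(pathway_sigs(p), brute_pathways(e),
                     info = paste("rep", rep))
  }
})

test_that("cycles terminate via the simple-path restriction", {
  e <- make_edges(c("A", "B", "B", "C"), c("B", "A", "C", "B"),
                  c("f", "g", "f", "g"))
  p <- enumerate_pathways(build_network(e))
  expect_identical(pathway_sigs(p), brute_pathways(e))
  for (i in seq_len(nrow(p))) {
    nodes <- pathway_nodes(p, i)$nodes
    expect_false(any(duplicated(nodes)))
  }
})

test_that("max_length caps pathway size; explosion guard warns", {
  ids <- sprintf("n%d", 1:8)
  e <- make_edges(ids[-8], ids[-1], "r")
  p <- enumerate_pathways(build_network(e), max_length = 4L)
  expect_true(all(p$n_nodes <= 4L))
  expect_error(enumerate_pathways(build_network(e), max_length = 1L), ">= 2")
  expect_warning(enumerate_pathways(build_network(e), max_paths = 2L),
                 "truncated")
})

test_that("returned pathways are mutually sub-path free", {
  set.seed(32)
  e <- random_dag_edges(10, p = 0.4)
  p <- enumerate_pathways(build_network(e))
  sigs <- paste0("|", pathway_sigs(p), "|")
  for (i in seq_along(sigs)) for (j in seq_along(sigs)) {
    if (i != j) expect_false(grepl(sigs[[i]], sigs[[j]], fixed = TRUE))
  }
})

test_that("pathway filters keep or drop whole paths only", {
  fs <- feature_set(
    toy_feature("A", "C10H12O2", first_time = 0L, mz = 300),
    toy_feature("B", "C11H14O2", first_time = 1L, mz = 500),
    toy_feature("C", "C12H16O2", first_time = 2L, mz = 900))
  p <- enumerate_pathways(build_network(
    make_edges(c("A", "B"), c("B", "C"), "methylation")))
  expect_identical(filter_pathways(p, fs), p)
  expect_identical(nrow(filter_pathways(p, fs, mz_range = c(100, 1000))), 1L)
  expect_identical(nrow(filter_pathways(p, fs, mz_range = c(100, 600))), 0L)
  expect_identical(nrow(filter_pathways(p, fs, time_points = 0L)), 0L)
  expect_identical(nrow(filter_pathways(p, fs, time_points = 0:5)), 1L)
})

test_that("pajek export writes the standard dialect, byte-stable", {
  e <- make_edges(c("b", "a"), c("a", "c"), c("r1", "r2"))
  net <- build_network(e)
  tf1 <- tempfile(fileext = ".net"); tf2 <- tempfile(fileext = ".net")
  export_pajek(net, tf1)
  lines <- readLines(tf1)
  expect_identical(lines[1], "*Vertices 3")
  expect_identical(lines[2:4], c('1 "a"', '2 "b"', '3 "c"'))
  expect_identical(lines[5], "*Arcs")
  expect_setequal(lines[6:7], c("2 1", "1 3"))
  export_pajek(net, tf2)
  expect_identical(readBin(tf1, "raw", file.size(tf1)),
                   readBin(tf2, "raw", file.size(tf2)))
  tfe <- tempfile(fileext = ".net")
  export_pajek(build_network(e[0, ]), tfe)
  expect_identical(readLines(tfe), c("*Vertices 0", "*Arcs"))
})

test_that("choose_formulas prefers the edge-supported candidate", {
  # rank-1 candidate of 'b' is a decoy; only rank 2 participates in edges
  a <- toy_feature("a", "C10H12O2")
  b <- feature("b", monoisotopic_mz(parse_formula("C11H14O2"), 1L), 0L,
               data.frame(formula = c("C7H18N2O3", "C11H14O2"),
                          ppm_error = c(0.1, 0.2)))
  fs <- feature_set(a, b)
  edges <- detect_transformations(fs, small_rules(methylation = "+1C+2H"))
  expect_identical(unname(choose_formulas(fs, edges)["b"]), "C11H14O2")
  expect_identical(unname(choose_formulas(fs)["b"]), "C7H18N2O3")
})
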