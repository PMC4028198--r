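test_that("a shared +O step resolves the kaempferol/quercetin pair", {
  rules <- small_rules("mono-oxygenation" = "+1O")
  k <- toy_feature("kaempferol", c("C15H11O6", "C11H15N2O7"))
  q <- toy_feature("quercetin", c("C15H11O7", "C11H15N2O8"))
  edges <- detect_transformations(feature_set(k, q), rules)
  expect_identical(nrow(edges), 1L)
  expect_identical(edges$source_id, "kaempferol")
  expect_identical(edges$target_id, "quercetin")
  expect_identical(edges$rule, "mono-oxygenation")
  expect_identical(edges$source_formula, "C15H11O6")
  expect_identical(edges$target_formula, "C15H11O7")
  # the decoy candidates also differ by +O: collapsed into the same edge
  expect_identical(edges$n_support, 2L)
})

test_that("hexosylation is detected between anchored chain members", {
  rules <- default_rules()
  a13 <- toy_feature("A13", "C35H35O17", first_time = 2L)
  a3 <- toy_feature("A3", "C41H45O22", first_time = 2L)
  edges <- detect_transformations(feature_set(a13, a3), rules)
  hex <- edges[edges$rule == "hexosylation", ]
  expect_identical(nrow(hex), 1L)
  expect_identical(hex$source_id, "A13")
  expect_identical(hex$target_id, "A3")
})

test_that("time filter forbids edges against chronology, keeps equal times", {
  rules <- small_rules(methylation = "+1C+2H")
  a <- toy_feature("a", "C10H12O2", first_time = 2L)
  b <- toy_feature("b", "C11H14O2", first_time = 1L)
  expect_identical(nrow(detect_transformations(feature_set(a, b), rules)), 0L)
  expect_identical(nrow(detect_transformations(feature_set(a, b), rules,
                                               time_filter = FALSE)), 1L)
  b_eq <- toy_feature("b", "C11H14O2", first_time = 2L)
  expect_identical(nrow(detect_transformations(feature_set(a, b_eq), rules)), 1L)
})

test_that("matching equals the naive quadruple loop on random sets", {
  rules <- small_rules("mono-oxygenation" = "+1O", methylation = "+1C+2H",
                       dehydration = "-2H-1O", hexosylation = "+6C+10H+5O")
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(4:10, 1)
    feats <- lapply(seq_len(n), function(i) {
      base <- c(C = sample(5:20, 1), H = sample(5:25, 1), O = sample(1:8, 1))
      k <- sample(1:3, 1)
      fml <- unique(vapply(seq_len(k), function(j) {
        jitter <- c(C = sample(-1:1, 1), H = sample(-2:2, 1), O = sample(-1:1, 1))
        format_formula(as_composition(pmax(base + jitter, 1)))
      }, ""))
      toy_feature(sprintf("f%02d", i), fml,
                  first_time = sample(0:2, 1),
                  mz = stats::runif(1, 100, 500))
    })
    fs <- feature_set(feats)
    for (tf in c(TRUE, FALSE)) {
      got <- detect_transformations(fs, rules, time_filter = tf)
      expect_identical(edge_keys(got), naive_edges(fs, rules, tf))
    }
  }
})

test_that("time-filtered edges are a subset of unfiltered edges", {
  res <- run_fixture_pipeline(seed = 3, n_decoys = 10L)
  feats <- res$bundle$features
  rules <- res$bundle$rules
  all_e <- detect_transformations(feats, rules, time_filter = FALSE)
  flt_e <- detect_transformations(feats, rules, time_filter = TRUE)
  expect_true(all(edge_keys(flt_e) %in% edge_keys(all_e)))
  expect_true(all(flt_e$source_first_time <= flt_e$target_first_time))
})

test_that("matching antisymmetry: A->B under d precludes B->A under d", {
  rules <- small_rules(methylation = "+1C+2H", demethylation = "-1C-2H")
  a <- toy_feature("a", "C10H12O2")
  b <- toy_feature("b", "C11H14O2")
  edges <- detect_transformations(feature_set(a, b), rules)
  keys <- edge_keys(edges)
  expect_true("a>b@methylation" %in% keys)
  expect_false("b>a@methylation" %in% keys)
  # the negated delta is its own rule, so the reverse arc exists under it
  expect_true("b>a@demethylation" %in% keys)
})

test_that("empty rules error; candidate-free features are skipped loudly", {
  a <- toy_feature("a", "C10H12O2")
  bare <- feature("bare", 150.0, 0L)
  expect_error(detect_transformations(feature_set(a), default_rules()[0, ]),
               "nonempty")
  expect_warning(
    edges <- detect_transformations(feature_set(a, bare),
                                    small_rules(m = "+1C+2H")),
    "bare")
  expect_identical(nrow(edges), 0L)
})

test_that("rule frequency ranking counts and orders correctly", {
  e <- make_edges(c("a", "b", "c", "d"), c("b", "c", "d", "e"),
                  c("mono-oxygenation", "mono-oxygenation",
                    "mono-oxygenation", "methylation"))
  freq <- rank_rule_frequencies(e)
  expect_identical(freq$rule, c("mono-oxygenation", "methylation"))
  expect_identical(freq$count, c(3L, 1L))
  expect_identical(sum(freq$count), nrow(e))
  expect_identical(nrow(rank_rule_frequencies(make_edges(character(0),
                                                         character(0),
                                                         character(0)))), 0L)
  # count ties broken by rule-file order
  rules <- small_rules(zeta = "+1O", alpha = "+1C+2H")
  e2 <- make_edges(c("a", "b"), c("b", "c"), c("alpha", "zeta"))
  expect_identical(rank_rule_frequencies(e2, rules)$rule, c("zeta", "alpha"))
})

test_that("unlisted-difference mining finds what the rules miss", {
  rules <- small_rules(methylation = "+1C+2H")
  # two independent pairs differing by acetylation (+C2H2O), not listed
  f <- feature_set(
    toy_feature("p1", "C10H12O2"), toy_feature("p2", "C12H14O3"),
    toy_feature("q1", "C8H10O4"), toy_feature("q2", "C10H12O5"))
  got <- discover_unlisted(f, rules, min_count = 2)
  expect_true("+2C+2H+1O" %in% got$delta)
  hit <- got[got$delta == "+2C+2H+1O", ]
  expect_identical(hit$occurrence_count, 2L)
  expect_setequal(strsplit(hit$example_pairs, ";")[[1]], c("p1>p2", "q1>q2"))
  # once acetylation is a listed rule its delta is no longer suggested
  rules2 <- small_rules(acetylation = "+2C+2H+1O")
  expect_false("+2C+2H+1O" %in% discover_unlisted(f, rules2,
                                                  min_count = 2)$delta)
})

test_that("removing a rule surfaces its delta as an unlisted suggestion", {
  res <- run_fixture_pipeline(seed = 5, n_decoys = 5L)
  rules <- res$bundle$rules
  no_pent <- rules[rules$name != "pentosylation", ]
  class(no_pent) <- class(rules)
  got <- discover_unlisted(res$bundle$features, no_pent, min_count = 1,
                           max_delta_mass = 300)
  expect_true("+5C+8H+4O" %in% got$delta)
  expect_true(got$occurrence_count[got$delta == "+5C+8H+4O"] >= 1L)
})
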