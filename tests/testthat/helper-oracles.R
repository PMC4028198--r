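# Independent oracles: deliberately naive implementations used only to
# check the package's optimized code paths on small inputs.

# Exhaustive quadruple-loop candidate enumeration over C/H/N/O bounds.
# Returns the sorted set of formula strings within the ppm window.
naive_candidates <- function(mz, tol_ppm, bounds, charge = 1L) {
  m <- c(C = 12.0, H = 1.0078250319, N = 14.0030740044, O = 15.9949146196)
  e <- 0.00054857990907
  b <- function(el) if (el %in% names(bounds)) bounds[[el]] else 0L
  out <- character(0)
  for (nc in 0:b("C")) for (nh in 0:b("H")) for (nn in 0:b("N")) for (no in 0:b("O")) {
    if (nc + nh + nn + no == 0) next
    mass <- nc * m[["C"]] + nh * m[["H"]] + nn * m[["N"]] + no * m[["O"]]
    theo <- (mass - charge * e) / abs(charge)
    if (abs(theo - mz) / mz * 1e6 <= tol_ppm) {
      cnt <- c(C = nc, H = nh, N = nn, O = no)
      cnt <- cnt[cnt > 0]
      out <- c(out, paste0(names(cnt), ifelse(cnt == 1, "", cnt), collapse = ""))
    }
  }
  sort(out)
}

# Naive quadruple loop over (ordered feature pair, candidate pair, rule).
# Returns sorted "src>tgt@rule" strings (deduplicated, as the package
# collapses candidate-pair multiplicity).
naive_edges <- function(features, rules, time_filter = TRUE) {
  out <- character(0)
  ids <- names(features)
  for (a in ids) for (b in ids) {
    if (a == b) next
    fa <- features[[a]]; fb <- features[[b]]
    if (time_filter && fa$first_time > fb$first_time) next
    for (i in seq_len(nrow(fa$candidates))) for (j in seq_len(nrow(fb$candidates))) {
      d <- composition_difference(fa$candidates$composition[[i]],
                                  fb$candidates$composition[[j]])
      for (r in seq_len(nrow(rules))) {
        if (identical(d, rules$composition[[r]]))
          out <- c(out, paste0(a, ">", b, "@", rules$name[r]))
      }
    }
  }
  sort(unique(out))
}

edge_keys <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  sort(paste0(edges$source_id, ">", edges$target_id, "@", edges$rule))
}

# Brute-force non-redundant pathway enumeration: list ALL simple paths
# (>= 2 nodes, <= max_len) by recursive extension, then delete every path
# that is a contiguous sub-path (same node and rule sequence) of another.
# Returns the sorted set of "n1|r1|n2|r2|..." signatures.
brute_pathways <- function(edges, max_len = 20L) {
  arcs <- data.frame(from = edges$source_id, to = edges$target_id,
                     rule = edges$rule, stringsAsFactors = FALSE)
  nodes <- unique(c(arcs$from, arcs$to))
  all_paths <- list()
  extend <- function(nseq, rseq) {
    if (length(nseq) >= 2)
      all_paths[[length(all_paths) + 1L]] <<- list(n = nseq, r = rseq)
    if (length(nseq) >= max_len) return()
    nxt <- arcs[arcs$from == nseq[length(nseq)], , drop = FALSE]
    for (k in seq_len(nrow(nxt))) {
      if (nxt$to[k] %in% nseq) next
      extend(c(nseq, nxt$to[k]), c(rseq, nxt$rule[k]))
    }
  }
  for (s in nodes) extend(s, character(0))
  sig <- vapply(all_paths, function(p) {
    v <- character(2L * length(p$n) - 1L)
    v[seq(1, by = 2, length.out = length(p$n))] <- p$n
    if (length(p$r)) v[seq(2, by = 2, length.out = length(p$r))] <- p$r
    paste0("|", paste(v, collapse = "|"), "|")
  }, "")
  sig <- unique(sig)
  keep <- vapply(seq_along(sig), function(i)
    !any(vapply(seq_along(sig), function(j)
      i != j && grepl(sig[[i]], sig[[j]], fixed = TRUE), TRUE)), TRUE)
  sort(gsub("^\\||\\|$", "", sig[keep]))
}

pathway_sigs <- function(paths) {
  sort(vapply(seq_len(nrow(paths)), function(i) {
    p <- pathway_nodes(paths, i)
    v <- character(2L * length(p$nodes) - 1L)
    v[seq(1, by = 2, length.out = length(p$nodes))] <- p$nodes
    if (length(p$rules)) v[seq(2, by = 2, length.out = length(p$rules))] <- p$rules
    paste(v, collapse = "|")
  }, ""))
}

# Random edge tables for property tests.
make_edges <- function(from, to, rule) {
  n <- length(from)
  data.frame(source_id = from, target_id = to, rule = rule,
             source_formula = rep("", n), target_formula = rep("", n),
             source_mz = rep(0, n), target_mz = rep(0, n),
             source_first_time = rep(0L, n), target_first_time = rep(0L, n),
             n_support = rep(1L, n), support = rep("", n),
             stringsAsFactors = FALSE)
}

random_dag_edges <- function(n_nodes, p = 0.3, rules = c("r1", "r2")) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  from <- character(0); to <- character(0)
  for (i in seq_len(n_nodes - 1)) for (j in (i + 1):n_nodes) {
    if (stats::runif(1) < p) { from <- c(from, ids[i]); to <- c(to, ids[j]) }
  }
  if (length(from) == 0) { from <- ids[1]; to <- ids[2] }
  make_edges(from, to, sample(rules, length(from), replace = TRUE))
}

# Quick feature constructor from formula strings.
toy_feature <- function(id, formulas, first_time = 0L, mz = NULL) {
  comps <- lapply(formulas, parse_formula)
  if (is.null(mz)) mz <- monoisotopic_mz(comps[[1]], 1L)
  feature(id, mz, first_time,
          data.frame(formula = formulas,
                     ppm_error = seq(0, by = 0.05, length.out = length(formulas)),
                     stringsAsFactors = FALSE))
}

small_rules <- function(...) {
  specs <- c(...)
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  utils::write.csv(data.frame(name = names(specs), delta = unname(specs),
                              note = ""), tf, row.names = FALSE)
  load_rules(tf)
}
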