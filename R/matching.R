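# Transformation detection: compare elemental differences of candidate
# formula pairs against the rule deltas.
#
# Matching is by exact integer composition difference, not by mass within a
# tolerance: two candidates match a rule iff target - source equals the
# rule's delta element-wise. This is what lets a shared modification resolve
# sum-formula ambiguity that mass accuracy alone cannot.

#' Detect transformation edges between features
#'
#' For every ordered feature pair (A, B) and every pair of their candidate
#' formulas (fA, fB), an edge A -> B under rule r is emitted iff
#' `fB - fA` equals r's delta exactly. Rules are directed: a reverse
#' reaction must be its own rule entry. With `time_filter = TRUE`
#' (default), edges whose source first appears strictly later than their
#' target are discarded — a transformation cannot run against observed
#' chronology; equal first appearance is allowed. Multiple supporting
#' candidate pairs for the same (A, B, rule) collapse into one edge (the
#' network is over features, not formulas); the best-ranked pair supplies
#' the edge's display formulas and all pairs are kept in `support`.
#'
#' @param features An `mz_feature_set` (or list of `mz_feature`).
#' @param rules An `mz_rules` data.frame (nonempty).
#' @param time_filter Drop chronology-violating edges (default `TRUE`).
#' @return A data.frame of class `mz_edges` with columns `source_id`,
#'   `target_id`, `rule`, `source_formula`, `target_formula`, `source_mz`,
#'   `target_mz`, `source_first_time`, `target_first_time`, `n_support`,
#'   `support` (supporting formula pairs, `"fA>fB"` joined by `";"`).
#' @examples
#' rules <- default_rules()
#' k <- feature("kaempferol", 287.05501, 0,
#'              data.frame(formula = "C15H11O6", ppm_error = 0))
#' q <- feature("quercetin", 303.04993, 0,
#'              data.frame(formula = "C15H11O7", ppm_error = 0))
#' detect_transformations(feature_set(k, q), rules)
#' @export
detect_transformations <- function(features, rules, time_filter = TRUE) {
  if (!inherits(features, "mz_feature_set")) features <- feature_set(features)
  if (!inherits(rules, "mz_rules") || nrow(rules) == 0)
    stop("rules must be a nonempty mz_rules set")
  empty <- vapply(features, function(f) nrow(f$candidates) == 0, TRUE)
  if (any(empty))
    warning("skipping ", sum(empty), " feature(s) without candidates: ",
            paste(names(features)[empty], collapse = ", "))
  tab <- .candidate_table(features)
  if (nrow(tab) == 0) return(.empty_edges())

  # integer composition matrix over the union of candidate and rule elements
  els <- unique(c(unlist(lapply(tab$composition, names)),
                  unlist(lapply(rules$composition, names))))
  els <- els[order(match(els, c("C", "H"), nomatch = 3L), els)]
  M <- .comp_matrix(tab$composition, els)
  index <- split(seq_len(nrow(tab)), .matrix_keys(M, els))

  src_row <- integer(0); tgt_row <- integer(0); rule_idx <- integer(0)
  for (r in seq_len(nrow(rules))) {
    delta <- integer(length(els))
    comp <- rules$composition[[r]]
    delta[match(names(comp), els)] <- comp
    targets <- M + rep(delta, each = nrow(M))
    hit_list <- index[.matrix_keys(targets, els)]
    ni <- lengths(hit_list)
    if (sum(ni) == 0) next
    s <- rep(seq_len(nrow(tab)), ni)
    t <- unlist(hit_list, use.names = FALSE)
    ok <- tab$feature_id[s] != tab$feature_id[t]
    if (time_filter) ok <- ok & tab$first_time[s] <= tab$first_time[t]
    src_row <- c(src_row, s[ok]); tgt_row <- c(tgt_row, t[ok])
    rule_idx <- c(rule_idx, rep.int(r, sum(ok)))
  }
  if (length(src_row) == 0L) return(.empty_edges())
  hits <- data.frame(
    source_id = tab$feature_id[src_row], target_id = tab$feature_id[tgt_row],
    rule = rules$name[rule_idx],
    source_formula = tab$formula[src_row],
    target_formula = tab$formula[tgt_row],
    source_mz = tab$mz[src_row], target_mz = tab$mz[tgt_row],
    source_first_time = tab$first_time[src_row],
    target_first_time = tab$first_time[tgt_row],
    pair_rank = tab$cand_rank[src_row] + tab$cand_rank[tgt_row],
    stringsAsFactors = FALSE
  )

  # collapse candidate-pair hits to one edge per (source, target, rule)
  grp <- paste(hits$source_id, hits$target_id, hits$rule, sep = "\x1f")
  ord <- order(grp, hits$pair_rank, hits$source_formula, hits$target_formula)
  hits <- hits[ord, ]
  grp <- grp[ord]
  first <- !duplicated(grp)
  edges <- hits[first, setdiff(names(hits), "pair_rank")]
  supp <- tapply(paste0(hits$source_formula, ">", hits$target_formula), grp,
                 paste, collapse = ";")
  edges$n_support <- as.integer(table(grp)[grp[first]])
  edges$support <- as.character(supp[grp[first]])
  # stable, readable order
  edges <- edges[order(edges$source_first_time, edges$source_mz,
                       edges$target_mz, edges$rule, edges$source_id,
                       edges$target_id), ]
  rownames(edges) <- NULL
  class(edges) <- c("mz_edges", "data.frame")
  edges
}

# Internal: compositions (list of named int vectors) -> integer matrix over
# the element vector els (canonical order).
.comp_matrix <- function(comps, els) {
  M <- matrix(0L, length(comps), length(els))
  for (i in seq_along(comps)) {
    comp <- comps[[i]]
    M[i, match(names(comp), els)] <- comp
  }
  M
}

# Internal: vectorized comp_key() over matrix rows; els must be in canonical
# (C, H, alphabetical) order for keys to agree with comp_key().
.matrix_keys <- function(M, els) {
  key <- rep("", nrow(M))
  for (e in seq_along(els)) {
    nz <- M[, e] != 0L
    key[nz] <- paste0(key[nz], "|", els[[e]], M[nz, e])
  }
  substring(key, 2L)
}

.empty_edges <- function() {
  e <- data.frame(source_id = character(0), target_id = character(0),
                  rule = character(0), source_formula = character(0),
                  target_formula = character(0), source_mz = numeric(0),
                  target_mz = numeric(0), source_first_time = integer(0),
                  target_first_time = integer(0), n_support = integer(0),
                  support = character(0), stringsAsFactors = FALSE)
  class(e) <- c("mz_edges", "data.frame")
  e
}

#' Rank transformation rules by edge frequency
#'
#' @param edges An `mz_edges` data.frame from [detect_transformations()].
#' @param rules Optional `mz_rules`: ties in count are broken by rule-file
#'   order; without it, by first appearance in `edges`.
#' @return A data.frame with columns `rule`, `count`, sorted by count
#'   descending. The counts sum to `nrow(edges)`.
#' @export
rank_rule_frequencies <- function(edges, rules = NULL) {
  if (nrow(edges) == 0)
    return(data.frame(rule = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  cnt <- table(edges$rule)
  nm <- names(cnt)
  file_order <- if (!is.null(rules)) match(nm, rules$name)
                else match(nm, unique(edges$rule))
  ord <- order(-as.integer(cnt), file_order)
  data.frame(rule = nm[ord], count = as.integer(cnt)[ord],
             stringsAsFactors = FALSE)
}

#' Mine recurrent composition differences not covered by the rules
#'
#' Over all ordered feature pairs and candidate-formula pairs, collects
#' nonzero composition differences that match no rule delta and whose
#' absolute mass is at most `max_delta_mass`, groups identical deltas, and
#' reports those seen between at least `min_count` distinct feature pairs —
#' suggestions for modifications missing from the rules file. Both a delta
#' and its negation are reported if both directions occur.
#'
#' @param features An `mz_feature_set`.
#' @param rules An `mz_rules` data.frame defining what is "listed".
#' @param min_count Minimum number of distinct feature pairs (default 2).
#' @param max_delta_mass Largest |mass| of a reported delta in Da (default 300).
#' @return A data.frame with columns `delta` (signed token string),
#'   `delta_mass`, `occurrence_count`, `example_pairs` (`"a>b"` joined by
#'   `";"`), plus list-column `composition`; sorted by count descending,
#'   ties by |mass| then delta string.
#' @export
discover_unlisted <- function(features, rules, min_count = 2L,
                              max_delta_mass = 300) {
  if (!inherits(features, "mz_feature_set")) features <- feature_set(features)
  if (min_count < 1) stop("min_count must be >= 1")
  tab <- .candidate_table(features)
  if (nrow(tab) < 2) return(.empty_unlisted())

  els <- unique(unlist(lapply(tab$composition, names)))
  if (length(els) == 0) return(.empty_unlisted())
  els <- els[order(match(els, c("C", "H"), nomatch = 3L), els)] # canonical order
  M <- .comp_matrix(tab$composition, els)

  pairs <- expand.grid(i = seq_len(nrow(tab)), j = seq_len(nrow(tab)),
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[tab$feature_id[pairs$i] != tab$feature_id[pairs$j], ]
  D <- M[pairs$j, , drop = FALSE] - M[pairs$i, , drop = FALSE]
  dm <- as.numeric(D %*% .MONOISOTOPIC_MASS[els])
  keep <- rowSums(D != 0L) > 0 & abs(dm) <= max_delta_mass
  D <- D[keep, , drop = FALSE]; pairs <- pairs[keep, ]; dm <- dm[keep]
  if (nrow(D) == 0) return(.empty_unlisted())

  key <- .matrix_keys(D, els)
  rule_keys <- vapply(rules$composition, comp_key, "")
  keep <- !(key %in% rule_keys)
  D <- D[keep, , drop = FALSE]; pairs <- pairs[keep, ]
  dm <- dm[keep]; key <- key[keep]
  if (nrow(D) == 0) return(.empty_unlisted())

  pair_id <- paste0(tab$feature_id[pairs$i], ">", tab$feature_id[pairs$j])
  by_key <- split(pair_id, key)
  uniq_pairs <- lapply(by_key, unique)
  counts <- lengths(uniq_pairs)
  first_row <- match(names(by_key), key)
  masses <- dm[first_row]

  sel <- counts >= min_count
  if (!any(sel)) return(.empty_unlisted())
  comps <- lapply(first_row[sel], function(r)
    as_composition(stats::setNames(D[r, ], els)))
  out <- data.frame(
    delta = vapply(comps, format_delta, ""),
    delta_mass = masses[sel],
    occurrence_count = as.integer(counts[sel]),
    example_pairs = vapply(uniq_pairs[sel], paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  out$composition <- comps
  out <- out[order(-out$occurrence_count, abs(out$delta_mass), out$delta), ]
  rownames(out) <- NULL
  out
}

.empty_unlisted <- function() {
  out <- data.frame(delta = character(0), delta_mass = numeric(0),
                    occurrence_count = integer(0),
                    example_pairs = character(0), stringsAsFactors = FALSE)
  out$composition <- list()
  out
}
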