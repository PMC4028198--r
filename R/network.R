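# Directed transformation network: assembly, non-redundant pathway
# enumeration, filtering, and Pajek export.
#
# Pathway semantics: a pathway is a maximal simple directed path — every
# simple path in the network is a contiguous sub-path of some returned
# pathway, and no returned pathway is a contiguous sub-path of another.
# "Contiguous" (not scattered subsequence) because a pathway is a chain of
# consecutive reactions; a 3-step chain A->B->C therefore yields the single
# pathway [A,B,C], its 1-step pieces being redundant.

#' Build a transformation network from edges
#'
#' @param edges An `mz_edges` data.frame from [detect_transformations()].
#' @param features Optional `mz_feature_set` supplying node attributes (and
#'   the best-formula choice via [choose_formulas()]); without it, node
#'   attributes come from the edge table itself.
#' @return An object of class `mz_network`: `list(nodes = <data.frame id,
#'   mz, first_time, formula>, arcs = <the edges>)`.
#' @export
build_network <- function(edges, features = NULL) {
  ids <- sort(unique(c(edges$source_id, edges$target_id)), method = "radix")
  if (length(ids) == 0) {
    nodes <- data.frame(id = character(0), mz = numeric(0),
                        first_time = integer(0), formula = character(0),
                        stringsAsFactors = FALSE)
  } else if (!is.null(features)) {
    if (!inherits(features, "mz_feature_set")) features <- feature_set(features)
    fml <- choose_formulas(features, edges)
    nodes <- data.frame(
      id = ids,
      mz = vapply(features[ids], `[[`, 0, "mz"),
      first_time = vapply(features[ids], `[[`, 0L, "first_time"),
      formula = unname(fml[ids]),
      stringsAsFactors = FALSE
    )
  } else {
    at_src <- match(ids, edges$source_id)
    at_tgt <- match(ids, edges$target_id)
    pick <- function(scol, tcol)
      ifelse(!is.na(at_src), scol[at_src], tcol[at_tgt])
    nodes <- data.frame(
      id = ids,
      mz = pick(edges$source_mz, edges$target_mz),
      first_time = as.integer(pick(edges$source_first_time,
                                   edges$target_first_time)),
      formula = pick(edges$source_formula, edges$target_formula),
      stringsAsFactors = FALSE
    )
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, arcs = edges), class = "mz_network")
}

#' @export
print.mz_network <- function(x, ...) {
  cat(sprintf("<mz_network> %d node(s), %d arc(s)\n",
              nrow(x$nodes), nrow(x$arcs)))
  invisible(x)
}

#' Pick one formula per feature
#'
#' The display/plot formula for a feature is the candidate participating in
#' the most transformation edges (the working hypothesis that a formula
#' embedded in many detected reactions is the right one), falling back to
#' the rank-1 candidate for features without edge support.
#'
#' @param features An `mz_feature_set`.
#' @param edges Optional `mz_edges`; without it, rank 1 is used throughout.
#' @return Named character vector, feature id -> formula string (`NA` for
#'   features with no candidates).
#' @export
choose_formulas <- function(features, edges = NULL) {
  if (!inherits(features, "mz_feature_set")) features <- feature_set(features)
  votes <- list()
  if (!is.null(edges) && nrow(edges) > 0) {
    src <- rep(edges$source_id, lengths(strsplit(edges$support, ";", fixed = TRUE)))
    prs <- unlist(strsplit(edges$support, ";", fixed = TRUE))
    tgt <- rep(edges$target_id, lengths(strsplit(edges$support, ";", fixed = TRUE)))
    sf <- sub(">.*$", "", prs)
    tf <- sub("^.*>", "", prs)
    votes <- split(c(sf, tf), c(src, tgt))
  }
  vapply(features, function(f) {
    if (nrow(f$candidates) == 0) return(NA_character_)
    v <- votes[[f$id]]
    if (!is.null(v)) {
      v <- v[v %in% f$candidates$formula]
      if (length(v)) {
        cnt <- table(v)
        best <- names(cnt)[cnt == max(cnt)]
        # tie-break by candidate rank
        return(best[[which.min(match(best, f$candidates$formula))]])
      }
    }
    f$candidates$formula[[which.min(f$candidates$rank)]]
  }, "")
}

# Internal: adjacency list id -> data.frame(to, rule)
.adjacency <- function(net) {
  if (nrow(net$arcs) == 0) return(list())
  split(data.frame(to = net$arcs$target_id, rule = net$arcs$rule,
                   stringsAsFactors = FALSE),
        factor(net$arcs$source_id, levels = unique(net$arcs$source_id)))
}

#' Enumerate non-redundant (maximal) pathways
#'
#' Depth-first enumeration of simple directed paths from every node,
#' recording each path once it can no longer be extended (dead end, all
#' successors already on the path, or `max_length` nodes reached), followed
#' by removal of every path that is a contiguous sub-path — same node and
#' rule sequence — of another. Parallel arcs (same node pair, different
#' rules) yield distinct pathways.
#'
#' @param net An `mz_network`.
#' @param max_length Maximum pathway length in nodes (default 20); bounds
#'   work in cyclic networks, where both a rule and its reverse are loaded.
#' @param max_paths Explosion guard: if more raw paths than this are
#'   generated, enumeration stops with a warning and the result is the
#'   non-redundant reduction of what was collected (default 10000).
#' @return A data.frame of class `mz_pathways` with columns `nodes` and
#'   `rules` (each `";"`-joined) and `n_nodes`, sorted by length descending
#'   then node sequence. Paths have at least 2 nodes.
#' @export
enumerate_pathways <- function(net, max_length = 20L, max_paths = 10000L) {
  stopifnot(inherits(net, "mz_network"))
  if (max_length < 2) stop("max_length must be >= 2 nodes")
  adj <- .adjacency(net)
  paths_nodes <- list(); paths_rules <- list()
  truncated <- FALSE

  emit <- function(nodes, rules) {
    if (length(nodes) < 2) return()
    paths_nodes[[length(paths_nodes) + 1L]] <<- nodes
    paths_rules[[length(paths_rules) + 1L]] <<- rules
  }
  dfs <- function(nodes, rules, on_path) {
    if (truncated) return()
    if (length(paths_nodes) >= max_paths) { truncated <<- TRUE; return() }
    head <- nodes[[length(nodes)]]
    nxt <- adj[[head]]
    extended <- FALSE
    if (!is.null(nxt) && length(nodes) < max_length) {
      for (k in seq_len(nrow(nxt))) {
        to <- nxt$to[[k]]
        if (!is.null(on_path[[to]])) next
        on_path[[to]] <- TRUE
        dfs(c(nodes, to), c(rules, nxt$rule[[k]]), on_path)
        rm(list = to, envir = on_path)
        extended <- TRUE
      }
    }
    if (!extended) emit(nodes, rules)
  }
  for (start in net$nodes$id) {
    on_path <- new.env(parent = emptyenv())
    on_path[[start]] <- TRUE
    dfs(start, character(0), on_path)
  }
  if (truncated)
    warning("pathway enumeration truncated at max_paths = ", max_paths,
            "; results are incomplete")

  .reduce_pathways(paths_nodes, paths_rules)
}

# Remove duplicate paths and contiguous sub-paths; sort; build mz_pathways.
.reduce_pathways <- function(paths_nodes, paths_rules) {
  if (length(paths_nodes) == 0) return(.empty_pathways())
  sig <- mapply(function(n, r) {
    inter <- character(2L * length(n) - 1L)
    inter[seq(1L, by = 2L, length.out = length(n))] <- n
    if (length(r)) inter[seq(2L, by = 2L, length.out = length(r))] <- r
    paste0("\x1f", paste(inter, collapse = "\x1f"), "\x1f")
  }, paths_nodes, paths_rules)
  keep <- !duplicated(sig)
  paths_nodes <- paths_nodes[keep]; paths_rules <- paths_rules[keep]
  sig <- sig[keep]
  len <- lengths(paths_nodes)
  ord <- order(-len)
  redundant <- logical(length(sig))
  for (i in seq_along(ord)) {
    a <- ord[[i]]
    if (redundant[[a]]) next
    longer <- ord[seq_len(i - 1L)]
    if (any(vapply(longer, function(b) grepl(sig[[a]], sig[[b]], fixed = TRUE),
                   TRUE)))
      redundant[[a]] <- TRUE
  }
  paths_nodes <- paths_nodes[!redundant]; paths_rules <- paths_rules[!redundant]
  if (length(paths_nodes) == 0) return(.empty_pathways())
  nodes_str <- vapply(paths_nodes, paste, "", collapse = ";")
  rules_str <- vapply(paths_rules, paste, "", collapse = ";")
  out <- data.frame(nodes = nodes_str, rules = rules_str,
                    n_nodes = lengths(paths_nodes), stringsAsFactors = FALSE)
  out <- out[order(-out$n_nodes, out$nodes, out$rules), ]
  rownames(out) <- NULL
  class(out) <- c("mz_pathways", "data.frame")
  out
}

.empty_pathways <- function() {
  out <- data.frame(nodes = character(0), rules = character(0),
                    n_nodes = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("mz_pathways", "data.frame")
  out
}

#' Split a pathway row back into node/rule vectors
#'
#' @param paths An `mz_pathways` data.frame.
#' @param i Row index.
#' @return `list(nodes = <chr>, rules = <chr>)`.
#' @export
pathway_nodes <- function(paths, i) {
  list(nodes = strsplit(paths$nodes[[i]], ";", fixed = TRUE)[[1]],
       rules = if (nzchar(paths$rules[[i]]))
         strsplit(paths$rules[[i]], ";", fixed = TRUE)[[1]] else character(0))
}

#' Filter pathways by m/z range and/or time points
#'
#' A pathway is retained iff every node passes every requested criterion:
#' node m/z within `mz_range`, and node observation time points intersecting
#' `time_points`. Filtering never splits a pathway; with no criteria it is
#' the identity.
#'
#' @param paths An `mz_pathways` data.frame.
#' @param features The `mz_feature_set` the pathways refer to (node
#'   attribute source).
#' @param mz_range Optional `c(lo, hi)` in Daltons.
#' @param time_points Optional integer vector of time-point indices.
#' @return The filtered `mz_pathways`.
#' @export
filter_pathways <- function(paths, features, mz_range = NULL,
                            time_points = NULL) {
  if (is.null(mz_range) && is.null(time_points)) return(paths)
  if (!inherits(features, "mz_feature_set")) features <- feature_set(features)
  keep <- vapply(seq_len(nrow(paths)), function(i) {
    ids <- pathway_nodes(paths, i)$nodes
    fs <- features[ids]
    if (any(vapply(fs, is.null, TRUE))) return(FALSE)
    if (!is.null(mz_range)) {
      mzs <- vapply(fs, `[[`, 0, "mz")
      if (any(mzs < mz_range[[1]] | mzs > mz_range[[2]])) return(FALSE)
    }
    if (!is.null(time_points)) {
      ok <- vapply(fs, function(f) length(intersect(f$time_points,
                                                    time_points)) > 0, TRUE)
      if (!all(ok)) return(FALSE)
    }
    TRUE
  }, TRUE)
  out <- paths[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mz_pathways", "data.frame")
  out
}

#' Export a network as a Pajek .net file
#'
#' Standard dialect: `*Vertices N`, one `i "label"` line per node (1-based
#' ids, labels = feature ids), then `*Arcs` with one `source target` line
#' per directed edge. Vertices are sorted byte-lexicographically, so
#' identical networks always export byte-identical files.
#'
#' @param net An `mz_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_pajek <- function(net, path) {
  stopifnot(inherits(net, "mz_network"))
  ids <- sort(net$nodes$id, method = "radix")
  idx <- stats::setNames(seq_along(ids), ids)
  lines <- c(
    paste0("*Vertices ", length(ids)),
    if (length(ids)) sprintf('%d "%s"', seq_along(ids), ids),
    "*Arcs",
    if (nrow(net$arcs))
      sprintf("%d %d", idx[net$arcs$source_id], idx[net$arcs$target_id])
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
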