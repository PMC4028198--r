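# Readers and writers for feature tables and result files.
#
# Feature-table schema (CSV, one file per time point):
#   feature_id   optional; auto-generated as "<mz>@<time>" when absent
#   mz           required, observed m/z
#   intensity    optional
#   formula_1, ppm_1, formula_2, ppm_2, ...   ranked candidate columns
# Vendor exports (Excel elemental-composition sheets) are expected to be
# saved as CSV with these headers before use.

#' Write one feature table
#'
#' @param tab A feature-table data.frame (see format above).
#' @param path Output CSV path.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write a generated fixture to a directory
#'
#' One `t<index>_day<label>.csv` per time point, ordered.
#'
#' @param tables Output of [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_fixture <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("t%d_%s.csv", seq_along(tables) - 1L,
                                  names(tables)))
  for (i in seq_along(tables)) write_feature_table(tables[[i]], paths[[i]])
  invisible(paths)
}

#' Read per-time-point feature tables into a feature set
#'
#' Files are taken in order as time points 0, 1, 2, ...; a feature present
#' in several files (matched by m/z within `merge_ppm`, or by identical
#' explicit id) becomes one feature whose `time_points` records every file
#' index it occurred in. The candidate list of the first occurrence is
#' kept. Malformed rows (missing/non-positive m/z) are skipped with a
#' warning, or fail the run under `strict = TRUE`.
#'
#' @param paths Ordered character vector of CSV paths (nonempty).
#' @param merge_ppm Cross-time m/z merge tolerance in ppm (default 2).
#' @param charge Ion charge recorded on the features (default +1).
#' @param strict Fail on any skipped row (default `FALSE`).
#' @return An `mz_feature_set`.
#' @export
read_feature_tables <- function(paths, merge_ppm = 2, charge = 1L,
                                strict = FALSE) {
  if (length(paths) == 0) stop("no input feature tables given")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))

  acc <- list()   # id -> mz_feature fields under construction
  mzs <- numeric(0); acc_ids <- character(0)
  n_skipped <- 0L

  for (t in seq_along(paths)) {
    tab <- utils::read.csv(paths[[t]], stringsAsFactors = FALSE)
    if (!"mz" %in% names(tab))
      stop(paths[[t]], ": no 'mz' column")
    f_cols <- grep("^formula_[0-9]+$", names(tab), value = TRUE)
    f_cols <- f_cols[order(as.integer(sub("^formula_", "", f_cols)))]
    has_id <- "feature_id" %in% names(tab)
    if (has_id) {
      id_col <- as.character(tab$feature_id)
      dup <- id_col[nzchar(id_col) & duplicated(id_col)]
      if (length(dup))
        stop(paths[[t]], ": duplicate feature id(s): ",
             paste(unique(dup), collapse = ", "))
    }
    ok_rows <- 0L
    for (r in seq_len(nrow(tab))) {
      mz <- suppressWarnings(as.numeric(tab$mz[[r]]))
      if (is.na(mz) || mz <= 0) { n_skipped <- n_skipped + 1L; next }
      ok_rows <- ok_rows + 1L
      id <- if (has_id && nzchar(id_col[[r]])) id_col[[r]]
            else sprintf("%.5f@%d", mz, t - 1L)
      # merge: explicit id match first, then m/z proximity
      hit <- match(id, acc_ids)
      if (is.na(hit) && length(mzs)) {
        rel <- abs(mzs - mz) / mz * 1e6
        cand <- which(rel <= merge_ppm)
        if (length(cand)) hit <- cand[[which.min(rel[cand])]]
      }
      if (!is.na(hit)) {
        acc[[hit]]$time_points <- c(acc[[hit]]$time_points, t - 1L)
        next
      }
      cands <- .parse_candidate_columns(tab, r, f_cols)
      intensity <- if ("intensity" %in% names(tab))
        suppressWarnings(as.numeric(tab$intensity[[r]])) else NA_real_
      acc[[length(acc) + 1L]] <- list(id = id, mz = mz,
                                      time_points = t - 1L,
                                      candidates = cands,
                                      intensity = intensity)
      acc_ids <- c(acc_ids, id); mzs <- c(mzs, mz)
    }
    if (ok_rows == 0L)
      stop(paths[[t]], ": no parsable feature rows")
  }
  if (n_skipped > 0L) {
    msg <- paste0(n_skipped, " malformed row(s) skipped")
    if (strict) stop(msg, " (strict mode)") else warning(msg)
  }
  feature_set(lapply(acc, function(a)
    feature(a$id, a$mz, a$time_points, a$candidates, charge = charge,
            intensity = a$intensity)))
}

.parse_candidate_columns <- function(tab, r, f_cols) {
  if (length(f_cols) == 0) return(NULL)
  fml <- character(0); ppm <- numeric(0)
  for (fc in f_cols) {
    f <- tab[[fc]][[r]]
    if (is.na(f) || !nzchar(f)) next
    pc <- sub("^formula_", "ppm_", fc)
    p <- if (pc %in% names(tab))
      suppressWarnings(as.numeric(tab[[pc]][[r]])) else NA_real_
    fml <- c(fml, f); ppm <- c(ppm, p)
  }
  if (length(fml) == 0) return(NULL)
  data.frame(formula = fml, ppm_error = ppm, rank = seq_along(fml),
             stringsAsFactors = FALSE)
}

#' Write / read the transformations table (result file 1)
#'
#' @param edges An `mz_edges` data.frame.
#' @param path CSV path.
#' @export
write_edges <- function(edges, path) {
  utils::write.csv(as.data.frame(edges), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(source_id = "character",
                                      target_id = "character"))
  class(e) <- c("mz_edges", "data.frame")
  e
}

#' Write the pathways table
#'
#' One row per pathway: semicolon-joined node ids, semicolon-joined rules.
#'
#' @param paths An `mz_pathways` data.frame.
#' @param path CSV path.
#' @export
write_pathways <- function(paths, path) {
  utils::write.csv(as.data.frame(paths), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write the results bundle (the pathway-viewer container)
#'
#' A documented JSON equivalent of the original tool's binary workspace:
#' feature summaries (id, m/z, time points, chosen formula), the edge list,
#' pathways, the rule-frequency ranking, and unlisted-difference
#' suggestions.
#'
#' @param bundle A list as produced by [run_pipeline()].
#' @param path Output `.json` path.
#' @export
write_bundle <- function(bundle, path) {
  feats <- lapply(bundle$features, function(f) list(
    id = f$id, mz = f$mz, charge = f$charge,
    time_points = f$time_points,
    candidates = f$candidates[, c("formula", "ppm_error", "rank")]
  ))
  names(feats) <- NULL
  obj <- list(
    format = "mzgroupnet-bundle",
    version = 1L,
    features = feats,
    chosen_formulas = as.list(choose_formulas(bundle$features, bundle$edges)),
    edges = as.data.frame(bundle$edges),
    pathways = as.data.frame(bundle$pathways),
    rule_frequencies = bundle$rule_frequencies,
    unlisted_differences =
      bundle$unlisted[, setdiff(names(bundle$unlisted), "composition")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
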