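# The Feature container: one observed m/z with its time points of
# occurrence and a ranked candidate-formula list.

#' Construct an m/z feature
#'
#' @param id Unique feature identifier (string).
#' @param mz Observed mass-to-charge ratio (> 0).
#' @param time_points Integer vector of 0-based time-point indices at which
#'   the feature was observed (at least one).
#' @param candidates A data.frame with at least columns `formula` and
#'   `ppm_error` (as produced by [generate_candidates()]); `rank` and the
#'   parsed `composition` list-column are derived when absent. May have zero
#'   rows: such features are skipped (with a warning) by the matching stage.
#' @param charge Signed integer ion charge (default +1).
#' @param intensity Optional nonnegative abundance value.
#' @return An object of class `mz_feature`.
#' @export
feature <- function(id, mz, time_points, candidates = NULL, charge = 1L,
                    intensity = NA_real_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(mz) || length(mz) != 1L || mz <= 0)
    stop("feature '", id, "': mz must be a single positive number")
  time_points <- sort(unique(as.integer(time_points)))
  if (length(time_points) == 0 || any(time_points < 0))
    stop("feature '", id, "': time_points must be nonnegative indices")
  if (is.null(candidates)) candidates <- .empty_candidates()
  if (!is.data.frame(candidates) || !all(c("formula", "ppm_error") %in% names(candidates)))
    stop("feature '", id, "': candidates must have 'formula' and 'ppm_error' columns")
  if (nrow(candidates) > 0) {
    if (is.null(candidates$composition))
      candidates$composition <- lapply(candidates$formula, parse_formula)
    if (is.null(candidates$rank))
      candidates$rank <- seq_len(nrow(candidates))
    if (anyDuplicated(candidates$rank))
      stop("feature '", id, "': candidate ranks must be unique")
  }
  structure(
    list(id = id, mz = mz, charge = as.integer(charge),
         time_points = time_points, first_time = time_points[[1]],
         candidates = candidates, intensity = intensity),
    class = "mz_feature"
  )
}

#' @export
print.mz_feature <- function(x, ...) {
  cat(sprintf("<mz_feature> %s  m/z %.5f (z=%+d)  time points {%s}  %d candidate(s)\n",
              x$id, x$mz, x$charge, paste(x$time_points, collapse = ","),
              nrow(x$candidates)))
  invisible(x)
}

#' Assemble features into a feature set
#'
#' A feature set is a named list of `mz_feature` objects (names = ids) with
#' class `mz_feature_set`; ids must be unique.
#'
#' @param ... `mz_feature` objects, or a single list of them.
#' @return An `mz_feature_set`.
#' @export
feature_set <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "mz_feature"))
    xs <- xs[[1]]
  if (!all(vapply(xs, inherits, TRUE, "mz_feature")))
    stop("all elements must be mz_feature objects")
  ids <- vapply(xs, `[[`, "", "id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  names(xs) <- ids
  structure(xs, class = c("mz_feature_set", "list"))
}

#' @export
print.mz_feature_set <- function(x, ...) {
  cat(sprintf("<mz_feature_set> %d feature(s), m/z %.4f..%.4f\n", length(x),
              min(vapply(x, `[[`, 0, "mz")), max(vapply(x, `[[`, 0, "mz"))))
  invisible(x)
}

# Internal: flat table of all candidates across a feature set.
# Columns: feature_id, mz, first_time, cand_rank, formula, key; list-col composition.
.candidate_table <- function(features) {
  rows <- lapply(features, function(f) {
    if (nrow(f$candidates) == 0) return(NULL)
    data.frame(feature_id = f$id, mz = f$mz, first_time = f$first_time,
               cand_rank = f$candidates$rank, formula = f$candidates$formula,
               key = vapply(f$candidates$composition, comp_key, ""),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  comp <- unlist(lapply(features, function(f)
    if (nrow(f$candidates)) f$candidates$composition else NULL),
    recursive = FALSE)
  if (is.null(tab)) {
    tab <- data.frame(feature_id = character(0), mz = numeric(0),
                      first_time = integer(0), cand_rank = integer(0),
                      formula = character(0), key = character(0),
                      stringsAsFactors = FALSE)
    comp <- list()
  }
  tab$composition <- comp
  tab
}
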