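# Transformation rules: named elemental-composition deltas.
#
# A rule set is a data.frame of class "mz_rules" with columns name, delta
# (canonical signed token string, e.g. "+1C+2H"), note, delta_mass, and a
# list-column composition. File order is preserved: it is the tie-break
# order for frequency ranking.

.new_rules <- function(name, comps, note) {
  df <- data.frame(
    name = name,
    delta = vapply(comps, format_delta, ""),
    note = note,
    delta_mass = vapply(comps, delta_mass, 0),
    stringsAsFactors = FALSE
  )
  df$composition <- comps
  class(df) <- c("mz_rules", "data.frame")
  df
}

#' Load a transformation rules file
#'
#' Reads a delimited rules file with header `name,delta[,note]`. Deltas may
#' be written in signed-token style (`"+1C+2H"`, `"-1C-2O"`) or plain-count
#' style (`"C1H2"`); see [parse_delta()]. Validation: every delta nonzero,
#' every name unique; violations are reported with their (1-based, header
#' excluded) row number.
#'
#' @param path Path to a CSV (or TSV, `sep = "\t"`) rules file.
#' @param sep Field separator (default `","`).
#' @return An `mz_rules` data.frame preserving file order.
#' @export
load_rules <- function(path, sep = ",") {
  if (!file.exists(path)) stop("rules file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character")
  if (!all(c("name", "delta") %in% names(raw)))
    stop("rules file must have 'name' and 'delta' columns: ", path)
  if (nrow(raw) == 0) stop("rules file has no rules: ", path)
  comps <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    comp <- tryCatch(parse_delta(raw$delta[i]), error = function(e)
      stop("rules file row ", i, " ('", raw$name[i], "'): ",
           conditionMessage(e), call. = FALSE))
    if (length(comp) == 0)
      stop("rules file row ", i, " ('", raw$name[i], "'): zero delta")
    comps[[i]] <- comp
  }
  dup <- which(duplicated(raw$name))
  if (length(dup))
    stop("rules file row ", dup[[1]], ": duplicate rule name '",
         raw$name[dup[[1]]], "'")
  note <- if ("note" %in% names(raw)) raw$note else rep("", nrow(raw))
  .new_rules(raw$name, comps, note)
}

#' Write a rule set to a CSV file
#'
#' Emits `name,delta,note` with canonical signed-token deltas; the output
#' round-trips through [load_rules()].
#'
#' @param rules An `mz_rules` data.frame.
#' @param path Output file path.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "mz_rules"))
  utils::write.csv(rules[, c("name", "delta", "note")], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The default transformation rule set
#'
#' 56 chemical and biochemical reaction steps: the predominant plant
#' secondary-metabolism reactions (mono-oxygenation, hydrogenation,
#' hydration, methoxylation, methylation, oxidoreduction, oxidation,
#' malonylation, hexosylation, dihydroxylation, coumaroylation,
#' pentosylation) plus common phase-I/II biotransformations and acyl/glycosyl
#' transfers, each as a signed elemental delta. The file ships with the
#' package (`system.file("extdata", "transformation_rules.csv", ...)`) and is
#' meant to be copied and edited.
#'
#' @return An `mz_rules` data.frame with 56 rows.
#' @export
default_rules <- function() {
  load_rules(default_rules_path())
}

#' @rdname default_rules
#' @export
default_rules_path <- function() {
  system.file("extdata", "transformation_rules.csv", package = "mzgroupnet",
              mustWork = TRUE)
}

#' Look up a rule delta by name
#'
#' @param rules An `mz_rules` data.frame.
#' @param name Rule name.
#' @return The rule's canonical composition delta.
#' @export
rule_delta <- function(rules, name) {
  i <- match(name, rules$name)
  if (is.na(i)) stop("no rule named '", name, "'")
  rules$composition[[i]]
}
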