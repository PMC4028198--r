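# Van Krevelen mapping: O/C and H/C atomic ratios of assigned formulas,
# and detection of the CH2/O "rhombus" motif (four formulas related
# pairwise by +CH2 and +O shifts, a parallelogram in ratio space).

#' Van Krevelen coordinates for a feature set
#'
#' Computes O/C and H/C atomic ratios from each feature's chosen formula.
#' Elements other than C, H, O are ignored (CHO projection). The canonical
#' display window is O/C in \[0, 1\] and H/C in \[0, 2\]; points outside it
#' are flagged via `in_bounds`, never dropped silently. Features whose
#' chosen formula has no carbon are skipped with a warning.
#'
#' @param features An `mz_feature_set`.
#' @param edges Optional `mz_edges`; when given, each feature's formula is
#'   the candidate with the most edge support (see [choose_formulas()]),
#'   otherwise the rank-1 candidate.
#' @param groups Optional named vector feature id -> group label (e.g. a
#'   time label) copied into the output.
#' @return A data.frame with columns `feature_id`, `formula`, `oc_ratio`,
#'   `hc_ratio`, `group`, `in_bounds`.
#' @export
van_krevelen <- function(features, edges = NULL, groups = NULL) {
  if (!inherits(features, "mz_feature_set")) features <- feature_set(features)
  fml <- choose_formulas(features, edges)
  fml <- fml[!is.na(fml)]
  if (length(fml) == 0)
    return(data.frame(feature_id = character(0), formula = character(0),
                      oc_ratio = numeric(0), hc_ratio = numeric(0),
                      group = character(0), in_bounds = logical(0),
                      stringsAsFactors = FALSE))
  comps <- lapply(fml, parse_formula)
  cn <- vapply(comps, function(x) if ("C" %in% names(x)) x[["C"]] else 0L, 0L)
  no_c <- cn <= 0
  if (any(no_c)) {
    warning("skipping ", sum(no_c), " feature(s) with carbon-free formula: ",
            paste(names(fml)[no_c], collapse = ", "))
    fml <- fml[!no_c]; comps <- comps[!no_c]; cn <- cn[!no_c]
  }
  hn <- vapply(comps, function(x) if ("H" %in% names(x)) x[["H"]] else 0L, 0L)
  on <- vapply(comps, function(x) if ("O" %in% names(x)) x[["O"]] else 0L, 0L)
  oc <- on / cn
  hc <- hn / cn
  grp <- if (is.null(groups)) NA_character_ else unname(groups[names(fml)])
  data.frame(
    feature_id = names(fml), formula = unname(fml),
    oc_ratio = oc, hc_ratio = hc, group = grp,
    in_bounds = oc >= 0 & oc <= 1 & hc >= 0 & hc <= 2,
    stringsAsFactors = FALSE
  )
}

#' Find CH2/O rhombic motifs
#'
#' Searches, by exact composition arithmetic, for quadruples (a, b, c, d)
#' with b = a + CH2, c = a + O, d = a + CH2 + O: four compounds
#' interconnected by net methylene and oxygen shifts, which plot as a
#' rhombus on the van Krevelen diagram.
#'
#' @param formulas Named character vector (feature id -> formula string) or
#'   named list of compositions.
#' @return A data.frame with columns `base`, `plus_ch2`, `plus_o`,
#'   `plus_ch2_o` holding feature ids, one row per motif.
#' @export
find_rhombic_motifs <- function(formulas) {
  if (length(formulas) == 0 || is.null(names(formulas)))
    return(.empty_motifs())
  comps <- if (is.character(formulas)) lapply(formulas, parse_formula)
           else lapply(formulas, as_composition)
  keys <- vapply(comps, comp_key, "")
  index <- split(names(formulas), keys)
  ch2 <- as_composition(c(C = 1, H = 2))
  o1 <- as_composition(c(O = 1))
  rows <- list()
  for (i in seq_along(comps)) {
    a <- comps[[i]]
    kb <- comp_key(comp_add(a, ch2))
    kc <- comp_key(comp_add(a, o1))
    kd <- comp_key(comp_add(comp_add(a, ch2), o1))
    b <- index[[kb]]; cc <- index[[kc]]; d <- index[[kd]]
    if (is.null(b) || is.null(cc) || is.null(d)) next
    combo <- expand.grid(base = names(formulas)[[i]], plus_ch2 = b,
                         plus_o = cc, plus_ch2_o = d,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- combo
  }
  if (length(rows) == 0) return(.empty_motifs())
  out <- do.call(rbind, rows)
  out <- out[order(out$base, out$plus_ch2, out$plus_o, out$plus_ch2_o), ]
  rownames(out) <- NULL
  out
}

.empty_motifs <- function() {
  data.frame(base = character(0), plus_ch2 = character(0),
             plus_o = character(0), plus_ch2_o = character(0),
             stringsAsFactors = FALSE)
}
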