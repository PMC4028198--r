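# Elemental-composition algebra and exact monoisotopic mass computation.
#
# A composition is a named integer vector (element symbol -> signed count) in
# canonical form: zero counts dropped, names in Hill order (C, H, then the
# remaining elements alphabetically). All exported operations return canonical
# compositions, so identical compositions are identical R objects.

# Monoisotopic atomic masses (CODATA/AME2020, truncated to 10 significant
# decimals; C is exactly 12 by definition of the unified atomic mass unit).
.MONOISOTOPIC_MASS <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740044,
  O  = 15.9949146196,
  S  = 31.9720711744,
  P  = 30.9737619984,
  Na = 22.9897692820,
  K  = 38.9637064864,
  Cl = 34.9688526820,
  F  = 18.9984031627,
  Br = 78.9183376000,
  I  = 126.9044719000,
  Si = 27.9769265350,
  Se = 79.9165218000
)

.ELECTRON_MASS <- 0.00054857990907

#' Supported chemical elements
#'
#' Elements for which a monoisotopic atomic mass is tabulated. Compositions
#' are restricted to these symbols.
#'
#' @return Character vector of element symbols.
#' @export
supported_elements <- function() names(.MONOISOTOPIC_MASS)

#' Canonicalize an elemental composition
#'
#' Drops zero counts, merges duplicate symbols, and orders elements in Hill
#' order (C first, H second, remaining elements alphabetically). Every
#' composition-returning function in the package emits this form, so two
#' compositions are equal iff `identical()` on the canonical vectors.
#'
#' @param counts Named numeric vector of signed integer element counts.
#' @return Named integer vector in canonical form (length 0 for the empty
#'   composition).
#' @export
as_composition <- function(counts) {
  if (length(counts) == 0) return(stats::setNames(integer(0), character(0)))
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("composition counts must be a named vector of element counts")
  bad <- setdiff(names(counts), names(.MONOISOTOPIC_MASS))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (any(counts != round(counts)))
    stop("element counts must be integers")
  x <- tapply(as.integer(round(counts)), names(counts), sum)
  x <- x[x != 0L]
  if (length(x) == 0) return(stats::setNames(integer(0), character(0)))
  nm <- names(x)
  ord <- order(match(nm, c("C", "H"), nomatch = 3L), nm)
  stats::setNames(as.integer(x[ord]), nm[ord])
}

#' Parse a sum formula
#'
#' Accepts plain Hill-style strings (`"C32H39O20"`, implicit count 1 as in
#' `"CH4"`) and the underscore-delimited dialect used in instrument exports
#' (`"C_32_H_39_O_20_"`).
#'
#' @param text A single formula string.
#' @return Canonical composition (named integer vector).
#' @examples
#' parse_formula("C32H39O20")
#' parse_formula("C_53_H_53_O_27_")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  s <- gsub("_", "", trimws(text))
  if (!nzchar(s)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("unparsable formula: '", text, "'")
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Z][a-z]?", "", toks)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  bad <- setdiff(sym, names(.MONOISOTOPIC_MASS))
  if (length(bad))
    stop("unknown element symbol '", bad[[1]], "' in formula '", text, "'")
  as_composition(stats::setNames(cnt, sym))
}

#' Format a composition as a plain Hill-order formula string
#'
#' @param comp Composition (any named integer vector; canonicalized first).
#'   Negative counts are rendered with a leading minus per element, which
#'   round-trips through [parse_delta()] but not [parse_formula()].
#' @return A single string; `""` for the empty composition.
#' @export
format_formula <- function(comp) {
  comp <- as_composition(comp)
  if (length(comp) == 0) return("")
  paste0(names(comp), ifelse(comp == 1L, "", comp), collapse = "")
}

#' Element-wise composition arithmetic
#'
#' @param a,b Compositions.
#' @return Canonical composition `a + b` (resp. `a - b`).
#' @export
comp_add <- function(a, b) {
  as_composition(c(as_composition(a), as_composition(b)))
}

#' @rdname comp_add
#' @export
comp_subtract <- function(a, b) {
  b <- as_composition(b)
  as_composition(c(as_composition(a), stats::setNames(-b, names(b))))
}

#' Signed composition difference b - a
#'
#' The delta that transforms `a` into `b`: `comp_add(a, composition_difference(a, b))`
#' equals `b`. Antisymmetric in its arguments.
#'
#' @param a,b Compositions.
#' @return Canonical signed composition.
#' @examples
#' composition_difference(parse_formula("C15H11O6"), parse_formula("C15H11O7"))
#' @export
composition_difference <- function(a, b) comp_subtract(b, a)

#' Monoisotopic m/z of an ion
#'
#' Computes `(sum of monoisotopic atomic masses - charge * electron mass) / |charge|`.
#' For an intrinsically charged cation such as the flavylium core of
#' anthocyanins, the formula is the intact ion (detected as `[M]+`) and the
#' single-electron correction reproduces instrument exact masses; this is not
#' an `[M+H]+` proton addition.
#'
#' @param comp Composition with nonnegative counts.
#' @param charge Signed integer charge, not zero (default +1, positive mode).
#' @return m/z in Daltons per unit charge.
#' @examples
#' monoisotopic_mz(parse_formula("C32H39O20"), 1) # 743.20292
#' @export
monoisotopic_mz <- function(comp, charge = 1L) {
  comp <- as_composition(comp)
  if (length(charge) != 1L || charge == 0 || charge != round(charge))
    stop("charge must be a nonzero integer")
  if (any(comp < 0))
    stop("negative element count: an ion formula must be nonnegative (use delta_mass() for rule deltas)")
  m <- sum(.MONOISOTOPIC_MASS[names(comp)] * comp)
  (m - charge * .ELECTRON_MASS) / abs(charge)
}

#' Mass of a (possibly signed) composition delta
#'
#' Plain sum of monoisotopic atomic masses; no electron term, since a neutral
#' modification leaves the charge unchanged.
#'
#' @param delta Composition with signed counts.
#' @return Signed mass in Daltons.
#' @examples
#' delta_mass(c(O = 1))           # 15.99491
#' delta_mass(parse_delta("+6C+10H+5O")) # hexose residue, 162.05282
#' @export
delta_mass <- function(delta) {
  delta <- as_composition(delta)
  if (length(delta) == 0) return(0)
  sum(.MONOISOTOPIC_MASS[names(delta)] * delta)
}

#' Parse a signed composition delta
#'
#' Accepts the signed-token rule dialect (`"+1C+2H"`, `"-1C-2O"`, counts
#' optional: `"+O"`), a plain formula (`"C6H10O5"`, all positive), and
#' per-element signed formulas (`"C2H-2O1"`). Whitespace is ignored.
#'
#' @param text A single delta string; `""` parses to the empty delta.
#' @return Canonical signed composition.
#' @examples
#' parse_delta("+1C+2H")
#' parse_delta("-1C-2O")
#' @export
parse_delta <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("delta must be a single character string")
  s <- gsub("[[:space:]_]", "", text)
  if (!nzchar(s)) return(as_composition(stats::setNames(integer(0), character(0))))
  # two dialects, decided per string: sign-before-count ("+1C+2H", "-O",
  # plain "C1H2") or sign-after-symbol ("C1H-2O1"); try in that order
  parsed <- .parse_delta_tokens(s, "([+-]?)([0-9]*)([A-Z][a-z]?)",
                                sym_grp = 4L, sign_grp = 2L, cnt_grp = 3L)
  if (is.null(parsed))
    parsed <- .parse_delta_tokens(s, "([A-Z][a-z]?)([+-]?)([0-9]*)",
                                  sym_grp = 2L, sign_grp = 3L, cnt_grp = 4L)
  if (is.null(parsed))
    stop("unparsable delta: '", text, "'")
  bad <- setdiff(names(parsed), names(.MONOISOTOPIC_MASS))
  if (length(bad))
    stop("unknown element symbol '", bad[[1]], "' in delta '", text, "'")
  as_composition(parsed)
}

#' Format a signed composition delta in rule notation
#'
#' Inverse of [parse_delta()] on canonical compositions: emits the
#' `"+1C+2H"` style with explicit counts and signs.
#'
#' @param delta Composition with signed counts.
#' @return A single string; `""` for the empty delta.
#' @export
format_delta <- function(delta) {
  delta <- as_composition(delta)
  if (length(delta) == 0) return("")
  paste0(ifelse(delta < 0, "-", "+"), abs(delta), names(delta), collapse = "")
}

# Internal: tokenize a delta string under one dialect; NULL if the pattern
# does not cover the whole string.
.parse_delta_tokens <- function(s, pat, sym_grp, sign_grp, cnt_grp) {
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[[1]] == -1 || sum(attr(m, "match.length")) != nchar(s)) return(NULL)
  toks <- regmatches(s, list(m))[[1]]
  parts <- regmatches(toks, regexec(pat, toks, perl = TRUE))
  sym <- vapply(parts, `[[`, "", sym_grp)
  if (any(!nzchar(sym))) return(NULL)
  cnt <- vapply(parts, function(p) {
    n <- if (nzchar(p[[cnt_grp]])) as.integer(p[[cnt_grp]]) else 1L
    if (identical(p[[sign_grp]], "-")) -n else n
  }, integer(1))
  stats::setNames(cnt, sym)
}

# Internal: stable string key for hashing compositions.
comp_key <- function(comp) {
  if (length(comp) == 0) return("")
  paste0(names(comp), comp, collapse = "|")
}
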