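# Exhaustive candidate sum-formula generation within a ppm window.
#
# Emulates the instrument-side elemental-composition step: every composition
# on the bounded element lattice whose theoretical ion m/z falls within the
# tolerance is returned (no heuristic pruning). Non-hydrogen counts are
# enumerated on a grid and the hydrogen count is solved from the mass
# remainder; at sub-ppm windows (<< 1 H mass) the neighbouring H counts are
# also probed so no lattice point is missed at any tolerance.

#' Generate candidate sum formulas for an observed m/z
#'
#' Exhaustively enumerates elemental compositions within `bounds` whose
#' theoretical ion m/z (electron-corrected, see [monoisotopic_mz()]) deviates
#' from `mz` by at most `tolerance_ppm`, sorted by absolute ppm error.
#'
#' @param mz Observed mass-to-charge ratio in Daltons (> 0).
#' @param tolerance_ppm Maximum absolute deviation in parts per million.
#' @param bounds Named integer vector of per-element maximum counts,
#'   e.g. `c(C = 100, H = 200, O = 50, N = 10)`. Elements not listed are
#'   excluded (count 0).
#' @param max_candidates Keep at most this many candidates (default 10).
#' @param charge Signed integer ion charge (default +1).
#' @param rdbe_filter If `TRUE`, drop candidates with ring-and-double-bond
#'   equivalents below zero. Off by default: downstream transformation
#'   matching, not plausibility filtering, is the disambiguation mechanism.
#' @return A data.frame with columns `formula`, `theoretical_mz`,
#'   `ppm_error`, `rank` and a list-column `composition`; zero rows when
#'   nothing fits. Ties in |ppm| are broken by the formula string.
#' @examples
#' generate_candidates(743.20292, 1, c(C = 100, H = 200, O = 50, N = 10))
#' @export
generate_candidates <- function(mz, tolerance_ppm, bounds, max_candidates = 10L,
                                charge = 1L, rdbe_filter = FALSE) {
  if (!is.numeric(mz) || length(mz) != 1L || is.na(mz) || mz <= 0)
    stop("mz must be a single positive number")
  if (!is.numeric(tolerance_ppm) || tolerance_ppm <= 0)
    stop("tolerance_ppm must be positive")
  if (length(bounds) == 0 || is.null(names(bounds)))
    stop("bounds must be a nonempty named vector of element maxima")
  bad <- setdiff(names(bounds), supported_elements())
  if (length(bad))
    stop("unknown element(s) in bounds: ", paste(bad, collapse = ", "))
  if (charge == 0) stop("charge must be nonzero")
  bounds <- floor(bounds)

  masses <- .MONOISOTOPIC_MASS
  # total neutral-atom mass of the ion's formula implied by the observed m/z
  target <- mz * abs(charge) + charge * .ELECTRON_MASS
  window <- mz * tolerance_ppm * 1e-6 * abs(charge)

  h_max <- if ("H" %in% names(bounds)) bounds[["H"]] else 0L
  others <- setdiff(names(bounds), "H")
  others <- others[bounds[others] > 0]

  # grid over non-H elements, each capped by what the target mass allows
  ranges <- lapply(others, function(el)
    0:min(bounds[[el]], floor((target + window) / masses[[el]])))
  names(ranges) <- others
  grid <- if (length(ranges)) as.matrix(expand.grid(ranges, KEEP.OUT.ATTRS = FALSE))
          else matrix(integer(0), nrow = 1, ncol = 0)
  base <- if (ncol(grid)) as.numeric(grid %*% masses[others]) else 0

  keep_mask <- base <= target + window
  grid <- grid[keep_mask, , drop = FALSE]
  base <- base[keep_mask]
  if (length(base) == 0) return(.empty_candidates())

  # solve H from the remainder; probe neighbours so wide tolerances
  # (window >= half an H mass) still see every lattice point
  h_mid <- round((target - base) / masses[["H"]])
  n_probe <- max(1L, ceiling(window / masses[["H"]] + 1))
  rows <- integer(0); hs <- integer(0)
  for (off in (-n_probe):n_probe) {
    h <- h_mid + off
    ok <- h >= 0 & h <= h_max & abs(base + h * masses[["H"]] - target) <= window
    rows <- c(rows, which(ok)); hs <- c(hs, h[ok])
  }
  if (length(rows) == 0) return(.empty_candidates())

  total_mass <- base[rows] + hs * masses[["H"]]
  theo_mz <- (total_mass - charge * .ELECTRON_MASS) / abs(charge)
  ppm <- (theo_mz - mz) / mz * 1e6

  cnt <- cbind(grid[rows, , drop = FALSE], H = hs)
  if (rdbe_filter) {
    g <- function(el) if (el %in% colnames(cnt)) cnt[, el] else 0
    rdbe <- g("C") + g("Si") + 1 - (g("H") + g("Cl") + g("Br") + g("F") + g("I")) / 2 +
      (g("N") + g("P")) / 2
    sel <- rdbe >= 0
    cnt <- cnt[sel, , drop = FALSE]; theo_mz <- theo_mz[sel]; ppm <- ppm[sel]
    if (nrow(cnt) == 0) return(.empty_candidates())
  }

  comps <- lapply(seq_len(nrow(cnt)), function(i)
    as_composition(stats::setNames(cnt[i, ], colnames(cnt))))
  formulas <- vapply(comps, format_formula, "")
  keep <- nzchar(formulas) # drop the all-zero composition if it sneaks in
  comps <- comps[keep]; formulas <- formulas[keep]
  theo_mz <- theo_mz[keep]; ppm <- ppm[keep]
  if (length(formulas) == 0) return(.empty_candidates())

  ord <- order(abs(ppm), formulas)
  ord <- ord[seq_len(min(length(ord), max_candidates))]
  out <- data.frame(
    formula = formulas[ord],
    theoretical_mz = theo_mz[ord],
    ppm_error = ppm[ord],
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  out$composition <- comps[ord]
  out
}

.empty_candidates <- function() {
  out <- data.frame(formula = character(0), theoretical_mz = numeric(0),
                    ppm_error = numeric(0), rank = integer(0),
                    stringsAsFactors = FALSE)
  out$composition <- list()
  out
}
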