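# Synthetic time-series fixture generator.
#
# Emulates a processed positive-mode LC-MS time series of a stressed plant:
# a planted anthocyanin elongation chain (cyanidin core progressively
# glycosylated and acylated, nominal m/z 287 -> 449 -> 595 -> 727 -> 889 ->
# 975 -> 1121) appearing on a fixed schedule, surrounded by decoy features
# with their own 1-ppm candidate-formula ambiguity. What it deliberately
# does NOT emulate: chromatography, isotope envelopes, adducts, intensity
# dynamics, missing observations.

# The planted chain. The three members absent from the reference compound
# table (m/z 287, 449, 595) are derived by walking the rule deltas back
# from the anchored C35H35O17 (m/z 727).
.CHAIN <- data.frame(
  formula = c("C15H11O6", "C21H21O11", "C30H27O13", "C35H35O17",
              "C41H45O22", "C44H47O25", "C53H53O27"),
  nominal = c(287L, 449L, 595L, 727L, 889L, 975L, 1121L),
  first_day = c(0L, 2L, 4L, 4L, 4L, 4L, 4L),
  stringsAsFactors = FALSE
)
.CHAIN_RULES <- c("hexosylation", "coumaroylation", "pentosylation",
                  "hexosylation", "malonylation", "coumaroylation")

#' Specification for a synthetic fixture
#'
#' Defaults state the emulated world: a 3-week cold/light-stress sampling
#' (days 0, 2, 4, 8, 12, 16, 20 — a day-2 sample is needed because the
#' second chain member first appears after 2 days), the 7-member anthocyanin
#' chain on its appearance schedule, 50 unrelated decoy features in the
#' 200-1600 Da range, Gaussian m/z noise of 0.3 ppm (comfortably inside the
#' instrument's 1-ppm assignment window), and up to 9 false candidate
#' formulas per feature (10 total, the instrument-export maximum).
#'
#' @param time_days Sampling days (ordered, unique).
#' @param n_decoys Number of decoy features.
#' @param decoy_mass_range `c(lo, hi)` mass window for decoys, Da.
#' @param ppm_noise_sd SD of Gaussian m/z noise, ppm.
#' @param n_false_candidates Maximum false candidates added per feature.
#' @param tolerance_ppm Candidate-assignment window, ppm.
#' @param bounds Element maxima for candidate generation.
#' @param seed Integer seed; fully determines the fixture.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(time_days = c(0L, 2L, 4L, 8L, 12L, 16L, 20L),
                         n_decoys = 50L,
                         decoy_mass_range = c(200, 1600),
                         ppm_noise_sd = 0.3,
                         n_false_candidates = 9L,
                         tolerance_ppm = 1,
                         bounds = c(C = 100L, H = 200L, O = 50L, N = 10L),
                         seed = 1L) {
  time_days <- as.integer(time_days)
  stopifnot(!is.unsorted(time_days, strictly = TRUE),
            n_decoys >= 0, ppm_noise_sd >= 0, tolerance_ppm > 0,
            length(decoy_mass_range) == 2L,
            diff(decoy_mass_range) > 0)
  if (!all(.CHAIN$first_day %in% time_days))
    stop("time_days must include the chain appearance days ",
         paste(unique(.CHAIN$first_day), collapse = ", "))
  structure(list(time_days = time_days, n_decoys = as.integer(n_decoys),
                 decoy_mass_range = decoy_mass_range,
                 ppm_noise_sd = ppm_noise_sd,
                 n_false_candidates = as.integer(n_false_candidates),
                 tolerance_ppm = tolerance_ppm, bounds = bounds,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' The planted pathway ground truth
#'
#' @return `list(formulas, nominal_mz, mz, first_day, rules)` describing the
#'   7-member chain and the 6 rules joining consecutive members.
#' @export
planted_chain <- function() {
  list(formulas = .CHAIN$formula,
       nominal_mz = .CHAIN$nominal,
       mz = vapply(.CHAIN$formula, function(f)
         monoisotopic_mz(parse_formula(f), 1L), 0, USE.NAMES = FALSE),
       first_day = .CHAIN$first_day,
       rules = .CHAIN_RULES)
}

#' Generate a synthetic per-time-point fixture
#'
#' Produces one feature table per sampling day in the format read by
#' [read_feature_tables()]. Planted features carry their true formula plus
#' the nearest false candidates from the exhaustive 1-ppm enumeration;
#' observed m/z is the theoretical cation m/z perturbed by Gaussian ppm
#' noise. A feature persists from its first appearance to the end of the
#' series. Decoy formulas are drawn uniformly in mass and accepted only if
#' no default rule links them to the chain: a decoy m/z must stay at least
#' 0.02 Da away from every (chain m/z +/- rule delta mass) and from every
#' chain m/z, so that no decoy candidate — true or false — can be
#' rule-matched to any chain candidate.
#'
#' @param spec A [fixture_spec()].
#' @return Named list of data.frames, one per day (`day0`, `day2`, ...),
#'   with attributes `truth` (chain ids, decoy ids, true formulas, observed
#'   m/z, first days) and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  rules <- default_rules()
  chain_mz <- planted_chain()$mz

  # forbidden decoy m/z centres: chain +/- every rule mass (and the chain itself)
  forbidden <- unique(c(chain_mz,
                        as.numeric(outer(chain_mz, rules$delta_mass, `+`)),
                        as.numeric(outer(chain_mz, rules$delta_mass, `-`))))
  margin <- 0.02

  ids <- character(0); true_formula <- character(0)
  obs_mz <- numeric(0); first_day <- integer(0)

  add_feature <- function(id, formula, day) {
    comp <- parse_formula(formula)
    mz0 <- monoisotopic_mz(comp, 1L)
    mz <- mz0 * (1 + stats::rnorm(1L, 0, spec$ppm_noise_sd) * 1e-6)
    ids <<- c(ids, id); true_formula <<- c(true_formula, formula)
    obs_mz <<- c(obs_mz, mz); first_day <<- c(first_day, day)
  }

  for (i in seq_len(nrow(.CHAIN)))
    add_feature(sprintf("M%d", .CHAIN$nominal[i]), .CHAIN$formula[i],
                .CHAIN$first_day[i])

  n_acc <- 0L; tries <- 0L
  while (n_acc < spec$n_decoys) {
    tries <- tries + 1L
    if (tries > 200L * max(1L, spec$n_decoys))
      stop("decoy generation failed: rejection rate too high")
    m <- stats::runif(1L, spec$decoy_mass_range[[1]], spec$decoy_mass_range[[2]])
    if (min(abs(m - forbidden)) < margin) next
    if (length(obs_mz) && min(abs(m - obs_mz)) < margin) next
    cand <- generate_candidates(m, spec$tolerance_ppm, spec$bounds,
                                max_candidates = 50L)
    if (nrow(cand) == 0) next
    pick <- sample.int(nrow(cand), 1L)
    n_acc <- n_acc + 1L
    add_feature(sprintf("D%02d", n_acc), cand$formula[[pick]],
                sample(spec$time_days, 1L))
  }

  # candidate lists: true formula + nearest false candidates within the window
  candidates <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cand <- generate_candidates(obs_mz[[i]], spec$tolerance_ppm, spec$bounds,
                                max_candidates = spec$n_false_candidates + 25L)
    cand <- cand[cand$formula != true_formula[[i]], , drop = FALSE]
    if (nrow(cand) > spec$n_false_candidates)
      cand <- cand[seq_len(spec$n_false_candidates), , drop = FALSE]
    tcomp <- parse_formula(true_formula[[i]])
    tmz <- monoisotopic_mz(tcomp, 1L)
    true_row <- data.frame(formula = true_formula[[i]], theoretical_mz = tmz,
                           ppm_error = (tmz - obs_mz[[i]]) / obs_mz[[i]] * 1e6,
                           rank = 0L, stringsAsFactors = FALSE)
    true_row$composition <- list(tcomp)
    cand <- rbind(true_row, cand[, names(true_row)])
    cand <- cand[order(abs(cand$ppm_error), cand$formula), ]
    cand$rank <- seq_len(nrow(cand))
    rownames(cand) <- NULL
    candidates[[i]] <- cand
  }
  intensity <- stats::rlnorm(length(ids), meanlog = log(1e6), sdlog = 1)

  k_max <- max(vapply(candidates, nrow, 0L))
  tables <- lapply(spec$time_days, function(day) {
    sel <- which(first_day <= day)
    tab <- data.frame(feature_id = ids[sel], mz = obs_mz[sel],
                      intensity = intensity[sel], stringsAsFactors = FALSE)
    for (k in seq_len(k_max)) {
      tab[[paste0("formula_", k)]] <- vapply(candidates[sel], function(cd)
        if (nrow(cd) >= k) cd$formula[[k]] else NA_character_, "")
      tab[[paste0("ppm_", k)]] <- vapply(candidates[sel], function(cd)
        if (nrow(cd) >= k) cd$ppm_error[[k]] else NA_real_, 0)
    }
    tab
  })
  names(tables) <- paste0("day", spec$time_days)
  attr(tables, "truth") <- list(
    chain_ids = ids[seq_len(nrow(.CHAIN))],
    decoy_ids = ids[-seq_len(nrow(.CHAIN))],
    true_formula = stats::setNames(true_formula, ids),
    observed_mz = stats::setNames(obs_mz, ids),
    first_day = stats::setNames(first_day, ids),
    chain_rules = .CHAIN_RULES
  )
  attr(tables, "spec") <- spec
  tables
}
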