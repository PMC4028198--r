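# Pipeline orchestration: read -> match -> network -> pathways -> reports.

#' Build a pipeline run configuration
#'
#' @param inputs Ordered character vector of per-time-point feature-table
#'   CSVs (time index = position, 0-based).
#' @param out_dir Output directory for the result files.
#' @param rules_path Rules CSV; `NULL` uses the shipped 56-rule default.
#' @param tolerance_ppm Candidate window in ppm, used only when a table has
#'   no candidate columns and candidates must be generated (default 1).
#' @param bounds Element maxima for on-the-fly candidate generation.
#' @param max_candidates Candidate-list cap (default 10).
#' @param merge_ppm Cross-time feature merge tolerance (default 2 ppm).
#' @param time_filter Enforce chronological edge direction (default `TRUE`).
#' @param max_path_length Pathway node cap (default 20).
#' @param novel_min_count,novel_max_delta_mass Thresholds for unlisted-
#'   difference mining (defaults 2 and 300 Da).
#' @param mz_range,time_points Optional pathway filters.
#' @param seed Optional integer seed (the pipeline itself is deterministic;
#'   the seed is recorded and set for reproducibility of any downstream
#'   sampling).
#' @return A list of class `run_config`.
#' @export
run_config <- function(inputs, out_dir, rules_path = NULL,
                       tolerance_ppm = 1,
                       bounds = c(C = 100L, H = 200L, O = 50L, N = 10L),
                       max_candidates = 10L, merge_ppm = 2,
                       time_filter = TRUE, max_path_length = 20L,
                       novel_min_count = 2L, novel_max_delta_mass = 300,
                       mz_range = NULL, time_points = NULL, seed = NULL) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be positive")
  structure(list(inputs = inputs, out_dir = out_dir, rules_path = rules_path,
                 tolerance_ppm = tolerance_ppm, bounds = bounds,
                 max_candidates = as.integer(max_candidates),
                 merge_ppm = merge_ppm, time_filter = isTRUE(time_filter),
                 max_path_length = as.integer(max_path_length),
                 novel_min_count = as.integer(novel_min_count),
                 novel_max_delta_mass = novel_max_delta_mass,
                 mz_range = mz_range, time_points = time_points, seed = seed),
            class = "run_config")
}

#' Run the full transformation-network pipeline
#'
#' Reads the per-time-point tables, generates candidates where a table
#' supplies none, detects transformation edges against the rules, builds
#' the network, enumerates and filters non-redundant pathways, ranks rule
#' frequencies, mines unlisted differences, computes van Krevelen
#' coordinates, and writes the result files to `out_dir`:
#'
#' * `transformations.csv` — the matched edges,
#' * `rule_frequencies.csv` — modification ranking,
#' * `unlisted_differences.csv` — suggested novel modifications,
#' * `results_bundle.json` — container for pathway viewing (with
#'   `pathways.csv` alongside),
#' * `network.net` — Pajek export,
#' * `van_krevelen.csv` — O/C and H/C scatter data.
#'
#' Identical inputs and configuration yield byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages (default `FALSE`).
#' @return The results bundle, invisibly: a list with `features`, `rules`,
#'   `edges`, `network`, `pathways`, `rule_frequencies`, `unlisted`,
#'   `van_krevelen`, `files`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[mzgroupnet] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  rules <- stage("rules", {
    r <- if (is.null(config$rules_path)) default_rules()
         else load_rules(config$rules_path)
    if (nrow(r) == 0) stop("empty rule set")
    r
  })
  say(nrow(rules), " transformation rules loaded")

  features <- stage("read", read_feature_tables(config$inputs,
                                                merge_ppm = config$merge_ppm))
  say(length(features), " features read from ", length(config$inputs),
      " time point(s)")

  features <- stage("candidates", {
    fs <- lapply(features, function(f) {
      if (nrow(f$candidates) > 0) return(f)
      cand <- generate_candidates(f$mz, config$tolerance_ppm, config$bounds,
                                  max_candidates = config$max_candidates,
                                  charge = f$charge)
      feature(f$id, f$mz, f$time_points, cand, charge = f$charge,
              intensity = f$intensity)
    })
    feature_set(fs)
  })

  edges <- stage("matching",
                 detect_transformations(features, rules,
                                        time_filter = config$time_filter))
  say(nrow(edges), " transformation edge(s) detected")

  net <- stage("network", build_network(edges, features))
  paths <- stage("pathways",
                 enumerate_pathways(net, max_length = config$max_path_length))
  say(nrow(paths), " non-redundant pathway(s)")
  paths <- stage("pathway-filter",
                 filter_pathways(paths, features, mz_range = config$mz_range,
                                 time_points = config$time_points))

  freq <- stage("frequencies", rank_rule_frequencies(edges, rules))
  unlisted <- stage("unlisted",
                    discover_unlisted(features, rules,
                                      min_count = config$novel_min_count,
                                      max_delta_mass = config$novel_max_delta_mass))
  say(nrow(unlisted), " unlisted recurrent difference(s)")
  vk <- stage("van-krevelen",
              suppressWarnings(van_krevelen(features, edges)))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  bundle <- list(features = features, rules = rules, edges = edges,
                 network = net, pathways = paths, rule_frequencies = freq,
                 unlisted = unlisted, van_krevelen = vk)
  files <- stage("write", {
    write_edges(edges, out("transformations.csv"))
    utils::write.csv(freq, out("rule_frequencies.csv"), row.names = FALSE)
    utils::write.csv(unlisted[, setdiff(names(unlisted), "composition")],
                     out("unlisted_differences.csv"), row.names = FALSE)
    write_pathways(paths, out("pathways.csv"))
    write_bundle(bundle, out("results_bundle.json"))
    export_pajek(net, out("network.net"))
    utils::write.csv(vk, out("van_krevelen.csv"), row.names = FALSE)
    c("transformations.csv", "rule_frequencies.csv",
      "unlisted_differences.csv", "pathways.csv", "results_bundle.json",
      "network.net", "van_krevelen.csv")
  })
  say("results written to ", config$out_dir)
  bundle$files <- file.path(config$out_dir, files)
  invisible(bundle)
}
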