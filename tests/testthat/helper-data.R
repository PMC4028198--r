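# Reference anthocyanin cation masses (flavylium [M]+ ions, charge +1).
# 36 sum formulas with their published electron-corrected exact masses.
# One published row (C62H69O35 / 1373.37156) is internally inconsistent:
# the mass of that formula is 1373.36139 (0.01017 Da off), a typo in the
# source table; it is kept here flagged with consistent = FALSE.
anthocyanin_reference <- function() {
  df <- data.frame(
    formula = c("C32H39O20", "C35H41O23", "C41H45O22", "C43H49O24",
                "C44H47O25", "C47H55O27", "C52H55O26", "C50H57O30",
                "C55H57O29", "C58H65O31", "C61H67O34", "C26H29O15",
                "C35H35O17", "C37H39O19", "C46H45O21", "C42H47O23",
                "C44H47O26", "C45H49O26", "C46H51O27", "C51H53O25",
                "C51H53O26", "C52H55O27", "C53H53O27", "C53H57O27",
                "C54H55O28", "C54H55O29", "C56H59O29", "C55H57O30",
                "C56H59O30", "C60H65O33", "C60H65O34", "C61H67O35",
                "C62H69O35", "C72H77O38", "C41H45O22", "C52H55O26"),
    exact_mass = c(743.20292, 829.20331, 889.23970, 949.26083,
                   975.24009, 1051.29252, 1095.29761, 1137.29292,
                   1181.29800, 1257.35043, 1343.35083, 581.15010,
                   727.18688, 787.20801, 933.24478, 919.25026,
                   991.23501, 1005.25066, 1035.26122, 1065.28704,
                   1081.28196, 1111.29252, 1121.27687, 1125.30817,
                   1151.28744, 1167.28235, 1195.31365, 1197.29292,
                   1211.30857, 1313.34026, 1329.33518, 1359.34574,
                   1373.37156, 1549.40873, 889.23970, 1095.29761),
    stringsAsFactors = FALSE
  )
  df$consistent <- df$formula != "C62H69O35"
  df
}

# Build the default synthetic fixture, write it to a temp dir, and run the
# full pipeline; returns list(fixture, bundle, dir).
run_fixture_pipeline <- function(seed, n_decoys = 50L, quiet = TRUE) {
  fx <- generate_fixture(fixture_spec(seed = seed, n_decoys = n_decoys))
  dir <- file.path(tempfile("fx"), "in")
  paths <- write_fixture(fx, dir)
  out <- file.path(dirname(dir), "out")
  bundle <- run_pipeline(run_config(inputs = paths, out_dir = out),
                         quiet = quiet)
  list(fixture = fx, bundle = bundle, out_dir = out)
}

# m/z sequence (nominal, rounded) of a pathway row, via the feature set.
pathway_nominal_mz <- function(paths, i, features) {
  ids <- pathway_nodes(paths, i)$nodes
  as.integer(round(unname(vapply(features[ids], `[[`, 0, "mz"))))
}
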