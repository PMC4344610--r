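#' Assemble and validate a run configuration
#'
#' Collects the inputs and options of a full analysis run. All referenced
#' files must exist at validation time; computation happens only in
#' [cmd_analyze()] / [cmd_scan()].
#'
#' @param out_dir Output directory (created if absent).
#' @param torsions Optional path to a torsion-table CSV
#'   (`frame,phi_deg,psi_deg`).
#' @param coordinates Optional path to a coordinate ensemble.
#' @param coord_format `"xyz"` or `"pdb"`.
#' @param linkage A [linkage_spec()] or a YAML path; default the packaged
#'   Fuc-GlA fragment spec.
#' @param karplus_set Name of the Karplus parameterization to use.
#' @param karplus_sets Named list of [karplus_params()] (or YAML path).
#' @param states A [conformer_states()] set (or YAML path).
#' @param couplings Optional path to a multi-source coupling CSV to compare
#'   against its experimental rows.
#' @param noe Optional path to a multi-source NOE CSV to screen for
#'   predicted-but-absent cross-peaks.
#' @param tolerance_hz Coupling agreement tolerance in Hz (> 0).
#' @param noe_threshold Smallest predicted NOE treated as observable.
#' @param scan_energy Name of a registered potential for [cmd_scan()].
#' @param scan_step Grid step in degrees for [cmd_scan()].
#' @param scan_window Energy window (kcal/mol) for minima reporting.
#' @param seed Integer seed for any stochastic step.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       torsions = NULL, coordinates = NULL,
                       coord_format = c("xyz", "pdb"),
                       linkage = default_linkage_spec(),
                       karplus_set = "tvaroska1989",
                       karplus_sets = default_karplus_sets(),
                       states = default_conformer_states(),
                       couplings = NULL, noe = NULL,
                       tolerance_hz = 0.5, noe_threshold = 0.05,
                       scan_energy = "two_well", scan_step = 10,
                       scan_window = 5, seed = 1L) {
  coord_format <- match.arg(coord_format)
  if (!is.numeric(tolerance_hz) || tolerance_hz <= 0)
    stop_gt("gt_config_error", "tolerance_hz must be positive")
  for (p in c(torsions, coordinates, couplings, noe))
    if (!is.null(p) && !file.exists(p))
      stop_gt("gt_config_error", "input file not found: %s", p)
  if (is.character(linkage)) linkage <- read_linkage_spec(linkage)
  if (is.character(karplus_sets)) karplus_sets <- read_karplus_sets(karplus_sets)
  if (is.character(states)) states <- read_conformer_states(states)
  if (!karplus_set %in% names(karplus_sets))
    stop_gt("gt_lookup_error", "unknown Karplus set '%s'; available: %s",
            karplus_set, paste(names(karplus_sets), collapse = ", "))
  structure(list(out_dir = out_dir, torsions = torsions,
                 coordinates = coordinates, coord_format = coord_format,
                 linkage = linkage, karplus_set = karplus_set,
                 karplus_sets = karplus_sets, states = states,
                 couplings = couplings, noe = noe,
                 tolerance_hz = tolerance_hz, noe_threshold = noe_threshold,
                 scan_energy = scan_energy, scan_step = scan_step,
                 scan_window = scan_window, seed = as.integer(seed)),
            class = "run_config")
}

config_stamp <- function(config) {
  hash <- config_hash(utils::capture.output(utils::str(config)))
  c(sprintf("glycotorsion %s",
            as.character(utils::packageVersion("glycotorsion"))),
    sprintf("config %s seed %d", hash, config$seed))
}

#' Registered energy functions for scanning
#'
#' @return Named list of energy functions usable as `scan_energy` in
#'   [run_config()]: `single_well` and `two_well` (see [toy_single_well()]).
#' @export
registered_potentials <- function() {
  list(single_well = toy_single_well(), two_well = toy_two_well())
}

load_config_ensemble <- function(config) {
  coords <- NULL
  if (!is.null(config$coordinates)) {
    coords <- switch(config$coord_format,
                     xyz = read_xyz_ensemble(config$coordinates),
                     pdb = read_pdb_ensemble(config$coordinates))
    tors <- extract_torsion_ensemble(coords, config$linkage)
  } else if (!is.null(config$torsions)) {
    tors <- read_torsion_csv(config$torsions, linkage = config$linkage$name)
  } else {
    return(NULL)
  }
  if (nrow(tors) == 0L)
    stop_gt("gt_empty_input", "ensemble input contains no frames")
  list(coords = coords, torsions = tors)
}

#' Run the full analysis and write a report bundle
#'
#' Deterministic given the configuration: reads the configured ensemble
#' and/or tables, computes ensemble-averaged couplings, conformer
#' populations, predicted relative NOEs (coordinates required) and
#' experimental-vs-calculated comparisons, and writes each as CSV into
#' `out_dir`. Every file carries the package version and a configuration
#' hash in comment headers. A machine-readable `summary.csv` holds the mean
#' absolute deviation and within-error count per calculated source.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the written file paths and the main
#'   in-memory results.
#' @export
cmd_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- config_stamp(config)
  params <- config$karplus_sets[[config$karplus_set]]
  outputs <- list()
  results <- list()

  ens <- load_config_ensemble(config)
  if (!is.null(ens)) {
    ts <- torsion_timeseries(ens$torsions)
    p_ts <- file.path(config$out_dir, "torsion_timeseries.csv")
    write_csv_commented(round_df(ts, 4), p_ts, stamp)
    outputs$timeseries <- p_ts

    lab <- classify_conformers(ens$torsions$phi_deg, ens$torsions$psi_deg,
                               config$states)
    p_cls <- file.path(config$out_dir, "classification.csv")
    write_csv_commented(round_df(cbind(ts, state = lab), 4), p_cls, stamp)
    outputs$classification <- p_cls

    pops <- conformer_populations(lab, config$states)
    p_pop <- file.path(config$out_dir, "populations.csv")
    write_csv_commented(data.frame(state = names(pops$counts),
                                   count = pops$counts,
                                   fraction = round(pops$fractions, 4)),
                        p_pop, stamp)
    outputs$populations <- p_pop
    results$populations <- pops

    jcalc <- data.frame(compound = "ensemble", linkage = config$linkage$name,
                        torsion_kind = c("phi", "psi"), source = "synthetic",
                        value_hz = round(c(ensemble_j(ens$torsions$phi_deg, params),
                                           ensemble_j(ens$torsions$psi_deg, params)), 4))
    p_j <- file.path(config$out_dir, "couplings_calculated.csv")
    write_csv_commented(jcalc, p_j, stamp)
    outputs$couplings_calculated <- p_j
    results$couplings <- jcalc

    if (!is.null(ens$coords)) {
      spec <- config$linkage
      donor <- spec$phi_atoms[1L]
      acceptors <- setdiff(grep("^H", ens$coords$atoms, value = TRUE), donor)
      ref <- proton_pair(donor, spec$psi_atoms[4L])
      pairs <- lapply(acceptors, function(a) proton_pair(donor, a))
      noe <- relative_noe(ens$coords, pairs, ref)
      noe$intensity <- round(noe$intensity, 4)
      p_noe <- file.path(config$out_dir, "noe_predicted.csv")
      write_csv_commented(noe, p_noe, stamp)
      outputs$noe_predicted <- p_noe
      results$noe <- noe
    }
  }

  if (!is.null(config$couplings)) {
    tab <- read_couplings(config$couplings)
    exp_rows <- tab[tab$source == "experimental", ]
    if (!nrow(exp_rows))
      stop_gt("gt_validation_error",
              "coupling table %s has no experimental rows", config$couplings)
    summary_rows <- list()
    for (src in setdiff(unique(tab$source), "experimental")) {
      cmp <- compare_couplings(exp_rows, tab[tab$source == src, ],
                               tolerance_hz = config$tolerance_hz)
      p_cmp <- file.path(config$out_dir, sprintf("comparison_%s.csv", src))
      write_csv_commented(round_df(as.data.frame(cmp), 4), p_cmp, stamp)
      outputs[[paste0("comparison_", src)]] <- p_cmp
      summary_rows[[src]] <- data.frame(source = src, n = nrow(cmp),
                                        mad_hz = mean_absolute_deviation(cmp),
                                        mad_hz_2dp = round(mean_absolute_deviation(cmp), 2),
                                        n_within_error = sum(cmp$within_error))
    }
    summary <- do.call(rbind, summary_rows)
    summary$mad_hz <- round(summary$mad_hz, 4)
    p_sum <- file.path(config$out_dir, "summary.csv")
    write_csv_commented(summary, p_sum, stamp)
    outputs$summary <- p_sum
    results$summary <- summary
  }

  if (!is.null(config$noe)) {
    tab <- read_noe_table(config$noe)
    obs <- tab[tab$source == "experimental", ]
    flag_rows <- list()
    for (src in setdiff(unique(tab$source), "experimental")) {
      fl <- flag_incompatible_noes(tab[tab$source == src, ], obs,
                                   threshold = config$noe_threshold)
      if (nrow(fl)) flag_rows[[src]] <- cbind(source = src, fl)
    }
    flags <- if (length(flag_rows)) do.call(rbind, flag_rows)
      else data.frame(source = character(), compound = character(),
                      pair = character(), predicted = numeric(),
                      observed = numeric(), problem = character())
    p_fl <- file.path(config$out_dir, "noe_flags.csv")
    write_csv_commented(flags, p_fl, stamp)
    outputs$noe_flags <- p_fl
    results$noe_flags <- flags
  }

  if (!length(outputs))
    stop_gt("gt_config_error",
            "configuration provides nothing to analyze (no ensemble, couplings or NOE input)")
  invisible(c(outputs, list(results = results)))
}

#' Run a dihedral-driving scan and write map and minima CSVs
#'
#' @param config A [run_config()]; uses `scan_energy`, `scan_step`,
#'   `scan_window`.
#' @return Invisibly, the written paths and the map / minima objects.
#' @export
cmd_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  reg <- registered_potentials()
  if (!config$scan_energy %in% names(reg))
    stop_gt("gt_lookup_error", "unknown energy function '%s'; registered: %s",
            config$scan_energy, paste(names(reg), collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- config_stamp(config)
  map <- scan_map(reg[[config$scan_energy]], step = config$scan_step)
  minima <- find_minima(map, energy_window = config$scan_window)
  p_mat <- file.path(config$out_dir, "map_matrix.csv")
  p_long <- file.path(config$out_dir, "map_long.csv")
  p_min <- file.path(config$out_dir, "minima.csv")
  m2 <- map; m2$energies <- round(m2$energies, 4)
  write_map_matrix_csv(m2, p_mat, stamp)
  write_map_long_csv(m2, p_long, stamp)
  write_csv_commented(round_df(minima, 4), p_min, stamp)
  invisible(list(map_matrix = p_mat, map_long = p_long, minima_csv = p_min,
                 map = map, minima = minima))
}

# round numeric columns for stable file output
round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}
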