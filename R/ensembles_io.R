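#' Bookkeeping for an MD sampling plan
#'
#' Records run length, snapshot interval, temperature and an optional
#' discarded equilibration prefix, all in ps / K. The reference protocol of
#' the packaged study data is a 20,000 ps constant-temperature (298 K) run
#' with snapshots every 2 ps, i.e. 10,000 snapshots per trajectory.
#'
#' @param run_length_ps Production run length in ps.
#' @param snapshot_interval_ps Snapshot spacing in ps.
#' @param temperature_k Temperature in K; default 298.
#' @param equilibration_ps Discarded prefix in ps; default 0 (supplied
#'   ensembles are assumed already equilibrated).
#' @return An object of class `simulation_plan`.
#' @examples
#' expected_snapshots(simulation_plan(20000, 2))
#' @export
simulation_plan <- function(run_length_ps, snapshot_interval_ps,
                            temperature_k = 298, equilibration_ps = 0) {
  if (run_length_ps <= 0)
    stop_gt("gt_validation_error", "run_length_ps must be positive")
  if (snapshot_interval_ps <= 0 || snapshot_interval_ps > run_length_ps)
    stop_gt("gt_validation_error",
            "snapshot_interval_ps must lie in (0, run_length_ps]")
  if (temperature_k <= 0)
    stop_gt("gt_validation_error", "temperature_k must be positive")
  if (equilibration_ps < 0 || equilibration_ps >= run_length_ps)
    stop_gt("gt_validation_error",
            "equilibration_ps must lie in [0, run_length_ps)")
  structure(list(run_length_ps = run_length_ps,
                 snapshot_interval_ps = snapshot_interval_ps,
                 temperature_k = temperature_k,
                 equilibration_ps = equilibration_ps),
            class = "simulation_plan")
}

#' @rdname simulation_plan
#' @param plan A `simulation_plan`.
#' @return `expected_snapshots()` returns the snapshot count
#'   `floor((run_length - equilibration) / interval)`.
#' @export
expected_snapshots <- function(plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  as.integer(floor((plan$run_length_ps - plan$equilibration_ps) /
                     plan$snapshot_interval_ps))
}

#' Construct a torsion ensemble
#'
#' Per-snapshot (phi, psi) series for one glycosidic linkage. Angles are
#' wrapped into (-180, 180]; frame indices are 0-based and strictly
#' increasing.
#'
#' @param phi_deg,psi_deg Numeric vectors of torsions in degrees.
#' @param frame Optional integer frame indices; default `0:(n-1)`.
#' @param linkage Linkage name.
#' @param provenance Free-text source description.
#' @return A data frame of class `torsion_ensemble` with columns `frame`,
#'   `phi_deg`, `psi_deg` and attributes `linkage`, `provenance`.
#' @export
torsion_ensemble <- function(phi_deg, psi_deg, frame = NULL,
                             linkage = "linkage", provenance = "") {
  check_finite(phi_deg, "phi_deg"); check_finite(psi_deg, "psi_deg")
  n <- length(phi_deg)
  if (length(psi_deg) != n)
    stop_gt("gt_validation_error", "phi_deg and psi_deg must have equal length")
  frame <- frame %||% (seq_len(n) - 1L)
  if (length(frame) != n || (n > 1L && any(diff(frame) <= 0)))
    stop_gt("gt_validation_error", "frame indices must be strictly increasing")
  out <- data.frame(frame = as.integer(frame),
                    phi_deg = wrap180(phi_deg),
                    psi_deg = wrap180(psi_deg))
  attr(out, "linkage") <- linkage
  attr(out, "provenance") <- provenance
  class(out) <- unique(c("torsion_ensemble", class(out)))
  out
}

#' @export
print.torsion_ensemble <- function(x, ...) {
  cat(sprintf("Torsion ensemble '%s': %d frames (%s)\n",
              attr(x, "linkage"), nrow(x), attr(x, "provenance")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more frames\n", nrow(x) - 6L))
  invisible(x)
}

#' Construct a coordinate ensemble
#'
#' @param frames List of coordinate matrices (rows named by atom id,
#'   columns x/y/z in Angstrom), all with the same atoms in the same order.
#' @param provenance Free-text source description.
#' @return An object of class `coordinate_ensemble`: list with `atoms`,
#'   `frames`, `provenance`.
#' @export
coordinate_ensemble <- function(frames, provenance = "") {
  if (!is.list(frames) || !length(frames))
    stop_gt("gt_empty_input", "frames must be a nonempty list of matrices")
  atoms <- rownames(frames[[1L]])
  if (is.null(atoms) || anyDuplicated(atoms))
    stop_gt("gt_validation_error",
            "each frame needs unique atom ids as row names")
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (!is.matrix(fr) || ncol(fr) != 3L || !identical(rownames(fr), atoms))
      stop_gt("gt_structural_error",
              "frame %d does not match the atom list of frame 0", i - 1L)
    check_finite(fr, sprintf("coordinates of frame %d", i - 1L))
  }
  structure(list(atoms = atoms, frames = frames, provenance = provenance),
            class = "coordinate_ensemble")
}

#' @export
print.coordinate_ensemble <- function(x, ...) {
  cat(sprintf("Coordinate ensemble: %d frames x %d atoms (%s)\n",
              length(x$frames), length(x$atoms), x$provenance))
  invisible(x)
}

# ---- multi-frame XYZ --------------------------------------------------------

#' Read / write multi-frame XYZ ensembles
#'
#' Standard XYZ: repeated blocks of an atom count line, a comment line, and
#' `n` lines of `name x y z`. Atom ids are the name tokens, suffixed by
#' their position when names repeat within a frame. Coordinates in Angstrom.
#'
#' @param path File path.
#' @return `read_xyz_ensemble()` returns a [coordinate_ensemble()].
#' @export
read_xyz_ensemble <- function(path) {
  if (!file.exists(path))
    stop_gt("gt_config_error", "XYZ file not found: %s", path)
  lines <- readLines(path)
  nz <- which(nzchar(trimws(lines)))  # drop trailing blank lines
  lines <- if (length(nz)) lines[seq_len(max(nz))] else character()
  frames <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L)
      stop_gt("gt_parse_error", "line %d: expected an atom count, got '%s'",
              i, lines[i])
    if (i + 1L + nat > length(lines))
      stop_gt("gt_parse_error",
              "truncated frame %d: %d atoms declared at line %d but file ends",
              fidx, nat, i)
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(toks, length, integer(1L)) < 4L)
    if (length(bad))
      stop_gt("gt_parse_error", "line %d: malformed XYZ atom record '%s'",
              i + 1L + bad[1L], block[bad[1L]])
    nm <- vapply(toks, `[[`, character(1L), 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3L)))
    if (any(!is.finite(xyz)))
      stop_gt("gt_parse_error", "non-numeric coordinates in frame %d", fidx)
    if (anyDuplicated(nm)) nm <- make.unique(nm, sep = "")
    rownames(xyz) <- nm
    colnames(xyz) <- c("x", "y", "z")
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nat
    fidx <- fidx + 1L
  }
  if (!length(frames))
    stop_gt("gt_parse_error", "no frames found in %s", path)
  coordinate_ensemble(frames, provenance = paste0("xyz:", basename(path)))
}

#' @rdname read_xyz_ensemble
#' @param ensemble A [coordinate_ensemble()].
#' @param comment Comment line written per frame.
#' @export
write_xyz_ensemble <- function(ensemble, path, comment = "frame") {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_along(ensemble$frames)) {
    fr <- ensemble$frames[[k]]
    writeLines(c(as.character(nrow(fr)), sprintf("%s %d", comment, k - 1L)), con)
    writeLines(sprintf("%-6s %14.8f %14.8f %14.8f",
                       rownames(fr), fr[, 1L], fr[, 2L], fr[, 3L]), con)
  }
  invisible(path)
}

# ---- multi-MODEL PDB --------------------------------------------------------

#' Read / write multi-MODEL PDB ensembles
#'
#' Frames are MODEL/ENDMDL blocks (a file without MODEL records is a single
#' frame). Atom ids are the trimmed PDB atom names, suffixed by position if
#' duplicated within a model. Atom count and order must agree across models.
#'
#' @param path File path.
#' @return `read_pdb_ensemble()` returns a [coordinate_ensemble()].
#' @export
read_pdb_ensemble <- function(path) {
  if (!file.exists(path))
    stop_gt("gt_config_error", "PDB file not found: %s", path)
  lines <- readLines(path)
  frames <- list()
  cur_nm <- character(); cur_xyz <- NULL
  in_model <- FALSE; saw_model <- FALSE
  flush_frame <- function() {
    if (is.null(cur_xyz)) return()
    nm <- if (anyDuplicated(cur_nm)) make.unique(cur_nm, sep = "") else cur_nm
    rownames(cur_xyz) <<- nm
    colnames(cur_xyz) <<- c("x", "y", "z")
    frames[[length(frames) + 1L]] <<- cur_xyz
    cur_nm <<- character(); cur_xyz <<- NULL
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    rec <- substr(line, 1L, 6L)
    if (startsWith(rec, "MODEL")) {
      if (in_model)
        stop_gt("gt_parse_error", "line %d: MODEL without preceding ENDMDL", ln)
      saw_model <- TRUE; in_model <- TRUE
    } else if (startsWith(rec, "ENDMDL")) {
      if (!in_model)
        stop_gt("gt_parse_error", "line %d: ENDMDL without MODEL", ln)
      if (is.null(cur_xyz))
        stop_gt("gt_parse_error", "line %d: empty MODEL block", ln)
      flush_frame()
      in_model <- FALSE
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      if (saw_model && !in_model)
        stop_gt("gt_parse_error", "line %d: ATOM record outside MODEL block", ln)
      xyz <- suppressWarnings(as.numeric(c(substr(line, 31L, 38L),
                                           substr(line, 39L, 46L),
                                           substr(line, 47L, 54L))))
      if (any(!is.finite(xyz)))
        stop_gt("gt_parse_error", "line %d: malformed ATOM coordinates", ln)
      cur_nm <- c(cur_nm, trimws(substr(line, 13L, 16L)))
      cur_xyz <- rbind(cur_xyz, xyz)
    }
  }
  if (in_model)
    stop_gt("gt_parse_error", "truncated final frame %d: missing ENDMDL",
            length(frames))
  if (!saw_model) flush_frame()
  if (!length(frames))
    stop_gt("gt_parse_error", "no coordinates found in %s", path)
  nat <- vapply(frames, nrow, integer(1L))
  if (length(unique(nat)) != 1L)
    stop_gt("gt_structural_error",
            "inconsistent atom count across models: %s",
            paste(unique(nat), collapse = ", "))
  coordinate_ensemble(frames, provenance = paste0("pdb:", basename(path)))
}

#' @rdname read_pdb_ensemble
#' @param ensemble A [coordinate_ensemble()].
#' @param resname Residue name stamped on every atom record.
#' @export
write_pdb_ensemble <- function(ensemble, path, resname = "LIG") {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_along(ensemble$frames)) {
    fr <- ensemble$frames[[k]]
    writeLines(sprintf("MODEL %8d", k), con)
    writeLines(sprintf("ATOM  %5d %-4s %3s A   1    %8.3f%8.3f%8.3f  1.00  0.00",
                       seq_len(nrow(fr)), substr(rownames(fr), 1L, 4L),
                       resname, fr[, 1L], fr[, 2L], fr[, 3L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- torsion tables ---------------------------------------------------------

#' Read / write torsion-table CSV ensembles
#'
#' First-class torsion input: CSV with header `frame,phi_deg,psi_deg` (and
#' optional extra columns, ignored), one row per snapshot. Lets the full
#' coupling/conformer pipeline run without any Cartesian coordinates.
#'
#' @param path CSV path.
#' @param linkage Linkage name recorded on the ensemble.
#' @return `read_torsion_csv()` returns a [torsion_ensemble()].
#' @export
read_torsion_csv <- function(path, linkage = "linkage") {
  if (!file.exists(path))
    stop_gt("gt_config_error", "torsion table not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "phi_deg", "psi_deg")
  if (!all(need %in% names(df)))
    stop_gt("gt_parse_error", "torsion table %s missing columns: %s",
            path, paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0L)
    stop_gt("gt_empty_input", "torsion table %s contains no frames", path)
  torsion_ensemble(df$phi_deg, df$psi_deg, frame = df$frame,
                   linkage = linkage,
                   provenance = paste0("csv:", basename(path)))
}

#' @rdname read_torsion_csv
#' @param ensemble A [torsion_ensemble()].
#' @param header_lines Optional comment lines written at the top.
#' @export
write_torsion_csv <- function(ensemble, path, header_lines = character()) {
  if (!inherits(ensemble, "torsion_ensemble"))
    stop_gt("gt_validation_error", "expected a torsion_ensemble")
  write_csv_commented(torsion_timeseries(ensemble), path, header_lines)
}

#' Extract per-frame linkage torsions from a coordinate ensemble
#'
#' @param coords A [coordinate_ensemble()].
#' @param spec A [linkage_spec()].
#' @return A [torsion_ensemble()] with one row per frame, in frame order.
#' @export
extract_torsion_ensemble <- function(coords, spec = default_linkage_spec()) {
  stopifnot(inherits(coords, "coordinate_ensemble"),
            inherits(spec, "linkage_spec"))
  tors <- vapply(seq_along(coords$frames), function(i) {
    tryCatch(linkage_torsions(coords$frames[[i]], spec),
             gt_lookup_error = function(e)
               stop_gt("gt_lookup_error", "frame %d: %s", i - 1L,
                       conditionMessage(e)))
  }, numeric(2L))
  torsion_ensemble(tors[1L, ], tors[2L, ], linkage = spec$name,
                   provenance = coords$provenance)
}
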