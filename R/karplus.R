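#' Karplus coefficient set for trans-glycosidic 3J(C-O-C-H)
#'
#' A named parameterization of the Karplus relation
#' J(theta) = A cos^2(theta) + B cos(theta) + C (Hz). Coefficients are data,
#' not constants: alternate parameterizations can be supplied anywhere a
#' `karplus_params` is accepted, or loaded from YAML with
#' [read_karplus_sets()].
#'
#' @param name Label for the parameterization.
#' @param A,B,C Coefficients in Hz.
#' @return An object of class `karplus_params`.
#' @export
karplus_params <- function(name, A, B, C) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_gt("gt_validation_error", "parameterization name must be nonempty")
  for (v in list(A, B, C)) check_finite(v, "Karplus coefficients")
  structure(list(name = name, A = A, B = B, C = C), class = "karplus_params")
}

#' @export
print.karplus_params <- function(x, ...) {
  cat(sprintf("Karplus parameterization '%s': J = %.3g cos^2(t) %+.3g cos(t) %+.3g Hz\n",
              x$name, x$A, x$B, x$C))
  invisible(x)
}

#' Shipped Karplus parameterizations
#'
#' The default set, `tvaroska1989`, is the classical parameterization for
#' three-bond C-O-C-H couplings across glycosidic linkages
#' (Tvaroska, Hricovini & Petrakova, Carbohydr. Res. 189 (1989) 359):
#' J(theta) = 5.7 cos^2(theta) - 0.6 cos(theta) + 0.5 Hz.
#'
#' @return Named list of [karplus_params()] objects.
#' @export
default_karplus_sets <- function() {
  list(tvaroska1989 = karplus_params("tvaroska1989", 5.7, -0.6, 0.5))
}

#' Read Karplus parameterizations from a YAML config
#'
#' Expects a mapping `name: {A: ..., B: ..., C: ...}`, optionally nested
#' under a `karplus:` key.
#'
#' @param path Path to a YAML file.
#' @return Named list of [karplus_params()] objects.
#' @export
read_karplus_sets <- function(path) {
  if (!file.exists(path))
    stop_gt("gt_config_error", "Karplus config not found: %s", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$karplus)) y <- y$karplus
  if (!length(y)) stop_gt("gt_config_error", "no Karplus sets in %s", path)
  out <- lapply(names(y), function(nm) {
    s <- y[[nm]]
    for (k in c("A", "B", "C")) if (is.null(s[[k]]))
      stop_gt("gt_config_error", "Karplus set '%s' missing coefficient %s", nm, k)
    karplus_params(nm, s$A, s$B, s$C)
  })
  stats::setNames(out, names(y))
}

#' Evaluate the Karplus relation
#'
#' @param theta Torsion angle(s) in degrees.
#' @param params A [karplus_params()] object.
#' @return Coupling(s) in Hz. Even and 360-degree periodic in `theta`.
#' @examples
#' karplus_j(60, default_karplus_sets()$tvaroska1989)
#' @export
karplus_j <- function(theta, params = default_karplus_sets()[[1L]]) {
  check_finite(theta, "theta")
  stopifnot(inherits(params, "karplus_params"))
  ct <- cos(deg2rad(theta))
  params$A * ct^2 + params$B * ct + params$C
}

#' Ensemble-averaged coupling over a torsion series
#'
#' Averages the Karplus curve over snapshots: returns the mean of J(theta)
#' over frames, i.e. <J(theta)>, which differs from J(<theta>) whenever the
#' torsional distribution is broad or multimodal. Weights default to uniform.
#'
#' @param torsions Numeric vector of snapshot torsions in degrees.
#' @param params A [karplus_params()].
#' @param weights Optional nonnegative snapshot weights (need not sum to 1).
#' @return Mean coupling in Hz.
#' @export
ensemble_j <- function(torsions, params = default_karplus_sets()[[1L]],
                       weights = NULL) {
  if (length(torsions) == 0L)
    stop_gt("gt_empty_input", "ensemble_j: empty torsion ensemble")
  check_finite(torsions, "torsions")
  w <- resolve_weights(weights, length(torsions))
  sum(w * karplus_j(torsions, params))
}

# ---- coupling records -------------------------------------------------------

coupling_sources <- c("experimental", "in_vacuo", "SASA", "water", "synthetic")

#' Validate a table of coupling records
#'
#' A coupling-record table has columns `compound`, `linkage`, `torsion_kind`
#' (`"phi"` or `"psi"`), `source` (one of experimental, in_vacuo, SASA,
#' water, synthetic) and `value_hz` (nonnegative).
#'
#' @param df A data frame in the layout above.
#' @return The validated data frame (invisibly classed `coupling_records`).
#' @export
coupling_records <- function(df) {
  need <- c("compound", "linkage", "torsion_kind", "source", "value_hz")
  if (!all(need %in% names(df)))
    stop_gt("gt_validation_error", "coupling table missing columns: %s",
            paste(setdiff(need, names(df)), collapse = ", "))
  bad <- setdiff(unique(df$source), coupling_sources)
  if (length(bad))
    stop_gt("gt_validation_error", "unknown coupling source(s): %s (allowed: %s)",
            paste(bad, collapse = ", "), paste(coupling_sources, collapse = ", "))
  if (!all(df$torsion_kind %in% c("phi", "psi")))
    stop_gt("gt_validation_error", "torsion_kind must be 'phi' or 'psi'")
  check_finite(df$value_hz, "value_hz")
  if (any(df$value_hz < 0))
    stop_gt("gt_validation_error", "coupling values must be nonnegative")
  class(df) <- unique(c("coupling_records", class(df)))
  df
}

#' Read / write coupling records as CSV
#'
#' @param path CSV path with header
#'   `compound,linkage,torsion_kind,source,value_hz`. Lines starting with
#'   `#` are ignored.
#' @return `read_couplings()` returns a validated data frame.
#' @export
read_couplings <- function(path) {
  if (!file.exists(path))
    stop_gt("gt_config_error", "couplings file not found: %s", path)
  coupling_records(utils::read.csv(path, comment.char = "#",
                                   stringsAsFactors = FALSE))
}

#' @rdname read_couplings
#' @param df A coupling-record data frame.
#' @export
write_couplings <- function(df, path) {
  utils::write.csv(coupling_records(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Experimental and calculated couplings for the FCS oligosaccharide fragments
#'
#' The packaged table of trans-glycosidic 3J(C-H) values (Hz) for five
#' synthetic fucosylated chondroitin sulfate fragments (compounds 1-5):
#' experimental J-HMBC measurements alongside values calculated from MD
#' ensembles in vacuo, with SASA continuum solvation and in explicit water,
#' for the Fuc-GlA and Fuc-Fuc linkages.
#'
#' @return A validated `coupling_records` data frame (56 rows).
#' @export
fcs_coupling_table <- function() {
  read_couplings(system.file("extdata", "fcs_couplings.csv",
                             package = "glycotorsion", mustWork = TRUE))
}

#' Pair experimental with calculated couplings and flag agreement
#'
#' Matches rows on (compound, linkage, torsion_kind); every experimental row
#' must have exactly one calculated partner. The default tolerance, 0.5 Hz,
#' is the experimental uncertainty of J-HMBC-measured 3J(C-H).
#'
#' @param experimental,calculated Coupling-record data frames (each a single
#'   source).
#' @param tolerance_hz Agreement tolerance in Hz.
#' @return A `comparison_table` data frame with columns `compound`,
#'   `linkage`, `torsion_kind`, `experimental_hz`, `calculated_hz`,
#'   `deviation_hz`, `within_error`, ordered by (compound, linkage,
#'   torsion_kind); the tolerance is kept in attribute `tolerance_hz`.
#' @export
compare_couplings <- function(experimental, calculated, tolerance_hz = 0.5) {
  experimental <- coupling_records(as.data.frame(experimental))
  calculated <- coupling_records(as.data.frame(calculated))
  if (!is.numeric(tolerance_hz) || tolerance_hz <= 0)
    stop_gt("gt_validation_error", "tolerance_hz must be positive")
  key <- function(d) paste(d$compound, d$linkage, d$torsion_kind, sep = "|")
  ke <- key(experimental); kc <- key(calculated)
  if (anyDuplicated(ke) || anyDuplicated(kc))
    stop_gt("gt_pairing_error", "duplicate (compound, linkage, torsion_kind) rows: %s",
            paste(unique(c(ke[duplicated(ke)], kc[duplicated(kc)])), collapse = "; "))
  orphans <- c(setdiff(ke, kc), setdiff(kc, ke))
  if (length(orphans))
    stop_gt("gt_pairing_error", "unpaired coupling rows: %s",
            paste(orphans, collapse = "; "))
  idx <- match(ke, kc)
  out <- data.frame(compound = experimental$compound,
                    linkage = experimental$linkage,
                    torsion_kind = experimental$torsion_kind,
                    experimental_hz = experimental$value_hz,
                    calculated_hz = calculated$value_hz[idx],
                    stringsAsFactors = FALSE)
  out$deviation_hz <- abs(out$experimental_hz - out$calculated_hz)
  out$within_error <- out$deviation_hz <= tolerance_hz
  out <- out[order(out$compound, out$linkage, out$torsion_kind), ]
  rownames(out) <- NULL
  attr(out, "tolerance_hz") <- tolerance_hz
  class(out) <- unique(c("comparison_table", class(out)))
  out
}

#' Mean absolute deviation of a coupling comparison
#'
#' Arithmetic mean of the per-row absolute deviations. Returned unrounded;
#' headline reporting conventionally rounds to 2 decimals (couplings
#' themselves to 1).
#'
#' @param table A `comparison_table` from [compare_couplings()].
#' @return Mean absolute deviation in Hz.
#' @export
mean_absolute_deviation <- function(table) {
  if (!is.data.frame(table) || !"deviation_hz" %in% names(table))
    stop_gt("gt_validation_error",
            "expected a comparison table with a deviation_hz column")
  if (nrow(table) == 0L)
    stop_gt("gt_empty_input", "comparison table is empty")
  mean(table$deviation_hz)
}

#' @export
print.comparison_table <- function(x, digits = 1, ...) {
  tol <- attr(x, "tolerance_hz")
  cat(sprintf("Coupling comparison: %d pairs, tolerance %.2g Hz\n", nrow(x), tol))
  y <- as.data.frame(x)
  y$experimental_hz <- round(y$experimental_hz, digits)
  y$calculated_hz <- round(y$calculated_hz, digits)
  y$deviation_hz <- round(y$deviation_hz, digits)
  print(y, ...)
  cat(sprintf("Mean absolute deviation: %.2f Hz (%d/%d within error)\n",
              mean_absolute_deviation(x), sum(x$within_error), nrow(x)))
  invisible(x)
}
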