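#' Define a proton pair for NOE prediction
#'
#' @param donor Atom id of the donor proton (conventionally the anomeric H1
#'   of the glycosylating residue).
#' @param acceptor Atom id of the acceptor proton.
#' @param label Optional display label, e.g. `"H1(Fuc)-H3(GlA)"`; defaults
#'   to `"donor-acceptor"`.
#' @return An object of class `proton_pair`.
#' @export
proton_pair <- function(donor, acceptor, label = NULL) {
  if (identical(donor, acceptor))
    stop_gt("gt_validation_error", "donor and acceptor must differ ('%s')", donor)
  structure(list(donor = donor, acceptor = acceptor,
                 label = label %||% paste0(donor, "-", acceptor)),
            class = "proton_pair")
}

# coerce the accepted ensemble representations to a list of coordinate matrices
as_frame_list <- function(frames) {
  if (inherits(frames, "coordinate_ensemble")) return(frames$frames)
  if (is.matrix(frames)) return(list(frames))
  if (is.list(frames) && all(vapply(frames, is.matrix, logical(1L))))
    return(frames)
  if (inherits(frames, "torsion_ensemble"))
    stop_gt("gt_capability_error",
            "NOE prediction needs Cartesian coordinates; a torsion-only ensemble cannot be used")
  stop_gt("gt_validation_error",
          "frames must be a coordinate_ensemble, a coordinate matrix, or a list of them")
}

#' Ensemble-averaged inverse sixth power of an interproton distance
#'
#' Computes the weighted mean over frames of r^-6 for one proton pair, the
#' quantity whose reciprocal ratio gives relative NOE intensities in the
#' isolated two-spin approximation.
#'
#' @param frames A `coordinate_ensemble`, a single coordinate matrix, or a
#'   list of matrices (rows named by atom id, coordinates in Angstrom).
#' @param pair A [proton_pair()].
#' @param weights Optional nonnegative frame weights.
#' @return Mean r^-6 in Angstrom^-6.
#' @export
mean_inv_r6 <- function(frames, pair, weights = NULL) {
  stopifnot(inherits(pair, "proton_pair"))
  fl <- as_frame_list(frames)
  if (!length(fl)) stop_gt("gt_empty_input", "empty coordinate ensemble")
  w <- resolve_weights(weights, length(fl))
  inv6 <- vapply(seq_along(fl), function(i) {
    fr <- fl[[i]]
    for (id in c(pair$donor, pair$acceptor))
      if (!id %in% rownames(fr))
        stop_gt("gt_lookup_error", "atom '%s' missing in frame %d", id, i - 1L)
    r2 <- sum((fr[pair$donor, ] - fr[pair$acceptor, ])^2)
    if (r2 <= .Machine$double.eps)
      stop_gt("gt_degenerate_geometry",
              "zero distance between '%s' and '%s' in frame %d",
              pair$donor, pair$acceptor, i - 1L)
    r2^-3
  }, numeric(1L))
  sum(w * inv6)
}

#' Relative NOE intensities from a coordinate ensemble
#'
#' For each pair, the predicted relative NOE is the ratio of ensemble-averaged
#' r^-6 values, <r_pair^-6> / <r_ref^-6> (isolated two-spin approximation,
#' valid within the linear NOE build-up regime). The reference pair's own
#' intensity is exactly 1.
#'
#' @param frames A coordinate ensemble (see [mean_inv_r6()]).
#' @param pairs List of [proton_pair()] objects.
#' @param reference The reference [proton_pair()] (needs not be in `pairs`).
#' @param weights Optional frame weights.
#' @return Data frame with columns `pair`, `intensity`, `reference`.
#' @export
relative_noe <- function(frames, pairs, reference, weights = NULL) {
  if (inherits(pairs, "proton_pair")) pairs <- list(pairs)
  stopifnot(length(pairs) > 0L, inherits(reference, "proton_pair"))
  ref6 <- mean_inv_r6(frames, reference, weights)
  if (ref6 <= 0)
    stop_gt("gt_normalization_error",
            "reference pair '%s' has nonpositive <r^-6>; cannot normalize",
            reference$label)
  same_pair <- function(p) identical(c(p$donor, p$acceptor),
                                     c(reference$donor, reference$acceptor))
  intens <- vapply(pairs, function(p) {
    if (same_pair(p)) 1 else mean_inv_r6(frames, p, weights) / ref6
  }, numeric(1L))
  data.frame(pair = vapply(pairs, `[[`, character(1L), "label"),
             intensity = intens,
             reference = reference$label,
             stringsAsFactors = FALSE)
}

#' Validate a relative-NOE table
#'
#' Layout: `compound`, `pair`, `source` (experimental, SASA, water or
#' synthetic), `intensity` (>= 0), `reference` (label of the unit-intensity
#' pair). Within each (compound, source) group the reference pair's own row,
#' if present, must carry intensity 1.
#'
#' @param df A data frame in the layout above.
#' @return The validated data frame (classed `noe_table`).
#' @export
noe_table <- function(df) {
  need <- c("compound", "pair", "source", "intensity", "reference")
  if (!all(need %in% names(df)))
    stop_gt("gt_validation_error", "NOE table missing columns: %s",
            paste(setdiff(need, names(df)), collapse = ", "))
  ok_src <- c("experimental", "SASA", "water", "synthetic")
  bad <- setdiff(unique(df$source), ok_src)
  if (length(bad))
    stop_gt("gt_validation_error", "unknown NOE source(s): %s", paste(bad, collapse = ", "))
  check_finite(df$intensity, "intensity")
  if (any(df$intensity < 0))
    stop_gt("gt_validation_error", "NOE intensities must be nonnegative")
  self <- df$pair == df$reference
  if (any(self & df$intensity != 1))
    stop_gt("gt_validation_error",
            "reference pair rows must have intensity exactly 1")
  class(df) <- unique(c("noe_table", class(df)))
  df
}

#' Read / write relative-NOE tables as CSV
#'
#' @param path CSV with header `compound,pair,source,intensity,reference`.
#' @return `read_noe_table()` returns a validated data frame.
#' @export
read_noe_table <- function(path) {
  if (!file.exists(path))
    stop_gt("gt_config_error", "NOE table not found: %s", path)
  noe_table(utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
}

#' @rdname read_noe_table
#' @param df A NOE table data frame.
#' @export
write_noe_table <- function(df, path) {
  utils::write.csv(noe_table(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Experimental and calculated relative NOEs for the FCS fragments
#'
#' The packaged table of relative NOE intensities for the non-sulfated
#' compounds 1 and 4: 2D-NOESY experimental values against predictions from
#' SASA-continuum and explicit-water MD ensembles, referenced to the
#' H1(Fuc)-H3(GlA) cross-peak. A literal 0 encodes an absent cross-peak.
#'
#' @return A validated `noe_table` data frame.
#' @export
fcs_noe_table <- function() {
  read_noe_table(system.file("extdata", "fcs_noe.csv",
                             package = "glycotorsion", mustWork = TRUE))
}

#' Flag NOE predictions incompatible with observation
#'
#' Lists pairs where a model predicts an intensity strictly above
#' `threshold` while the observed value is 0 (a cross-peak that should
#' exist but does not), and vice versa. This is the model-selection logic
#' that rejects an ensemble whose inverted conformers predict cross-peaks
#' the spectra lack.
#'
#' @param predicted,observed `noe_table` data frames (single source each),
#'   matched on (compound, pair).
#' @param threshold Largest predicted intensity still treated as consistent
#'   with an absent cross-peak; default 0.05.
#' @return Data frame of discrepancies with columns `compound`, `pair`,
#'   `predicted`, `observed`, `problem`.
#' @export
flag_incompatible_noes <- function(predicted, observed, threshold = 0.05) {
  predicted <- noe_table(as.data.frame(predicted))
  observed <- noe_table(as.data.frame(observed))
  key <- function(d) paste(d$compound, d$pair, sep = "|")
  kp <- key(predicted); ko <- key(observed)
  orphans <- c(setdiff(kp, ko), setdiff(ko, kp))
  if (length(orphans))
    stop_gt("gt_pairing_error", "unmatched NOE pair labels: %s",
            paste(orphans, collapse = "; "))
  idx <- match(kp, ko)
  pred <- predicted$intensity
  obs <- observed$intensity[idx]
  bad_missing <- pred > threshold & obs == 0
  bad_extra <- obs > threshold & pred == 0
  flagged <- bad_missing | bad_extra
  data.frame(compound = predicted$compound[flagged],
             pair = predicted$pair[flagged],
             predicted = pred[flagged],
             observed = obs[flagged],
             problem = ifelse(bad_missing[flagged],
                              "predicted_but_absent", "observed_but_absent"),
             stringsAsFactors = FALSE)
}
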