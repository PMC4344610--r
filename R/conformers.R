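#' Circular distance between two angles
#'
#' Shortest angular separation on the circle, in `[0, 180]` degrees. Needed
#' because the inverted conformer region straddles the +/-180 boundary.
#'
#' @param a,b Angles in degrees (vectorized, recycled).
#' @return Distance(s) in degrees.
#' @examples
#' circular_distance(170, -170)  # 20
#' @export
circular_distance <- function(a, b) {
  check_finite(a, "a"); check_finite(b, "b")
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Declare conformer states on the phi/psi torus
#'
#' A conformer state is a labelled circular region: a (phi, psi) center plus
#' a per-coordinate acceptance radius. The defaults formalize the states
#' commonly populated by 1->3 glycosidic linkages of fucose branches:
#' phi near +30 (exo-anomeric effect) throughout, with psi near +40
#' (state I), near 0 (state II), or inverted near +/-180 (state III).
#'
#' @param centers Data frame with columns `label`, `phi`, `psi` (degrees).
#' @param radius Per-coordinate circular acceptance radius in degrees.
#' @return An object of class `conformer_states`.
#' @export
conformer_states <- function(centers, radius = 35) {
  need <- c("label", "phi", "psi")
  if (!is.data.frame(centers) || !all(need %in% names(centers)))
    stop_gt("gt_validation_error",
            "centers must be a data frame with columns label, phi, psi")
  if (!is.numeric(radius) || radius <= 0)
    stop_gt("gt_validation_error", "radius must be positive")
  if (anyDuplicated(centers$label))
    stop_gt("gt_validation_error", "state labels must be distinct")
  for (i in seq_len(nrow(centers))) for (j in seq_len(i - 1L)) {
    if (circular_distance(centers$phi[i], centers$phi[j]) < 1e-9 &&
        circular_distance(centers$psi[i], centers$psi[j]) < 1e-9)
      stop_gt("gt_validation_error", "states '%s' and '%s' share a center",
              centers$label[i], centers$label[j])
  }
  structure(list(centers = centers, radius = radius),
            class = "conformer_states")
}

#' @rdname conformer_states
#' @export
default_conformer_states <- function() {
  conformer_states(data.frame(label = c("I", "II", "III"),
                              phi = c(30, 30, 30),
                              psi = c(40, 0, 180),
                              stringsAsFactors = FALSE),
                   radius = 35)
}

#' Read conformer states from a YAML config
#'
#' Expects `radius` and a `states` list of `{label, phi, psi}` mappings,
#' optionally nested under `conformer_states:`.
#'
#' @param path Path to a YAML file.
#' @return A [conformer_states()] object.
#' @export
read_conformer_states <- function(path) {
  if (!file.exists(path))
    stop_gt("gt_config_error", "conformer-state config not found: %s", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$conformer_states)) y <- y$conformer_states
  if (is.null(y$states))
    stop_gt("gt_config_error", "conformer-state config missing 'states'")
  centers <- do.call(rbind, lapply(y$states, function(s)
    data.frame(label = s$label, phi = s$phi, psi = s$psi,
               stringsAsFactors = FALSE)))
  conformer_states(centers, y$radius %||% 35)
}

#' @export
print.conformer_states <- function(x, ...) {
  cat(sprintf("Conformer states (radius %g deg per coordinate):\n", x$radius))
  print(x$centers, row.names = FALSE)
  invisible(x)
}

#' Classify snapshots into conformer states
#'
#' Each (phi, psi) snapshot is assigned to the state whose center is nearest
#' in combined circular distance (Euclidean norm of the two per-coordinate
#' circular distances), provided both coordinates lie within the acceptance
#' radius; otherwise `"unassigned"`. Exact ties are broken by state
#' declaration order, so assignment is deterministic and single-valued even
#' where acceptance regions overlap.
#'
#' @param phi,psi Numeric vectors of torsions in degrees (same length).
#' @param states A [conformer_states()] set.
#' @return Character vector of state labels (or `"unassigned"`).
#' @examples
#' classify_conformers(c(30, 30, 30), c(40, 0, -175))
#' @export
classify_conformers <- function(phi, psi, states = default_conformer_states()) {
  stopifnot(inherits(states, "conformer_states"))
  check_finite(phi, "phi"); check_finite(psi, "psi")
  if (length(phi) != length(psi))
    stop_gt("gt_validation_error", "phi and psi must have equal length")
  cen <- states$centers
  dphi <- outer(phi, cen$phi, circular_distance)
  dpsi <- outer(psi, cen$psi, circular_distance)
  within <- dphi <= states$radius & dpsi <= states$radius
  comb <- sqrt(dphi^2 + dpsi^2)
  comb[!within] <- Inf
  # max.col with ties.method = "first" implements declaration-order tie-break
  best <- max.col(-comb, ties.method = "first")
  lab <- cen$label[best]
  lab[!is.finite(comb[cbind(seq_along(phi), best)])] <- "unassigned"
  lab
}

#' Conformer populations from a sequence of state labels
#'
#' @param labels Character vector of state labels (e.g. from
#'   [classify_conformers()]); `"unassigned"` is tallied separately.
#' @param states Optional [conformer_states()]; when given, every declared
#'   state appears in the report even with zero count.
#' @return An object of class `population_report`: a list with `counts`,
#'   `fractions` (both named, including `unassigned`) and `total`.
#' @export
conformer_populations <- function(labels, states = NULL) {
  if (length(labels) == 0L)
    stop_gt("gt_empty_input", "no frames to tally")
  levels <- if (!is.null(states)) {
    stopifnot(inherits(states, "conformer_states"))
    c(states$centers$label, "unassigned")
  } else unique(c(labels[labels != "unassigned"], "unassigned"))
  extra <- setdiff(labels, levels)
  if (length(extra))
    stop_gt("gt_validation_error", "labels outside declared states: %s",
            paste(unique(extra), collapse = ", "))
  counts <- table(factor(labels, levels = levels))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts,
                 fractions = counts / sum(counts),
                 total = sum(counts)),
            class = "population_report")
}

#' @export
print.population_report <- function(x, ...) {
  cat(sprintf("Conformer populations over %d frames:\n", x$total))
  for (nm in names(x$counts))
    cat(sprintf("  %-10s %6d  (%.3f)\n", nm, x$counts[[nm]], x$fractions[[nm]]))
  invisible(x)
}

#' Ordered torsion time series of an ensemble
#'
#' Returns the per-frame rows of a torsion ensemble in frame order, suitable
#' for angle-vs-time plots and phi/psi scatter plots.
#'
#' @param ensemble A `torsion_ensemble` (see [torsion_ensemble()]).
#' @return Data frame with columns `frame`, `phi_deg`, `psi_deg`.
#' @export
torsion_timeseries <- function(ensemble) {
  if (!inherits(ensemble, "torsion_ensemble"))
    stop_gt("gt_validation_error", "expected a torsion_ensemble")
  data.frame(frame = ensemble$frame,
             phi_deg = ensemble$phi_deg,
             psi_deg = ensemble$psi_deg)
}
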