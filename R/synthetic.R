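#' Wrapped-Gaussian mixture model of linkage conformer states
#'
#' Generative model for torsional ensembles with the statistical structure
#' glycosidic linkages exhibit: a mixture of localized states, each a
#' wrapped Gaussian on the phi/psi torus. Wrapped Gaussians (rather than
#' von Mises) are used because at the spreads relevant here (well under
#' 35 degrees) the two are practically indistinguishable and the wrapped
#' form inverts trivially for testing.
#'
#' @param states Data frame with columns `weight`, `phi`, `psi` and
#'   optionally `phi_sd`, `psi_sd` (degrees; default 8) and `label`.
#'   Weights must be nonnegative with a positive sum (a zero-weight state is
#'   a documented absence, e.g. a suppressed conformer); they are
#'   normalized to sum to 1.
#' @param n_frames Number of snapshots to draw.
#' @param seed Integer seed; all randomness flows through it.
#' @return An object of class `state_mixture`.
#' @export
state_mixture <- function(states, n_frames = 10000L, seed = 1L) {
  need <- c("weight", "phi", "psi")
  if (!is.data.frame(states) || !all(need %in% names(states)))
    stop_gt("gt_validation_error",
            "states must be a data frame with columns weight, phi, psi")
  if (any(states$weight < 0) || sum(states$weight) <= 0)
    stop_gt("gt_validation_error",
            "state weights must be nonnegative with a positive sum")
  if (n_frames < 1L)
    stop_gt("gt_validation_error", "n_frames must be at least 1")
  states$weight <- states$weight / sum(states$weight)
  if (is.null(states$phi_sd)) states$phi_sd <- 8
  if (is.null(states$psi_sd)) states$psi_sd <- 8
  if (any(states$phi_sd <= 0) || any(states$psi_sd <= 0))
    stop_gt("gt_validation_error", "angular spreads must be positive")
  if (is.null(states$label)) states$label <- as.character(seq_len(nrow(states)))
  structure(list(states = states, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "state_mixture")
}

#' @export
print.state_mixture <- function(x, ...) {
  cat(sprintf("State mixture: %d states, %d frames, seed %d\n",
              nrow(x$states), x$n_frames, x$seed))
  print(x$states, row.names = FALSE)
  invisible(x)
}

#' Preset mixtures mirroring the solvent-model scenarios
#'
#' Documented synthetic presets on the default state set (I, II, III at
#' phi = 30 and psi = 40 / 0 / 180):
#' \describe{
#'   \item{fuc_gla_sasa_like}{weights I 0.75, II 0.20, III 0.05 -- a
#'     Fuc-GlA linkage whose continuum-solvation ensemble retains trace
#'     inverted conformers.}
#'   \item{fuc_gla_water_like}{weights I 0.8, II 0.2, III exactly 0 -- the
#'     inverted conformer vanishes in explicit water.}
#'   \item{fuc_fuc_like}{states I and II only (0.8 / 0.2) -- a Fuc-Fuc
#'     linkage, where axial crowding blocks the inverted state.}
#' }
#' The weights are synthetic choices consistent with the qualitative
#' behaviour of the solvent models, not measured populations.
#'
#' @param name One of the preset names above.
#' @param n_frames,seed Passed to [state_mixture()].
#' @return A [state_mixture()].
#' @export
mixture_scenario <- function(name = c("fuc_gla_sasa_like", "fuc_gla_water_like",
                                      "fuc_fuc_like"),
                             n_frames = 10000L, seed = 1L) {
  if (length(name) != 1L || !name %in% c("fuc_gla_sasa_like",
                                         "fuc_gla_water_like", "fuc_fuc_like"))
    stop_gt("gt_lookup_error",
            "unknown scenario '%s'; available: fuc_gla_sasa_like, fuc_gla_water_like, fuc_fuc_like",
            paste(name, collapse = ", "))
  st <- switch(name,
    fuc_gla_sasa_like = data.frame(label = c("I", "II", "III"),
                                   weight = c(0.75, 0.20, 0.05),
                                   phi = 30, psi = c(40, 0, 180)),
    fuc_gla_water_like = data.frame(label = c("I", "II", "III"),
                                    weight = c(0.8, 0.2, 0),
                                    phi = 30, psi = c(40, 0, 180)),
    fuc_fuc_like = data.frame(label = c("I", "II"),
                              weight = c(0.8, 0.2),
                              phi = 30, psi = c(40, 0)))
  state_mixture(st, n_frames = n_frames, seed = seed)
}

#' Sample a torsional ensemble from a state mixture
#'
#' Frames are i.i.d.: a component is chosen by weight, then phi and psi are
#' drawn from Gaussians about the component centers and wrapped into
#' (-180, 180]. Fully reproducible from the model seed; the global RNG
#' state is left untouched.
#'
#' @param model A [state_mixture()].
#' @param linkage Linkage name recorded on the ensemble.
#' @return A [torsion_ensemble()] with `model$n_frames` rows.
#' @export
sample_torsions <- function(model, linkage = "synthetic") {
  stopifnot(inherits(model, "state_mixture"))
  st <- model$states
  with_local_seed(model$seed, {
    comp <- sample.int(nrow(st), model$n_frames, replace = TRUE,
                       prob = st$weight)
    phi <- stats::rnorm(model$n_frames, st$phi[comp], st$phi_sd[comp])
    psi <- stats::rnorm(model$n_frames, st$psi[comp], st$psi_sd[comp])
    torsion_ensemble(phi, psi, linkage = linkage,
                     provenance = sprintf("state_mixture(seed=%d)", model$seed))
  })
}

#' Sample a Cartesian ensemble from a state mixture
#'
#' Draws torsions with [sample_torsions()] and realizes each frame as an
#' idealized fragment with [build_fragment()], so that
#' [extract_torsion_ensemble()] on the result recovers the sampled torsions
#' to round-off.
#'
#' @param model A [state_mixture()].
#' @param geom A [fragment_geometry()].
#' @param spec A [linkage_spec()].
#' @return A [coordinate_ensemble()].
#' @export
sample_coordinates <- function(model, geom = fragment_geometry(),
                               spec = geom$spec) {
  tors <- sample_torsions(model, linkage = spec$name)
  frames <- lapply(seq_len(nrow(tors)), function(i)
    build_fragment(tors$phi_deg[i], tors$psi_deg[i], geom, spec))
  coordinate_ensemble(frames,
                      provenance = sprintf("state_mixture(seed=%d)+build_fragment",
                                           model$seed))
}
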