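#' Dihedral-driving scan of an energy function over the phi/psi grid
#'
#' Evaluates a pluggable conformational energy function on a uniform torsion
#' grid covering `[-180, 180)` once per step in each coordinate (rigid
#' single-point scan, no relaxation of other coordinates) and shifts
#' energies so the global minimum is 0. The energy function must be
#' deterministic and 360-degree periodic in both arguments; periodicity is
#' spot-checked at the grid edges.
#'
#' @param energy Function `(phi_deg, psi_deg) -> kcal/mol`.
#' @param step Grid step in degrees; must divide 360. Default 10.
#' @return An object of class `conformational_map`: list with `phi_grid`,
#'   `psi_grid`, `energies` (psi rows x phi columns, relative kcal/mol) and
#'   `step`.
#' @examples
#' m <- scan_map(toy_single_well(), step = 30)
#' find_minima(m)
#' @export
scan_map <- function(energy, step = 10) {
  if (!is.function(energy))
    stop_gt("gt_validation_error", "energy must be a function(phi, psi)")
  if (!is.numeric(step) || step <= 0 || (360 %% step) != 0)
    stop_gt("gt_validation_error", "step (%s) must be a positive divisor of 360",
            format(step))
  grid <- seq(-180, 180 - step, by = step)
  # spot-check 360-degree periodicity at the wrap edges
  for (v in c(-90, 0, 90)) {
    if (abs(energy(-180, v) - energy(180, v)) > 1e-8 ||
        abs(energy(v, -180) - energy(v, 180)) > 1e-8)
      stop_gt("gt_validation_error",
              "energy function is not 360-degree periodic at the grid edge")
  }
  e <- outer(grid, grid, function(ps, ph) mapply(energy, ph, ps))
  if (any(!is.finite(e)))
    stop_gt("gt_validation_error", "energy function returned non-finite values")
  e <- e - min(e)
  dimnames(e) <- list(psi = format(grid), phi = format(grid))
  structure(list(phi_grid = grid, psi_grid = grid, energies = e, step = step),
            class = "conformational_map")
}

#' @export
print.conformational_map <- function(x, ...) {
  cat(sprintf("Conformational map: %dx%d grid, step %g deg, max rel. energy %.2f kcal/mol\n",
              length(x$psi_grid), length(x$phi_grid), x$step, max(x$energies)))
  invisible(x)
}

#' Locate local minima of a conformational map
#'
#' Grid-local minima under 8-neighbour comparison with periodic wrapping,
#' restricted to an energy window above the global minimum, sorted by
#' energy (global minimum first). Detection is on the discrete grid only.
#'
#' @param map A [scan_map()] result.
#' @param energy_window Report minima within this many kcal/mol of the
#'   global minimum. Default 5.
#' @return Data frame with columns `phi_deg`, `psi_deg`, `energy`.
#' @export
find_minima <- function(map, energy_window = 5) {
  if (!inherits(map, "conformational_map"))
    stop_gt("gt_validation_error", "expected a conformational_map")
  e <- map$energies
  n <- nrow(e); m <- ncol(e)
  shift <- function(x, k) if (k == 0L) seq_len(x) else ((seq_len(x) - 1L + k) %% x) + 1L
  is_min <- matrix(TRUE, n, m)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    is_min <- is_min & (e < e[shift(n, di), shift(m, dj)])
  }
  idx <- which(is_min, arr.ind = TRUE)
  out <- data.frame(phi_deg = map$phi_grid[idx[, 2L]],
                    psi_deg = map$psi_grid[idx[, 1L]],
                    energy = e[idx])
  out <- out[out$energy <= energy_window, , drop = FALSE]
  out <- out[order(out$energy, out$phi_deg, out$psi_deg), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Boltzmann populations of discrete minima
#'
#' Fractions proportional to exp(-E / RT) with
#' R = 0.0019872 kcal/(mol K).
#'
#' @param energies Relative energies in kcal/mol.
#' @param temperature Temperature in K; default 298.
#' @return Numeric vector of fractions summing to 1.
#' @export
boltzmann_population <- function(energies, temperature = 298) {
  if (length(energies) == 0L)
    stop_gt("gt_empty_input", "no energies supplied")
  check_finite(energies, "energies")
  if (temperature <= 0)
    stop_gt("gt_validation_error", "temperature must be positive")
  R <- 0.0019872  # kcal/(mol K)
  w <- exp(-(energies - min(energies)) / (R * temperature))
  w / sum(w)
}

#' Toy conformational energy functions
#'
#' Simple periodic potentials for exercising the scan machinery.
#' `toy_single_well()` is a cosine bowl with one minimum at
#' `(phi0, psi0)`. `toy_two_well()` adds an exo-anomeric-style cosine term
#' on phi and a tilted double well on psi: minima at `(phi0, psi0)`
#' (energy 0) and at `(phi0, psi0 + 180)` (energy `2 * tilt` kcal/mol).
#'
#' @param phi0,psi0 Location of the (global) minimum in degrees.
#' @param k Well stiffness prefactor in kcal/mol.
#' @return A function `(phi, psi) -> kcal/mol`.
#' @export
toy_single_well <- function(phi0 = 30, psi0 = 40, k = 2) {
  force(phi0); force(psi0); force(k)
  function(phi, psi)
    k * (1 - cos(deg2rad(phi - phi0))) + k * (1 - cos(deg2rad(psi - psi0)))
}

#' @rdname toy_single_well
#' @param barrier Height coefficient of the psi double-well term (kcal/mol);
#'   must exceed `tilt / 4` for two minima to exist.
#' @param tilt Half the energy gap between the two psi wells (kcal/mol).
#' @export
toy_two_well <- function(phi0 = 30, psi0 = 40, k = 2, barrier = 1.5, tilt = 1.5) {
  if (barrier <= tilt / 4)
    stop_gt("gt_validation_error",
            "barrier must exceed tilt/4 for a double well")
  force(phi0); force(psi0); force(k); force(barrier); force(tilt)
  function(phi, psi) {
    dps <- deg2rad(psi - psi0)
    k * (1 - cos(deg2rad(phi - phi0))) +
      barrier * (1 - cos(2 * dps)) + tilt * (1 - cos(dps))
  }
}

#' Export a conformational map as CSV
#'
#' `write_map_matrix_csv()` writes the psi-rows x phi-columns energy matrix
#' with grid angles as header row/column; `write_map_long_csv()` writes
#' long-form rows `(phi_deg, psi_deg, energy)`.
#'
#' @param map A [scan_map()] result.
#' @param path Output CSV path.
#' @param header_lines Optional comment lines written at the top.
#' @return The path, invisibly.
#' @export
write_map_matrix_csv <- function(map, path, header_lines = character()) {
  df <- data.frame(psi_deg = map$psi_grid, map$energies, check.names = FALSE)
  names(df) <- c("psi_deg", format(map$phi_grid, trim = TRUE))
  write_csv_commented(df, path, header_lines)
}

#' @rdname write_map_matrix_csv
#' @export
write_map_long_csv <- function(map, path, header_lines = character()) {
  df <- expand.grid(psi_deg = map$psi_grid, phi_deg = map$phi_grid,
                    KEEP.OUT.ATTRS = FALSE)
  df$energy <- as.vector(map$energies)
  write_csv_commented(df[, c("phi_deg", "psi_deg", "energy")], path, header_lines)
}
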