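#' Define a glycosidic linkage by its phi/psi atom quadruples
#'
#' A glycosidic linkage C1--O--Cx is described by two torsional angles,
#' following the NMR-oriented convention that makes them directly comparable
#' with trans-glycosidic couplings: phi = H1--C1--O--Cx and
#' psi = C1--O--Cx--Hx, where x is the aglycon position (the x in 1->x).
#'
#' @param name Linkage label, e.g. `"Fuc-GlA"`.
#' @param phi_atoms Character vector of four atom identifiers (H1, C1, O, Cx).
#' @param psi_atoms Character vector of four atom identifiers (C1, O, Cx, Hx).
#' @param aglycon_position Integer, the substitution position x of the
#'   aglycon residue (3 for a 1->3 linkage).
#' @return An object of class `linkage_spec`.
#' @examples
#' linkage_spec("Fuc-GlA", c("H1", "C1", "O", "CX"), c("C1", "O", "CX", "HX"), 3)
#' @export
linkage_spec <- function(name, phi_atoms, psi_atoms, aglycon_position = 3L) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_gt("gt_validation_error", "linkage name must be a nonempty string")
  phi_atoms <- as.character(phi_atoms)
  psi_atoms <- as.character(psi_atoms)
  if (length(phi_atoms) != 4L || length(psi_atoms) != 4L)
    stop_gt("gt_validation_error",
            "phi_atoms and psi_atoms must each name four atoms")
  if (anyDuplicated(phi_atoms) || anyDuplicated(psi_atoms))
    stop_gt("gt_validation_error",
            "atom identifiers must be distinct within each torsion quadruple")
  if (phi_atoms[3L] != psi_atoms[2L])
    stop_gt("gt_validation_error",
            "phi_atoms[3] and psi_atoms[2] must both be the glycosidic oxygen (got '%s' vs '%s')",
            phi_atoms[3L], psi_atoms[2L])
  if (phi_atoms[2L] != psi_atoms[1L])
    stop_gt("gt_validation_error",
            "phi_atoms[2] and psi_atoms[1] must both be the anomeric carbon (got '%s' vs '%s')",
            phi_atoms[2L], psi_atoms[1L])
  structure(list(name = name, phi_atoms = phi_atoms, psi_atoms = psi_atoms,
                 aglycon_position = as.integer(aglycon_position)),
            class = "linkage_spec")
}

#' @export
print.linkage_spec <- function(x, ...) {
  cat(sprintf("Glycosidic linkage '%s' (1->%d)\n", x$name, x$aglycon_position))
  cat("  phi:", paste(x$phi_atoms, collapse = "-"), "\n")
  cat("  psi:", paste(x$psi_atoms, collapse = "-"), "\n")
  invisible(x)
}

#' Default linkage specification for the packaged idealized fragment
#'
#' Atom ids follow the fragment built by [build_fragment()]: `H1`, `C1`
#' (glycosylating residue), `O` (glycosidic oxygen), `CX`, `HX` (aglycon).
#'
#' @return A `linkage_spec`.
#' @export
default_linkage_spec <- function() {
  linkage_spec("Fuc-GlA", c("H1", "C1", "O", "CX"), c("C1", "O", "CX", "HX"), 3L)
}

#' Read a linkage specification from a YAML config
#'
#' Expects keys `name`, `phi_atoms`, `psi_atoms`, `aglycon_position` either at
#' the top level or under a `linkage:` key.
#'
#' @param path Path to a YAML file.
#' @return A `linkage_spec`.
#' @export
read_linkage_spec <- function(path) {
  if (!file.exists(path))
    stop_gt("gt_config_error", "linkage config not found: %s", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$linkage)) y <- y$linkage
  for (k in c("name", "phi_atoms", "psi_atoms"))
    if (is.null(y[[k]]))
      stop_gt("gt_config_error", "linkage config missing key '%s'", k)
  linkage_spec(y$name, unlist(y$phi_atoms), unlist(y$psi_atoms),
               y$aglycon_position %||% 3L)
}

#' Signed dihedral angle of four points
#'
#' Computes the torsional angle p1-p2-p3-p4 in degrees using the IUPAC sign
#' convention: 0 for the cis (eclipsed) arrangement, positive when, viewed
#' along p2 -> p3, the far bond is rotated clockwise from the near bond.
#' The result lies in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Dihedral angle in degrees.
#' @examples
#' dihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(-1, 1, 0))  # 0 (cis)
#' @export
dihedral <- function(p1, p2, p3, p4) {
  for (p in list(p1, p2, p3, p4)) check_finite(p, "coordinates")
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  if (vnorm(b1) < 1e-10)
    stop_gt("gt_degenerate_geometry",
            "central atoms p2 and p3 coincide; dihedral undefined")
  b1u <- b1 / vnorm(b1)
  v <- b0 - sum(b0 * b1u) * b1u
  w <- b2 - sum(b2 * b1u) * b1u
  if (vnorm(v) < 1e-10 || vnorm(w) < 1e-10)
    stop_gt("gt_degenerate_geometry",
            "collinear atom triple (%s); dihedral undefined",
            if (vnorm(v) < 1e-10) "p1,p2,p3" else "p2,p3,p4")
  ang <- rad2deg(atan2(sum(cross3(b1u, v) * w), sum(v * w)))
  wrap180(ang)
}

#' Extract (phi, psi) torsions of a linkage from one coordinate frame
#'
#' @param frame Numeric matrix with 3 columns and atom identifiers as row
#'   names, or a named list of length-3 coordinate vectors.
#' @param spec A [linkage_spec()].
#' @return Named numeric vector `c(phi = ..., psi = ...)` in degrees.
#' @export
linkage_torsions <- function(frame, spec = default_linkage_spec()) {
  stopifnot(inherits(spec, "linkage_spec"))
  get_atom <- function(id) {
    p <- if (is.matrix(frame)) {
      if (!id %in% rownames(frame)) NULL else frame[id, ]
    } else frame[[id]]
    if (is.null(p))
      stop_gt("gt_lookup_error",
              "atom '%s' required by linkage '%s' not present in frame",
              id, spec$name)
    as.numeric(p)
  }
  ap <- lapply(spec$phi_atoms, get_atom)
  as_ <- lapply(spec$psi_atoms, get_atom)
  c(phi = dihedral(ap[[1L]], ap[[2L]], ap[[3L]], ap[[4L]]),
    psi = dihedral(as_[[1L]], as_[[2L]], as_[[3L]], as_[[4L]]))
}

#' Idealized internal geometry for a glycosidic-linkage fragment
#'
#' Bond lengths, bond angles and extra-proton placement rules used by
#' [build_fragment()]. Defaults are idealized values (C-H 1.09 A, C-O 1.43 A,
#' tetrahedral angles, glycosidic valence angle 117 deg); only relative
#' quantities (torsions, distance ratios) are consumed downstream, so
#' idealized geometry suffices.
#'
#' Extra protons model aglycon ring protons observed in NOE work (the H2/H4
#' analogues of the aglycon residue). They are placed by fixed internal
#' coordinates that ride with the psi torsion (`torsion = psi + offset_deg`
#' about the O-Cx bond), because the aglycon ring rotates rigidly with psi.
#'
#' @param spec A [linkage_spec()] supplying atom identifiers.
#' @param c_h,c_o Bond lengths in Angstrom.
#' @param glycosidic_angle Valence angle C1-O-Cx in degrees.
#' @param tetrahedral_angle Valence angle at carbons in degrees.
#' @param extra_protons Data frame with columns `id`, `residue`
#'   (`"aglycon"` or `"glycosyl"`), `bond` (A, from Cx or C1), `angle` (deg)
#'   and `offset_deg` (deg, added to psi or phi).
#' @return An object of class `fragment_geometry`.
#' @export
fragment_geometry <- function(spec = default_linkage_spec(),
                              c_h = 1.09, c_o = 1.43,
                              glycosidic_angle = 117,
                              tetrahedral_angle = 109.47,
                              extra_protons = default_extra_protons()) {
  for (v in c(c_h, c_o)) if (v <= 0)
    stop_gt("gt_validation_error", "bond lengths must be positive")
  for (a in c(glycosidic_angle, tetrahedral_angle)) if (a <= 0 || a >= 180)
    stop_gt("gt_validation_error", "bond angles must lie in (0, 180) degrees")
  if (!is.null(extra_protons)) {
    need <- c("id", "residue", "bond", "angle", "offset_deg")
    if (!all(need %in% names(extra_protons)))
      stop_gt("gt_config_error",
              "extra_protons must have columns: %s (missing: %s)",
              paste(need, collapse = ", "),
              paste(setdiff(need, names(extra_protons)), collapse = ", "))
    if (any(extra_protons$bond <= 0) ||
        any(extra_protons$angle <= 0 | extra_protons$angle >= 180))
      stop_gt("gt_validation_error",
              "extra proton bonds must be > 0 and angles in (0, 180)")
  }
  structure(list(spec = spec, c_h = c_h, c_o = c_o,
                 glycosidic_angle = glycosidic_angle,
                 tetrahedral_angle = tetrahedral_angle,
                 extra_protons = extra_protons),
            class = "fragment_geometry")
}

#' Default extra-proton placement rules
#'
#' Two pseudo-protons on the aglycon residue standing in for the ring protons
#' flanking the linkage carbon (H2 and H4 analogues). Bond length 2.16 A from
#' Cx approximates the distance from the linkage carbon to a proton on an
#' adjacent ring carbon; the torsional offsets (+100 and +120 deg about the
#' O-Cx axis) place both protons far from H1 in the common conformers
#' (psi around 0 to +40) and close to H1 in the inverted psi ~ 180
#' conformer, with the H4 analogue the closer of the two -- the distance
#' pattern of a rigid pyranose ring that makes these pairs diagnostic of
#' inverted-conformer population.
#'
#' @return A data frame of placement rules.
#' @export
default_extra_protons <- function() {
  data.frame(id = c("H2X", "H4X"),
             residue = "aglycon",
             bond = 2.16,
             angle = 90,
             offset_deg = c(100, 120),
             stringsAsFactors = FALSE)
}

# NeRF atom placement: position d with |c-d| = bond, angle(b,c,d) = ang,
# torsion(a,b,c,d) = tor (degrees)
place_atom <- function(a, b, c_, bond, ang, tor) {
  th <- deg2rad(ang)
  ph <- deg2rad(tor)
  bc <- unit3(c_ - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c_ + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Build an idealized fragment realizing requested (phi, psi) torsions
#'
#' Places the five linkage atoms (H1, C1, O, Cx, Hx) plus any extra protons
#' so that [linkage_torsions()] on the result returns exactly the requested
#' angles. Deterministic; used for round-trip testing, synthetic Cartesian
#' ensembles and NOE distance work.
#'
#' @param phi,psi Torsions in degrees.
#' @param geom A [fragment_geometry()].
#' @param spec A [linkage_spec()]; defaults to the one inside `geom`.
#' @return Numeric matrix (atoms x 3) with atom identifiers as row names.
#' @examples
#' fr <- build_fragment(30, 40)
#' linkage_torsions(fr)
#' @export
build_fragment <- function(phi, psi, geom = fragment_geometry(),
                           spec = geom$spec) {
  check_finite(phi, "phi")
  check_finite(psi, "psi")
  stopifnot(inherits(geom, "fragment_geometry"),
            inherits(spec, "linkage_spec"))
  h1 <- spec$phi_atoms[1L]; c1 <- spec$phi_atoms[2L]
  o <- spec$phi_atoms[3L]; cx <- spec$phi_atoms[4L]
  hx <- spec$psi_atoms[4L]

  p_c1 <- c(0, 0, 0)
  p_o <- c(geom$c_o, 0, 0)
  thg <- deg2rad(geom$glycosidic_angle)
  p_cx <- c(geom$c_o - geom$c_o * cos(thg), geom$c_o * sin(thg), 0)
  # torsion(H1,C1,O,Cx) == torsion(Cx,O,C1,H1) == phi
  p_h1 <- place_atom(p_cx, p_o, p_c1, geom$c_h, geom$tetrahedral_angle, phi)
  p_hx <- place_atom(p_c1, p_o, p_cx, geom$c_h, geom$tetrahedral_angle, psi)

  ids <- c(h1, c1, o, cx, hx)
  coords <- rbind(p_h1, p_c1, p_o, p_cx, p_hx)
  if (!is.null(geom$extra_protons) && nrow(geom$extra_protons)) {
    for (i in seq_len(nrow(geom$extra_protons))) {
      ep <- geom$extra_protons[i, ]
      p <- if (ep$residue == "aglycon")
        place_atom(p_c1, p_o, p_cx, ep$bond, ep$angle, psi + ep$offset_deg)
      else
        place_atom(p_cx, p_o, p_c1, ep$bond, ep$angle, phi + ep$offset_deg)
      ids <- c(ids, ep$id)
      coords <- rbind(coords, p)
    }
  }
  if (anyDuplicated(ids))
    stop_gt("gt_config_error", "duplicate atom identifiers in fragment: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rownames(coords) <- ids
  colnames(coords) <- c("x", "y", "z")
  coords
}
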