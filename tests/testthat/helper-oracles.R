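# Independent oracles used by the tests. These deliberately do not share
# code paths with the package implementation.

# -- projection oracle for dihedrals ----------------------------------------
# Rotate the frame so p2 -> p3 lies along +z, project the outer bonds onto
# the xy plane, and take the signed angle between the projections.
oracle_dihedral <- function(p1, p2, p3, p4) {
  u <- p3 - p2
  u <- u / sqrt(sum(u^2))
  # build a right-handed orthonormal frame (e1, e2, u)
  aux <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(u[2] * aux[3] - u[3] * aux[2],
          u[3] * aux[1] - u[1] * aux[3],
          u[1] * aux[2] - u[2] * aux[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  v <- p1 - p2
  w <- p4 - p3
  v2 <- c(sum(v * e1), sum(v * e2))
  w2 <- c(sum(w * e1), sum(w * e2))
  atan2(v2[1] * w2[2] - v2[2] * w2[1], sum(v2 * w2)) * 180 / pi
}

# -- Rodrigues rotation ------------------------------------------------------
rodrigues <- function(v, axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  kxv <- c(k[2] * v[3] - k[3] * v[2],
           k[3] * v[1] - k[1] * v[3],
           k[1] * v[2] - k[2] * v[1])
  v * cos(th) + kxv * sin(th) + k * sum(k * v) * (1 - cos(th))
}

random_rotation_matrix <- function() {
  axis <- stats::rnorm(3)
  ang <- stats::runif(1, 0, 360)
  t(vapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           rodrigues, numeric(3), axis = axis, angle_deg = ang))
}

apply_rigid <- function(coords, R = random_rotation_matrix(),
                        shift = stats::rnorm(3, sd = 5)) {
  out <- coords %*% t(R)
  out <- sweep(out, 2, -shift)
  rownames(out) <- rownames(coords)
  out
}

# -- Z-matrix chain builder (Rodrigues-based, independent of NeRF) -----------
# Places atom D bonded to C with angle(B,C,D) and torsion(A,B,C,D), by
# rotating the back-bond direction about the plane normal and then about
# the B->C axis.
zmat_place <- function(a, b, c_, bond, angle_deg, torsion_deg) {
  back <- (b - c_) / sqrt(sum((b - c_)^2))
  n <- c((b - a)[2] * (c_ - b)[3] - (b - a)[3] * (c_ - b)[2],
         (b - a)[3] * (c_ - b)[1] - (b - a)[1] * (c_ - b)[3],
         (b - a)[1] * (c_ - b)[2] - (b - a)[2] * (c_ - b)[1])
  u <- rodrigues(back, n, -angle_deg)     # in-plane at the valence angle, torsion 0
  u <- rodrigues(u, c_ - b, torsion_deg)  # twist about the central bond
  c_ + bond * u
}

# H1..Hx chain from internal coordinates; returns named list of positions
zmat_chain <- function(phi, psi, c_h = 1.09, c_o = 1.43,
                       glyc = 117, tetra = 109.47) {
  h1 <- c(0, 0, 0)
  c1 <- c(c_h, 0, 0)
  th <- (180 - tetra) * pi / 180
  o <- c1 + c_o * c(cos(th), sin(th), 0)   # angle(H1,C1,O) = tetra
  cx <- zmat_place(h1, c1, o, c_o, glyc, phi)     # torsion(H1,C1,O,Cx) = phi
  hx <- zmat_place(c1, o, cx, c_h, tetra, psi)    # torsion(C1,O,Cx,Hx) = psi
  list(H1 = h1, C1 = c1, O = o, CX = cx, HX = hx)
}

# -- quadrature oracle for wrapped-Gaussian mixture <J> ----------------------
# E[J(theta)] over a Gaussian component equals the wrapped-Gaussian
# expectation because J is 360-periodic.
quadrature_mixture_j <- function(weights, centers, sds, params) {
  comps <- vapply(seq_along(weights), function(k) {
    stats::integrate(function(t) karplus_j(t, params) *
                       stats::dnorm(t, centers[k], sds[k]),
                     centers[k] - 12 * sds[k], centers[k] + 12 * sds[k],
                     rel.tol = 1e-10)$value
  }, numeric(1))
  sum(weights * comps)
}
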