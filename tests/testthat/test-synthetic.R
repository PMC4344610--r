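test_that("a degenerate-spread single state pins every frame to its center", {
  m <- state_mixture(data.frame(weight = 1, phi = 30, psi = 40,
                                phi_sd = 1e-9, psi_sd = 1e-9),
                     n_frames = 200L, seed = 71L)
  tors <- sample_torsions(m)
  expect_equal(tors$phi_deg, rep(30, 200), tolerance = 1e-7)
  expect_equal(tors$psi_deg, rep(40, 200), tolerance = 1e-7)
})

test_that("sampling is reproducible from the seed and leaves the RNG alone", {
  m <- mixture_scenario("fuc_gla_sasa_like", n_frames = 500L, seed = 72L)
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  t1 <- sample_torsions(m)
  after <- runif(1)
  t2 <- sample_torsions(m)
  expect_identical(t1, t2)
  expect_identical(before, after)  # global RNG stream untouched
})

test_that("sampled circular means converge to the component centers", {
  m <- state_mixture(data.frame(label = c("I", "III"), weight = c(0.5, 0.5),
                                phi = 30, psi = c(40, 180)),
                     n_frames = 10000L, seed = 73L)
  tors <- sample_torsions(m)
  lab <- classify_conformers(tors$phi_deg, tors$psi_deg)
  for (st in c("I", "III")) {
    sel <- lab == st
    center <- if (st == "I") 40 else 180
    # circular mean via the mean resultant direction
    rad <- tors$psi_deg[sel] * pi / 180
    cmean <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
    se <- 8 / sqrt(sum(sel))   # spread 8 deg per coordinate
    expect_lt(circular_distance(cmean, center), 3 * se)
  }
})

test_that("scenario presets encode the solvent-model contrasts", {
  sasa <- mixture_scenario("fuc_gla_sasa_like")
  water <- mixture_scenario("fuc_gla_water_like")
  fucfuc <- mixture_scenario("fuc_fuc_like")
  expect_gt(sasa$states$weight[sasa$states$label == "III"], 0)
  expect_equal(water$states$weight[water$states$label == "III"], 0)
  expect_false("III" %in% fucfuc$states$label)
  for (m in list(sasa, water, fucfuc))
    expect_equal(sum(m$states$weight), 1)
  expect_error(mixture_scenario("nope"), class = "gt_lookup_error")
})

test_that("invalid mixtures are rejected", {
  expect_error(state_mixture(data.frame(weight = -0.1, phi = 0, psi = 0)),
               class = "gt_validation_error")
  expect_error(state_mixture(data.frame(weight = 1, phi = 0, psi = 0),
                             n_frames = 0), class = "gt_validation_error")
  expect_error(state_mixture(data.frame(weight = 1, phi = 0, psi = 0,
                                        phi_sd = 0)),
               class = "gt_validation_error")
})

test_that("Cartesian sampling round-trips the drawn torsions", {
  m <- mixture_scenario("fuc_gla_sasa_like", n_frames = 50L, seed = 74L)
  tors <- sample_torsions(m, linkage = "Fuc-GlA")
  coords <- sample_coordinates(m)
  back <- extract_torsion_ensemble(coords)
  expect_true(all(circular_distance(back$phi_deg, tors$phi_deg) < 1e-6))
  expect_true(all(circular_distance(back$psi_deg, tors$psi_deg) < 1e-6))
})

test_that("near-degenerate coordinate ensembles reproduce single-conformer NOEs", {
  m <- state_mixture(data.frame(weight = 1, phi = 30, psi = 40,
                                phi_sd = 1e-6, psi_sd = 1e-6),
                     n_frames = 100L, seed = 75L)
  coords <- sample_coordinates(m)
  fr <- build_fragment(30, 40)
  ref <- proton_pair("H1", "HX"); pr <- proton_pair("H1", "H2X")
  r_ref <- sqrt(sum((fr["H1", ] - fr["HX", ])^2))
  r_pr <- sqrt(sum((fr["H1", ] - fr["H2X", ])^2))
  expect_equal(relative_noe(coords, list(pr), ref)$intensity,
               (r_ref / r_pr)^6, tolerance = 1e-4)
})

test_that("two-state coordinate ensembles match closed-form J and NOE mixtures", {
  w <- 0.6
  m <- state_mixture(data.frame(weight = c(w, 1 - w), phi = 30,
                                psi = c(40, 180),
                                phi_sd = 1e-7, psi_sd = 1e-7),
                     n_frames = 4000L, seed = 76L)
  tors <- sample_torsions(m)
  coords <- sample_coordinates(m)
  n1 <- sum(abs(tors$psi_deg - 40) < 1)   # realized component counts
  p1 <- n1 / nrow(tors)
  pars <- default_karplus_sets()$tvaroska1989
  expect_equal(ensemble_j(tors$psi_deg, pars),
               p1 * karplus_j(40, pars) + (1 - p1) * karplus_j(180, pars),
               tolerance = 1e-6)
  f1 <- build_fragment(30, 40); f3 <- build_fragment(30, 180)
  ref <- proton_pair("H1", "HX"); pr <- proton_pair("H1", "H4X")
  d <- function(fr, p) sqrt(sum((fr[p$donor, ] - fr[p$acceptor, ])^2))
  want <- (p1 * d(f1, pr)^-6 + (1 - p1) * d(f3, pr)^-6) /
    (p1 * d(f1, ref)^-6 + (1 - p1) * d(f3, ref)^-6)
  expect_equal(relative_noe(coords, list(pr), ref)$intensity, want,
               tolerance = 1e-4)
})

test_that("the water-like preset carries no inverted-conformer signal", {
  m <- mixture_scenario("fuc_gla_water_like", n_frames = 2000L, seed = 77L)
  tors <- sample_torsions(m)
  lab <- classify_conformers(tors$phi_deg, tors$psi_deg)
  pops <- conformer_populations(lab, default_conformer_states())
  expect_equal(pops$fractions[["III"]], 0)
})
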