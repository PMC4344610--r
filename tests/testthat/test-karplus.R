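tvaroska <- default_karplus_sets()$tvaroska1989

test_that("karplus_j evaluates the trigonometric polynomial", {
  expect_equal(karplus_j(90, karplus_params("a", 1, 0, 0)), 0)
  expect_equal(karplus_j(0, karplus_params("b", 1, 1, 1)), 3)
  # hand-evaluated values of the default parameterization
  expect_equal(karplus_j(0, tvaroska), 5.6)
  expect_equal(karplus_j(60, tvaroska), 1.625)
  expect_equal(karplus_j(180, tvaroska), 6.8)
})

test_that("karplus_j is even and 360-degree periodic", {
  set.seed(21)
  th <- runif(50, -720, 720)
  expect_equal(karplus_j(th, tvaroska), karplus_j(-th, tvaroska))
  expect_equal(karplus_j(th, tvaroska), karplus_j(th + 360, tvaroska))
})

test_that("ensemble_j averages the curve, not the angle", {
  expect_equal(ensemble_j(rep(40, 1000), tvaroska), karplus_j(40, tvaroska))
  expect_equal(ensemble_j(c(10, 100), tvaroska),
               mean(karplus_j(c(10, 100), tvaroska)))
  # asymmetric bimodal ensemble: <J(theta)> and J(<theta>) differ by > 0.2 Hz
  th <- c(rep(40, 7), rep(180, 3))
  j_of_mean <- karplus_j(mean(th), tvaroska)
  mean_of_j <- 0.7 * karplus_j(40, tvaroska) + 0.3 * karplus_j(180, tvaroska)
  expect_gt(abs(mean_of_j - j_of_mean), 0.2)
  expect_equal(ensemble_j(th, tvaroska), mean_of_j)
})

test_that("ensemble_j respects weights and is linear in mixture weight", {
  set.seed(22)
  e1 <- runif(50, -180, 180); e2 <- runif(50, -180, 180)
  w <- 0.3
  j_mix <- ensemble_j(c(e1, e2), tvaroska,
                      weights = c(rep(w / 50, 50), rep((1 - w) / 50, 50)))
  expect_equal(j_mix, w * ensemble_j(e1, tvaroska) +
                 (1 - w) * ensemble_j(e2, tvaroska))
  j_all <- karplus_j(c(e1, e2), tvaroska)
  expect_gte(ensemble_j(c(e1, e2), tvaroska), min(j_all))
  expect_lte(ensemble_j(c(e1, e2), tvaroska), max(j_all))
})

test_that("ensemble_j rejects bad input", {
  expect_error(ensemble_j(numeric(), tvaroska), class = "gt_empty_input")
  expect_error(ensemble_j(c(1, 2), tvaroska, weights = c(1, -1)),
               class = "gt_validation_error")
  expect_error(ensemble_j(c(1, 2), tvaroska, weights = c(1, 1, 1)),
               class = "gt_validation_error")
})

test_that("ensemble average over a two-state mixture matches quadrature", {
  m <- state_mixture(data.frame(weight = c(0.7, 0.3), phi = c(30, 30),
                                psi = c(40, 0), phi_sd = 10, psi_sd = 10),
                     n_frames = 10000L, seed = 515L)
  tors <- sample_torsions(m)
  got <- ensemble_j(tors$psi_deg, tvaroska)
  want <- quadrature_mixture_j(c(0.7, 0.3), c(40, 0), c(10, 10), tvaroska)
  mc_se <- stats::sd(karplus_j(tors$psi_deg, tvaroska)) / sqrt(nrow(tors))
  expect_lt(abs(got - want), 3 * mc_se)
})

test_that("the packaged coupling table matches its published layout", {
  tab <- fcs_coupling_table()
  expect_equal(nrow(tab), 56)
  expect_setequal(unique(tab$source),
                  c("experimental", "in_vacuo", "SASA", "water"))
  # 14 measurable (compound, linkage, torsion) cells
  expect_equal(sum(tab$source == "experimental"), 14)
})

test_that("compare_couplings reproduces the per-row published deviations", {
  tab <- fcs_coupling_table()
  exp_rows <- tab[tab$source == "experimental", ]
  cmp_sasa <- compare_couplings(exp_rows, tab[tab$source == "SASA", ])
  r <- cmp_sasa[cmp_sasa$compound == 3 & cmp_sasa$torsion_kind == "phi" &
                  cmp_sasa$linkage == "Fuc-GlA", ]
  expect_equal(r$deviation_hz, 0.3)
  expect_true(r$within_error)
  cmp_vac <- compare_couplings(exp_rows, tab[tab$source == "in_vacuo", ])
  r2 <- cmp_vac[cmp_vac$compound == 1 & cmp_vac$torsion_kind == "psi", ]
  expect_equal(r2$deviation_hz, 1.3)
  expect_false(r2$within_error)
})

test_that("identical record sets compare with zero deviation", {
  tab <- fcs_coupling_table()
  exp_rows <- tab[tab$source == "experimental", ]
  cmp <- compare_couplings(exp_rows, exp_rows)
  expect_true(all(cmp$deviation_hz == 0))
  expect_true(all(cmp$within_error))
})

test_that("unmatched rows raise a pairing error listing orphans", {
  tab <- fcs_coupling_table()
  exp_rows <- tab[tab$source == "experimental", ]
  calc <- tab[tab$source == "SASA", ][-1, ]
  expect_error(compare_couplings(exp_rows, calc), class = "gt_pairing_error")
})

test_that("mean_absolute_deviation is permutation-invariant and guards empties", {
  tab <- fcs_coupling_table()
  cmp <- compare_couplings(tab[tab$source == "experimental", ],
                           tab[tab$source == "SASA", ])
  set.seed(23)
  shuffled <- cmp[sample(nrow(cmp)), ]
  expect_equal(mean_absolute_deviation(shuffled), mean_absolute_deviation(cmp))
  expect_equal(mean_absolute_deviation(cmp[1, ]), cmp$deviation_hz[1])
  expect_error(mean_absolute_deviation(cmp[0, ]), class = "gt_empty_input")
})

test_that("coupling records validate sources and values", {
  df <- data.frame(compound = 1, linkage = "x", torsion_kind = "phi",
                   source = "dream", value_hz = 1)
  expect_error(coupling_records(df), class = "gt_validation_error")
  df$source <- "SASA"; df$value_hz <- -1
  expect_error(coupling_records(df), class = "gt_validation_error")
})

test_that("Karplus sets round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("karplus:", "  alt: {A: 7.49, B: -0.96, C: 0.15}"), path)
  sets <- read_karplus_sets(path)
  expect_equal(sets$alt$A, 7.49)
  expect_equal(karplus_j(0, sets$alt), 7.49 - 0.96 + 0.15)
})
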