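test_that("expected_snapshots implements the sampling-plan arithmetic", {
  expect_equal(expected_snapshots(simulation_plan(20000, 2)), 10000L)
  expect_equal(expected_snapshots(simulation_plan(10, 2)), 5L)
  expect_equal(expected_snapshots(simulation_plan(20000, 2,
                                                  equilibration_ps = 1000)),
               9500L)
})

test_that("simulation plans validate their fields", {
  expect_error(simulation_plan(0, 2), class = "gt_validation_error")
  expect_error(simulation_plan(10, 20), class = "gt_validation_error")
  expect_error(simulation_plan(10, 2, temperature_k = -1),
               class = "gt_validation_error")
  expect_error(simulation_plan(10, 2, equilibration_ps = 10),
               class = "gt_validation_error")
})

test_that("XYZ ensembles round-trip losslessly", {
  m <- mixture_scenario("fuc_gla_sasa_like", n_frames = 3L, seed = 61L)
  coords <- sample_coordinates(m)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_ensemble(coords, path)
  back <- read_xyz_ensemble(path)
  expect_equal(length(back$frames), 3)
  expect_equal(back$atoms, coords$atoms)
  for (k in 1:3)
    expect_equal(back$frames[[k]], coords$frames[[k]], tolerance = 1e-7)
})

test_that("a small handwritten XYZ fixture parses to frames and atoms", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "frame 0",
               "C  0.0 0.0 0.0", "O  1.4 0.0 0.0", "H  2.0 0.9 0.0",
               "3", "frame 1",
               "C  0.0 0.0 0.1", "O  1.4 0.0 0.1", "H  2.0 0.9 0.1"), path)
  ens <- read_xyz_ensemble(path)
  expect_equal(length(ens$frames), 2)
  expect_equal(ens$atoms, c("C", "O", "H"))
  expect_equal(unname(ens$frames[[2]]["H", "z"]), 0.1)
})

test_that("truncated and malformed XYZ input raises parse errors", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "frame 0",
               "C 0 0 0", "O 1.4 0 0", "H 2 0.9 0",
               "3", "frame 1", "C 0 0 0"), path)
  expect_error(read_xyz_ensemble(path), "frame 1", class = "gt_parse_error")
  writeLines(c("1", "c", "C 1 2"), path)
  expect_error(read_xyz_ensemble(path), class = "gt_parse_error")
})

test_that("multi-MODEL PDB ensembles round-trip to coordinate precision", {
  m <- mixture_scenario("fuc_fuc_like", n_frames = 4L, seed = 62L)
  coords <- sample_coordinates(m)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(coords, path)
  back <- read_pdb_ensemble(path)
  expect_equal(length(back$frames), 4)   # frame count == MODEL count
  expect_equal(back$atoms, coords$atoms)
  for (k in 1:4)
    expect_equal(back$frames[[k]], coords$frames[[k]], tolerance = 1e-3)
})

test_that("PDB structural problems are reported", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1",
               "ATOM      1  H1  LIG A   1       0.000   0.000   0.000  1.00  0.00",
               "ENDMDL",
               "MODEL        2",
               "ATOM      1  H1  LIG A   1       0.000   0.000   0.000  1.00  0.00",
               "ATOM      2  H2  LIG A   1       1.000   0.000   0.000  1.00  0.00",
               "ENDMDL"), path)
  expect_error(read_pdb_ensemble(path), class = "gt_structural_error")
  writeLines(c("MODEL        1",
               "ATOM      1  H1  LIG A   1       0.000   0.000   0.000  1.00  0.00"),
             path)
  expect_error(read_pdb_ensemble(path), class = "gt_parse_error")
})

test_that("extract_torsion_ensemble recovers construction torsions", {
  set.seed(63)
  phis <- runif(25, -180, 180); psis <- runif(25, -180, 180)
  frames <- lapply(seq_along(phis), function(i) build_fragment(phis[i], psis[i]))
  coords <- coordinate_ensemble(frames)
  tors <- extract_torsion_ensemble(coords)
  expect_equal(nrow(tors), 25)
  expect_true(all(circular_distance(tors$phi_deg, phis) < 1e-6))
  expect_true(all(circular_distance(tors$psi_deg, psis) < 1e-6))
})

test_that("extraction matches a naive per-frame loop and commutes with subsetting", {
  m <- mixture_scenario("fuc_gla_sasa_like", n_frames = 100L, seed = 64L)
  coords <- sample_coordinates(m)
  tors <- extract_torsion_ensemble(coords)
  naive <- t(vapply(coords$frames, linkage_torsions, numeric(2),
                    spec = default_linkage_spec()))
  expect_equal(tors$phi_deg, unname(naive[, "phi"]))
  expect_equal(tors$psi_deg, unname(naive[, "psi"]))
  sub <- coordinate_ensemble(coords$frames[11:20])
  expect_equal(extract_torsion_ensemble(sub)$phi_deg, tors$phi_deg[11:20])
})

test_that("missing atoms during extraction name the frame", {
  fr1 <- build_fragment(30, 40)
  fr2 <- fr1
  rownames(fr2)[1] <- "HQ"
  coords <- structure(list(atoms = rownames(fr1), frames = list(fr1, fr2),
                           provenance = ""), class = "coordinate_ensemble")
  expect_error(extract_torsion_ensemble(coords), "frame 1",
               class = "gt_lookup_error")
})

test_that("torsion ensembles wrap angles and enforce frame monotonicity", {
  ens <- torsion_ensemble(c(190, -190), c(360, 180))
  expect_equal(ens$phi_deg, c(-170, 170))
  expect_equal(ens$psi_deg, c(0, 180))
  expect_error(torsion_ensemble(c(1, 2), c(1, 2), frame = c(3, 3)),
               class = "gt_validation_error")
})
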