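# Structure/trajectory readers and writers, mapping configs, parameter export.

test_that("PDB structures read with Angstrom-to-nm conversion and element masses", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1  MOL A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  C2  MOL A   1       1.500   0.000   0.000  1.00  0.00           C"),
    f)
  st <- read_structure(f)
  expect_equal(nrow(st$topology$atoms), 2)
  expect_equal(unname(st$frame$coordinates[1, ]), c(0, 0, 0))
  expect_equal(unname(st$frame$coordinates[2, ]), c(0.15, 0, 0))
  expect_equal(st$topology$atoms$mass, rep(12.011, 2))
})

test_that("malformed and empty structure files raise informative parse errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(read_structure(f), "line")

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("ATOM      1  C1  MOL A   1       0.000   xxx", f2)
  expect_error(read_structure(f2), "line 1")

  f3 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "comment", "C 0 0 0", "C 1 bad 0"), f3)
  expect_error(read_trajectory(f3), "frame 1, line 4")

  # unknown element needs a mass override
  f4 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "c", "Qq 0 0 0"), f4)
  expect_error(read_structure(f4), "unknown element")
  st <- read_structure(f4, mass_overrides = list(Qq = 72))
  expect_equal(st$topology$atoms$mass, 72)
})

test_that("multi-frame XYZ reads as a trajectory and round-trips", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "m1", "C 0 0 0", "C 1 0 0",
               "2", "m2", "C 0 0 0", "C 1.2 0 0",
               "2", "m3", "C 0 0 0", "C 1.4 0 0"), f)
  tr <- read_trajectory(f)
  expect_equal(tr$n_frames, 3)
  expect_equal(tr$atom_count, 2)

  tr2 <- gen_bonded_trajectory(two_bead_topology(),
                               list("1-2" = list(mean = 0.47, sigma = 0.02)),
                               7, seed = 4)
  g <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(tr2, g)
  back <- read_trajectory(g)
  expect_equal(back$n_frames, 7)
  expect_lt(max(abs(back$coords - tr2$coords)), 1e-6)  # 1e-6 A precision
  # GRO stores 3 decimals in nm
  g2 <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(tr2, g2)
  back2 <- read_trajectory(g2)
  expect_lt(max(abs(back2$coords - tr2$coords)), 5.1e-4)
})

test_that("trajectories with inconsistent atom counts name the offending frame", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "m1", "C 0 0 0", "C 1 0 0",
               "3", "m2", "C 0 0 0", "C 1 0 0", "C 2 0 0"), f)
  expect_error(read_trajectory(f), "frame 2")
})

test_that("triclinic boxes are rejected explicitly", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t", "1",
               "    1MOL     C1    1   0.000   0.000   0.000",
               "  5.0 5.0 5.0 0.0 0.0 1.3"), f)
  expect_error(read_trajectory(f), "triclinic")
})

test_that("PDB write/read reproduces Angstrom coordinates within 1e-3 A", {
  set.seed(9)
  sc <- gen_stack_scene(3, 0.4, c(90, 270), jitter_sigma = 0.02, seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_scene(sc, f)
  sc2 <- read_scene(f)
  for (i in seq_along(sc$molecules)) {
    errA <- max(abs(sc$molecules[[i]]$coords - sc2$molecules[[i]]$coords)) * 10
    expect_lt(errA, 1e-3)
  }
  expect_true(all(vapply(sc2$molecules, `[[`, character(1), "species") ==
                    "stacker"))
})

test_that("PDB coordinates agree with an independent reader", {
  skip_if_not_installed("bio3d")
  sc <- gen_stack_scene(2, 0.4, 90, jitter_sigma = 0.01, seed = 6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_scene(sc, f)
  pdb <- bio3d::read.pdb(f)
  X <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10
  expect_lt(max(abs(X - do.call(rbind, lapply(sc$molecules, `[[`, "coords")))),
            1e-4)
})

test_that("mapping configs parse with documented defaults and named errors", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("molecule: toy",
               "atoms: [C1, C2, C3, C4, C5, C6]",
               "beads:",
               "  - {name: B1, atoms: [C1, C2, C3]}",
               "  - {name: B2, atoms: [C4, C5, C6]}",
               "bonds: [[B1, B2]]"), f)
  cfg <- load_mapping_config(f)
  expect_length(cfg$scheme, 2)
  expect_equal(nrow(cfg$cg_topology$bond_terms), 1)
  expect_equal(nrow(cfg$cg_topology$angle_terms), 0)
  # weighting defaults to mass (the only silent default)
  expect_true(all(vapply(cfg$scheme, `[[`, character(1), "weighting") == "mass"))

  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("atoms: [C1, C2]",
               "beads:",
               "  - {name: B3, atoms: [C1, X9]}"), f2)
  err <- tryCatch(load_mapping_config(f2), error = conditionMessage)
  expect_match(err, "B3")
  expect_match(err, "X9")

  f3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("atoms: [C1, C2]",
               "beads:",
               "  - {name: B1, atoms: [C1]}",
               "  - {name: B1, atoms: [C2]}"), f3)
  expect_error(load_mapping_config(f3), "duplicate bead name")

  f4 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("atoms: [C1, C2]",
               "beads:",
               "  - {name: B1, atoms: [C1]}",
               "  - {name: B2, atoms: [C2]}",
               "angles: [[B1, B2, B9]]"), f4)
  expect_error(load_mapping_config(f4), "B9")
})

test_that("ITP export writes the documented bonded sections", {
  topo <- two_bead_topology()
  ff <- bond_ff(0.470, 1250)
  txt <- export_parameters(ff, topo, "itp")
  expect_match(txt, "\\[ bonds \\]")
  expect_match(txt, "1\\s+2\\s+1\\s+0\\.4700\\s+1250\\.0")
  # missing angle parameters are an error naming the term
  topo3 <- chain3_topology()
  ff3 <- force_field(bond_params = list(
    "1-2" = harmonic_params(0.47, 1250, "bond"),
    "2-3" = harmonic_params(0.40, 1250, "bond")))
  expect_error(export_parameters(ff3, topo3, "itp"), "1-2-3")
})

test_that("structured serialization round-trips the force field losslessly", {
  ff <- lj_chain_ff()
  topo <- lj_chain_topology()
  txt <- export_parameters(ff, topo, "structured")
  ff2 <- import_parameters(txt)
  for (k in names(ff$bond_params)) {
    expect_identical(ff$bond_params[[k]]$equilibrium,
                     ff2$bond_params[[k]]$equilibrium)
    expect_identical(ff$bond_params[[k]]$force_constant,
                     ff2$bond_params[[k]]$force_constant)
  }
  for (k in names(ff$angle_params)) {
    expect_identical(ff$angle_params[[k]]$force_constant,
                     ff2$angle_params[[k]]$force_constant)
  }
  expect_identical(ff$cutoff, ff2$cutoff)
  expect_equal(sort(names(ff$pair_params)), sort(names(ff2$pair_params)))
  expect_identical(ff$pair_params[["T1:T2"]]$sigma,
                   ff2$pair_params[["T1:T2"]]$sigma)
  # ITP re-import reproduces values to the printed precision
  itp <- export_parameters(ff, topo, "itp")
  ff3 <- import_parameters(itp)
  expect_equal(ff3$bond_params[["1-2"]]$equilibrium, 0.47, tolerance = 1e-3)
  expect_equal(ff3$angle_params[["1-2-3"]]$force_constant, 85, tolerance = 1e-2)
})
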