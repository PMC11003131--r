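# Force evaluation and BAOAB/velocity-Verlet dynamics.

test_that("bond forces are zero at equilibrium and harmonic off it", {
  topo <- two_bead_topology()
  ff <- bond_ff(0.47, 100)
  at_eq <- compute_forces(new_frame(rbind(c(0, 0, 0), c(0.47, 0, 0))), ff, topo)
  expect_equal(at_eq$potential, 0)
  expect_equal(max(abs(at_eq$forces)), 0)

  stretched <- compute_forces(new_frame(rbind(c(0, 0, 0), c(0.57, 0, 0))), ff, topo)
  expect_equal(stretched$potential, 0.5 * 100 * 0.1^2)
  expect_equal(unname(stretched$forces[1, 1]), 10)   # pulled toward the bond
  expect_equal(stretched$forces[1, ], -stretched$forces[2, ])
  expect_equal(sqrt(sum(stretched$forces[2, ]^2)), 10)
})

test_that("angle forces vanish at the equilibrium angle", {
  topo <- chain3_topology()
  ff <- force_field(
    bond_params = list("1-2" = harmonic_params(0.5, 100, "bond"),
                       "2-3" = harmonic_params(0.5, 100, "bond")),
    angle_params = list("1-2-3" = harmonic_params(90, 50, "angle")))
  X <- rbind(c(0.5, 0, 0), c(0, 0, 0), c(0, 0.5, 0))
  out <- compute_forces(new_frame(X), ff, topo)
  expect_equal(out$potential, 0, tolerance = 1e-12)
  expect_lt(max(abs(out$forces)), 1e-9)
})

test_that("analytic forces match central-difference gradients on random configurations", {
  set.seed(201)
  topo <- lj_chain_topology()
  ff <- lj_chain_ff()
  for (rep in 1:20) {
    X <- matrix(runif(12, 0, 1.2), 4, 3)
    while (min(dist(X)) < 0.3) X <- matrix(runif(12, 0, 1.2), 4, 3)
    out <- compute_forces(new_frame(X, box = c(5, 5, 5)), ff, topo)
    Ffd <- fd_forces(X, ff, topo, box = c(5, 5, 5))
    rel <- max(abs(out$forces - Ffd)) / max(max(abs(out$forces)), 1)
    expect_lt(rel, 1e-6)
    expect_lt(max(abs(colSums(out$forces))), 1e-9)  # zero net force
  }
})

test_that("missing parameters are an error naming the term", {
  topo <- chain3_topology()
  ff <- force_field(bond_params = list("1-2" = harmonic_params(0.5, 100, "bond")))
  expect_error(compute_forces(new_frame(matrix(rnorm(9), 3, 3)), ff, topo), "2-3")
})

test_that("n_steps = 0 yields only the initial frame", {
  topo <- two_bead_topology()
  res <- run_dynamics(new_frame(rbind(c(0, 0, 0), c(0.5, 0, 0))), bond_ff(),
                      topo, engine_config(n_steps = 0), masses = c(72, 72))
  expect_equal(res$trajectory$n_frames, 1)
  expect_equal(nrow(res$energies), 1)
})

test_that("identical seed and config give bitwise-identical trajectories", {
  topo <- two_bead_topology()
  fr <- new_frame(rbind(c(0, 0, 0), c(0.5, 0, 0)))
  cfg <- engine_config(n_steps = 2000, friction = 5, seed = 42)
  r1 <- run_dynamics(fr, bond_ff(), topo, cfg, masses = c(72, 72))
  r2 <- run_dynamics(fr, bond_ff(), topo, cfg, masses = c(72, 72))
  expect_identical(r1$trajectory$coords, r2$trajectory$coords)
  cfg2 <- engine_config(n_steps = 2000, friction = 5, seed = 43)
  r3 <- run_dynamics(fr, bond_ff(), topo, cfg2, masses = c(72, 72))
  expect_false(identical(r1$trajectory$coords, r3$trajectory$coords))
})

test_that("NVE total energy is conserved for a harmonic bond", {
  topo <- two_bead_topology()
  fr <- new_frame(rbind(c(0, 0, 0), c(0.52, 0, 0)))
  cfg <- engine_config(n_steps = 2e4, friction = 0, save_interval = 50, seed = 3)
  res <- run_dynamics(fr, bond_ff(0.47, 1250), topo, cfg, masses = c(72, 72))
  E <- res$energies$total
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-4)
})

test_that("Langevin runs thermalize toward the target temperature", {
  topo <- two_bead_topology()
  fr <- new_frame(rbind(c(0, 0, 0), c(0.5, 0, 0)))
  cfg <- engine_config(n_steps = 3e5, friction = 30, save_interval = 50, seed = 7)
  ff <- force_field(bond_params = list("1-2" = harmonic_params(0.47, 1e4, "bond")))
  res <- run_dynamics(fr, ff, topo, cfg, masses = c(36, 36))
  expect_lt(abs(res$average_temperature / 310.15 - 1), 0.05)
})

test_that("kinetic temperature follows the 3N-3 convention", {
  expect_equal(kinetic_temperature(matrix(0, 3, 3), rep(1, 3)), 0)
  v <- 0.3
  # two unit masses, opposite velocities: COM at rest, sum m v^2 = 2 v^2,
  # Ndof = 3 -> T = 2 v^2 / (3 kB)
  T2 <- kinetic_temperature(rbind(c(v, 0, 0), c(-v, 0, 0)), c(1, 1))
  expect_equal(T2, 2 * v^2 / (3 * kB))
  T4 <- kinetic_temperature(rbind(c(2 * v, 0, 0), c(-2 * v, 0, 0)), c(1, 1))
  expect_equal(T4, 4 * T2)
  expect_error(kinetic_temperature(matrix(1, 1, 3), 1), "at least 2")
})

test_that("LJ pairs beyond the cutoff contribute nothing", {
  topo <- cg_topology(list(bead_definition("A", 1, "T1"),
                           bead_definition("B", 2, "T1")))
  ff <- force_field(pair_params = list("T1:T1" = list(epsilon = 2, sigma = 0.4)),
                    cutoff = 1.1)
  far <- compute_forces(new_frame(rbind(c(0, 0, 0), c(1.2, 0, 0))), ff, topo)
  expect_equal(far$potential, 0)
  near <- compute_forces(new_frame(rbind(c(0, 0, 0), c(0.5, 0, 0))), ff, topo)
  s6 <- (0.4 / 0.5)^6
  expect_equal(near$potential, 4 * 2 * (s6^2 - s6), tolerance = 1e-12)
})
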