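# Iterative distribution-matching refinement.

measure_targets <- function(ff, topo, masses, n_steps = 4e5, seed = 900) {
  cfg <- engine_config(n_steps = n_steps, friction = 20, save_interval = 20,
                       seed = seed)
  res <- run_dynamics(build_initial_frame(topo, ff), ff, topo, cfg, masses)
  traj <- res$trajectory
  traj <- new_trajectory(traj$coords[, , -1, drop = FALSE],
                         times = traj$times[-1])
  out <- list()
  bt <- topo$bond_terms
  for (r in seq_len(nrow(bt))) {
    k <- paste(sort(bt[r, ]), collapse = "-")
    out[[k]] <- summarize_distribution(measure_bond_series(traj, bt[r, ]),
                                       kind = "bond", term = k)
  }
  at <- topo$angle_terms
  for (r in seq_len(nrow(at))) {
    tr <- at[r, ]
    if (tr[1] > tr[3]) tr <- rev(tr)
    k <- paste(tr, collapse = "-")
    out[[k]] <- summarize_distribution(measure_angle_series(traj, at[r, ]),
                                       kind = "angle", term = k)
  }
  out
}

test_that("max_iterations = 0 returns the initial force field unrefined", {
  topo <- chain3_topology()
  truth <- benchmark_truth()
  targets <- measure_targets(truth, topo, rep(72, 3), n_steps = 1e4)
  rep0 <- refine_parameters(targets, truth, topo,
                            engine_config(n_steps = 1e3, friction = 20),
                            rep(72, 3), max_iterations = 0)
  expect_false(rep0$converged)
  expect_equal(rep0$iterations_run, 0)
  expect_identical(rep0$final_force_field$bond_params[["1-2"]]$force_constant,
                   truth$bond_params[["1-2"]]$force_constant)
  expect_equal(nrow(rep0$divergence_history), 0)
})

test_that("starting at the truth converges in one iteration", {
  topo <- chain3_topology()
  truth <- benchmark_truth()
  masses <- rep(72, 3)
  targets <- measure_targets(truth, topo, masses, n_steps = 4e5)
  cfg <- engine_config(n_steps = 4e5, friction = 20, save_interval = 20, seed = 5)
  rep1 <- refine_parameters(targets, truth, topo, cfg, masses,
                            threshold = 0.02, max_iterations = 5)
  expect_true(rep1$converged)
  expect_equal(rep1$iterations_run, 1)
  expect_true(all(rep1$divergence_history[1, ] <= 0.02))
  # report integrity: the converged flag agrees with the recorded divergences
  expect_identical(rep1$converged,
                   all(rep1$divergence_history[nrow(rep1$divergence_history), ]
                       <= rep1$threshold))
})

test_that("a perturbed force field is recovered by moment matching", {
  topo <- chain3_topology()
  truth <- benchmark_truth()
  masses <- rep(72, 3)
  targets <- measure_targets(truth, topo, masses, n_steps = 8e5, seed = 901)
  init <- perturb_ff(truth)
  cfg <- engine_config(n_steps = 6e5, friction = 20, save_interval = 20, seed = 31)
  rep <- refine_parameters(targets, init, topo, cfg, masses,
                           threshold = 0.02, max_iterations = 10)
  expect_true(rep$converged)
  expect_lte(rep$iterations_run, 10)
  for (k in names(truth$bond_params)) {
    expect_lt(abs(rep$final_force_field$bond_params[[k]]$force_constant /
                    truth$bond_params[[k]]$force_constant - 1), 0.05)
    expect_lt(abs(rep$final_force_field$bond_params[[k]]$equilibrium /
                    truth$bond_params[[k]]$equilibrium - 1), 0.01)
  }
})

test_that("median divergence is non-increasing across the recovery benchmark", {
  topo <- chain3_topology()
  truth <- benchmark_truth()
  masses <- rep(72, 3)
  n_iter <- 4
  med <- matrix(NA_real_, 5, n_iter)
  for (s in 1:5) {
    targets <- measure_targets(truth, topo, masses, n_steps = 2e5,
                               seed = 950 + s)
    cfg <- engine_config(n_steps = 2e5, friction = 20, save_interval = 20,
                         seed = s)
    rep <- refine_parameters(targets, perturb_ff(truth), topo, cfg, masses,
                             threshold = 1e-9, max_iterations = n_iter)
    med[s, ] <- apply(rep$divergence_history, 1, stats::median)
  }
  pooled <- apply(med, 2, stats::median)  # median across seeds per iteration
  expect_true(all(diff(pooled) <= 1e-6))
})

test_that("at a Boltzmann fixed point the expected parameter update is zero", {
  topo <- chain3_topology()
  truth <- benchmark_truth()
  masses <- rep(72, 3)
  targets <- measure_targets(truth, topo, masses, n_steps = 8e5, seed = 970)
  cfg <- engine_config(n_steps = 8e5, friction = 20, save_interval = 20, seed = 8)
  # forbid early stopping so exactly one update is applied
  rep <- refine_parameters(targets, truth, topo, cfg, masses,
                           threshold = 1e-9, max_iterations = 1)
  for (k in names(truth$bond_params)) {
    p0 <- truth$bond_params[[k]]
    p1 <- rep$final_force_field$bond_params[[k]]
    sg <- sqrt(kB * 310.15 / p0$force_constant)
    expect_lt(abs(p1$equilibrium - p0$equilibrium), 4 * sg / sqrt(2000))
    expect_lt(abs(p1$force_constant / p0$force_constant - 1), 0.05)
  }
})

test_that("engine failures propagate with the iteration index", {
  topo <- chain3_topology()
  truth <- benchmark_truth()
  targets <- measure_targets(truth, topo, rep(72, 3), n_steps = 1e4)
  # absurd timestep makes the integrator blow up
  cfg <- engine_config(n_steps = 1e4, timestep = 1, friction = 0, seed = 2)
  expect_error(refine_parameters(targets, truth, topo, cfg, rep(72, 3)),
               "iteration 1")
})
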