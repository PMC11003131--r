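# R interface to the compiled BAOAB Langevin / velocity-Verlet engine.

#' Engine configuration
#'
#' @param n_steps number of integration steps (>= 0).
#' @param timestep integration step in ps (default 0.001 ps = 1 fs).
#' @param temperature target temperature, Kelvin (default 310.15 K = 37 C).
#' @param friction Langevin friction in ps^-1; `0` gives NVE velocity
#'   Verlet.
#' @param seed RNG seed used for initial velocities and the Langevin noise.
#' @param save_interval record every this many steps (the initial frame is
#'   always recorded).
#' @param box optional orthorhombic box, nm.
#' @param neighbor_update_interval steps between nonbonded pair-list
#'   rebuilds (default 20).
#' @return an object of class `engine_config`.
#' @export
engine_config <- function(n_steps, timestep = 0.001, temperature = 310.15,
                          friction = 0, seed = 1L, save_interval = 10L,
                          box = NULL, neighbor_update_interval = 20L) {
  .assert(timestep > 0, "timestep must be > 0")
  .assert(n_steps >= 0, "n_steps must be >= 0")
  .assert(temperature >= 0, "temperature must be >= 0")
  .assert(friction >= 0, "friction must be >= 0")
  .assert(save_interval >= 1, "save_interval must be >= 1")
  .assert(neighbor_update_interval >= 1, "neighbor_update_interval must be >= 1")
  if (!is.null(box)) {
    box <- as.numeric(box)
    .assert(length(box) == 3 && all(box > 0), "box must be 3 positive edges")
  }
  structure(list(n_steps = as.integer(n_steps), timestep = timestep,
                 temperature = temperature, friction = friction,
                 seed = as.integer(seed), save_interval = as.integer(save_interval),
                 box = box,
                 neighbor_update_interval = as.integer(neighbor_update_interval)),
            class = "engine_config")
}

# assemble flat parameter arrays for the C++ core; errors on missing terms.
engine_arrays <- function(ff, topology) {
  pars <- collect_params(ff, topology)
  nbd <- length(topology$beads)
  bt <- topology$bond_terms
  at <- topology$angle_terms
  b0 <- vapply(pars$bond, `[[`, numeric(1), "equilibrium")
  kb <- vapply(pars$bond, `[[`, numeric(1), "force_constant")
  th0 <- vapply(pars$angle, `[[`, numeric(1), "equilibrium") * pi / 180
  ka <- vapply(pars$angle, `[[`, numeric(1), "force_constant")
  eps <- matrix(0, nbd, nbd)
  sig <- matrix(1, nbd, nbd)
  if (!is.null(ff$pair_params) && length(ff$pair_params) > 0) {
    types <- vapply(topology$beads, `[[`, character(1), "bead_type")
    for (i in seq_len(nbd)) for (j in seq_len(nbd)) {
      p <- ff$pair_params[[pair_key(types[i], types[j])]]
      if (!is.null(p)) { eps[i, j] <- p$epsilon; sig[i, j] <- p$sigma }
    }
    # standard 1-2 and 1-3 exclusions: beads joined by a bond or an angle
    # term do not interact through LJ
    for (r in seq_len(nrow(bt))) {
      eps[bt[r, 1], bt[r, 2]] <- 0; eps[bt[r, 2], bt[r, 1]] <- 0
    }
    for (r in seq_len(nrow(at))) {
      eps[at[r, 1], at[r, 3]] <- 0; eps[at[r, 3], at[r, 1]] <- 0
      eps[at[r, 1], at[r, 2]] <- 0; eps[at[r, 2], at[r, 1]] <- 0
      eps[at[r, 2], at[r, 3]] <- 0; eps[at[r, 3], at[r, 2]] <- 0
    }
  }
  list(bonds = matrix(as.integer(bt - 1L), ncol = 2), b0 = as.numeric(b0),
       kb = as.numeric(kb),
       angles = matrix(as.integer(at - 1L), ncol = 3), th0 = as.numeric(th0),
       ka = as.numeric(ka), eps = eps, sig = sig)
}

#' Compute forces and potential energy of a CG configuration
#'
#' Bond terms contribute `0.5 k (r - r0)^2`, angle terms
#' `0.5 k (theta - theta0)^2` (theta in radians) with the standard
#' three-body gradient, and Lennard-Jones 12-6 pairs are truncated
#' (unshifted) at the force-field cutoff. Beads joined by a bond or angle
#' term are excluded from LJ. Total force sums to zero.
#'
#' @param cg_frame a bead `cg_frame`, nm.
#' @param ff a [force_field()] covering every term of `cg_topology`.
#' @param cg_topology the [cg_topology()].
#' @return `list(forces =, potential =)`: an n x 3 matrix in
#'   kJ mol^-1 nm^-1 and the energy in kJ mol^-1.
#' @export
compute_forces <- function(cg_frame, ff, cg_topology) {
  .assert(inherits(cg_frame, "cg_frame"), "cg_frame must be a cg_frame")
  .assert(nrow(cg_frame$coordinates) == length(cg_topology$beads),
          "frame bead count does not match topology")
  a <- engine_arrays(ff, cg_topology)
  .cg_eval_cpp(cg_frame$coordinates, a$bonds, a$b0, a$kb, a$angles, a$th0,
               a$ka, a$eps, a$sig, ff$cutoff,
               if (is.null(cg_frame$box)) numeric(0) else cg_frame$box)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Component-wise Gaussian with variance `kB T / m`, mass-weighted
#' centre-of-mass drift removed. Uses the current RNG state.
#'
#' @param masses bead masses, amu.
#' @param temperature Kelvin.
#' @return n x 3 velocity matrix, nm/ps.
#' @export
maxwell_velocities <- function(masses, temperature) {
  n <- length(masses)
  if (temperature <= 0) return(matrix(0, n, 3))
  v <- matrix(rnorm(n * 3), n, 3) * sqrt(KB_KJ_PER_MOL_K * temperature / masses)
  vcm <- colSums(v * masses) / sum(masses)
  sweep(v, 2, vcm)
}

#' Run CG dynamics
#'
#' BAOAB-splitting Langevin integration; `friction = 0` reduces exactly to
#' velocity Verlet (NVE). Initial velocities are drawn from the
#' Maxwell-Boltzmann distribution at `config$temperature` using
#' `config$seed` unless supplied. Frames are recorded every
#' `config$save_interval` steps, including the initial frame. Identical seed
#' and config give bitwise-identical trajectories.
#'
#' @param initial_frame a bead `cg_frame` (its box, or `config$box`, sets
#'   the periodic boundaries; `config$box` wins when both are present).
#' @param ff a [force_field()].
#' @param cg_topology the [cg_topology()].
#' @param config an [engine_config()].
#' @param masses bead masses, amu (positive).
#' @param velocities optional n x 3 initial velocities, nm/ps.
#' @return an object of class `dynamics_result`: `trajectory`
#'   (a `cg_trajectory`), `energies` (data.frame `step`, `time`,
#'   `potential`, `kinetic`, `total`, `temperature`), `final_velocities`,
#'   and `average_temperature` (time average over every step, K).
#' @export
run_dynamics <- function(initial_frame, ff, cg_topology, config, masses,
                         velocities = NULL) {
  .assert(inherits(config, "engine_config"), "config must be an engine_config")
  .assert(all(masses > 0), "masses must be positive")
  n <- length(cg_topology$beads)
  .assert(length(masses) == n, "need one mass per bead")
  .assert(nrow(initial_frame$coordinates) == n,
          "frame bead count does not match topology")
  .assert(all(is.finite(initial_frame$coordinates)),
          "initial coordinates must be finite")
  a <- engine_arrays(ff, cg_topology)
  box <- if (!is.null(config$box)) config$box else initial_frame$box

  # local, restorable RNG scope so a run is reproducible from its seed
  # without clobbering the caller's stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  if (is.null(velocities)) velocities <- maxwell_velocities(masses, config$temperature)
  .assert(nrow(velocities) == n && ncol(velocities) == 3,
          "velocities must be n x 3")

  res <- .cg_run_cpp(initial_frame$coordinates, velocities, masses,
                     a$bonds, a$b0, a$kb, a$angles, a$th0, a$ka,
                     a$eps, a$sig, ff$cutoff,
                     if (is.null(box)) numeric(0) else box,
                     config$timestep, config$n_steps, config$friction,
                     KB_KJ_PER_MOL_K * config$temperature,
                     config$save_interval, config$neighbor_update_interval,
                     initial_frame$time)

  traj <- new_trajectory(res$coords, times = res$times,
                         box = if (is.null(box)) NULL else
                           matrix(box, length(res$times), 3, byrow = TRUE))
  energies <- data.frame(step = res$steps, time = res$times,
                         potential = res$potential, kinetic = res$kinetic,
                         total = res$potential + res$kinetic)
  ndof <- 3 * n - 3
  energies$temperature <- if (ndof > 0)
    2 * res$kinetic / (ndof * KB_KJ_PER_MOL_K) else NA_real_
  structure(list(trajectory = traj, energies = energies,
                 final_velocities = res$final_velocities,
                 average_temperature = res$avg_temperature,
                 config = config),
            class = "dynamics_result")
}

#' @export
print.dynamics_result <- function(x, ...) {
  cat(sprintf("dynamics_result: %d saved frames, <T> = %.2f K, dt = %g ps\n",
              x$trajectory$n_frames,
              x$average_temperature, x$config$timestep))
  invisible(x)
}

#' Instantaneous kinetic temperature
#'
#' `T = sum(m v'^2) / (Ndof kB)` with the mass-weighted centre-of-mass
#' velocity removed and `Ndof = 3N - 3`.
#'
#' @param velocities n x 3 matrix, nm/ps.
#' @param masses bead masses, amu.
#' @return temperature in Kelvin.
#' @export
kinetic_temperature <- function(velocities, masses) {
  velocities <- as.matrix(velocities)
  .assert(nrow(velocities) == length(masses),
          "velocity count must equal mass count")
  n <- length(masses)
  if (n < 2) stop("kinetic temperature needs at least 2 particles (Ndof <= 0)",
                  call. = FALSE)
  vcm <- colSums(velocities * masses) / sum(masses)
  vp <- sweep(velocities, 2, vcm)
  sum(masses * vp^2) / ((3 * n - 3) * KB_KJ_PER_MOL_K)
}
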