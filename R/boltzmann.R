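# Harmonic Boltzmann inversion: a Gaussian equilibrium marginal with mean mu
# and variance s2 at temperature T is the Boltzmann density of the harmonic
# potential U(x) = 0.5 * k * (x - mu)^2 with k = kB * T / s2.

#' Fit a harmonic bond potential by Boltzmann inversion
#'
#' @param dist a `bonded_distribution` of kind `"bond"` (nm samples).
#' @param thermo a [thermo_state()].
#' @return [harmonic_params()] with `equilibrium = mean(dist)` (nm) and
#'   `force_constant = kB * T / variance(dist)` (kJ mol^-1 nm^-2).
#' @export
fit_bond_harmonic <- function(dist, thermo = thermo_state()) {
  .assert(inherits(dist, "bonded_distribution") && dist$kind == "bond",
          "dist must be a bond bonded_distribution")
  .assert(inherits(thermo, "thermo_state"), "thermo must be a thermo_state")
  .assert(all(dist$samples >= 0), "bond samples must be non-negative")
  if (!(dist$variance > 0))
    stop("degenerate distribution: zero variance", call. = FALSE)
  harmonic_params(equilibrium = dist$mean,
                  force_constant = thermo$kB * thermo$temperature / dist$variance,
                  kind = "bond")
}

#' Fit a harmonic angle potential by Boltzmann inversion
#'
#' The equilibrium angle is reported in degrees; the force constant uses the
#' variance expressed in rad^2, matching the ITP funct-2 convention. With
#' `jacobian_correct = TRUE` the samples are reweighted by `1 / sin(theta)`
#' before computing the moments, removing the volume-element bias of angle
#' marginals sampled in Cartesian space; weighted moments use reliability
#' weights with the standard unbiased variance correction.
#'
#' @param dist a `bonded_distribution` of kind `"angle"` (degree samples).
#' @param thermo a [thermo_state()].
#' @param jacobian_correct reweight by `1/sin(theta)` (default `FALSE`;
#'   samples touching 0 or 180 degrees are an error because the weight
#'   diverges).
#' @return [harmonic_params()] with equilibrium in degrees and
#'   `force_constant = kB * T / variance_rad2` (kJ mol^-1 rad^-2).
#' @export
fit_angle_harmonic <- function(dist, thermo = thermo_state(),
                               jacobian_correct = FALSE) {
  .assert(inherits(dist, "bonded_distribution") && dist$kind == "angle",
          "dist must be an angle bonded_distribution")
  .assert(inherits(thermo, "thermo_state"), "thermo must be a thermo_state")
  x <- dist$samples
  if (jacobian_correct) {
    if (any(x <= 0 | x >= 180))
      stop("jacobian_correct: samples touching 0 or 180 degrees (1/sin weight diverges)",
           call. = FALSE)
    w <- 1 / sin(x * pi / 180)
    sw <- sum(w)
    mu <- sum(w * x) / sw
    v <- sum(w * (x - mu)^2) / (sw - sum(w^2) / sw)
  } else {
    mu <- dist$mean
    v <- dist$variance
  }
  if (!(v > 0)) stop("degenerate distribution: zero variance", call. = FALSE)
  v_rad <- v * (pi / 180)^2
  harmonic_params(equilibrium = mu,
                  force_constant = thermo$kB * thermo$temperature / v_rad,
                  kind = "angle")
}

#' Boltzmann-invert every term of a measured trajectory
#'
#' Convenience wrapper: measures all bonded terms of `topology` on a bead
#' trajectory, then fits each by Boltzmann inversion.
#'
#' @param cg_traj a bead `cg_trajectory`.
#' @param topology the [cg_topology()].
#' @param thermo a [thermo_state()].
#' @param jacobian_correct forwarded to [fit_angle_harmonic()].
#' @param cutoff nonbonded cutoff stored in the returned force field, nm.
#' @return a [force_field()] with one harmonic term per topology term.
#' @export
fit_force_field <- function(cg_traj, topology, thermo = thermo_state(),
                            jacobian_correct = FALSE, cutoff = 1.1) {
  dists <- measure_all_terms(cg_traj, topology)
  tk <- term_keys(topology)
  bp <- lapply(dists[tk$bonds], fit_bond_harmonic, thermo = thermo)
  ap <- lapply(dists[tk$angles], fit_angle_harmonic, thermo = thermo,
               jacobian_correct = jacobian_correct)
  force_field(bond_params = bp, angle_params = ap, cutoff = cutoff)
}
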