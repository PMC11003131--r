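# Projection of atomistic coordinates onto bead coordinates.

bead_weights <- function(bead, topology) {
  if (bead$weighting == "mass") topology$atoms$mass[bead$member_atoms]
  else rep(1, length(bead$member_atoms))
}

#' Map one atomistic frame onto bead coordinates
#'
#' Each bead is the mass-weighted (default) or unweighted mean of its member
#' atoms. Under periodic boundaries the member atoms are first made whole by
#' minimum-image unwrapping relative to the bead's first member atom, so a
#' molecule straddling the box edge does not produce a bead in the box
#' interior.
#'
#' @param frame a `cg_frame` of atomistic coordinates, nm.
#' @param scheme list of [bead_definition()]s.
#' @param topology the [molecular_topology()] providing atom masses.
#' @return a `cg_frame` of bead coordinates (same box and time).
#' @export
map_frame <- function(frame, scheme, topology) {
  X <- frame$coordinates
  .assert(all(is.finite(X)), "frame has non-finite coordinates")
  out <- matrix(0, length(scheme), 3)
  for (b in seq_along(scheme)) {
    bead <- scheme[[b]]
    .assert(max(bead$member_atoms) <= nrow(X),
            "bead '%s': member atom out of range", bead$bead_name)
    w <- bead_weights(bead, topology)
    ref <- X[bead$member_atoms[1], ]
    M <- X[bead$member_atoms, , drop = FALSE]
    D <- sweep(M, 2, ref)
    D <- min_image(D, frame$box)
    out[b, ] <- ref + colSums(D * w) / sum(w)
  }
  new_frame(out, box = frame$box, time = frame$time)
}

#' Map an atomistic trajectory onto bead coordinates
#'
#' Applies [map_frame()] to every frame, preserving frame count, times and
#' boxes. Vectorized across frames per bead member.
#'
#' @param traj an atomistic `cg_trajectory`, nm.
#' @param scheme list of [bead_definition()]s.
#' @param topology the [molecular_topology()] providing atom masses.
#' @return a bead-coordinate `cg_trajectory`.
#' @export
map_trajectory <- function(traj, scheme, topology) {
  .assert(inherits(traj, "cg_trajectory"), "traj must be a cg_trajectory")
  n <- traj$atom_count
  nf <- traj$n_frames
  out <- array(0, dim = c(length(scheme), 3, nf))
  boxes <- traj$box  # nf x 3 or NULL
  for (b in seq_along(scheme)) {
    bead <- scheme[[b]]
    .assert(max(bead$member_atoms) <= n,
            "bead '%s': member atom out of range", bead$bead_name)
    w <- bead_weights(bead, topology)
    ref <- traj$coords[bead$member_atoms[1], , , drop = FALSE]  # 1 x 3 x nf
    acc <- array(0, dim = c(1, 3, nf))
    for (a in seq_along(bead$member_atoms)) {
      d <- traj$coords[bead$member_atoms[a], , , drop = FALSE] - ref
      if (!is.null(boxes)) {
        for (k in 1:3)
          d[1, k, ] <- d[1, k, ] - boxes[, k] * round(d[1, k, ] / boxes[, k])
      }
      acc <- acc + w[a] * d
    }
    out[b, , ] <- ref[1, , ] + acc[1, , ] / sum(w)
  }
  if (any(!is.finite(out)))
    stop("mapping produced non-finite bead coordinates", call. = FALSE)
  tr <- new_trajectory(out, times = traj$times, box = boxes)
  attr(tr, "atom_names") <- vapply(scheme, `[[`, character(1), "bead_name")
  tr
}
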