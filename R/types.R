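#' cgstack: coarse-grained parametrization and stacking analysis
#'
#' Parametrize coarse-grained models of planar stacking molecules by
#' trajectory mapping and Boltzmann inversion, refine them against a
#' built-in Langevin engine, and analyse aggregation geometry (clusters,
#' rod/sphere shape, inter-plane rotations, additive placement).
#'
#' Internal units are nm, ps, amu, kJ/mol and Kelvin; angles are degrees at
#' every interface and radians only inside angle arithmetic. All atom and
#' bead indices are 1-based.
#'
#' @useDynLib cgstack, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif var setNames
#' @importFrom utils head read.table write.table
#' @keywords internal
"_PACKAGE"

#' Boltzmann constant in kJ mol^-1 K^-1
#'
#' Fixed, not configurable: a single constant prevents silent unit drift
#' between the fitting and simulation layers.
#' @export
KB_KJ_PER_MOL_K <- 0.0083144621

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
}

#' Construct a coordinate frame
#'
#' A single snapshot of a molecular system: one row of nm coordinates per
#' atom (or bead), an optional orthorhombic box and a time stamp.
#'
#' @param coordinates numeric matrix, n x 3, nm.
#' @param box optional numeric vector of three positive orthorhombic edge
#'   lengths in nm; `NULL` for open boundaries. Triclinic boxes are not
#'   supported.
#' @param time time stamp in ps.
#' @return an object of class `cg_frame`.
#' @export
new_frame <- function(coordinates, box = NULL, time = 0) {
  coordinates <- as.matrix(coordinates)
  .assert(ncol(coordinates) == 3, "coordinates must be an n x 3 matrix")
  .assert(all(is.finite(coordinates)), "coordinates must all be finite")
  if (!is.null(box)) {
    box <- as.numeric(box)
    .assert(length(box) == 3 && all(is.finite(box)) && all(box > 0),
            "box must be three positive orthorhombic edge lengths (nm)")
  }
  .assert(is.finite(time), "time must be finite")
  structure(list(coordinates = coordinates, box = box, time = as.numeric(time)),
            class = "cg_frame")
}

#' Construct a trajectory from a coordinate array
#'
#' Coordinates are stored as an `n_atoms x 3 x n_frames` array for fast
#' per-term time-series extraction; [get_frame()] recovers individual
#' `cg_frame` objects.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames`, nm.
#' @param times numeric vector of non-decreasing frame times, ps.
#' @param box `NULL`, a length-3 vector (constant box) or an
#'   `n_frames x 3` matrix of per-frame boxes, nm.
#' @return an object of class `cg_trajectory`.
#' @export
new_trajectory <- function(coords, times = NULL, box = NULL) {
  .assert(length(dim(coords)) == 3 && dim(coords)[2] == 3,
          "coords must be an n_atoms x 3 x n_frames array")
  nf <- dim(coords)[3]
  if (is.null(times)) times <- seq_len(nf) - 1
  .assert(length(times) == nf, "times must have one entry per frame")
  .assert(!is.unsorted(times), "frame times must be non-decreasing")
  .assert(all(is.finite(coords)), "trajectory coordinates must be finite")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
    .assert(nrow(box) == nf && ncol(box) == 3, "box must be n_frames x 3")
    .assert(all(box > 0), "box edges must be positive")
  }
  structure(list(coords = coords, times = as.numeric(times), box = box,
                 atom_count = dim(coords)[1], n_frames = nf),
            class = "cg_trajectory")
}

#' Assemble a trajectory from a list of frames
#'
#' @param frames list of `cg_frame` objects with a constant atom count.
#' @return a `cg_trajectory`.
#' @export
trajectory_from_frames <- function(frames) {
  .assert(length(frames) >= 1, "need at least one frame")
  n <- nrow(frames[[1]]$coordinates)
  for (i in seq_along(frames)) {
    .assert(inherits(frames[[i]], "cg_frame"), "frames must be cg_frame objects")
    .assert(nrow(frames[[i]]$coordinates) == n,
            "frame %d has %d atoms, expected %d", i,
            nrow(frames[[i]]$coordinates), n)
  }
  coords <- array(0, dim = c(n, 3, length(frames)))
  boxes <- NULL
  if (!is.null(frames[[1]]$box)) boxes <- matrix(0, length(frames), 3)
  for (i in seq_along(frames)) {
    coords[, , i] <- frames[[i]]$coordinates
    if (!is.null(boxes)) {
      .assert(!is.null(frames[[i]]$box), "mixed boxed and unboxed frames")
      boxes[i, ] <- frames[[i]]$box
    }
  }
  new_trajectory(coords, times = vapply(frames, `[[`, numeric(1), "time"),
                 box = boxes)
}

#' Extract one frame of a trajectory
#'
#' @param traj a `cg_trajectory`.
#' @param i frame index (1-based).
#' @return a `cg_frame`.
#' @export
get_frame <- function(traj, i) {
  .assert(inherits(traj, "cg_trajectory"), "traj must be a cg_trajectory")
  .assert(i >= 1 && i <= traj$n_frames, "frame index %d out of range", i)
  new_frame(traj$coords[, , i, drop = FALSE][, , 1],
            box = if (is.null(traj$box)) NULL else traj$box[i, ],
            time = traj$times[i])
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d atoms, %d frames, t = [%g, %g] ps%s\n",
              x$atom_count, x$n_frames, x$times[1], x$times[x$n_frames],
              if (is.null(x$box)) ", no box" else ", boxed"))
  invisible(x)
}

#' Construct an atomistic molecular topology
#'
#' Describes one molecule (or a set of molecules sharing an atom list): atom
#' names, elements, masses and bonds, plus the planar-core annotation used by
#' the stacking analysis.
#'
#' @param molecule_name label.
#' @param atoms data.frame with columns `name`, `element`, `mass` (amu) and
#'   optionally `molecule_id` (integer tag grouping atoms into molecules;
#'   defaults to 1).
#' @param bonds integer matrix, n x 2, 1-based atom index pairs (may be
#'   empty).
#' @param core_atoms integer vector of atom indices marking the planar core,
#'   or `NULL`.
#' @param reference_axis ordered pair of atom indices defining the in-plane
#'   orientation vector (tail, head), or `NULL`. Both must belong to
#'   `core_atoms` when a core is declared.
#' @return an object of class `mol_topology`.
#' @export
molecular_topology <- function(molecule_name, atoms, bonds = NULL,
                               core_atoms = NULL, reference_axis = NULL) {
  .assert(is.data.frame(atoms) && all(c("name", "element", "mass") %in% names(atoms)),
          "atoms must be a data.frame with name, element, mass")
  if (is.null(atoms$molecule_id)) atoms$molecule_id <- 1L
  n <- nrow(atoms)
  .assert(n >= 1, "topology needs at least one atom")
  .assert(all(nzchar(atoms$name)), "atom names must be non-empty")
  .assert(all(atoms$mass > 0), "atom masses must be strictly positive")
  .assert(all(atoms$molecule_id >= 0), "molecule_id must be >= 0")
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    .assert(all(bonds >= 1 & bonds <= n), "bond index out of range")
    .assert(all(bonds[, 1] != bonds[, 2]), "self-bond not allowed")
  }
  if (!is.null(core_atoms)) {
    core_atoms <- as.integer(core_atoms)
    .assert(all(core_atoms >= 1 & core_atoms <= n), "core atom index out of range")
  }
  if (!is.null(reference_axis)) {
    reference_axis <- as.integer(reference_axis)
    .assert(length(reference_axis) == 2 && reference_axis[1] != reference_axis[2],
            "reference_axis must be two distinct atom indices")
    .assert(all(reference_axis >= 1 & reference_axis <= n),
            "reference_axis index out of range")
    if (!is.null(core_atoms) && length(core_atoms) > 0)
      .assert(all(reference_axis %in% core_atoms),
              "reference_axis atoms must belong to core_atoms")
  }
  structure(list(molecule_name = molecule_name, atoms = atoms, bonds = bonds,
                 core_atoms = core_atoms, reference_axis = reference_axis),
            class = "mol_topology")
}

#' Define one coarse-grained bead
#'
#' @param bead_name label, unique within a scheme.
#' @param member_atoms non-empty vector of unique 1-based atom indices.
#' @param bead_type label used for nonbonded parameter lookup.
#' @param weighting `"mass"` (mass-weighted mean, the default) or
#'   `"geometric"` (unweighted mean).
#' @return an object of class `bead_definition`.
#' @export
bead_definition <- function(bead_name, member_atoms, bead_type = bead_name,
                            weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  member_atoms <- as.integer(member_atoms)
  .assert(length(member_atoms) >= 1, "bead '%s': member_atoms must be non-empty",
          bead_name)
  .assert(!anyDuplicated(member_atoms), "bead '%s': duplicate member atoms",
          bead_name)
  .assert(all(member_atoms >= 1), "bead '%s': atom index out of range", bead_name)
  structure(list(bead_name = bead_name, bead_type = bead_type,
                 member_atoms = member_atoms, weighting = weighting),
            class = "bead_definition")
}

#' Construct a coarse-grained topology
#'
#' @param beads ordered list of [bead_definition()] objects.
#' @param bond_terms integer matrix, n x 2, 1-based bead index pairs.
#' @param angle_terms integer matrix, n x 3, ordered bead index triples
#'   (vertex in the middle).
#' @return an object of class `cg_topology`.
#' @export
cg_topology <- function(beads, bond_terms = NULL, angle_terms = NULL) {
  .assert(length(beads) >= 1, "need at least one bead")
  for (b in beads) .assert(inherits(b, "bead_definition"),
                           "beads must be bead_definition objects")
  nm <- vapply(beads, `[[`, character(1), "bead_name")
  .assert(!anyDuplicated(nm), "duplicate bead name '%s'", nm[duplicated(nm)][1])
  nb <- length(beads)
  if (is.null(bond_terms)) bond_terms <- matrix(integer(0), 0, 2)
  bond_terms <- matrix(as.integer(bond_terms), ncol = 2)
  if (nrow(bond_terms) > 0) {
    .assert(all(bond_terms >= 1 & bond_terms <= nb), "bond term index out of range")
    .assert(all(bond_terms[, 1] != bond_terms[, 2]), "self-bond not allowed")
  }
  if (is.null(angle_terms)) angle_terms <- matrix(integer(0), 0, 3)
  angle_terms <- matrix(as.integer(angle_terms), ncol = 3)
  if (nrow(angle_terms) > 0) {
    .assert(all(angle_terms >= 1 & angle_terms <= nb),
            "angle term index out of range")
    ok <- apply(angle_terms, 1, function(t) length(unique(t)) == 3)
    .assert(all(ok), "angle terms need three distinct bead indices")
  }
  structure(list(beads = beads, bond_terms = bond_terms,
                 angle_terms = angle_terms),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("cg_topology: %d beads, %d bond terms, %d angle terms\n",
              length(x$beads), nrow(x$bond_terms), nrow(x$angle_terms)))
  invisible(x)
}

# canonical string keys for bonded terms: bonds i-j with i<j, angles i-j-k
# with the vertex j fixed and i<k.
bond_key <- function(i, j) paste(min(i, j), max(i, j), sep = "-")

angle_key <- function(i, j, k) {
  if (i > k) { tmp <- i; i <- k; k <- tmp }
  paste(i, j, k, sep = "-")
}

term_keys <- function(topology) {
  bk <- apply(topology$bond_terms, 1, function(t) bond_key(t[1], t[2]))
  ak <- if (nrow(topology$angle_terms) > 0)
    apply(topology$angle_terms, 1, function(t) angle_key(t[1], t[2], t[3]))
  else character(0)
  list(bonds = as.character(bk), angles = as.character(ak))
}

#' Harmonic bonded parameters
#'
#' @param equilibrium equilibrium value: nm for bonds, degrees in (0, 180]
#'   for angles.
#' @param force_constant force constant, strictly positive:
#'   kJ mol^-1 nm^-2 for bonds, kJ mol^-1 rad^-2 for angles.
#' @param kind `"bond"` or `"angle"`.
#' @return an object of class `harmonic_params`.
#' @export
harmonic_params <- function(equilibrium, force_constant,
                            kind = c("bond", "angle")) {
  kind <- match.arg(kind)
  .assert(is.finite(force_constant) && force_constant > 0,
          "force_constant must be > 0")
  if (kind == "bond") {
    .assert(is.finite(equilibrium) && equilibrium > 0,
            "bond equilibrium must be > 0 (nm)")
  } else {
    .assert(is.finite(equilibrium) && equilibrium > 0 && equilibrium <= 180,
            "angle equilibrium must be in (0, 180] degrees")
  }
  structure(list(equilibrium = equilibrium, force_constant = force_constant,
                 kind = kind),
            class = "harmonic_params")
}

#' Construct a coarse-grained force field
#'
#' Harmonic bonded parameters keyed by canonical term strings (`"i-j"` for
#' bonds with i < j, `"i-j-k"` for angles with the vertex in the middle and
#' i < k), optional Lennard-Jones pair parameters keyed by sorted bead-type
#' pairs (`"A:B"`), and the nonbonded cutoff.
#'
#' @param bond_params named list of bond [harmonic_params()].
#' @param angle_params named list of angle [harmonic_params()].
#' @param pair_params optional named list of `list(epsilon =, sigma =)`
#'   (kJ/mol, nm), keyed `"typeA:typeB"` with types sorted.
#' @param cutoff nonbonded cutoff in nm (default 1.1).
#' @return an object of class `force_field`.
#' @export
force_field <- function(bond_params = list(), angle_params = list(),
                        pair_params = NULL, cutoff = 1.1) {
  .assert(is.finite(cutoff) && cutoff > 0, "cutoff must be > 0")
  for (p in bond_params)
    .assert(inherits(p, "harmonic_params") && p$kind == "bond",
            "bond_params must hold bond harmonic_params")
  for (p in angle_params)
    .assert(inherits(p, "harmonic_params") && p$kind == "angle",
            "angle_params must hold angle harmonic_params")
  if (length(bond_params)) .assert(!is.null(names(bond_params)) &&
      all(nzchar(names(bond_params))), "bond_params must be named by term key")
  if (length(angle_params)) .assert(!is.null(names(angle_params)) &&
      all(nzchar(names(angle_params))), "angle_params must be named by term key")
  if (!is.null(pair_params)) {
    for (p in pair_params)
      .assert(is.list(p) && all(c("epsilon", "sigma") %in% names(p)) &&
                p$epsilon >= 0 && p$sigma > 0,
              "pair_params entries need epsilon >= 0 and sigma > 0")
  }
  structure(list(bond_params = bond_params, angle_params = angle_params,
                 pair_params = pair_params, cutoff = cutoff),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf("force_field: %d bonds, %d angles, %d LJ pair types, cutoff %.3g nm\n",
              length(x$bond_params), length(x$angle_params),
              length(x$pair_params), x$cutoff))
  invisible(x)
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = ":")

# check a force field covers every bonded term of a topology; returns the
# parameters in topology order.
collect_params <- function(ff, topology) {
  tk <- term_keys(topology)
  for (k in tk$bonds)
    if (is.null(ff$bond_params[[k]]))
      stop(sprintf("missing bond parameters for term %s", k), call. = FALSE)
  for (k in tk$angles)
    if (is.null(ff$angle_params[[k]]))
      stop(sprintf("missing angle parameters for term %s", k), call. = FALSE)
  list(bond = ff$bond_params[tk$bonds], angle = ff$angle_params[tk$angles],
       keys = tk)
}

#' Construct a multi-molecule scene
#'
#' A scene is one configuration of several molecules, each carrying its own
#' topology, coordinate block and species label. Stacking molecules are
#' labelled `"stacker"`; additives `"additive:<name>"`.
#'
#' @param molecules list of `list(topology =, coords =, species =)` where
#'   `coords` is an n x 3 nm matrix matching the topology's atom count.
#' @param box optional orthorhombic box, nm.
#' @return an object of class `cg_scene`.
#' @export
new_scene <- function(molecules, box = NULL) {
  .assert(length(molecules) >= 1, "scene needs at least one molecule")
  for (i in seq_along(molecules)) {
    m <- molecules[[i]]
    .assert(all(c("topology", "coords", "species") %in% names(m)),
            "molecule %d must have topology, coords, species", i)
    m$coords <- as.matrix(m$coords)
    .assert(nrow(m$coords) == nrow(m$topology$atoms) && ncol(m$coords) == 3,
            "molecule %d: coordinate block does not match its topology", i)
    .assert(is.character(m$species) && nzchar(m$species),
            "molecule %d: species label must be non-empty", i)
    molecules[[i]] <- m
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    .assert(length(box) == 3 && all(box > 0), "box must be 3 positive edges")
  }
  structure(list(molecules = molecules, box = box), class = "cg_scene")
}

#' @export
print.cg_scene <- function(x, ...) {
  sp <- table(vapply(x$molecules, `[[`, character(1), "species"))
  cat("cg_scene:", length(x$molecules), "molecules (",
      paste(sprintf("%s: %d", names(sp), sp), collapse = ", "), ")",
      if (is.null(x$box)) "no box" else "boxed", "\n")
  invisible(x)
}

#' Subset a scene by molecule indices
#'
#' @param scene a `cg_scene`.
#' @param indices molecule indices to keep.
#' @return a `cg_scene`.
#' @export
scene_subset <- function(scene, indices) {
  new_scene(scene$molecules[indices], box = scene$box)
}

#' Thermodynamic state for Boltzmann inversion
#'
#' @param temperature temperature in Kelvin (default 310.15 K, i.e. 37 C).
#' @return an object of class `thermo_state` with fields `temperature` and
#'   the fixed Boltzmann constant `kB` (kJ mol^-1 K^-1).
#' @export
thermo_state <- function(temperature = 310.15) {
  .assert(is.finite(temperature) && temperature > 0, "temperature must be > 0")
  structure(list(temperature = temperature, kB = KB_KJ_PER_MOL_K),
            class = "thermo_state")
}

# minimum-image wrap of displacement rows (n x 3) for an orthorhombic box
min_image <- function(d, box) {
  if (is.null(box)) return(d)
  if (is.null(dim(d))) {
    return(d - box * round(d / box))
  }
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}
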