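# Mapping-scheme configuration: a declarative YAML file that names the
# molecule's atoms, assigns them to beads and declares the CG bonded terms.
#
# Schema (all bead/atom references are by name):
#
#   molecule: C14EDTA-toy            # optional label
#   atoms:                           # required unless a topology is supplied
#     - {name: C1, element: C}       #   element optional (guessed from name)
#     - {name: C2, element: C, mass: 13.019}   # mass override optional
#   beads:
#     - {name: B1, type: C1T, atoms: [C1, C2], weighting: mass}
#     - {name: B2, type: C1T, atoms: [C3, C4]}     # weighting defaults to mass
#   bonds:  [[B1, B2]]
#   angles: [[B1, B2, B3]]
#   ground_truth:                    # optional, used by synthetic generators
#     bonds:  [{term: [B1, B2], mean: 0.47, sigma: 0.02}]
#     angles: [{term: [B1, B2, B3], mean: 120, sigma: 10}]

#' Load a bead mapping scheme and CG topology from a YAML config
#'
#' The only silent default is `weighting: mass`; every other field either
#' parses or raises a named error (unknown atom names name the bead and the
#' atom, duplicate bead names and undefined beads in bond/angle terms are
#' errors).
#'
#' @param path YAML config path.
#' @param topology optional [molecular_topology()] whose atom names resolve
#'   the bead memberships; when `NULL` the config's `atoms` block is
#'   required and a skeleton topology is built from it.
#' @return `list(scheme =, cg_topology =, aa_topology =, ground_truth =)`:
#'   the list of [bead_definition()]s, the [cg_topology()], the atomistic
#'   topology used for name resolution, and any `ground_truth` block
#'   (named per-term `list(mean =, sigma =)`, keys as in [force_field()]).
#' @export
load_mapping_config <- function(path, topology = NULL) {
  .assert(file.exists(path), "file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  .assert(is.list(cfg), "mapping config must be a YAML mapping")
  unknown <- setdiff(names(cfg), c("molecule", "atoms", "beads", "bonds",
                                   "angles", "ground_truth"))
  .assert(length(unknown) == 0, "unknown config field '%s'", unknown[1])

  if (is.null(topology)) {
    .assert(!is.null(cfg$atoms),
            "config must declare 'atoms' when no topology is supplied")
    nm <- character(0); el <- character(0); ms <- numeric(0)
    for (a in cfg$atoms) {
      if (is.character(a) && length(a) == 1) a <- list(name = a)
      .assert(is.list(a) && !is.null(a$name), "each atom needs a 'name'")
      # YAML 1.1 reads bare N/Y as booleans; fall back to the name-derived
      # element in that case (or quote the symbol in the config)
      e <- if (is.character(a$element)) a$element else guess_element(a$name)
      m <- if (!is.null(a$mass)) as.numeric(a$mass)
           else mass_for(e, a$name)
      nm <- c(nm, a$name); el <- c(el, e); ms <- c(ms, m)
    }
    .assert(!anyDuplicated(nm), "duplicate atom name '%s' in config",
            nm[duplicated(nm)][1])
    topology <- molecular_topology(
      molecule_name = if (!is.null(cfg$molecule)) cfg$molecule else "molecule",
      atoms = data.frame(name = nm, element = el, mass = ms,
                         molecule_id = 1L, stringsAsFactors = FALSE))
  }
  atom_names <- topology$atoms$name

  .assert(!is.null(cfg$beads) && length(cfg$beads) > 0,
          "config must declare at least one bead")
  scheme <- vector("list", length(cfg$beads))
  for (i in seq_along(cfg$beads)) {
    b <- cfg$beads[[i]]
    .assert(is.list(b) && !is.null(b$name), "bead %d needs a 'name'", i)
    .assert(!is.null(b$atoms) && length(b$atoms) > 0,
            "bead '%s' declares no atoms", b$name)
    idx <- match(unlist(b$atoms), atom_names)
    if (anyNA(idx)) {
      bad <- unlist(b$atoms)[is.na(idx)][1]
      stop(sprintf("bead '%s' references unknown atom '%s'", b$name, bad),
           call. = FALSE)
    }
    w <- if (is.null(b$weighting)) "mass" else b$weighting
    .assert(w %in% c("mass", "geometric"),
            "bead '%s': weighting must be 'mass' or 'geometric'", b$name)
    scheme[[i]] <- bead_definition(b$name, idx,
                                   bead_type = if (is.null(b$type)) b$name else b$type,
                                   weighting = w)
  }
  bead_names <- vapply(scheme, `[[`, character(1), "bead_name")
  .assert(!anyDuplicated(bead_names), "duplicate bead name '%s'",
          bead_names[duplicated(bead_names)][1])

  resolve_term <- function(term, k, what) {
    .assert(length(term) == k, "%s term must list %d beads", what, k)
    idx <- match(unlist(term), bead_names)
    if (anyNA(idx)) {
      bad <- unlist(term)[is.na(idx)][1]
      stop(sprintf("%s term references undefined bead '%s'", what, bad),
           call. = FALSE)
    }
    idx
  }
  bonds <- if (is.null(cfg$bonds)) matrix(integer(0), 0, 2) else
    do.call(rbind, lapply(cfg$bonds, resolve_term, k = 2, what = "bond"))
  angles <- if (is.null(cfg$angles)) matrix(integer(0), 0, 3) else
    do.call(rbind, lapply(cfg$angles, resolve_term, k = 3, what = "angle"))
  topo_cg <- cg_topology(scheme, bond_terms = bonds, angle_terms = angles)

  gt <- NULL
  if (!is.null(cfg$ground_truth)) {
    gt <- list()
    for (g in cfg$ground_truth$bonds) {
      idx <- resolve_term(g$term, 2, "ground_truth bond")
      gt[[bond_key(idx[1], idx[2])]] <- list(mean = as.numeric(g$mean),
                                             sigma = as.numeric(g$sigma))
    }
    for (g in cfg$ground_truth$angles) {
      idx <- resolve_term(g$term, 3, "ground_truth angle")
      gt[[angle_key(idx[1], idx[2], idx[3])]] <- list(mean = as.numeric(g$mean),
                                                      sigma = as.numeric(g$sigma))
    }
  }
  list(scheme = scheme, cg_topology = topo_cg, aa_topology = topology,
       ground_truth = gt)
}
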