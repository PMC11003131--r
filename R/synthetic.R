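# Synthetic-data generators with known ground truth: Gaussian-bonded
# single-molecule trajectories (the statistical structure harmonic
# Boltzmann inversion assumes) and stacked / aggregated scenes with
# controlled geometry emulating reduced versions of the simulated
# compositions (100 stackers : 14 additives and scalings thereof).

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Square-planar stacker template
#'
#' A deliberate geometric abstraction of a planar tetrapyrrole core: four
#' sites on a ring of the given radius in the xy-plane, core = all sites,
#' reference axis from site 3 to site 1 (+x).
#'
#' @param radius ring radius, nm (default 0.25).
#' @return `list(topology =, coords =)`.
#' @export
stacker_template <- function(radius = 0.25) {
  coords <- rbind(c(radius, 0, 0), c(0, radius, 0),
                  c(-radius, 0, 0), c(0, -radius, 0))
  topo <- molecular_topology(
    "stacker",
    data.frame(name = paste0("S", 1:4), element = "C",
               mass = rep(element_masses()["C"], 4), molecule_id = 1L,
               stringsAsFactors = FALSE),
    bonds = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L)),
    core_atoms = 1:4, reference_axis = c(3L, 1L))
  list(topology = topo, coords = coords)
}

#' Linear additive template
#'
#' A short chain molecule standing in for an amphiphilic additive tail.
#'
#' @param n_sites number of sites (default 3).
#' @param spacing site spacing along the chain, nm (default 0.12).
#' @param name additive name used in the species label (default `"C14"`).
#' @return `list(topology =, coords =, species =)`.
#' @export
additive_template <- function(n_sites = 3, spacing = 0.12, name = "C14") {
  x <- (seq_len(n_sites) - (n_sites + 1) / 2) * spacing
  coords <- cbind(x, 0, 0)
  bonds <- if (n_sites > 1) cbind(seq_len(n_sites - 1), seq_len(n_sites - 1) + 1L)
           else NULL
  topo <- molecular_topology(
    name,
    data.frame(name = paste0("A", seq_len(n_sites)), element = "C",
               mass = rep(element_masses()["C"], n_sites), molecule_id = 1L,
               stringsAsFactors = FALSE),
    bonds = bonds)
  list(topology = topo, coords = coords, species = paste0("additive:", name))
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# uniform random rotation matrix (from a random quaternion)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Generate a stack of planar molecules with controlled rotations
#'
#' Replicates the square-planar stacker template along the +z axis at the
#' given spacing; molecule `m + 1` is rotated about the axis by the `m`-th
#' entry of `rotation_sequence` relative to molecule `m`. On the jitter-free
#' output, [stack_analysis()] recovers every spacing and rotation exactly.
#'
#' @param n_molecules number of stackers.
#' @param spacing inter-plane spacing, nm (> 0).
#' @param rotation_sequence degrees, length `n_molecules - 1`.
#' @param jitter_sigma Gaussian coordinate jitter sd, nm (default 0).
#' @param seed RNG seed (used for the jitter).
#' @param template stacker template (see [stacker_template()]).
#' @return a `cg_scene` of stackers.
#' @export
gen_stack_scene <- function(n_molecules, spacing = 0.4,
                            rotation_sequence = NULL, jitter_sigma = 0,
                            seed = 1L, template = stacker_template()) {
  .assert(n_molecules >= 1, "need at least one molecule")
  .assert(spacing > 0, "spacing must be > 0")
  if (is.null(rotation_sequence)) rotation_sequence <- numeric(max(0, n_molecules - 1))
  .assert(length(rotation_sequence) == n_molecules - 1,
          "rotation_sequence must have length n_molecules - 1")
  with_seed(seed, {
    cum <- cumsum(c(0, rotation_sequence))
    mols <- lapply(seq_len(n_molecules), function(m) {
      X <- template$coords %*% t(rot_z(cum[m]))
      X[, 3] <- X[, 3] + (m - 1) * spacing
      if (jitter_sigma > 0)
        X <- X + matrix(rnorm(length(X), sd = jitter_sigma), nrow(X), 3)
      list(topology = template$topology, coords = X, species = "stacker")
    })
    new_scene(mols)
  })
}

# build a rod stack with per-gap spacings (used for intercalation scenes)
stack_with_gaps <- function(gaps, template, jitter_sigma) {
  n <- length(gaps) + 1
  z <- cumsum(c(0, gaps))
  rot <- cumsum(c(0, rep(c(90, 270), length.out = n - 1)))
  lapply(seq_len(n), function(m) {
    X <- template$coords %*% t(rot_z(rot[m]))
    X[, 3] <- X[, 3] + z[m]
    if (jitter_sigma > 0)
      X <- X + matrix(rnorm(length(X), sd = jitter_sigma), nrow(X), 3)
    list(topology = template$topology, coords = X, species = "stacker")
  })
}

# simple-cubic lattice ball of n points with the given spacing
lattice_ball <- function(n, spacing) {
  r <- 1
  repeat {
    g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
    if (nrow(g) >= n) break
    r <- r + 1
  }
  g <- as.matrix(g) * spacing
  g[order(rowSums(g^2))[seq_len(n)], , drop = FALSE]
}

# walk a molecule block inward along direction u until its minimum site
# distance to `sites` drops to `target` (never below `floor`)
place_radially <- function(block, u, sites, target, step = 0.02) {
  d <- max(sites %*% u) + target + 1
  repeat {
    X <- sweep(block, 2, d * u, "+")
    f <- min_site_distance(X, sites)
    if (f <= target || d <= 0) return(X)
    d <- d - min(step, f - target + step / 2)
  }
}

#' Generate an aggregate scene with controlled additive placement
#'
#' Stackers form either a single rod-like stack (alternating 90/270
#' rotations) or an isotropic spherical cluster; additives are then placed
#' so that [classify_placement()] returns the requested label for every
#' additive:
#' \describe{
#'   \item{intercalate}{additives inserted between distinct consecutive
#'     planes of the rod (gap widened to 0.6 nm, still inside the default
#'     separation window). With `split_stacks = TRUE` the gap is widened to
#'     1.2 nm instead, severing the stacker cluster at each intercalation
#'     point — the geometry used to study aggregate disruption (labels are
#'     then no longer guaranteed).}
#'   \item{surface}{additives adsorbed just outside the aggregate boundary,
#'     within contact of a stacker site.}
#'   \item{none}{additives scattered beyond 3 x `contact_cutoff` of every
#'     stacker site.}
#'   \item{co_cluster}{a separate packed additive cluster placed near (but
#'     not touching) the aggregate.}
#' }
#'
#' @param n_stackers number of stacking molecules (>= 1; `intercalate`
#'   needs >= 2).
#' @param n_additives number of additives (`intercalate` needs
#'   `<= n_stackers - 1`; `co_cluster` needs >= 2).
#' @param placement_mode one of `"intercalate"`, `"surface"`, `"none"`,
#'   `"co_cluster"`.
#' @param geometry `"rod"` or `"sphere"` (intercalation requires `"rod"`).
#' @param seed RNG seed.
#' @param spacing rod inter-plane spacing, nm.
#' @param contact_cutoff contact distance the placements are engineered
#'   against, nm.
#' @param jitter_sigma Gaussian jitter on stacker coordinates, nm.
#' @param split_stacks widen intercalated gaps beyond the contact cutoff
#'   (see above).
#' @param additive_name label for the additive species.
#' @return a `cg_scene`.
#' @export
gen_aggregate_scene <- function(n_stackers, n_additives,
                                placement_mode = c("intercalate", "surface",
                                                   "none", "co_cluster"),
                                geometry = c("rod", "sphere"), seed = 1L,
                                spacing = 0.4, contact_cutoff = 0.6,
                                jitter_sigma = 0.005, split_stacks = FALSE,
                                additive_name = "C14") {
  placement_mode <- match.arg(placement_mode)
  geometry <- match.arg(geometry)
  .assert(n_stackers >= 1, "n_stackers must be >= 1")
  .assert(n_additives >= 0, "n_additives must be >= 0")
  if (placement_mode == "intercalate") {
    if (n_stackers < 2)
      stop("intercalate requires at least 2 stackers", call. = FALSE)
    .assert(geometry == "rod", "intercalate requires rod geometry")
    .assert(n_additives <= n_stackers - 1,
            "intercalate: need n_additives <= n_stackers - 1 gaps")
  }
  if (placement_mode == "co_cluster" && n_additives > 0)
    .assert(n_additives >= 2, "co_cluster requires at least 2 additives")
  tmpl <- stacker_template()
  atmpl <- additive_template(name = additive_name)

  with_seed(seed, {
    gap_idx <- integer(0)
    if (geometry == "rod") {
      gaps <- rep(spacing, max(0, n_stackers - 1))
      if (placement_mode == "intercalate" && n_additives > 0) {
        gap_idx <- sort(sample.int(n_stackers - 1, n_additives))
        # widened gap stays inside the default separation window (0.55 nm)
        # unless the stack is deliberately split at the intercalation point
        gaps[gap_idx] <- if (split_stacks) 2 * contact_cutoff else 0.55
      }
      mols <- stack_with_gaps(gaps, tmpl, jitter_sigma)
      z <- cumsum(c(0, gaps))
    } else {
      centers <- lattice_ball(n_stackers, 0.55)
      mols <- lapply(seq_len(n_stackers), function(m) {
        X <- tmpl$coords %*% t(random_rotation())
        X <- sweep(X, 2, centers[m, ], "+")
        if (jitter_sigma > 0)
          X <- X + matrix(rnorm(length(X), sd = jitter_sigma), nrow(X), 3)
        list(topology = tmpl$topology, coords = X, species = "stacker")
      })
    }
    stacker_sites <- do.call(rbind, lapply(mols, `[[`, "coords"))

    adds <- list()
    if (n_additives > 0) {
      if (placement_mode == "intercalate") {
        for (a in seq_len(n_additives)) {
          g <- gap_idx[a]
          zmid <- (z[g] + z[g + 1]) / 2
          X <- atmpl$coords %*% t(rot_z(runif(1, 0, 360)))
          X[, 3] <- X[, 3] + zmid
          adds[[a]] <- list(topology = atmpl$topology, coords = X,
                            species = atmpl$species)
        }
      } else if (placement_mode == "surface") {
        for (a in seq_len(n_additives)) {
          u <- rnorm(3)
          if (geometry == "rod") u[3] <- 0  # adsorb on the rod's side
          u <- u / sqrt(sum(u^2))
          # chain oriented perpendicular to the approach direction
          perp <- c(-u[2], u[1], 0)
          if (sqrt(sum(perp^2)) < 1e-6) perp <- c(1, 0, 0)
          perp <- perp / sqrt(sum(perp^2))
          block <- atmpl$coords[, 1] %o% perp
          if (geometry == "rod")  # adsorb at a random height along the rod
            block[, 3] <- block[, 3] + runif(1, 0, max(stacker_sites[, 3]))
          X <- place_radially(block, u, stacker_sites,
                              target = 0.6 * contact_cutoff)
          adds[[a]] <- list(topology = atmpl$topology, coords = X,
                            species = atmpl$species)
        }
      } else if (placement_mode == "none") {
        R <- sqrt(max(rowSums(stacker_sites^2))) + 3.5 * contact_cutoff
        for (a in seq_len(n_additives)) {
          # golden-spiral directions keep the scattered additives apart
          h <- -1 + 2 * (a - 0.5) / n_additives
          th <- acos(h); ph <- a * pi * (3 - sqrt(5))
          u <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
          X <- sweep(atmpl$coords %*% t(random_rotation()), 2, R * u, "+")
          adds[[a]] <- list(topology = atmpl$topology, coords = X,
                            species = atmpl$species)
        }
      } else {  # co_cluster
        grid <- lattice_ball(n_additives, 0.35)
        block <- do.call(rbind, lapply(seq_len(n_additives), function(a)
          sweep(atmpl$coords %*% t(random_rotation()), 2, grid[a, ], "+")))
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        # attached but not wetting: gap between cutoff and 2 x cutoff
        X <- place_radially(block, u, stacker_sites,
                            target = 1.45 * contact_cutoff)
        ns <- nrow(atmpl$coords)
        for (a in seq_len(n_additives)) {
          adds[[a]] <- list(topology = atmpl$topology,
                            coords = X[((a - 1) * ns + 1):(a * ns), , drop = FALSE],
                            species = atmpl$species)
        }
      }
    }
    new_scene(c(mols, adds))
  })
}

#' Generate a Gaussian-bonded CG trajectory with known ground truth
#'
#' Builds each frame by sequential placement over the topology's bond tree:
#' every bond length is drawn from its Gaussian, every angle (where an angle
#' term is declared for the grandparent-parent-child triple) from its
#' Gaussian, torsions and unconstrained directions uniform (the
#' maximum-entropy choice). Measured bond/angle marginals therefore match
#' the ground truth within sampling error, and `sigma = 0` reproduces the
#' means exactly in every frame.
#'
#' @param cg_topology a [cg_topology()] whose bond graph is an acyclic
#'   connected chain/tree.
#' @param ground_truth named list keyed by canonical term key, each entry
#'   `list(mean =, sigma =)` (nm/degrees); must cover every bond term.
#' @param n_frames number of frames.
#' @param seed RNG seed; identical seeds give bitwise-identical output.
#' @return a `cg_trajectory`.
#' @export
gen_bonded_trajectory <- function(cg_topology, ground_truth, n_frames,
                                  seed = 1L) {
  .assert(n_frames >= 1, "n_frames must be >= 1")
  n <- length(cg_topology$beads)
  adj <- bond_adjacency(cg_topology)
  order <- tree_order(adj, n)  # errors on cycles / disconnection
  tk <- term_keys(cg_topology)
  for (k in tk$bonds)
    .assert(!is.null(ground_truth[[k]]), "no ground truth for bond term %s", k)
  for (gt in ground_truth)
    .assert(gt$sigma >= 0, "sigma must be >= 0")

  with_seed(seed, {
    F <- n_frames
    X <- array(0, dim = c(n, 3, F))
    unit_rows <- function(M) M / sqrt(rowSums(M^2))
    for (idx in seq_along(order$children)) {
      child <- order$children[idx]; parent <- order$parents[idx]
      gp <- order$grandparents[idx]
      gt <- ground_truth[[bond_key(parent, child)]]
      r <- rnorm(F, gt$mean, gt$sigma)
      agt <- if (!is.na(gp)) ground_truth[[angle_key(gp, parent, child)]] else NULL
      if (is.null(agt)) {
        d <- unit_rows(matrix(rnorm(3 * F), F, 3))
      } else {
        th <- rnorm(F, agt$mean, agt$sigma) * pi / 180
        W <- t(X[gp, , ] - X[parent, , ])        # F x 3, arm toward grandparent
        if (F == 1) W <- matrix(W, 1, 3)
        W <- unit_rows(W)
        H <- matrix(rep(c(0, 0, 1), each = F), F, 3)
        flip <- abs(W[, 3]) > 0.9
        H[flip, ] <- matrix(rep(c(0, 1, 0), each = sum(flip)), sum(flip), 3)
        E1 <- H - rowSums(H * W) * W
        E1 <- unit_rows(E1)
        E2 <- cbind(W[, 2] * E1[, 3] - W[, 3] * E1[, 2],
                    W[, 3] * E1[, 1] - W[, 1] * E1[, 3],
                    W[, 1] * E1[, 2] - W[, 2] * E1[, 1])
        phi <- runif(F, 0, 2 * pi)
        d <- cos(th) * W + sin(th) * (cos(phi) * E1 + sin(phi) * E2)
      }
      X[child, , ] <- X[parent, , ] + t(r * d)
    }
    new_trajectory(X)
  })
}
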