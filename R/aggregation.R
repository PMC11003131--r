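# Structural aggregation analyses for scenes of planar stacking molecules:
# single-linkage clusters, gyration-tensor shape metrics, stacking geometry
# with inter-plane rotation angles, and additive placement classification.

# minimum inter-molecular site distance (minimum image under PBC)
min_site_distance <- function(A, B, box = NULL) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    D <- sweep(B, 2, A[i, ])
    D <- min_image(D, box)
    best <- min(best, min(rowSums(D^2)))
  }
  sqrt(best)
}

#' Single-linkage cluster detection
#'
#' Two molecules are linked iff their minimum inter-molecular site distance
#' (minimum image under periodic boundaries) is below `contact_cutoff`;
#' clusters are the connected components of the resulting contact graph.
#'
#' @param scene a `cg_scene`.
#' @param contact_cutoff contact distance, nm (default 0.6, a typical CG
#'   bead contact).
#' @return an object of class `cluster_result`: `assignment` (cluster id per
#'   molecule, contiguous from 1), `sizes` (molecule count per cluster) and
#'   `contact_cutoff`.
#' @export
find_clusters <- function(scene, contact_cutoff = 0.6) {
  .assert(inherits(scene, "cg_scene"), "scene must be a cg_scene")
  .assert(contact_cutoff > 0, "contact_cutoff must be > 0")
  n <- length(scene$molecules)
  edges <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      Ai <- scene$molecules[[i]]$coords
      for (j in seq(i + 1, n)) {
        if (min_site_distance(Ai, scene$molecules[[j]]$coords, scene$box) <
              contact_cutoff)
          edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  structure(list(assignment = as.integer(comp$membership),
                 sizes = as.integer(comp$csize),
                 contact_cutoff = contact_cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters over %d molecules (cutoff %.3g nm); sizes: %s\n",
              length(x$sizes), length(x$assignment), x$contact_cutoff,
              paste(sort(x$sizes, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Gyration-tensor shape metrics of a point set
#'
#' The gyration tensor about the centroid is eigendecomposed into
#' `lambda1 >= lambda2 >= lambda3` (nm^2). Asphericity is
#' `lambda1 - (lambda2 + lambda3) / 2`; the relative shape anisotropy is
#' `kappa^2 = 1 - 3 (l1 l2 + l2 l3 + l3 l1) / (l1 + l2 + l3)^2`, exactly 1
#' for collinear points and 0 for spherically symmetric sets. A single site
#' (or fully coincident sites) returns all metrics 0 by convention.
#'
#' @param coords n x 3 matrix of site coordinates, nm.
#' @return `list(eigenvalues =, asphericity =, kappa_sq =, rg =)` with `rg`
#'   the radius of gyration (nm).
#' @export
cluster_shape <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2)
    return(list(eigenvalues = c(0, 0, 0), asphericity = 0, kappa_sq = 0, rg = 0))
  C <- sweep(coords, 2, colMeans(coords))
  S <- crossprod(C) / nrow(coords)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  tr <- sum(ev)
  if (tr < 1e-300)
    return(list(eigenvalues = c(0, 0, 0), asphericity = 0, kappa_sq = 0, rg = 0))
  kappa <- 1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / tr^2
  list(eigenvalues = ev, asphericity = ev[1] - (ev[2] + ev[3]) / 2,
       kappa_sq = min(1, max(0, kappa)), rg = sqrt(tr))
}

# best-fit plane normal of a molecule's core sites: eigenvector of the
# smallest eigenvalue of the core covariance. Errors when the core is
# (near-)collinear.
core_normal <- function(coords, core_atoms) {
  P <- coords[core_atoms, , drop = FALSE]
  if (nrow(P) < 3) stop("degenerate plane: need >= 3 core atoms", call. = FALSE)
  C <- sweep(P, 2, colMeans(P))
  S <- crossprod(C) / nrow(P)
  e <- eigen(S, symmetric = TRUE)
  ev <- e$values  # decreasing
  if (ev[2] < 1e-9 * max(ev[1], 1e-12))
    stop("degenerate plane: collinear core atoms", call. = FALSE)
  list(normal = e$vectors[, 3], centroid = colMeans(P))
}

#' Stacking geometry of the scene's stacker molecules
#'
#' For every molecule with species `"stacker"`, the plane normal is the
#' smallest-eigenvalue eigenvector of its core-site covariance, with signs
#' co-oriented by propagating the first stacker's orientation (preventing
#' spurious 180-degree flips in rotation angles). Neighbor pairs are stacker
#' pairs whose normals are aligned within `alignment_tolerance_deg` and
#' whose core-centroid separation projected on the pair's mean normal falls
#' inside `separation_window`. The rotation angle of a pair is the signed
#' (counter-clockwise about the co-oriented normal) angle between the two
#' reference-axis vectors projected into the mean plane, mapped to
#' `[0, 360)`.
#'
#' @param scene a `cg_scene`; every stacker needs >= 3 non-collinear core
#'   atoms and a `reference_axis` in its topology.
#' @param alignment_tolerance_deg maximum angle between pair normals
#'   (default 30).
#' @param separation_window inclusive projected-separation window, nm
#'   (default `c(0.3, 0.7)`).
#' @return an object of class `stack_geometry`: `molecule_indices` (scene
#'   indices of the stackers), `normals` (unit vectors, one row per
#'   stacker), `centroids` (core centroids), `pairs` (data.frame `i`, `j`
#'   scene indices ordered along the pair normal, `separation` nm,
#'   `rotation_deg` in `[0, 360)`), `pair_normals`, and the parameters used.
#' @export
stack_analysis <- function(scene, alignment_tolerance_deg = 30,
                           separation_window = c(0.3, 0.7)) {
  .assert(inherits(scene, "cg_scene"), "scene must be a cg_scene")
  sp <- vapply(scene$molecules, `[[`, character(1), "species")
  st <- which(sp == "stacker")
  m <- length(st)
  normals <- matrix(0, m, 3)
  centroids <- matrix(0, m, 3)
  axes <- matrix(0, m, 3)
  for (a in seq_len(m)) {
    mol <- scene$molecules[[st[a]]]
    core <- mol$topology$core_atoms
    .assert(!is.null(core) && length(core) >= 3,
            "stacker %d: needs >= 3 core atoms", st[a])
    ax <- mol$topology$reference_axis
    if (is.null(ax))
      stop(sprintf("stacker %d: missing reference_axis", st[a]), call. = FALSE)
    pn <- core_normal(mol$coords, core)
    normals[a, ] <- pn$normal
    centroids[a, ] <- pn$centroid
    v <- mol$coords[ax[2], ] - mol$coords[ax[1], ]
    axes[a, ] <- v / sqrt(sum(v^2))
  }
  # co-orient normals by propagating the first stacker's sign
  for (a in seq_len(m)) {
    if (a > 1 && sum(normals[a, ] * normals[1, ]) < 0)
      normals[a, ] <- -normals[a, ]
  }
  cos_tol <- cos(alignment_tolerance_deg * pi / 180)
  pi_ <- integer(0); pj <- integer(0); sep <- numeric(0); rot <- numeric(0)
  pnormals <- matrix(0, 0, 3)
  if (m > 1) {
    for (a in seq_len(m - 1)) for (b in seq(a + 1, m)) {
      ca <- sum(normals[a, ] * normals[b, ])
      if (abs(ca) < cos_tol) next
      nb <- if (ca >= 0) normals[b, ] else -normals[b, ]
      nbar <- normals[a, ] + nb
      nbar <- nbar / sqrt(sum(nbar^2))
      d <- min_image(centroids[b, ] - centroids[a, ], scene$box)
      s <- sum(d * nbar)
      if (abs(s) < separation_window[1] || abs(s) > separation_window[2]) next
      if (s >= 0) { i <- a; j <- b } else { i <- b; j <- a }
      # project reference axes into the mean plane
      axi <- axes[i, ] - sum(axes[i, ] * nbar) * nbar
      axj <- axes[j, ] - sum(axes[j, ] * nbar) * nbar
      ni <- sqrt(sum(axi^2)); nj <- sqrt(sum(axj^2))
      if (ni < 1e-12 || nj < 1e-12)
        stop("reference axis parallel to the stack normal", call. = FALSE)
      axi <- axi / ni; axj <- axj / nj
      cr <- c(axi[2] * axj[3] - axi[3] * axj[2],
              axi[3] * axj[1] - axi[1] * axj[3],
              axi[1] * axj[2] - axi[2] * axj[1])
      ang <- atan2(sum(cr * nbar), sum(axi * axj)) * 180 / pi
      pi_ <- c(pi_, st[i]); pj <- c(pj, st[j])
      sep <- c(sep, abs(s)); rot <- c(rot, ang %% 360)
      pnormals <- rbind(pnormals, nbar)
    }
  }
  structure(list(molecule_indices = st, normals = normals,
                 centroids = centroids,
                 pairs = data.frame(i = pi_, j = pj, separation = sep,
                                    rotation_deg = rot),
                 pair_normals = pnormals,
                 alignment_tolerance_deg = alignment_tolerance_deg,
                 separation_window = separation_window),
            class = "stack_geometry")
}

#' @export
print.stack_geometry <- function(x, ...) {
  cat(sprintf("stack_geometry: %d stackers, %d neighbor pairs\n",
              length(x$molecule_indices), nrow(x$pairs)))
  if (nrow(x$pairs) > 0)
    cat("rotations (deg):",
        paste(sprintf("%.1f", x$pairs$rotation_deg), collapse = ", "), "\n")
  invisible(x)
}

#' Classify inter-plane rotation angles
#'
#' Bins each angle to the nearest of 0, 90, 180 or 270 degrees (circular
#' distance) when within `bin_tolerance_deg`, else `"other"`. Stacking of
#' the planar cores permits only the 90- and 270-degree registrations, so
#' `permitted` is `TRUE` exactly for bins 90 and 270.
#'
#' @param angle_deg numeric vector of angles in `[0, 360)`.
#' @param bin_tolerance_deg half-width of each bin (default 15; must be
#'   < 45 or the bins would overlap).
#' @return `data.frame(angle, bin, permitted)` with `bin` in
#'   `{"0", "90", "180", "270", "other"}`.
#' @export
classify_rotation <- function(angle_deg, bin_tolerance_deg = 15) {
  if (bin_tolerance_deg >= 45)
    stop("bin_tolerance_deg must be < 45 degrees (bins overlap)", call. = FALSE)
  .assert(all(is.finite(angle_deg)), "angles must be finite")
  .assert(all(angle_deg >= 0 & angle_deg < 360), "angles must lie in [0, 360)")
  refs <- c(0, 90, 180, 270)
  bin <- character(length(angle_deg))
  for (i in seq_along(angle_deg)) {
    d <- abs(((angle_deg[i] - refs + 180) %% 360) - 180)
    j <- which.min(d)
    bin[i] <- if (d[j] <= bin_tolerance_deg) as.character(refs[j]) else "other"
  }
  data.frame(angle = angle_deg, bin = bin,
             permitted = bin %in% c("90", "270"), stringsAsFactors = FALSE)
}

#' Classify additive placement relative to the stacker aggregate
#'
#' Labels every non-stacker molecule with exactly one of:
#' \describe{
#'   \item{intercalated}{at least one site lies strictly between two
#'     consecutive stack planes (projected along the pair's normal) and
#'     within `lateral_radius` of the pair axis.}
#'   \item{surface}{shares a single-linkage cluster with a stacker and has a
#'     site within `contact_cutoff` of a stacker site.}
#'   \item{co_cluster}{belongs to an additive-only cluster of >= 2 additives
#'     whose sites come within `attachment_factor * contact_cutoff` of a
#'     stacker site (a co-existing cluster attached to, but not wetting, the
#'     aggregate).}
#'   \item{free}{none of the above.}
#' }
#'
#' @param scene a `cg_scene` containing at least one stacker.
#' @param stack_geom optional precomputed [stack_analysis()] result.
#' @param contact_cutoff contact distance, nm (default 0.6).
#' @param lateral_radius maximum distance from the stack axis for
#'   intercalation; default 1.5 x the mean core radius of gyration of the
#'   stackers.
#' @param attachment_factor multiple of `contact_cutoff` within which an
#'   additive cluster counts as attached (default 2).
#' @return `data.frame(molecule, species, label)` with one row per additive.
#' @export
classify_placement <- function(scene, stack_geom = NULL, contact_cutoff = 0.6,
                               lateral_radius = NULL, attachment_factor = 2) {
  .assert(inherits(scene, "cg_scene"), "scene must be a cg_scene")
  sp <- vapply(scene$molecules, `[[`, character(1), "species")
  st <- which(sp == "stacker")
  ad <- which(sp != "stacker")
  if (length(st) == 0) stop("no stackers in scene", call. = FALSE)
  if (is.null(stack_geom)) stack_geom <- stack_analysis(scene)
  if (is.null(lateral_radius)) {
    rgs <- vapply(st, function(i) {
      mol <- scene$molecules[[i]]
      P <- mol$coords[mol$topology$core_atoms, , drop = FALSE]
      sqrt(mean(rowSums(sweep(P, 2, colMeans(P))^2)))
    }, numeric(1))
    lateral_radius <- 1.5 * mean(rgs)
  }
  if (length(ad) == 0)
    return(data.frame(molecule = integer(0), species = character(0),
                      label = character(0), stringsAsFactors = FALSE))

  clusters <- find_clusters(scene, contact_cutoff)
  stacker_clusters <- unique(clusters$assignment[st])
  stacker_sites <- do.call(rbind, lapply(st, function(i) scene$molecules[[i]]$coords))

  # additive-only single-linkage clusters for the co_cluster rule
  ad_scene_clusters <- if (length(ad) > 1)
    find_clusters(scene_subset(scene, ad), contact_cutoff)$assignment
  else rep(1L, length(ad))

  geom_idx <- match(seq_along(scene$molecules), stack_geom$molecule_indices)
  pairs <- stack_geom$pairs

  label_one <- function(aidx) {
    X <- scene$molecules[[ad[aidx]]]$coords
    # intercalated?
    for (p in seq_len(nrow(pairs))) {
      gi <- geom_idx[pairs$i[p]]; gj <- geom_idx[pairs$j[p]]
      cmid <- (stack_geom$centroids[gi, ] + stack_geom$centroids[gj, ]) / 2
      nb <- stack_geom$pair_normals[p, ]
      s <- pairs$separation[p]
      D <- sweep(X, 2, cmid)
      D <- min_image(D, scene$box)
      t <- D %*% nb
      lat2 <- rowSums(D^2) - t^2
      if (any(abs(t) < s / 2 & lat2 < lateral_radius^2)) return("intercalated")
    }
    # surface?
    same_cluster <- clusters$assignment[ad[aidx]] %in% stacker_clusters
    dmin <- min_site_distance(X, stacker_sites, scene$box)
    if (same_cluster && dmin < contact_cutoff) return("surface")
    # co_cluster?
    members <- ad[ad_scene_clusters == ad_scene_clusters[aidx]]
    if (length(members) >= 2) {
      msites <- do.call(rbind, lapply(members,
                                      function(i) scene$molecules[[i]]$coords))
      if (min_site_distance(msites, stacker_sites, scene$box) <
            attachment_factor * contact_cutoff)
        return("co_cluster")
    }
    "free"
  }
  data.frame(molecule = ad, species = sp[ad],
             label = vapply(seq_along(ad), label_one, character(1)),
             stringsAsFactors = FALSE)
}
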