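# Cluster detection, shape metrics, stacking geometry, placement labels.

two_mol_scene <- function(sep) {
  t1 <- stacker_template()
  m1 <- list(topology = t1$topology, coords = t1$coords, species = "stacker")
  m2 <- list(topology = t1$topology,
             coords = sweep(t1$coords, 2, c(sep, 0, 0), "+"),
             species = "stacker")
  new_scene(list(m1, m2))
}

test_that("single-linkage clustering links molecules by minimum site distance", {
  cl <- find_clusters(two_mol_scene(0.8), 0.6)  # site gap 0.8 - 0.5 = 0.3
  expect_equal(length(cl$sizes), 1)
  expect_equal(cl$sizes, 2L)

  far <- find_clusters(two_mol_scene(5.5), 0.6)
  expect_equal(length(far$sizes), 2)
  expect_equal(far$sizes, c(1L, 1L))

  # chain A-B close, B-C close, A-C far -> one cluster of 3
  t1 <- stacker_template()
  mk <- function(x) list(topology = t1$topology,
                         coords = sweep(t1$coords, 2, c(x, 0, 0), "+"),
                         species = "stacker")
  chain <- new_scene(list(mk(0), mk(0.9), mk(1.8)))
  cl3 <- find_clusters(chain, 0.6)
  expect_equal(cl3$sizes, 3L)
  expect_equal(length(unique(cl3$assignment)), 1)
})

test_that("cluster assignments are a valid partition under molecule reordering", {
  set.seed(301)
  sc <- gen_aggregate_scene(12, 3, "surface", "rod", seed = 4)
  perm <- sample(seq_along(sc$molecules))
  sc2 <- new_scene(sc$molecules[perm], box = sc$box)
  a1 <- find_clusters(sc, 0.6)$assignment
  a2 <- find_clusters(sc2, 0.6)$assignment
  expect_equal(sum(a1 > 0), length(sc$molecules))
  expect_equal(sort(table(a1)), sort(table(a2)))  # same partition sizes
  # co-membership is permutation invariant
  same1 <- outer(a1, a1, "==")
  same2 <- outer(a2, a2, "==")[order(perm), order(perm)]
  expect_identical(same1, same2)
})

test_that("shape metrics hit the exact collinear and spherical limits", {
  line <- cbind(seq(0, 2, 0.25), 0, 0)
  s <- cluster_shape(line)
  expect_equal(s$kappa_sq, 1)
  a <- 0.7
  octa <- rbind(c(a, 0, 0), c(-a, 0, 0), c(0, a, 0), c(0, -a, 0),
                c(0, 0, a), c(0, 0, -a))
  so <- cluster_shape(octa)
  expect_equal(so$kappa_sq, 0, tolerance = 1e-12)
  expect_equal(so$asphericity, 0, tolerance = 1e-12)
  expect_equal(so$eigenvalues, rep(a^2 / 3, 3))
  expect_equal(cluster_shape(matrix(1, 1, 3))$kappa_sq, 0)
})

test_that("shape metrics agree with a direct gyration-tensor oracle", {
  set.seed(302)
  X <- matrix(rnorm(3e4), ncol = 3)
  s <- cluster_shape(X)
  C <- sweep(X, 2, colMeans(X))
  S <- t(C) %*% C / nrow(X)
  ev <- sort(eigen(S)$values, decreasing = TRUE)
  expect_equal(s$eigenvalues, ev, tolerance = 1e-12)
  expect_lt(s$kappa_sq, 0.01)  # isotropic cloud
  expect_true(s$kappa_sq >= 0 && s$kappa_sq <= 1)
})

test_that("stack analysis recovers constructed separations and rotations", {
  for (rot in c(90, 180, 270)) {
    sc <- gen_stack_scene(2, 0.4, rot, jitter_sigma = 0, seed = 1)
    g <- stack_analysis(sc)
    expect_equal(nrow(g$pairs), 1)
    expect_equal(g$pairs$separation, 0.4, tolerance = 1e-12)
    expect_equal(g$pairs$rotation_deg, rot, tolerance = 1e-9)
    expect_equal(sqrt(rowSums(g$normals^2)), rep(1, 2), tolerance = 1e-9)
  }
  # jittered construction recovered within 3 degrees
  scj <- gen_stack_scene(2, 0.4, 90, jitter_sigma = 0.01, seed = 12)
  gj <- stack_analysis(scj)
  expect_lt(abs(gj$pairs$rotation_deg - 90), 3)
})

test_that("degenerate cores and missing reference axes are errors", {
  line_topo <- molecular_topology("bad",
    data.frame(name = paste0("S", 1:3), element = "C", mass = 12,
               molecule_id = 1L, stringsAsFactors = FALSE),
    core_atoms = 1:3, reference_axis = c(1L, 3L))
  bad <- new_scene(list(list(topology = line_topo,
                             coords = cbind(c(0, 0.2, 0.4), 0, 0),
                             species = "stacker")))
  expect_error(stack_analysis(bad), "degenerate plane")

  t1 <- stacker_template()
  noax <- molecular_topology("noax", t1$topology$atoms,
                             bonds = t1$topology$bonds, core_atoms = 1:4)
  sc <- new_scene(list(list(topology = noax, coords = t1$coords,
                            species = "stacker")))
  expect_error(stack_analysis(sc), "reference_axis")
})

test_that("rotation angles are invariant under rigid rotation of the scene", {
  sc <- gen_stack_scene(4, 0.4, c(90, 270, 90), jitter_sigma = 0.004, seed = 2)
  base <- stack_analysis(sc)$pairs$rotation_deg
  for (rep in 1:4) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, 360))
    rot <- stack_analysis(transform_scene(sc, R, rnorm(3)))$pairs$rotation_deg
    expect_equal(rot, base, tolerance = 1e-6)
  }
})

test_that("rotation classification bins to the permitted registrations", {
  out <- classify_rotation(c(92, 179, 45, 271, 359, 2), 10)
  expect_equal(out$bin, c("90", "180", "other", "270", "0", "0"))
  expect_equal(out$permitted, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_error(classify_rotation(10, 45), "45")
})

test_that("placement labels match constructed geometries and are exhaustive", {
  # constructed intercalation: additive between planes 2 and 3 of a stack
  sc <- gen_aggregate_scene(6, 1, "intercalate", "rod", seed = 5)
  lab <- classify_placement(sc)
  expect_equal(lab$label, "intercalated")

  # adsorbed outside the lateral boundary
  sc2 <- gen_aggregate_scene(6, 1, "surface", "rod", seed = 5)
  expect_equal(classify_placement(sc2)$label, "surface")

  # far from everything
  t1 <- stacker_template(); a1 <- additive_template()
  far <- new_scene(list(
    list(topology = t1$topology, coords = t1$coords, species = "stacker"),
    list(topology = t1$topology,
         coords = sweep(t1$coords, 2, c(0, 0, 0.4), "+"), species = "stacker"),
    list(topology = a1$topology, coords = sweep(a1$coords, 2, c(10, 0, 0), "+"),
         species = a1$species)))
  expect_equal(classify_placement(far)$label, "free")

  # labels are one of the four classes, one per additive
  sc3 <- gen_aggregate_scene(10, 4, "co_cluster", "rod", seed = 9)
  lab3 <- classify_placement(sc3)
  expect_equal(nrow(lab3), 4)
  expect_true(all(lab3$label %in% c("intercalated", "surface", "co_cluster",
                                    "free")))

  # no stackers -> error
  only_add <- new_scene(list(list(topology = a1$topology, coords = a1$coords,
                                  species = a1$species)))
  expect_error(classify_placement(only_add), "no stackers")
})
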