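# Generators: statistical closure with the analysis operations.

test_that("generated bond marginals match the ground truth within sampling error", {
  topo <- two_bead_topology()
  n <- 5e4
  tr <- gen_bonded_trajectory(topo, list("1-2" = list(mean = 0.47, sigma = 0.02)),
                              n, seed = 41)
  r <- measure_bond_series(tr, c(1, 2))
  expect_lt(abs(mean(r) - 0.47), 3 * 0.02 / sqrt(n))
  expect_lt(abs(var(r) / 0.02^2 - 1), 4 * sqrt(2 / n))
})

test_that("zero sigma reproduces the exact internal geometry in every frame", {
  cfg <- load_mapping_config(system.file("extdata/toy_mapping.yaml",
                                         package = "cgstack"))
  gt0 <- lapply(cfg$ground_truth, function(g) list(mean = g$mean, sigma = 0))
  tr <- gen_bonded_trajectory(cfg$cg_topology, gt0, 50, seed = 2)
  expect_equal(measure_bond_series(tr, c(1, 2)), rep(0.47, 50), tolerance = 1e-12)
  expect_equal(measure_bond_series(tr, c(2, 3)), rep(0.37, 50), tolerance = 1e-12)
  expect_equal(measure_angle_series(tr, c(1, 2, 3)), rep(130, 50),
               tolerance = 1e-9)
})

test_that("generators are deterministic in their seed", {
  topo <- two_bead_topology()
  gt <- list("1-2" = list(mean = 0.47, sigma = 0.02))
  expect_identical(gen_bonded_trajectory(topo, gt, 100, seed = 7)$coords,
                   gen_bonded_trajectory(topo, gt, 100, seed = 7)$coords)
  expect_identical(gen_stack_scene(5, 0.4, rep(90, 4), 0.01, seed = 3),
                   gen_stack_scene(5, 0.4, rep(90, 4), 0.01, seed = 3))
  expect_identical(gen_aggregate_scene(10, 3, "surface", "rod", seed = 5),
                   gen_aggregate_scene(10, 3, "surface", "rod", seed = 5))
})

test_that("cyclic bond graphs are rejected", {
  topo <- cg_topology(list(bead_definition("A", 1), bead_definition("B", 2),
                           bead_definition("C", 3)),
                      bond_terms = rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)))
  gt <- list("1-2" = list(mean = 0.4, sigma = 0.01),
             "2-3" = list(mean = 0.4, sigma = 0.01),
             "1-3" = list(mean = 0.4, sigma = 0.01))
  expect_error(gen_bonded_trajectory(topo, gt, 10), "chain/tree")
})

test_that("stack scenes invert exactly through stack_analysis", {
  sc <- gen_stack_scene(4, 0.4, c(90, 270, 90), jitter_sigma = 0, seed = 1)
  g <- stack_analysis(sc)
  expect_equal(nrow(g$pairs), 3)
  expect_equal(g$pairs$separation, rep(0.4, 3), tolerance = 1e-12)
  expect_equal(g$pairs$rotation_deg, c(90, 270, 90), tolerance = 1e-9)

  single <- gen_stack_scene(1, 0.4, numeric(0), seed = 1)
  expect_equal(nrow(stack_analysis(single)$pairs), 0)

  expect_error(gen_stack_scene(3, -0.1, c(90, 90)), "spacing")
})

test_that("0 and 180 degree registrations are flagged as not permitted", {
  sc <- gen_stack_scene(3, 0.4, c(0, 180), jitter_sigma = 0, seed = 1)
  g <- stack_analysis(sc)
  cls <- classify_rotation(g$pairs$rotation_deg, 10)
  expect_equal(sort(cls$bin), c("0", "180"))
  expect_false(any(cls$permitted))
})

test_that("aggregate scenes close the loop with classify_placement and shape", {
  sc <- gen_aggregate_scene(20, 4, "intercalate", "rod", seed = 11)
  expect_true(all(classify_placement(sc)$label == "intercalated"))
  expect_gt(cluster_shape(stacker_sites_of(sc))$kappa_sq, 0.8)

  sp <- gen_aggregate_scene(20, 4, "none", "sphere", seed = 11)
  expect_true(all(classify_placement(sp)$label == "free"))
  expect_lt(cluster_shape(stacker_sites_of(sp))$kappa_sq, 0.2)

  bare <- gen_aggregate_scene(20, 0, "none", "sphere", seed = 11)
  expect_equal(length(find_clusters(bare)$sizes), 1)

  expect_error(gen_aggregate_scene(1, 1, "intercalate", "rod"), "2 stackers")
})

test_that("compositions scale to reduced stacker:additive ratios", {
  # 50:7 is the reduced version of the 100:14 simulated composition
  sc <- gen_aggregate_scene(50, 7, "surface", "rod", seed = 13)
  sp <- vapply(sc$molecules, `[[`, character(1), "species")
  expect_equal(sum(sp == "stacker"), 50)
  expect_equal(sum(sp != "stacker"), 7)
  expect_true(all(classify_placement(sc)$label == "surface"))
})

test_that("scenes written via the standard formats double as round-trip checks", {
  sc <- gen_aggregate_scene(8, 2, "surface", "rod", seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_scene(sc, f)
  sc2 <- read_scene(f)
  expect_equal(length(sc2$molecules), length(sc$molecules))
  expect_equal(vapply(sc2$molecules, `[[`, character(1), "species"),
               vapply(sc$molecules, `[[`, character(1), "species"))
  expect_equal(classify_placement(sc2)$label, classify_placement(sc)$label)
})
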