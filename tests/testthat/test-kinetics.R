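# Kinetics matrix assembly, archetypes, clustering and group means.

test_that("relative lengths are ratios to the wild-type reference", {
  long <- tidyr::expand_grid(mutant = "mutA", streak = 1:9)
  long$length_bp <- 176
  kin <- build_kinetics_matrix(long, wt_reference = 352)
  expect_equal(unname(unlist(kin[1, -1])), rep(0.5, 9))
})

test_that("short gaps are interpolated, edge gaps held, poor coverage excluded", {
  long <- tibble::tibble(mutant = "mutA", streak = setdiff(1:9, 5),
                         length_bp = c(1, 1, 1, 0.9, 0.7, 1, 1, 1) * 352)
  kin <- build_kinetics_matrix(long, wt_reference = 352)
  expect_equal(kin$streak_5, 0.8)

  # leading edge gap -> nearest value
  long2 <- tibble::tibble(mutant = "mutB", streak = 2:9, length_bp = 2:9)
  kin2 <- build_kinetics_matrix(long2, wt_reference = 1)
  expect_equal(kin2$streak_1, 2)

  long3 <- dplyr::bind_rows(
    tibble::tibble(mutant = "good", streak = 1:9, length_bp = 300),
    tibble::tibble(mutant = "bad", streak = 1:4, length_bp = 300))
  expect_warning(kin3 <- build_kinetics_matrix(long3, wt_reference = 352),
                 class = "telka_warning_coverage")
  expect_equal(kin3$mutant, "good")

  expect_error(build_kinetics_matrix(long3[0, ], 352),
               class = "telka_error_input")
  long_bad <- tibble::tibble(mutant = "x", streak = 1:9, length_bp = -1)
  expect_error(build_kinetics_matrix(long_bad, 352),
               class = "telka_error_input")
})

test_that("archetype mean curves match their stated kinetics", {
  # group2 plateaus at 0.80 from streak 3 on
  g2 <- simulate_trajectory(kinetic_archetype("group2", noise_sd = 0))
  expect_equal(g2[3:9], rep(0.80, 7))
  expect_equal(g2[1], 1 - 0.2 / 3)

  # group3 is at its plateau from the first streak
  g3 <- simulate_trajectory(kinetic_archetype("group3", noise_sd = 0))
  expect_equal(g3, rep(0.55, 9))

  # group1 is within 1% of its plateau by streak 6, not by streak 2
  g1 <- simulate_trajectory(kinetic_archetype("group1", noise_sd = 0))
  expect_lt(abs(g1[6] - 0.85) / 0.85, 0.01)
  expect_gt(abs(g1[2] - 0.85) / 0.85, 0.01)

  # group4 is essentially at its (mild) plateau by streak 2
  g4 <- simulate_trajectory(kinetic_archetype("group4", noise_sd = 0))
  expect_lt(abs(g4[2] - 0.82) / 0.82, 0.012)
  expect_gt(g4[9], 0.80)

  expect_error(kinetic_archetype("group9"), class = "telka_error_archetype")
})

test_that("trajectory simulation is seeded and stays in (0, 1.2]", {
  t1 <- simulate_trajectory("group1", seed = 5)
  t2 <- simulate_trajectory("group1", seed = 5)
  expect_identical(t1, t2)
  sim <- simulate_kinetics(seed = 3)
  vals <- as.matrix(sim$kinetics[, -1])
  expect_true(all(vals > 0 & vals <= 1.2))
  expect_true(all(vals[, 9] <= 0.9))  # mutants at least 10% shorter than wt
  sim2 <- simulate_kinetics(seed = 3)
  expect_identical(sim$kinetics, sim2$kinetics)
})

test_that("archetype mean curves are well separated relative to noise (property)", {
  mus <- sapply(paste0("group", 1:4), function(g)
    simulate_trajectory(kinetic_archetype(g, noise_sd = 0)))
  between <- as.matrix(dist(t(mus)))
  min_between <- min(between[upper.tri(between)])
  set.seed(8)
  within <- mean(sapply(1:200, function(i) {
    g <- sample(paste0("group", 1:4), 1)
    sqrt(sum((simulate_trajectory(g) - simulate_trajectory(g))^2))
  }))
  expect_gt(min_between, 5 * within)
})

test_that("clustering recovers archetypes, identical rows collapse, blocks split", {
  sim <- simulate_kinetics(seed = 1)
  cl <- cluster_kinetics(sim$kinetics, k = 4)
  ari <- mclust::adjustedRandIndex(cl$labels$cluster,
                                   sim$labels$group)
  expect_equal(ari, 1)

  # all rows identical -> every merge at height 0, gap cut gives k = 1
  same <- make_kin(matrix(0.7, nrow = 6, ncol = 9))
  cl1 <- cluster_kinetics(same)
  expect_equal(cl1$k, 1)
  expect_equal(cl1$statistic, 0)

  # two blocks of identical rows at distance d -> exact blocks
  blocks <- make_kin(rbind(matrix(0.9, 4, 9), matrix(0.5, 4, 9)))
  cl2 <- cluster_kinetics(blocks, k = 2)
  expect_equal(length(unique(cl2$labels$cluster[1:4])), 1)
  expect_equal(length(unique(cl2$labels$cluster[5:8])), 1)
  expect_false(cl2$labels$cluster[1] == cl2$labels$cluster[5])

  expect_error(cluster_kinetics(blocks, k = 50), class = "telka_error_input")
  expect_error(cluster_kinetics(blocks[1, ]), class = "telka_error_input")
})

test_that("the gap-based cut finds k = 4 across seeds with ARI 1 (property)", {
  for (s in 1:20) {
    sim <- simulate_kinetics(seed = s)
    cl <- cluster_kinetics(sim$kinetics)
    expect_equal(cl$k, 4)
    expect_equal(mclust::adjustedRandIndex(cl$labels$cluster,
                                           sim$labels$group), 1)
  }
})

test_that("partitions are invariant to row order (property)", {
  sim <- simulate_kinetics(seed = 6)
  cl <- cluster_kinetics(sim$kinetics)
  set.seed(1)
  shuffled <- sim$kinetics[sample(nrow(sim$kinetics)), ]
  cl2 <- cluster_kinetics(shuffled)
  merged <- dplyr::inner_join(cl$labels, cl2$labels, by = "mutant")
  expect_equal(mclust::adjustedRandIndex(merged$cluster.x, merged$cluster.y), 1)
})

test_that("final-length-only clustering merges groups that kinetics separate", {
  # two archetypes constructed with the same final length, different kinetics
  set.seed(2)
  rows <- rbind(
    t(replicate(6, simulate_trajectory(kinetic_archetype("group2")))),
    t(replicate(6, simulate_trajectory(kinetic_archetype("group4",
                                                         plateau = 0.80)))),
    t(replicate(4, simulate_trajectory(kinetic_archetype("group3")))))
  truth <- rep(c("a", "b", "c"), c(6, 6, 4))
  kin <- make_kin(rows)
  full <- cluster_kinetics(kin, k = 3)
  expect_equal(mclust::adjustedRandIndex(full$labels$cluster, truth), 1)

  final_only <- kin[, c("mutant", "streak_9")]
  names(final_only)[2] <- "streak_1"  # single-feature matrix
  fl <- cluster_kinetics(final_only, k = 3)
  # at least one a/b pair that the kinetics separate is merged on final length
  lab <- fl$labels$cluster
  expect_true(any(outer(lab[truth == "a"], lab[truth == "b"], "==")))
})

test_that("group mean profiles average within clusters", {
  kin <- make_kin(rbind(c(1.0, 0.8), c(0.8, 0.6), c(0.5, 0.5)))
  gm <- group_mean_profiles(kin, c(1, 1, 2))
  expect_equal(gm$mean_rel_length[gm$cluster == 1], c(0.9, 0.7))
  expect_equal(gm$mean_rel_length[gm$cluster == 2], c(0.5, 0.5))

  # zero-noise group means equal the archetype curve exactly
  sim <- simulate_kinetics(group_sizes = c(0, 12, 0, 0), seed = 4,
                           noise_sd = 0)
  gm2 <- group_mean_profiles(sim$kinetics, rep(1, 12))
  expect_equal(gm2$mean_rel_length,
               simulate_trajectory(kinetic_archetype("group2", noise_sd = 0)))
})

test_that("tidy and glance expose the partition and fit summary", {
  sim <- simulate_kinetics(seed = 1)
  cl <- cluster_kinetics(sim$kinetics)
  td <- tidy(cl)
  expect_named(td, c("mutant", "cluster"))
  expect_equal(nrow(td), 30)
  gl <- glance(cl)
  expect_equal(gl$k, 4)
  expect_gte(gl$statistic, 0)
})
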