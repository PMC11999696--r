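mk_map <- function(types, orientations, xs, species = "mouse") {
  data.frame(cell_id = paste0("c", seq_along(types)), x = xs, y = 0,
             morph_type = types, orientation = orientations,
             foliar = "Bank", lobule = "L6", hemisphere = "vermis",
             individual = "i1", species = species)
}

test_that("adjacency scores follow the -1/0/+1 rule", {
  # isolated cell: neighbors beyond threshold
  far <- mk_map(rep("Poly", 3), rep("Vertical", 3), c(0, 500, 1000))
  expect_equal(adjacency_scores(far)$score, c(-1, -1, -1))  # mouse, 200 um
  # three identical adjacent cells
  near <- mk_map(rep("Poly", 3), rep("Vertical", 3), c(0, 100, 200))
  expect_equal(adjacency_scores(near)$score, c(1, 2, 1))
  # mouse sequence N,S,S,P at 100 um spacing, complete match
  m <- mk_map(c("Normative", "Split", "Split", "Poly"),
              c(NA, "Vertical", "Vertical", "Vertical"),
              c(0, 100, 200, 300))
  expect_equal(adjacency_scores(m)$score, c(0, 1, 1, 0))
  # a vertical Split does not completely match a horizontal Split
  vh <- mk_map(c("Split", "Split"), c("Vertical", "Horizontal"), c(0, 100))
  expect_equal(adjacency_scores(vh)$score, c(0, 0))
  expect_equal(adjacency_scores(vh, match_mode = "type_only")$score, c(1, 1))
  expect_equal(adjacency_scores(vh, match_mode = "orientation_only")$score,
               c(0, 0))
})

test_that("cluster runs count cells and sum inter-somatic distances", {
  ident <- mk_map(rep("Poly", 3), rep("Vertical", 3), c(0, 100, 200))
  runs <- cluster_runs(ident)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$n_cells, 3)
  expect_equal(runs$run_length, 200)
  # no matches anywhere
  mix <- mk_map(c("Normative", "Split", "Poly"), c(NA, "Vertical", "Vertical"),
                c(0, 100, 200))
  expect_equal(nrow(cluster_runs(mix)), 0)
  # alternating categories
  alt <- mk_map(rep(c("Split", "Poly"), 5), rep("Vertical", 10),
                seq(0, 900, by = 100))
  expect_equal(nrow(cluster_runs(alt)), 0)
  # a sub-threshold gap terminates the run
  gap <- mk_map(rep("Poly", 4), rep("Vertical", 4), c(0, 100, 900, 1000))
  runs_gap <- cluster_runs(gap)
  expect_equal(runs_gap$n_cells, c(2, 2))
})

test_that("scores, runs and surround rates equal brute-force enumeration", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(5:30, 1)
    map <- random_tiny_map(n)
    mode <- sample(c("complete", "type_only", "orientation_only"), 1)
    got <- adjacency_scores(map, match_mode = mode)
    expect_equal(got$score, oracle_adjacency_scores(map, 200, mode))
    runs <- cluster_runs(map, match_mode = mode)
    oruns <- oracle_runs(map, 200, mode)
    expect_equal(nrow(runs), nrow(oruns))
    if (nrow(runs)) {
      expect_equal(runs$n_cells, oruns$n_cells)
      expect_equal(runs$run_length, oruns$run_length)
    }
    classes <- sort(unique(pc_class_labels(map, mode)))
    r <- runif(1, 50, 400)
    got_m <- pcmorph:::surround_composition(
      map$x, map$y, pc_class_labels(map, mode), classes, 0, r)$M
    expect_equal(got_m, oracle_surround(map, classes, 0, r, mode))
  }
})

test_that("label shuffles conserve the multiset and are seed-deterministic", {
  set.seed(62)
  map <- random_tiny_map(200)
  sh <- shuffle_map(map, shuffle_spec("global", n_reps = 5, seed = 99))
  for (m in sh) {
    expect_equal(table(pc_class_labels(m)), table(pc_class_labels(map)))
    expect_equal(m$x, map$x)
    expect_equal(m$foliar, map$foliar)
  }
  # within-foliar mode conserves each stratum's multiset
  shf <- shuffle_map(map, shuffle_spec("within_foliar", n_reps = 5,
                                       seed = 99))
  for (m in shf)
    for (f in unique(map$foliar))
      expect_equal(table(pc_class_labels(m[m$foliar == f, ])),
                   table(pc_class_labels(map[map$foliar == f, ])))
  # determinism: identical seed, identical permutation sequence
  again <- shuffle_map(map, shuffle_spec("global", n_reps = 5, seed = 99))
  expect_identical(sh, again)
})

test_that("clustering excess is zero for uniform maps and flags isolation", {
  ident <- mk_map(rep("Poly", 50), rep("Vertical", 50),
                  seq(0, by = 100, length.out = 50))
  ex <- clustering_excess(ident, shuffle_spec(n_reps = 5, seed = 1))
  expect_equal(ex$excess, 0)  # observed and shuffled rates are both 100%
  iso <- mk_map(rep("Poly", 3), rep("Vertical", 3), c(0, 5000, 10000))
  expect_error(clustering_excess(iso), "isolated")
})

test_that("population match profile matches small-map enumeration", {
  # alternating 2-category map: at 1-neighbor radius every surround is the
  # other category, so the matching elevation is strongly negative
  alt <- mk_map(rep(c("Split", "Poly"), 10), rep("Vertical", 20),
                seq(0, by = 100, length.out = 20))
  prof <- population_match_profile(alt, radii = 110,
                                   spec = shuffle_spec(n_reps = 40,
                                                       seed = 3))
  expect_lt(prof$matching, -40)
  expect_gt(prof$nonmatching, 40)
  # single-category map: observed == shuffled == 100%
  mono <- mk_map(rep("Poly", 10), rep("Vertical", 10),
                 seq(0, by = 100, length.out = 10))
  prof_mono <- population_match_profile(mono, radii = 150,
                                        spec = shuffle_spec(n_reps = 3,
                                                            seed = 4))
  expect_equal(prof_mono$matching, 0)
  # independent labels: elevations ~ 0
  set.seed(63)
  null_map <- simulate_cell_map(map_sim_config(
    n_cells = 400, species = "mouse", copy_probability = 0, seed = 63))$map
  prof0 <- population_match_profile(null_map, radii = 100,
                                    spec = shuffle_spec(n_reps = 20,
                                                        seed = 5))
  expect_lt(abs(prof0$matching), 3)
})

test_that("match-rate elevations satisfy the conservation identity", {
  set.seed(64)
  map <- simulate_cell_map(map_sim_config(n_cells = 300, species = "mouse",
                                          seed = 64))$map
  spec <- shuffle_spec(n_reps = 10, seed = 6)
  prof <- population_match_profile(map, radii = 200, spec = spec)
  det <- attr(prof, "detail")[[1]]
  # per focal class, observed and shuffled compositions each sum to 100%,
  # so class-frequency-weighted elevations sum to ~0
  w <- table(factor(pc_class_labels(map), levels = det$classes))
  w <- as.numeric(w) / sum(w)
  expect_lt(abs(sum(w * rowSums(det$elevation))), 1e-8)
})

test_that("shell profile isolates distance bands and tiles the line", {
  set.seed(65)
  map <- simulate_cell_map(map_sim_config(n_cells = 400, species = "mouse",
                                          seed = 65))$map
  w <- 100
  d <- abs(outer(map$x, map$x, `-`))
  core <- d < w
  shells <- lapply(1:4, function(k) d >= k * w & d < (k + 1) * w)
  cover <- Reduce(`|`, shells) | core
  expect_true(all(cover[d < 5 * w]))                  # union covers the ball
  for (a in 1:3) for (b in (a + 1):4)
    expect_true(!any(shells[[a]] & shells[[b]]))      # shells are disjoint
  # short-range copying only: elevation ~ 0 beyond the first shells
  spec <- shuffle_spec(n_reps = 10, seed = 7)
  prof <- shell_match_profile(map, shell_width = w, shells = c(1, 6),
                              spec = spec)
  expect_lt(abs(prof$matching[2]), 4)
})

test_that("demographics tabulates percentages and delegates the test", {
  set.seed(66)
  map <- random_tiny_map(120)
  map$lobule <- rep(c("L5", "L6"), each = 60)
  map$morph_type[61:120] <- map$morph_type[1:60]
  map$orientation[61:120] <- map$orientation[1:60]
  dem <- demographics(map, "lobule")
  expect_equal(unname(dem$test$statistic), 0, tolerance = 1e-9)
  expect_gt(dem$test$p.value, 0.99)
  expect_equal(unname(rowSums(dem$percent)), c(100, 100))
  # innervation class counts -> rates
  rates <- category_rates(c(mono = 22, absence = 11, putative = 6,
                            full = 5))
  expect_equal(round(unname(rates), 1), c(50.0, 25.0, 13.6, 11.4))
  expect_equal(unname(rates[["full"]] + rates[["putative"]]), 25)
})

test_that("inter-hemisphere differences are symmetric and normalized", {
  set.seed(67)
  left <- random_tiny_map(150)
  left$lobule <- sample(c("L5", "L6", "CrusI"), 150, replace = TRUE)
  right <- random_tiny_map(150)
  right$lobule <- sample(c("L5", "L6", "CrusI"), 150, replace = TRUE)
  d1 <- interhemisphere_difference(left, right)
  d2 <- interhemisphere_difference(right, left)
  expect_equal(d1$mean_abs_difference, d2$mean_abs_difference)
  expect_equal(d1$normalized[d1$lobule == "L6"], 1)
  # identical hemispheres: zero difference, normalization flagged
  expect_warning(d0 <- interhemisphere_difference(left, left),
                 "undefined")
  expect_equal(d0$mean_abs_difference, rep(0, 3))
  expect_error(interhemisphere_difference(left, right,
                                          reference_lobule = "L9"),
               "absent")
})

test_that("pc_clustering fit bundles scores, runs, excess and p-value", {
  set.seed(68)
  map <- simulate_cell_map(map_sim_config(n_cells = 400,
                                          copy_probability = 0.5,
                                          seed = 68))$map
  fit <- pc_clustering(map, n_shuffles = 20, seed = 68)
  expect_s3_class(fit, "pc_clustering")
  expect_gt(fit$excess, 5)       # strong copying is detected
  expect_lt(fit$p_value, 0.1)
  expect_equal(fit$observed_rate,
               100 * sum(fit$scores$score >= 1) /
                 sum(fit$scores$score >= 0))
  s <- summary(fit)
  expect_gt(s$mean_run_cells, 1.9)
  expect_output(print(fit), "excess over null")
})
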