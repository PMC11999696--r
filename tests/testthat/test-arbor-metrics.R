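test_that("branch decomposition partitions simple trees correctly", {
  segs <- decompose_branches(y_arbor())
  expect_equal(nrow(segs), 3)
  expect_equal(sort(segs$order), c(1, 2, 2))
  expect_equal(sum(segs$is_terminal), 2)

  chain <- decompose_branches(chain_arbor(steps = c(2, 2, 2)))
  expect_equal(nrow(chain), 1)
  expect_equal(chain$order, 1)
  expect_true(chain$is_terminal)

  none <- decompose_branches(arbor(node_df(1, "soma", 0, 0, 0, 5, -1)))
  expect_equal(nrow(none), 0)
})

test_that("random binary trees yield 2k + trunks segments (induction)", {
  set.seed(21)
  for (i in 1:10) {
    k <- sample(1:8, 1)
    a <- arbor(random_arbor_nodes(n_bif = k))
    expect_equal(nrow(decompose_branches(a)), 2 * k + 1)
  }
})

test_that("segment lengths partition total dendritic length exactly", {
  set.seed(22)
  for (i in 1:5) {
    a <- arbor(random_arbor_nodes(n_bif = sample(2:10, 1)))
    segs <- decompose_branches(a)
    expect_equal(sum(segs$length), total_length(a))
  }
})

test_that("total length sums dendrite edges only", {
  expect_equal(total_length(chain_arbor(steps = c(3, 4))), 7)  # 3-4-5 legs
  expect_equal(total_length(y_arbor(trunk = 5, limb = 2)), 9)
  # axon material is excluded
  nodes <- rbind(node_df(1, "soma", 0, 0, 0, 5, -1),
                 node_df(2, "dendrite", 0, 3, 0, 1, 1),
                 node_df(3, "axon", 0, -10, 0, 1, 1))
  expect_equal(total_length(arbor(nodes)), 0)
})

test_that("extent and shape index follow the signed percent convention", {
  mk <- function(w, h) {
    nodes <- rbind(node_df(1, "soma", 0, 0, 0, 5, -1),
                   node_df(2, "dendrite", 0, 0, 0, 1, 1),
                   node_df(3, "dendrite", w, 0, 0, 1, 2),
                   node_df(4, "dendrite", w / 2, h, 0, 1, 3))
    arbor_extent_and_shape(arbor(nodes))
  }
  wide <- mk(644, 366)
  expect_equal(wide$shape_index, 100 * (644 / 366 - 1))
  expect_lt(abs(wide$shape_index - 76), 1)
  expect_equal(mk(100, 100)$shape_index, 0)
  tall <- mk(143, 158)
  expect_equal(tall$shape_index, -100 * (158 / 143 - 1))
  expect_lt(abs(tall$shape_index - (-10.5)), 0.1)
  single <- arbor(rbind(node_df(1, "soma", 0, 0, 0, 5, -1),
                        node_df(2, "dendrite", 0, 1, 0, 1, 1)))
  expect_error(arbor_extent_and_shape(single), "zero extent")
})

test_that("eccentricity uses the through-origin fit with mirroring", {
  expect_equal(branch_eccentricity(c(0, 5), c(0, 0)), 0)
  expect_equal(branch_eccentricity(c(0, 1), c(0, 1)), 45)
  expect_equal(branch_eccentricity(c(0, -1), c(0, -1)), 45)  # mirrored twin
  # through-origin slope oracle: sum(xy)/sum(x^2) = 4/8
  expect_equal(branch_eccentricity(c(0, 2, 2), c(0, 0, 2)),
               atan(0.5) * 180 / pi)
  expect_equal(branch_eccentricity(c(0, 0), c(0, 3)), 90)  # vertical
  expect_true(is.na(branch_eccentricity(c(0, 0), c(0, 0))))
})

test_that("eccentricity lies in [0, 90] and is mirror-invariant", {
  set.seed(23)
  for (i in 1:50) {
    m <- sample(2:6, 1)
    vx <- c(0, cumsum(rnorm(m)))
    vy <- c(0, cumsum(rnorm(m)))
    e <- branch_eccentricity(vx, vy)
    expect_gte(e, 0); expect_lte(e, 90)
    expect_equal(branch_eccentricity(-vx, -vy), e)
    expect_equal(branch_eccentricity(vx, -vy), e)
  }
})

test_that("region assignment bins by thirds with closed upper edges", {
  a <- y_arbor()
  a$ml_thickness <- 100
  segs <- data.frame(midpoint_radial = c(10, 50, 90, 100 / 3, 120))
  expect_warning(reg <- assign_region(segs, a), "clamped to distal")
  expect_equal(as.character(reg),
               c("proximal", "intermediate", "distal", "proximal", "distal"))
})

test_that("diameter profile normalizes by the primary and flags thin caliber", {
  a <- y_arbor(radius = 1)
  dp <- diameter_profile(a, threshold = 1)  # all diameters 2 um
  expect_true(all(dp$normalized_diameter_by_order == 1))
  expect_equal(dp$thin_fraction, 0)
  expect_equal(dp$max_primary_diameter, 2)
})

test_that("thin threshold converges to exp(mu + sigma) for log-normal pools", {
  set.seed(24)
  d <- rlnorm(20000, meanlog = log(1), sdlog = 0.5)
  expect_equal(thin_caliber_threshold(d), exp(log(1) + 0.5), tolerance = 0.02)
  expect_warning(thin_caliber_threshold(c(1, 2, 0)), "non-positive")
})

test_that("thin fraction weighs segment lengths below the threshold", {
  # thick trunk of 5 um (diameter 5) splitting into two thin limbs of
  # 47.5 um each (diameter ~0.8): 95% of the 100 um total is thin caliber
  nodes <- rbind(node_df(1, "soma", 0, 0, 0, 5, -1),
                 node_df(2, "dendrite", 0, 0, 0, 2.5, 1),
                 node_df(3, "dendrite", 0, 5, 0, 2.5, 2),
                 node_df(4, "dendrite", 0.01, 5, 0, 0.4, 3),
                 node_df(5, "dendrite", 47.50, 5, 0, 0.4, 4),
                 node_df(6, "dendrite", -0.01, 5, 0, 0.4, 3),
                 node_df(7, "dendrite", -47.50, 5, 0, 0.4, 6))
  a <- arbor(nodes)
  dp <- diameter_profile(a, threshold = 1.31)
  expect_equal(dp$thin_fraction, 95)
})

test_that("Sholl shells conserve length and localize simple geometries", {
  a <- chain_arbor(steps = rep(1, 10), soma_radius = 0.01)
  sh <- sholl_profile(a)
  expect_equal(sum(sh$length), total_length(a), tolerance = 1e-9)
  expect_equal(sh$length, rep(1, 10), tolerance = 1e-6)

  # circle arc at constant radius r: all length lands in shell ceil(r)
  r <- 6.5
  theta <- seq(0, pi / 2, length.out = 100)
  nodes <- rbind(node_df(1, "soma", 0, 0, 0, 0.01, -1),
                 node_df(2, "dendrite", r, 0, 0, 1, 1),
                 node_df(1 + seq_along(theta)[-1], "dendrite",
                         r * cos(theta[-1]), r * sin(theta[-1]), 0, 1,
                         seq_along(theta)[-1]))
  arc <- arbor(nodes)
  sha <- sholl_profile(arc)
  expect_equal(sum(sha$length), total_length(arc), tolerance = 1e-9)
  expect_equal(which.max(sha$length), 7)  # shell (6, 7]
  expect_gt(sha$length[7] / sum(sha$length), 0.999)

  # cumulative profile is monotone and ends at 1
  set.seed(25)
  b <- arbor(random_arbor_nodes(n_bif = 6))
  shb <- sholl_profile(b)
  expect_true(all(diff(shb$cumulative) >= -1e-12))
  expect_equal(tail(shb$cumulative, 1), 1)
})

test_that("Sholl conservation holds on simulated arbors within 0.5%", {
  sim <- simulate_arbor(arbor_sim_config("mouse", seed = 31))
  sh <- sholl_profile(sim$arbor)
  expect_lt(abs(sum(sh$length) - total_length(sim$arbor)) /
              total_length(sim$arbor), 0.005)
})

test_that("branch height profile localizes branch points", {
  expect_equal(nrow(branch_height_profile(chain_arbor())), 0)
  a <- y_arbor(trunk = 5, limb = 0.01)  # limbs level with the branch point
  bh <- branch_height_profile(a, n_bins = 3)
  expect_equal(bh$count, c(0, 0, 1))  # branch point sits at the arbor top
  # upward limbs: bifurcation at exactly half the dendritic height
  nodes <- rbind(node_df(1, "soma", 0, 0, 0, 5, -1),
                 node_df(2, "dendrite", 0, 0, 0, 1, 1),
                 node_df(3, "dendrite", 0, 5, 0, 1, 2),
                 node_df(4, "dendrite", 2, 10, 0, 1, 3),
                 node_df(5, "dendrite", -2, 10, 0, 1, 3))
  bh2 <- branch_height_profile(arbor(nodes), n_bins = 3)
  expect_equal(which.max(bh2$count), 2)
})

test_that("arbor summary is self-consistent", {
  sim <- simulate_arbor(arbor_sim_config("mouse", seed = 32))
  s <- arbor_summary(sim$arbor)
  expect_lte(s$n_terminal_branches, s$n_branches)
  expect_gte(s$thin_fraction, 0); expect_lte(s$thin_fraction, 100)
  expect_equal(s$total_length, sim$truth$total_length)
  expect_equal(s$n_branches, sim$truth$n_branches)
  expect_equal(s$n_primary_dendrites, sim$truth$n_trunks)
})
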