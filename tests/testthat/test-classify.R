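test_that("morphology decision table is covered exhaustively", {
  # Poly: multiple trunks, regardless of everything else, both species
  for (sp in c("human", "mouse"))
    expect_equal(classify_morphology(pc_features(sp, n_trunks = 2,
                                                 soma_diameter = 30)),
                 "Poly")
  # human Normative: single trunk, no bifurcation within 2 soma diameters
  expect_equal(classify_morphology(pc_features(
    "human", 1, soma_diameter = 30, first_bifurcation_distance = 70)),
    "Normative")
  # human Split: symmetric bifurcation inside the window
  expect_equal(classify_morphology(pc_features(
    "human", 1, soma_diameter = 30, first_bifurcation_distance = 30,
    bifurcation_symmetric = TRUE)), "Split")
  # human Split: asymmetric, but minor branch projects > 200 um
  expect_equal(classify_morphology(pc_features(
    "human", 1, soma_diameter = 30, first_bifurcation_distance = 30,
    minor_branch_max_projection = 250)), "Split")
  # human Normative: asymmetric with minor projection below 200 um
  expect_equal(classify_morphology(pc_features(
    "human", 1, soma_diameter = 30, first_bifurcation_distance = 30,
    minor_branch_max_projection = 150)), "Normative")
  # mouse window is a fixed 40 um, minor threshold 100 um
  expect_equal(classify_morphology(pc_features(
    "mouse", 1, first_bifurcation_distance = 39,
    bifurcation_symmetric = TRUE)), "Split")
  expect_equal(classify_morphology(pc_features(
    "mouse", 1, first_bifurcation_distance = 41,
    bifurcation_symmetric = TRUE)), "Normative")
  expect_equal(classify_morphology(pc_features(
    "mouse", 1, first_bifurcation_distance = 30,
    minor_branch_max_projection = 120)), "Split")
  # numeric symmetry criterion: daughter ratio >= 0.75 counts as symmetric
  expect_equal(classify_morphology(pc_features(
    "human", 1, soma_diameter = 30, first_bifurcation_distance = 30,
    bifurcation_symmetric = 0.8)), "Split")
  expect_equal(classify_morphology(pc_features(
    "human", 1, soma_diameter = 30, first_bifurcation_distance = 30,
    bifurcation_symmetric = 0.5)), "Normative")
  expect_error(classify_morphology(pc_features("human", 0,
                                               soma_diameter = 30)),
               "at least one trunk")
})

test_that("orientation rules use species run lengths and the 30 deg angle", {
  # human Split: one dendrite parallel 350 um at 20 deg -> Horizontal
  f <- pc_features("human", 1, soma_diameter = 30,
                   first_bifurcation_distance = 30,
                   bifurcation_symmetric = TRUE,
                   parallel_run_lengths = c(350, 50),
                   angles_at_threshold = c(20, 80),
                   directions = c(1, 1))
  expect_equal(classify_orientation(f, "Split"), "Horizontal")
  # human Poly: opposing pair at 160 um each, < 30 deg -> Horizontal
  f2 <- pc_features("human", 2, parallel_run_lengths = c(160, 160),
                    angles_at_threshold = c(25, 25), directions = c(1, -1))
  expect_equal(classify_orientation(f2, "Poly"), "Horizontal")
  # same pair but co-directed -> Vertical
  f3 <- pc_features("human", 2, parallel_run_lengths = c(160, 160),
                    angles_at_threshold = c(25, 25), directions = c(1, 1))
  expect_equal(classify_orientation(f3, "Poly"), "Vertical")
  # angle at threshold >= 30 deg defeats the run length
  f4 <- pc_features("human", 2, parallel_run_lengths = c(400, 50),
                    angles_at_threshold = c(35, 10), directions = c(1, -1))
  expect_equal(classify_orientation(f4, "Poly"), "Vertical")
  # mouse Split with longest run 100 um (< 150) -> Vertical
  f5 <- pc_features("mouse", 1, first_bifurcation_distance = 30,
                    bifurcation_symmetric = TRUE,
                    parallel_run_lengths = c(100, 60),
                    angles_at_threshold = c(10, 10), directions = c(1, -1))
  expect_equal(classify_orientation(f5, "Split"), "Vertical")
  # mouse thresholds are halved: 160 um single run is enough
  f6 <- pc_features("mouse", 2, parallel_run_lengths = c(160, 10),
                    angles_at_threshold = c(10, 80), directions = c(1, 1))
  expect_equal(classify_orientation(f6, "Poly"), "Horizontal")
  expect_error(classify_orientation(f, "Normative"), "undefined")
})

test_that("foliar classification compares pial and GCL/WM border lengths", {
  expect_equal(classify_foliar(1200, 1000), "Gyrus")
  expect_equal(classify_foliar(1000, 1000), "Bank")
  expect_equal(classify_foliar(900, 1000), "Sulcus")
  expect_equal(classify_foliar(1040, 1000, tolerance = 0.05), "Bank")
  expect_equal(classify_foliar(1040, 1000, tolerance = 0), "Gyrus")
  expect_error(classify_foliar(-1, 1000), "positive")
  expect_error(classify_foliar(1000, 1000, tolerance = 1), "tolerance")
})

test_that("classification recovers generating labels away from boundaries", {
  set.seed(51)
  draw_features <- function(label, species) {
    preset <- species_preset(species)
    soma <- if (species == "human") runif(1, 25, 35) else runif(1, 18, 22)
    window <- if (species == "human") 2 * soma else 40
    if (label == "Poly")
      pc_features(species, n_trunks = sample(2:4, 1), soma_diameter = soma)
    else if (label == "Split")
      pc_features(species, 1, soma_diameter = soma,
                  first_bifurcation_distance = runif(1, 1, 0.8 * window),
                  bifurcation_symmetric = TRUE)
    else
      pc_features(species, 1, soma_diameter = soma,
                  first_bifurcation_distance = runif(1, 1.2, 3) * window,
                  minor_branch_max_projection =
                    0.5 * preset$minor_branch_projection)
  }
  for (i in 1:60) {
    species <- sample(c("human", "mouse"), 1)
    label <- sample(c("Normative", "Split", "Poly"), 1)
    expect_equal(classify_morphology(draw_features(label, species)), label)
  }
})
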