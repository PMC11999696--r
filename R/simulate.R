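## Synthetic-data generators. Each generator is seeded, deterministic and
## emits exact ground-truth bookkeeping alongside the data, so every
## analysis stage can be tested for parameter recovery without microscopy
## data. Defaults are calibrated to the cohort means in species_preset().

rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Cell-map simulation configuration
#'
#' Parameters of the 1-D cell map generator. Cells are laid out
#' anterior to posterior with positive spacing draws; the class label of
#' cell i copies cell i-1 with probability `copy_probability` (kappa) and is
#' otherwise drawn from `category_frequencies`. This first-order Markov
#' copying is the clustering mechanism: kappa = 0 gives independent labels
#' (the null), and kappa around 0.3--0.5 reproduces the published mean run
#' sizes of about 2.6--3.1 cells (expected run length 1/(1 - p_match) with
#' p_match = kappa + (1 - kappa) * sum(f^2)). Foliar labels follow an
#' alternating gyrus/bank/sulcus segmentation of the layer by position.
#'
#' @param n_cells number of cells.
#' @param species `"human"` or `"mouse"`; sets spacing and foliar-plan
#'   scale defaults.
#' @param category_frequencies named frequencies over the five classes
#'   (Normative, V-Split, H-Split, V-Poly, H-Poly), summing to 1.
#' @param copy_probability kappa in `[0, 1)`; kappa = 1 is rejected as
#'   degenerate.
#' @param spacing_mean,spacing_sd nearest-neighbor spacing along the layer,
#'   um (defaults 300/100 human, 30/10 mouse — within the species adjacency
#'   threshold so consecutive cells are usually adjacent, as in real maps).
#' @param foliar_lengths named vector of alternating segment lengths in um
#'   (`gyrus`, `bank`, `sulcus`); default c(1500, 2000, 1000) scaled by 0.2
#'   for mouse.
#' @param lobule,hemisphere,individual labels stamped on every cell.
#' @param seed RNG seed.
#' @return list of class `map_sim_config`.
#' @export
map_sim_config <- function(n_cells = 500, species = "human",
                           category_frequencies = c(
                             "Normative" = 0.10, "V-Split" = 0.25,
                             "H-Split" = 0.20, "V-Poly" = 0.25,
                             "H-Poly" = 0.20),
                           copy_probability = 0.4,
                           spacing_mean = NULL, spacing_sd = NULL,
                           foliar_lengths = NULL,
                           lobule = "L6", hemisphere = "vermis",
                           individual = "sim1", seed = 1) {
  species <- match.arg(species, c("human", "mouse"))
  if (abs(sum(category_frequencies) - 1) > 1e-8)
    stop("category frequencies must sum to 1")
  if (!setequal(names(category_frequencies), PC_CLASSES))
    stop("frequencies must be named over the five classes: ",
         paste(PC_CLASSES, collapse = ", "))
  if (copy_probability < 0 || copy_probability >= 1)
    stop("copy probability must lie in [0, 1); 1 is degenerate")
  scale <- if (species == "human") 1 else 0.1
  if (is.null(spacing_mean)) spacing_mean <- 300 * scale
  if (is.null(spacing_sd)) spacing_sd <- 100 * scale
  if (spacing_mean <= 0) stop("spacing mean must be positive")
  if (is.null(foliar_lengths))
    foliar_lengths <- c(gyrus = 1500, bank = 2000, sulcus = 1000) *
      (if (species == "human") 1 else 0.2)
  structure(list(n_cells = as.integer(n_cells), species = species,
                 category_frequencies = category_frequencies[PC_CLASSES],
                 copy_probability = copy_probability,
                 spacing_mean = spacing_mean, spacing_sd = spacing_sd,
                 foliar_lengths = foliar_lengths, lobule = lobule,
                 hemisphere = hemisphere, individual = individual,
                 seed = as.integer(seed)),
            class = "map_sim_config")
}

class_to_type <- function(label) {
  ifelse(label == "Normative", "Normative",
         ifelse(grepl("Split", label), "Split", "Poly"))
}

class_to_orientation <- function(label) {
  ifelse(label == "Normative", NA_character_,
         ifelse(substr(label, 1, 1) == "V", "Vertical", "Horizontal"))
}

#' Simulate a parasagittal cell map
#'
#' @param config a [map_sim_config()].
#' @return list with `map` (a `cell_map` data.frame in anterior-posterior
#'   order) and `truth` (the generative kappa, frequencies, spacing and
#'   seed).
#' @export
simulate_cell_map <- function(config) {
  stopifnot(inherits(config, "map_sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  spac <- rtnorm(max(n - 1L, 0L), config$spacing_mean, config$spacing_sd,
                 lower = 1e-6)
  x <- cumsum(c(0, spac))
  y <- stats::rnorm(n, 0, config$spacing_mean * 0.02)
  freq <- config$category_frequencies
  labels <- character(n)
  labels[1] <- sample(names(freq), 1, prob = freq)
  if (n > 1) {
    copy <- stats::runif(n - 1) < config$copy_probability
    fresh <- sample(names(freq), n - 1, replace = TRUE, prob = freq)
    for (i in 2:n) labels[i] <- if (copy[i - 1]) labels[i - 1] else
      fresh[i - 1]
  }
  cycle <- sum(config$foliar_lengths)
  edges <- cumsum(config$foliar_lengths)
  phase <- x %% cycle
  foliar <- c("Gyrus", "Bank", "Sulcus")[findInterval(phase, edges) + 1L]
  map <- data.frame(cell_id = paste0("c", seq_len(n)), x = x, y = y,
                    morph_type = class_to_type(labels),
                    orientation = class_to_orientation(labels),
                    foliar = foliar, lobule = config$lobule,
                    hemisphere = config$hemisphere,
                    individual = config$individual,
                    species = config$species)
  class(map) <- c("cell_map", "data.frame")
  list(map = map,
       truth = list(copy_probability = config$copy_probability,
                    category_frequencies = freq,
                    spacing_mean = config$spacing_mean,
                    seed = config$seed))
}

#' Arbor simulation configuration
#'
#' Parameters of the stochastic branching-tree generator. The number of
#' branch segments is drawn around the cohort mean and the topology built
#' by repeatedly bifurcating a uniformly random open tip until the drawn
#' count is reached, so the emitted segment count is exact; segment lengths
#' are gamma draws whose mean is the cohort total length divided by the
#' cohort branch count, making the expected total dendritic length equal to
#' the cohort target by construction. Growth is steered to stay below the
#' molecular-layer height cap (direction reflection, never truncation, so
#' bookkeeping length is preserved exactly).
#'
#' @param species `"human"` or `"mouse"`; fills all defaults from
#'   [species_preset()].
#' @param n_branches_mean,n_branches_sd branch-segment count distribution
#'   (cohort: 2750 +/- 247 human, 707 +/- 118 mouse).
#' @param total_length_target cohort mean total dendritic length, um
#'   (63645 human, 6004 mouse); sets the mean segment length
#'   `total_length_target / n_branches_mean`.
#' @param segment_length_cv coefficient of variation of segment lengths.
#' @param trunk_count_probs named probabilities for the number of primary
#'   dendrites (human PCs are mostly multi-trunked).
#' @param taper_ratio child/parent diameter ratio per branch order.
#' @param diameter_floor minimum (spiny) dendrite diameter, um.
#' @param height_cap molecular layer thickness bound, um.
#' @param node_step target inter-node spacing, um.
#' @param wiggle direction noise per node step (0 = straight segments).
#' @param seed RNG seed.
#' @return list of class `arbor_sim_config`.
#' @export
arbor_sim_config <- function(species = "human",
                             n_branches_mean = NULL, n_branches_sd = NULL,
                             total_length_target = NULL,
                             segment_length_cv = 0.6,
                             trunk_count_probs = NULL,
                             taper_ratio = 0.8, diameter_floor = NULL,
                             height_cap = NULL, node_step = 5,
                             wiggle = 0.35, seed = 1) {
  species <- match.arg(species, c("human", "mouse"))
  preset <- species_preset(species)
  if (is.null(n_branches_mean)) n_branches_mean <- preset$n_branches_mean
  if (is.null(n_branches_sd)) n_branches_sd <- preset$n_branches_sd
  if (is.null(total_length_target))
    total_length_target <- preset$total_length_mean
  if (is.null(trunk_count_probs))
    trunk_count_probs <- if (species == "human")
      c("1" = 0.35, "2" = 0.45, "3" = 0.20) else
      c("1" = 0.60, "2" = 0.35, "3" = 0.05)
  if (is.null(diameter_floor))
    diameter_floor <- preset$dendrite_diameter_spiny
  if (is.null(height_cap)) height_cap <- preset$max_height
  stopifnot(n_branches_mean > 0, total_length_target > 0, height_cap > 0,
            segment_length_cv > 0, node_step > 0)
  structure(list(species = species, n_branches_mean = n_branches_mean,
                 n_branches_sd = n_branches_sd,
                 total_length_target = total_length_target,
                 segment_length_mean = total_length_target / n_branches_mean,
                 segment_length_cv = segment_length_cv,
                 trunk_count_probs = trunk_count_probs,
                 taper_ratio = taper_ratio,
                 diameter_floor = diameter_floor,
                 primary_diameter = preset$primary_diameter,
                 soma_diameter = preset$soma_diameter,
                 height_cap = height_cap, node_step = node_step,
                 wiggle = wiggle, seed = as.integer(seed)),
            class = "arbor_sim_config")
}

#' Simulate a dendritic arbor
#'
#' @param config an [arbor_sim_config()].
#' @return list with `arbor` (an [arbor()]) and `truth` (exact bookkeeping:
#'   `total_length` equal to the emitted dendritic geometry, `n_branches`,
#'   `n_trunks`, `seed`).
#' @export
simulate_arbor <- function(config) {
  stopifnot(inherits(config, "arbor_sim_config"))
  set.seed(config$seed)
  n_trunks <- as.integer(sample(names(config$trunk_count_probs), 1,
                                prob = config$trunk_count_probs))
  B <- max(n_trunks, round(stats::rnorm(1, config$n_branches_mean,
                                        config$n_branches_sd)))
  # bifurcation bookkeeping needs B = n_trunks + 2 * n_bifurcations
  if ((B - n_trunks) %% 2L != 0L) B <- B + 1L
  n_bif <- (B - n_trunks) %/% 2L

  # topology: bifurcate a uniformly random open tip until B segments exist
  parent_seg <- rep(0L, n_trunks)
  tips <- seq_len(n_trunks)
  for (i in seq_len(n_bif)) {
    t <- tips[sample.int(length(tips), 1)]
    new_ids <- length(parent_seg) + 1:2
    parent_seg <- c(parent_seg, t, t)
    tips <- c(setdiff(tips, t), new_ids)
  }
  nseg <- length(parent_seg)
  ord <- ifelse(parent_seg == 0L, 1L, NA_integer_)
  for (i in seq_len(nseg)) if (is.na(ord[i])) ord[i] <- ord[parent_seg[i]] + 1L

  m <- config$segment_length_mean
  s <- m * config$segment_length_cv
  seg_len <- stats::rgamma(nseg, shape = (m / s)^2, scale = s^2 / m)
  seg_len <- pmax(seg_len, 0.5)
  diam <- pmax(config$primary_diameter * config$taper_ratio^(ord - 1L),
               config$diameter_floor)

  # geometry: soma at origin, trunks anchored on the soma top; each node
  # step has exact length so emitted length equals bookkeeping exactly
  r_soma <- config$soma_diameter / 2
  cap <- config$height_cap
  est_nodes <- sum(pmax(1L, ceiling(seg_len / config$node_step))) + nseg +
    n_trunks + 1L
  xyz <- matrix(NA_real_, est_nodes, 3)
  radius <- numeric(est_nodes)
  parent_node <- integer(est_nodes)
  structure_lab <- character(est_nodes)
  xyz[1, ] <- c(0, 0, 0); radius[1] <- r_soma
  parent_node[1] <- -1L; structure_lab[1] <- "soma"
  nn <- 1L

  tip_node <- integer(nseg)
  tip_dir <- matrix(NA_real_, nseg, 3)
  trunk_idx <- 0L
  for (i in seq_len(nseg)) {
    if (parent_seg[i] == 0L) {
      trunk_idx <- trunk_idx + 1L
      azim <- stats::runif(1, 0, 2 * pi)
      elev <- stats::runif(1, pi / 6, pi / 2)  # upward to oblique
      dir <- c(cos(elev) * cos(azim), sin(elev), 0.3 * cos(elev) * sin(azim))
      dir <- dir / sqrt(sum(dir^2))
      # anchor node on the soma surface; the soma->dendrite edge carries no
      # dendritic length
      nn <- nn + 1L
      xyz[nn, ] <- c(0, r_soma, 0)
      radius[nn] <- diam[i] / 2
      parent_node[nn] <- 1L
      structure_lab[nn] <- "dendrite"
      start_node <- nn
    } else {
      start_node <- tip_node[parent_seg[i]]
      pdir <- tip_dir[parent_seg[i], ]
      rot <- stats::rnorm(3, 0, 0.5)
      dir <- pdir + rot
      dir <- dir / sqrt(sum(dir^2))
    }
    nsteps <- max(1L, ceiling(seg_len[i] / config$node_step))
    step_len <- seg_len[i] / nsteps
    pos <- xyz[start_node, ]
    prev <- start_node
    for (k in seq_len(nsteps)) {
      d <- dir + stats::rnorm(3, 0, config$wiggle)
      # steer back inside the molecular layer [0, cap]
      if (pos[2] > 0.9 * cap) d[2] <- -abs(d[2])
      if (pos[2] < 0.1 * cap) d[2] <- abs(d[2])
      d <- d / sqrt(sum(d^2))
      pos <- pos + step_len * d
      nn <- nn + 1L
      xyz[nn, ] <- pos
      radius[nn] <- diam[i] / 2
      parent_node[nn] <- prev
      structure_lab[nn] <- "dendrite"
      prev <- nn
      dir <- d
    }
    tip_node[i] <- nn
    tip_dir[i, ] <- dir
  }
  nodes <- data.frame(id = seq_len(nn),
                      structure = structure_lab[seq_len(nn)],
                      x = xyz[seq_len(nn), 1], y = xyz[seq_len(nn), 2],
                      z = xyz[seq_len(nn), 3],
                      radius = radius[seq_len(nn)],
                      parent = parent_node[seq_len(nn)])
  a <- arbor(nodes, species = config$species, ml_thickness = cap)
  list(arbor = a,
       truth = list(total_length = sum(seg_len), n_branches = nseg,
                    n_trunks = n_trunks, seed = config$seed))
}

#' Spiny-branch simulation configuration
#'
#' Per-type spine counts are Poisson at `densities * branch_length`;
#' geometric attributes are drawn from truncated normals consistent with
#' the classification rules (thin heads below 0.5 um, mushroom at or above,
#' clusters with 3+ puncta and diameters scaling linearly with puncta
#' count). The mouse preset has cluster density 0: spine clusters are
#' modeled as absent in mouse.
#'
#' @param species `"human"` or `"mouse"`.
#' @param densities named per-type densities in spines/um; default from
#'   [species_preset()] (human total 6.80/um).
#' @param branch_length branch segment length in um.
#' @param region branch location label.
#' @param cluster_diameter_slope linear um-per-punctum scaling of cluster
#'   head diameter.
#' @param seed RNG seed.
#' @return list of class `spine_sim_config`.
#' @export
spine_sim_config <- function(species = "human", densities = NULL,
                             branch_length = 30, region = "intermediate",
                             cluster_diameter_slope = 0.06, seed = 1) {
  species <- match.arg(species, c("human", "mouse"))
  preset <- species_preset(species)
  if (is.null(densities)) densities <- preset$spine_density
  if (any(densities < 0)) stop("densities must be non-negative")
  if (!setequal(names(densities), SPINE_TYPES))
    stop("densities must be named over: ",
         paste(SPINE_TYPES, collapse = ", "))
  stopifnot(branch_length > 0)
  structure(list(species = species, densities = densities[SPINE_TYPES],
                 branch_length = branch_length, region = region,
                 cluster_diameter_slope = cluster_diameter_slope,
                 preset = preset, seed = as.integer(seed)),
            class = "spine_sim_config")
}

#' Simulate a spiny branch segment
#'
#' @param config a [spine_sim_config()].
#' @return list with `spines` (one row per spine), `length`,
#'   `mean_dendrite_diameter`, `region` and `truth` (generative densities
#'   and exact per-type counts).
#' @export
simulate_spiny_branch <- function(config) {
  stopifnot(inherits(config, "spine_sim_config"))
  set.seed(config$seed)
  p <- config$preset
  L <- config$branch_length
  counts <- stats::rpois(4, config$densities * L)
  names(counts) <- SPINE_TYPES
  rows <- list()
  mk <- function(type, n, diam, neck, protrusion, puncta, volume) {
    if (!n) return(NULL)
    data.frame(type = type, head_diameter = diam, neck_length = neck,
               protrusion_distance = protrusion, puncta_count = puncta,
               head_volume = volume)
  }
  nthin <- counts[["thin"]]
  if (nthin) {
    d <- rtnorm(nthin, if (config$species == "human") 0.34 else 0.28, 0.07,
                lower = 0.1, upper = 0.499)
    rows$thin <- mk("thin", nthin, d,
                    rtnorm(nthin, p$neck_length_mean, p$neck_length_sd, 0.05),
                    rtnorm(nthin, p$protrusion_mean, p$protrusion_sd, 0.2),
                    1L, sphere_volume(d))
  }
  nmush <- counts[["mushroom"]]
  if (nmush) {
    d <- rtnorm(nmush, 0.58, 0.07, lower = 0.5)
    rows$mushroom <- mk("mushroom", nmush, d,
                        rtnorm(nmush, p$neck_length_mean, p$neck_length_sd,
                               0.05),
                        rtnorm(nmush, p$protrusion_mean, p$protrusion_sd,
                               0.2),
                        1L, sphere_volume(d))
  }
  nbr <- counts[["branched"]]
  if (nbr) {
    d <- rtnorm(nbr, 0.4, 0.08, lower = 0.15)
    rows$branched <- mk("branched", nbr, d,
                        rtnorm(nbr, p$neck_length_mean, p$neck_length_sd,
                               0.05),
                        rtnorm(nbr, p$protrusion_mean, p$protrusion_sd, 0.2),
                        1L, 2 * sphere_volume(d))
  }
  ncl <- counts[["cluster"]]
  if (ncl) {
    puncta <- pmax(3L, round(stats::rnorm(ncl, p$cluster_puncta_mean,
                                          p$cluster_puncta_sd)))
    d <- pmax(0.5, p$cluster_head_diameter_mean +
                config$cluster_diameter_slope *
                (puncta - p$cluster_puncta_mean) +
                stats::rnorm(ncl, 0, 0.1))
    rows$cluster <- mk("cluster", ncl, d,
                       rtnorm(ncl, p$neck_length_mean, p$neck_length_sd,
                              0.05),
                       rtnorm(ncl, p$protrusion_mean, p$protrusion_sd, 0.2),
                       puncta,
                       rtnorm(ncl, p$cluster_head_volume_mean,
                              p$cluster_head_volume_sd, lower = 0.05))
  }
  spines <- do.call(rbind, rows)
  if (is.null(spines))
    spines <- data.frame(type = character(0), head_diameter = numeric(0),
                         neck_length = numeric(0),
                         protrusion_distance = numeric(0),
                         puncta_count = integer(0), head_volume = numeric(0))
  spines$spine_id <- seq_len(nrow(spines))
  rownames(spines) <- NULL
  list(spines = spines, length = L,
       mean_dendrite_diameter = p$dendrite_diameter_spiny,
       region = config$region,
       truth = list(densities = config$densities, counts = counts,
                    seed = config$seed))
}
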