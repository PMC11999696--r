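#' Species preset constants
#'
#' Default analysis thresholds and generative targets for adult human and
#' mouse Purkinje cells. The analysis thresholds (adjacency distance,
#' bifurcation window, orientation run lengths, shell widths) are the
#' published species-specific criteria; the generative targets (cohort mean
#' arbor size, per-type spine densities, spine geometry) are the cohort means
#' the synthetic-data generators are calibrated to reproduce.
#'
#' All lengths are in micrometers, densities in spines per micrometer,
#' angles in degrees.
#'
#' @param species `"human"` or `"mouse"`.
#' @return A named list of constants:
#' \describe{
#'   \item{adjacency_threshold}{max inter-somatic distance for two cells to
#'     count as adjacent in cluster scoring (1000 human / 200 mouse).}
#'   \item{bifurcation_window}{distance from the soma within which a primary
#'     trunk bifurcation makes a cell Split; `NA` for human, where it is
#'     2 x the measured soma diameter, fixed 40 for mouse.}
#'   \item{minor_branch_projection}{parasagittal projection an asymmetric
#'     minor daughter must exceed to count as a Split compartment
#'     (200 human / 100 mouse).}
#'   \item{parallel_run_single, parallel_run_pair}{run lengths for the
#'     single-dendrite (300/150) and opposing-pair (150/75) horizontal rules.}
#'   \item{parallel_angle}{maximum angle from the Purkinje cell layer plane
#'     for a dendrite to count as parallel (30).}
#'   \item{population_radius_min, population_radius_max}{population
#'     match-rate radii (250--10000 human, 50--2000 mouse).}
#'   \item{shell_width}{shell increment for shell match-rate profiles
#'     (500 human / 100 mouse).}
#'   \item{total_length_mean, total_length_sd}{cohort total dendritic length
#'     (63645 +/- 4572 human, 6004 +/- 831 mouse).}
#'   \item{n_branches_mean, n_branches_sd}{cohort branch-segment count
#'     (2750 +/- 247 human, 707 +/- 118 mouse).}
#'   \item{max_width, max_height}{cohort arbor extents (644 x 366 human,
#'     143 x 158 mouse).}
#'   \item{soma_diameter}{32.8 human / 16.5 mouse.}
#'   \item{primary_diameter}{thickest primary dendrite (6.49 / 3.12).}
#'   \item{spine_density}{named per-type densities (thin, mushroom, branched,
#'     cluster); human 5.37/0.49/0.42/0.52, mouse 4.56/0.13/0.49/0 (spine
#'     clusters are effectively absent in mouse).}
#'   \item{head_diameter_mean, head_diameter_sd}{thin/mushroom head diameter
#'     (0.36 +/- 0.10 human, 0.29 +/- 0.08 mouse).}
#'   \item{neck_length_mean, neck_length_sd}{0.83 +/- 0.48 / 0.70 +/- 0.31.}
#'   \item{protrusion_mean, protrusion_sd}{1.41 +/- 0.57 / 1.13 +/- 0.41.}
#'   \item{cluster_puncta_mean, cluster_puncta_sd}{4.84 +/- 1.75 (human).}
#'   \item{cluster_head_volume_mean, cluster_head_volume_sd}{0.49 +/- 0.42
#'     um^3 (human).}
#'   \item{cluster_head_diameter_mean, cluster_head_diameter_sd}{0.93 +/-
#'     0.19 (human).}
#'   \item{dendrite_diameter_spiny}{spiny dendrite caliber (0.68 / 0.73).}
#' }
#' @examples
#' species_preset("human")$adjacency_threshold  # 1000
#' species_preset("mouse")$spine_density[["cluster"]]  # 0
#' @export
species_preset <- function(species = c("human", "mouse")) {
  species <- match.arg(species)
  if (species == "human") {
    list(
      species = "human",
      adjacency_threshold = 1000,
      bifurcation_window = NA_real_,   # 2 x measured soma diameter
      minor_branch_projection = 200,
      parallel_run_single = 300,
      parallel_run_pair = 150,
      parallel_angle = 30,
      population_radius_min = 250,
      population_radius_max = 10000,
      shell_width = 500,
      total_length_mean = 63645, total_length_sd = 4572,
      n_branches_mean = 2750, n_branches_sd = 247,
      max_order = 50,
      max_width = 644, max_height = 366,
      soma_diameter = 32.8,
      primary_diameter = 6.49,
      spine_density = c(thin = 5.37, mushroom = 0.49,
                        branched = 0.42, cluster = 0.52),
      head_diameter_mean = 0.36, head_diameter_sd = 0.10,
      neck_length_mean = 0.83, neck_length_sd = 0.48,
      protrusion_mean = 1.41, protrusion_sd = 0.57,
      cluster_puncta_mean = 4.84, cluster_puncta_sd = 1.75,
      cluster_head_volume_mean = 0.49, cluster_head_volume_sd = 0.42,
      cluster_head_diameter_mean = 0.93, cluster_head_diameter_sd = 0.19,
      dendrite_diameter_spiny = 0.68
    )
  } else {
    list(
      species = "mouse",
      adjacency_threshold = 200,
      bifurcation_window = 40,
      minor_branch_projection = 100,
      parallel_run_single = 150,
      parallel_run_pair = 75,
      parallel_angle = 30,
      population_radius_min = 50,
      population_radius_max = 2000,
      shell_width = 100,
      total_length_mean = 6004, total_length_sd = 831,
      n_branches_mean = 707, n_branches_sd = 118,
      max_order = 28,
      max_width = 143, max_height = 158,
      soma_diameter = 16.5,
      primary_diameter = 3.12,
      spine_density = c(thin = 4.56, mushroom = 0.13,
                        branched = 0.49, cluster = 0),
      head_diameter_mean = 0.29, head_diameter_sd = 0.08,
      neck_length_mean = 0.70, neck_length_sd = 0.31,
      protrusion_mean = 1.13, protrusion_sd = 0.41,
      cluster_puncta_mean = NA_real_, cluster_puncta_sd = NA_real_,
      cluster_head_volume_mean = NA_real_, cluster_head_volume_sd = NA_real_,
      cluster_head_diameter_mean = NA_real_, cluster_head_diameter_sd = NA_real_,
      dendrite_diameter_spiny = 0.73
    )
  }
}

# The five complete morphology-orientation classes used throughout the
# clustering analyses.
PC_CLASSES <- c("Normative", "V-Split", "H-Split", "V-Poly", "H-Poly")

MORPH_TYPES <- c("Normative", "Split", "Poly")
ORIENTATIONS <- c("Vertical", "Horizontal")
FOLIAR_LABELS <- c("Gyrus", "Bank", "Sulcus")
SPINE_TYPES <- c("thin", "mushroom", "branched", "cluster")
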