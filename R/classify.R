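## Rule-based Purkinje cell classifiers: primary-dendrite morphology
## (Normative / Split / Poly), orientation (Vertical / Horizontal) and
## foliar subregion (Gyrus / Bank / Sulcus), with species-specific
## thresholds from species_preset().

#' Primary-dendrite feature bundle
#'
#' Collects the measurements the morphology and orientation rules consume.
#'
#' @param species `"human"` or `"mouse"`.
#' @param n_trunks number of primary dendrites emerging from the soma (>= 1).
#' @param soma_diameter soma diameter in um (sets the human bifurcation
#'   window of two soma distances).
#' @param first_bifurcation_distance distance from the soma at which the
#'   primary trunk first bifurcates, um; `Inf` if it never does.
#' @param bifurcation_symmetric was that bifurcation symmetric? A numeric
#'   daughter diameter ratio may be supplied instead (>= `symmetry_ratio`
#'   counts as symmetric), as an automated stand-in for the visual call.
#' @param minor_branch_max_projection parasagittal distance the smaller
#'   daughter of an asymmetric bifurcation projects from the main dendritic
#'   compartment, um.
#' @param parallel_run_lengths per primary dendrite, the length (um) over
#'   which it ramifies parallel with the Purkinje cell layer.
#' @param angles_at_threshold per primary dendrite, the angle (degrees) from
#'   the layer plane at the species run-length threshold.
#' @param directions per primary dendrite, the parasagittal direction sign
#'   (+1 / -1), used by the opposing-pair rule.
#' @param symmetry_ratio daughter diameter ratio treated as symmetric when
#'   `bifurcation_symmetric` is numeric, default 0.75.
#' @return list of class `pc_features`.
#' @export
pc_features <- function(species, n_trunks, soma_diameter = NA,
                        first_bifurcation_distance = Inf,
                        bifurcation_symmetric = FALSE,
                        minor_branch_max_projection = 0,
                        parallel_run_lengths = numeric(0),
                        angles_at_threshold = numeric(0),
                        directions = numeric(0),
                        symmetry_ratio = 0.75) {
  species <- match.arg(species, c("human", "mouse"))
  if (is.numeric(bifurcation_symmetric))
    bifurcation_symmetric <- bifurcation_symmetric >= symmetry_ratio
  if (length(angles_at_threshold) &&
      any(angles_at_threshold < 0 | angles_at_threshold > 90, na.rm = TRUE))
    stop("angles must lie in [0, 90] degrees")
  structure(list(species = species, n_trunks = n_trunks,
                 soma_diameter = soma_diameter,
                 first_bifurcation_distance = first_bifurcation_distance,
                 bifurcation_symmetric = isTRUE(bifurcation_symmetric),
                 minor_branch_max_projection = minor_branch_max_projection,
                 parallel_run_lengths = parallel_run_lengths,
                 angles_at_threshold = angles_at_threshold,
                 directions = directions),
            class = "pc_features")
}

#' Classify primary-dendrite morphology
#'
#' A cell is `Poly` if more than one trunk emerges from the soma, regardless
#' of relative size. With a single trunk it is `Split` if the trunk
#' bifurcates within the species bifurcation window (two measured soma
#' diameters in human, a fixed 40 um in mouse) and the bifurcation is either
#' symmetric or its smaller daughter projects more than 200 um (human;
#' 100 um mouse) in the parasagittal axis from the main dendritic
#' compartment; otherwise `Normative`.
#'
#' @param features a [pc_features()] bundle.
#' @return `"Normative"`, `"Split"` or `"Poly"`.
#' @examples
#' classify_morphology(pc_features("human", n_trunks = 2))  # Poly
#' classify_morphology(pc_features("human", n_trunks = 1, soma_diameter = 30,
#'   first_bifurcation_distance = 30, bifurcation_symmetric = FALSE,
#'   minor_branch_max_projection = 250))  # Split
#' @export
classify_morphology <- function(features) {
  stopifnot(inherits(features, "pc_features"))
  f <- features
  if (is.na(f$n_trunks) || f$n_trunks < 1)
    stop("cell must have at least one trunk")
  if (f$n_trunks > 1) return("Poly")
  preset <- species_preset(f$species)
  window <- if (f$species == "human") {
    if (is.na(f$soma_diameter))
      stop("human morphology rule needs the measured soma diameter")
    2 * f$soma_diameter
  } else preset$bifurcation_window
  if (f$first_bifurcation_distance <= window &&
      (f$bifurcation_symmetric ||
       f$minor_branch_max_projection > preset$minor_branch_projection))
    "Split" else "Normative"
}

#' Classify primary-dendrite orientation
#'
#' Split and Poly cells are `Horizontal` if a single primary dendrite
#' ramifies parallel with the Purkinje cell layer for more than 300 um in
#' human (150 um mouse), or two primary dendrites ramify in opposing
#' parasagittal directions for more than 150 um each (75 um mouse). A
#' dendrite counts as parallel when, at the relevant run-length threshold
#' from the soma, it ramifies at less than 30 degrees from the layer plane.
#' Otherwise the cell is `Vertical`. Orientation is undefined for Normative
#' cells.
#'
#' @param features a [pc_features()] bundle; `parallel_run_lengths`,
#'   `angles_at_threshold` and `directions` must be aligned per dendrite.
#' @param morph_type the cell's morphology class; calling on `"Normative"`
#'   is an error.
#' @return `"Vertical"` or `"Horizontal"`.
#' @export
classify_orientation <- function(features,
                                 morph_type = classify_morphology(features)) {
  stopifnot(inherits(features, "pc_features"))
  if (morph_type == "Normative")
    stop("orientation undefined for Normative cells")
  f <- features
  preset <- species_preset(f$species)
  run <- f$parallel_run_lengths
  ang <- f$angles_at_threshold
  dir <- f$directions
  if (!length(run)) return("Vertical")
  if (length(ang) != length(run))
    stop("need one angle per dendrite run length")
  parallel <- ang < preset$parallel_angle
  if (any(run > preset$parallel_run_single & parallel)) return("Horizontal")
  if (length(dir) == length(run)) {
    cand <- which(run > preset$parallel_run_pair & parallel)
    if (length(cand) >= 2L &&
        any(outer(dir[cand], dir[cand], `*`) < 0)) return("Horizontal")
  }
  "Vertical"
}

#' Classify a foliar subregion
#'
#' Compares the parasagittal length of the pial surface to that of the
#' border between the granule cell layer and the white matter. Regions
#' where the pial surface is longer (expanded molecular layer) are `Gyrus`,
#' where it is shorter (compressed) `Sulcus`, and where the two are equal
#' within a relative tolerance `Bank`. The tolerance exists because exact
#' equality is a qualitative call on traced outlines.
#'
#' @param pial_length parasagittal pial surface length, um.
#' @param gcl_wm_border_length granule-layer/white-matter border length, um.
#' @param tolerance relative band around a ratio of 1 treated as equal,
#'   default 0.05.
#' @return `"Gyrus"`, `"Bank"` or `"Sulcus"`.
#' @examples
#' classify_foliar(1200, 1000)  # Gyrus
#' classify_foliar(1000, 1000)  # Bank
#' classify_foliar(900, 1000)   # Sulcus
#' @export
classify_foliar <- function(pial_length, gcl_wm_border_length,
                            tolerance = 0.05) {
  if (pial_length <= 0 || gcl_wm_border_length <= 0)
    stop("outline lengths must be positive")
  if (tolerance < 0 || tolerance >= 1)
    stop("tolerance must lie in [0, 1)")
  rho <- pial_length / gcl_wm_border_length
  if (rho > 1 + tolerance) "Gyrus"
  else if (rho < 1 - tolerance) "Sulcus"
  else "Bank"
}
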