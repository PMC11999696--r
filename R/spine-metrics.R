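## Dendritic spine taxonomy, densities and spine-to-surround volume
## fractions, plus the confocal resolution helper.

#' Rayleigh diffraction limit
#'
#' Minimum resolvable distance `R = 0.61 * lambda / NA` for a confocal
#' objective, modestly more conservative than the Abbe limit (0.5 constant).
#' At 555 nm (Cy3 excitation) and NA 1.4 this is 241.8 nm, the practical
#' floor for spine head measurements.
#'
#' @param wavelength_nm fluorophore excitation wavelength in nm.
#' @param numerical_aperture objective numerical aperture.
#' @return limit in nm.
#' @examples
#' rayleigh_limit(555, 1.4)  # 241.8
#' @export
rayleigh_limit <- function(wavelength_nm, numerical_aperture) {
  if (any(wavelength_nm <= 0) || any(numerical_aperture <= 0))
    stop("wavelength and numerical aperture must be positive")
  0.61 * wavelength_nm / numerical_aperture
}

#' Classify a dendritic spine
#'
#' Rule-based taxonomy: a spine with two heads emerging from a shared neck
#' is `branched`; a single head bearing three or more distinct puncta is a
#' `cluster`; otherwise a single smooth head below 0.5 um diameter is `thin`
#' and at or above 0.5 um is `mushroom` (the 500 nm boundary is assigned to
#' mushroom).
#'
#' @param head_count number of heads (>= 1).
#' @param head_diameters head diameter(s) in um; the largest is used.
#' @param puncta_per_head distinct puncta on the (single) head, default 1.
#' @return one of `"thin"`, `"mushroom"`, `"branched"`, `"cluster"`.
#' @examples
#' classify_spine(1, 0.4)       # thin
#' classify_spine(1, 0.6)       # mushroom
#' classify_spine(1, 0.9, 4)    # cluster
#' classify_spine(2, c(0.3, 0.4))  # branched
#' @export
classify_spine <- function(head_count, head_diameters, puncta_per_head = 1) {
  if (length(head_count) != 1L || is.na(head_count) || head_count < 1)
    stop("spine must have at least one head")
  if (head_count >= 2) return("branched")
  if (max(puncta_per_head) >= 3) return("cluster")
  if (max(head_diameters) < 0.5) "thin" else "mushroom"
}

#' Spine densities on a branch segment
#'
#' Counts per micrometer, overall and by spine type. Branched spines count
#' once (as one spine) regardless of head number; per-head counts stay in
#' the record for synapse extrapolation. Per-type densities sum to the total
#' exactly.
#'
#' @param spines data.frame of spine records with a `type` column (may have
#'   zero rows).
#' @param length branch segment length in um, > 0.
#' @return named vector: `total`, `thin`, `mushroom`, `branched`, `cluster`,
#'   all in spines/um.
#' @export
spine_densities <- function(spines, length) {
  if (length <= 0) stop("branch length must be positive")
  counts <- table(factor(spines$type, levels = SPINE_TYPES))
  dens <- as.numeric(counts) / length
  names(dens) <- SPINE_TYPES
  c(total = sum(dens), dens)
}

#' Spine-to-surround volume fraction
#'
#' Percentage of the space around a dendrite occupied by spine heads: the
#' summed head volumes divided by the volume of the cylindrical shell
#' between the dendrite surface (mean dendritic radius `r`) and the reach of
#' the spines (`r + p`, with `p` the mean head protrusion distance), i.e.
#' `100 * sum(V) / (pi * L * ((r + p)^2 - r^2))`.
#'
#' @param spines data.frame with `head_volume` (um^3) and
#'   `protrusion_distance` (um) columns.
#' @param length branch length `L` in um.
#' @param dendrite_radius mean dendritic radius `r` in um, > 0.
#' @param protrusion mean protrusion distance `p` in um; defaults to the
#'   mean of the spine records.
#' @return percent.
#' @examples
#' sp <- data.frame(head_volume = c(0.5, 0.5), protrusion_distance = 1)
#' volume_fraction(sp, length = 10, dendrite_radius = 0.5)  # ~1.59
#' @export
volume_fraction <- function(spines, length, dendrite_radius,
                            protrusion = mean(spines$protrusion_distance)) {
  if (length <= 0 || dendrite_radius <= 0)
    stop("branch length and dendrite radius must be positive")
  if (!nrow(spines)) return(0)
  if (is.na(protrusion) || protrusion <= 0)
    stop("degenerate shell: zero mean protrusion with spines present")
  shell <- pi * length *
    ((dendrite_radius + protrusion)^2 - dendrite_radius^2)
  100 * sum(spines$head_volume) / shell
}

#' Spherical head volume from diameter
#'
#' Default head volume model, `(pi/6) d^3`; measured volumes (e.g. for
#' spine clusters) may be supplied instead.
#'
#' @param diameter head diameter in um.
#' @return volume in um^3.
#' @export
sphere_volume <- function(diameter) pi / 6 * diameter^3

#' Extrapolated total spine count
#'
#' Product of total dendritic length and mean spine density, rounded to the
#' nearest spine; e.g. 6004 um x 5.1/um gives about 30,620 spines for a
#' mouse Purkinje cell, 63,645 x 6.81 about 433,422 for human.
#'
#' @param total_length_um total dendritic length in um.
#' @param density_per_um spine density in spines/um.
#' @return integer count.
#' @export
extrapolate_total_spines <- function(total_length_um, density_per_um) {
  if (total_length_um < 0 || density_per_um < 0)
    stop("length and density must be non-negative")
  round(total_length_um * density_per_um)
}

#' Spine cluster puncta statistics
#'
#' Summaries of the cluster-type spines on a branch: mean puncta per
#' cluster, mean head volume, the ordinary least-squares slope of head
#' diameter on puncta count (linear scaling of cluster size with discrete
#' puncta), and the density of clustered puncta per um of branch.
#'
#' @param spines data.frame of spine records (`type`, `puncta_count`,
#'   `head_diameter`, `head_volume`).
#' @param length branch length in um (for the puncta density).
#' @return list with `mean_puncta`, `mean_head_volume`,
#'   `diameter_puncta_slope` (`NA` when fewer than 2 distinct puncta
#'   counts), `clustered_puncta_density` (puncta/um) and `n_clusters`.
#' @export
cluster_puncta_stats <- function(spines, length) {
  if (length <= 0) stop("branch length must be positive")
  cl <- spines[spines$type == "cluster", , drop = FALSE]
  if (!nrow(cl))
    return(list(mean_puncta = NA_real_, mean_head_volume = NA_real_,
                diameter_puncta_slope = NA_real_,
                clustered_puncta_density = 0, n_clusters = 0L))
  slope <- if (length(unique(cl$puncta_count)) >= 2L)
    stats::coef(stats::lm(head_diameter ~ puncta_count, data = cl))[["puncta_count"]]
  else NA_real_
  list(mean_puncta = mean(cl$puncta_count),
       mean_head_volume = mean(cl$head_volume),
       diameter_puncta_slope = slope,
       clustered_puncta_density = sum(cl$puncta_count) / length,
       n_clusters = nrow(cl))
}
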