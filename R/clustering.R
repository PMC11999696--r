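## 1-D spatial cell-type clustering along the Purkinje cell layer:
## adjacency cluster scores, run statistics, label-permutation nulls, and
## population / shell match-rate profiles.

#' Cell class labels for a match mode
#'
#' Collapses morphology and orientation into the label used for matching.
#' In `complete` mode cells fall into the five classes Normative, V-Split,
#' H-Split, V-Poly and H-Poly (a vertical Split does not match a horizontal
#' Split). `type_only` matches on Normative/Split/Poly alone and
#' `orientation_only` on Vertical/Horizontal; Normative cells, which carry
#' no orientation, match only other Normative cells in that mode.
#'
#' @param map a cell map (data.frame with `morph_type` and `orientation`).
#' @param match_mode `"complete"`, `"type_only"` or `"orientation_only"`.
#' @return character vector of labels.
#' @export
pc_class_labels <- function(map, match_mode = c("complete", "type_only",
                                                "orientation_only")) {
  match_mode <- match.arg(match_mode)
  type <- as.character(map$morph_type)
  ori <- as.character(map$orientation)
  switch(match_mode,
    complete = ifelse(type == "Normative", "Normative",
                      paste0(substr(ori, 1, 1), "-", type)),
    type_only = type,
    orientation_only = ifelse(type == "Normative", "Normative", ori))
}

consecutive_distances <- function(map) {
  n <- nrow(map)
  if (n < 2L) return(numeric(0))
  sqrt(diff(map$x)^2 + diff(map$y)^2)
}

default_threshold <- function(map, threshold) {
  if (!is.null(threshold)) return(threshold)
  sp <- unique(as.character(map$species))
  if (length(sp) != 1L)
    stop("map mixes species; pass `threshold` explicitly")
  species_preset(sp)$adjacency_threshold
}

#' Adjacency cluster scores
#'
#' Each cell starts at a cluster score of -1. If it has at least one
#' immediately adjacent cell (leading or following along the
#' anterior-posterior order) within the species threshold distance (1000 um
#' human, 200 um mouse) the score becomes 0, and each adjacent within-
#' threshold cell whose class label matches adds +1, for a final score in
#' {-1, 0, 1, 2}.
#'
#' @param map a cell map for one slice, ordered anterior to posterior.
#' @param threshold adjacency distance in um; default from the map's
#'   species preset.
#' @inheritParams pc_class_labels
#' @return data.frame with `cell_id`, `label`, `score` and `run_id`
#'   (consecutive id shared by cells of an uninterrupted matching run, `NA`
#'   outside runs).
#' @examples
#' m <- data.frame(cell_id = 1:4, x = c(0, 100, 200, 300), y = 0,
#'                 morph_type = c("Normative", "Split", "Split", "Poly"),
#'                 orientation = c(NA, "Vertical", "Vertical", "Vertical"),
#'                 species = "mouse")
#' adjacency_scores(m)$score  # 0 1 1 0
#' @export
adjacency_scores <- function(map, threshold = NULL,
                             match_mode = "complete") {
  threshold <- default_threshold(map, threshold)
  if (threshold <= 0) stop("threshold must be positive")
  n <- nrow(map)
  labels <- pc_class_labels(map, match_mode)
  score <- rep(-1L, n)
  if (n >= 2L) {
    d <- consecutive_distances(map)
    within <- d <= threshold
    matched <- within & labels[-n] == labels[-1]
    has_prev <- c(FALSE, within)
    has_next <- c(within, FALSE)
    adj <- has_prev | has_next
    score[adj] <- 0L
    score <- score + c(FALSE, matched) + c(matched, FALSE)
  } else if (n == 1L) {
    matched <- logical(0)
  } else matched <- logical(0)
  run_id <- rep(NA_integer_, n)
  if (n >= 2L && any(matched)) {
    r <- rle(matched)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- 0L
    for (j in which(r$values)) {
      k <- k + 1L
      run_id[starts[j]:(ends[j] + 1L)] <- k
    }
  }
  data.frame(cell_id = map$cell_id, label = labels, score = score,
             run_id = run_id)
}

#' Cluster run statistics
#'
#' Maximal stretches of consecutive cells in which every adjacent pair is
#' within the threshold distance and shares the same class label. A
#' sub-threshold gap or a label change terminates the run. Run length is the
#' summed consecutive Euclidean inter-somatic distance.
#'
#' @inheritParams adjacency_scores
#' @param scores optionally reuse an [adjacency_scores()] result.
#' @return data.frame with one row per run: `run_id`, `label`, `n_cells`,
#'   `run_length` (um); zero rows when nothing matches.
#' @export
cluster_runs <- function(map, threshold = NULL, match_mode = "complete",
                         scores = adjacency_scores(map, threshold,
                                                   match_mode)) {
  d <- consecutive_distances(map)
  ids <- sort(unique(scores$run_id[!is.na(scores$run_id)]))
  out <- data.frame(run_id = integer(0), label = character(0),
                    n_cells = integer(0), run_length = numeric(0))
  for (id in ids) {
    rows <- which(scores$run_id == id)
    out <- rbind(out, data.frame(
      run_id = id, label = scores$label[rows[1]],
      n_cells = length(rows),
      run_length = sum(d[rows[-length(rows)]])))
  }
  out
}

#' Shuffle specification
#'
#' Parameters of the label-permutation null: `global` mode permutes the
#' (morphology, orientation) pairs across all cells of the map without
#' replacement; `within_foliar` permutes only within each foliar subdivision
#' so foliar composition is held fixed. Coordinates and every other field
#' stay untouched, and the label multiset is conserved exactly. The
#' permutation sequence is a seeded Fisher-Yates shuffle: the same seed
#' always yields the same shuffles.
#'
#' @param mode `"global"` or `"within_foliar"`.
#' @param n_reps number of shuffles, default 20.
#' @param seed integer RNG seed.
#' @return list of class `shuffle_spec`.
#' @export
shuffle_spec <- function(mode = c("global", "within_foliar"), n_reps = 20,
                         seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_reps >= 1, is.finite(seed))
  structure(list(mode = mode, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)), class = "shuffle_spec")
}

permute_labels <- function(map, mode) {
  n <- nrow(map)
  perm <- if (mode == "global") sample.int(n) else {
    p <- seq_len(n)
    for (stratum in split(seq_len(n), map$foliar))
      p[stratum] <- stratum[sample.int(length(stratum))]
    p
  }
  map$morph_type <- map$morph_type[perm]
  map$orientation <- map$orientation[perm]
  map
}

#' Shuffled-label null maps
#'
#' @param map a cell map.
#' @param spec a [shuffle_spec()].
#' @return list of `spec$n_reps` maps with permuted labels.
#' @export
shuffle_map <- function(map, spec = shuffle_spec()) {
  stopifnot(inherits(spec, "shuffle_spec"))
  set.seed(spec$seed)
  lapply(seq_len(spec$n_reps), function(i) permute_labels(map, spec$mode))
}

clustered_rate <- function(scores, include_isolated = FALSE) {
  denom <- if (include_isolated) length(scores$score) else
    sum(scores$score >= 0L)
  if (denom == 0L) return(NA_real_)
  sum(scores$score >= 1L) / denom
}

#' Adjacent clustering excess over the shuffled null
#'
#' The observed rate of nonzero cluster scores (share of cells with score
#' >= 1 among cells with at least one adjacent neighbor, score >= 0) minus
#' the mean of the same rate over label-shuffled maps, in percentage
#' points. Positive values mean adjacent cells share morphological classes
#' more often than chance.
#'
#' @inheritParams adjacency_scores
#' @param spec a [shuffle_spec()].
#' @param include_isolated count score -1 cells in the denominator
#'   (default `FALSE`).
#' @return list with `excess` (percentage points), `observed_rate`,
#'   `shuffled_rates` (per shuffle), both as percent.
#' @export
clustering_excess <- function(map, spec = shuffle_spec(), threshold = NULL,
                              match_mode = "complete",
                              include_isolated = FALSE) {
  threshold <- default_threshold(map, threshold)
  obs <- clustered_rate(adjacency_scores(map, threshold, match_mode),
                        include_isolated)
  if (is.na(obs)) stop("all cells are isolated; clustering rate undefined")
  null_rates <- vapply(shuffle_map(map, spec), function(m)
    clustered_rate(adjacency_scores(m, threshold, match_mode),
                   include_isolated), numeric(1))
  list(excess = 100 * (obs - mean(null_rates)),
       observed_rate = 100 * obs,
       shuffled_rates = 100 * null_rates)
}

# Mean per-class surround composition within [inner, outer] of each cell.
# Returns the 5 x 5 matrix M[focal, surround]: the mean, over cells of the
# focal class with a non-empty surround, of the class proportions among
# surrounding cells; plus the count of contributing cells per focal class.
surround_composition <- function(x, y, labels, classes, inner, outer) {
  n <- length(x)
  d <- sqrt(outer(x, x, `-`)^2 + outer(y, y, `-`)^2)
  keep <- d >= inner & d <= outer
  diag(keep) <- FALSE
  lab_ind <- outer(labels, classes, `==`) * 1  # n x K indicator
  counts <- keep %*% lab_ind                   # per-cell surround counts
  tot <- rowSums(counts)
  props <- counts / ifelse(tot > 0, tot, NA)
  M <- matrix(NA_real_, length(classes), length(classes),
              dimnames = list(focal = classes, surround = classes))
  contributing <- setNames(integer(length(classes)), classes)
  for (k in seq_along(classes)) {
    rows <- which(labels == classes[k] & tot > 0)
    contributing[k] <- length(rows)
    if (length(rows))
      M[k, ] <- colMeans(props[rows, , drop = FALSE])
  }
  list(M = M, contributing = contributing)
}

match_profile_point <- function(map, spec, inner, outer, match_mode) {
  classes <- sort(unique(pc_class_labels(map, match_mode)))
  labels <- pc_class_labels(map, match_mode)
  obs <- surround_composition(map$x, map$y, labels, classes, inner, outer)
  nulls <- lapply(shuffle_map(map, spec), function(m)
    surround_composition(m$x, m$y, pc_class_labels(m, match_mode),
                         classes, inner, outer)$M)
  null_mean <- Reduce(`+`, nulls) / length(nulls)
  elev <- 100 * (obs$M - null_mean)
  diag_ok <- !is.na(diag(elev))
  off <- elev; diag(off) <- NA
  list(classes = classes,
       observed = 100 * obs$M, shuffled = 100 * null_mean,
       elevation = elev,
       matching = mean(diag(elev), na.rm = TRUE),
       nonmatching = mean(off, na.rm = TRUE),
       n_contributing = obs$contributing)
}

#' Population match-rate profile
#'
#' For each cell, the class composition of the whole surrounding population
#' within a given distance is tallied (excluding the cell itself); per focal
#' class these compositions are averaged and the same quantity computed on
#' label-shuffled maps is subtracted. The per-class elevations are averaged
#' (unweighted) into a matching summary (same-class surround, diagonal) and
#' a nonmatching summary (off-diagonal), in percentage points. Published
#' radii run from 250 um (human) / 50 um (mouse) up to 10 mm / 2 mm.
#'
#' @param map a cell map.
#' @param radii one or more radii in um, > 0.
#' @param spec a [shuffle_spec()].
#' @inheritParams pc_class_labels
#' @return object of class `match_profile`: data.frame with one row per
#'   radius (`inner`, `outer`, `matching`, `nonmatching`) and attribute
#'   `detail`, the per-radius list of observed/shuffled/elevation matrices.
#' @export
population_match_profile <- function(map, radii, spec = shuffle_spec(),
                                     match_mode = "complete") {
  if (any(radii <= 0)) stop("radii must be positive")
  pts <- lapply(radii, function(r)
    match_profile_point(map, spec, 0, r, match_mode))
  out <- data.frame(inner = 0, outer = radii,
                    matching = vapply(pts, `[[`, numeric(1), "matching"),
                    nonmatching = vapply(pts, `[[`, numeric(1),
                                         "nonmatching"))
  structure(out, detail = pts,
            class = c("match_profile", "data.frame"))
}

#' Shell match-rate profile
#'
#' Like [population_match_profile()] but restricted to an annulus
#' `[k * w, (k + 1) * w)` on either side of each cell, ignoring the core of
#' more local cells, which isolates clustering at distance from the strong
#' local signal. Default shell width 500 um in human; mouse shells are 20%
#' of the human length (100 um), matching the species dendritic-width
#' ratio. Cells with an empty shell are excluded from that shell's average.
#'
#' @param map a cell map.
#' @param shell_width shell increment `w` in um; default from the map's
#'   species preset.
#' @param shells shell indices `k` (shell k spans `[k*w, (k+1)*w)`).
#' @inheritParams population_match_profile
#' @return a `match_profile` (one row per shell).
#' @export
shell_match_profile <- function(map, shell_width = NULL, shells = 1:6,
                                spec = shuffle_spec(),
                                match_mode = "complete") {
  if (is.null(shell_width)) {
    sp <- unique(as.character(map$species))
    if (length(sp) != 1L) stop("map mixes species; pass `shell_width`")
    shell_width <- species_preset(sp)$shell_width
  }
  if (shell_width <= 0) stop("shell width must be positive")
  pts <- lapply(shells, function(k)
    match_profile_point(map, spec, k * shell_width,
                        (k + 1) * shell_width - 1e-9, match_mode))
  out <- data.frame(inner = shells * shell_width,
                    outer = (shells + 1) * shell_width,
                    matching = vapply(pts, `[[`, numeric(1), "matching"),
                    nonmatching = vapply(pts, `[[`, numeric(1),
                                         "nonmatching"))
  structure(out, detail = pts,
            class = c("match_profile", "data.frame"))
}

#' @export
plot.match_profile <- function(x, ...) {
  r <- x$outer
  graphics::plot(r, x$matching, type = "b", pch = 16,
                 ylim = range(c(x$matching, x$nonmatching, 0)),
                 xlab = "distance (um)",
                 ylab = "elevation over shuffled (%)", ...)
  graphics::lines(r, x$nonmatching, type = "b", pch = 1, col = "grey50")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("matching", "nonmatching"),
                   pch = c(16, 1), col = c("black", "grey50"), bty = "n")
  invisible(x)
}

#' Demographic table and chi-squared comparison
#'
#' Per-group category counts and percentages for a cell map, with a
#' chi-squared test of independence on the count table (delegated to
#' [stats::chisq.test()]). Empty groups are dropped with a warning.
#'
#' @param map a cell map.
#' @param group_by grouping column, e.g. `"lobule"`, `"foliar"` or
#'   `"hemisphere"`.
#' @param match_mode class definition, see [pc_class_labels()].
#' @return list with `counts` (groups x classes), `percent`, and `test`
#'   (`htest` from [stats::chisq.test()], `NULL` with fewer than 2 groups).
#' @export
demographics <- function(map, group_by = "lobule",
                         match_mode = "complete") {
  labels <- pc_class_labels(map, match_mode)
  groups <- as.character(map[[group_by]])
  counts <- table(group = groups, class = labels)
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("dropping empty group(s): ",
            paste(rownames(counts)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  percent <- 100 * prop.table(counts, 1)
  test <- if (nrow(counts) >= 2L)
    suppressWarnings(stats::chisq.test(counts)) else NULL
  list(counts = counts, percent = percent, test = test)
}

#' Category rates from counts
#'
#' Percentages of a count vector; e.g. innervation class counts
#' `c(22, 11, 6, 5)` of 44 cells give rates 50.0, 25.0, 13.6, 11.4.
#'
#' @param counts named or unnamed non-negative counts.
#' @return percentages summing to 100.
#' @export
category_rates <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  100 * counts / sum(counts)
}

#' Inter-hemisphere demographic difference
#'
#' Per lobule, the mean over the five morphology-orientation classes of the
#' absolute difference in class percentage between the left and right
#' hemisphere of one individual, and the same normalized to a reference
#' lobule (default L6, the most functionally symmetric).
#'
#' @param left_map,right_map cell maps of the two hemispheres (same lobule
#'   set).
#' @param reference_lobule lobule used for normalization.
#' @param match_mode class definition, see [pc_class_labels()].
#' @return data.frame with `lobule`, `mean_abs_difference` (percentage
#'   points) and `normalized` (ratio to the reference lobule; `NaN` flagged
#'   when the reference difference is 0).
#' @export
interhemisphere_difference <- function(left_map, right_map,
                                       reference_lobule = "L6",
                                       match_mode = "complete") {
  lobes <- sort(unique(c(as.character(left_map$lobule),
                         as.character(right_map$lobule))))
  if (!reference_lobule %in% lobes)
    stop("reference lobule ", reference_lobule, " absent from the maps")
  classes <- sort(unique(c(pc_class_labels(left_map, match_mode),
                           pc_class_labels(right_map, match_mode))))
  pct <- function(map, lobe) {
    sub <- map[as.character(map$lobule) == lobe, , drop = FALSE]
    if (!nrow(sub)) return(setNames(rep(NA_real_, length(classes)), classes))
    tab <- table(factor(pc_class_labels(sub, match_mode), levels = classes))
    100 * as.numeric(tab) / sum(tab)
  }
  diffs <- vapply(lobes, function(l)
    mean(abs(pct(left_map, l) - pct(right_map, l))), numeric(1))
  ref <- diffs[[reference_lobule]]
  if (!is.na(ref) && ref == 0)
    warning("reference lobule difference is 0; normalized values undefined")
  data.frame(lobule = lobes, mean_abs_difference = unname(diffs),
             normalized = unname(diffs) / ref)
}
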