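## Per-arbor morphometrics: branch decomposition, lengths, extent/shape,
## eccentricity, caliber statistics and Sholl profiles. All operations work
## on dendrite nodes only; soma and axon nodes never contribute length.

soma_centroid <- function(x) {
  n <- x$nodes
  soma <- n[n$structure == "soma", , drop = FALSE]
  if (!nrow(soma)) soma <- n[n$parent == -1L, , drop = FALSE]
  c(x = mean(soma$x), y = mean(soma$y), z = mean(soma$z))
}

soma_diameter <- function(x) {
  n <- x$nodes
  soma <- n[n$structure == "soma", , drop = FALSE]
  if (!nrow(soma)) return(NA_real_)
  if (nrow(soma) == 1L) return(2 * soma$radius)
  d <- stats::dist(soma[, c("x", "y", "z")])
  max(max(d), 2 * max(soma$radius))
}

# Edge table over the whole arbor: one row per non-root node, with its
# parent's row index and the Euclidean edge length.
arbor_edges <- function(x) {
  n <- x$nodes
  keep <- n$parent != -1L
  child <- which(keep)
  parent <- match(n$parent[keep], n$id)
  len <- sqrt((n$x[child] - n$x[parent])^2 +
              (n$y[child] - n$y[parent])^2 +
              (n$z[child] - n$z[parent])^2)
  data.frame(child = child, parent = parent, length = len)
}

#' Total dendritic length
#'
#' Sum of Euclidean inter-node distances over edges whose both endpoints are
#' dendrite nodes; edges leaving the soma and all axon material are excluded.
#'
#' @param x an [arbor()].
#' @return length in um.
#' @examples
#' a <- arbor(data.frame(id = 1:3, structure = c("soma", "dendrite", "dendrite"),
#'                       x = c(0, 3, 3), y = c(0, 0, 4), z = 0,
#'                       radius = c(5, 1, 1), parent = c(-1, 1, 2)))
#' total_length(a)  # 5 (the 3-4-5 edge; the soma-dendrite edge is excluded)
#' @export
total_length <- function(x) {
  stopifnot(inherits(x, "arbor"))
  n <- x$nodes
  e <- arbor_edges(x)
  dend <- n$structure == "dendrite"
  sum(e$length[dend[e$child] & dend[e$parent]])
}

#' Decompose a dendritic arbor into branch segments
#'
#' A branch segment is the maximal path between consecutive branch points or
#' tips of the dendritic tree. Every dendrite node belongs to exactly one
#' segment; a branch point terminates its own segment and each of its
#' children starts a new one, so the segments partition the dendritic edges
#' and segment lengths sum exactly to [total_length()]. Orders are
#' centrifugal: each trunk (dendrite emerging from the soma) is order 1 and
#' a segment's order is its parent segment's order plus one.
#'
#' @param x an [arbor()].
#' @param plane columns used for the eccentricity plane, default
#'   parasagittal (`x`) by radial (`y`).
#' @return data.frame with one row per segment: `segment_id`, `parent_segment`
#'   (0 for trunks), `order`, `length` (um), `mean_diameter` (length-weighted
#'   mean of node diameters, um), `is_terminal`, `eccentricity_deg` (`NA` for
#'   degenerate segments, see [branch_eccentricity()]), `midpoint_radial`
#'   (radial distance of the segment's arc-length midpoint from the soma,
#'   um), and a list column `path` of node ids. An arbor with no dendrite
#'   nodes yields zero rows.
#' @export
decompose_branches <- function(x, plane = c("x", "y")) {
  stopifnot(inherits(x, "arbor"))
  n <- x$nodes
  dend <- n$structure == "dendrite"
  if (!any(dend))
    return(data.frame(segment_id = integer(0), parent_segment = integer(0),
                      order = integer(0), length = numeric(0),
                      mean_diameter = numeric(0), is_terminal = logical(0),
                      eccentricity_deg = numeric(0),
                      midpoint_radial = numeric(0)))
  parent_row <- match(n$parent, n$id)
  # number of dendrite children per row
  ndc <- tabulate(parent_row[dend & n$parent != -1L], nbins = nrow(n))
  parent_is_dend <- !is.na(parent_row) & dend[parent_row]
  # a dendrite node starts a segment if its parent is not a dendrite node
  # (trunk) or its parent is a dendritic branch point
  starts <- which(dend & (!parent_is_dend | ndc[parent_row] >= 2L))
  # single-dendrite-child lookup so path walking is O(path length)
  only_child <- rep(NA_integer_, nrow(n))
  dchild <- which(dend & !is.na(parent_row))
  sole <- dchild[ndc[parent_row[dchild]] == 1L]
  only_child[parent_row[sole]] <- sole

  sc <- soma_centroid(x)
  e <- arbor_edges(x)
  edge_len <- rep(NA_real_, nrow(n))
  edge_len[e$child] <- e$length
  diam <- 2 * n$radius

  paths <- list()
  for (s in starts) {
    path <- integer(64); path[1] <- s; np <- 1L
    cur <- s
    while (ndc[cur] == 1L) {
      cur <- only_child[cur]
      np <- np + 1L
      if (np > length(path)) path <- c(path, integer(length(path)))
      path[np] <- cur
    }
    paths[[length(paths) + 1L]] <- path[seq_len(np)]
  }
  nseg <- length(paths)
  # map each node row to its segment id
  node_seg <- integer(nrow(n))
  for (i in seq_len(nseg)) node_seg[paths[[i]]] <- i

  par_seg <- integer(nseg)
  seg_len <- numeric(nseg)
  seg_diam <- numeric(nseg)
  seg_term <- logical(nseg)
  seg_ecc <- numeric(nseg)
  seg_mid <- numeric(nseg)
  nx <- n[[plane[1]]]; ny <- n[[plane[2]]]
  cx <- n$x; cy <- n$y; cz <- n$z
  soma_y <- sc[["y"]]
  for (i in seq_len(nseg)) {
    path <- paths[[i]]
    first <- path[1]
    origin_row <- parent_row[first]
    trunk <- !parent_is_dend[first]
    par_seg[i] <- if (trunk) 0L else node_seg[origin_row]
    # edge lengths internal to the segment: every path node whose parent is
    # a dendrite node contributes its incoming edge
    internal <- path[parent_is_dend[path]]
    lens <- edge_len[internal]
    seg_len[i] <- sum(lens)
    # length-weighted mean diameter over edges (node-pair means); a
    # zero-length segment falls back to its node diameters
    if (length(internal) && sum(lens) > 0) {
      dpair <- (diam[internal] + diam[parent_row[internal]]) / 2
      seg_diam[i] <- sum(dpair * lens) / sum(lens)
    } else seg_diam[i] <- mean(diam[path])
    seg_term[i] <- ndc[path[length(path)]] == 0L
    # eccentricity plane vertices: branch origin first, then path nodes
    verts <- c(origin_row, path)
    seg_ecc[i] <- eccentricity_from_vertices(nx[verts], ny[verts])
    # arc-length midpoint, radial distance from the soma centroid
    poly <- if (trunk) path else verts
    seg_mid[i] <- polyline_midpoint_y(cx[poly], cy[poly], cz[poly]) - soma_y
  }
  # centrifugal orders by propagation from trunks
  ord <- ifelse(par_seg == 0L, 1L, NA_integer_)
  par_idx <- ifelse(par_seg == 0L, NA_integer_, par_seg)
  while (anyNA(ord)) {
    todo <- which(is.na(ord) & !is.na(ord[par_idx]))
    if (!length(todo)) stop("segment order propagation failed")
    ord[todo] <- ord[par_idx[todo]] + 1L
  }
  out <- data.frame(segment_id = seq_len(nseg), parent_segment = par_seg,
                    order = ord, length = seg_len,
                    mean_diameter = seg_diam, is_terminal = seg_term,
                    eccentricity_deg = seg_ecc, midpoint_radial = seg_mid)
  out$path <- paths
  out
}

# Radial (y) coordinate of the point halfway along a 3-D polyline.
polyline_midpoint_y <- function(px, py, pz) {
  if (length(px) == 1L) return(py)
  seg <- sqrt(diff(px)^2 + diff(py)^2 + diff(pz)^2)
  tot <- sum(seg)
  if (tot == 0) return(py[1])
  target <- tot / 2
  cum <- cumsum(seg)
  k <- which(cum >= target)[1]
  prev <- if (k == 1L) 0 else cum[k - 1L]
  f <- (target - prev) / seg[k]
  py[k] + f * (py[k + 1L] - py[k])
}

eccentricity_from_vertices <- function(vx, vy) {
  dx <- vx[-1] - vx[1]
  dy <- vy[-1] - vy[1]
  if (all(abs(dx) < 1e-12) && all(abs(dy) < 1e-12)) return(NA_real_)
  if (mean(dy) < 0) dy <- -dy  # mirror branches projecting downward
  if (mean(dx) < 0) dx <- -dx  # mirror branches projecting leftward
  sxx <- sum(dx^2)
  if (sxx < 1e-12) return(90)  # vertical segment
  b <- sum(dx * dy) / sxx      # through-origin fit
  min(max(atan(b) * 180 / pi, 0), 90)
}

#' Branch segment eccentricity
#'
#' Angle of a branch segment relative to the Purkinje cell layer plane, in
#' degrees. The branch origin is translated to (0, 0); if the mean radial
#' displacement of the remaining vertices is negative they are mirrored over
#' the horizontal axis, and likewise over the vertical axis for a negative
#' mean parasagittal displacement, so direction is discarded while the angle
#' from the layer is kept. The slope is the through-origin least-squares fit
#' b = sum(xy)/sum(x^2) (set `intercept = TRUE` for an ordinary
#' least-squares slope instead) and the eccentricity is `atan(b)` clamped to
#' `[0, 90]`; purely vertical segments give 90.
#'
#' @param vx,vy vertex coordinates in the (parasagittal, radial) plane,
#'   first vertex = branch origin; at least 2 vertices.
#' @param intercept fit an intercept (ordinary least squares) instead of the
#'   default through-origin fit.
#' @return degrees in `[0, 90]`; `NA` when all vertices coincide (such
#'   segments are excluded from aggregates).
#' @examples
#' branch_eccentricity(c(0, 5), c(0, 0))          # 0, horizontal
#' branch_eccentricity(c(0, -1), c(0, -1))        # 45, mirrored twin of (1,1)
#' branch_eccentricity(c(0, 2, 2), c(0, 0, 2))    # atan(1/2) ~ 26.57
#' @export
branch_eccentricity <- function(vx, vy, intercept = FALSE) {
  if (length(vx) < 2L || length(vx) != length(vy))
    stop("need at least 2 vertices with matching coordinates")
  if (!intercept) return(eccentricity_from_vertices(vx, vy))
  dx <- vx[-1] - vx[1]; dy <- vy[-1] - vy[1]
  if (all(abs(dx) < 1e-12) && all(abs(dy) < 1e-12)) return(NA_real_)
  if (mean(dy) < 0) dy <- -dy
  if (mean(dx) < 0) dx <- -dx
  if (stats::var(dx) < 1e-12) return(90)
  b <- stats::coef(stats::lm(dy ~ dx))[["dx"]]
  min(max(atan(b) * 180 / pi, 0), 90)
}

#' Arbor extent and shape index
#'
#' Width is the parasagittal extent (max minus min `x`) over dendrite nodes
#' and height the radial extent (`y`), measured on the raw coordinates
#' without any rotation. The shape index is `+100 * (W/H - 1)` when width
#' exceeds height and `-100 * (H/W - 1)` otherwise, so positive values mean
#' arbors wider than tall.
#'
#' @param x an [arbor()].
#' @return list with `max_width`, `max_height` (um) and `shape_index`
#'   (signed percent).
#' @export
arbor_extent_and_shape <- function(x) {
  stopifnot(inherits(x, "arbor"))
  n <- x$nodes
  d <- n[n$structure == "dendrite", , drop = FALSE]
  if (nrow(d) < 2L) stop("zero extent: arbor has fewer than 2 dendrite nodes")
  w <- diff(range(d$x)); h <- diff(range(d$y))
  if (w == 0 || h == 0) stop("zero extent: degenerate dendritic bounding box")
  si <- if (w >= h) 100 * (w / h - 1) else -100 * (h / w - 1)
  list(max_width = w, max_height = h, shape_index = si)
}

#' Assign branch segments to molecular-layer thirds
#'
#' Segments are classed proximal, intermediate or distal by which third of
#' the molecular layer thickness contains the radial distance of their
#' arc-length midpoint from the soma. When the arbor carries no
#' `ml_thickness` the measured arbor height is used as a proxy. Bins close
#' on their upper edge so a midpoint exactly at T/3 is proximal; midpoints
#' above T are clamped to distal with a warning.
#'
#' @param segments output of [decompose_branches()].
#' @param x the [arbor()] the segments came from.
#' @return factor with levels proximal/intermediate/distal.
#' @export
assign_region <- function(segments, x) {
  thick <- x$ml_thickness
  if (is.na(thick)) {
    n <- x$nodes
    d <- n[n$structure == "dendrite", , drop = FALSE]
    thick <- max(d$y) - soma_centroid(x)["y"]
  }
  m <- segments$midpoint_radial
  if (any(m > thick))
    warning(sum(m > thick), " segment midpoint(s) above the molecular layer",
            " thickness; clamped to distal")
  region <- ifelse(m <= thick / 3, "proximal",
                   ifelse(m <= 2 * thick / 3, "intermediate", "distal"))
  factor(region, levels = c("proximal", "intermediate", "distal"))
}

#' Log-normal thin-caliber threshold
#'
#' `exp(mean(log d) + sd(log d))` over a pool of branch mean diameters;
#' pooling both species reproduces the published cross-species 1.31 um
#' threshold scale. Non-positive diameters are dropped with a warning.
#'
#' @param diameters branch mean diameters in um.
#' @return threshold in um.
#' @export
thin_caliber_threshold <- function(diameters) {
  bad <- diameters <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive diameter(s) excluded from log statistics")
    diameters <- diameters[!bad]
  }
  if (length(diameters) < 2L) stop("need at least 2 positive diameters")
  ld <- log(diameters)
  exp(mean(ld) + stats::sd(ld))
}

#' Dendrite diameter profile and thin-caliber fraction
#'
#' Computes the maximum primary dendrite diameter (largest node diameter on
#' order-1 segments within two soma diameters of the soma), the per-order
#' mean segment diameter normalized to it, and the percentage of total
#' dendritic length on segments whose mean diameter falls below a
#' thin-caliber threshold. By default the threshold is the log-normal
#' mean + 1 SD of the segment mean diameters supplied in `pool_diameters`
#' (this arbor's own segments if omitted; pool across species to reproduce
#' the published 1.31 um cross-species threshold), or pass `threshold`
#' directly.
#'
#' @param x an [arbor()].
#' @param pool_diameters optional pooled branch mean diameters used to
#'   compute the threshold (um).
#' @param threshold optional fixed threshold in um, overrides the pool.
#' @param segments optionally reuse a [decompose_branches()] result.
#' @return list with `max_primary_diameter` (um),
#'   `normalized_diameter_by_order` (named vector, one entry per order),
#'   `thin_fraction` (percent of total dendritic length) and `threshold`
#'   (um).
#' @export
diameter_profile <- function(x, pool_diameters = NULL, threshold = NULL,
                             segments = decompose_branches(x)) {
  stopifnot(inherits(x, "arbor"))
  if (is.null(threshold)) {
    pool <- if (is.null(pool_diameters)) segments$mean_diameter else
      pool_diameters
    threshold <- thin_caliber_threshold(pool)
  }
  mpd <- max_primary_diameter(x, segments)
  by_order <- tapply(segments$mean_diameter, segments$order, mean)
  normalized <- by_order / mpd
  tot <- sum(segments$length)
  thin <- if (tot > 0)
    100 * sum(segments$length[segments$mean_diameter < threshold]) / tot
  else 0
  list(max_primary_diameter = mpd,
       normalized_diameter_by_order = normalized,
       thin_fraction = thin, threshold = threshold)
}

max_primary_diameter <- function(x, segments = decompose_branches(x)) {
  n <- x$nodes
  sc <- soma_centroid(x)
  sd2 <- soma_diameter(x)
  window <- if (is.na(sd2)) Inf else 2 * sd2
  rows <- unlist(segments$path[segments$order == 1L])
  if (is.null(rows) || !length(rows)) return(NA_real_)
  r <- sqrt((n$x[rows] - sc["x"])^2 + (n$y[rows] - sc["y"])^2 +
            (n$z[rows] - sc["z"])^2)
  near <- rows[r <= window]
  if (!length(near)) near <- rows[which.min(r)]
  max(2 * n$radius[near])
}

#' Sholl profile
#'
#' Dendritic length and branch counts in concentric 1 um shells around the
#' soma centroid. "Centrifugal" distance is the 3-D Euclidean radius by
#' default (`mode = "radial"`); `mode = "path"` uses distance along the tree
#' instead. Each inter-node edge is subdivided into short pieces assigned to
#' the shell containing their midpoint, so total shell length equals
#' [total_length()] exactly and the published 0.5% conservation bound holds
#' by construction. A branch segment is counted in every shell its path
#' intersects.
#'
#' @param x an [arbor()].
#' @param step shell width in um, default 1.
#' @param mode `"radial"` (Euclidean shells) or `"path"` (path distance).
#' @param piece maximum subdivision piece length in um.
#' @return object of class `sholl_profile`: data.frame with `radius` (outer
#'   shell bound, um), `length` (um per shell), `branches` (segments
#'   intersecting the shell) and `cumulative` (normalized cumulative length,
#'   monotone, ending at 1).
#' @export
sholl_profile <- function(x, step = 1, mode = c("radial", "path"),
                          piece = 0.25) {
  stopifnot(inherits(x, "arbor"))
  mode <- match.arg(mode)
  n <- x$nodes
  segments <- decompose_branches(x)
  if (!nrow(segments))
    return(structure(data.frame(radius = numeric(0), length = numeric(0),
                                branches = integer(0),
                                cumulative = numeric(0)),
                     class = c("sholl_profile", "data.frame")))
  sc <- soma_centroid(x)
  parent_row <- match(n$parent, n$id)
  dend <- n$structure == "dendrite"
  child <- which(dend & !is.na(parent_row) & dend[parent_row])
  par <- parent_row[child]
  seg_of <- integer(nrow(n))
  for (i in seq_len(nrow(segments))) seg_of[segments$path[[i]]] <- i
  elen <- sqrt((n$x[child] - n$x[par])^2 + (n$y[child] - n$y[par])^2 +
               (n$z[child] - n$z[par])^2)
  if (mode == "path") {
    # path distance from the soma centroid: accumulate down the tree
    pd <- numeric(nrow(n))
    r0 <- sqrt((n$x - sc["x"])^2 + (n$y - sc["y"])^2 + (n$z - sc["z"])^2)
    for (k in seq_len(nrow(n))) {
      p <- parent_row[k]
      if (is.na(p)) { pd[k] <- 0; next }
      step_len <- sqrt((n$x[k] - n$x[p])^2 + (n$y[k] - n$y[p])^2 +
                       (n$z[k] - n$z[p])^2)
      pd[k] <- if (dend[p]) pd[p] + step_len else r0[k]
    }
  }
  npieces <- pmax(1L, ceiling(elen / piece))
  idx <- rep.int(seq_along(child), npieces)
  k <- sequence(npieces)
  tmid <- (k - 0.5) / npieces[idx]
  plen <- elen[idx] / npieces[idx]
  if (mode == "radial") {
    mx <- n$x[par][idx] + tmid * (n$x[child][idx] - n$x[par][idx]) - sc["x"]
    my <- n$y[par][idx] + tmid * (n$y[child][idx] - n$y[par][idx]) - sc["y"]
    mz <- n$z[par][idx] + tmid * (n$z[child][idx] - n$z[par][idx]) - sc["z"]
    r <- sqrt(mx^2 + my^2 + mz^2)
  } else {
    r <- pd[par][idx] + tmid * elen[idx]
  }
  shell <- pmax(1L, ceiling(r / step))
  nshell <- max(shell)
  len_per <- numeric(nshell)
  agg <- rowsum(plen, shell)
  len_per[as.integer(rownames(agg))] <- agg[, 1]
  seg_shell <- unique(data.frame(seg = seg_of[child][idx], shell = shell))
  br_per <- tabulate(seg_shell$shell, nbins = nshell)
  tot <- sum(len_per)
  out <- data.frame(radius = seq_len(nshell) * step, length = len_per,
                    branches = br_per,
                    cumulative = cumsum(len_per) / tot)
  structure(out, class = c("sholl_profile", "data.frame"))
}

#' @export
plot.sholl_profile <- function(x, ...) {
  graphics::plot(x$radius, x$length, type = "h",
                 xlab = "Sholl radius (um)", ylab = "dendritic length (um)",
                 ...)
  invisible(x)
}

#' Branch emergence height profile
#'
#' Histogram of dendritic branch-point radial positions normalized to arbor
#' height, quantifying where along the molecular layer depth branching
#' happens.
#'
#' @param x an [arbor()].
#' @param n_bins number of equal bins on `[0, 1]`.
#' @return data.frame with `bin_mid` and `count`; zero rows for an
#'   unbranched arbor.
#' @export
branch_height_profile <- function(x, n_bins = 10) {
  stopifnot(inherits(x, "arbor"))
  n <- x$nodes
  parent_row <- match(n$parent, n$id)
  dend <- n$structure == "dendrite"
  ndc <- tabulate(parent_row[dend & n$parent != -1L], nbins = nrow(n))
  bp <- which(dend & ndc >= 2L)
  if (!length(bp))
    return(data.frame(bin_mid = numeric(0), count = integer(0)))
  sc <- soma_centroid(x)
  h <- max(n$y[dend]) - sc["y"]
  rel <- pmin(pmax((n$y[bp] - sc["y"]) / h, 0), 1)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  cnt <- tabulate(findInterval(rel, breaks, rightmost.closed = TRUE),
                  nbins = n_bins)
  data.frame(bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             count = cnt)
}

#' Arbor summary statistics
#'
#' One row of cohort-comparable per-cell metrics: total dendritic length,
#' branch counts and orders, extent and shape, soma and primary dendrite
#' diameters, thin-caliber fraction and trunk count.
#'
#' @param x an [arbor()].
#' @param thin_threshold thin-caliber threshold in um passed to
#'   [diameter_profile()]; `NULL` computes it from this arbor's segments.
#' @return data.frame with one row, class `arbor_summary`.
#' @export
arbor_summary <- function(x, thin_threshold = NULL) {
  stopifnot(inherits(x, "arbor"))
  segments <- decompose_branches(x)
  ext <- arbor_extent_and_shape(x)
  dp <- diameter_profile(x, threshold = thin_threshold, segments = segments)
  out <- data.frame(
    total_length = sum(segments$length),
    n_branches = nrow(segments),
    n_terminal_branches = sum(segments$is_terminal),
    max_order = max(segments$order),
    mean_order = mean(segments$order),
    max_width = ext$max_width,
    max_height = ext$max_height,
    shape_index = ext$shape_index,
    soma_diameter = soma_diameter(x),
    max_primary_diameter = dp$max_primary_diameter,
    thin_fraction = dp$thin_fraction,
    n_primary_dendrites = sum(segments$order == 1L)
  )
  class(out) <- c("arbor_summary", "data.frame")
  out
}

#' @export
summary.arbor <- function(object, ...) arbor_summary(object, ...)
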