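#' Construct an arbor from a node table
#'
#' An `arbor` is the reconstruction unit for all morphometric operations: a
#' rooted tree of 3-D nodes with radii, in micrometers. The coordinate
#' convention is parasagittal-plane dominant: `x` runs anterior--posterior
#' along the Purkinje cell layer, `y` is radial depth (soma towards pia) and
#' `z` is mediolateral. An alternative mapping can be declared through
#' `axis_map`.
#'
#' @param nodes data.frame with columns `id` (positive integer), `structure`
#'   (one of `"soma"`, `"axon"`, `"dendrite"`, `"unspecified"`), `x`, `y`,
#'   `z` (um), `radius` (um, >= 0) and `parent` (id of an earlier-declared
#'   node, or -1 for the root).
#' @param species `"human"` or `"mouse"`, or `NA`.
#' @param ml_thickness molecular layer thickness in um (optional); bounds
#'   arbor height and defines the proximal/intermediate/distal thirds. When
#'   `NA`, metrics fall back to the measured arbor height.
#' @param axis_map named character vector mapping roles to columns, default
#'   `c(parasagittal = "x", radial = "y", mediolateral = "z")`.
#' @return An object of class `arbor`.
#' @seealso [read_swc()], [arbor_summary()], [decompose_branches()]
#' @export
arbor <- function(nodes, species = NA_character_, ml_thickness = NA_real_,
                  axis_map = c(parasagittal = "x", radial = "y",
                               mediolateral = "z")) {
  required <- c("id", "structure", "x", "y", "z", "radius", "parent")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols))
    stop("node table lacks column(s): ", paste(missing_cols, collapse = ", "))
  nodes <- as.data.frame(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  if (anyDuplicated(nodes$id))
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
  if (any(nodes$id <= 0)) stop("node ids must be positive integers")
  if (any(nodes$radius < 0)) stop("negative radius at node ",
                                  nodes$id[which(nodes$radius < 0)[1]])
  bad_structure <- setdiff(unique(nodes$structure),
                           c("soma", "axon", "dendrite", "unspecified"))
  if (length(bad_structure))
    stop("unknown structure label: ", bad_structure[1])

  roots <- which(nodes$parent == -1L)
  if (length(roots) != 1L)
    stop("arbor must have exactly one root (parent -1), found ",
         length(roots))
  # parents must be declared earlier; this also rules out cycles
  pos <- match(nodes$parent, nodes$id)
  nonroot <- nodes$parent != -1L
  orphan <- nonroot & is.na(pos)
  if (any(orphan))
    stop("node ", nodes$id[which(orphan)[1]], " references undeclared parent ",
         nodes$parent[which(orphan)[1]])
  backref <- nonroot & pos >= seq_len(nrow(nodes))
  if (any(backref))
    stop("node ", nodes$id[which(backref)[1]],
         " references a later node (", nodes$parent[which(backref)[1]],
         "); possible cycle")
  # soma nodes must form a contiguous subtree containing the root
  if (any(nodes$structure == "soma")) {
    soma <- nodes$structure == "soma"
    if (!soma[roots]) stop("root must be a soma node when soma nodes exist")
    parent_is_soma <- soma[pos]
    if (any(soma & nonroot & !parent_is_soma))
      stop("soma nodes must form a contiguous subtree containing the root")
  }
  if (!is.na(species)) species <- match.arg(species, c("human", "mouse"))
  if (!is.na(ml_thickness) && ml_thickness <= 0)
    stop("ml_thickness must be positive")
  structure(list(nodes = nodes, species = species,
                 ml_thickness = ml_thickness, axis_map = axis_map),
            class = "arbor")
}

# SWC structure code <-> label mapping (codes 1 = soma, 2 = axon,
# 3 = dendrite; anything else -> unspecified, written back as 0)
swc_code_to_label <- function(code) {
  out <- rep("unspecified", length(code))
  out[code == 1] <- "soma"
  out[code == 2] <- "axon"
  out[code == 3] <- "dendrite"
  out
}

swc_label_to_code <- function(label) {
  unname(c(soma = 1L, axon = 2L, dendrite = 3L, unspecified = 0L)[label])
}

#' Read an SWC reconstruction
#'
#' Parses a standard 7-column SWC file (`id type x y z radius parent`,
#' whitespace-delimited, `#` comments) into an [arbor()]. Coordinates and
#' radii are taken as micrometers. Structure codes 1/2/3 map to
#' soma/axon/dendrite; all other codes become `"unspecified"`. Multiple soma
#' nodes (ring convention) are allowed provided they form a contiguous
#' subtree containing the root. No shrinkage factor or z-correction is
#' applied; see `scale_z` for an optional hook.
#'
#' @param path path to an SWC file.
#' @inheritParams arbor
#' @param scale_z optional multiplicative z correction, default 1 (off).
#' @return An [arbor()].
#' @export
read_swc <- function(path, species = NA_character_, ml_thickness = NA_real_,
                     scale_z = 1) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"),
                           colClasses = "numeric")
  if (!nrow(tab)) stop("empty SWC file: ", path)
  nodes <- data.frame(id = as.integer(tab$id),
                      structure = swc_code_to_label(tab$type),
                      x = tab$x, y = tab$y, z = tab$z * scale_z,
                      radius = tab$radius,
                      parent = as.integer(tab$parent))
  arbor(nodes, species = species, ml_thickness = ml_thickness)
}

#' Write an arbor to SWC
#'
#' Inverse of [read_swc()] modulo whitespace and comments.
#'
#' @param x an [arbor()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(x, path) {
  stopifnot(inherits(x, "arbor"))
  n <- x$nodes
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d", n$id,
                   swc_label_to_code(n$structure),
                   n$x, n$y, n$z, n$radius, n$parent)
  writeLines(c("# id type x y z radius parent", lines), path)
  invisible(path)
}

#' @export
print.arbor <- function(x, ...) {
  n <- x$nodes
  cat(sprintf("<arbor> %d nodes (%d soma, %d dendrite, %d axon)%s\n",
              nrow(n), sum(n$structure == "soma"),
              sum(n$structure == "dendrite"), sum(n$structure == "axon"),
              if (is.na(x$species)) "" else paste0(", species: ", x$species)))
  if (!is.na(x$ml_thickness))
    cat(sprintf("  molecular layer thickness: %g um\n", x$ml_thickness))
  invisible(x)
}

#' @export
plot.arbor <- function(x, col_by_structure = TRUE, ...) {
  n <- x$nodes
  keep <- n$parent != -1L
  p <- match(n$parent[keep], n$id)
  cols <- if (col_by_structure)
    c(soma = "black", dendrite = "forestgreen", axon = "grey50",
      unspecified = "orange")[n$structure[keep]] else "black"
  graphics::plot(n$x, n$y, type = "n", xlab = "parasagittal (um)",
                 ylab = "radial (um)", asp = 1, ...)
  graphics::segments(n$x[keep], n$y[keep], n$x[p], n$y[p], col = cols)
  invisible(x)
}

cell_map_required_cols <- c("cell_id", "x", "y", "morph_type", "orientation",
                            "foliar", "lobule", "hemisphere", "individual",
                            "species")

validate_cell_map <- function(map) {
  missing_cols <- setdiff(cell_map_required_cols, names(map))
  if (length(missing_cols))
    stop("cell map lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(map$cell_id))
    stop("duplicate cell_id: ", map$cell_id[duplicated(map$cell_id)][1])
  check_enum <- function(col, allowed, allow_na = FALSE) {
    vals <- unique(map[[col]])
    if (allow_na) vals <- vals[!is.na(vals)]
    bad <- setdiff(vals, allowed)
    if (length(bad))
      stop("invalid ", col, " value: ", bad[1])
  }
  if (nrow(map)) {
    check_enum("morph_type", MORPH_TYPES)
    check_enum("orientation", c(ORIENTATIONS, "NA"), allow_na = TRUE)
    check_enum("foliar", FOLIAR_LABELS)
    check_enum("hemisphere", c("left", "right", "vermis"))
    check_enum("species", c("human", "mouse"))
    if (!is.numeric(map$x) || !is.numeric(map$y))
      stop("cell map coordinates must be numeric")
  }
  invisible(map)
}

#' Read a parasagittal cell-map table
#'
#' Reads a CSV of Purkinje cells mapped along the layer of a parasagittal
#' slice. Required columns: `cell_id`, `x`, `y` (um), `morph_type`
#' (Normative/Split/Poly), `orientation` (Vertical/Horizontal/NA), `foliar`
#' (Gyrus/Bank/Sulcus), `lobule`, `hemisphere` (left/right/vermis),
#' `individual`, `species`. Rows are kept in file order, which is assumed to
#' be anterior to posterior along the layer within each
#' (individual, hemisphere, slice) group. Unknown enum values are rejected.
#'
#' @param path path to a CSV file with a header.
#' @return A data.frame of class `cell_map` in file order; an empty table
#'   yields an empty map without error.
#' @export
read_cell_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(map)) {
    for (col in setdiff(cell_map_required_cols, names(map)))
      map[[col]] <- character(0)
    map <- map[cell_map_required_cols]
  }
  map$orientation[!is.na(map$orientation) & map$orientation == "NA"] <-
    NA_character_
  validate_cell_map(map)
  class(map) <- c("cell_map", "data.frame")
  map
}

#' Write a cell map to CSV
#' @param map a `cell_map` (or conforming data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_map <- function(map, path) {
  validate_cell_map(map)
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a spine annotation table
#'
#' One row per spine: `spine_id`, `branch_id`, `type` (thin/mushroom/
#' branched/cluster), `head_diameter`, `neck_length`,
#' `protrusion_distance` (um), `puncta_count` (integer >= 1),
#' `head_volume` (um^3). A companion branch table maps `branch_id` to
#' `length`, `mean_dendrite_diameter` and `region`.
#'
#' @param path path to a CSV file.
#' @return data.frame of spine records.
#' @export
read_spine_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("spine_id", "branch_id", "type", "head_diameter",
                "neck_length", "protrusion_distance", "puncta_count",
                "head_volume")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("spine table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(tab$type), SPINE_TYPES)
  if (length(bad)) stop("invalid spine type: ", bad[1])
  if (nrow(tab) && any(tab$puncta_count < 1))
    stop("puncta_count must be >= 1")
  tab
}

#' @rdname read_spine_table
#' @param tab spine table to write.
#' @param path output path.
#' @export
write_spine_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
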