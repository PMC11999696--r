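# In-code fixtures: tiny arbors and SWC files built at test time.

node_df <- function(id, structure, x, y, z, radius, parent)
  data.frame(id = id, structure = structure, x = x, y = y, z = z,
             radius = radius, parent = parent)

# soma + straight dendritic chain with given inter-node steps along +y
chain_arbor <- function(steps = c(3, 4), radius = 1, soma_radius = 5) {
  n <- length(steps)
  node_df(id = 1:(n + 2),
          structure = c("soma", rep("dendrite", n + 1)),
          x = 0, y = c(0, 0, cumsum(steps)), z = 0,
          radius = c(soma_radius, rep(radius, n + 1)),
          parent = c(-1, 1:(n + 1))) |> arbor()
}

# one trunk of length `trunk`, bifurcating into two limbs along +/- x
y_arbor <- function(trunk = 5, limb = 2, radius = 1) {
  nodes <- node_df(
    id = 1:5,
    structure = c("soma", rep("dendrite", 4)),
    x = c(0, 0, 0, limb, -limb),
    y = c(0, 0, trunk, trunk, trunk),
    z = 0,
    radius = c(5, radius, radius, radius, radius),
    parent = c(-1, 1, 2, 3, 3))
  arbor(nodes)
}

write_swc_text <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}

random_arbor_nodes <- function(n_bif = 3, seed = NULL) {
  # random binary dendritic tree grown node by node; returns the node table
  if (!is.null(seed)) set.seed(seed)
  nodes <- node_df(1, "soma", 0, 0, 0, 4, -1)
  nodes <- rbind(nodes, node_df(2, "dendrite", 0, 4, 0, 1, 1))
  tips <- 2L
  next_id <- 3L
  for (b in seq_len(n_bif)) {
    t <- tips[sample.int(length(tips), 1)]
    for (k in 1:2) {
      tx <- nodes$x[nodes$id == t] + runif(1, -3, 3)
      ty <- nodes$y[nodes$id == t] + runif(1, 1, 4)
      nodes <- rbind(nodes, node_df(next_id, "dendrite", tx, ty,
                                    runif(1, -1, 1), 1, t))
      tips <- c(tips, next_id)
      next_id <- next_id + 1L
    }
    tips <- setdiff(tips, t)
  }
  nodes
}

make_cell_map_csv <- function(map) {
  f <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(map), f, row.names = FALSE, na = "NA")
  f
}
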