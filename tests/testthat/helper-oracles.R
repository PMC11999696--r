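# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementation.

oracle_labels <- function(map, match_mode = "complete") {
  out <- character(nrow(map))
  for (i in seq_len(nrow(map))) {
    type <- map$morph_type[i]
    ori <- map$orientation[i]
    out[i] <- if (match_mode == "type_only") type
    else if (match_mode == "orientation_only") {
      if (type == "Normative") "Normative" else ori
    } else {
      if (type == "Normative") "Normative"
      else paste0(substr(ori, 1, 1), "-", type)
    }
  }
  out
}

oracle_adjacency_scores <- function(map, threshold,
                                    match_mode = "complete") {
  n <- nrow(map)
  lab <- oracle_labels(map, match_mode)
  dist2 <- function(i, j)
    sqrt((map$x[i] - map$x[j])^2 + (map$y[i] - map$y[j])^2)
  score <- integer(n)
  for (i in seq_len(n)) {
    s <- -1L
    for (j in c(i - 1L, i + 1L)) {
      if (j < 1L || j > n) next
      if (dist2(i, j) <= threshold) {
        if (s < 0L) s <- 0L
        if (lab[j] == lab[i]) s <- s + 1L
      }
    }
    score[i] <- s
  }
  score
}

oracle_runs <- function(map, threshold, match_mode = "complete") {
  n <- nrow(map)
  lab <- oracle_labels(map, match_mode)
  runs <- list()
  i <- 1L
  while (i < n) {
    d <- sqrt((map$x[i + 1] - map$x[i])^2 + (map$y[i + 1] - map$y[i])^2)
    if (d <= threshold && lab[i + 1] == lab[i]) {
      j <- i
      len <- 0
      while (j < n) {
        dj <- sqrt((map$x[j + 1] - map$x[j])^2 +
                   (map$y[j + 1] - map$y[j])^2)
        if (dj <= threshold && lab[j + 1] == lab[j]) {
          len <- len + dj
          j <- j + 1L
        } else break
      }
      runs[[length(runs) + 1L]] <- c(n_cells = j - i + 1L, run_length = len)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs))
    return(data.frame(n_cells = integer(0), run_length = numeric(0)))
  as.data.frame(do.call(rbind, runs))
}

# Mean surround composition matrix by double loop over cell pairs.
oracle_surround <- function(map, classes, inner, outer,
                            match_mode = "complete") {
  n <- nrow(map)
  lab <- oracle_labels(map, match_mode)
  K <- length(classes)
  M <- matrix(0, K, K, dimnames = list(focal = classes, surround = classes))
  denom <- integer(K)
  for (i in seq_len(n)) {
    counts <- setNames(numeric(K), classes)
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((map$x[i] - map$x[j])^2 + (map$y[i] - map$y[j])^2)
      if (d >= inner && d <= outer) counts[lab[j]] <- counts[lab[j]] + 1
    }
    if (sum(counts) == 0) next
    k <- match(lab[i], classes)
    M[k, ] <- M[k, ] + counts / sum(counts)
    denom[k] <- denom[k] + 1L
  }
  for (k in seq_len(K)) M[k, ] <- if (denom[k]) M[k, ] / denom[k] else NA
  M
}

random_tiny_map <- function(n, species = "mouse", spacing = 60) {
  classes <- c("Normative", "V-Split", "H-Split", "V-Poly", "H-Poly")
  lab <- sample(classes, n, replace = TRUE)
  data.frame(
    cell_id = paste0("c", seq_len(n)),
    x = cumsum(runif(n, 10, spacing)),
    y = rnorm(n, 0, 5),
    morph_type = ifelse(lab == "Normative", "Normative",
                        ifelse(grepl("Split", lab), "Split", "Poly")),
    orientation = ifelse(lab == "Normative", NA,
                         ifelse(substr(lab, 1, 1) == "V", "Vertical",
                                "Horizontal")),
    foliar = sample(c("Gyrus", "Bank", "Sulcus"), n, replace = TRUE),
    lobule = "L6", hemisphere = "vermis", individual = "i1",
    species = species)
}
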