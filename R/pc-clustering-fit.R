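#' Fit the adjacency clustering analysis for a cell map
#'
#' High-level wrapper around [adjacency_scores()], [cluster_runs()] and
#' [clustering_excess()]: computes per-cell cluster scores, uninterrupted
#' run statistics, the observed rate of nonzero scores and its elevation
#' over a seeded label-permutation null, with a one-sided permutation
#' p-value (share of shuffles at least as clustered as observed, with the
#' +1 correction).
#'
#' @param map a cell map for one slice, ordered anterior to posterior.
#' @param threshold adjacency distance in um; default from the map's
#'   species preset (1000 human / 200 mouse).
#' @param match_mode `"complete"`, `"type_only"` or `"orientation_only"`.
#' @param n_shuffles permutation null size, default 20.
#' @param seed RNG seed for the permutations.
#' @param shuffle_mode `"global"` or `"within_foliar"`.
#' @param include_isolated count score -1 cells in the rate denominator.
#' @return object of class `pc_clustering` with elements `scores`, `runs`,
#'   `observed_rate`, `shuffled_rates`, `excess` (percentage points),
#'   `p_value`, `threshold`, `match_mode`, `spec`, `n_cells`.
#' @examples
#' map <- simulate_cell_map(map_sim_config(n_cells = 300, seed = 7))$map
#' fit <- pc_clustering(map, seed = 7)
#' fit$excess
#' @export
pc_clustering <- function(map, threshold = NULL, match_mode = "complete",
                          n_shuffles = 20, seed = 1,
                          shuffle_mode = "global",
                          include_isolated = FALSE) {
  threshold <- default_threshold(map, threshold)
  spec <- shuffle_spec(shuffle_mode, n_shuffles, seed)
  scores <- adjacency_scores(map, threshold, match_mode)
  runs <- cluster_runs(map, threshold, match_mode, scores = scores)
  ex <- clustering_excess(map, spec, threshold, match_mode,
                          include_isolated)
  p <- (sum(ex$shuffled_rates >= ex$observed_rate) + 1) /
    (length(ex$shuffled_rates) + 1)
  structure(list(scores = scores, runs = runs,
                 observed_rate = ex$observed_rate,
                 shuffled_rates = ex$shuffled_rates,
                 excess = ex$excess, p_value = p,
                 threshold = threshold, match_mode = match_mode,
                 spec = spec, n_cells = nrow(map)),
            class = "pc_clustering")
}

#' @export
print.pc_clustering <- function(x, ...) {
  cat(sprintf("Adjacency clustering (%s match, threshold %g um, %d cells)\n",
              x$match_mode, x$threshold, x$n_cells))
  cat(sprintf("  observed clustered rate: %.1f%%\n", x$observed_rate))
  cat(sprintf("  shuffled mean rate:      %.1f%% (%d shuffles)\n",
              mean(x$shuffled_rates), length(x$shuffled_rates)))
  cat(sprintf("  excess over null:        %+.1f points (perm. p = %.3f)\n",
              x$excess, x$p_value))
  invisible(x)
}

#' @export
summary.pc_clustering <- function(object, ...) {
  runs <- object$runs
  out <- list(excess = object$excess, p_value = object$p_value,
              n_runs = nrow(runs),
              mean_run_cells = if (nrow(runs)) mean(runs$n_cells) else NA,
              mean_run_length = if (nrow(runs)) mean(runs$run_length) else NA,
              score_table = table(object$scores$score))
  class(out) <- "summary.pc_clustering"
  out
}

#' @export
print.summary.pc_clustering <- function(x, ...) {
  cat(sprintf("excess %+.1f points (p = %.3f); %d runs", x$excess,
              x$p_value, x$n_runs))
  if (x$n_runs)
    cat(sprintf(", mean %.1f cells / %.0f um", x$mean_run_cells,
                x$mean_run_length))
  cat("\nscore distribution:\n")
  print(x$score_table)
  invisible(x)
}

#' @export
plot.pc_clustering <- function(x, ...) {
  graphics::hist(x$shuffled_rates, col = "grey80", border = "white",
                 xlim = range(c(x$shuffled_rates, x$observed_rate)),
                 main = "Observed vs shuffled clustered rate",
                 xlab = "clustered rate (%)", ...)
  graphics::abline(v = x$observed_rate, col = "red3", lwd = 2)
  invisible(x)
}
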