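# Deterministic generation of small test inputs.

# the classic toy configuration: two cherries (1,3) and (7,8), leaf 5
# equidistant from 7 and 8, all cross-subtree distances 2.0
.toy_matrix <- function() {
  lab <- c("1", "3", "5", "7", "8")
  m <- matrix(2, 5, 5, dimnames = list(lab, lab))
  diag(m) <- 0
  m["1", "3"] <- m["3", "1"] <- 0.3
  m["7", "8"] <- m["8", "7"] <- 0.2
  m["5", "7"] <- m["7", "5"] <- 0.6
  m["5", "8"] <- m["8", "5"] <- 0.6
  as_distance_matrix(m, height = 1)
}

#' Generate the bundled deterministic fixtures
#'
#' Writes, under \code{dir}:
#' \describe{
#'   \item{\code{toy_matrix.tsv}}{a 5-leaf matrix with exactly two cherries,
#'     (1,3) and (7,8), and a nearest-neighbour tie at leaf 5.}
#'   \item{\code{nineteen_leaves.tsv}}{the distance matrix of a simulated
#'     tree conditioned (by rejection) to exactly 19 observed leaves
#'     (\eqn{\lambda=11, \mu=5, \sigma=0.01, T=1}), hence 171 pairs ---
#'     the sparse-data regime.}
#'   \item{\code{trees10.nwk}}{10 simulated observed-leaf subtrees
#'     (\eqn{\lambda=6, \mu=3, \sigma=0.1, T=1}, each with at least 2
#'     observed leaves) as Newick, one per line.}
#'   \item{\code{hist_exact_{pairwise,nth_min1,cherry}.tsv}}{noise-free
#'     histograms sampled from the closed-form densities at
#'     (\eqn{\lambda=6, \mu=3, \sigma=0.1, T=1}), for fitter tests.}
#' }
#' Identical \code{seed} gives byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 20150331) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  p <- file.path(dir, "toy_matrix.tsv")
  write_distance_matrix(.toy_matrix(), p)
  paths["toy_matrix"] <- p

  set.seed(seed)
  sparse <- yule_params(lambda = 11, mu = 5, sigma = 0.01, height = 1)
  repeat {
    tr <- simulate_yule_tree(sparse)
    if (sum(tr$observed) == 19) break
  }
  p <- file.path(dir, "nineteen_leaves.tsv")
  write_distance_matrix(as_distance_matrix(tree_distance_matrix(tr),
                                           height = 1), p)
  paths["nineteen_leaves"] <- p

  panel <- yule_params(lambda = 6, mu = 3, sigma = 0.1, height = 1)
  nwk <- character(0)
  while (length(nwk) < 10) {
    tr <- simulate_yule_tree(panel)
    if (sum(tr$observed) >= 2) nwk <- c(nwk, tree_newick(tr))
  }
  p <- file.path(dir, "trees10.nwk")
  writeLines(nwk, p)
  paths["trees10"] <- p

  edges <- seq(0, 2, length.out = 101)
  mids <- edges[-1] - diff(edges[1:2]) / 2
  curves <- list(pairwise = pairwise_density(panel, mids),
                 nth_min1 = nth_min_density(panel, mids, 1),
                 cherry = cherry_density(panel, mids))
  for (k in names(curves)) {
    h <- build_histogram_counts(k, edges, curves[[k]] * diff(edges[1:2]),
                                trees = 1)
    p <- file.path(dir, sprintf("hist_exact_%s.tsv", k))
    write_histogram(h, p, seed = seed)
    paths[paste0("hist_exact_", k)] <- p
  }
  invisible(paths)
}
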