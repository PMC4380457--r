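# Kinetic Monte Carlo tree simulation: R-level interface over the compiled
# core, full-genealogy tree objects, and ensemble histogram accumulation.

#' Simulate a Yule tree by Kinetic Monte Carlo
#'
#' Grows a single birth--death tree of height \eqn{T}: starting from one
#' lineage at time 0, waiting times between events are exponential with mean
#' \eqn{1/(M(\lambda+\mu))} for \eqn{M} currently alive lineages; a uniformly
#' chosen lineage then splits with probability \eqn{\lambda/(\lambda+\mu)}
#' or dies.  The event whose waiting time overshoots \eqn{T} is discarded
#' (the state is frozen at \eqn{T}).  Extant leaves are finally marked
#' observed independently with probability \eqn{\sigma}.  The complete
#' genealogy --- including extinct and unobserved subtrees --- is retained.
#'
#' @param params a \code{\link{yule_params}} object.
#' @param seed optional integer; if given, \code{set.seed(seed)} is called
#'   first.  Otherwise the current RNG stream is used.
#' @param cap abort with an error if the number of simultaneously alive
#'   lineages exceeds this guard (explosive growth).
#' @return A \code{"yule_tree"}: a data frame with one row per lineage and
#'   columns \code{id}, \code{parent} (\code{NA} for the root),
#'   \code{t_birth}, \code{t_end}, \code{kind} (\code{"split"},
#'   \code{"death"}, \code{"extant"}) and \code{observed}; the generating
#'   parameters are attached as attribute \code{"params"}.
#' @examples
#' tr <- simulate_yule_tree(yule_params(2, 1, 0.5, 1), seed = 1)
#' table(tr$kind)
#' @export
simulate_yule_tree <- function(params, seed = NULL, cap = 1e6) {
  .check_params(params)
  if (!is.null(seed)) set.seed(seed)
  raw <- sim_tree_cpp(params$lambda, params$mu, params$sigma, params$height,
                      as.integer(cap))
  tr <- data.frame(
    id = seq_along(raw$parent),
    parent = raw$parent,
    t_birth = raw$t_birth,
    t_end = raw$t_end,
    kind = c("split", "death", "extant")[raw$kind + 1L],
    observed = raw$observed == 1L)
  attr(tr, "params") <- params
  class(tr) <- c("yule_tree", "data.frame")
  tr
}

#' @export
print.yule_tree <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Yule tree: %d lineages, %d extant, %d observed (height %g)\n",
              nrow(x), sum(x$kind == "extant"), sum(x$observed), p$height))
  invisible(x)
}

# per-node counts of observed descendant leaves
.obs_counts <- function(tree) {
  n <- nrow(tree)
  cnt <- integer(n)
  cnt[tree$observed] <- 1L
  for (i in rev(seq_len(n))[seq_len(max(n - 1L, 0L))]) {
    p <- tree$parent[i]
    cnt[p] <- cnt[p] + cnt[i]
  }
  cnt
}

#' Pairwise time distances between the observed leaves of a simulated tree
#'
#' For each unordered pair of observed leaves the distance is
#' \eqn{2(T - t_{MRCA})}, found by walking the parent links to the most
#' recent common ancestor.
#'
#' @param tree a \code{"yule_tree"} from \code{\link{simulate_yule_tree}}.
#' @return data frame with columns \code{leaf1}, \code{leaf2},
#'   \code{distance}; \eqn{M(M-1)/2} rows for \eqn{M} observed leaves
#'   (zero rows if \eqn{M < 2}).
#' @export
tree_pair_distances <- function(tree) {
  stopifnot(inherits(tree, "yule_tree"))
  m <- tree_distance_matrix(tree)
  M <- nrow(m)
  if (M < 2)
    return(data.frame(leaf1 = integer(0), leaf2 = integer(0),
                      distance = numeric(0)))
  idx <- which(upper.tri(m), arr.ind = TRUE)
  data.frame(leaf1 = as.integer(rownames(m)[idx[, 1]]),
             leaf2 = as.integer(colnames(m)[idx[, 2]]),
             distance = m[idx])
}

#' Distance matrix of the observed leaves of a simulated tree
#'
#' @param tree a \code{"yule_tree"}.
#' @return symmetric matrix of pairwise time distances, with leaf ids as
#'   dimnames, suitable for \code{\link{as_distance_matrix}}.
#' @export
tree_distance_matrix <- function(tree) {
  stopifnot(inherits(tree, "yule_tree"))
  params <- attr(tree, "params")
  leaves <- which(tree$observed)
  M <- length(leaves)
  m <- matrix(0, M, M, dimnames = list(leaves, leaves))
  if (M < 2) return(m)
  # root path (node -> sequence of ancestors) per leaf, with split times
  paths <- lapply(leaves, function(L) {
    anc <- integer(0)
    v <- L
    while (!is.na(tree$parent[v])) {
      v <- tree$parent[v]
      anc <- c(anc, v)
    }
    anc
  })
  for (i in seq_len(M - 1)) {
    for (j in seq(i + 1, M)) {
      common <- intersect(paths[[i]], paths[[j]])
      mrca_t <- max(tree$t_end[common])  # most recent common ancestor splits latest
      m[i, j] <- m[j, i] <- 2 * (params$height - mrca_t)
    }
  }
  m
}

#' Newick string of the observed (or extant) subtree
#'
#' Prunes the genealogy to the observed leaves (default) or all extant
#' leaves, suppressing the unifurcations left by pruning, and returns a
#' Newick string with branch lengths in time units.  Leaf labels are
#' \code{t<id>}.  Requires at least 2 retained leaves.
#'
#' @param tree a \code{"yule_tree"}.
#' @param keep_unobserved if \code{TRUE}, keep all extant leaves, not only
#'   the observed ones.
#' @return a single Newick string (with trailing \code{";"}), or
#'   \code{NA_character_} if fewer than 2 leaves are retained.
#' @export
tree_newick <- function(tree, keep_unobserved = FALSE) {
  stopifnot(inherits(tree, "yule_tree"))
  keep_leaf <- if (keep_unobserved) tree$kind == "extant" else tree$observed
  n <- nrow(tree)
  cnt <- integer(n)
  cnt[keep_leaf] <- 1L
  for (i in rev(seq_len(n))[seq_len(max(n - 1L, 0L))])
    cnt[tree$parent[i]] <- cnt[tree$parent[i]] + cnt[i]
  if (cnt[1] < 2) return(NA_character_)
  children <- split(seq_len(n)[-1], tree$parent[-1])
  build <- function(v, top) {
    if (keep_leaf[v] && tree$kind[v] == "extant")
      return(sprintf("t%d:%.10g", v, tree$t_end[v] - top))
    kids <- children[[as.character(v)]]
    kids <- kids[cnt[kids] > 0]
    if (length(kids) == 1L) return(build(kids, top))  # suppress unifurcation
    sprintf("(%s,%s):%.10g", build(kids[1], tree$t_end[v]),
            build(kids[2], tree$t_end[v]), tree$t_end[v] - top)
  }
  v <- 1L
  # drop the root stem down to the first split with survivors on both sides
  repeat {
    if (keep_leaf[v] && tree$kind[v] == "extant") break
    kids <- children[[as.character(v)]]
    kids <- kids[cnt[kids] > 0]
    if (length(kids) != 1L) break
    v <- kids
  }
  kids <- children[[as.character(v)]]
  kids <- kids[cnt[kids] > 0]
  paste0(sprintf("(%s,%s);", build(kids[1], tree$t_end[v]),
                 build(kids[2], tree$t_end[v])))
}

.hist_kind_layout <- function(kinds, nmin_orders) {
  kinds <- match.arg(kinds, c("pairwise", "nth_min", "cherry", "min2"),
                     several.ok = TRUE)
  if (length(kinds) == 0) stop("at least one statistic kind is required")
  labels <- character(0)
  if ("pairwise" %in% kinds) labels <- c(labels, "pairwise")
  if ("nth_min" %in% kinds)
    labels <- c(labels, paste0("nth_min", nmin_orders))
  if ("cherry" %in% kinds) labels <- c(labels, "cherry")
  if ("min2" %in% kinds) labels <- c(labels, "min2")
  labels
}

#' Ensemble distance histograms from simulated trees
#'
#' Simulates \code{s} independent trees and accumulates, per statistic kind
#' and per bin: the pooled count, the number of trees with a non-zero count
#' (for the conditional, non-empty-bin mean) and the sum of squared per-tree
#' counts (for empirical standard errors).  Bins are uniform over
#' \code{range}, half-open \code{[l, r)} with the last bin closed.
#'
#' @param params a \code{\link{yule_params}} object.
#' @param s number of trees (replicates).
#' @param kinds subset of \code{c("pairwise", "nth_min", "cherry", "min2")}.
#' @param nmin_orders integer vector of neighbour orders when
#'   \code{"nth_min"} is requested.
#' @param bins number of bins.
#' @param range histogram range; default \code{c(0, 2*height)}, the full
#'   support of all pair-distance statistics.
#' @param seed optional integer seed.
#' @param cap lineage-count guard per tree.
#' @param keep_covariance if \code{TRUE}, also store the empirical
#'   covariance matrix of the per-tree bin-count vector
#'   (\code{count_cov}); the bins of an ensemble histogram are positively
#'   correlated because they share trees, and covariance-aware comparisons
#'   need this matrix.  Memory grows with \code{bins^2}.
#' @return A named list of \code{"distance_histogram"} objects (see
#'   \code{\link{build_histogram}}), one per requested statistic, each with
#'   extra fields \code{nonzero} (trees with a non-zero bin count),
#'   \code{conditional_density} (mean bin density over those trees) and
#'   \code{se_count} (empirical standard error of the pooled count).  The
#'   observed leaf-count tally across trees is attached as attribute
#'   \code{"m_tally"}.
#' @examples
#' h <- ensemble_histograms(yule_params(6, 3, 0.1, 1), s = 200, seed = 1)
#' h$pairwise$density
#' @export
ensemble_histograms <- function(params, s,
                                kinds = c("pairwise", "nth_min", "cherry",
                                          "min2"),
                                nmin_orders = 1L, bins = 40,
                                range = c(0, 2 * params$height),
                                seed = NULL, cap = 1e6,
                                keep_covariance = FALSE) {
  .check_params(params)
  stopifnot(s >= 1, bins >= 1, length(range) == 2, range[2] > range[1])
  labels <- .hist_kind_layout(kinds, nmin_orders)
  if (!is.null(seed)) set.seed(seed)
  edges <- seq(range[1], range[2], length.out = bins + 1)
  if (!"nth_min" %in% kinds) nmin_orders <- integer(0)
  raw <- ensemble_hist_cpp(params$lambda, params$mu, params$sigma,
                           params$height, as.integer(s), edges,
                           as.integer(nmin_orders),
                           "pairwise" %in% kinds,
                           "cherry" %in% kinds,
                           "min2" %in% kinds,
                           as.integer(cap),
                           isTRUE(keep_covariance))
  width <- diff(edges[1:2])
  out <- lapply(seq_along(labels), function(k) {
    counts <- raw$counts[, k]
    nonzero <- raw$nonzero[, k]
    # empirical variance of the per-tree count (zeros included)
    v <- pmax(raw$sumsq[, k] / s - (counts / s)^2, 0)
    h <- build_histogram_counts(labels[k], edges, counts, trees = s)
    h$nonzero <- nonzero
    h$conditional_density <- ifelse(nonzero > 0, counts / (nonzero * width), 0)
    h$se_count <- sqrt(s * v)
    h$sumsq <- raw$sumsq[, k]
    # total statistic count across the range, with its empirical s.e.
    h$total <- raw$total[k]
    h$se_total <- sqrt(s * max(raw$totalsq[k] / s - (raw$total[k] / s)^2, 0))
    if (isTRUE(keep_covariance)) {
      # empirical covariance of the per-tree bin-count vector
      m2 <- matrix(raw$covacc[seq_len(bins^2) + (k - 1) * bins^2],
                   bins, bins) / s
      mu1 <- counts / s
      h$count_cov <- m2 - tcrossprod(mu1)
    }
    h$params <- params
    h
  })
  names(out) <- labels
  attr(out, "m_tally") <- raw$m_tally
  out
}

#' Distribution of the pair count in one narrow bin, by simulation
#'
#' Simulates \code{s} trees and tallies how many observed pairs fall in the
#' distance bin \code{[t, t + dt)} on each tree; the empirical counterpart
#' of \code{\link{prob_pair_count_in_bin}}.
#'
#' @inheritParams ensemble_histograms
#' @param t bin left edge.
#' @param dt bin width.
#' @param n_max largest count tallied individually; larger counts are pooled
#'   into the final element.
#' @return integer vector of tree tallies named \code{"0"..."n_max"} plus
#'   \code{">n_max"}.
#' @export
occupancy_distribution <- function(params, s, t, dt, n_max = 20,
                                   seed = NULL, cap = 1e6) {
  .check_params(params)
  if (!is.null(seed)) set.seed(seed)
  tally <- occupancy_cpp(params$lambda, params$mu, params$sigma,
                         params$height, as.integer(s), t, dt,
                         as.integer(n_max), as.integer(cap))
  stats::setNames(tally, c(as.character(0:n_max), paste0(">", n_max)))
}
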