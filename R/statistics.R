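# Tree-free distance statistics: everything here needs only a square
# symmetric matrix of pairwise time distances, which is how empirical data
# (posterior tree samples reduced to cophenetic matrices) enter the package.

#' Validate a distance matrix of pairwise time distances
#'
#' @param m square numeric matrix: symmetric (relative tolerance 1e-9),
#'   zero diagonal, non-negative entries.  Row/column names are used as
#'   leaf labels; unlabeled matrices get labels \code{"1", "2", ...}.
#' @param height tree height \eqn{T}; if \code{NULL}, inferred as
#'   \code{max(m)/2} (the support of pair distances is \eqn{[0, 2T]}).
#' @return object of class \code{"distance_matrix"}: the matrix with an
#'   attached \code{height}.
#' @export
as_distance_matrix <- function(m, height = NULL) {
  if (inherits(m, "distance_matrix")) return(m)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0))
    stop("distances must be finite and non-negative", call. = FALSE)
  if (any(diag(m) != 0)) stop("diagonal must be exactly 0", call. = FALSE)
  scale <- max(abs(m), 1e-300)
  if (max(abs(m - t(m))) > 1e-9 * scale)
    stop("matrix is not symmetric within 1e-9 relative tolerance",
         call. = FALSE)
  m <- (m + t(m)) / 2
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- seq_len(nrow(m))
  if (is.null(height)) height <- max(m) / 2
  structure(m, height = height, class = c("distance_matrix", "matrix"))
}

#' All pairwise distances of a distance matrix
#'
#' @param m a matrix accepted by \code{\link{as_distance_matrix}}.
#' @return numeric vector of the \eqn{M(M-1)/2} upper-triangle values.
#' @export
pairwise_list <- function(m) {
  m <- as_distance_matrix(m)
  m[upper.tri(m)]
}

#' Distance of every leaf to its n-th nearest neighbour
#'
#' For each leaf with at least \code{n} other leaves, the \code{n}-th
#' smallest off-diagonal entry of its row, counting ties with multiplicity
#' (sorted multiset): a leaf with two equidistant nearest neighbours has
#' that distance as both its 1st and 2nd value.
#'
#' @inheritParams pairwise_list
#' @param n neighbour order, integer \eqn{\ge 1}.
#' @return data frame with columns \code{leaf} (label) and \code{distance};
#'   zero rows when no leaf has \code{n} neighbours.
#' @export
nth_nearest_list <- function(m, n = 1) {
  m <- as_distance_matrix(m)
  stopifnot(n >= 1, n == floor(n))
  M <- nrow(m)
  if (M <= n)
    return(data.frame(leaf = character(0), distance = numeric(0)))
  d <- vapply(seq_len(M), function(i) sort(m[i, -i])[n], numeric(1))
  data.frame(leaf = rownames(m), distance = d)
}

#' Cherries of a distance matrix
#'
#' Unordered pairs of leaves that are reciprocal nearest neighbours.  Ties
#' (a leaf with several equidistant nearest neighbours) are resolved
#' deterministically: candidate mutual-nearest pairs are sorted by ascending
#' distance, then lexicographically by label, and accepted greedily so that
#' each leaf appears in at most one cherry.
#'
#' @inheritParams pairwise_list
#' @return data frame with columns \code{leaf1}, \code{leaf2},
#'   \code{distance}.
#' @export
cherry_list <- function(m) {
  m <- as_distance_matrix(m)
  M <- nrow(m)
  empty <- data.frame(leaf1 = character(0), leaf2 = character(0),
                      distance = numeric(0))
  if (M < 2) return(empty)
  nn <- vapply(seq_len(M), function(i) min(m[i, -i]), numeric(1))
  cand <- which(upper.tri(m) & m == outer(nn, rep(1, M)) &
                  m == outer(rep(1, M), nn), arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  lab <- rownames(m)
  ord <- order(m[cand], lab[cand[, 1]], lab[cand[, 2]])
  cand <- cand[ord, , drop = FALSE]
  used <- rep(FALSE, M)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used[i] && !used[j]) {
      keep[k] <- TRUE
      used[i] <- used[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(leaf1 = lab[cand[, 1]], leaf2 = lab[cand[, 2]],
             distance = m[cand])
}

#' Pairwise minima of nearest-neighbour distances
#'
#' For every unordered pair of leaves, the smaller of the two members'
#' nearest-neighbour distances.  A leaf alone on its tree has, by
#' convention, nearest-neighbour distance \eqn{2T}; with a bare matrix this
#' only arises for \eqn{M = 1}, which yields no pairs.
#'
#' @inheritParams pairwise_list
#' @param height tree height; defaults to the matrix's attached or inferred
#'   height.
#' @return numeric vector of \eqn{M(M-1)/2} values.
#' @export
min2_list <- function(m, height = NULL) {
  m <- as_distance_matrix(m, height = height)
  M <- nrow(m)
  if (M < 2) return(numeric(0))
  nn <- vapply(seq_len(M), function(i) min(m[i, -i]), numeric(1))
  pm <- outer(nn, nn, pmin)
  pm[upper.tri(pm)]
}

# shared constructor for histogram objects built from pre-binned counts
build_histogram_counts <- function(kind, edges, counts, trees = 1) {
  width <- diff(edges)
  structure(list(kind = kind, edges = edges, mids = edges[-1] - width / 2,
                 counts = counts, width = width[1],
                 density = counts / (width * trees), trees = trees),
            class = "distance_histogram")
}

#' Bin statistic values into a distance histogram
#'
#' Uniform bins, half-open \code{[left, right)} with the last bin closed.
#' The reported density is \code{count / (width * trees)}: when values are
#' pooled across \code{trees} replicate trees (as with a posterior sample
#' of trees), the density is the per-tree average, directly comparable to
#' the analytic expected densities.
#'
#' @param values numeric vector of statistic values (distances).
#' @param bins number of bins.
#' @param range histogram range; values outside are dropped.
#' @param trees number of pooled trees the values came from.
#' @param kind label for the statistic (free-form).
#' @return object of class \code{"distance_histogram"} with fields
#'   \code{kind}, \code{edges}, \code{mids}, \code{counts}, \code{density},
#'   \code{width}, \code{trees}.
#' @export
build_histogram <- function(values, bins = 40, range = NULL, trees = 1,
                            kind = "pairwise") {
  stopifnot(bins >= 1, trees >= 1)
  if (is.null(range)) range <- c(0, max(values, 1e-12))
  if (range[2] <= range[1]) stop("'range' must have positive width")
  edges <- seq(range[1], range[2], length.out = bins + 1)
  width <- diff(edges[1:2])
  idx <- floor((values - range[1]) / width)
  idx[values == range[2]] <- bins - 1  # closed last bin
  idx <- idx[idx >= 0 & idx < bins]
  counts <- tabulate(idx + 1L, nbins = bins)
  build_histogram_counts(kind, edges, counts, trees)
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("Distance histogram (%s): %d bins on [%g, %g], %g values, %d tree(s)\n",
              x$kind, length(x$counts), x$edges[1],
              x$edges[length(x$edges)], sum(x$counts), x$trees))
  invisible(x)
}
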