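# File formats: Newick trees (via ape), TSV / PHYLIP-square distance
# matrices, histogram TSVs with commented headers, JSON fit reports.

#' Read trees and reduce them to distance matrices
#'
#' Reads one or more Newick trees with branch lengths (multi-tree files:
#' one tree per line or concatenated) and converts each to its cophenetic
#' distance matrix --- the sum of branch lengths on the path between each
#' pair of tips.  For ultrametric (clock-like) trees this equals twice the
#' time to the pair's most recent common ancestor.  Non-ultrametric trees
#' are accepted with a warning; branch lengths are interpreted as time,
#' optionally rescaled.
#'
#' @param path file with Newick tree(s).
#' @param time_scale multiplier applied to all branch lengths on read
#'   (e.g. convert units).
#' @return list of \code{"distance_matrix"} objects (see
#'   \code{\link{as_distance_matrix}}), each with the tree height (maximum
#'   root-to-tip path) attached.
#' @export
read_trees <- function(path, time_scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  trees <- tryCatch(ape::read.tree(path),
                    error = function(e) stop("Newick parse error in '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
  if (is.null(trees)) stop("no trees in '", path, "'", call. = FALSE)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, function(phy) {
    if (is.null(phy$edge.length))
      stop("tree has no branch lengths", call. = FALSE)
    if (any(phy$edge.length < 0))
      stop("negative branch length in tree", call. = FALSE)
    phy$edge.length <- phy$edge.length * time_scale
    if (!ape::is.ultrametric(phy, tol = 1e-6))
      warning("tree is not ultrametric; distances are path lengths, ",
              "not necessarily 2*(T - t_MRCA)")
    depths <- ape::node.depth.edgelength(phy)
    height <- max(depths[seq_len(length(phy$tip.label))])
    m <- as.matrix(stats::cophenetic(phy))
    as_distance_matrix(m, height = height)
  })
}

#' Read a square distance matrix
#'
#' Dialects: \code{"tsv"} (tab-separated, leaf labels in the first row and
#' first column) and \code{"phylip"} (square PHYLIP: first line the leaf
#' count, then one row per leaf: label followed by the distances).
#'
#' @param path input file.
#' @param dialect \code{"tsv"} or \code{"phylip"}.
#' @param height optional tree height (else inferred as \code{max/2}).
#' @return a \code{"distance_matrix"}.
#' @export
read_distance_matrix <- function(path, dialect = c("tsv", "phylip"),
                                 height = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (dialect == "tsv") {
    cells <- strsplit(lines, "\t", fixed = TRUE)
    labels <- cells[[1]][-1]
    rows <- cells[-1]
    if (any(lengths(rows) != length(labels) + 1))
      stop("ragged rows in matrix file", call. = FALSE)
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
    rownames(m) <- vapply(rows, `[[`, "", 1)
    colnames(m) <- labels
  } else {
    n <- as.integer(trimws(lines[1]))
    rows <- strsplit(trimws(lines[-1]), "[[:space:]]+")
    if (length(rows) != n || any(lengths(rows) != n + 1))
      stop("malformed PHYLIP-square matrix", call. = FALSE)
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
    rownames(m) <- colnames(m) <- vapply(rows, `[[`, "", 1)
  }
  if (any(is.na(m))) stop("non-numeric entries in matrix", call. = FALSE)
  as_distance_matrix(m, height = height)
}

#' Write a distance matrix
#'
#' Full double precision (\code{\%.17g}); \code{read(write(x))} round-trips
#' bit-exactly.
#'
#' @param m a matrix accepted by \code{\link{as_distance_matrix}}.
#' @param path output file.
#' @param dialect \code{"tsv"} or \code{"phylip"}.
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(m, path, dialect = c("tsv", "phylip")) {
  dialect <- match.arg(dialect)
  m <- as_distance_matrix(m)
  fmt <- function(x) sprintf("%.17g", x)
  rows <- vapply(seq_len(nrow(m)),
                 function(i) paste(c(rownames(m)[i], fmt(m[i, ])),
                                   collapse = "\t"),
                 "")
  header <- if (dialect == "tsv")
    paste(c("", colnames(m)), collapse = "\t") else as.character(nrow(m))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write / read a distance histogram as TSV
#'
#' Columns \code{bin_left}, \code{bin_right}, \code{count}, \code{density}
#' (and, when present, \code{conditional_density} and \code{trees_nonzero}),
#' preceded by commented header lines (\code{# key=value}) recording the
#' statistic kind, pooled tree count, generating parameters and seed.
#'
#' @param hist a \code{"distance_histogram"}.
#' @param path output (input) file.
#' @param seed optional seed to record in the header.
#' @return \code{write_histogram}: \code{path} invisibly;
#'   \code{read_histogram}: a \code{"distance_histogram"}.
#' @export
write_histogram <- function(hist, path, seed = NULL) {
  stopifnot(inherits(hist, "distance_histogram"))
  hdr <- c(sprintf("# kind=%s", hist$kind),
           sprintf("# trees=%d", hist$trees),
           sprintf("# version=%s",
                   as.character(utils::packageVersion("yuledist"))))
  if (!is.null(hist$params))
    hdr <- c(hdr, sprintf("# params=lambda:%.17g,mu:%.17g,sigma:%.17g,height:%.17g",
                          hist$params$lambda, hist$params$mu,
                          hist$params$sigma, hist$params$height))
  if (!is.null(seed)) hdr <- c(hdr, sprintf("# seed=%d", seed))
  nb <- length(hist$counts)
  cols <- list(bin_left = hist$edges[-(nb + 1)], bin_right = hist$edges[-1],
               count = hist$counts, density = hist$density)
  if (!is.null(hist$conditional_density)) {
    cols$conditional_density <- hist$conditional_density
    cols$trees_nonzero <- hist$nonzero
  }
  body <- do.call(paste, c(lapply(cols, function(x) sprintf("%.17g", x)),
                           sep = "\t"))
  writeLines(c(hdr, paste(names(cols), collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  kind <- sub("^# kind=", "", grep("^# kind=", hdr, value = TRUE)[1])
  trees <- as.integer(sub("^# trees=", "",
                          grep("^# trees=", hdr, value = TRUE)[1]))
  cn <- strsplit(body[1], "\t")[[1]]
  if (length(body) < 2) {  # header-only file: zero bins
    return(build_histogram_counts(kind, numeric(0), numeric(0),
                                  trees = max(trees, 1)))
  }
  vals <- do.call(rbind, lapply(strsplit(body[-1], "\t"), as.numeric))
  colnames(vals) <- cn
  col <- function(name) as.numeric(vals[, name])
  edges <- unname(c(col("bin_left"), vals[nrow(vals), "bin_right"]))
  h <- build_histogram_counts(kind, edges, col("count"),
                              trees = max(trees, 1))
  if ("conditional_density" %in% cn) {
    h$conditional_density <- col("conditional_density")
    h$nonzero <- as.integer(col("trees_nonzero"))
  }
  h
}

#' Write a fit report as JSON
#'
#' Serializes a \code{"yule_fit"} plus derived sampling-fraction numbers:
#' keys \code{r}, \code{q}, \code{A}, standard errors,
#' \code{sigma_upper_bound}, an \code{implied_sigma} table over the given
#' \eqn{\mu/\lambda} ratios, convergence information and any
#' maximum-detection verdicts.
#'
#' @param fit a \code{"yule_fit"}.
#' @param path output JSON file.
#' @param mu_over_lambda ratios for the implied-sigma table.
#' @param verdicts optional list of \code{\link{maximum_based_sigma_bound}}
#'   results.
#' @return \code{path}, invisibly.
#' @export
write_fit_report <- function(fit, path, mu_over_lambda = c(0, 0.2, 0.4,
                                                           0.6, 0.8),
                             verdicts = NULL) {
  stopifnot(inherits(fit, "yule_fit"))
  e <- fit$estimates
  report <- list(
    r = unname(e["r"]), q = unname(e["q"]), A = unname(e["A"]),
    se = as.list(fit$se),
    converged = fit$converged,
    iterations = fit$iterations,
    window = fit$window,
    sigma_upper_bound = sigma_upper_bound(fit),
    implied_sigma = data.frame(
      mu_over_lambda = mu_over_lambda,
      sigma = implied_sigma(fit, mu_over_lambda)),
    maximum_verdicts = verdicts)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
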