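# Robust fitting of the closed-form densities to distance histograms.
#
# All fitted curves depend on the model parameters only through the three
# identifiable combinations
#   r = lambda - mu,   q = lambda * sigma,   A = sigma * exp(r * T),
# with g(t) = (exp(r t/2) - 1)/r:
#   pairwise:  (q A / 2) exp(r t / 2)
#   nth_min n: n(n+1)/2 * q A (q g)^(n-1) exp(r t/2) / (1 + q g)^(n+2)
#   cherry:    (q A / 2) exp(r t / 2) / (1 + q g)^4
# (lambda, mu, sigma, T individually are NOT identifiable from distances.)
# Fitting is iteratively reweighted least squares with bisquare weights,
# the standard robust scheme for histogram points with occasional outliers.

# predicted density for one kind at bin midpoints, given theta = (r, q, A)
.curve_value <- function(kind, n, theta, t) {
  r <- theta[1]; q <- theta[2]; A <- theta[3]
  g <- .growth(r, t / 2)
  base <- exp(r * t / 2)
  switch(kind,
         pairwise = q * A / 2 * base,
         nth_min = n * (n + 1) / 2 * q * A * (q * g)^(n - 1) * base /
           (1 + q * g)^(n + 2),
         cherry = q * A / 2 * base / (1 + q * g)^4,
         stop("kind '", kind, "' cannot be fitted in (r, q, A)",
              call. = FALSE))
}

# conditional (non-empty-bin) pairwise curve: (1 + q g)^2 / dt
.curve_value_conditional <- function(theta, t, dt) {
  (1 + theta[2] * .growth(theta[1], t / 2))^2 / dt
}

.parse_fit_kind <- function(kind) {
  if (grepl("^nth_min[0-9]+$", kind))
    return(list(kind = "nth_min", n = as.integer(sub("nth_min", "", kind))))
  if (kind %in% c("pairwise", "cherry")) return(list(kind = kind, n = NA))
  stop("unsupported fit kind: ", kind, call. = FALSE)
}

#' Construct a fit result by hand
#'
#' Wraps given values of the identifiable combinations \eqn{r = \lambda-\mu},
#' \eqn{q = \lambda\sigma} and \eqn{A = \sigma e^{rT}} into the same object
#' that \code{\link{fit_densities}} returns, so that
#' \code{\link{sigma_upper_bound}} and \code{\link{implied_sigma}} can be
#' applied to externally reported estimates.
#'
#' @param r net growth rate \eqn{\lambda - \mu} (per time).
#' @param q \eqn{\lambda \sigma} (per time).
#' @param A \eqn{\sigma e^{rT}} (dimensionless), optional.
#' @return object of class \code{"yule_fit"}.
#' @examples
#' implied_sigma(fit_result(r = 8e-8, q = 6.4e-8), 0)
#' @export
fit_result <- function(r, q, A = NA_real_) {
  stopifnot(is.finite(r), r > 0, is.finite(q), q > 0)
  structure(list(estimates = c(r = r, q = q, A = A),
                 se = c(r = NA_real_, q = NA_real_, A = NA_real_),
                 converged = TRUE, iterations = 0L,
                 window = c(NA_real_, NA_real_), residual_scale = NA_real_),
            class = "yule_fit")
}

#' @export
print.yule_fit <- function(x, ...) {
  e <- x$estimates; s <- x$se
  cat("Yule density fit (identifiable combinations):\n")
  cat(sprintf("  r = lambda - mu     : %.6g (se %.3g)\n", e["r"], s["r"]))
  cat(sprintf("  q = lambda * sigma  : %.6g (se %.3g)\n", e["q"], s["q"]))
  cat(sprintf("  A = sigma * exp(rT) : %.6g (se %.3g)\n", e["A"], s["A"]))
  cat(sprintf("  converged: %s (%d IRLS iterations)\n",
              x$converged, x$iterations))
  if (is.finite(e["r"]) && is.finite(e["q"]))
    cat(sprintf("  sigma upper bound q/r (mu = 0): %.4g\n",
                sigma_upper_bound(x)))
  invisible(x)
}

# assemble (t, y, kind, n, dt) points from histograms within the window
.fit_points <- function(histograms, kinds, window, conditional) {
  pts <- list()
  for (i in seq_along(histograms)) {
    h <- histograms[[i]]
    if (!inherits(h, "distance_histogram"))
      stop("inputs must be distance_histogram objects", call. = FALSE)
    ki <- .parse_fit_kind(kinds[i])
    y <- if (conditional && ki$kind == "pairwise" &&
             !is.null(h$conditional_density)) {
      # single-tree / sparse regime: fit the non-empty-bin mean, drop zeros
      h$conditional_density
    } else h$density
    keep <- h$mids >= window[1] & h$mids <= window[2]
    if (conditional) keep <- keep & y > 0
    pts[[i]] <- data.frame(t = as.numeric(h$mids[keep]),
                           y = as.numeric(y[keep]), kind = ki$kind,
                           n = ki$n, dt = h$width,
                           conditional = conditional & ki$kind == "pairwise",
                           row.names = NULL)
  }
  do.call(rbind, pts)
}

.predict_points <- function(theta, pts) {
  out <- numeric(nrow(pts))
  for (k in unique(paste(pts$kind, pts$n, pts$conditional))) {
    idx <- paste(pts$kind, pts$n, pts$conditional) == k
    p1 <- pts[idx, ][1, ]
    out[idx] <- if (p1$conditional)
      .curve_value_conditional(theta, pts$t[idx], p1$dt)
    else .curve_value(p1$kind, p1$n, theta, pts$t[idx])
  }
  out
}

# damped Gauss-Newton for weighted least squares in log-parameters
.wls_fit <- function(ltheta, pts, w, max_iter = 50, tol = 1e-12) {
  obj <- function(lt) {
    res <- pts$y - .predict_points(exp(lt), pts)
    sum(w * res^2)
  }
  lt <- ltheta
  f0 <- obj(lt)
  lambda_lm <- 1e-4
  for (it in seq_len(max_iter)) {
    pred <- .predict_points(exp(lt), pts)
    res <- pts$y - pred
    # numeric Jacobian wrt log-parameters
    J <- vapply(1:3, function(j) {
      h <- 1e-6
      ltp <- lt; ltp[j] <- ltp[j] + h
      (.predict_points(exp(ltp), pts) - pred) / h
    }, numeric(nrow(pts)))
    A <- crossprod(J, w * J)
    b <- crossprod(J, w * res)
    step_ok <- FALSE
    for (tries in 1:30) {
      delta <- tryCatch(solve(A + lambda_lm * diag(diag(A) + 1e-30), b),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        lt_new <- lt + as.numeric(delta)
        f_new <- obj(lt_new)
        if (is.finite(f_new) && f_new <= f0) {
          step_ok <- TRUE
          lambda_lm <- max(lambda_lm / 3, 1e-12)
          break
        }
      }
      lambda_lm <- lambda_lm * 10
    }
    if (!step_ok) break
    moved <- max(abs(lt_new - lt))
    lt <- lt_new
    f_prev <- f0
    f0 <- f_new
    if (moved < tol || (f_prev - f0) <= 1e-14 * (f_prev + 1e-300)) break
  }
  list(ltheta = lt, J = J, obj = f0)
}

#' Fit closed-form distance densities to histograms
#'
#' Jointly fits the pairwise, n-th nearest-neighbour and/or cherry expected
#' densities --- reparameterized in the identifiable combinations
#' \eqn{r = \lambda-\mu}, \eqn{q = \lambda\sigma},
#' \eqn{A = \sigma e^{rT}} --- to the bins of one or more histograms, by
#' iteratively reweighted least squares with bisquare weights (tuning
#' constant 4.685).  The IRLS loop stops when the relative parameter change
#' drops below \code{1e-8} or after \code{max_iter} iterations; a fit that
#' fails to initialize or iterate is returned with
#' \code{converged = FALSE}, not as an error.
#'
#' Initialization: a log-linear regression of the positive pairwise bins
#' gives starting \eqn{r} and amplitude \eqn{qA/2}; \eqn{q} is then seeded
#' by a one-dimensional grid search on the shape-carrying histograms.  When
#' no pairwise histogram is supplied, the grid search runs over \eqn{r}
#' as well.
#'
#' @param histograms a single \code{"distance_histogram"} or list of them.
#' @param kinds character vector, one per histogram: \code{"pairwise"},
#'   \code{"nth_min<k>"} (e.g. \code{"nth_min1"}) or \code{"cherry"};
#'   default: the histograms' own \code{kind} fields.
#' @param window numeric \code{c(lo, hi)}: only bins with midpoints inside
#'   are fitted.  Default: the full support.
#' @param conditional if \code{TRUE}, the pairwise histogram is fitted with
#'   the conditional non-empty-bin curve \eqn{(1+qg)^2/dt} and zero bins are
#'   dropped --- the appropriate regime for a single tree's sparse histogram.
#' @param init optional named vector \code{c(r=, q=, A=)} of starting values.
#' @param max_iter IRLS iteration cap.
#' @return object of class \code{"yule_fit"}: list with \code{estimates}
#'   (named \code{r, q, A}), \code{se} (heteroscedasticity-robust asymptotic
#'   standard errors), \code{converged}, \code{iterations}, \code{window},
#'   \code{residual_scale}, \code{n_points}.
#'
#' @section Standard errors: the reported standard errors treat histogram
#'   bins as independent observations.  For histograms pooled over one
#'   batch of trees the bins are positively correlated (they share the same
#'   trees), and the standard errors understate the true sampling
#'   uncertainty of the batch; compare fits across replicate batches when
#'   that uncertainty matters.
#' @export
fit_densities <- function(histograms, kinds = NULL, window = NULL,
                          conditional = FALSE, init = NULL, max_iter = 100) {
  if (inherits(histograms, "distance_histogram")) histograms <- list(histograms)
  if (length(histograms) < 1) stop("at least one histogram is required")
  if (is.null(kinds)) kinds <- vapply(histograms, `[[`, "", "kind")
  stopifnot(length(kinds) == length(histograms))
  support <- range(unlist(lapply(histograms, `[[`, "edges")))
  if (is.null(window)) window <- support
  if (window[2] <= window[1] || window[1] > support[2] ||
      window[2] < support[1])
    stop("empty fit window", call. = FALSE)

  failed <- structure(
    list(estimates = c(r = NA_real_, q = NA_real_, A = NA_real_),
         se = c(r = NA_real_, q = NA_real_, A = NA_real_),
         converged = FALSE, iterations = 0L, window = window,
         residual_scale = NA_real_, n_points = 0L),
    class = "yule_fit")

  pts <- .fit_points(histograms, kinds, window, conditional)
  if (is.null(pts) || nrow(pts) < 3 || all(pts$y <= 0)) return(failed)

  theta0 <- if (!is.null(init)) init[c("r", "q", "A")] else .init_theta(pts)
  if (any(!is.finite(theta0)) || any(theta0 <= 0)) return(failed)

  lt <- log(as.numeric(theta0))
  w <- rep(1, nrow(pts))
  yscale <- max(abs(pts$y))
  iterations <- 0L
  converged <- FALSE
  scale <- NA_real_
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    fit <- .wls_fit(lt, pts, w)
    moved <- max(abs(fit$ltheta - lt))
    lt <- fit$ltheta
    res <- pts$y - .predict_points(exp(lt), pts)
    scale <- median(abs(res[abs(res) > 0])) / 0.6745
    if (!is.finite(scale) || scale < 1e-10 * yscale) {
      converged <- TRUE  # (near-)perfect fit; robust weighting is moot
      break
    }
    u <- res / (4.685 * scale)
    w_new <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w_new) < 3) w_new <- rep(1, nrow(pts))
    w <- w_new
    if (moved < 1e-8) {
      converged <- TRUE
      break
    }
  }
  theta <- exp(lt)
  # heteroscedasticity-robust (sandwich) covariance from the final weighted
  # Jacobian in log scale -- bin densities span orders of magnitude, so a
  # homoscedastic residual variance would understate the uncertainty --
  # then delta method back to (r, q, A)
  fit <- .wls_fit(lt, pts, w, max_iter = 1)
  J <- fit$J
  res <- pts$y - .predict_points(theta, pts)
  dof_inflate <- nrow(pts) / max(nrow(pts) - 3, 1)
  cov_lt <- tryCatch({
    bread <- solve(crossprod(J, w * J))
    meat <- crossprod(J * w * res, J * w * res)
    dof_inflate * bread %*% meat %*% bread
  }, error = function(e) matrix(NA_real_, 3, 3))
  se <- theta * sqrt(pmax(diag(cov_lt), 0))
  structure(list(estimates = c(r = theta[1], q = theta[2], A = theta[3]),
                 se = c(r = se[1], q = se[2], A = se[3]),
                 converged = converged, iterations = iterations,
                 window = window, residual_scale = scale,
                 n_points = nrow(pts)),
            class = "yule_fit")
}

# starting values: log-linear regression on pairwise bins, grid search for q
.init_theta <- function(pts) {
  pw <- pts[pts$kind == "pairwise" & pts$y > 0 & !pts$conditional, ]
  if (nrow(pw) >= 3) {
    co <- coef(lm(log(y) ~ t, data = pw))
    r0 <- max(2 * co[2], 1e-8)
    B0 <- 2 * exp(co[1])  # q * A
    r_grid <- r0
  } else {
    # no usable pairwise bins: coarse grid over r, amplitude from peak value
    any_pos <- pts[pts$y > 0, ]
    r_ref <- 2 / max(any_pos$t) * log(max(any_pos$y) / min(any_pos$y) + 1)
    r_grid <- r_ref * c(0.25, 0.5, 1, 2, 4)
    B0 <- NA
  }
  best <- NULL
  for (r0 in r_grid) {
    if (is.na(B0)) B0 <- max(pts$y) * 2
    for (q0 in r0 * c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8, 1.5)) {
      th <- c(r0, q0, B0 / q0)
      ss <- sum((pts$y - .predict_points(th, pts))^2)
      if (is.finite(ss) && (is.null(best) || ss < best$ss))
        best <- list(th = th, ss = ss)
    }
  }
  if (is.null(best)) return(c(NA_real_, NA_real_, NA_real_))
  setNames(best$th, c("r", "q", "A"))
}

#' Upper bound on the sampling fraction
#'
#' From fitted combinations \eqn{q = \lambda\sigma} and
#' \eqn{r = \lambda-\mu}: since \eqn{\mu \ge 0},
#' \eqn{\sigma = q(1-\mu/\lambda)/r \le q/r}.  Capped at 1.
#'
#' @param fit a \code{"yule_fit"} (from \code{\link{fit_densities}} or
#'   \code{\link{fit_result}}).
#' @return upper bound for \eqn{\sigma}.
#' @export
sigma_upper_bound <- function(fit) {
  stopifnot(inherits(fit, "yule_fit"))
  e <- fit$estimates
  if (!is.finite(e["r"]) || !is.finite(e["q"]))
    stop("fit has no usable estimates", call. = FALSE)
  min(1, unname(e["q"] / e["r"]))
}

#' Sampling fraction implied by an assumed extinction-to-speciation ratio
#'
#' \eqn{\sigma = (q/r)(1 - \mu/\lambda)}: the fitted combinations determine
#' \eqn{\sigma} once a ratio \eqn{\mu/\lambda} is assumed.  At ratio 0 this
#' equals \code{\link{sigma_upper_bound}}, and it decreases linearly in the
#' ratio.
#'
#' @inheritParams sigma_upper_bound
#' @param mu_over_lambda assumed ratio(s) \eqn{\mu/\lambda} in \eqn{[0, 1)};
#'   vectorized.
#' @return implied sampling fraction(s), capped at 1.
#' @export
implied_sigma <- function(fit, mu_over_lambda = 0) {
  stopifnot(inherits(fit, "yule_fit"),
            all(mu_over_lambda >= 0), all(mu_over_lambda < 1))
  e <- fit$estimates
  pmin(1, unname(e["q"] / e["r"]) * (1 - mu_over_lambda))
}

#' Sampling-fraction bound from an observed density maximum
#'
#' The nearest-neighbour, cherry and min2 densities develop an interior
#' maximum only when sampling is sparse (\code{\link{sigma_threshold}}).
#' This helper inspects the FITTED curve (not the raw counts) of a
#' histogram's kind on a fine grid over the support: if an interior maximum
#' is present, it returns the corresponding bound claim
#' (\eqn{\sigma < 1/3}, \eqn{1/4} or \eqn{1/5}); otherwise \code{NULL}.
#'
#' @param histogram the fitted \code{"distance_histogram"} (supplies kind
#'   and support).
#' @param fit the \code{"yule_fit"} for that histogram.
#' @return \code{NULL}, or a list with \code{bound}, \code{kind},
#'   \code{t_max} (location of the fitted maximum) and \code{caveat}
#'   ("upper bound assumes mu >= 0").
#' @export
maximum_based_sigma_bound <- function(histogram, fit) {
  stopifnot(inherits(histogram, "distance_histogram"),
            inherits(fit, "yule_fit"))
  if (identical(histogram$kind, "min2")) {
    ki <- list(kind = "min2", n = NA)
  } else {
    ki <- .parse_fit_kind(histogram$kind)
  }
  if (ki$kind == "pairwise")
    stop("the pairwise density is monotone for all sigma: no criterion exists",
         call. = FALSE)
  bound <- switch(ki$kind, nth_min = 1 / 3, cherry = 1 / 4, min2 = 1 / 5)
  if (ki$kind == "nth_min" && ki$n != 1)
    stop("maximum criterion applies to the first nearest neighbour only",
         call. = FALSE)
  support <- range(histogram$edges)
  tt <- seq(support[1], support[2], length.out = 2001)
  yy <- if (ki$kind == "min2") {
    # large-T shape of the min2 density in the identifiable combinations
    r <- fit$estimates[1]; q <- fit$estimates[2]
    exp(r * tt / 2) / (1 + q * .growth(r, tt / 2))^5
  } else {
    .curve_value(ki$kind, ki$n, fit$estimates, tt)
  }
  i <- which.max(yy)
  if (i == 1 || i == length(tt)) return(NULL)
  if (yy[i] <= max(yy[1], yy[length(yy)])) return(NULL)
  list(bound = bound, kind = histogram$kind, t_max = tt[i],
       caveat = "upper bound assumes mu >= 0")
}
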