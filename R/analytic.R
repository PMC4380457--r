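# Closed-form laws for a birth-death tree of height T with Bernoulli leaf
# sampling.  Internal parameterization used throughout:
#   r = lambda - mu,  a = lambda * sigma,  E = exp(r*T),
#   G = (E - 1)/r  (growth integral),  g(t) = (exp(r*t/2) - 1)/r.
# The observed leaf-count law is geometric:
#   P(0) = 1 - sigma*E/(1 + a*G),  P(m>=1) = (1-P0) (1-eta) eta^(m-1),
#   eta = a*G/(1 + a*G),
# and every density below reduces to rational functions of these pieces.

# geometric pieces of the observed leaf-count law at height `height`
.leaf_law <- function(params, height = params$height) {
  r <- params$r
  a <- params$lambda * params$sigma
  E <- exp(r * height)
  G <- .growth(r, height)
  denom <- 1 + a * G
  list(surv = params$sigma * E / denom,   # 1 - P(0)
       eta = a * G / denom,               # geometric ratio
       one_minus_eta = 1 / denom)
}

#' Distribution of the number of observed leaves
#'
#' Probability of observing exactly \code{m} leaves on a Yule tree of height
#' \eqn{T}, after Bernoulli sampling of the extant leaves with probability
#' \eqn{\sigma}.  With \eqn{\sigma = 1} this is the classical birth--death
#' leaf-count law (zero-inflated geometric); incomplete sampling keeps the
#' geometric form with rescaled survival probability and ratio.
#'
#' @param params a \code{\link{yule_params}} object.
#' @param m vector of non-negative integer leaf counts.
#' @return \code{P(m | T)}, vectorized over \code{m}; sums to 1 over
#'   \code{m = 0, 1, 2, ...}.
#' @examples
#' p <- yule_params(2, 1, 1, 1)
#' leaf_count_pmf(p, 0)       # extinction-or-unobserved probability
#' sum(leaf_count_pmf(p, 0:500))
#' @export
leaf_count_pmf <- function(params, m) {
  .check_params(params)
  if (any(m < 0) || any(m != floor(m))) stop("'m' must be non-negative integers")
  law <- .leaf_law(params)
  ifelse(m == 0, 1 - law$surv,
         law$surv * law$one_minus_eta * law$eta^(pmax(m, 1) - 1))
}

#' Probability of observing more than k leaves
#'
#' Tail of the observed leaf-count law, \eqn{P_>(k|T) = 1 - \sum_{m \le k}
#' P(m|T)}.  Computed from the geometric form of the law,
#' \eqn{(1 - P(0)) \eta^k}, which equals the complemented cumulative sum
#' exactly but is stable for large \code{k}.
#'
#' @inheritParams leaf_count_pmf
#' @param k vector of non-negative integers.
#' @return \code{P(M > k | T)}, vectorized over \code{k}.
#' @export
prob_more_than <- function(params, k) {
  .check_params(params)
  if (any(k < 0) || any(k != floor(k))) stop("'k' must be non-negative integers")
  law <- .leaf_law(params)
  law$surv * law$eta^k
}

#' Expected number of observed leaves
#'
#' \eqn{\langle M \rangle = \sigma e^{(\lambda-\mu)T}}.
#'
#' @inheritParams leaf_count_pmf
#' @return expected observed leaf count.
#' @export
mean_leaves <- function(params) {
  .check_params(params)
  params$sigma * exp(params$r * params$height)
}

#' Expected number of observed leaf pairs
#'
#' \eqn{\langle M(M-1)/2 \rangle = \sigma^2 \lambda\, e^{(\lambda-\mu)T}
#' (e^{(\lambda-\mu)T} - 1)/(\lambda-\mu)}, evaluated through the growth
#' integral so that \eqn{\lambda = \mu} is handled exactly
#' (limit \eqn{\sigma^2 \lambda T}).
#'
#' @inheritParams leaf_count_pmf
#' @return expected number of unordered observed pairs.
#' @export
mean_pairs <- function(params) {
  .check_params(params)
  params$sigma^2 * params$lambda * exp(params$r * params$height) *
    .growth(params$r, params$height)
}

#' Expected total branch length of the full tree
#'
#' Sum of all branch lengths of the complete genealogy (including extinct and
#' unobserved parts): \eqn{(e^{(\lambda-\mu)T} - 1)/(\lambda-\mu)}, with the
#' \eqn{\lambda=\mu} limit \eqn{T}.
#'
#' @inheritParams leaf_count_pmf
#' @return expected total branch length (time units).
#' @export
total_branch_length <- function(params) {
  .check_params(params)
  .growth(params$r, params$height)
}

#' Expected number of ancestral lineages with observed descendants
#'
#' Expected number of lineages alive at time \code{t} that leave at least one
#' observed descendant at the tree height:
#' \eqn{e^{(\lambda-\mu)t} [1 - P(0 | T - t)]}.  At \code{t = 0} this is the
#' probability that the tree has any observed leaf; at \code{t = T} it equals
#' \code{\link{mean_leaves}}.
#'
#' @inheritParams leaf_count_pmf
#' @param t time in \eqn{[0, T]}, vectorized.
#' @return expected lineage count at each \code{t}.
#' @export
mean_ancestral_lineages <- function(params, t) {
  .check_params(params)
  if (any(t < 0 | t > params$height)) stop("'t' must lie in [0, height]")
  r <- params$r
  a <- params$lambda * params$sigma
  # e^{rt} * sigma e^{r(T-t)} / (1 + a G(T-t)) = sigma E / (1 + a G(T-t))
  params$sigma * exp(r * params$height) / (1 + a * .growth(r, params$height - t))
}

#' Expected branch length of the reconstructed (observed) tree
#'
#' Expected total length of the branches that lead to at least one observed
#' leaf, i.e. the branch length of the tree reconstructed from the observed
#' leaves alone: the integral of \code{\link{mean_ancestral_lineages}} over
#' \eqn{[0, T]}, available in closed form.  Converges to
#' \code{\link{total_branch_length}} as \eqn{\mu \to 0},
#' \eqn{\sigma \to 1}, and to 0 as \eqn{\sigma \to 0}.
#'
#' @inheritParams leaf_count_pmf
#' @return expected reconstructed branch length (time units).
#' @export
reconstructed_branch_length <- function(params) {
  .check_params(params)
  r <- params$r
  a <- params$lambda * params$sigma
  G <- .growth(r, params$height)
  x <- -(r - a) * G * exp(-r * params$height)
  params$sigma * G * .l1pr(x)
}

# support mask for a pair-distance density
.support <- function(params, t) t >= 0 & t <= 2 * params$height

# g(t) = (exp(r t/2) - 1)/r
.gt <- function(params, t) .growth(params$r, t / 2)

#' Expected density of pairwise distances
#'
#' Expected number of unordered observed leaf pairs per unit time distance,
#' \eqn{N(t|T) = (\sigma^2 \lambda / 2)\, e^{(\lambda-\mu)T}
#' e^{(\lambda-\mu)t/2}} for \eqn{0 \le t \le 2T} and 0 otherwise.  A pair's
#' distance is twice the time back to its most recent common ancestor, so the
#' support is cut off at \eqn{2T}.  The density integrates exactly to
#' \code{\link{mean_pairs}}, which fixes the \eqn{\lambda/2} prefactor.
#'
#' @inheritParams leaf_count_pmf
#' @param t time distance, any real vector.
#' @return density (pairs per unit time), vectorized over \code{t}.
#' @examples
#' p <- yule_params(6, 0, 1, 1)
#' integrate(function(t) pairwise_density(p, t), 0, 2)$value
#' mean_pairs(p)
#' @export
pairwise_density <- function(params, t) {
  .check_params(params, need_lambda = TRUE)
  r <- params$r
  ifelse(.support(params, t),
         0.5 * params$sigma^2 * params$lambda * exp(r * params$height + r * t / 2),
         0)
}

#' Expected density of n-th nearest-neighbour distances
#'
#' Expected number of observed leaves per unit time whose \code{n}-th closest
#' observed leaf sits at time distance \code{t}:
#' \deqn{N_n(t|T) = \frac{n(n+1)}{2}\, \sigma (\lambda\sigma)^n\,
#'   g(t)^{n-1}\, \frac{e^{(\lambda-\mu)(T + t/2)}}{(1 + \lambda\sigma
#'   g(t))^{n+2}}, \qquad g(t) = \frac{e^{(\lambda-\mu)t/2}-1}{\lambda-\mu},}
#' for \eqn{0 \le t \le 2T} and 0 otherwise.  \code{n = 1} is the
#' nearest-neighbour (minimal-distance) law; ties are counted with
#' multiplicity, so each leaf on a tree with at least \code{n} other observed
#' leaves contributes exactly one value.
#'
#' @inheritParams pairwise_density
#' @param n neighbour order, integer \eqn{\ge 1}.
#' @return density (leaves per unit time), vectorized over \code{t}.
#' @export
nth_min_density <- function(params, t, n = 1) {
  .check_params(params, need_lambda = TRUE)
  if (length(n) != 1L || n < 1 || n != floor(n))
    stop("'n' must be a single integer >= 1", call. = FALSE)
  r <- params$r
  a <- params$lambda * params$sigma
  g <- .gt(params, t)
  val <- n * (n + 1) / 2 * params$sigma * a^n * g^(n - 1) *
    exp(r * params$height + r * t / 2) / (1 + a * g)^(n + 2)
  ifelse(.support(params, t), val, 0)
}

#' Expected density of cherry distances
#'
#' Expected number of cherries (pairs of observed leaves that are reciprocal
#' nearest neighbours) per unit time distance:
#' \deqn{N_\Lambda(t|T) = \frac{\lambda\sigma^2}{2}\,
#'   \frac{e^{(\lambda-\mu)(T + t/2)}}{(1 + \lambda\sigma g(t))^4}}
#' for \eqn{0 \le t \le 2T} and 0 otherwise.  Each cherry contributes two
#' leaves to the nearest-neighbour law, so \eqn{2\int N_\Lambda \le \int N_1}.
#'
#' @inheritParams pairwise_density
#' @return density (cherries per unit time), vectorized over \code{t}.
#' @export
cherry_density <- function(params, t) {
  .check_params(params, need_lambda = TRUE)
  r <- params$r
  a <- params$lambda * params$sigma
  g <- .gt(params, t)
  ifelse(.support(params, t),
         0.5 * params$lambda * params$sigma^2 *
           exp(r * params$height + r * t / 2) / (1 + a * g)^4,
         0)
}

#' Expected density of the pairwise minimum of nearest-neighbour distances
#'
#' For every unordered pair of observed leaves, consider the smaller of the
#' two members' nearest-neighbour distances; \code{min2_density} is the
#' expected number of pairs per unit time whose minimum equals \code{t}.
#' The closed form has two parts: pairs whose minimum is attained by exactly
#' one member,
#' \deqn{2\lambda^2\sigma^3\, e^{(\lambda-\mu)(T+t)}\,
#'   \frac{(e^{(\lambda-\mu)(T - t/2)}-1)/(\lambda-\mu)}
#'        {(1+\lambda\sigma g(t))^5},}
#' plus the reciprocal-nearest (cherry) pairs, for which both members attain
#' the minimum on each other and which contribute exactly
#' \code{\link{cherry_density}}.  The total integrates exactly to
#' \code{\link{mean_pairs}}.  The density has an interior maximum only for
#' \eqn{\sigma} below \code{sigma_threshold("min2", mu/lambda)} (for large
#' \eqn{T}), which makes it a sensitive indicator of incomplete sampling.
#'
#' @inheritParams pairwise_density
#' @return density (pairs per unit time), vectorized over \code{t}.
#' @export
min2_density <- function(params, t) {
  .check_params(params, need_lambda = TRUE)
  r <- params$r
  a <- params$lambda * params$sigma
  g <- .gt(params, t)
  tail_int <- .growth(r, params$height - t / 2)  # (e^{r(T-t/2)}-1)/r
  cross <- 2 * params$lambda^2 * params$sigma^3 *
    exp(r * (params$height + t)) * tail_int / (1 + a * g)^5
  ifelse(.support(params, t), cross, 0) + cherry_density(params, t)
}

.kind_names <- c("pairwise", "nth_min", "cherry", "min2")

#' Critical sampling fraction for an interior maximum
#'
#' The nearest-neighbour, cherry and min2 densities are monotone on their
#' support when sampling is dense, but develop an interior maximum when the
#' sampling fraction drops below a critical value that depends only on
#' \eqn{\mu/\lambda}:
#' \eqn{(1-\mu/\lambda)/3} for the nearest-neighbour law,
#' \eqn{(1-\mu/\lambda)/4} for cherries and \eqn{(1-\mu/\lambda)/5} for the
#' min2 statistic.  Observing such a maximum therefore bounds \eqn{\sigma}
#' above by 1/3, 1/4 or 1/5 respectively (since \eqn{\mu \ge 0}).
#'
#' @param kind one of \code{"nth_min"} (order 1), \code{"cherry"},
#'   \code{"min2"}.  The pairwise density is monotone for all \eqn{\sigma}
#'   and is not accepted.
#' @param mu_over_lambda the ratio \eqn{\mu/\lambda} in \eqn{[0, 1)}.
#' @return the critical sampling fraction.
#' @examples
#' sigma_threshold("nth_min")          # 1/3
#' sigma_threshold("cherry", 0.5)      # 1/8
#' @export
sigma_threshold <- function(kind = c("nth_min", "cherry", "min2"),
                            mu_over_lambda = 0) {
  kind <- match.arg(kind)
  stopifnot(mu_over_lambda >= 0, mu_over_lambda < 1)
  k <- switch(kind, nth_min = 3, cherry = 4, min2 = 5)
  (1 - mu_over_lambda) / k
}

#' Location of the interior maximum of a distance density
#'
#' Position of the interior maximum of the nearest-neighbour or cherry
#' density, in closed form:
#' \deqn{t^{max}_1 = \frac{2}{\lambda-\mu}
#'   \ln\frac{\lambda(1-\sigma)-\mu}{2\lambda\sigma}, \qquad
#'   t^{max}_\Lambda = \frac{2}{\lambda-\mu}
#'   \ln\frac{\lambda(1-\sigma)-\mu}{3\lambda\sigma},}
#' or the numerically located maximum of \code{\link{min2_density}}.
#' Returns \code{NA} when no interior maximum exists in \eqn{(0, 2T)}
#' (sampling fraction at or above the critical value, or maximum outside the
#' support).
#'
#' @param kind \code{"nth_min"} (order 1), \code{"cherry"} or \code{"min2"}.
#' @param params a \code{\link{yule_params}} object.
#' @return the maximum location in time units, or \code{NA_real_}.
#' @export
density_maximum_location <- function(kind = c("nth_min", "cherry", "min2"),
                                     params) {
  kind <- match.arg(kind)
  .check_params(params, need_lambda = TRUE)
  lam <- params$lambda; mu <- params$mu; sig <- params$sigma
  if (kind == "min2") {
    f <- function(t) min2_density(params, t)
    opt <- stats::optimize(f, c(0, 2 * params$height), maximum = TRUE,
                           tol = 1e-10)
    tm <- opt$maximum
    eps <- 1e-6 * max(1, 2 * params$height)
    # reject boundary solutions (monotone density)
    if (tm < eps || tm > 2 * params$height - eps) return(NA_real_)
    if (opt$objective <= max(f(0), f(2 * params$height))) return(NA_real_)
    return(tm)
  }
  denom <- switch(kind, nth_min = 2, cherry = 3) * lam * sig
  num <- lam * (1 - sig) - mu
  if (sig <= 0 || num <= 0) return(NA_real_)
  ratio <- num / denom
  if (ratio < 1) return(NA_real_)  # maximum would sit at negative t
  if (params$r == 0) return(NA_real_)
  tm <- 2 / params$r * log(ratio)
  if (tm < 0 || tm > 2 * params$height) return(NA_real_)
  tm
}

.divisors <- function(n) {
  if (n > 1e6) stop("'n' larger than 1e6 not supported", call. = FALSE)
  small <- Filter(function(d) n %% d == 0, seq_len(floor(sqrt(n))))
  sort(unique(c(small, n / small)))
}

#' Distribution of the pair count in a narrow distance bin
#'
#' For a narrow bin \eqn{[t, t+dt)} of pair distances, the number of observed
#' pairs on a single random tree is highly dispersed: with probability close
#' to one the bin is empty, and conditional on a branching event at depth
#' \eqn{t/2} the count is a product of two independent leaf counts.  The
#' probability of observing exactly \code{n} pairs in the bin is
#' \deqn{\Pr(0) = 1 - \lambda e^{(\lambda-\mu)(T-t/2)}\frac{dt}{2}
#'   [1 - P(0|t/2)]^2,\qquad
#'   \Pr(n) = \lambda e^{(\lambda-\mu)(T-t/2)}\frac{dt}{2}
#'   \sum_{d | n} P(d|t/2)\,P(n/d|t/2)}
#' where the sum runs over all divisors of \code{n} (divisor structure:
#' \eqn{n} must factor as a product of the two subtree leaf counts).
#'
#' @inheritParams pairwise_density
#' @param t bin left edge (single value).
#' @param dt bin width, \eqn{> 0}; should satisfy
#'   \code{pairwise_density(params, t) * dt << 1} (warns above 0.1).
#' @param n vector of non-negative pair counts.
#' @return \code{Pr(n pairs in [t, t+dt))}, vectorized over \code{n}.
#' @export
prob_pair_count_in_bin <- function(params, t, dt, n) {
  .check_params(params, need_lambda = TRUE)
  if (length(t) != 1L || length(dt) != 1L) stop("'t' and 'dt' must be scalars")
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (any(n < 0) || any(n != floor(n))) stop("'n' must be non-negative integers")
  if (pairwise_density(params, t) * dt > 0.1)
    warning("bin too wide: pairwise_density * dt > 0.1; ",
            "the narrow-bin law is inaccurate")
  sub <- .at_height(params, t / 2)
  branch <- params$lambda * exp(params$r * (params$height - t / 2)) * dt / 2
  surv <- 1 - leaf_count_pmf(sub, 0)
  vapply(n, function(ni) {
    if (ni == 0) return(1 - branch * surv^2)
    d <- .divisors(ni)
    branch * sum(leaf_count_pmf(sub, d) * leaf_count_pmf(sub, ni / d))
  }, numeric(1))
}

#' Conditional pair density given a non-empty bin
#'
#' Expected pair density in a narrow bin conditioned on the bin being
#' non-empty: \eqn{\tilde N(t|T) = N(t|T) / [1 - \Pr(0)]}, where
#' \eqn{\Pr(0)} is the empty-bin probability of
#' \code{\link{prob_pair_count_in_bin}}.  For a single tree's sparse
#' histogram, \eqn{\tilde N} --- not \eqn{N} --- is the expected height of
#' the non-empty bins, and algebraically
#' \eqn{\tilde N = (1 + \lambda\sigma g(t))^2 / dt}.
#'
#' @inheritParams prob_pair_count_in_bin
#' @return conditional density (pairs per unit time) at \code{t}.
#' @export
conditional_pair_density <- function(params, t, dt) {
  .check_params(params, need_lambda = TRUE)
  vapply(t, function(ti) {
    pr0 <- prob_pair_count_in_bin(params, ti, dt, 0L)
    nz <- 1 - pr0
    if (nz <= 0) stop("degenerate bin: empty-bin probability is 1")
    pairwise_density(params, ti) / nz
  }, numeric(1))
}
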