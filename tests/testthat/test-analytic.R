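# Closed-form laws checked against literal transcriptions of the published
# algebraic forms (helper-oracles.R), against quadrature, and against each
# other through the exact integral/moment identities that pin them down.

test_that("leaf-count law matches the raw published forms and normalizes", {
  set.seed(101)
  for (p in random_params(20)) {
    lam <- p$lambda; mu <- p$mu; sig <- p$sigma; TT <- p$height
    m <- 0:30
    # incomplete-sampling forms
    expect_equal(leaf_count_pmf(p, 0), raw_p0_sampled(lam, mu, sig, TT),
                 tolerance = 1e-10)
    expect_equal(leaf_count_pmf(p, m[-1]),
                 raw_pm_sampled(lam, mu, sig, TT, m[-1]),
                 tolerance = 1e-10)
    # sigma = 1 reduction to the complete-sampling law
    p1 <- yule_params(lam, mu, 1, TT)
    expect_equal(leaf_count_pmf(p1, 0), raw_p0_complete(lam, mu, TT),
                 tolerance = 1e-12)
    expect_equal(leaf_count_pmf(p1, m[-1]),
                 raw_pm_complete(lam, mu, TT, m[-1]),
                 tolerance = 1e-12)
    # normalization with geometric tail bound
    mm <- 0:4000
    expect_equal(sum(leaf_count_pmf(p, mm)), 1, tolerance = 1e-10)
  }
})

test_that("degenerate corners of the leaf-count law are exact", {
  # no extinction, full sampling: survival is certain
  expect_equal(leaf_count_pmf(yule_params(3, 0, 1, 2.7), 0), 0)
  # zero height: the single root leaf is observed with probability sigma
  p0 <- yule_params(1, 0, 0.5, 0)
  expect_equal(leaf_count_pmf(p0, 0:1), c(0.5, 0.5))
  # printed example value
  expect_equal(leaf_count_pmf(yule_params(2, 1, 1, 1), 0), 0.38730,
               tolerance = 1e-4)
})

test_that("tail probabilities equal complemented cumulative sums", {
  set.seed(102)
  for (p in random_params(10)) {
    for (k in c(0L, 1L, 3L, 10L)) {
      expect_equal(prob_more_than(p, k),
                   1 - sum(leaf_count_pmf(p, 0:k)),
                   tolerance = 1e-10)
    }
    expect_lt(prob_more_than(p, 5000L), 1e-8)
  }
  expect_equal(prob_more_than(yule_params(2, 1, 1, 1), 0), 0.61270,
               tolerance = 1e-4)
  # brute-force example: pure Yule geometric law P(m) = e^-T (1-e^-T)^(m-1)
  p <- yule_params(1, 0, 1, 1)
  expect_equal(prob_more_than(p, 2),
               1 - sum(exp(-1) * (1 - exp(-1))^(0:1)),
               tolerance = 1e-12)
})

test_that("moments equal truncated pmf sums", {
  set.seed(103)
  for (p in random_params(10)) {
    m <- 0:6000
    pmf <- leaf_count_pmf(p, m)
    expect_equal(mean_leaves(p), sum(m * pmf), tolerance = 1e-8)
    expect_equal(mean_pairs(p), sum(m * (m - 1) / 2 * pmf), tolerance = 1e-8)
  }
  expect_equal(mean_leaves(yule_params(2, 0.3, 0.7, 0)), 0.7)
  expect_equal(mean_leaves(yule_params(1, 0, 1, log(2))), 2)
  expect_equal(mean_leaves(yule_params(6, 3, 0.1, 1)), 0.1 * exp(3))
})

test_that("pairwise density integrates to the expected pair count", {
  set.seed(104)
  for (p in random_params(20)) {
    expect_equal(
      integrate(function(t) pairwise_density(p, t), 0, 2 * p$height,
                rel.tol = 1e-10)$value,
      mean_pairs(p), tolerance = 1e-8)
  }
  # boundary value and support cutoff
  p6 <- yule_params(6, 0, 1, 1)
  expect_equal(pairwise_density(p6, 0), 3 * exp(6))
  expect_equal(pairwise_density(p6, 2 + 1e-12), 0)
  expect_equal(pairwise_density(p6, -1e-12), 0)
  # sigma^2 scaling
  p6s <- yule_params(6, 0, 0.1, 1)
  expect_equal(pairwise_density(p6s, 0.7), 0.01 * pairwise_density(p6, 0.7))
})

test_that("branch-length formulas match their integral definitions", {
  expect_equal(total_branch_length(yule_params(2, 2, 1, 3)), 3)
  expect_equal(total_branch_length(yule_params(1, 0, 1, 1)), exp(1) - 1)
  expect_equal(total_branch_length(yule_params(2, 1, 1, 2)), exp(2) - 1)
  set.seed(105)
  for (p in random_params(10)) {
    # reconstructed branch length = integral of the ancestral-lineage count
    expect_equal(
      reconstructed_branch_length(p),
      integrate(function(t) mean_ancestral_lineages(p, t), 0, p$height,
                rel.tol = 1e-12)$value,
      tolerance = 1e-8)
  }
  # limits: exhaustive sampling/no extinction recovers the full tree length;
  # no sampling leaves nothing to reconstruct
  p_lim <- yule_params(2, 1e-9, 1 - 1e-9, 1)
  expect_equal(reconstructed_branch_length(p_lim),
               total_branch_length(p_lim), tolerance = 1e-6)
  expect_equal(reconstructed_branch_length(yule_params(2, 1, 1e-12, 1)), 0,
               tolerance = 1e-10)
})

test_that("ancestral-lineage counts interpolate between root and leaves", {
  p <- yule_params(2, 1, 0.5, 1)
  expect_equal(mean_ancestral_lineages(yule_params(2, 0, 1, 1), 0), 1)
  expect_equal(mean_ancestral_lineages(p, p$height), mean_leaves(p))
  # explicit value at an interior time
  sub <- yule_params(2, 1, 0.5, 0.5)
  expect_equal(mean_ancestral_lineages(p, 0.5),
               exp(0.5) * (1 - leaf_count_pmf(sub, 0)))
  expect_error(mean_ancestral_lineages(p, 1.5), "height")
})

test_that("n-th nearest densities equal the printed closed forms", {
  set.seed(106)
  tt <- seq(0.01, 1.9, length.out = 23)
  for (p in random_params(12)) {
    lam <- p$lambda; mu <- p$mu; sig <- p$sigma; TT <- p$height
    if (abs(p$r) * TT < 1e-3) next  # raw forms are 0/0 fragile there
    ts <- tt[tt <= 2 * TT]
    expect_equal(nth_min_density(p, ts, 1), raw_N1(lam, mu, sig, TT, ts),
                 tolerance = 1e-9)
    expect_equal(nth_min_density(p, ts, 2), raw_N2(lam, mu, sig, TT, ts),
                 tolerance = 1e-9)
    for (n in c(1L, 2L, 3L, 5L)) {
      expect_equal(nth_min_density(p, ts, n),
                   raw_Nn(lam, mu, sig, TT, ts, n), tolerance = 1e-9)
    }
  }
  expect_error(nth_min_density(yule_params(1, 0, 1, 1), 0.5, 0), "n")
})

test_that("nearest-neighbour density integrates to the leaf-with-neighbour count", {
  set.seed(107)
  for (p in random_params(8)) {
    m <- 1:6000
    # every leaf on a tree with >= 2 observed leaves has exactly one nearest
    # neighbour: the integral counts observed leaves minus singletons
    expect_equal(
      integrate(function(t) nth_min_density(p, t, 1), 0, 2 * p$height,
                rel.tol = 1e-10)$value,
      sum(m[-1] * leaf_count_pmf(p, m[-1])),
      tolerance = 1e-7)
  }
})

test_that("cherry density matches the printed form and the pairing bound", {
  set.seed(108)
  tt <- seq(0.01, 1.9, length.out = 17)
  for (p in random_params(12)) {
    if (abs(p$r) * p$height < 1e-3) next
    ts <- tt[tt <= 2 * p$height]
    expect_equal(cherry_density(p, ts),
                 raw_cherry(p$lambda, p$mu, p$sigma, p$height, ts),
                 tolerance = 1e-9)
    # each cherry pairs two mutually-nearest leaves
    int_cherry <- integrate(function(t) cherry_density(p, t), 0,
                            2 * p$height, rel.tol = 1e-9)$value
    int_n1 <- integrate(function(t) nth_min_density(p, t, 1), 0,
                        2 * p$height, rel.tol = 1e-9)$value
    expect_lte(2 * int_cherry, int_n1 * (1 + 1e-9))
  }
  expect_equal(cherry_density(yule_params(2, 0, 1, 1), -0.1), 0)
})

test_that("min2 density integrates exactly to the expected pair count", {
  set.seed(109)
  for (p in random_params(12)) {
    expect_equal(
      integrate(function(t) min2_density(p, t), 0, 2 * p$height,
                rel.tol = 1e-10)$value,
      mean_pairs(p), tolerance = 1e-7)
  }
  expect_equal(min2_density(yule_params(5, 0, 0.1, 1), 2 + 1e-9), 0)
})

test_that("critical sampling fractions are 1/3, 1/4, 1/5 scaled by 1-mu/lambda", {
  expect_equal(sigma_threshold("nth_min", 0), 1 / 3)
  expect_equal(sigma_threshold("cherry", 0), 1 / 4)
  expect_equal(sigma_threshold("min2", 0), 1 / 5)
  expect_equal(sigma_threshold("nth_min", 0.5), 1 / 6)
  expect_error(sigma_threshold("pairwise"), "arg")
})

test_that("maximum locations match numeric maximization of the densities", {
  p <- yule_params(6, 0, 0.1, 1)
  tm <- density_maximum_location("nth_min", p)
  expect_equal(tm, log(4.5) / 3, tolerance = 1e-12)
  opt <- optimize(function(t) nth_min_density(p, t, 1), c(0, 2),
                  maximum = TRUE, tol = 1e-10)
  expect_equal(tm, opt$maximum, tolerance = 1e-6)

  tmc <- density_maximum_location("cherry", p)
  optc <- optimize(function(t) cherry_density(p, t), c(0, 2),
                   maximum = TRUE, tol = 1e-10)
  expect_equal(tmc, optc$maximum, tolerance = 1e-6)

  # at the critical sigma the maximum sits exactly at the origin
  pc <- yule_params(6, 0, 1 / 3, 4)
  expect_equal(density_maximum_location("nth_min", pc), 0)
  # above the threshold the density is monotone: no interior maximum
  expect_true(is.na(density_maximum_location("nth_min",
                                             yule_params(6, 0, 0.5, 1))))
  expect_true(is.na(density_maximum_location("cherry",
                                             yule_params(6, 0, 0.5, 1))))
  # min2: interior maximum below 1/5, monotone above (mu = 0, generous T)
  expect_false(is.na(density_maximum_location("min2",
                                              yule_params(5, 0, 0.15, 4))))
  expect_true(is.na(density_maximum_location("min2",
                                             yule_params(5, 0, 0.3, 4))))
})

test_that("densities are monotone above threshold, unimodal below", {
  tt <- seq(1e-4, 2 - 1e-4, length.out = 400)
  sign_changes <- function(y) {
    d <- sign(diff(y))
    d <- d[d != 0]
    sum(diff(d) != 0)
  }
  for (kind in c("nth_min", "cherry", "min2")) {
    f <- switch(kind,
                nth_min = function(p, t) nth_min_density(p, t, 1),
                cherry = cherry_density,
                min2 = min2_density)
    thr <- sigma_threshold(kind, 0)
    below <- yule_params(6, 0, thr * 0.5, 1)
    above <- yule_params(6, 0, min(1, thr * 2.5), 1)
    expect_equal(sign_changes(f(below, tt)), 1)  # one interior maximum
    expect_equal(sign_changes(f(above, tt)), 0)  # monotone
  }
})

test_that("every operation is continuous across the critical case", {
  TT <- 1.2
  for (d in c(1e-10, -1e-10)) {
    pa <- yule_params(2, 2 - 1e-6, 0.6, TT)   # analytic side
    pc <- yule_params(2, 2 - d, 0.6, TT)      # essentially critical
    for (f in list(function(p) leaf_count_pmf(p, 0:5),
                   function(p) mean_pairs(p),
                   function(p) total_branch_length(p),
                   function(p) reconstructed_branch_length(p),
                   function(p) pairwise_density(p, c(0.3, 1.7)),
                   function(p) nth_min_density(p, c(0.3, 1.7), 2),
                   function(p) cherry_density(p, c(0.3, 1.7)),
                   function(p) min2_density(p, c(0.3, 1.7)))) {
      expect_equal(f(pc), f(pa), tolerance = 1e-4)
    }
  }
})

test_that("narrow-bin occupancy probabilities form a distribution", {
  p <- yule_params(11, 5, 0.01, 1)
  t0 <- 1.5; dt <- 1e-5
  pr <- prob_pair_count_in_bin(p, t0, dt, 0:300)
  expect_true(all(pr >= 0))
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  # n = 1: only divisor is 1
  sub <- yule_params(11, 5, 0.01, t0 / 2)
  branch <- 11 * exp(6 * (1 - t0 / 2)) * dt / 2
  expect_equal(prob_pair_count_in_bin(p, t0, dt, 1),
               branch * leaf_count_pmf(sub, 1)^2)
  # divisor enumeration for n = 6: {1, 2, 3, 6}
  expect_equal(yuledist:::.divisors(6), c(1, 2, 3, 6))
  expect_equal(yuledist:::.divisors(1), 1)
  expect_equal(prob_pair_count_in_bin(p, t0, dt, 6),
               branch * sum(leaf_count_pmf(sub, c(1, 2, 3, 6)) *
                              leaf_count_pmf(sub, c(6, 3, 2, 1))))
  expect_error(prob_pair_count_in_bin(p, t0, 0, 1), "dt")
  expect_warning(prob_pair_count_in_bin(yule_params(6, 0, 1, 1), 0.1, 0.1, 0),
                 "bin too wide")
})

test_that("conditional density obeys its defining identity and bounds", {
  p <- yule_params(11, 5, 0.01, 1)
  dt <- 0.005
  tt <- c(0.3, 0.9, 1.5, 1.9)
  nt <- suppressWarnings(conditional_pair_density(p, tt, dt))
  for (i in seq_along(tt)) {
    pr0 <- suppressWarnings(prob_pair_count_in_bin(p, tt[i], dt, 0))
    # N dt = (conditional N) dt (1 - Pr0), by construction
    expect_equal(pairwise_density(p, tt[i]) * dt, nt[i] * dt * (1 - pr0))
    # conditioning can only raise the density
    expect_gte(nt[i], pairwise_density(p, tt[i]))
  }
  # algebraic closed form of the conditional curve
  g <- yuledist:::.growth(6, tt / 2)
  expect_equal(nt, (1 + 0.11 * g)^2 / dt, tolerance = 1e-12)
  # regime where the empty-bin probability nearly vanishes: conditioning
  # becomes immaterial and the conditional curve approaches the plain one
  pd <- yule_params(6, 0, 1, 1)
  t0 <- 0.01
  dt0 <- 1 / pairwise_density(pd, t0)
  suppressWarnings({
    pr0 <- prob_pair_count_in_bin(pd, t0, dt0, 0)
    ratio <- conditional_pair_density(pd, t0, dt0) / pairwise_density(pd, t0)
  })
  expect_lt(pr0, 0.1)
  expect_equal(ratio, 1 / (1 - pr0), tolerance = 1e-10)
  expect_equal(ratio, 1, tolerance = 0.1)
})
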