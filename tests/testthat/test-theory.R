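test_that("rate matrix entries follow the five-case formula", {
  # hand-computed for q0 = 0.2, q1 = 0.8, m = 3
  A <- unclass(build_rate_matrix(mutation_model(c(0.2, 0.8)), 3))
  expect_equal(A,
               matrix(c(0, 0, 0,
                        0.93333, -1.33333, 0,
                        0.13333, 1.6, -2.13333),
                      3, 3, byrow = TRUE),
               tolerance = 1e-5, ignore_attr = TRUE)
  # row 0 is identically zero for any model
  set.seed(20)
  for (i in 1:5) {
    A <- build_rate_matrix(random_model(sample(1:4, 1)), sample(4:12, 1))
    expect_true(all(unclass(A)[1, ] == 0))
  }
  # pure substitution: diagonal q0(r - 8/3) - r = -8/3, column 0 = 2/3,
  # rest zero (consistent with the 1/4 fixed point: 2/3 - (8/3)/4 = 0)
  A <- unclass(build_rate_matrix(mutation_model(1), 3))
  expect_equal(diag(A)[-1], rep(-8 / 3, 2), ignore_attr = TRUE)
  expect_equal(A[-1, 1], rep(2 / 3, 2), ignore_attr = TRUE)
  expect_equal(A[2, 3], 0)
  expect_error(build_rate_matrix(mutation_model(1), 1), ">= 2")
})

test_that("lag-wise drift matches its fixed points and the rate matrix", {
  # constant-sequence profile under pure substitution: every component -2
  expect_equal(drift(mutation_model(1), rep(1, 6))[-1], rep(-2, 5))
  # the i.i.d. profile is the substitution fixed point
  expect_equal(drift(mutation_model(1), c(1, rep(0.25, 5)))[-1], rep(0, 5))
  # algebraic identity drift == A rho for m >= K
  set.seed(21)
  for (i in 1:20) {
    model <- random_model(sample(1:3, 1), k_max = sample(1:4, 1),
                          q0_range = c(0.05, 0.6))
    K <- length(model) - 1
    m <- K + sample(1:4, 1)
    rho <- c(1, runif(m - 1))
    expect_equal(drift(model, rho),
                 unname(drop(unclass(build_rate_matrix(model, m)) %*% rho)),
                 tolerance = 1e-12)
  }
})

test_that("substitution drift closed form is exact (enumeration, 4^L)", {
  # full enumeration for L = 4 here; acceptance covers L <= 6
  for (s in all_sequences(4)) {
    m <- 3  # lags 1..2, including the boundary lag L/2
    orc <- oracle_substitution_drift(s, m)
    rho <- as.numeric(circular_autocorrelation(s, m))
    expect_equal(orc[-1], (-8 / 3 * rho + 2 / 3)[-1], tolerance = 1e-12)
  }
  # structured cases
  expect_equal(oracle_substitution_drift("AAAAAA", 3)[2:3], c(-2, -2))
  expect_equal(oracle_substitution_drift("ACGTACGT", 5)[5], -2)
})

test_that("duplication drift matches enumeration with circular lag reading", {
  # constant sequence: R^r grows deterministically by ell
  for (ell in c(1, 3)) {
    orc <- oracle_duplication_drift("AAAAAAAA", ell, 4)
    expect_equal(orc, rep(ell, 4))
  }
  # period-2 sequence, ell = 2, r = 2: duplication preserves periodicity
  expect_equal(oracle_duplication_drift("ACAC", 2, 3)[3], 2)
  # random cases: delta = r rho^{r-ell} + (ell - r) rho^r, lags circular
  set.seed(22)
  for (i in 1:15) {
    L <- sample(6:14, 1)
    s <- random_seed(L)
    full <- as.numeric(circular_autocorrelation(s, L))
    rho_circ <- function(k) {
      k <- abs(k) %% L
      full[min(k, L - k) + 1]
    }
    ell <- sample(L, 1)
    m <- L %/% 2 + 1
    orc <- oracle_duplication_drift(s, ell, m)
    for (r in 0:(m - 1)) {
      expect_equal(orc[r + 1], r * rho_circ(r - ell) + (ell - r) * rho_circ(r),
                   tolerance = 1e-10)
    }
  }
})

test_that("stationary profile solves A rho = 0 with the 1/4 structure", {
  # hand-solved 2x2 system for q0 = 0.2, q1 = 0.8
  expect_equal(as.numeric(stationary_profile(mutation_model(c(0.2, 0.8)), 3)),
               c(1, 0.7, 0.5875), tolerance = 1e-9)
  # residual and off-period entries across random models
  set.seed(23)
  for (i in 1:50) {
    d <- sample(1:4, 1)
    model <- random_model(d, k_max = sample(1:4, 1),
                          q0_range = c(0.05, 0.6))
    K <- length(model) - 1
    m <- K + sample(2:6, 1)
    rho <- stationary_profile(model, m)
    A <- unclass(build_rate_matrix(model, m))
    expect_lt(max(abs(A %*% as.numeric(rho))), 1e-9)
    off <- which((attr(rho, "lags") %% d) != 0)
    if (length(off))
      expect_equal(as.numeric(rho)[off], rep(0.25, length(off)),
                   tolerance = 1e-8)
  }
  # near-pure substitution: all lags approach the i.i.d. value 1/4
  m <- 6
  rho <- stationary_profile(mutation_model(c(1 - 1e-9, 1e-9)), m)
  expect_equal(as.numeric(rho)[-1], rep(0.25, m - 1), tolerance = 1e-6)
  expect_error(stationary_profile(mutation_model(c(0, 1)), 4),
               "null_space_basis")
})

test_that("pure-duplication null space has the mirror-periodic structure", {
  # lengths {4,6}: d = 2, dimension 2
  b <- null_space_basis(mutation_model(c(0, 0, 0, 0, .5, 0, .5)), 12)
  expect_equal(attr(b, "d"), 2)
  expect_equal(ncol(b), 2)
  # single length 3: d = 3, dimension 2, span equals the analytic basis
  q3 <- mutation_model(c(0, 0, 0, 1))
  b <- null_space_basis(q3, 12)
  expect_equal(ncol(b), 2)
  V <- periodic_null_basis(3, 12)
  # every analytic basis vector lies in the numeric span (projection residual)
  P <- b %*% solve(crossprod(b), t(b))
  expect_lt(max(abs(P %*% V - V)), 1e-8)
  # coprime lengths {2,3}: d = 1, null vector proportional to all-ones
  b <- null_space_basis(mutation_model(c(0, 0, .5, .5)), 12)
  expect_equal(ncol(b), 1)
  expect_lt(max(abs(b[, 1] / b[1, 1] - 1)), 1e-8)
  expect_error(null_space_basis(mutation_model(c(0.5, 0.5)), 6),
               "stationary_profile")
})

test_that("duplication period is the gcd of the support", {
  expect_equal(duplication_period(mutation_model(c(0, 0, 0, 0, .5, 0, .5))), 2)
  expect_equal(duplication_period(mutation_model(c(0, 0, 0, 1))), 3)
  expect_equal(duplication_period(mutation_model(c(0, 0, .5, .5))), 1)
  expect_error(duplication_period(mutation_model(1)), "no duplication")
})

test_that("ODE trajectory interpolates between seed profile and limit", {
  model <- mutation_model(c(0.3, 0.7))
  rho0 <- c(1, runif(5))
  expect_equal(profile_trajectory(model, rho0, 0), rho0)
  limit <- as.numeric(stationary_profile(model, 6))
  expect_equal(profile_trajectory(model, rho0, 60), limit, tolerance = 1e-6)
})
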