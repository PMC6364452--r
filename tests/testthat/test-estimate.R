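test_that("window rule follows min(max(10d, 5r*), L/2)", {
  # r* = 10 (L = 1000): max(100, 50) = 100
  rho <- make_profile(c(1, rep(0.3, 9), 0.9, rep(0.3, 490)), L = 1000)
  expect_equal(unname(select_window(rho, d = 10)), c(100, 100))
  # capped by floor(30/2)
  rho <- make_profile(c(1, 0.2, 0.2, 0.95, rep(0.2, 11)), L = 30)
  expect_equal(unname(select_window(rho, d = 3)), c(15, 15))
  # 5 r* = 200 capped at floor(200/2)
  rho <- make_profile(c(1, rep(0.3, 38), 0.9, rep(0.3, 60)), L = 200)
  expect_equal(unname(select_window(rho, d = 4)), c(100, 100))
  # first maximizer wins on ties
  rho <- make_profile(c(1, 0.9, 0.9, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3), L = 16)
  expect_equal(unname(select_window(rho, d = 1))[1], min(max(10, 5), 8))
})

test_that("design matrix matches the closed-form entries", {
  rho <- make_profile(c(1, 0.7, 0.5875, 0.5, 0.45), L = 100)
  des <- build_design_matrix(rho, m_prime = 1, m_dprime = 1)
  expect_equal(des$C[1, 1], 2 / 3 + (1 - 8 / 3) * 0.7)  # -0.5
  expect_equal(des$C[1, 2], 1)                          # r * rho^0
  expect_equal(des$rhs[1], 0.7)
  # consistency: with q = (0.2, 0.8), C q = rhs at the stationary profile
  expect_equal(-0.5 * 0.2 + 1 * 0.8, 0.7)
  # constant sequence: C_{r0} = r - 2, C_{ri} = r, rhs_r = r
  rho1 <- make_profile(rep(1, 11), L = 60)
  des <- build_design_matrix(rho1, 4, 4)
  r <- 1:4
  expect_equal(unname(des$C[, 1]), r - 2)
  for (k in 2:5) expect_equal(unname(des$C[, k]), r)
  expect_equal(unname(des$rhs), r)
  # multiples-of-d reduction keeps rows {3,6}, columns {0,3,6}
  rho <- make_profile(c(1, runif(12, 0.2, 0.9)), L = 60)
  des <- build_design_matrix(rho, 6, 6, d = 3)
  expect_equal(des$rows, c(3L, 6L))
  expect_equal(des$cols, c(0L, 3L, 6L))
  expect_error(build_design_matrix(make_profile(c(1, .5), 8), 5, 5),
               "lag")
})

test_that("estimate_q recovers models exactly from stationary profiles", {
  set.seed(30)
  for (i in 1:20) {
    d <- sample(1:4, 1)
    k_max <- sample(2:5, 1)
    model <- random_model(d, k_max = k_max, q0_range = c(0.05, 0.5))
    K <- length(model) - 1
    m_prime <- K
    m_dprime <- K + 2 * d
    rho <- stationary_profile(model, m_prime + m_dprime + 1)
    # exact inversion: the pragmatic expected-length constraint is off, since
    # true models may gain less than one symbol per mutation on average
    fit <- estimate_q(rho, m_prime, m_dprime, d = d,
                      enforce_length_constraint = FALSE)
    expect_lt(l2_error(fit$q_hat, as.numeric(model)), 1e-6)
    expect_lt(fit$residual, 1e-10)
  }
})

test_that("estimate_q output is a probability vector honouring constraints", {
  set.seed(31)
  for (i in 1:15) {
    rho <- make_profile(c(1, runif(40, 0, 1)), L = 200)
    d <- sample(c(list(NULL), as.list(1:3)), 1)[[1]]
    fit <- estimate_q(rho, 12, 12, d = d)
    expect_true(all(fit$q_hat >= 0))
    expect_equal(sum(fit$q_hat), 1, tolerance = 1e-9)
    if (!is.null(d)) {
      i_len <- as.integer(names(fit$q_hat))
      expect_gte(sum(i_len * fit$q_hat), 1 - 1e-9)
    }
  }
})

test_that("mutation count estimate follows the length-growth formula", {
  q <- setNames(c(0, 0, 0, 0, 1), 0:4)         # all mass on length 4
  expect_equal(estimate_n(q, 100, 4), 24)
  q <- setNames(c(0.5, 0, 0, 0, 0.5), 0:4)     # mean gain 2
  expect_equal(estimate_n(q, 100, 4), 48)
  q <- setNames(c(1, 0), 0:1)                  # degenerate: no growth
  expect_warning(nh <- estimate_n(q, 100, 4), "undefined")
  expect_true(is.na(nh))
})

test_that("n_hat is bounded by the added length when the constraint is on", {
  set.seed(32)
  for (i in 1:10) {
    d <- sample(1:5, 1)
    tr <- evolve(random_seed(d), random_model(d), 150)
    fit <- suppressWarnings(smtr(tr$final, d = d, L_seed = d))
    expect_lte(fit$n_hat, length(tr$final) - d + 1e-9)
  }
})

test_that("perfect repeats give near-zero substitution, near-uniform lengths", {
  fit <- smtr(strrep("A", 60), d = 1)
  expect_lt(coef(fit)[["0"]], 0.02)
  fit <- smtr(strrep("ACGGT", 24), d = 5)
  expect_lt(coef(fit)[["0"]], 0.02)
  qc <- coef(fit, "conditional")
  sup <- qc[qc > 1e-8]
  expect_lt(max(abs(sup - 1 / length(sup))), 0.1)
})

test_that("smtr recovers simulated mutation parameters", {
  set.seed(33)
  errs <- replicate(40, {
    tr <- evolve(random_seed(3), mutation_model(c(0.2, 0, 0, 0.8)), 500)
    fit <- smtr(tr$final, d = 3, L_seed = 3)
    l2_error(coef(fit), c(0.2, 0, 0, 0.8))
  })
  expect_lt(median(errs), 0.15)
})

test_that("estimates are invariant under rotation of the input", {
  set.seed(34)
  tr <- evolve(random_seed(4), mutation_model(c(0.25, 0, 0, 0, 0.75)), 200)
  fit <- smtr(tr$final, d = 4)
  for (k in c(1, 17)) {
    fit2 <- smtr(rotate(tr$final, k), d = 4)
    expect_equal(coef(fit2), coef(fit), tolerance = 1e-9)
    expect_equal(fit2$n_hat, fit$n_hat, tolerance = 1e-6)
  }
})

test_that("low copy number triggers a structured warning and the hook", {
  expect_warning(smtr(strrep("ACG", 3), d = 3),
                 class = "smtr_low_copy_warning")
  called <- FALSE
  hook <- function(s, d, fit) { called <<- TRUE; fit }
  suppressWarnings(smtr(strrep("ACG", 3), d = 3, low_copy_estimator = hook))
  expect_true(called)
  expect_no_warning(smtr(strrep("ACG", 10), d = 3))
})

test_that("fit methods are coherent", {
  set.seed(35)
  tr <- evolve(random_seed(3), mutation_model(c(0.3, 0, 0, 0.7)), 400)
  fit <- smtr(tr$final, d = 3)
  expect_s3_class(fit, "smtr")
  expect_output(print(fit), "substitution probability")
  expect_output(print(summary(fit)), "mutation probabilities")
  # coef types
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-9)
  expect_equal(sum(coef(fit, "conditional")), 1, tolerance = 1e-8)
  expect_true(all(coef(fit, "nonzero") > 1e-8))
  # fitted + residuals reconstruct the observed profile at design lags
  obs <- as.numeric(fit$rho)[fit$design$rows + 1]
  expect_equal(unname(fitted(fit) + residuals(fit)), obs)
  # predict returns the stationary profile of the fitted model
  pr <- predict(fit, m = 10)
  A <- build_rate_matrix(mutation_model(coef(fit) / sum(coef(fit))), 10)
  expect_lt(max(abs(unclass(A) %*% as.numeric(pr))), 1e-8)
  # simulate returns sequences of plausible length
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_true(all(vapply(sims, inherits, TRUE, "circular_sequence")))
  # plot runs silently on a null device
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
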