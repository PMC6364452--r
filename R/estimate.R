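# The SMTR inverse problem: from the autocorrelation profile of a single
# observed sequence, recover the conditional mutation probabilities q-hat by
# simplex-constrained least squares and the total mutation count n-hat.

#' Window rule for the estimation problem
#'
#' Chooses the number of unknown probabilities \eqn{m'} and the number of
#' equations \eqn{m''} from the autocorrelation profile:
#' \deqn{m' = m'' = \min(\max(10 d,\, 5 r^*),\, \lfloor L/2 \rfloor),}
#' where \eqn{r^* = \arg\max_{r \ge 1} \rho^r} (smallest maximizer on ties --
#' deterministic, and favouring short periods). The max keeps the window
#' large enough to cover the duplication-length support; the min keeps every
#' needed lag available.
#'
#' @param rho an [circular_autocorrelation()] profile computed to lag
#'   \eqn{\lfloor L/2\rfloor}.
#' @param d pattern length.
#' @return Named integer vector `c(m_prime =, m_dprime =)`.
#' @export
select_window <- function(rho, d) {
  if (length(rho) < 2L)
    stop("profile must cover at least lags 0 and 1", call. = FALSE)
  d <- as.integer(d)
  r_star <- which.max(as.numeric(rho)[-1L])  # first maximizer, lag >= 1
  L <- attr(rho, "L")
  cap <- if (is.finite(L)) L %/% 2L else length(rho) - 1L
  w <- min(max(10L * d, 5L * r_star), cap)
  c(m_prime = w, m_dprime = w)
}

#' Design matrix of the inverse problem
#'
#' Rearranges the stationarity condition \eqn{A\rho_\infty = 0} into a linear
#' system in the unknown probabilities, \eqn{C' q = \tilde\rho}, with one row
#' per lag \eqn{r = 1..m''} and one column per unknown
#' \eqn{q_0, q_1, \dots, q_{m'}}:
#' \deqn{C_{r0} = \frac23 + \left(r - \frac83\right)\rho^r, \qquad
#'   C_{ri} = r\,\rho^{|i-r|} \ (i \ge 1), \qquad
#'   \tilde\rho_r = r\,\rho^r.}
#' (The lag \eqn{|i - r|} uses the symmetry of circular autocorrelation.)
#'
#' When the pattern length `d` is known, duplication lengths are multiples of
#' `d` and off-period autocorrelation values equal 1/4 in the limit: those
#' values are substituted, and only rows and columns whose indices are
#' multiples of `d` (plus the substitution column 0) are kept.
#'
#' @param rho an [circular_autocorrelation()] profile.
#' @param m_prime number of unknown duplication lengths (largest index).
#' @param m_dprime number of equations (largest lag used).
#' @param d optional pattern length.
#' @return A list with `C` (matrix), `rhs`, `rows` (lags used) and `cols`
#'   (indices of the unknowns, starting with 0).
#' @export
build_design_matrix <- function(rho, m_prime, m_dprime, d = NULL) {
  rho_v <- as.numeric(rho)
  m_prime <- as.integer(m_prime); m_dprime <- as.integer(m_dprime)
  if (m_prime < 1L || m_dprime < 1L)
    stop("'m_prime' and 'm_dprime' must be >= 1", call. = FALSE)
  if (!is.null(d)) {
    d <- as.integer(d)
    rows <- seq.int(d, m_dprime, by = d)
    cols <- c(0L, seq.int(d, m_prime, by = d))
    lag <- seq_along(rho_v) - 1L
    rho_v[lag >= 1L & lag %% d != 0L] <- 0.25  # limit value off-period
  } else {
    rows <- seq_len(m_dprime)
    cols <- 0:m_prime
  }
  if (length(cols) < 2L)
    stop("no duplication-length unknowns: m_prime (= ", m_prime,
         ") is smaller than the pattern length", call. = FALSE)
  max_lag <- max(m_dprime, abs(outer(cols[-1L], rows, "-")))
  if (max_lag > length(rho_v) - 1L)
    stop("profile covers lags 0..", length(rho_v) - 1L,
         " but the design needs lag ", max_lag, call. = FALSE)
  C <- matrix(0, length(rows), length(cols),
              dimnames = list(rows, cols))
  C[, 1L] <- 2 / 3 + (rows - 8 / 3) * rho_v[rows + 1L]
  for (k in seq_along(cols)[-1L])
    C[, k] <- rows * rho_v[abs(cols[k] - rows) + 1L]
  rhs <- rows * rho_v[rows + 1L]
  list(C = C, rhs = rhs, rows = rows, cols = cols)
}

#' Estimate conditional mutation probabilities
#'
#' Solves the simplex-constrained least-squares problem
#' \deqn{\hat q = \arg\min_q \|C' q - \tilde\rho\|_2^2 \quad \text{s.t.}\quad
#'   \sum_i q_i = 1,\ q_i \ge 0,}
#' optionally with the expected-length constraint
#' \eqn{\sum_{k} (kd)\, q_{kd} \ge 1} (each mutation adds at least one
#' symbol on average), via the dual active-set quadratic-programming method
#' of Goldfarb and Idnani. A tiny relative ridge (`ridge` times the mean
#' diagonal of \eqn{C'^T C'}) keeps the Hessian positive definite; for
#' rank-deficient designs (e.g. perfect repeats, where any duplication mix
#' fits exactly) it selects the minimum-norm solution, i.e. near-uniform
#' duplication probabilities.
#'
#' @param rho an [circular_autocorrelation()] profile.
#' @param m_prime,m_dprime window parameters, e.g. from [select_window()].
#' @param d optional pattern length (reduces the design to multiples of `d`).
#' @param enforce_length_constraint logical; default on when `d` is known.
#' @param ridge relative Tikhonov regularization, default `1e-10`.
#' @return A list with `q_hat` (full vector indexed `0..m_prime`, zeros off
#'   the support columns), `residual` (the least-squares objective
#'   \eqn{\|C'\hat q - \tilde\rho\|_2^2}) and the design.
#' @export
estimate_q <- function(rho, m_prime, m_dprime, d = NULL,
                       enforce_length_constraint = !is.null(d),
                       ridge = 1e-10) {
  des <- build_design_matrix(rho, m_prime, m_dprime, d)
  nv <- length(des$cols)
  D <- crossprod(des$C)
  D <- D + diag(ridge * max(1, mean(diag(D))), nv)
  dvec <- crossprod(des$C, des$rhs)
  Amat <- cbind(rep(1, nv), diag(nv))
  bvec <- c(1, rep(0, nv))
  if (enforce_length_constraint) {
    Amat <- cbind(Amat, c(0, des$cols[-1L]))
    bvec <- c(bvec, 1)
  }
  sol <- tryCatch(
    quadprog::solve.QP(D, dvec, Amat, bvec, meq = 1),
    error = function(e)
      stop("constrained least-squares failed (constraints: simplex",
           if (enforce_length_constraint) " + expected-length >= 1", "): ",
           conditionMessage(e), call. = FALSE))
  q <- sol$solution
  q[q < 0] <- 0
  q_full <- stats::setNames(numeric(m_prime + 1L), 0:m_prime)
  q_full[des$cols + 1L] <- q
  fitted <- drop(des$C %*% q)
  list(q_hat = q_full,
       residual = sum((fitted - des$rhs)^2),
       fitted = fitted,
       design = des)
}

#' Estimate the total mutation count
#'
#' Each mutation adds \eqn{\sum_{i \ge 1} i\, q_i} symbols on average
#' (substitutions add none), so the number of mutations behind an observed
#' sequence of length \eqn{L} grown from a seed of length \eqn{L_0} is
#' estimated as
#' \deqn{\hat n = \frac{L - L_0}{\sum_{i \ge 1} i\,\hat q_i}.}
#' For genomic repeats the seed length is taken equal to the pattern length.
#' With the expected-length constraint active the denominator is at least 1,
#' so \eqn{\hat n \le L - L_0}.
#'
#' @param q_hat estimated probability vector indexed `0..m_prime` (named by
#'   index, as returned by [estimate_q()]).
#' @param L_final observed sequence length.
#' @param L_seed assumed seed length (default: the pattern length).
#' @return The estimate \eqn{\hat n} (`NA` with a warning if the expected
#'   length per mutation is zero, i.e. all mass on substitution with the
#'   constraint disabled).
#' @export
estimate_n <- function(q_hat, L_final, L_seed) {
  i <- as.integer(names(q_hat))
  if (is.null(names(q_hat)) || anyNA(i)) i <- seq_along(q_hat) - 1L
  denom <- sum(i * q_hat)
  if (denom <= 1e-12) {
    warning("expected length gain per mutation is zero; ",
            "mutation count undefined", call. = FALSE)
    return(NA_real_)
  }
  (L_final - L_seed) / denom
}

#' Fit the SMTR estimator to a tandem repeat sequence
#'
#' The main entry point: estimates, from one observed repeat sequence, the
#' conditional probabilities of substitution and of tandem duplications of
#' each length, and the total number of mutations in the sequence's history.
#' The pipeline is: circular autocorrelation ([circular_autocorrelation()]),
#' window rule ([select_window()]), design matrix
#' ([build_design_matrix()]), simplex-constrained least squares
#' ([estimate_q()]) and mutation-count estimate ([estimate_n()]).
#'
#' Observed genomic repeats are linear; the statistic is computed on the
#' wrapped circular sequence, with an edge bias of order 1/copy-number. When
#' the pattern length `d` is known (e.g. from a repeat-finder catalog), the
#' design is reduced to multiples of `d` and the expected-length constraint
#' is enforced by default. When `d` is unknown the full design is used; a
#' pattern-length suggestion (smallest lag with \eqn{\rho > 0.8}) is reported
#' as a diagnostic only.
#'
#' The estimator relies on asymptotic approximation; for sequences with
#' copy number \eqn{L/d \le 3} a structured warning (class
#' `smtr_low_copy_warning`) is attached, and a `low_copy_estimator` hook can
#' be supplied to post-process such fits without changing the interface.
#'
#' @param s the observed sequence: a character string,
#'   [circular_sequence()], or any object with an `as.character` method
#'   yielding a DNA string.
#' @param d pattern length (repeat-unit length), or `NULL` if unknown.
#' @param L_seed assumed seed length; defaults to `d` when known.
#' @param enforce_length_constraint logical; default on when `d` is known.
#' @param m_prime,m_dprime optional window override (default:
#'   [select_window()] rule).
#' @param ridge relative regularization passed to [estimate_q()].
#' @param low_copy_estimator optional `function(s, d, fit)` applied to the
#'   fit when copy number is 3 or less.
#' @return An object of class `"smtr"`; see [coef.smtr()], [summary.smtr()],
#'   [predict.smtr()], [plot.smtr()], [simulate.smtr()].
#' @examples
#' fit <- smtr(strrep("ACG", 20), d = 3)
#' coef(fit, "nonzero")
#' fit$n_hat
#' @export
smtr <- function(s, d = NULL, L_seed = NULL,
                 enforce_length_constraint = !is.null(d),
                 m_prime = NULL, m_dprime = NULL, ridge = 1e-10,
                 low_copy_estimator = NULL) {
  cl <- match.call()
  if (!is.character(s) && !inherits(s, "circular_sequence"))
    s <- as.character(s)
  s <- circular_sequence(s)
  L <- length(s)
  rho <- circular_autocorrelation(s)
  if (length(rho) < 2L)
    stop("sequence too short for estimation (L = ", L, ")", call. = FALSE)
  r_star <- which.max(as.numeric(rho)[-1L])
  w <- select_window(rho, if (is.null(d)) 1L else d)
  if (is.null(m_prime)) m_prime <- w[["m_prime"]]
  if (is.null(m_dprime)) m_dprime <- w[["m_dprime"]]
  d_suggest <- {
    hi <- which(as.numeric(rho)[-1L] > 0.8)
    if (length(hi)) hi[1L] else NA_integer_
  }
  fit <- estimate_q(rho, m_prime, m_dprime, d = d,
                    enforce_length_constraint = enforce_length_constraint,
                    ridge = ridge)
  if (is.null(L_seed))
    L_seed <- if (!is.null(d)) d
              else if (!is.na(d_suggest)) d_suggest else r_star
  n_hat <- estimate_n(fit$q_hat, L, L_seed)
  low_copy <- !is.null(d) && (L / d) <= 3
  res <- structure(list(
    call = cl, L = L, d = d, d_suggest = d_suggest, L_seed = L_seed,
    rho = rho, r_star = r_star,
    m_prime = m_prime, m_dprime = m_dprime,
    q_hat = fit$q_hat, n_hat = n_hat,
    residual = fit$residual,
    denominator = sum(as.integer(names(fit$q_hat)) * fit$q_hat),
    length_constraint = enforce_length_constraint,
    low_copy = low_copy,
    design = fit$design, fitted_rhs = fit$fitted
  ), class = "smtr")
  if (low_copy) {
    warning(warningCondition(
      paste0("copy number ", format(L / d, digits = 3),
             " <= 3: asymptotic approximation is unreliable"),
      class = "smtr_low_copy_warning"))
    if (!is.null(low_copy_estimator))
      res <- low_copy_estimator(s, d, res)
  }
  res
}
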