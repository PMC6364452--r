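# Forward theory: drift of the autocorrelation profile, the linear ODE rate
# matrix, stationary profiles and null spaces, and exact enumeration oracles
# for the drift formulas.

# q_ell with indices beyond the model length read as zero
q_ell <- function(q, ell) ifelse(ell >= 0 & ell < length(q), q[ell + 1L], 0)

#' Rate matrix of the autocorrelation ODE
#'
#' In the large-sequence limit the normalized circular autocorrelation
#' \eqn{\rho_t} of an evolving tandem repeat follows the linear ODE
#' \eqn{d\rho_t/dt = A \rho_t}. This function builds the \eqn{m \times m}
#' matrix \eqn{A} (rows and columns indexed by lags \eqn{0..m-1}) from the
#' mutation model:
#' \deqn{A_{rj} = \cases{2q_0/3 + r q_r & r > j = 0 \cr
#'   r q_{r-j} + r q_{r+j} & r > j > 0 \cr
#'   q_0 (r - 8/3) + r q_{2r} - r & r = j > 0 \cr
#'   r q_{r+j} & j > r > 0 \cr 0 & r = 0}}
#' with \eqn{q_\ell = 0} for \eqn{\ell} beyond the model. Row 0 is zero
#' because \eqn{\rho^0 = 1} identically. The equivalence with the lag-wise
#' drift [drift()] holds for \eqn{m \ge K}.
#'
#' @param model a [mutation_model()].
#' @param m matrix dimension (number of lags), `m >= 2`.
#' @return An `m` x `m` matrix of class `rate_matrix` with `dimnames` giving
#'   the lags and attribute `model`.
#' @export
build_rate_matrix <- function(model, m) {
  model <- mutation_model(model)
  m <- as.integer(m)
  if (m < 2L) stop("'m' must be >= 2", call. = FALSE)
  q <- as.numeric(model)
  q0 <- q[1L]
  A <- matrix(0, m, m, dimnames = list(0:(m - 1L), 0:(m - 1L)))
  for (r in 1:(m - 1L)) {
    A[r + 1L, 1L] <- 2 * q0 / 3 + r * q_ell(q, r)
    for (j in seq_len(m - 1L)) {
      A[r + 1L, j + 1L] <-
        if (r > j)      r * q_ell(q, r - j) + r * q_ell(q, r + j)
        else if (r == j) q0 * (r - 8 / 3) + r * q_ell(q, 2 * r) - r
        else            r * q_ell(q, r + j)
    }
  }
  structure(A, model = model, class = c("rate_matrix", class(A)))
}

#' Drift of the autocorrelation profile
#'
#' The expected instantaneous change of the normalized autocorrelation under
#' the mutation model, evaluated lag-wise:
#' \deqn{\frac{d\rho^r}{dt} = q_0\left(-\frac83 \rho^r + \frac23\right)
#'   + r \sum_{\ell > 0} q_\ell \rho^{r-\ell} - (1 - q_0)\, r \rho^r,}
#' for \eqn{r \ge 1}; the lag-0 component is 0 (\eqn{\rho^0 = 1} always).
#' Negative lags are resolved by symmetry, \eqn{\rho^{-k} = \rho^k}.
#' For `m >= K` this equals `build_rate_matrix(model, m) %*% rho`.
#'
#' @param model a [mutation_model()].
#' @param rho an [circular_autocorrelation()] profile (or numeric vector with
#'   `rho[1] = 1`).
#' @return Numeric vector of the same length as `rho`; component `r + 1` is
#'   the drift of \eqn{\rho^r}.
#' @export
drift <- function(model, rho) {
  model <- mutation_model(model)
  q <- as.numeric(model)
  q0 <- q[1L]
  rho_v <- as.numeric(rho)
  m <- length(rho_v)
  ells <- which(q[-1L] > 0)
  if (length(ells) && max(ells) > m - 1L && m >= 2L) {
    # rho^{r-l} with r <= m-1, l <= K: |r-l| can reach K; need profile cover
    needed <- max(abs(outer(1:(m - 1L), ells, "-")))
    if (needed > m - 1L)
      stop("profile too short: drift needs rho at lag ", needed, call. = FALSE)
  }
  out <- numeric(m)
  for (r in seq_len(m - 1L)) {
    dup <- 0
    if (length(ells))
      dup <- sum(q[ells + 1L] * rho_at(rho_v, r - ells))
    out[r + 1L] <- q0 * (-8 / 3 * rho_v[r + 1L] + 2 / 3) +
      r * dup - (1 - q0) * r * rho_v[r + 1L]
  }
  out
}

#' Exact expected autocorrelation change under one substitution
#'
#' Brute-force oracle: enumerates all `L` positions times 3 replacement
#' symbols, rebuilds the mutated sequence, recomputes the unnormalized
#' autocorrelation \eqn{R^r} by direct shift-and-compare, and averages the
#' change. Independent of both the FFT autocorrelation path and the
#' closed-form drift; used to validate the substitution drift
#' \eqn{-\frac83\rho^r + \frac23} (exact for all \eqn{1 \le r \le L - 1}).
#'
#' @param s a [circular_sequence()] with `L >= 3`.
#' @param m number of lags; the oracle covers lags `1..m-1`.
#' @return Numeric vector of length `m`; component `r + 1` is the expected
#'   change of \eqn{R^r} (component 1, lag 0, is 0: substitutions do not
#'   change the length).
#' @export
oracle_substitution_drift <- function(s, m) {
  s <- circular_sequence(s)
  L <- length(s)
  if (L < 3L) stop("'s' must have length >= 3", call. = FALSE)
  m <- as.integer(m)
  codes <- unclass(s)
  lags <- seq_len(m - 1L)
  R0 <- autocorr_counts_direct(codes, lags)
  acc <- numeric(m - 1L)
  for (i in seq_len(L)) {
    for (b in setdiff(1:4, codes[i])) {
      mut <- codes
      mut[i] <- b
      acc <- acc + (autocorr_counts_direct(mut, lags) - R0)
    }
  }
  c(0, acc / (3 * L))
}

#' Exact expected autocorrelation change under one tandem duplication
#'
#' Brute-force oracle for duplications of length `ell`: enumerates all `L`
#' start positions, builds each duplicated sequence, recomputes \eqn{R^r}
#' directly, and averages the change. Validates the duplication drift
#' \eqn{\delta_\ell^r \approx r\rho^{r-\ell} + (\ell - r)\rho^r}, whose
#' remainder is \eqn{O(1/L)}.
#'
#' @param s a [circular_sequence()].
#' @param ell duplication length, `1 <= ell <= L`.
#' @param m number of lags; the oracle covers lags `0..m-1`.
#' @return Numeric vector of length `m`; component `r + 1` is the expected
#'   change of \eqn{R^r}. The lag-0 component is exactly `ell`.
#' @export
oracle_duplication_drift <- function(s, ell, m) {
  s <- circular_sequence(s)
  L <- length(s)
  ell <- as.integer(ell)
  if (ell < 1L || ell > L) stop("'ell' must be in 1..L", call. = FALSE)
  m <- as.integer(m)
  codes <- unclass(s)
  lags <- 0:(m - 1L)
  R0 <- autocorr_counts_direct(codes, lags)
  acc <- numeric(m)
  for (start in seq_len(L)) {
    idx <- ((start - 1L + 0:(ell - 1L)) %% L) + 1L
    after <- ((start + ell - 2L) %% L) + 1L
    dup <- append(codes, codes[idx], after = after)
    acc <- acc + (autocorr_counts_direct(dup, lags) - R0)
  }
  acc / L
}

#' Stationary autocorrelation profile
#'
#' When substitutions occur with positive probability (\eqn{q_0 > 0}) the
#' autocorrelation ODE has a one-dimensional stationary set: the unique
#' profile \eqn{\rho_\infty} with \eqn{\rho^0 = 1} solving
#' \eqn{A\rho_\infty = 0}. Entries at lags not divisible by the duplication
#' period \eqn{d} equal exactly 1/4 (the i.i.d. matching probability for a
#' 4-letter alphabet). Solved as a bordered linear system: \eqn{\rho^0 = 1}
#' imposed, rows \eqn{1..m-1} solved exactly -- deterministic, no eigen
#' iteration.
#'
#' For full fidelity to the infinite-lag system, `m` should exceed the
#' largest duplication length `K` in the model.
#'
#' @param model a [mutation_model()] with \eqn{q_0 > 0}.
#' @param m number of lags.
#' @return An `autocorrelation_profile` (with `L = Inf`, analytic).
#' @export
stationary_profile <- function(model, m) {
  model <- mutation_model(model)
  if (as.numeric(model)[1L] <= 0)
    stop("q0 = 0: the stationary set is multi-dimensional; ",
         "use null_space_basis()", call. = FALSE)
  A <- unclass(build_rate_matrix(model, m))
  sub <- A[-1L, -1L, drop = FALSE]
  rhs <- -A[-1L, 1L]
  x <- tryCatch(solve(sub, rhs),
                error = function(e) stop("singular stationary system at m = ",
                                         m, ": ", conditionMessage(e),
                                         call. = FALSE))
  structure(c(1, x), L = Inf, lags = 0:(m - 1L),
            class = "autocorrelation_profile")
}

#' Finite-time solution of the autocorrelation ODE
#'
#' Solves \eqn{d\rho_t/dt = A\rho_t} forward from an initial profile by
#' matrix exponential: \eqn{\rho_t = e^{At}\rho_0}. The ODE time
#' corresponding to `n` discrete mutation events is
#' \eqn{t \approx \sum_{k<n} 1/L_k} (the step size of the underlying
#' stochastic recursion), so this predicts the expected autocorrelation
#' profile of a simulated sequence after finitely many mutations, up to the
#' O(1/L) per-step remainder of the approximation.
#'
#' @param model a [mutation_model()].
#' @param rho0 initial profile (numeric, `rho0[1] = 1`); its length sets the
#'   lag window and should exceed the largest duplication length.
#' @param t ODE time (>= 0).
#' @return Numeric vector: the profile at time `t`.
#' @export
profile_trajectory <- function(model, rho0, t) {
  rho0 <- as.numeric(rho0)
  A <- unclass(build_rate_matrix(model, length(rho0)))
  unname(drop(as.matrix(Matrix::expm(A * t)) %*% rho0))
}

#' Null space of the rate matrix under pure duplication
#'
#' With \eqn{q_0 = 0} the stationary set of the autocorrelation ODE is the
#' span of \eqn{\lfloor d/2\rfloor + 1} vectors, where \eqn{d} is the gcd of
#' the duplication-length support: the space of profiles that are
#' "mirror-periodic" with period \eqn{d} (value at lag \eqn{j} depends only
#' on \eqn{\pm j \bmod d}). This function computes the null space
#' numerically by SVD, with rank threshold `1e-10` times the largest
#' singular value.
#'
#' @param model a [mutation_model()] with \eqn{q_0 = 0}.
#' @param m number of lags.
#' @return A matrix whose columns form an orthonormal basis of the null
#'   space, with attributes `d` (the gcd period) and `dim`.
#' @seealso [periodic_null_basis()] for the closed-form basis.
#' @export
null_space_basis <- function(model, m) {
  model <- mutation_model(model)
  if (as.numeric(model)[1L] > 0)
    stop("q0 > 0: the null space is one-dimensional; ",
         "use stationary_profile()", call. = FALSE)
  A <- unclass(build_rate_matrix(model, m))
  sv <- svd(A)
  keep <- sv$d < 1e-10 * max(sv$d)
  basis <- sv$v[, keep, drop = FALSE]
  structure(basis, d = duplication_period(model), dim_null = ncol(basis))
}

#' Closed-form mirror-periodic basis
#'
#' The analytic basis \eqn{v_0, \dots, v_{\lfloor d/2\rfloor}} of the pure-
#' duplication stationary set: \eqn{v_{i,j} = 1} when
#' \eqn{j \equiv \pm i \pmod d} and 0 otherwise, for lags \eqn{j = 0..m-1}.
#'
#' @param d period.
#' @param m number of lags.
#' @return An `m` x `(floor(d/2) + 1)` 0/1 matrix, columns \eqn{v_i}.
#' @export
periodic_null_basis <- function(d, m) {
  d <- as.integer(d); m <- as.integer(m)
  j <- 0:(m - 1L)
  vapply(0:(d %/% 2L), function(i)
    as.numeric((j %% d) == (i %% d) | (j %% d) == ((-i) %% d)),
    numeric(m))
}
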