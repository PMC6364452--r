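# Error metrics and the parameter-recovery simulation harness.

#' L2 error between probability vectors
#'
#' Euclidean norm of the difference; the shorter vector is zero-padded, so
#' estimates and truths indexed over different maximal duplication lengths
#' are comparable.
#'
#' @param q_hat,q numeric vectors (element 1 = substitution probability).
#' @return \eqn{\|\hat q - q\|_2}.
#' @export
l2_error <- function(q_hat, q) {
  n <- max(length(q_hat), length(q))
  a <- c(as.numeric(q_hat), numeric(n - length(q_hat)))
  b <- c(as.numeric(q), numeric(n - length(q)))
  sqrt(sum((a - b)^2))
}

#' Normalized root-mean-square error of a mutation-count estimate
#'
#' \deqn{\mathrm{NRMSE}(n) = \frac1n \sqrt{\frac1N \sum_{i=1}^N
#'   (\hat n_i - n)^2}.}
#'
#' @param n true mutation count (> 0).
#' @param estimates vector of estimates \eqn{\hat n_i}.
#' @return The NRMSE (dimensionless).
#' @export
nrmse <- function(n, estimates) {
  if (n <= 0) stop("'n' must be positive", call. = FALSE)
  sqrt(mean((as.numeric(estimates) - n)^2)) / n
}

#' Conditional duplication-length probabilities
#'
#' Converts a full mutation-probability vector into probabilities of each
#' duplication length given that the mutation is a duplication:
#' \eqn{q'_i = q_i / (1 - q_0)}.
#'
#' @param q probability vector (element 1 = \eqn{q_0}); requires
#'   \eqn{q_0 < 1}.
#' @return Vector \eqn{(q'_1, q'_2, \dots)}, summing to 1.
#' @export
conditional_duplication_probs <- function(q) {
  q <- as.numeric(q)
  if (q[1L] >= 1)
    stop("q0 = 1: no duplications to condition on", call. = FALSE)
  q[-1L] / (1 - q[1L])
}

#' Probability that a random subset matches a fixed one
#'
#' The chance that `k` items drawn uniformly without replacement from `n`
#' coincide exactly with a given `k`-subset: \eqn{1/\binom{n}{k}}. Used to
#' judge agreement between two top-`k` rankings, e.g. the five chromosomes
#' with the highest repeat substitution rates versus the five with the
#' highest human--chimpanzee divergence among the 24 human chromosomes.
#'
#' @param n number of items (e.g. 24 chromosomes).
#' @param k subset size (e.g. top 5).
#' @return The probability \eqn{1/\binom{n}{k}}.
#' @examples
#' subset_match_pvalue(24, 5)  # ~ 2e-5
#' @export
subset_match_pvalue <- function(n, k) 1 / choose(n, k)

#' Parameter-recovery simulation experiment
#'
#' For each mutation count in `n_grid` and each of `N` replicates: draw a
#' pattern length `d`, a random seed of length `d` and a random mutation
#' model ([random_model()]); evolve `n_s` independent sequences; fit
#' [smtr()] (with `d` and the true seed length known, as in a controlled
#' recovery study) to each. Per replicate the single-sample estimate is the
#' first sequence's fit, and the multi-sample estimate averages the `n_s`
#' individual estimates (estimates are averaged, not autocorrelations).
#'
#' @param n_grid mutation counts to study.
#' @param N replicates per grid point.
#' @param n_s sequences per replicate.
#' @param d_range integer range the pattern length is drawn from.
#' @param k_max,q0_range passed to [random_model()].
#' @param rng_seed master seed; the whole table is reproducible given it.
#' @return A data frame with one row per grid point: mean L2 error of
#'   \eqn{\hat q} (`l2_single`, `l2_multi`), NRMSE of \eqn{\hat n}
#'   (`nrmse_single`, `nrmse_multi`), and the design sizes.
#' @export
run_recovery_experiment <- function(n_grid = c(10L, seq(50L, 500L, 50L)),
                                    N = 100L, n_s = 5L, d_range = 1:10,
                                    k_max = 5L, q0_range = c(0, 0.5),
                                    rng_seed = NULL) {
  n_grid <- as.integer(n_grid)
  if (!length(n_grid)) stop("'n_grid' is empty", call. = FALSE)
  with_rng_seed(rng_seed, {
    rows <- lapply(n_grid, function(n) {
      l2_s <- l2_m <- nh_s <- nh_m <- numeric(N)
      for (i in seq_len(N)) {
        d <- if (length(d_range) == 1L) d_range else sample(d_range, 1L)
        model <- random_model(d, k_max = k_max, q0_range = q0_range)
        seed <- random_seed(d)
        q_true <- as.numeric(model)
        q_hats <- vector("list", n_s)
        n_hats <- numeric(n_s)
        for (k in seq_len(n_s)) {
          s_obs <- evolve(seed, model, n)$final
          fit <- suppressWarnings(smtr(s_obs, d = d, L_seed = d))
          q_hats[[k]] <- fit$q_hat
          n_hats[k] <- fit$n_hat
        }
        pad <- max(vapply(q_hats, length, 1L))
        q_mat <- vapply(q_hats, function(q) c(q, numeric(pad - length(q))),
                        numeric(pad))
        l2_s[i] <- l2_error(q_hats[[1L]], q_true)
        l2_m[i] <- l2_error(rowMeans(q_mat), q_true)
        nh_s[i] <- n_hats[1L]
        nh_m[i] <- mean(n_hats)
      }
      data.frame(n = n, N = N, n_s = n_s,
                 l2_single = mean(l2_s), l2_multi = mean(l2_m),
                 nrmse_single = nrmse(n, nh_s), nrmse_multi = nrmse(n, nh_m))
    })
    do.call(rbind, rows)
  })
}
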