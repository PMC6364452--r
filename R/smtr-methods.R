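# Methods for fitted SMTR objects.

#' @export
print.smtr <- function(x, ...) {
  cat("SMTR fit: sequence length ", x$L,
      if (!is.null(x$d)) paste0(", pattern length ", x$d), "\n", sep = "")
  cat("  substitution probability q0 =", format(x$q_hat[[1L]], digits = 4),
      "\n")
  cat("  estimated mutation count n  =", format(x$n_hat, digits = 5), "\n")
  invisible(x)
}

#' Extract estimated mutation probabilities
#'
#' @param object a fitted [smtr()] object.
#' @param type `"all"`: the full vector \eqn{\hat q_0..\hat q_{m'}};
#'   `"nonzero"`: entries above `1e-8`; `"conditional"`: duplication-length
#'   probabilities conditioned on the mutation being a duplication,
#'   \eqn{q'_i = \hat q_i / (1 - \hat q_0)}.
#' @param ... unused.
#' @return Named numeric vector (names are duplication lengths; `"0"` is
#'   substitution).
#' @export
coef.smtr <- function(object, type = c("all", "nonzero", "conditional"),
                      ...) {
  type <- match.arg(type)
  q <- object$q_hat
  switch(type,
         all = q,
         nonzero = q[q > 1e-8],
         conditional = conditional_duplication_probs(q))
}

#' @export
fitted.smtr <- function(object, ...) {
  stats::setNames(object$fitted_rhs / object$design$rows,
                  object$design$rows)
}

#' @export
residuals.smtr <- function(object, ...) {
  rows <- object$design$rows
  stats::setNames(as.numeric(object$rho)[rows + 1L] - fitted(object), rows)
}

#' Summary of an SMTR fit
#'
#' @param object a fitted [smtr()] object.
#' @param ... unused.
#' @return An object of class `summary.smtr`.
#' @export
summary.smtr <- function(object, ...) {
  structure(list(
    call = object$call, L = object$L, d = object$d,
    d_suggest = object$d_suggest,
    copy_number = if (!is.null(object$d)) object$L / object$d else NA,
    window = c(m_prime = object$m_prime, m_dprime = object$m_dprime),
    r_star = object$r_star,
    q0 = object$q_hat[[1L]],
    q_nonzero = object$q_hat[object$q_hat > 1e-8],
    q_conditional = if (object$q_hat[[1L]] < 1)
      conditional_duplication_probs(object$q_hat),
    n_hat = object$n_hat,
    expected_gain = object$denominator,
    residual = object$residual,
    low_copy = object$low_copy
  ), class = "summary.smtr")
}

#' @export
print.summary.smtr <- function(x, ...) {
  cat("SMTR estimate of tandem-repeat mutation history\n\n")
  cat("Sequence length:", x$L)
  if (!is.null(x$d))
    cat("   pattern length:", x$d,
        "  copy number:", format(x$copy_number, digits = 4))
  else if (!is.na(x$d_suggest))
    cat("   suggested pattern length (diagnostic):", x$d_suggest)
  cat("\n")
  cat("Window: m' = m'' =", x$window[["m_prime"]],
      "  (peak autocorrelation lag r* =", paste0(x$r_star, ")"), "\n\n")
  cat("Estimated conditional mutation probabilities (q > 1e-8):\n")
  print(round(x$q_nonzero, 4))
  cat("\nEstimated total mutations n =", format(x$n_hat, digits = 5),
      "  (mean length gain/mutation =",
      paste0(format(x$expected_gain, digits = 4), ")"), "\n")
  cat("Least-squares residual:", format(x$residual, digits = 4), "\n")
  if (x$low_copy)
    cat("NOTE: copy number <= 3; asymptotic estimate unreliable\n")
  invisible(x)
}

#' Predicted asymptotic autocorrelation of a fitted model
#'
#' Computes the stationary autocorrelation profile implied by the estimated
#' mutation probabilities -- the profile the observed sequence would approach
#' after many further mutations.
#'
#' @param object a fitted [smtr()] object with \eqn{\hat q_0 > 0}.
#' @param m number of lags (default: the fitted window).
#' @param ... unused.
#' @return An `autocorrelation_profile`.
#' @export
predict.smtr <- function(object, m = NULL, ...) {
  q0 <- object$q_hat[[1L]]
  if (q0 <= 0)
    stop("fitted q0 = 0: the asymptotic profile is not unique ",
         "(pure-duplication regime); see null_space_basis()", call. = FALSE)
  if (is.null(m)) m <- max(object$m_dprime + 1L, length(object$q_hat))
  stationary_profile(mutation_model(object$q_hat / sum(object$q_hat)), m)
}

#' Plot an SMTR fit
#'
#' Observed circular autocorrelation profile with the fitted values at the
#' lags used in the estimation (the design rows), and the i.i.d. reference
#' level 1/4.
#'
#' @param x a fitted [smtr()] object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.smtr <- function(x, ...) {
  lags <- attr(x$rho, "lags")
  graphics::plot(lags, as.numeric(x$rho), type = "l", col = "grey40",
                 xlab = "lag r", ylab = expression(rho^r),
                 ylim = c(0, 1), ...)
  graphics::abline(h = 0.25, lty = 3)
  graphics::points(x$design$rows, fitted(x), pch = 19, col = "firebrick")
  graphics::legend("topright", bty = "n",
                   legend = c("observed", "fitted (design lags)",
                              "i.i.d. level 1/4"),
                   col = c("grey40", "firebrick", "black"),
                   lty = c(1, NA, 3), pch = c(NA, 19, NA))
  invisible(x)
}

#' Simulate sequences from a fitted SMTR model
#'
#' Draws new repeat sequences by running the generative model with the
#' estimated probabilities \eqn{\hat q} for the estimated number of
#' mutations, starting from fresh random seeds of the pattern length.
#'
#' @param object a fitted [smtr()] object.
#' @param nsim number of sequences.
#' @param seed optional RNG seed (as in [stats::simulate()]).
#' @param n number of mutation events per sequence; default
#'   `round(object$n_hat)`.
#' @param ... unused.
#' @return A list of `nsim` [circular_sequence()] objects.
#' @export
simulate.smtr <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (is.null(n)) n <- round(object$n_hat)
  if (is.na(n)) stop("mutation count estimate is NA; supply 'n'",
                     call. = FALSE)
  d0 <- if (!is.null(object$d)) object$d
        else if (!is.na(object$d_suggest)) object$d_suggest else 1L
  model <- mutation_model(object$q_hat / sum(object$q_hat))
  with_rng_seed(seed, lapply(seq_len(nsim), function(i)
    evolve(random_seed(d0), model, n)$final))
}
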