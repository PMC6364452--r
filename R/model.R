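# Mutation model: conditional probabilities of substitution and of tandem
# duplications of each length.

#' Mutation model for tandem repeat evolution
#'
#' A mutation model is the probability vector
#' \eqn{q = (q_0, q_1, \dots, q_K)}: given that a mutation occurs, \eqn{q_0}
#' is the probability that it is a substitution and \eqn{q_\ell}
#' (\eqn{\ell \ge 1}) the probability that it is a tandem duplication of
#' length \eqn{\ell}. These are conditional probabilities, not per-generation
#' rates; they must be nonnegative and sum to one.
#'
#' @param q numeric vector of probabilities; element 1 is \eqn{q_0}
#'   (substitution), element \eqn{\ell + 1} is \eqn{q_\ell}.
#' @return An object of class `mutation_model`: the probability vector with
#'   names `"0", "1", ...`.
#' @examples
#' mutation_model(c(0.2, 0, 0, 0.8))  # q0 = 0.2, duplications of length 3
#' @export
mutation_model <- function(q) {
  if (inherits(q, "mutation_model")) return(q)
  q <- as.numeric(q)
  if (length(q) < 1L || anyNA(q))
    stop("'q' must be a numeric probability vector", call. = FALSE)
  if (any(q < 0))
    stop("mutation probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(q) - 1) > 1e-12)
    stop("mutation probabilities must sum to 1 (got ", format(sum(q)), ")",
         call. = FALSE)
  structure(q, names = as.character(seq_along(q) - 1L),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("Tandem-repeat mutation model\n")
  cat("  substitution q0 =", format(x[[1L]], digits = 4), "\n")
  sup <- duplication_support(x)
  if (length(sup)) {
    cat("  duplication lengths:",
        paste0(sup, " (", format(as.numeric(x)[sup + 1L], digits = 4), ")",
               collapse = ", "), "\n")
    cat("  gcd period d =", duplication_period(x), "\n")
  } else cat("  no duplication lengths with positive probability\n")
  invisible(x)
}

#' @rdname mutation_model
#' @param model a `mutation_model`.
#' @return `duplication_support()` returns the integer lengths \eqn{\ell > 0}
#'   with \eqn{q_\ell > 0}.
#' @export
duplication_support <- function(model) {
  q <- as.numeric(mutation_model(model))
  which(q[-1L] > 0)
}

#' Period implied by a duplication model
#'
#' Under pure duplication (no substitutions) a sequence evolving with
#' duplication lengths \eqn{P = \{\ell : q_\ell > 0\}} becomes almost
#' periodic, and the emergent period is \eqn{d = \gcd P} -- not the most
#' common or the shortest duplication length. For example, duplication
#' lengths \{4, 6\} produce period 2.
#'
#' @param model a [mutation_model()].
#' @return The integer \eqn{\gcd} of the duplication-length support.
#' @examples
#' duplication_period(mutation_model(c(0, 0, 0, 0, .5, 0, .5)))  # {4,6} -> 2
#' @export
duplication_period <- function(model) {
  sup <- duplication_support(model)
  if (!length(sup))
    stop("no duplication length has positive probability", call. = FALSE)
  Reduce(gcd2, sup)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# Run expr with a locally seeded RNG stream, restoring the caller's stream.
with_rng_seed <- function(rng_seed, expr) {
  if (is.null(rng_seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(rng_seed)
  expr
}

#' Random mutation model
#'
#' Draws a mutation model of the kind observed for genomic tandem repeats:
#' duplication lengths are multiples of the pattern length `d`. The
#' substitution probability \eqn{q_0} is uniform on `q0_range` and the
#' remaining mass is spread over \eqn{\{d, 2d, \dots, k_{max} d\}} by a
#' symmetric Dirichlet(1, ..., 1) draw.
#'
#' @param d pattern length (the gcd of the duplication support is a multiple
#'   of `d` by construction).
#' @param k_max number of multiples of `d` receiving duplication mass.
#' @param q0_range interval for the uniform draw of \eqn{q_0}.
#' @param rng_seed optional integer; if given, the draw uses a local RNG
#'   stream seeded with it and leaves the global stream untouched.
#' @return A [mutation_model()] of length `k_max * d + 1`.
#' @export
random_model <- function(d, k_max = 5L, q0_range = c(0, 0.5),
                         rng_seed = NULL) {
  d <- as.integer(d); k_max <- as.integer(k_max)
  if (d < 1L) stop("'d' must be >= 1", call. = FALSE)
  if (k_max < 1L) stop("'k_max' must be >= 1 (empty duplication support)",
                       call. = FALSE)
  with_rng_seed(rng_seed, {
    q0 <- stats::runif(1, q0_range[1L], q0_range[2L])
    w <- stats::rexp(k_max)            # Dirichlet(1,...,1) via normalized exps
    w <- w / sum(w)
    q <- numeric(k_max * d + 1L)
    q[1L] <- q0
    q[seq_len(k_max) * d + 1L] <- (1 - q0) * w
    mutation_model(q / sum(q))
  })
}

#' Random seed sequence
#'
#' Draws a seed (the ancestral sequence a tandem repeat grew from) of `d`
#' i.i.d. uniform symbols.
#'
#' @param d seed length; in observed repeats the seed length is taken equal
#'   to the pattern length.
#' @inheritParams random_model
#' @return A [circular_sequence()] of length `d`.
#' @export
random_seed <- function(d, rng_seed = NULL) {
  d <- as.integer(d)
  if (d < 1L) stop("'d' must be >= 1", call. = FALSE)
  with_rng_seed(rng_seed, circular_sequence(sample.int(4L, d, replace = TRUE)))
}
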