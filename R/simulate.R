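# Generative model: evolve a seed by random substitutions and tandem
# duplications, keeping a full event trace.

#' Evolve a circular sequence by duplication and substitution
#'
#' Runs the generative tandem-repeat model for `n` mutation events. At each
#' step the event type is drawn from the mutation model `q`. A substitution
#' picks a uniform position and replaces its symbol with one of the three
#' other letters, uniformly (possibly re-hitting a previously mutated site --
#' the model is memoryless). A tandem duplication of length \eqn{\ell} picks a
#' uniform start position, copies the circular substring of length
#' \eqn{\ell} starting there, and inserts the copy immediately after the
#' template.
#'
#' @param seed the ancestral [circular_sequence()] (or coercible).
#' @param model a [mutation_model()].
#' @param n number of mutation events (>= 0).
#' @param rng_seed optional integer seed for a local RNG stream.
#' @return An object of class `evolution_trace`: a list with elements
#'   `seed`, `final` (both `circular_sequence`), `n`, and `events`, a data
#'   frame with one row per event (`type`, `pos`, `len`, `to`). For a
#'   substitution `pos` is the mutated position and `to` the new symbol code;
#'   for a duplication `pos` is the template start and `len` its length.
#' @examples
#' tr <- evolve("ACGT", mutation_model(c(0, 1)), n = 3, rng_seed = 1)
#' length(tr$final)  # 4 + 3 length-1 duplications = 7
#' @export
evolve <- function(seed, model, n, rng_seed = NULL) {
  seed <- circular_sequence(seed)
  model <- mutation_model(model)
  n <- as.integer(n)
  if (n < 0L) stop("'n' must be >= 0", call. = FALSE)
  q <- as.numeric(model)
  with_rng_seed(rng_seed, {
    types <- if (n > 0L)
      sample.int(length(q), n, replace = TRUE, prob = q) - 1L else integer(0)
    s <- unclass(seed)
    ev_type <- integer(n); ev_pos <- integer(n)
    ev_len <- integer(n); ev_to <- integer(n)
    for (i in seq_len(n)) {
      L <- length(s)
      ell <- types[i]
      if (ell == 0L) {                      # substitution
        pos <- sample.int(L, 1L)
        to <- sample.int(3L, 1L)
        to <- ((s[pos] - 1L + to) %% 4L) + 1L   # uniform over the 3 others
        s[pos] <- to
        ev_type[i] <- 0L; ev_pos[i] <- pos; ev_len[i] <- 0L; ev_to[i] <- to
      } else {                              # tandem duplication, length ell
        start <- sample.int(L, 1L)
        idx <- ((start - 1L + 0:(ell - 1L)) %% L) + 1L
        copy <- s[idx]
        after <- ((start + ell - 2L) %% L) + 1L  # template end (linear index)
        s <- append(s, copy, after = after)
        ev_type[i] <- 1L; ev_pos[i] <- start; ev_len[i] <- ell; ev_to[i] <- NA
      }
    }
    structure(list(
      seed = seed,
      final = circular_sequence(s),
      n = n,
      events = data.frame(
        type = c("substitution", "duplication")[ev_type + 1L],
        pos = ev_pos, len = ev_len, to = ev_to)
    ), class = "evolution_trace")
  })
}

#' @export
print.evolution_trace <- function(x, ...) {
  cat("Evolution trace: ", x$n, " events, seed length ", length(x$seed),
      " -> final length ", length(x$final), "\n", sep = "")
  if (x$n > 0) print(table(x$events$type))
  invisible(x)
}

#' Replay an evolution trace
#'
#' Re-applies the recorded events to the recorded seed; the result must
#' reproduce the final sequence exactly. Used to validate the bookkeeping of
#' [evolve()].
#'
#' @param trace an `evolution_trace`.
#' @return A [circular_sequence()].
#' @export
replay_trace <- function(trace) {
  stopifnot(inherits(trace, "evolution_trace"))
  s <- unclass(trace$seed)
  ev <- trace$events
  for (i in seq_len(nrow(ev))) {
    L <- length(s)
    if (ev$type[i] == "substitution") {
      s[ev$pos[i]] <- ev$to[i]
    } else {
      ell <- ev$len[i]; start <- ev$pos[i]
      idx <- ((start - 1L + 0:(ell - 1L)) %% L) + 1L
      after <- ((start + ell - 2L) %% L) + 1L
      s <- append(s, s[idx], after = after)
    }
  }
  circular_sequence(s)
}
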