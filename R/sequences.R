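# Circular DNA sequences and the circular autocorrelation statistic.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Circular DNA sequence
#'
#' Constructs a circular sequence over the alphabet \{A, C, G, T\}. A circular
#' sequence has no boundary: all index arithmetic is modulo its length. This is
#' the evolving object of the tandem-repeat mutation model; observed (linear)
#' genomic repeats are wrapped into circular form when their autocorrelation is
#' computed, which introduces an edge effect of order 1/copy-number (see the
#' package vignette).
#'
#' Input is case-insensitive. Symbols outside \{A, C, G, T\} (including N) are
#' rejected rather than silently mapped: repeats containing ambiguous bases are
#' expected to be filtered out upstream with [preprocess_repeats()].
#'
#' @param x a single character string (e.g. `"ACGT"`), a character vector of
#'   single letters, or an object already of class `circular_sequence`.
#' @return An object of class `circular_sequence`: an integer vector of symbol
#'   codes (1--4 for A, C, G, T) with attribute `alphabet`.
#' @examples
#' s <- circular_sequence("ACGTACGT")
#' length(s)
#' as.character(s)
#' @export
circular_sequence <- function(x) {
  if (inherits(x, "circular_sequence")) return(x)
  if (is.character(x)) {
    if (length(x) == 1L) x <- strsplit(x, "")[[1L]]
    codes <- match(toupper(x), DNA_ALPHABET)
  } else if (is.numeric(x)) {
    codes <- as.integer(x)
    codes[codes < 1L | codes > 4L] <- NA_integer_
  } else {
    stop("cannot interpret 'x' as a DNA sequence", call. = FALSE)
  }
  if (length(codes) < 1L)
    stop("a circular sequence must contain at least one symbol", call. = FALSE)
  if (anyNA(codes))
    stop("invalid symbol(s) in sequence: only A, C, G, T are allowed",
         call. = FALSE)
  structure(codes, alphabet = DNA_ALPHABET, class = "circular_sequence")
}

#' @export
as.character.circular_sequence <- function(x, ...) {
  paste(DNA_ALPHABET[unclass(x)], collapse = "")
}

#' @export
print.circular_sequence <- function(x, ...) {
  s <- as.character(x)
  if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
  cat("Circular DNA sequence, length ", length(x), "\n  ", s, "\n", sep = "")
  invisible(x)
}

#' Rotate a circular sequence
#'
#' Returns the same circular sequence read from a different starting point.
#' All statistics of the model (autocorrelation, and hence every estimate
#' derived from it) are invariant under rotation.
#'
#' @param s a [circular_sequence()] (or coercible).
#' @param k integer offset; the symbol at position `k + 1` becomes first.
#' @return A `circular_sequence` of the same length.
#' @export
rotate <- function(s, k = 1L) {
  s <- circular_sequence(s)
  L <- length(s)
  k <- ((as.integer(k)) %% L)
  if (k == 0L) return(s)
  circular_sequence(unclass(s)[c((k + 1L):L, 1L:k)])
}

#' Circular autocorrelation profile
#'
#' Computes the normalized circular autocorrelation
#' \deqn{\rho^r = \frac{1}{L}\sum_{i=1}^{L} \langle s_i, s_{i+r} \rangle,}
#' where indices are modulo the sequence length \eqn{L} and
#' \eqn{\langle a,b\rangle} is 1 if the symbols match and 0 otherwise.
#' \eqn{\rho^0 = 1} always, and the profile is symmetric:
#' \eqn{\rho^r = \rho^{L-r}}. The default lag range 0..\eqn{\lfloor L/2\rfloor}
#' therefore carries all the information, and each reported value is an
#' average of at least \eqn{L/2} indicator terms.
#'
#' The match counts are accumulated per letter via FFT (the circular
#' autocorrelation of each letter-indicator vector) and rounded back to exact
#' integers, so the profile is exact, not approximate.
#'
#' @param s a [circular_sequence()] or character string.
#' @param m number of lags (profile covers lags `0..m-1`). Default
#'   `floor(L/2) + 1`. Must satisfy `1 <= m <= L`.
#' @return An object of class `autocorrelation_profile`: a numeric vector of
#'   length `m` whose element `r + 1` is \eqn{\rho^r}, with attributes `L`
#'   (source length) and `lags`.
#' @examples
#' circular_autocorrelation("ACAC", m = 3)   # (1, 0, 1)
#' @export
circular_autocorrelation <- function(s, m = NULL) {
  s <- circular_sequence(s)
  L <- length(s)
  if (is.null(m)) m <- L %/% 2L + 1L
  m <- as.integer(m)
  if (m < 1L || m > L)
    stop("'m' must satisfy 1 <= m <= L (L = ", L, ")", call. = FALSE)
  R <- numeric(L)
  codes <- unclass(s)
  for (a in 1:4) {
    x <- as.numeric(codes == a)
    f <- stats::fft(x)
    R <- R + Re(stats::fft(f * Conj(f), inverse = TRUE)) / L
  }
  R <- round(R)  # exact integer match counts
  rho <- R[seq_len(m)] / L
  structure(rho, L = L, lags = 0:(m - 1L), class = "autocorrelation_profile")
}

#' @export
print.autocorrelation_profile <- function(x, ...) {
  L <- attr(x, "L")
  cat("Circular autocorrelation profile: ", length(x), " lags",
      if (is.finite(L)) paste0(" (sequence length ", L, ")"), "\n", sep = "")
  print(stats::setNames(round(as.numeric(x), 4),
                        paste0("r", attr(x, "lags"))), ...)
  invisible(x)
}

# rho at arbitrary (possibly negative) lag, resolved by circular symmetry
# rho^{-k} = rho^{k}; errors if the lag is not covered by the profile.
rho_at <- function(rho, lag) {
  lag <- abs(as.integer(lag))
  if (any(lag > length(rho) - 1L))
    stop("autocorrelation profile does not cover lag ",
         max(lag), " (have lags 0..", length(rho) - 1L, ")", call. = FALSE)
  as.numeric(rho)[lag + 1L]
}

# Direct (shift-and-compare) autocorrelation counts R^r used by the
# enumeration oracles; deliberately an independent code path from the FFT
# implementation above.
autocorr_counts_direct <- function(codes, lags) {
  L <- length(codes)
  vapply(lags, function(r) {
    shifted <- codes[((seq_len(L) - 1L + r) %% L) + 1L]
    sum(codes == shifted)
  }, numeric(1))
}
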