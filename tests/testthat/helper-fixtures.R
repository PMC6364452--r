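# Shared helpers: independent reference implementations and fixture builders.

# Naive circular autocorrelation, independent of the package's FFT path:
# string-level shift and compare.
naive_rho <- function(s, m) {
  x <- strsplit(toupper(s), "")[[1L]]
  L <- length(x)
  vapply(0:(m - 1L), function(r) {
    mean(x == x[((seq_len(L) - 1L + r) %% L) + 1L])
  }, numeric(1))
}

# All sequences of length L over the given alphabet (as strings)
all_sequences <- function(L, alphabet = c("A", "C", "G", "T")) {
  g <- do.call(expand.grid, rep(list(alphabet), L))
  apply(g, 1L, paste, collapse = "")
}

# An analytic autocorrelation profile object (for window/design tests)
make_profile <- function(rho, L) {
  structure(as.numeric(rho), L = L, lags = seq_along(rho) - 1L,
            class = "autocorrelation_profile")
}

random_dna_string <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# A small Tandem Repeats Finder .dat fixture (synthetic records)
write_trf_fixture <- function(path) {
  writeLines(c(
    "Tandem Repeats Finder Program written by:",
    "",
    "Sequence: chr1 Homo sapiens synthetic",
    "",
    "Parameters: 2 7 7 80 10 50 500",
    "",
    paste("100 129 3 10.0 3 95 0 51 30 20 25 25 1.92 ACG",
          strrep("ACG", 10)),
    paste("150 250 10 10.1 10 88 5 120 25 25 25 25 1.99 ACGTACGTTA",
          paste(rep("ACGTACGTTA", 10), collapse = "")),
    "Sequence: chr2",
    "",
    paste("5 24 2 10.0 2 100 0 40 50 50 0 0 1.0 AC", strrep("AC", 10))
  ), path)
  path
}
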