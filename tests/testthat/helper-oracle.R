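# Independent brute-force oracles used to cross-check the package's
# alignment backend. Deliberately written without reference to the code
# under test: a plain affine-gap Smith-Waterman in base R where a gap of
# length k costs gap_open + k * gap_ext.

.AA20_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptide <- function(n) {
  paste(sample(.AA20_TEST, n, replace = TRUE), collapse = "")
}

blosum62_test <- local({
  env <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

sw_score_oracle <- function(a, b, mat = blosum62_test,
                            gap_open = 11, gap_ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)   # best alignment ending in a match/mismatch
  X <- matrix(-Inf, n + 1, m + 1) # ending in a gap in b (a residue unmatched)
  Y <- matrix(-Inf, n + 1, m + 1) # ending in a gap in a
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
      s <- mat[a[i - 1], b[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      if (M[i, j] < 0) M[i, j] <- 0
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Karlin-Altschul transform the package applies to raw gapped scores
# (published BLOSUM62 11/1 constants); restated independently here.
ka_bits <- function(raw) (0.267 * raw - log(0.041)) / log(2)
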