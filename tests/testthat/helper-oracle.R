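# Independent brute-force affine-gap global-alignment oracle (Gotoh
# three-state DP, score only). Written directly from the recurrence, with
# end gaps penalised; a gap of length L costs gap_open + gap_extend * L.
# Deliberately independent of the package's alignment path.

blosum62_oracle <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

oracle_global_score <- function(a, b, mat = blosum62_oracle,
                                gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # ends in a gap in b (A consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in a gap in a (B consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + gap_extend * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + gap_extend * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend,
                     Y[i - 1, j] - gap_open - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     X[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_peptide <- function(n, seed = NULL) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
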