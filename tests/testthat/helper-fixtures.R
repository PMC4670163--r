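# Shared fixture builders: everything is generated in code at test time.

make_profile <- function(ages, values, gene = "G", region = "SIM") {
  n <- length(ages)
  ord <- order(ages)
  tibble::tibble(gene = gene,
                 sample_id = sprintf("S%03d_%s", seq_len(n), region)[ord],
                 subject_id = sprintf("S%03d", seq_len(n))[ord],
                 region = region, age_pcd = ages[ord], value = values[ord])
}

# Equal-length peptides whose Needleman-Wunsch alignment is ungapped by
# construction (equal length, worst mismatch far cheaper than two end
# gaps), with an exact number of identical positions.
peptides_with_identity <- function(len, n_identical, seed = 42) {
  withr::local_seed(seed)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  a <- sample(alphabet, len, replace = TRUE)
  b <- a
  flip <- sample(len, len - n_identical)
  for (i in flip) b[i] <- sample(setdiff(alphabet, a[i]), 1)
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# Write a tiny expression + metadata TSV pair, returning the two paths.
write_tiny_expression <- function(dir, values, samples) {
  mp <- file.path(dir, "expr.tsv")
  sp <- file.path(dir, "meta.tsv")
  df <- tibble::as_tibble(values, rownames = "gene")
  readr::write_tsv(df, mp)
  readr::write_tsv(samples, sp)
  list(matrix = mp, metadata = sp)
}

# Evaluate fun() under a temporary seed without touching the session RNG.
.with_seed_test <- function(seed, fun) withr::with_seed(seed, fun())
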