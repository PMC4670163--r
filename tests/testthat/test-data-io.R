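test_that("age conversion to post-conception days follows the fixed anchors", {
  expect_equal(age_to_pcd(10, "pcw"), 70)
  expect_equal(age_to_pcd(1, "years"), 645.25)
  expect_equal(age_to_pcd(6, "months"), 280 + 6 * 30.44)
  expect_equal(age_to_pcd(123, "pcd"), 123)
  expect_error(age_to_pcd(1, "fortnights"), "unknown age unit")
  expect_error(age_to_pcd(-1, "pcd"), "positive")
})

test_that("age conversion is strictly monotone within each unit", {
  for (u in c("pcw", "pcd", "months", "years")) {
    v <- sort(runif(50, 0.1, 80))
    expect_true(all(diff(age_to_pcd(v, u)) > 0), info = u)
  }
})

test_that("age groups partition the age axis with left-closed bounds", {
  tab <- age_group_table()
  # contiguity of the partition
  expect_equal(tab$lower_pcd[-1], tab$upper_pcd[-nrow(tab)])
  # every lower bound maps to its own group; just below maps to the previous
  expect_equal(assign_age_group(tab$lower_pcd), tab$label)
  inner <- tab$lower_pcd[-1]
  expect_equal(assign_age_group(inner - 1e-9), tab$label[-nrow(tab)])
  # the documented anchor cases
  expect_equal(assign_age_group(age_to_pcd(10, "pcw")), "EF3")
  expect_equal(assign_age_group(age_to_pcd(24, "pcw")), "LF7")
  expect_equal(assign_age_group(age_to_pcd(12, "years")), "Adol12")
  expect_equal(assign_age_group(age_to_pcd(82, "years")), "LA15")
  expect_error(assign_age_group(69), "excluded")
})

test_that("expression round-trips through TSV bit-exactly", {
  co <- simulate_cohort(cohort_config(n_subjects = 12, n_noise_genes = 5,
                                      n_hkg_genes = 2), seed = 11)
  dir <- withr::local_tempdir()
  write_expression(co$es, file.path(dir, "e.tsv"), file.path(dir, "m.tsv"))
  es2 <- suppressWarnings(read_expression(file.path(dir, "e.tsv"),
                                          file.path(dir, "m.tsv"),
                                          region_vocabulary = NULL))
  expect_identical(es2$values, co$es$values)
  expect_equal(as.data.frame(es2$samples), as.data.frame(co$es$samples))
})

test_that("read_expression rejects malformed inputs with informative errors", {
  dir <- withr::local_tempdir()
  vals <- matrix(rnorm(6), 2, 3,
                 dimnames = list(c("G1", "G2"), c("s1", "s2", "s3")))
  samples <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                            subject_id = c("d1", "d2", "d3"),
                            region = "PFC", age_pcd = c(100, 400, 9000))
  p <- write_tiny_expression(dir, vals, samples)

  # sample column missing from metadata
  p2 <- write_tiny_expression(dir, vals, samples[1:2, ])
  expect_error(read_expression(p2$matrix, p2$metadata), "s3")

  # non-numeric cell names its position
  lines <- readLines(p$matrix)
  lines[2] <- sub("\t[^\t]+$", "\toops", lines[2])
  writeLines(lines, p$matrix)
  expect_error(read_expression(p$matrix, p$metadata), "oops")

  # duplicate gene ids
  vals_dup <- rbind(vals, vals[1, , drop = FALSE])
  df <- tibble::as_tibble(vals_dup, rownames = "gene")
  df$gene <- c("G1", "G2", "G1")
  readr::write_tsv(df, p$matrix)
  expect_error(read_expression(p$matrix, p$metadata), "duplicate gene")
})

test_that("metadata ages can arrive in mixed units", {
  dir <- withr::local_tempdir()
  vals <- matrix(rnorm(4), 1, 4,
                 dimnames = list("G1", paste0("s", 1:4)))
  samples <- tibble::tibble(sample_id = paste0("s", 1:4),
                            subject_id = paste0("d", 1:4),
                            region = "PFC",
                            age_value = c(10, 20, 6, 30),
                            age_unit = c("pcw", "pcw", "months", "years"))
  p <- write_tiny_expression(dir, vals, samples)
  es <- read_expression(p$matrix, p$metadata)
  expect_equal(es$samples$age_pcd,
               c(70, 140, 280 + 6 * 30.44, 280 + 30 * 365.25))
  # unknown regions only warn when a vocabulary is enforced
  samples$region <- "NOT_A_REGION"
  p <- write_tiny_expression(dir, vals, samples)
  expect_warning(read_expression(p$matrix, p$metadata), "NOT_A_REGION")
})

test_that("expression_profile extracts an age-sorted per-gene tibble", {
  co <- simulate_cohort(cohort_config(n_subjects = 15), seed = 5)
  pr <- expression_profile(co$es, "SW1A", "SIM")
  expect_equal(nrow(pr), 15)
  expect_true(!is.unsorted(pr$age_pcd))
  expect_equal(pr$value,
               unname(co$es$values["SW1A", ][order(co$es$samples$age_pcd)]))
  expect_error(expression_profile(co$es, "NOPE", "SIM"), "not found")
})

test_that("FASTA reading uppercases, validates and keeps header tokens", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "p.fasta")
  writeLines(c(">P1 some description", "acdef", "ghik",
               ">P2", "MKWVX"), fa)
  seqs <- read_protein_fasta(fa)
  expect_equal(seqs$id, c("P1", "P2"))
  expect_equal(seqs$residues, c("ACDEFGHIK", "MKWVX"))
  expect_equal(seqs$length, c(9L, 5L))

  writeLines(c(">P1", "ACD1F"), fa)
  expect_error(read_protein_fasta(fa), "illegal residue")
  writeLines(c(">P1", "ACDEF", ">P1", "MKWV"), fa)
  expect_error(read_protein_fasta(fa), "duplicate")
})

test_that("pathway-element tables group and deduplicate rows", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "el.tsv")
  readr::write_tsv(tibble::tibble(
    pathway_id = "04724",
    element_id = c("NMDAR", "NMDAR", "NMDAR", "NMDAR", "SOLO"),
    gene_symbol = c("GRIN2A", "GRIN2B", "GRIN2C", "GRIN2A", "GRIN1")), path)
  el <- read_pathway_elements(path)
  expect_equal(nrow(el), 4)  # duplicate (NMDAR, GRIN2A) collapsed
  expect_equal(sum(el$element_id == "NMDAR"), 3)
  # single-gene elements are retained
  expect_true("SOLO" %in% el$element_id)

  readr::write_tsv(tibble::tibble(pathway_id = "x", gene_symbol = "y"), path)
  expect_error(read_pathway_elements(path), "element_id")
})

test_that("the packaged pathway list and region vocabulary have the expected shape", {
  expect_equal(nrow(kegg_brain_pathways()), 17)
  expect_true("04724" %in% kegg_brain_pathways()$kegg_id)
  expect_length(brain_region_codes(), 17)
})
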