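make_noise_matrix <- function(n_genes, n_samples, seed) {
  withr::local_seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                         sprintf("s%04d", seq_len(n_samples))))
}

test_that("random-pair baseline is seed-deterministic and well-formed", {
  m <- make_noise_matrix(100, 30, 51)
  d1 <- random_pair_baseline(m, n_pairs = 500, seed = 7)
  d2 <- random_pair_baseline(m, n_pairs = 500, seed = 7)
  expect_identical(d1$counts, d2$counts)
  expect_equal(sum(d1$fractions), 1, tolerance = 1e-12)
  expect_equal(d1$n_pairs, 500)
  d3 <- random_pair_baseline(m, n_pairs = 1, seed = 7)
  expect_equal(sum(d3$counts), 1)
  expect_error(random_pair_baseline(m, n_pairs = 10), "seed")
})

test_that("under i.i.d. noise the baseline p-values are uniform", {
  m <- make_noise_matrix(400, 40, 52)
  d <- random_pair_baseline(m, n_pairs = 20000, seed = 3)
  # fraction with p < 0.05 is the mass above -log10(p) = 1.301
  frac_sig <- sum(d$fractions[d$bin_edges[-length(d$bin_edges)] >= 1.5]) +
    d$fractions[3] * (1.5 - -log10(0.05)) / 0.5
  expect_gt(frac_sig, 0.03)
  expect_lt(frac_sig, 0.07)
})

test_that("overlap binning uses left-closed bins with a closed top", {
  pairs <- tibble::tibble(gene_a = "a", gene_b = "b",
                          overlap = c(0, 29.9, 30, 59.9, 60, 100))
  out <- bin_paralogs_by_overlap(pairs, bin_edges = c(0, 30, 60, 100))
  expect_equal(as.character(out$overlap_bin),
               c("[0,30)", "[0,30)", "[30,60)", "[30,60)", "[60,100]",
                 "[60,100]"))
  expect_error(bin_paralogs_by_overlap(dplyr::mutate(pairs, overlap = 101)),
               "\\[0, 100\\]")
})

test_that("permutation enrichment p-values respect the add-one bounds", {
  edges <- c(0, 1, 2, Inf)
  obs <- devswitch:::.new_pval_dist(c(0.5, 0.05, 0.001), edges, "obs", 3)
  # a null sampler with all mass in the first bin
  null_low <- function(seed) devswitch:::.new_pval_dist(
    rep(0.9, 3), edges, "null", 3)
  out <- bin_enrichment_test(obs, null_low, n_permutations = 1000, seed = 1,
                             flag_threshold = 1e-3)
  # bins 2 and 3 are never reached by the null
  expect_equal(out$perm_p[2:3], rep(1 / 1001, 2))
  # identical observed and null with one permutation gives p = 1
  ident <- bin_enrichment_test(obs, function(seed) obs, n_permutations = 1,
                               seed = 1, flag_threshold = 0.6)
  expect_equal(ident$perm_p, rep(1, 3))
  expect_error(
    bin_enrichment_test(obs, null_low, n_permutations = 500, seed = 1,
                        flag_threshold = 1e-3),
    "unreachable")
})

test_that("permutation test flags a genuinely enriched bin", {
  m <- make_noise_matrix(200, 40, 53)
  sampler <- function(seed) random_pair_baseline(m, n_pairs = 150, seed = seed)
  # plant an observed distribution with far too many strong p-values
  obs <- devswitch:::.new_pval_dist(
    c(10^-runif(30, 3, 6), runif(120)), default_bin_edges(), "planted", 150)
  out <- bin_enrichment_test(obs, sampler, n_permutations = 999, seed = 2,
                             flag_threshold = 0.01)
  expect_true(any(out$flagged[out$bin_lo >= 3]))
})

test_that("subject subsampling is exact, deterministic and size-checked", {
  co <- simulate_cohort(cohort_config(n_subjects = 40,
                                      regions = c("CBC", "HIP")), seed = 55)
  s1 <- subsample_subjects(co$es, 15, seed = 4)
  s2 <- subsample_subjects(co$es, 15, seed = 4)
  expect_identical(s1$values, s2$values)
  expect_equal(length(unique(s1$samples$subject_id)), 15)
  # all regions of a kept subject are retained
  expect_true(all(table(s1$samples$subject_id) == 2))
  full <- subsample_subjects(co$es, 40, seed = 4)
  expect_setequal(full$samples$sample_id, co$es$samples$sample_id)
  expect_error(subsample_subjects(co$es, 41, seed = 4), "available")
})

test_that("housekeeping baseline compares pathway and HKG detection rates", {
  cfg <- cohort_config(n_subjects = 100,
                       pairs = replicate(4, switch_pair_spec(),
                                         simplify = FALSE),
                       n_noise_genes = 0, n_hkg_genes = 12, hkg_sd = 0.3)
  co <- simulate_cohort(cfg, seed = 56)
  hkg <- co$truth$genes$gene[co$truth$genes$class == "hkg"]
  pw <- tibble::tibble(gene_a = sprintf("SW%dA", 1:4),
                       gene_b = sprintf("SW%dB", 1:4))
  out <- housekeeping_baseline(co$es, hkg, pw, "SIM",
                               thresholds = c(1, 2), max_hkg_pairs = 30)
  expect_equal(nrow(out), 2)
  expect_true(all(out$frac_hkg >= 0 & out$frac_hkg <= 1))
  # coupled pathway pairs reach significance more often than flat HKGs
  expect_gt(out$frac_pathway[1], out$frac_hkg[1])
  # identical sets give ratio 1
  hp <- t(utils::combn(hkg[1:6], 2))
  same <- housekeeping_baseline(
    co$es, hkg, tibble::tibble(gene_a = hp[, 1], gene_b = hp[, 2]),
    "SIM", thresholds = 0.3, max_hkg_pairs = 1e6)
  hkg_all <- t(utils::combn(sort(hkg), 2))
  same_full <- housekeeping_baseline(
    co$es, hkg, tibble::tibble(gene_a = hkg_all[, 1], gene_b = hkg_all[, 2]),
    "SIM", thresholds = 0.3, max_hkg_pairs = 1e6)
  expect_equal(same_full$ratio, 1)
  expect_error(housekeeping_baseline(co$es, hkg, pw, "SIM",
                                     thresholds = numeric()), "empty")
})
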