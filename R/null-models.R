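#' Default histogram edges on the -log10(p) axis
#'
#' Half-unit bins from 0 to 5 with a final open bin for p < 1e-5.
#'
#' @return numeric vector of bin edges.
#' @export
default_bin_edges <- function() c(seq(0, 5, by = 0.5), Inf)

# Vectorised two-sided Pearson correlation p-values for many pairs of
# rows of a genes x samples matrix. Rows are standardised once.
.pair_pearson_p <- function(values, idx_a, idx_b) {
  n <- ncol(values)
  z <- values - rowMeans(values)
  s <- sqrt(rowSums(z^2))
  r <- rowSums(z[idx_a, , drop = FALSE] * z[idx_b, , drop = FALSE]) /
    (s[idx_a] * s[idx_b])
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  pmax(p, .Machine$double.xmin)
}

.new_pval_dist <- function(p, bin_edges, label, n_pairs) {
  lg <- -log10(p)
  counts <- as.vector(table(cut(lg, breaks = bin_edges, right = FALSE,
                                include.lowest = TRUE)))
  structure(list(label = label, bin_edges = bin_edges, counts = counts,
                 fractions = counts / sum(counts), n_pairs = n_pairs),
            class = "pval_dist")
}

#' @export
print.pval_dist <- function(x, ...) {
  cat(sprintf("<pval_dist> '%s': %d pairs over %d bins on -log10(p)\n",
              x$label, x$n_pairs, length(x$counts)))
  invisible(x)
}

#' @export
tidy.pval_dist <- function(x, ...) {
  k <- length(x$counts)
  tibble::tibble(label = x$label,
                 bin_lo = x$bin_edges[seq_len(k)],
                 bin_hi = x$bin_edges[seq_len(k) + 1],
                 count = x$counts, fraction = x$fractions)
}

#' Random-pairing baseline distribution
#'
#' Draws unordered gene pairs uniformly at random (no self-pairs;
#' repeats across draws allowed), computes the two-sided Pearson
#' p-value of each pair's profile correlation in one region, and bins
#' the p-values on the -log10 axis. This is the genome-wide baseline
#' against which pathway-pair enrichment is judged.
#'
#' @param es an `expression_set` (or a plain genes x samples numeric
#'   matrix).
#' @param region region code; ignored for a plain matrix.
#' @param n_pairs number of random pairs; the full-scale default is
#'   100000.
#' @param seed integer seed (required; no implicit global state).
#' @param bin_edges edges on the -log10(p) axis.
#' @param genes optional subset of gene ids to draw from.
#' @return a `pval_dist`.
#' @export
random_pair_baseline <- function(es, region = NULL, n_pairs = 1e5, seed,
                                 bin_edges = default_bin_edges(),
                                 genes = NULL) {
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  values <- if (inherits(es, "expression_set")) {
    keep <- if (is.null(region)) rep(TRUE, ncol(es$values)) else
      es$samples$region == region
    es$values[, keep, drop = FALSE]
  } else es
  if (!is.null(genes)) values <- values[genes, , drop = FALSE]
  g <- nrow(values)
  if (g < 2) stop("need at least 2 genes", call. = FALSE)
  rs <- .seeded_rng(seed)
  idx_a <- rs$sample_int(g, n_pairs, replace = TRUE)
  idx_b <- rs$sample_int(g - 1, n_pairs, replace = TRUE)
  idx_b <- idx_b + (idx_b >= idx_a)   # uniform over the g-1 partners, no self-pairs
  p <- .pair_pearson_p(values, idx_a, idx_b)
  .new_pval_dist(p, bin_edges, "random pairs", n_pairs)
}

# Minimal local RNG wrapper: every draw runs with a private
# .Random.seed (derived from the supplied seed, advanced per call), so
# package randomness never perturbs — or silently depends on — the
# caller's RNG state.
.seeded_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  state <- NULL
  rng_do <- function(fun) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    res <- fun()
    state <<- get(".Random.seed", globalenv())
    res
  }
  list(
    sample_int = function(n, size, replace = FALSE)
      rng_do(function() sample.int(n, size, replace = replace)),
    runif = function(n, min = 0, max = 1)
      rng_do(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1)
      rng_do(function() stats::rnorm(n, mean, sd))
  )
}

#' Bin paralog pairs by sequence overlap
#'
#' Groups gene pairs by their sequence-overlap percentage into
#' left-closed/right-open bins (the last bin includes its upper edge),
#' for computing one p-value distribution per similarity stratum.
#'
#' @param pairs tibble with columns `gene_a`, `gene_b`, `overlap`
#'   (percent, in `[0, 100]`).
#' @param bin_edges ascending edges within `[0, 100]`.
#' @return the input with an `overlap_bin` factor column.
#' @export
bin_paralogs_by_overlap <- function(pairs, bin_edges = c(0, 30, 60, 100)) {
  stopifnot("overlap" %in% names(pairs))
  if (any(pairs$overlap < 0 | pairs$overlap > 100)) {
    stop("overlap values must lie in [0, 100]", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(pairs),
    overlap_bin = cut(.data$overlap, breaks = bin_edges, right = FALSE,
                      include.lowest = TRUE))
}

#' Permutation enrichment test over histogram bins
#'
#' Tests, bin by bin, whether an observed -log10(p) histogram holds
#' more pairs than expected under random pairing. Each permutation
#' redraws a random pair set of the same size via `null_sampler`; the
#' per-bin permutation p-value uses the add-one estimator
#' `(1 + #{count >= observed}) / (n_permutations + 1)`, so it can never
#' be zero. Bins with `perm_p < flag_threshold` are flagged.
#'
#' @param observed a `pval_dist` for the pair set of interest.
#' @param null_sampler `function(seed)` returning a `pval_dist` with
#'   identical `bin_edges` for one random same-size pair set.
#' @param n_permutations number of permutations; default 10000.
#' @param seed integer seed.
#' @param flag_threshold per-bin significance threshold; default 1e-3.
#'   Requires `(n_permutations + 1) * flag_threshold >= 1`, otherwise
#'   the threshold is unreachable and an error is raised.
#' @return tibble per bin: `bin_lo`, `bin_hi`, `observed_count`,
#'   `null_mean`, `perm_p`, `flagged`; `n_permutations` as an attribute.
#' @export
bin_enrichment_test <- function(observed, null_sampler,
                                n_permutations = 10000, seed,
                                flag_threshold = 1e-3) {
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  stopifnot(inherits(observed, "pval_dist"), is.function(null_sampler))
  if ((n_permutations + 1) * flag_threshold < 1) {
    stop("flag threshold ", flag_threshold, " unreachable with ",
         n_permutations, " permutations", call. = FALSE)
  }
  k <- length(observed$counts)
  ge <- integer(k)
  null_sum <- numeric(k)
  for (b in seq_len(n_permutations)) {
    nd <- null_sampler(seed + b)
    if (!identical(nd$bin_edges, observed$bin_edges)) {
      stop("null sampler returned different bin edges", call. = FALSE)
    }
    ge <- ge + (nd$counts >= observed$counts)
    null_sum <- null_sum + nd$counts
  }
  perm_p <- (1 + ge) / (n_permutations + 1)
  out <- tibble::tibble(
    bin_lo = observed$bin_edges[seq_len(k)],
    bin_hi = observed$bin_edges[seq_len(k) + 1],
    observed_count = observed$counts,
    null_mean = null_sum / n_permutations,
    perm_p = perm_p,
    flagged = perm_p < flag_threshold)
  attr(out, "n_permutations") <- n_permutations
  out
}

#' Housekeeping-gene baseline for age-corrected correlations
#'
#' Spurious subject-level correlation (RNA quality, cell-composition
#' drift) would inflate residual correlations genome-wide, so
#' housekeeping genes — expressed but developmentally flat — serve as a
#' negative baseline. For each threshold theta on -log10(p), reports
#' the fraction of housekeeping pairs and of pathway pairs whose
#' age-corrected correlation p-value falls below `10^-theta`, and their
#' ratio.
#'
#' @param es an `expression_set`.
#' @param hkg_genes character vector of housekeeping gene ids (>= 10)
#'   present in the matrix.
#' @param pathway_pairs tibble with `gene_a`, `gene_b` (the pairs under
#'   study).
#' @param region region code.
#' @param thresholds grid of theta values on -log10(p); must be
#'   non-empty.
#' @param max_hkg_pairs cap on the number of housekeeping pairs tested
#'   (all unordered pairs by default, subsampled deterministically if
#'   more).
#' @param seed integer seed (used only if subsampling is needed).
#' @param ... passed to [fit_trend_spline()].
#' @return tibble: `theta`, `frac_hkg`, `frac_pathway`, `ratio`
#'   (`frac_pathway / frac_hkg`, `Inf` where no housekeeping pair
#'   reaches the threshold but a pathway pair does, `NaN` where
#'   neither does).
#' @export
housekeeping_baseline <- function(es, hkg_genes, pathway_pairs, region,
                                  thresholds = seq(1, 8, by = 1),
                                  max_hkg_pairs = 500, seed = 1, ...) {
  if (length(thresholds) == 0) stop("empty threshold grid", call. = FALSE)
  hkg_genes <- intersect(hkg_genes, rownames(es$values))
  if (length(hkg_genes) < 10) {
    stop("need at least 10 housekeeping genes with profiles", call. = FALSE)
  }
  cmb <- utils::combn(sort(hkg_genes), 2)
  hkg_pairs <- tibble::tibble(gene_a = cmb[1, ], gene_b = cmb[2, ])
  if (nrow(hkg_pairs) > max_hkg_pairs) {
    rs <- .seeded_rng(seed)
    hkg_pairs <- hkg_pairs[sort(rs$sample_int(nrow(hkg_pairs), max_hkg_pairs)), ]
  }
  resid_p_of <- function(prs) {
    purrr::map2_dbl(prs$gene_a, prs$gene_b, function(a, b) {
      ac <- age_corrected_correlation(expression_profile(es, a, region),
                                      expression_profile(es, b, region), ...)
      ac$summary$resid_p
    })
  }
  p_hkg <- resid_p_of(hkg_pairs)
  p_path <- resid_p_of(pathway_pairs)
  purrr::map_dfr(thresholds, function(th) {
    fh <- mean(p_hkg < 10^(-th), na.rm = TRUE)
    fp <- mean(p_path < 10^(-th), na.rm = TRUE)
    tibble::tibble(theta = th, frac_hkg = fh, frac_pathway = fp,
                   ratio = fp / fh)
  })
}

#' Subsample subjects uniformly
#'
#' Draws `n_subjects` subjects uniformly without replacement and keeps
#' all their samples, bringing a large cohort to the same subject count
#' as a smaller one so correlation p-values are on a common scale. The
#' default target is 53 subjects.
#'
#' @param es an `expression_set`.
#' @param n_subjects target subject count; default 53.
#' @param seed integer seed.
#' @return an `expression_set` restricted to the drawn subjects.
#' @export
subsample_subjects <- function(es, n_subjects = 53, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  stopifnot(inherits(es, "expression_set"))
  subjects <- unique(es$samples$subject_id)
  if (n_subjects > length(subjects)) {
    stop("requested ", n_subjects, " subjects but only ", length(subjects),
         " available", call. = FALSE)
  }
  rs <- .seeded_rng(seed)
  chosen <- subjects[sort(rs$sample_int(length(subjects), n_subjects))]
  keep <- es$samples$subject_id %in% chosen
  new_expression_set(es$values[, keep, drop = FALSE],
                     es$samples[keep, , drop = FALSE])
}
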