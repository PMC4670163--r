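# Study-age span used by the generator (10 post-conception weeks to
# ~81 years), matching the donor range of developmental brain cohorts.
.AGE_SPAN_PCD <- c(70, 30000)

#' Parametric trend function of age
#'
#' Trend shapes for the synthetic cohort, defined on the log2 age axis
#' (mirroring the detrending default): `"constant"`; `"linear"`, a
#' straight line in log2(age) scaled so `amplitude` is the total change
#' over the study span; and `"logistic"`, the canonical switch shape —
#' a sigmoidal transition of size `amplitude` centred at `midpoint_pcd`
#' with slope scale `tau` (log2-age units).
#'
#' @param type `"constant"`, `"linear"` or `"logistic"`.
#' @param baseline expression level (log2 units) at the lower plateau /
#'   span start.
#' @param amplitude total change in log2 units (negative for a falling
#'   trend).
#' @param midpoint_pcd logistic midpoint in post-conception days;
#'   default birth (280).
#' @param tau logistic slope scale on the log2-age axis; the default 1
#'   spreads the transition over roughly four log2-age units, the
#'   perinatal-to-childhood window over which documented subunit
#'   switches unfold.
#' @return a list of class `trend_function`: a callable `fn(age_pcd)`
#'   plus its parameters.
#' @export
trend_function <- function(type = c("logistic", "linear", "constant"),
                           baseline = 6, amplitude = 3,
                           midpoint_pcd = 280, tau = 1) {
  type <- match.arg(type)
  span <- log2(.AGE_SPAN_PCD)
  fn <- switch(type,
    constant = function(age_pcd) rep(baseline, length(age_pcd)),
    linear = function(age_pcd) {
      baseline + amplitude * (log2(age_pcd) - span[1]) / diff(span)
    },
    logistic = function(age_pcd) {
      baseline + amplitude / (1 + exp(-(log2(age_pcd) - log2(midpoint_pcd)) / tau))
    })
  structure(list(fn = fn, type = type, baseline = baseline,
                 amplitude = amplitude, midpoint_pcd = midpoint_pcd,
                 tau = tau), class = "trend_function")
}

.eval_trend <- function(tf, age_pcd) tf$fn(age_pcd)

#' Specification of a simulated switch pair
#'
#' Generative model for one candidate pair:
#' `y_g(s) = trend_g(age_s) + loading_g * u_s + eps_gs`, with a shared
#' subject-level latent factor `u_s ~ N(0, shared_factor_sd^2)` and
#' independent noise `eps ~ N(0, noise_sd^2)`. The implied residual
#' correlation between the two genes (what age-correction should
#' recover) is
#' `loading_a * loading_b * su^2 / sqrt((loading_a^2 su^2 + s^2)(loading_b^2 su^2 + s^2))`
#' and is stored as `target_residual_corr`.
#'
#' The defaults encode a canonical developmental switch: gene A rising
#' and gene B falling by 3 log2 units around birth (anti-correlated
#' logistic trends), with equal loadings and `shared_factor_sd =
#' noise_sd`, giving a target residual correlation of 0.5.
#'
#' @param trend_a,trend_b `trend_function`s for the two genes.
#' @param shared_factor_sd sd of the shared subject factor (log2
#'   units); 0 removes subject-level coupling.
#' @param loading_a,loading_b factor loadings of the two genes.
#' @param noise_sd per-sample noise sd (log2 units); must be > 0.
#' @return a list of class `switch_pair_spec`.
#' @export
switch_pair_spec <- function(trend_a = trend_function("logistic", baseline = 6,
                                                      amplitude = 3),
                             trend_b = trend_function("logistic", baseline = 9,
                                                      amplitude = -3),
                             shared_factor_sd = 0.3,
                             loading_a = 1, loading_b = 1,
                             noise_sd = 0.3) {
  stopifnot(inherits(trend_a, "trend_function"),
            inherits(trend_b, "trend_function"),
            shared_factor_sd >= 0, noise_sd > 0)
  su2 <- shared_factor_sd^2
  target <- loading_a * loading_b * su2 /
    sqrt((loading_a^2 * su2 + noise_sd^2) * (loading_b^2 * su2 + noise_sd^2))
  structure(list(trend_a = trend_a, trend_b = trend_b,
                 shared_factor_sd = shared_factor_sd,
                 loading_a = loading_a, loading_b = loading_b,
                 noise_sd = noise_sd, target_residual_corr = target),
            class = "switch_pair_spec")
}

#' Sample donor ages
#'
#' Draws subject ages (post-conception days) over the study span. The
#' `"mixed"` design guarantees developmental coverage: when
#' `n_subjects >= 26`, two subjects are drawn uniformly inside each of
#' the 13 reporting age groups and the remainder log-uniformly over the
#' whole span; smaller cohorts and the `"loguniform"` design draw all
#' ages log-uniformly.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer seed.
#' @param design `"mixed"` (default) or `"loguniform"`.
#' @return sorted numeric vector of ages in post-conception days.
#' @export
sample_ages <- function(n_subjects, seed, design = c("mixed", "loguniform")) {
  design <- match.arg(design)
  stopifnot(n_subjects >= 2)
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  span <- log2(.AGE_SPAN_PCD)
  .with_seed(seed, function() {
    ages <- numeric(0)
    n_rest <- n_subjects
    if (design == "mixed" && n_subjects >= 26) {
      tab <- age_group_table()
      lo <- tab$lower_pcd
      hi <- pmin(tab$upper_pcd, .AGE_SPAN_PCD[2])
      ages <- as.vector(vapply(seq_len(nrow(tab)), function(g)
        stats::runif(2, lo[g], hi[g]), numeric(2)))
      n_rest <- n_subjects - length(ages)
    }
    if (n_rest > 0) {
      ages <- c(ages, 2^stats::runif(n_rest, span[1], span[2]))
    }
    sort(ages)
  })
}

#' Simulate one switch pair
#'
#' Draws expression profiles for the two genes of a
#' [switch_pair_spec()] at the given subject ages, returning tidy
#' profiles plus the generative ground truth.
#'
#' @param spec a `switch_pair_spec`.
#' @param ages numeric vector of subject ages (post-conception days).
#' @param seed integer seed.
#' @param genes names for the two genes.
#' @param region region code stamped on the profiles.
#' @return list with profile tibbles `x` and `y` (columns `gene`,
#'   `sample_id`, `subject_id`, `region`, `age_pcd`, `value`), the
#'   latent tibble `latent` (`subject_id`, `u`) and the `spec`.
#' @export
simulate_switch_pair <- function(spec, ages, seed,
                                 genes = c("GENE_A", "GENE_B"),
                                 region = "SIM") {
  stopifnot(inherits(spec, "switch_pair_spec"), length(genes) == 2)
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  ages <- sort(ages)
  n <- length(ages)
  sim <- .with_seed(seed, function() {
    u <- stats::rnorm(n, 0, spec$shared_factor_sd)
    list(u = u,
         va = .eval_trend(spec$trend_a, ages) + spec$loading_a * u +
           stats::rnorm(n, 0, spec$noise_sd),
         vb = .eval_trend(spec$trend_b, ages) + spec$loading_b * u +
           stats::rnorm(n, 0, spec$noise_sd))
  })
  ids <- sprintf("S%03d", seq_len(n))
  mk <- function(g, v) tibble::tibble(gene = g, sample_id = paste0(ids, "_", region),
                                      subject_id = ids, region = region,
                                      age_pcd = ages, value = v)
  list(x = mk(genes[1], sim$va), y = mk(genes[2], sim$vb),
       latent = tibble::tibble(subject_id = ids, u = sim$u),
       spec = spec)
}

#' Configuration of a synthetic cohort
#'
#' Validated settings for [simulate_cohort()]. The defaults emulate a
#' single-region developmental brain cohort at the scale of the
#' smaller postmortem studies: 53 donors spanning 10 post-conception
#' weeks to ~81 years, one planted switch pair, a background of
#' trendless variable genes (which pass the expression-range filter but
#' carry no subject coupling) and a set of housekeeping-like flat genes
#' (low variance, filtered out by range).
#'
#' @param regions character vector of region codes.
#' @param n_subjects donors per region (ages shared across regions).
#' @param pairs list of [switch_pair_spec()]s to plant.
#' @param n_noise_genes trendless genes with per-sample sd
#'   `noise_gene_sd`.
#' @param n_hkg_genes flat housekeeping-like genes with per-sample sd
#'   `hkg_sd`.
#' @param noise_gene_sd,hkg_sd per-sample standard deviations (log2
#'   units).
#' @param age_design passed to [sample_ages()].
#' @return a validated config list of class `cohort_config`.
#' @export
cohort_config <- function(regions = "SIM", n_subjects = 53,
                          pairs = list(switch_pair_spec()),
                          n_noise_genes = 20, n_hkg_genes = 10,
                          noise_gene_sd = 1, hkg_sd = 0.2,
                          age_design = "mixed") {
  if (length(regions) < 1) stop("config$regions: need at least one region", call. = FALSE)
  if (n_subjects < 2) stop("config$n_subjects: need at least 2 subjects", call. = FALSE)
  if (!is.list(pairs) ||
      !all(vapply(pairs, inherits, logical(1), "switch_pair_spec"))) {
    stop("config$pairs: must be a list of switch_pair_spec objects", call. = FALSE)
  }
  if (n_noise_genes < 0 || n_hkg_genes < 0) {
    stop("config$n_noise_genes / config$n_hkg_genes: must be non-negative",
         call. = FALSE)
  }
  structure(list(regions = regions, n_subjects = n_subjects, pairs = pairs,
                 n_noise_genes = n_noise_genes, n_hkg_genes = n_hkg_genes,
                 noise_gene_sd = noise_gene_sd, hkg_sd = hkg_sd,
                 age_design = age_design), class = "cohort_config")
}

#' Simulate a full synthetic cohort
#'
#' Generates an expression matrix with the statistical structure the
#' pipeline assumes: smooth (anti-correlated) age trends for planted
#' switch pairs, a shared subject-level factor inducing residual
#' correlation within each pair, trendless background genes, flat
#' housekeeping-like genes, and i.i.d. Gaussian per-sample noise.
#' Subject ages are shared across regions; latent factors and noise
#' are drawn independently per region.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the same (config, seed) reproduces the
#'   cohort bit-exactly.
#' @return a list of class `synthetic_cohort`: `es` (the
#'   `expression_set`), `truth` (`pairs`, `genes` and `latent`
#'   tibbles), `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  ages <- sample_ages(config$n_subjects, seed = seed, design = config$age_design)
  subj <- sprintf("S%03d", seq_along(ages))
  n_pairs <- length(config$pairs)
  pair_genes <- if (n_pairs > 0) {
    lapply(seq_len(n_pairs), function(j) c(sprintf("SW%dA", j), sprintf("SW%dB", j)))
  } else list()
  noise_genes <- if (config$n_noise_genes > 0)
    sprintf("NOISE%03d", seq_len(config$n_noise_genes)) else character()
  hkg_genes <- if (config$n_hkg_genes > 0)
    sprintf("HKG%03d", seq_len(config$n_hkg_genes)) else character()
  genes <- c(unlist(pair_genes), noise_genes, hkg_genes)
  if (length(genes) == 0) stop("config produces no genes", call. = FALSE)

  sim <- .with_seed(seed, function() {
    noise_base <- stats::runif(length(noise_genes), 4, 10)
    hkg_base <- stats::runif(length(hkg_genes), 4, 10)
    samples <- list()
    vals <- list()
    latent <- list()
    for (r in config$regions) {
      n <- length(ages)
      m <- matrix(NA_real_, nrow = length(genes), ncol = n,
                  dimnames = list(genes, NULL))
      for (j in seq_len(n_pairs)) {
        sp <- config$pairs[[j]]
        u <- stats::rnorm(n, 0, sp$shared_factor_sd)
        m[pair_genes[[j]][1], ] <- .eval_trend(sp$trend_a, ages) +
          sp$loading_a * u + stats::rnorm(n, 0, sp$noise_sd)
        m[pair_genes[[j]][2], ] <- .eval_trend(sp$trend_b, ages) +
          sp$loading_b * u + stats::rnorm(n, 0, sp$noise_sd)
        latent[[length(latent) + 1]] <- tibble::tibble(
          region = r, pair = j, subject_id = subj, u = u)
      }
      for (i in seq_along(noise_genes)) {
        m[noise_genes[i], ] <- noise_base[i] + stats::rnorm(n, 0, config$noise_gene_sd)
      }
      for (i in seq_along(hkg_genes)) {
        m[hkg_genes[i], ] <- hkg_base[i] + stats::rnorm(n, 0, config$hkg_sd)
      }
      colnames(m) <- paste0(subj, "_", r)
      vals[[r]] <- m
      samples[[r]] <- tibble::tibble(sample_id = colnames(m), subject_id = subj,
                                     region = r, age_pcd = ages)
    }
    list(values = do.call(cbind, vals),
         samples = dplyr::bind_rows(samples),
         latent = dplyr::bind_rows(latent))
  })

  truth_pairs <- if (n_pairs > 0) {
    purrr::map_dfr(seq_len(n_pairs), function(j) {
      sp <- config$pairs[[j]]
      tibble::tibble(pair = j, gene_a = pair_genes[[j]][1],
                     gene_b = pair_genes[[j]][2],
                     trend_type_a = sp$trend_a$type, trend_type_b = sp$trend_b$type,
                     amplitude_a = sp$trend_a$amplitude,
                     amplitude_b = sp$trend_b$amplitude,
                     shared_factor_sd = sp$shared_factor_sd,
                     noise_sd = sp$noise_sd,
                     target_residual_corr = sp$target_residual_corr)
    })
  } else tibble::tibble()
  truth_genes <- tibble::tibble(
    gene = genes,
    class = c(rep("switch", 2 * n_pairs),
              rep("noise", length(noise_genes)),
              rep("hkg", length(hkg_genes))))

  structure(list(
    es = new_expression_set(sim$values, sim$samples),
    truth = list(pairs = truth_pairs, genes = truth_genes, latent = sim$latent),
    config = config, seed = seed
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> seed %d, %d planted pair(s)\n",
              x$seed, nrow(x$truth$pairs)))
  print(x$es)
  invisible(x)
}

#' Write a synthetic cohort to TSV files
#'
#' Writes `expression.tsv`, `metadata.tsv`, `truth_pairs.tsv` and
#' `truth_genes.tsv` under a directory, in the formats
#' [read_expression()] consumes.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth_pairs = file.path(dir, "truth_pairs.tsv"),
             truth_genes = file.path(dir, "truth_genes.tsv"))
  write_expression(cohort$es, paths["expression"], paths["metadata"])
  readr::write_tsv(cohort$truth$pairs, paths["truth_pairs"])
  readr::write_tsv(cohort$truth$genes, paths["truth_genes"])
  invisible(paths)
}
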