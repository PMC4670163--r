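#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].
#' Every analysis threshold is surfaced here with its standard default:
#' similarity 0.30, expression range 1.5 (log2), q-value threshold
#' 0.01, sliding-window width 10, log2 age transform, Pearson
#' correlations.
#'
#' @param expression,metadata,fasta,elements input file paths (see
#'   [read_expression()], [read_protein_fasta()],
#'   [read_pathway_elements()]).
#' @param min_similarity candidate-pair similarity threshold.
#' @param min_range expression-range filter threshold (log2 units).
#' @param alpha q-value significance threshold.
#' @param method correlation method, `"pearson"` or `"spearman"`.
#' @param window sliding-window width for the noise-variance estimate.
#' @param age_transform `"log2"` or `"linear"`.
#' @param regions regions to analyse (`NULL` = all in the metadata).
#' @param top_n rows of the ranked heatmap table.
#' @param loo compute the leave-one-out R^2 of every tested gene's
#'   trend fit (reported per pair as `r2_loo_a` / `r2_loo_b`).
#' @param seed integer seed recorded in the manifest.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, metadata, fasta, elements,
                            min_similarity = 0.30, min_range = 1.5,
                            alpha = 0.01, method = "pearson", window = 10,
                            age_transform = "log2", regions = NULL,
                            top_n = 20, loo = TRUE, seed = 1) {
  cfg <- list(expression = expression, metadata = metadata, fasta = fasta,
              elements = elements, min_similarity = min_similarity,
              min_range = min_range, alpha = alpha, method = method,
              window = window, age_transform = age_transform,
              regions = regions, top_n = top_n, loo = loo, seed = seed)
  for (f in c("expression", "metadata", "fasta", "elements")) {
    if (!file.exists(cfg[[f]])) {
      stop("config$", f, ": file not found: ", cfg[[f]], call. = FALSE)
    }
  }
  stopifnot(cfg$min_similarity >= 0, cfg$min_similarity <= 1,
            cfg$min_range >= 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$method %in% c("pearson", "spearman"),
            cfg$age_transform %in% c("log2", "linear"))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; relative input paths are resolved against the
#'   YAML file's directory.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  for (f in c("expression", "metadata", "fasta", "elements")) {
    if (!is.null(raw[[f]]) && !file.exists(raw[[f]])) {
      raw[[f]] <- file.path(base, raw[[f]])
    }
  }
  do.call(pipeline_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full switch-detection pipeline
#'
#' Orchestrates candidate enumeration (pathway-element co-membership +
#' sequence similarity), the per-region anti-correlation trend screen,
#' per-region age-corrected (residual) correlations, cross-region
#' ranking, and the heatmap-style report table. When `out_dir` is
#' given, every stage's table is written as TSV with the governing
#' parameters as `#`-comment header lines, plus a YAML run manifest
#' (config, config hash, seed, package version) sufficient to re-run
#' any stage in isolation.
#'
#' @param config a [pipeline_config()], a path to a YAML file, or a
#'   plain list of [pipeline_config()] arguments.
#' @param out_dir optional output directory.
#' @return a list of class `pipeline_result`: `config`, `candidates`,
#'   `trend_screen`, `residual`, `report`, `ranked`, `heatmap`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  es <- .stage("read_expression",
               read_expression(config$expression, config$metadata))
  seqs <- .stage("read_fasta", read_protein_fasta(config$fasta))
  elements <- .stage("read_pathway_elements",
                     read_pathway_elements(config$elements))
  candidates <- .stage("enumerate_candidates",
    enumerate_candidates(elements, seqs, min_similarity = config$min_similarity))

  regions <- config$regions
  if (is.null(regions)) regions <- sort(unique(es$samples$region))

  if (nrow(candidates) == 0) {
    warning("no candidate pairs pass the similarity threshold; ",
            "emitting an empty report", call. = FALSE)
    empty <- tibble::tibble()
    res <- structure(list(config = config, candidates = candidates,
                          trend_screen = empty, residual = empty,
                          report = empty, ranked = empty, heatmap = empty),
                     class = "pipeline_result")
    if (!is.null(out_dir)) .write_pipeline(res, out_dir)
    return(res)
  }

  trend_screen <- .stage("trend_screen",
    screen_regions(es, candidates[c("gene_a", "gene_b")], regions = regions,
                   method = config$method, min_range = config$min_range,
                   alpha = config$alpha))
  residual <- .stage("residual_correlation",
    purrr::map_dfr(regions, function(r) {
      residual_screen(es, candidates[c("gene_a", "gene_b")], r,
                      method = config$method, min_range = config$min_range,
                      alpha = config$alpha, window = config$window,
                      age_transform = config$age_transform)
    }))

  loo_tbl <- if (isTRUE(config$loo)) {
    .stage("loo_r2", {
      tested <- dplyr::filter(trend_screen, .data$tested)
      gene_region <- dplyr::distinct(dplyr::bind_rows(
        dplyr::select(tested, gene = "gene_a", "region"),
        dplyr::select(tested, gene = "gene_b", "region")))
      dplyr::mutate(gene_region,
        r2_loo = purrr::map2_dbl(.data$gene, .data$region, function(g, r) {
          loo_r2(expression_profile(es, g, r), window = config$window,
                 age_transform = config$age_transform)
        }))
    })
  } else NULL

  report <- .stage("report", {
    dplyr::left_join(
      dplyr::select(trend_screen, "gene_a", "gene_b", "region",
                    "passed_range_a", "passed_range_b", "tested",
                    trend_rho = "rho", trend_p = "p_value",
                    trend_q = "q_value", "n_samples",
                    "significant_switch", "significant_abs"),
      dplyr::select(residual, "gene_a", "gene_b", "region",
                    "raw_rho", "trend_corr", "resid_rho", "resid_p",
                    "resid_q", "significant_residual"),
      by = c("gene_a", "gene_b", "region")) |>
      dplyr::left_join(dplyr::select(candidates, "gene_a", "gene_b",
                                     "similarity", "element_ids"),
                       by = c("gene_a", "gene_b")) |>
      dplyr::relocate("similarity", .after = "region")
  })
  if (!is.null(loo_tbl)) {
    report <- dplyr::left_join(report,
      dplyr::rename(loo_tbl, gene_a = "gene", r2_loo_a = "r2_loo"),
      by = c("gene_a", "region")) |>
      dplyr::left_join(
        dplyr::rename(loo_tbl, gene_b = "gene", r2_loo_b = "r2_loo"),
        by = c("gene_b", "region"))
  }
  ranked <- .stage("rank_pairs", rank_pairs(trend_screen))
  heatmap <- .stage("render_heatmap_table",
                    render_heatmap_table(report, top_n = config$top_n,
                                         alpha = config$alpha))
  res <- structure(list(config = config, candidates = candidates,
                        trend_screen = trend_screen, residual = residual,
                        report = report, ranked = ranked, heatmap = heatmap),
                   class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d candidate pair(s), %d region(s); %d significant switch row(s)\n",
    nrow(x$candidates),
    if (nrow(x$report) > 0) length(unique(x$report$region)) else 0,
    if (nrow(x$report) > 0) sum(x$report$significant_switch, na.rm = TRUE) else 0))
  invisible(x)
}

.write_tsv_commented <- function(df, path, params) {
  hdr <- paste0("# ", names(params), ": ",
                vapply(params, function(v) paste(format(v), collapse = ","),
                       character(1)))
  writeLines(hdr, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
}

.write_pipeline <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- res$config
  params <- list(min_similarity = cfg$min_similarity,
                 min_range = cfg$min_range, alpha = cfg$alpha,
                 method = cfg$method, window = cfg$window,
                 age_transform = cfg$age_transform, seed = cfg$seed)
  for (nm in c("candidates", "trend_screen", "residual", "report",
               "ranked", "heatmap")) {
    if (nrow(res[[nm]]) > 0) {
      .write_tsv_commented(res[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                           params)
    }
  }
  manifest <- list(
    config = lapply(unclass(cfg), function(v) if (is.null(v)) "all" else v),
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    package = "devswitch",
    package_version = as.character(utils::packageVersion("devswitch")),
    inputs = lapply(cfg[c("expression", "metadata", "fasta", "elements")],
                    function(p) list(path = p, size = file.size(p))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(res)
}

#' Heatmap-style ranked report table
#'
#' Long pair-by-region table of `-log10(q)` scores mirroring the
#' cross-region significance heatmaps: a cell is marked missing (the
#' "gray pixel" rule) when the pair failed the expression-range filter
#' in that region or its q-value is not significant at `alpha`. Pairs
#' are ranked by the mean score over their tested regions and the top
#' `top_n` kept; pairs filtered everywhere are dropped.
#'
#' @param report the pipeline's per-pair/region report (needs `gene_a`,
#'   `gene_b`, `region`, `tested` and a q-value column).
#' @param top_n number of top-ranked pairs to keep.
#' @param score `"trend"` (uses `trend_q`) or `"residual"` (uses
#'   `resid_q`).
#' @param alpha significance threshold for the gray rule.
#' @return tibble: `rank`, `gene_a`, `gene_b`, `region`, `score`
#'   (`-log10(q)`, NA where missing), `missing`.
#' @export
render_heatmap_table <- function(report, top_n = 20,
                                 score = c("trend", "residual"),
                                 alpha = 0.01) {
  score <- match.arg(score)
  if (nrow(report) == 0) stop("empty report", call. = FALSE)
  q_col <- if (score == "trend") "trend_q" else "resid_q"
  if (!q_col %in% names(report)) {
    q_col <- if ("q_value" %in% names(report)) "q_value" else q_col
  }
  stopifnot(q_col %in% names(report))
  long <- dplyr::mutate(report,
    score = -log10(.data[[q_col]]),
    missing = !.data$tested | is.na(.data[[q_col]]) | .data[[q_col]] >= alpha,
    score = ifelse(.data$missing, NA_real_, .data$score))
  # rank on the gray-masked scores: a filtered or insignificant cell is
  # excluded from the pair's cross-region mean
  ranked <- long |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(mean_score = mean(.data$score, na.rm = TRUE),
                     n_regions = sum(!is.na(.data$score)), .groups = "drop") |>
    dplyr::filter(.data$n_regions > 0) |>
    dplyr::arrange(dplyr::desc(.data$mean_score), .data$gene_a, .data$gene_b) |>
    dplyr::mutate(rank = dplyr::row_number())
  top <- utils::head(ranked, top_n)
  long |>
    dplyr::inner_join(dplyr::select(top, "gene_a", "gene_b", "rank"),
                      by = c("gene_a", "gene_b")) |>
    dplyr::select("rank", "gene_a", "gene_b", "region", "score", "missing") |>
    dplyr::arrange(.data$rank, .data$region)
}

.random_peptide <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.mutate_peptide <- function(seq, frac) {
  chars <- strsplit(seq, "")[[1]]
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  idx <- sample(length(chars), round(frac * length(chars)))
  for (i in idx) chars[i] <- sample(setdiff(alphabet, chars[i]), 1)
  paste(chars, collapse = "")
}

#' Generate a bundled demonstration dataset
#'
#' Simulates a two-region cohort of 200 donors with one planted switch
#' pair and
#' writes every input the pipeline needs: expression + metadata TSVs,
#' a synthetic protein FASTA in which the planted pair is ~70%
#' identical, a decoy element pair with similar sequences but no
#' planted structure, a low-similarity pair that the similarity filter
#' must drop, and the pathway-element table tying them together.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param n_subjects donors per region.
#' @param regions region codes.
#' @return list with `paths` (named input files), `cohort` (the
#'   `synthetic_cohort`) and `config` (a ready [pipeline_config()]).
#' @export
demo_inputs <- function(dir = tempfile("devswitch-demo-"), seed = 1,
                        n_subjects = 200, regions = c("CBC", "HIP")) {
  cfg <- cohort_config(regions = regions, n_subjects = n_subjects,
                       pairs = list(switch_pair_spec()),
                       n_noise_genes = 20, n_hkg_genes = 10)
  cohort <- simulate_cohort(cfg, seed = seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- write_cohort(cohort, dir)

  seqs <- .with_seed(seed + 1, function() {
    base_sw <- .random_peptide(140)
    base_decoy <- .random_peptide(120)
    list(SW1A = base_sw,
         SW1B = .mutate_peptide(base_sw, 0.30),
         NOISE001 = base_decoy,
         NOISE002 = .mutate_peptide(base_decoy, 0.30),
         NOISE003 = .random_peptide(110),
         NOISE004 = .random_peptide(110))
  })
  fasta <- file.path(dir, "proteins.fasta")
  writeLines(unlist(purrr::imap(seqs, function(s, id) c(paste0(">", id), s))),
             fasta)
  elements <- file.path(dir, "elements.tsv")
  readr::write_tsv(tibble::tribble(
    ~pathway_id, ~element_id, ~gene_symbol,
    "04724", "RECEPTOR_SW", "SW1A",
    "04724", "RECEPTOR_SW", "SW1B",
    "04724", "DECOY_EL",    "NOISE001",
    "04724", "DECOY_EL",    "NOISE002",
    "04726", "LOWSIM_EL",   "NOISE003",
    "04726", "LOWSIM_EL",   "NOISE004"), elements)

  paths <- c(paths, fasta = fasta, elements = elements)
  config <- pipeline_config(expression = unname(paths["expression"]),
                            metadata = unname(paths["metadata"]),
                            fasta = fasta, elements = elements,
                            regions = regions, seed = seed)
  list(paths = paths, cohort = cohort, config = config)
}
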