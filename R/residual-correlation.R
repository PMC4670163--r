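#' Age-corrected correlation between two genes
#'
#' Separates the two notions of co-expression across a developmental
#' cohort: the *trend correlation* — the correlation of the two fitted
#' population age-trends evaluated at the sample ages, capturing the
#' life-long rise/fall pattern — and the *age-corrected (residual)
#' correlation* — the correlation of the fluctuations around each trend,
#' capturing subject-to-subject co-variation once the population effect
#' of age is removed. The latter is the nonlinear analogue of the
#' partial correlation given age; with a linear trend model the two
#' coincide exactly.
#'
#' @param x,y profile tibbles (as from [expression_profile()]) sharing
#'   the same sample set (matched on `sample_id`).
#' @param method correlation method for raw and residual correlations;
#'   Pearson by default, Spearman selectable.
#' @param age_window optional `c(lo, hi)` in post-conception days; the
#'   samples are restricted to the window and the trends refitted
#'   inside it (prenatal/postnatal splits). At least 8 samples must
#'   remain.
#' @param ... passed to [fit_trend_spline()] (e.g. `age_transform`,
#'   `degree`, `n_knots` to force the linear limit).
#' @return an object of class `age_corrected` whose `summary` is a
#'   one-row tibble: `gene_a`, `gene_b`, `raw_rho`, `raw_p`,
#'   `trend_corr`, `resid_rho`, `resid_p`, `n_samples`, `age_lo`,
#'   `age_hi`; the two `trend_fit`s are kept in `fit_a`, `fit_b`.
#' @export
age_corrected_correlation <- function(x, y, method = c("pearson", "spearman"),
                                      age_window = NULL, ...) {
  method <- match.arg(method)
  stopifnot(is.data.frame(x), is.data.frame(y),
            all(c("sample_id", "age_pcd", "value") %in% names(x)),
            all(c("sample_id", "age_pcd", "value") %in% names(y)))
  if (!setequal(x$sample_id, y$sample_id)) {
    stop("profiles do not share the same sample set", call. = FALSE)
  }
  y <- y[match(x$sample_id, y$sample_id), , drop = FALSE]
  if (!is.null(age_window)) {
    keep <- x$age_pcd >= age_window[1] & x$age_pcd <= age_window[2]
    x <- x[keep, , drop = FALSE]
    y <- y[keep, , drop = FALSE]
  }
  if (nrow(x) < 8) {
    stop("fewer than 8 samples after age-window restriction", call. = FALSE)
  }
  ord <- order(x$age_pcd)
  x <- x[ord, , drop = FALSE]
  y <- y[ord, , drop = FALSE]

  raw <- trend_correlation(x$value, y$value, method = method)
  fit_a <- fit_trend_spline(x, ...)
  fit_b <- fit_trend_spline(y, ...)
  trend_corr <- if (stats::sd(fit_a$fitted) == 0 || stats::sd(fit_b$fitted) == 0) {
    NA_real_
  } else {
    stats::cor(fit_a$fitted, fit_b$fitted)
  }
  ra <- fit_a$residuals
  rb <- fit_b$residuals
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    resid_rho <- NA_real_
    resid_p <- NA_real_
  } else {
    rc <- trend_correlation(ra, rb, method = method)
    resid_rho <- rc$rho
    resid_p <- rc$p_value
  }
  structure(list(
    summary = tibble::tibble(
      gene_a = if ("gene" %in% names(x)) x$gene[1] else NA_character_,
      gene_b = if ("gene" %in% names(y)) y$gene[1] else NA_character_,
      raw_rho = raw$rho, raw_p = raw$p_value,
      trend_corr = trend_corr,
      resid_rho = resid_rho, resid_p = resid_p,
      n_samples = nrow(x), method = method,
      age_lo = if (is.null(age_window)) min(x$age_pcd) else age_window[1],
      age_hi = if (is.null(age_window)) max(x$age_pcd) else age_window[2]),
    fit_a = fit_a, fit_b = fit_b
  ), class = "age_corrected")
}

#' @export
print.age_corrected <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<age_corrected> %s vs %s: raw rho %.3f, trend corr %.3f, residual rho %.3f (p = %.3g), n = %d\n",
    s$gene_a, s$gene_b, s$raw_rho, s$trend_corr, s$resid_rho, s$resid_p,
    s$n_samples))
  invisible(x)
}

#' @export
tidy.age_corrected <- function(x, ...) x$summary

#' First-order partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of
#' `z` from both: `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' equivalently the correlation of the residuals from least-squares
#' lines on `z`. The age-corrected correlation reduces to this when the
#' trend model is linear in age.
#'
#' @param x,y,z equal-length numeric vectors, n >= 4.
#' @return the partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  if (length(x) < 4) stop("need at least 4 observations", call. = FALSE)
  r_xy <- stats::cor(x, y)
  r_xz <- stats::cor(x, z)
  r_yz <- stats::cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("partial correlation undefined: a variable is collinear with z",
         call. = FALSE)
  }
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Age-corrected correlations for candidate pairs in one region
#'
#' Runs [age_corrected_correlation()] for every candidate pair in a
#' region (after the expression-range filter) and adjusts residual
#' p-values by Benjamini-Hochberg within the region's family of tested
#' pairs.
#'
#' @inheritParams screen_region
#' @param age_window optional `c(lo, hi)` in post-conception days.
#' @param ... passed to [fit_trend_spline()].
#' @return tibble, one row per pair: `raw_rho`, `trend_corr`,
#'   `resid_rho`, `resid_p`, `resid_q`, `n_samples`, range-filter flags.
#' @export
residual_screen <- function(es, pairs, region, method = c("pearson", "spearman"),
                            min_range = 1.5, alpha = 0.01, age_window = NULL,
                            ...) {
  method <- match.arg(method)
  stopifnot(inherits(es, "expression_set"))
  keep <- es$samples$region == region
  if (!any(keep)) stop("region not present in metadata: ", region, call. = FALSE)
  sub <- es$values[, keep, drop = FALSE]
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  rng <- apply(sub[genes, , drop = FALSE], 1, function(v) max(v) - min(v))
  pass <- rng >= min_range

  out <- dplyr::mutate(tibble::as_tibble(pairs),
    region = region,
    passed_range_a = unname(pass[.data$gene_a]),
    passed_range_b = unname(pass[.data$gene_b]),
    tested = .data$passed_range_a & .data$passed_range_b)

  res <- purrr::pmap(list(out$gene_a, out$gene_b, out$tested),
                     function(a, b, tested) {
    empty <- tibble::tibble(raw_rho = NA_real_, trend_corr = NA_real_,
                            resid_rho = NA_real_, resid_p = NA_real_,
                            n_samples = NA_integer_)
    if (!tested) return(empty)
    ac <- age_corrected_correlation(expression_profile(es, a, region),
                                    expression_profile(es, b, region),
                                    method = method, age_window = age_window,
                                    ...)
    dplyr::select(ac$summary, "raw_rho", "trend_corr", "resid_rho",
                  "resid_p", "n_samples")
  })
  out <- dplyr::bind_cols(out, dplyr::bind_rows(res))
  out$resid_q <- NA_real_
  ok <- out$tested & !is.na(out$resid_p)
  if (any(ok)) out$resid_q[ok] <- fdr_bh(out$resid_p[ok])
  dplyr::mutate(out,
    method = method,
    significant_residual = !is.na(.data$resid_q) & .data$resid_q < alpha)
}

#' Rank pairs by their average score across regions
#'
#' Orders pairs the way the cross-region heatmaps are ordered: by the
#' mean score over the regions where the pair was actually tested
#' (filtered/missing regions are excluded from the mean, not counted as
#' zero). The default score is `-log10(q)`; `abs_rho` ranks by the
#' absolute correlation instead. Ties break lexicographically on
#' (gene_a, gene_b).
#'
#' @param results long tibble with columns `gene_a`, `gene_b`, `region`
#'   and the score ingredients (`q_value` or `resid_q` for
#'   `"neglog10_q"`; `rho` or `resid_rho` for `"abs_rho"`).
#' @param score `"neglog10_q"` (default) or `"abs_rho"`.
#' @param q_col,rho_col column names to use; defaults pick the trend
#'   screen's columns, falling back to the residual screen's.
#' @return tibble, one row per pair: `gene_a`, `gene_b`, `mean_score`,
#'   `n_regions`, `rank`.
#' @export
rank_pairs <- function(results, score = c("neglog10_q", "abs_rho"),
                       q_col = NULL, rho_col = NULL) {
  score <- match.arg(score)
  if (is.null(q_col)) {
    q_col <- if ("q_value" %in% names(results)) "q_value" else "resid_q"
  }
  if (is.null(rho_col)) {
    rho_col <- if ("rho" %in% names(results)) "rho" else "resid_rho"
  }
  col <- if (score == "neglog10_q") q_col else rho_col
  stopifnot(col %in% names(results))
  vals <- if (score == "neglog10_q") {
    -log10(results[[col]])
  } else {
    abs(results[[col]])
  }
  ranked <- results |>
    dplyr::mutate(.score = vals) |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(mean_score = mean(.data$.score, na.rm = TRUE),
                     n_regions = sum(!is.na(.data$.score)),
                     .groups = "drop") |>
    dplyr::filter(.data$n_regions > 0) |>
    dplyr::arrange(dplyr::desc(.data$mean_score), .data$gene_a, .data$gene_b)
  dplyr::mutate(ranked, rank = dplyr::row_number())
}
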