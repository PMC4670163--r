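#' Expression-range filter
#'
#' A gene is considered differentially expressed over life in a region
#' only if its expression range (maximum minus minimum, log2 scale)
#' reaches `min_range`; genes strictly below are excluded from the
#' screen. The default 1.5 corresponds to an ~2.8-fold change.
#'
#' @param values numeric vector of log2 expression values, or a profile
#'   tibble with a `value` column.
#' @param min_range minimum range in log2 units; default 1.5.
#' @return `TRUE` if the profile passes.
#' @export
range_filter <- function(values, min_range = 1.5) {
  if (is.data.frame(values)) values <- values$value
  if (length(values) == 0) stop("empty profile", call. = FALSE)
  if (length(values) < 2) stop("range filter needs at least 2 samples", call. = FALSE)
  (max(values) - min(values)) >= min_range
}

.profile_values <- function(x) {
  if (is.data.frame(x)) x$value else x
}

#' Correlation between two expression profiles
#'
#' Pearson or Spearman correlation (midranks for ties) with a two-sided
#' p-value between the life-long expression profiles of two genes
#' measured on the same samples. Used both for the anti-correlation
#' trend screen and, applied to residuals, for age-corrected
#' correlation.
#'
#' @param x,y numeric vectors, or profile tibbles sharing an identical
#'   `sample_id` list.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return one-row tibble: `rho`, `p_value`, `method`, `n_samples`.
#' @export
trend_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.data.frame(x) && is.data.frame(y)) {
    if (!identical(x$sample_id, y$sample_id)) {
      stop("profiles do not share an identical sample list", call. = FALSE)
    }
  }
  xv <- .profile_values(x)
  yv <- .profile_values(y)
  if (length(xv) != length(yv)) stop("profiles differ in length", call. = FALSE)
  n <- length(xv)
  if (n < 4) stop("need at least 4 samples for a correlation", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("zero-variance profile: apply the range filter upstream", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(xv, yv, method = method,
                                         alternative = "two.sided"))
  tibble::tibble(rho = unname(ct$estimate),
                 p_value = max(ct$p.value, .Machine$double.xmin),
                 method = method, n_samples = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, `q_(i) = min_{j>=i}(p_(j) * m / j)` capped
#' at 1, mapped back to the input order. A thin validated wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return numeric vector of q-values, same order as the input.
#' @export
fdr_bh <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (length(p_values) == 0) return(numeric())
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Screen one region for anti-correlated trends
#'
#' For each candidate pair: both genes must pass the expression-range
#' filter in the region; surviving pairs get a profile correlation with
#' two-sided p-value; q-values are Benjamini-Hochberg adjusted within
#' the family of all pairs tested in this region. A pair is flagged as
#' a significant switch when `q < alpha` and `rho < 0`; a two-sided
#' significance flag (`q < alpha` regardless of sign) is also emitted.
#'
#' @param es an `expression_set`.
#' @param pairs tibble with columns `gene_a`, `gene_b` (extra columns
#'   such as `similarity` are carried through).
#' @param region region code present in the metadata.
#' @param method correlation method; the screen default is Pearson.
#' @param min_range expression-range threshold (log2 units).
#' @param alpha q-value significance threshold; default 0.01.
#' @return tibble with one row per pair: range-filter flags,
#'   `rho`, `p_value`, `q_value` (NA for filtered pairs),
#'   `significant_switch`, `significant_abs`, `n_samples`.
#' @export
screen_region <- function(es, pairs, region, method = c("pearson", "spearman"),
                          min_range = 1.5, alpha = 0.01) {
  method <- match.arg(method)
  stopifnot(inherits(es, "expression_set"))
  keep <- es$samples$region == region
  if (!any(keep)) stop("region not present in metadata: ", region, call. = FALSE)
  if (sum(keep) < 4) stop("region ", region, " has fewer than 4 samples", call. = FALSE)
  sub <- es$values[, keep, drop = FALSE]
  n <- ncol(sub)

  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  missing <- setdiff(genes, rownames(es$values))
  if (length(missing) > 0) {
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rng <- apply(sub[genes, , drop = FALSE], 1, function(v) max(v) - min(v))
  pass <- rng >= min_range

  out <- dplyr::mutate(tibble::as_tibble(pairs),
    region = region,
    passed_range_a = unname(pass[.data$gene_a]),
    passed_range_b = unname(pass[.data$gene_b]),
    tested = .data$passed_range_a & .data$passed_range_b)

  res <- purrr::pmap(list(out$gene_a, out$gene_b, out$tested),
                     function(a, b, tested) {
    if (!tested) return(tibble::tibble(rho = NA_real_, p_value = NA_real_))
    tc <- trend_correlation(sub[a, ], sub[b, ], method = method)
    tibble::tibble(rho = tc$rho, p_value = tc$p_value)
  })
  out <- dplyr::bind_cols(out, dplyr::bind_rows(res))
  out$q_value <- NA_real_
  if (any(out$tested)) {
    out$q_value[out$tested] <- fdr_bh(out$p_value[out$tested])
  }
  dplyr::mutate(out,
    n_samples = n,
    method = method,
    significant_switch = !is.na(.data$q_value) & .data$q_value < alpha & .data$rho < 0,
    significant_abs = !is.na(.data$q_value) & .data$q_value < alpha)
}

#' Screen several regions
#'
#' Applies [screen_region()] to each region (all regions in the
#' metadata by default) and row-binds the results; the FDR family stays
#' per region.
#'
#' @inheritParams screen_region
#' @param regions character vector of region codes; default all.
#' @return long tibble, one row per pair x region.
#' @export
screen_regions <- function(es, pairs, regions = NULL,
                           method = c("pearson", "spearman"),
                           min_range = 1.5, alpha = 0.01) {
  method <- match.arg(method)
  if (is.null(regions)) regions <- sort(unique(es$samples$region))
  purrr::map_dfr(regions, function(r) {
    screen_region(es, pairs, r, method = method,
                  min_range = min_range, alpha = alpha)
  })
}
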