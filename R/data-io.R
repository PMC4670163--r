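#' Convert an age to post-conception days
#'
#' The package stores every age on a single internal axis: post-conception
#' days (pcd). Birth is fixed at 280 pcd (40 post-conception weeks); one
#' month is 30.44 days and one year 365.25 days, so postnatal ages are
#' `280 + 30.44 * months` or `280 + 365.25 * years`.
#'
#' @param value numeric vector of ages.
#' @param unit one of `"pcd"`, `"pcw"`, `"months"`, `"years"` (recycled
#'   against `value` if length 1).
#' @return numeric vector of ages in post-conception days.
#' @examples
#' age_to_pcd(10, "pcw")    # 70
#' age_to_pcd(1, "years")   # 645.25
#' @export
age_to_pcd <- function(value, unit) {
  stopifnot(is.numeric(value))
  unit <- rep_len(as.character(unit), length(value))
  bad <- setdiff(unique(unit), c("pcd", "pcw", "months", "years"))
  if (length(bad) > 0) {
    stop("unknown age unit(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::case_when(
    unit == "pcd"    ~ value,
    unit == "pcw"    ~ value * 7,
    unit == "months" ~ 280 + value * 30.44,
    unit == "years"  ~ 280 + value * 365.25
  )
  if (any(out <= 0, na.rm = TRUE)) {
    stop("ages must be positive after conversion to post-conception days",
         call. = FALSE)
  }
  out
}

# Birth in post-conception days; shared by the age-group table and the
# synthetic-age sampler.
.BIRTH_PCD <- 280

#' Donor age-group table
#'
#' The 13 developmental age groups used for reporting (early fetal through
#' late adulthood), as left-closed/right-open intervals on the
#' post-conception-day axis. The late-fetal group is extended to birth
#' (280 pcd) so that the intervals partition `[70, Inf)`; group labels are
#' presentation metadata only and are never used by the analysis.
#'
#' @return a tibble with columns `label`, `description`, `lower_pcd`,
#'   `upper_pcd`.
#' @export
age_group_table <- function() {
  tibble::tibble(
    label = c("EF3", "EMF4", "EMF5", "LMF6", "LF7", "EI8", "LI9", "EC10",
              "MLC11", "Adol12", "YA13", "MA14", "LA15"),
    description = c(
      "Early fetal", "Early-mid fetal", "Early-mid fetal", "Late-mid fetal",
      "Late fetal", "Neonatal and early infancy", "Late infancy",
      "Early childhood", "Middle and late childhood", "Adolescence",
      "Young adulthood", "Middle adulthood", "Late adulthood"),
    lower_pcd = c(10 * 7, 13 * 7, 16 * 7, 19 * 7, 24 * 7,
                  .BIRTH_PCD, .BIRTH_PCD + 6 * 30.44, .BIRTH_PCD + 365.25,
                  .BIRTH_PCD + 6 * 365.25, .BIRTH_PCD + 12 * 365.25,
                  .BIRTH_PCD + 20 * 365.25, .BIRTH_PCD + 40 * 365.25,
                  .BIRTH_PCD + 60 * 365.25),
    upper_pcd = c(13 * 7, 16 * 7, 19 * 7, 24 * 7, .BIRTH_PCD,
                  .BIRTH_PCD + 6 * 30.44, .BIRTH_PCD + 365.25,
                  .BIRTH_PCD + 6 * 365.25, .BIRTH_PCD + 12 * 365.25,
                  .BIRTH_PCD + 20 * 365.25, .BIRTH_PCD + 40 * 365.25,
                  .BIRTH_PCD + 60 * 365.25, Inf)
  )
}

#' Assign developmental age-group labels
#'
#' Maps ages (post-conception days) to the 13 reporting age groups of
#' [age_group_table()]. Intervals are left-closed/right-open, so a donor at
#' exactly 24 post-conception weeks falls in the late-fetal group.
#'
#' @param age_pcd numeric vector of ages in post-conception days; must be
#'   at least 70 (10 post-conception weeks), the youngest age retained in
#'   the analysis.
#' @return character vector of group labels.
#' @examples
#' assign_age_group(c(70, 24 * 7, 280 + 12 * 365.25))
#' @export
assign_age_group <- function(age_pcd) {
  stopifnot(is.numeric(age_pcd))
  if (any(age_pcd < 70)) {
    stop("age below 10 post-conception weeks (70 pcd): subjects this young ",
         "are excluded from the analysis", call. = FALSE)
  }
  tab <- age_group_table()
  idx <- findInterval(age_pcd, c(tab$lower_pcd, Inf), rightmost.closed = FALSE)
  tab$label[idx]
}

#' The default brain-region vocabulary
#'
#' 17 region codes: four prefrontal (DFC, OFC, VFC, MFC), three
#' frontal-parietal (M1C, S1C, IPC), four temporal-occipital (ITC, STC,
#' A1C, V1C), five subcortical (AMY, CBC, HIP, MD, STR) and PFC
#' (prefrontal cortex in single-region cohorts).
#'
#' @return character vector of region codes.
#' @export
brain_region_codes <- function() {
  c("DFC", "OFC", "VFC", "MFC",
    "M1C", "S1C", "IPC",
    "ITC", "STC", "A1C", "V1C",
    "AMY", "CBC", "HIP", "MD", "STR",
    "PFC")
}

#' Brain-related KEGG pathways used for candidate selection
#'
#' The default list of 17 KEGG pathways whose diagram elements supply
#' candidate variant pairs: the nervous-system synapse pathways,
#' long-term potentiation/depression, the neurodegenerative-disease and
#' substance-dependence pathways, and neuroactive ligand-receptor
#' interaction.
#'
#' @return a tibble with columns `pathway`, `kegg_id`, `category`.
#' @export
kegg_brain_pathways <- function() {
  tibble::tribble(
    ~pathway,                                   ~kegg_id, ~category,
    "Long-term potentiation (LTP)",             "04020", "Nervous system",
    "Glutamatergic synapse",                    "04724", "Nervous system",
    "Cholinergic synapse",                      "04725", "Nervous system",
    "Serotonergic synapse",                     "04726", "Nervous system",
    "GABAergic synapse",                        "04727", "Nervous system",
    "Dopaminergic synapse",                     "04728", "Nervous system",
    "Long-term depression",                     "04730", "Nervous system",
    "Alzheimer's disease",                      "05010", "Neurodegenerative diseases",
    "Parkinson's disease",                      "05012", "Neurodegenerative diseases",
    "Amyotrophic lateral sclerosis (ALS)",      "05014", "Neurodegenerative diseases",
    "Huntington's disease",                     "05016", "Neurodegenerative diseases",
    "Cocaine addiction",                        "05030", "Substance dependence",
    "Amphetamine addiction",                    "05031", "Substance dependence",
    "Morphine addiction",                       "05032", "Substance dependence",
    "Nicotine addiction",                       "05033", "Substance dependence",
    "Alcoholism",                               "05034", "Substance dependence",
    "Neuroactive ligand-receptor interaction",  "04080", "Signaling molecules and interaction"
  )
}

new_expression_set <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values))
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "subject_id", "region", "age_pcd")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0) {
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene identifiers: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!identical(colnames(values), samples$sample_id)) {
    stop("matrix columns and metadata rows are not aligned", call. = FALSE)
  }
  if (anyDuplicated(samples[c("subject_id", "region")])) {
    stop("duplicate (subject_id, region) pairs in sample metadata", call. = FALSE)
  }
  if (any(samples$age_pcd <= 0)) {
    stop("non-positive ages in sample metadata", call. = FALSE)
  }
  structure(list(values = values, samples = samples), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d genes x %d samples, %d region(s): %s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$region)),
              paste(sort(unique(x$samples$region)), collapse = ", ")))
  invisible(x)
}

#' Read an expression matrix with sample metadata
#'
#' Reads a genes-by-samples expression table (TSV, first column gene ids,
#' one column per sample) plus a sample-metadata TSV with columns
#' `sample_id`, `subject_id`, `region` and either `age_pcd` or
#' `age_value` + `age_unit` (`pcw`/`pcd`/`months`/`years`). Ages are
#' converted to post-conception days; expression values are taken as-is
#' and assumed already on the log2 scale (quantile normalisation and log
#' transformation are upstream concerns).
#'
#' @param matrix_path path to the expression TSV (gzip accepted).
#' @param metadata_path path to the metadata TSV (gzip accepted).
#' @param region_vocabulary character vector of allowed region codes, or
#'   `NULL` to skip validation. Unknown codes raise a warning.
#' @return an `expression_set`: a genes x samples numeric matrix plus a
#'   sample tibble.
#' @export
read_expression <- function(matrix_path, metadata_path,
                            region_vocabulary = brain_region_codes()) {
  mat_raw <- readr::read_tsv(matrix_path, col_types = readr::cols(
    .default = readr::col_character()))
  if (ncol(mat_raw) < 2) stop("expression matrix needs a gene column and at least one sample column", call. = FALSE)
  genes <- mat_raw[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids in expression matrix: ",
         paste(utils::head(unique(genes[duplicated(genes)]), 5), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(mat_raw[-1])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric expression value '%s' at gene %s, sample column %s",
                 vals[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]), call. = FALSE)
  }
  rownames(num) <- genes

  meta <- readr::read_tsv(metadata_path, col_types = readr::cols())
  req <- c("sample_id", "subject_id", "region")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"age_pcd" %in% names(meta)) {
    if (!all(c("age_value", "age_unit") %in% names(meta))) {
      stop("metadata needs either age_pcd or age_value + age_unit", call. = FALSE)
    }
    meta$age_pcd <- age_to_pcd(meta$age_value, meta$age_unit)
  }
  meta$sample_id <- as.character(meta$sample_id)

  unmatched <- setdiff(colnames(num), meta$sample_id)
  if (length(unmatched) > 0) {
    stop("matrix sample column(s) absent from metadata: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(colnames(num), meta$sample_id), , drop = FALSE]

  if (!is.null(region_vocabulary)) {
    unknown <- setdiff(unique(meta$region), region_vocabulary)
    if (length(unknown) > 0) {
      warning("region code(s) outside the configured vocabulary: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  new_expression_set(num, meta[c("sample_id", "subject_id", "region", "age_pcd")])
}

#' Write an expression set back to TSV
#'
#' Inverse of [read_expression()]: writes the genes-by-samples matrix and
#' the metadata tibble as two TSV files, preserving values exactly
#' (full-precision formatting).
#'
#' @param es an `expression_set`.
#' @param matrix_path,metadata_path output paths.
#' @return `es`, invisibly.
#' @export
write_expression <- function(es, matrix_path, metadata_path) {
  stopifnot(inherits(es, "expression_set"))
  df <- tibble::as_tibble(es$values, rownames = "gene")
  readr::write_tsv(df, matrix_path)
  readr::write_tsv(es$samples, metadata_path)
  invisible(es)
}

#' Extract one gene's expression profile in one region
#'
#' Returns a tidy per-sample tibble for a single gene restricted to one
#' region, sorted by ascending age — the unit of data every trend and
#' correlation operation consumes.
#'
#' @param es an `expression_set`.
#' @param gene gene identifier (a matrix row).
#' @param region region code, or `NULL` to take all samples.
#' @return tibble with columns `gene`, `sample_id`, `subject_id`,
#'   `region`, `age_pcd`, `value`, sorted by `age_pcd`.
#' @export
expression_profile <- function(es, gene, region = NULL) {
  stopifnot(inherits(es, "expression_set"))
  if (!gene %in% rownames(es$values)) {
    stop("gene not found: ", gene, call. = FALSE)
  }
  keep <- if (is.null(region)) rep(TRUE, nrow(es$samples)) else es$samples$region == region
  if (!any(keep)) stop("no samples in region ", region, call. = FALSE)
  out <- es$samples[keep, , drop = FALSE]
  out$gene <- gene
  out$value <- unname(es$values[gene, keep])
  dplyr::arrange(
    dplyr::select(out, "gene", "sample_id", "subject_id", "region", "age_pcd", "value"),
    .data$age_pcd)
}

#' Read protein sequences from FASTA
#'
#' Sequence ids are the first whitespace-delimited token of each header;
#' residues are uppercased and validated against the 20-letter amino-acid
#' alphabet plus `X`.
#'
#' @param path FASTA file (gzip accepted).
#' @return tibble with columns `id`, `residues`, `length`.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seqs)
  if (!all(ok)) {
    stop("illegal residue characters in sequence(s): ",
         paste(ids[!ok], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = ids, residues = unname(seqs),
                 length = unname(nchar(seqs)))
}

#' Read a pathway-element membership table
#'
#' A pathway element is a node of a pathway diagram grouping functionally
#' interchangeable proteins (e.g. the NMDA-receptor subunits); candidate
#' variant pairs are formed only within elements. Input is a TSV with
#' columns `pathway_id`, `element_id`, `gene_symbol`; duplicate
#' (element, gene) rows are collapsed.
#'
#' @param path TSV file (gzip accepted).
#' @return tibble with one row per (pathway_id, element_id, gene_symbol).
#' @export
read_pathway_elements <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  req <- c("pathway_id", "element_id", "gene_symbol")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    stop("pathway-element table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0) stop("empty pathway-element table: ", path, call. = FALSE)
  dplyr::distinct(dplyr::select(tab, dplyr::all_of(req)))
}
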