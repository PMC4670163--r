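#' Global protein alignment with affine gap costs
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with the BLAST
#' 2 Sequences gap convention: a gap of length L costs
#' `gap_open + gap_extend * L` (11 + L by default), and end gaps are
#' penalised like any other gap. The dynamic program is delegated to
#' [Biostrings::pairwiseAlignment()]; ties among co-optimal alignments
#' are broken by its deterministic traceback, and the reported identity
#' refers to that canonical alignment (the optimal score is unique).
#'
#' @param seq_a,seq_b amino-acid strings (20-letter alphabet plus `X`).
#' @param substitution_matrix scoring matrix name or matrix; default
#'   `"BLOSUM62"`.
#' @param gap_open,gap_extend gap existence and per-residue extension
#'   costs (positive penalties).
#' @return a list of class `global_alignment` with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score`,
#'   `n_identical` (equal, non-gap aligned positions) and `similarity`
#'   (`n_identical / max(nchar(seq_a), nchar(seq_b))`).
#' @examples
#' align_global("HEAGAWGHEE", "PAWHEAE")
#' @export
align_global <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  mat <- if (is.character(substitution_matrix)) {
    get(data(list = substitution_matrix, package = "Biostrings",
             envir = environment()))
  } else substitution_matrix
  for (s in c(seq_a, seq_b)) {
    chars <- unique(strsplit(s, "")[[1]])
    bad <- setdiff(chars, rownames(mat))
    if (length(bad) > 0) {
      stop("residue character(s) not in the substitution matrix: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  aligned_a <- as.character(Biostrings::alignedPattern(aln))
  aligned_b <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  n_identical <- sum(ca == cb & ca != "-")
  structure(list(
    aligned_a = unname(aligned_a),
    aligned_b = unname(aligned_b),
    score = Biostrings::score(aln),
    n_identical = n_identical,
    similarity = sequence_similarity(n_identical, nchar(seq_a), nchar(seq_b))
  ), class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf("<global_alignment> score %.1f, %d identities, similarity %.3f\n",
              x$score, x$n_identical, x$similarity))
  cat(x$aligned_a, x$aligned_b, sep = "\n")
  invisible(x)
}

#' Sequence similarity of an alignment
#'
#' The fraction of identical residues out of the number of residues in
#' the longer of the two unaligned sequences.
#'
#' @param n_identical number of identical aligned residue pairs, or a
#'   `global_alignment` object.
#' @param len_a,len_b raw (ungapped) sequence lengths.
#' @return a number in `[0, 1]`.
#' @export
sequence_similarity <- function(n_identical, len_a, len_b) {
  if (inherits(n_identical, "global_alignment")) {
    n_identical <- n_identical$n_identical
  }
  stopifnot(n_identical >= 0, len_a >= 1, len_b >= 1,
            n_identical <= min(len_a, len_b))
  n_identical / max(len_a, len_b)
}

#' Enumerate candidate variant pairs
#'
#' Forms all unordered gene pairs that co-reside in at least one pathway
#' element and whose protein sequences reach the similarity threshold
#' under global alignment (pairs strictly below the threshold are
#' dropped; the boundary value is kept). Pairs found in several elements
#' are reported once with their element ids unioned.
#'
#' @param elements tibble with columns `pathway_id`, `element_id`,
#'   `gene_symbol` (as from [read_pathway_elements()]).
#' @param sequences tibble with columns `id`, `residues` (as from
#'   [read_protein_fasta()]); ids are matched to gene symbols. Genes
#'   without a sequence are skipped with a warning.
#' @param min_similarity similarity threshold; default 0.30.
#' @param ... passed to [align_global()].
#' @return tibble with columns `gene_a`, `gene_b`
#'   (lexicographically ordered), `similarity`, `element_ids`
#'   (semicolon-joined), `n_elements`, sorted by (`gene_a`, `gene_b`).
#' @export
enumerate_candidates <- function(elements, sequences, min_similarity = 0.30,
                                 ...) {
  stopifnot(all(c("pathway_id", "element_id", "gene_symbol") %in% names(elements)),
            all(c("id", "residues") %in% names(sequences)))
  seq_map <- stats::setNames(sequences$residues, sequences$id)
  missing_genes <- setdiff(unique(elements$gene_symbol), names(seq_map))
  if (length(missing_genes) > 0) {
    warning("skipping gene(s) without a protein sequence: ",
            paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  el <- dplyr::filter(elements, .data$gene_symbol %in% names(seq_map))
  el <- dplyr::mutate(el,
    element_key = paste(.data$pathway_id, .data$element_id, sep = ":"))

  pair_rows <- el |>
    dplyr::group_by(.data$element_key) |>
    dplyr::summarise(genes = list(sort(unique(.data$gene_symbol))),
                     .groups = "drop") |>
    dplyr::mutate(pairs = purrr::map(.data$genes, function(g) {
      if (length(g) < 2) return(tibble::tibble(gene_a = character(),
                                               gene_b = character()))
      cmb <- utils::combn(g, 2)
      tibble::tibble(gene_a = cmb[1, ], gene_b = cmb[2, ])
    })) |>
    dplyr::select("element_key", "pairs") |>
    tidyr::unnest("pairs")
  if (nrow(pair_rows) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          similarity = numeric(), element_ids = character(),
                          n_elements = integer()))
  }

  pairs <- pair_rows |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(element_ids = paste(sort(unique(.data$element_key)),
                                         collapse = ";"),
                     n_elements = dplyr::n_distinct(.data$element_key),
                     .groups = "drop")
  pairs$similarity <- purrr::map2_dbl(pairs$gene_a, pairs$gene_b, function(a, b) {
    align_global(seq_map[[a]], seq_map[[b]], ...)$similarity
  })
  pairs |>
    dplyr::filter(.data$similarity >= min_similarity) |>
    dplyr::select("gene_a", "gene_b", "similarity", "element_ids", "n_elements") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}
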