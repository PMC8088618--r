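## Structure-versus-network similarity analysis: do interactome embeddings
## capture information beyond sequence homology (proteins) and beyond
## chemical-structure similarity (compounds)?

#' Local alignment similarity of two protein sequences
#'
#' Built-in scheme: Smith-Waterman local alignment score under BLOSUM62 with
#' gap open 11 / gap extend 1 (the scoring conventional for fast homology
#' search tools). Returns 0 when no positive-scoring local alignment exists.
#' Externally computed scores (e.g. from a dedicated aligner) can be used
#' instead by passing precomputed similarity functions to
#' [modality_scatter()] / [nearest_training_pair()].
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @param gap_open,gap_extend positive gap penalties.
#' @return Non-negative alignment score.
#' @export
sequence_similarity <- function(seq_a, seq_b, gap_open = 11, gap_extend = 1) {
  check_that(is.character(seq_a) && length(seq_a) == 1L && nzchar(seq_a),
             "`seq_a` must be a non-empty string")
  check_that(is.character(seq_b) && length(seq_b) == 1L && nzchar(seq_b),
             "`seq_b` must be a non-empty string")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = get("BLOSUM62"),
    gapOpening = gap_open, gapExtension = gap_extend)
  max(0, Biostrings::score(pa))
}

resolve_sim <- function(sim, pairs) {
  if (is.function(sim)) {
    vapply(seq_len(nrow(pairs)),
           function(i) sim(pairs[[1]][i], pairs[[2]][i]), 0)
  } else {
    check_that(is.numeric(sim) && length(sim) == nrow(pairs),
               "similarity vector length must match the pair list")
    as.numeric(sim)
  }
}

#' Cross-modality similarity scatter and Pearson correlation
#'
#' For a list of entity pairs, tabulates one similarity per axis (e.g.
#' sequence similarity vs embedding cosine) and reports the Pearson
#' correlation coefficient — near-zero r indicates the two modalities carry
#' complementary information.
#'
#' @param pairs data.frame whose first two columns are entity IDs.
#' @param sim_x,sim_y either a function `(id_a, id_b) -> real` or a numeric
#'   vector aligned with `pairs`.
#' @return List of class `modality_scatter`: `table` (data.frame id_a, id_b,
#'   x, y) and `pearson_r`.
#' @export
modality_scatter <- function(pairs, sim_x, sim_y) {
  check_that(is.data.frame(pairs) && nrow(pairs) >= 3,
             "need at least 3 pairs")
  x <- resolve_sim(sim_x, pairs)
  y <- resolve_sim(sim_y, pairs)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance on one axis", call. = FALSE)
  }
  tab <- data.frame(id_a = as.character(pairs[[1]]),
                    id_b = as.character(pairs[[2]]), x = x, y = y,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, pearson_r = stats::cor(x, y)),
            class = "modality_scatter")
}

#' @export
print.modality_scatter <- function(x, ...) {
  cat(sprintf("modality_scatter: %d pairs, Pearson r = %.4f\n",
              nrow(x$table), x$pearson_r))
  invisible(x)
}

#' Most similar training pairs to a test pair
#'
#' Ranks training (protein, compound) pairs by a combined similarity to the
#' test pair: the product of the per-side similarities, each normalized by
#' its maximum over the training set (so both sides contribute on a common
#' scale). Ties are broken by protein then compound ID for a stable order.
#'
#' @param test_pair list or one-row data.frame with `protein_id` and
#'   `compound_id`.
#' @param training_pairs a [labeled_pairs()] set (or data.frame with the
#'   same ID columns).
#' @param protein_sim,compound_sim functions `(id_test, id_train) -> real`
#'   (e.g. wrapping [sequence_similarity()] / [jaccard()] / [cosine()]).
#' @param k number of neighbours to return.
#' @return data.frame: protein_id, compound_id, protein_similarity,
#'   compound_similarity, combined, ordered best-first.
#' @export
nearest_training_pair <- function(test_pair, training_pairs, protein_sim,
                                  compound_sim, k = 5L) {
  check_that(nrow(training_pairs) >= 1, "empty training set")
  ps <- vapply(training_pairs$protein_id,
               function(id) protein_sim(test_pair$protein_id, id), 0)
  cs <- vapply(training_pairs$compound_id,
               function(id) compound_sim(test_pair$compound_id, id), 0)
  psn <- if (max(ps) > 0) ps / max(ps) else ps
  csn <- if (max(cs) > 0) cs / max(cs) else cs
  combined <- psn * csn
  ord <- order(-combined, training_pairs$protein_id,
               training_pairs$compound_id)
  out <- data.frame(protein_id = training_pairs$protein_id,
                    compound_id = training_pairs$compound_id,
                    protein_similarity = unname(ps),
                    compound_similarity = unname(cs),
                    combined = unname(combined),
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}
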