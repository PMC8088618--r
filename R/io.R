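## Parsing of STITCH/STRING-style link tables, FASTA sequences and
## compound SMILES tables, plus negative-pair sampling.

## Read a whitespace/tab-delimited link table with a header; returns the raw
## data.frame plus the integer scores of the requested channel. Shared by
## read_links() and read_positive_pairs().
read_link_table <- function(path, score_channel, threshold) {
  check_that(file.exists(path), sprintf("file not found: %s", path))
  check_that(is.character(score_channel) && length(score_channel) == 1L,
             "`score_channel` must be a single column name")
  check_that(is.numeric(threshold) && length(threshold) == 1L && threshold >= 0,
             "`threshold` must be a single number >= 0")
  df <- tryCatch(
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, comment.char = ""),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (ncol(df) < 3L) {
    stop(sprintf("link table '%s' needs two ID columns plus score columns",
                 path), call. = FALSE)
  }
  if (!score_channel %in% names(df)) {
    stop(sprintf(
      "format error: channel column '%s' not found in '%s' (available: %s)",
      score_channel, path, paste(setdiff(names(df), names(df)[1:2]),
                                 collapse = ", ")), call. = FALSE)
  }
  raw <- df[[score_channel]]
  scores <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(scores) & !is.na(raw))
  if (length(bad)) {
    stop(sprintf("unreadable score in '%s' at line %d (value '%s')",
                 path, bad[1] + 1L, as.character(raw[bad[1]])), call. = FALSE)
  }
  bad_na <- which(is.na(scores))
  if (length(bad_na)) {
    stop(sprintf("missing score in '%s' at line %d", path, bad_na[1] + 1L),
         call. = FALSE)
  }
  if (any(scores < 0 | scores > 1000)) {
    stop(sprintf("channel scores in '%s' must lie in [0, 1000]", path),
         call. = FALSE)
  }
  list(id_a = as.character(df[[1]]), id_b = as.character(df[[2]]),
       score = scores, col_names = names(df))
}

#' Read a confidence-filtered interaction network from a link table
#'
#' Parses a STITCH/STRING-style flat file (header plus whitespace/tab-delimited
#' columns: two entity IDs followed by per-channel integer confidence scores in
#' 0-1000) and keeps exactly the edges whose named channel score is greater
#' than or equal to `threshold` ("score >= threshold" retention, matching the
#' databases' "700 or higher" convention). Edge weight is `score / 1000`.
#' Self-loops are dropped and duplicate rows (including reversed `B A`
#' duplicates of `A B`) collapse to one undirected edge keeping the maximum
#' score; both with a warning.
#'
#' @param path link-table file path.
#' @param score_channel name of the confidence channel column to filter on
#'   (e.g. `"experimental"`).
#' @param threshold minimum retained score; the field convention is 700 for
#'   high-confidence protein-chemical links and 150 for medium-confidence
#'   protein-protein / chemical-chemical links.
#' @return An [interaction_network()].
#' @examples
#' tf <- tempfile()
#' writeLines(c("item_id_a item_id_b experimental",
#'              "p1 p2 800", "p2 p3 650", "p1 p3 700"), tf)
#' read_links(tf, "experimental", 700)  # keeps 2 of 3 edges
#' @export
read_links <- function(path, score_channel, threshold) {
  tab <- read_link_table(path, score_channel, threshold)
  a <- tab$id_a; b <- tab$id_b; s <- tab$score
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropped %d self-loop(s) in '%s'", sum(self), path))
    a <- a[!self]; b <- b[!self]; s <- s[!self]
  }
  ## canonical unordered key; collapse duplicates keeping max score
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("collapsed %d duplicate/reversed edge row(s) in '%s'",
                    sum(duplicated(key)), path))
    s <- tapply(s, key, max)
    parts <- strsplit(names(s), "\r", fixed = TRUE)
    lo <- vapply(parts, `[`, "", 1L)
    hi <- vapply(parts, `[`, "", 2L)
    s <- as.numeric(s)
  }
  keep <- s >= threshold
  interaction_network(data.frame(from = lo[keep], to = hi[keep],
                                 weight = s[keep] / 1000,
                                 stringsAsFactors = FALSE))
}

#' Labelled protein-compound pair set
#'
#' @param protein_id,compound_id character vectors of equal length.
#' @param label integer 0/1 labels.
#' @param fold optional integer fold assignment (0-based).
#' @return data.frame of class `labeled_pairs` with columns `protein_id`,
#'   `compound_id`, `label` and optionally `fold`. Duplicate
#'   (protein, compound) pairs are an error.
#' @export
labeled_pairs <- function(protein_id, compound_id, label, fold = NULL) {
  df <- data.frame(protein_id = as.character(protein_id),
                   compound_id = as.character(compound_id),
                   label = as.integer(label), stringsAsFactors = FALSE)
  check_that(all(df$label %in% c(0L, 1L)), "labels must be 0/1")
  key <- paste(df$protein_id, df$compound_id, sep = "\r")
  check_that(!anyDuplicated(key), "duplicate (protein, compound) pairs")
  if (!is.null(fold)) df$fold <- as.integer(fold)
  class(df) <- c("labeled_pairs", "data.frame")
  df
}

pair_key <- function(pairs) paste(pairs$protein_id, pairs$compound_id, sep = "\r")

#' Read positive protein-compound pairs from a link table
#'
#' As [read_links()] but for the bipartite protein-chemical table: rows whose
#' channel score passes `threshold` become positive (label 1) pairs;
#' duplicates collapse. By default the first column is taken as the protein
#' ID; if the first column name contains "chem" or "compound" (the STITCH
#' chemical-protein layout) the two ID columns are swapped.
#'
#' @inheritParams read_links
#' @return A [labeled_pairs()] set, all labels 1.
#' @export
read_positive_pairs <- function(path, score_channel, threshold) {
  tab <- read_link_table(path, score_channel, threshold)
  prot <- tab$id_a; comp <- tab$id_b
  if (grepl("chem|compound", tab$col_names[1], ignore.case = TRUE)) {
    tmp <- prot; prot <- comp; comp <- tmp
  }
  keep <- tab$score >= threshold
  prot <- prot[keep]; comp <- comp[keep]
  key <- paste(prot, comp, sep = "\r")
  dup <- duplicated(key)
  labeled_pairs(prot[!dup], comp[!dup], rep(1L, sum(!dup)))
}

#' Sample negative protein-compound pairs
#'
#' Augments a positive pair set with `round(ratio * n_positives)` distinct
#' negative pairs (label 0) drawn uniformly without replacement from the
#' complement of the positive set within `proteins x compounds`. Pairs absent
#' from the interaction database are treated as non-interacting, and the
#' default ratio of 2 gives the 1:2 positive:negative design. Rounding is
#' half-up.
#'
#' @param positives a [labeled_pairs()] set (labels all 1).
#' @param proteins,compounds character vectors defining the pair universe.
#' @param ratio negatives per positive (> 0); default 2.
#' @param seed integer RNG seed; the same seed reproduces the same negatives.
#' @return A [labeled_pairs()] set: the positives plus sampled negatives.
#' @export
sample_negatives <- function(positives, proteins, compounds, ratio = 2,
                             seed = 1L) {
  check_that(is.numeric(ratio) && ratio > 0, "`ratio` must be > 0")
  proteins <- sort(unique(as.character(proteins)))
  compounds <- sort(unique(as.character(compounds)))
  np <- length(proteins); nc <- length(compounds)
  n_pos <- nrow(positives)
  n_neg <- as.integer(round_half_up(ratio * n_pos))
  total <- as.double(np) * nc
  ## index positives inside the universe (positives outside it don't shrink
  ## the complement)
  pi_idx <- match(positives$protein_id, proteins)
  ci_idx <- match(positives$compound_id, compounds)
  inside <- !is.na(pi_idx) & !is.na(ci_idx)
  pos_lin <- (pi_idx[inside] - 1) * nc + ci_idx[inside]  # 1-based linear index
  n_free <- total - length(pos_lin)
  if (n_neg > n_free) {
    stop(sprintf(
      "requested %d negatives but only %.0f non-positive pairs exist (maximum achievable: %.0f)",
      n_neg, n_free, n_free), call. = FALSE)
  }
  sel <- with_seed(seed, {
    if (total <= 2e6) {
      complement <- setdiff(seq_len(total), pos_lin)
      sample(complement, n_neg)
    } else {
      ## rejection sampling for large universes
      chosen <- integer(0)
      taken <- c(pos_lin)
      while (length(chosen) < n_neg) {
        cand <- unique(ceiling(stats::runif(2L * (n_neg - length(chosen))) * total))
        cand <- cand[!(cand %in% taken)]
        chosen <- c(chosen, cand)
        taken <- c(taken, cand)
      }
      chosen[seq_len(n_neg)]
    }
  })
  neg_p <- proteins[(sel - 1) %/% nc + 1]
  neg_c <- compounds[(sel - 1) %% nc + 1]
  labeled_pairs(c(positives$protein_id, neg_p),
                c(positives$compound_id, neg_c),
                c(rep(1L, n_pos), rep(0L, n_neg)))
}

#' Restrict pairs to entities covered by every modality
#'
#' Keeps only pairs whose protein appears in the protein-protein network and
#' the sequence map, and whose compound appears in the compound-compound
#' network and the SMILES map — the "all data available" intersection used to
#' build the benchmark datasets. Dropped counts are reported via a message
#' and attached as attribute `dropped`.
#'
#' @param pairs a [labeled_pairs()] set.
#' @param ppi,cci [interaction_network()]s for proteins and compounds.
#' @param sequences named character vector (or list) of protein sequences.
#' @param smiles named character vector of compound SMILES.
#' @return The filtered [labeled_pairs()] set (possibly empty).
#' @export
restrict_to_common_entities <- function(pairs, ppi, cci, sequences, smiles) {
  ok_p <- pairs$protein_id %in% ppi$nodes & pairs$protein_id %in% names(sequences)
  ok_c <- pairs$compound_id %in% cci$nodes & pairs$compound_id %in% names(smiles)
  keep <- ok_p & ok_c
  dropped <- c(missing_protein = sum(!ok_p), missing_compound = sum(!ok_c),
               total_dropped = sum(!keep))
  if (any(!keep)) {
    message(sprintf(
      "restrict_to_common_entities: dropped %d of %d pairs (%d protein-side, %d compound-side)",
      sum(!keep), nrow(pairs), sum(!ok_p), sum(!ok_c)))
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("labeled_pairs", "data.frame")
  attr(out, "dropped") <- dropped
  out
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over Biostrings with line-wrapping tolerance; returns plain
#' uppercase character sequences named by the first whitespace-delimited
#' token of each header.
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_sequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write protein sequences to FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(unlist(sequences)), path, width = 60L)
  invisible(path)
}

#' Read/write a two-column compound table (compound_id, SMILES)
#' @param path TSV file path with header `compound_id<TAB>smiles`.
#' @return Named character vector of SMILES.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  check_that(ncol(df) >= 2L, "compound table needs two columns")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_compound_table
#' @param smiles named character vector of SMILES.
#' @export
write_compound_table <- function(smiles, path) {
  utils::write.table(
    data.frame(compound_id = names(smiles), smiles = unname(smiles)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read labelled pairs as TSV
#'
#' Serialization of [labeled_pairs()] (protein_id, compound_id, label and, if
#' present, fold).
#' @param pairs a [labeled_pairs()] set.
#' @param path TSV path.
#' @return `path` invisibly / a [labeled_pairs()] set.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  labeled_pairs(df$protein_id, df$compound_id, df$label,
                fold = if ("fold" %in% names(df)) df$fold else NULL)
}
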