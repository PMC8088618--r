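## Cross-validation split constructors: baseline (random pairs),
## unseen-compound (compound-grouped) and hard (protein- and
## compound-grouped) k-fold datasets, plus a leakage auditor.

new_fold_assignment <- function(mode, k, pairs, protein_group = NULL,
                                compound_group = NULL) {
  structure(list(mode = mode, k = as.integer(k), pairs = pairs,
                 protein_group = protein_group,
                 compound_group = compound_group),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold_assignment: mode=%s, k=%d, %d pairs\n",
              x$mode, x$k, nrow(x$pairs)))
  if (x$mode == "hard") {
    for (i in 0:(x$k - 1)) {
      s <- hard_fold_sets(x, i)
      cat(sprintf("  fold %d: %d test, %d train, %d excluded\n",
                  i, length(s$test), length(s$train), length(s$excluded)))
    }
  } else {
    print(table(fold = x$pairs$fold))
  }
  invisible(x)
}

## Greedy largest-first bin packing: assign entities (with pair counts) to k
## groups balancing total pair count. Entities are shuffled first (seeded by
## the caller) so ties break randomly but reproducibly.
greedy_balance <- function(counts, k) {
  counts <- counts[sample(length(counts))]
  counts <- counts[order(-counts)]        # stable: keeps shuffled tie order
  load <- numeric(k)
  grp <- integer(length(counts))
  for (i in seq_along(counts)) {
    g <- which.min(load)
    grp[i] <- g - 1L
    load[g] <- load[g] + counts[i]
  }
  stats::setNames(grp, names(counts))
}

#' Baseline k-fold split
#'
#' Uniform random partition of all pairs (positives and negatives alike) into
#' `k` folds whose sizes differ by at most one. Fold labels are 0..k-1.
#'
#' @param pairs a [labeled_pairs()] set.
#' @param k number of folds (>= 2).
#' @param seed integer RNG seed.
#' @return A `fold_assignment` (mode `"baseline"`); `$pairs` carries a `fold`
#'   column.
#' @export
split_baseline <- function(pairs, k, seed = 1L) {
  check_that(is.numeric(k) && k >= 2, "`k` must be an integer >= 2")
  k <- as.integer(k)
  check_that(nrow(pairs) >= k, "need at least k pairs")
  fold <- with_seed(seed, {
    perm <- sample(nrow(pairs))
    f <- integer(nrow(pairs))
    f[perm] <- (seq_along(perm) - 1L) %% k
    f
  })
  pairs$fold <- fold
  new_fold_assignment("baseline", k, pairs)
}

#' Unseen-compound k-fold split
#'
#' Partitions the distinct compounds into `k` groups balanced by pair count
#' (greedy largest-first packing after a seeded shuffle); every pair inherits
#' its compound's group as its fold. Test fold i therefore shares no compound
#' with any other fold: the cold-start "new compound" evaluation.
#'
#' @inheritParams split_baseline
#' @return A `fold_assignment` (mode `"unseen"`) with `$compound_group`.
#' @export
split_unseen_compound <- function(pairs, k, seed = 1L) {
  check_that(is.numeric(k) && k >= 2, "`k` must be an integer >= 2")
  k <- as.integer(k)
  counts <- table(pairs$compound_id)
  check_that(length(counts) >= k, "fewer distinct compounds than folds")
  grp <- with_seed(seed, greedy_balance(
    stats::setNames(as.integer(counts), names(counts)), k))
  pairs$fold <- unname(grp[pairs$compound_id])
  new_fold_assignment("unseen", k, pairs, compound_group = grp)
}

#' Hard k-fold split (unseen proteins and compounds)
#'
#' Proteins and compounds are independently partitioned into `k` groups
#' (greedy pair-count balancing, seeded). Test fold i contains the pairs
#' whose protein group and compound group are both i; its training set
#' contains the pairs with protein group != i and compound group != i.
#' Mixed-group pairs would leak one entity and are excluded from that fold
#' entirely. `$pairs$fold` records the test fold (NA for never-tested pairs);
#' use [hard_fold_sets()] or [train_pairs()] / [test_pairs()] for the
#' per-fold sets.
#'
#' @inheritParams split_baseline
#' @return A `fold_assignment` (mode `"hard"`) with `$protein_group` and
#'   `$compound_group`.
#' @export
split_hard <- function(pairs, k, seed = 1L) {
  check_that(is.numeric(k) && k >= 2, "`k` must be an integer >= 2")
  k <- as.integer(k)
  pc <- table(pairs$protein_id)
  cc <- table(pairs$compound_id)
  check_that(length(pc) >= k, "fewer distinct proteins than folds")
  check_that(length(cc) >= k, "fewer distinct compounds than folds")
  groups <- with_seed(seed, list(
    p = greedy_balance(stats::setNames(as.integer(pc), names(pc)), k),
    c = greedy_balance(stats::setNames(as.integer(cc), names(cc)), k)))
  pg <- unname(groups$p[pairs$protein_id])
  cg <- unname(groups$c[pairs$compound_id])
  pairs$fold <- ifelse(pg == cg, pg, NA_integer_)
  empty <- setdiff(0:(k - 1), unique(stats::na.omit(pairs$fold)))
  if (length(empty)) {
    stop(sprintf(
      "hard split: test fold(s) %s are empty; try a different seed or smaller k",
      paste(empty, collapse = ", ")), call. = FALSE)
  }
  new_fold_assignment("hard", k, pairs, protein_group = groups$p,
                      compound_group = groups$c)
}

## Per-fold index sets for a hard split: test / train / excluded.
hard_fold_sets <- function(fa, fold) {
  pg <- unname(fa$protein_group[fa$pairs$protein_id])
  cg <- unname(fa$compound_group[fa$pairs$compound_id])
  test <- which(pg == fold & cg == fold)
  train <- which(pg != fold & cg != fold)
  excluded <- setdiff(seq_len(nrow(fa$pairs)), c(test, train))
  list(test = test, train = train, excluded = excluded)
}

#' Training / test pairs of one fold
#'
#' For baseline and unseen splits the training set of fold i is every pair
#' not in fold i; for the hard split, pairs sharing a protein group or a
#' compound group with test fold i are excluded from its training set.
#'
#' @param fa a `fold_assignment`.
#' @param fold fold index in 0..k-1.
#' @return A [labeled_pairs()] subset.
#' @export
train_pairs <- function(fa, fold) {
  idx <- if (fa$mode == "hard") hard_fold_sets(fa, fold)$train
         else which(fa$pairs$fold != fold)
  out <- fa$pairs[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname train_pairs
#' @export
test_pairs <- function(fa, fold) {
  idx <- if (fa$mode == "hard") hard_fold_sets(fa, fold)$test
         else which(fa$pairs$fold == fold)
  out <- fa$pairs[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Audit a fold assignment for train/test leakage
#'
#' Verifies the disjointness contract of the split mode: baseline — folds
#' partition the pairs; unseen — no compound occurs in two folds; hard — for
#' every fold, the test and training sets share neither proteins nor
#' compounds.
#'
#' @param fa a `fold_assignment`.
#' @param mode audit mode; defaults to the assignment's own mode.
#' @return A list of class `leakage_audit` with elements `pass` (logical),
#'   `mode` and `offenders` (character vector of leaking entity IDs, empty on
#'   pass).
#' @export
audit_leakage <- function(fa, mode = fa$mode) {
  mode <- match.arg(mode, c("baseline", "unseen", "hard"))
  offenders <- character()
  if (mode == "baseline") {
    if (anyNA(fa$pairs$fold)) offenders <- "<unassigned pairs>"
  } else if (mode == "unseen") {
    tab <- table(fa$pairs$compound_id, fa$pairs$fold) > 0
    leak <- rownames(tab)[rowSums(tab) > 1]
    offenders <- leak
  } else {
    for (i in 0:(fa$k - 1)) {
      tr <- train_pairs(fa, i); te <- test_pairs(fa, i)
      pp <- intersect(unique(tr$protein_id), unique(te$protein_id))
      cc <- intersect(unique(tr$compound_id), unique(te$compound_id))
      offenders <- c(offenders, pp, cc)
    }
    offenders <- unique(offenders)
  }
  structure(list(pass = length(offenders) == 0L, mode = mode,
                 offenders = offenders),
            class = "leakage_audit")
}

#' @export
print.leakage_audit <- function(x, ...) {
  cat(sprintf("leakage audit (%s): %s\n", x$mode,
              if (x$pass) "pass" else "FAIL"))
  if (!x$pass) cat("  offending entities:",
                   paste(utils::head(x$offenders, 10), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fold assignment
#'
#' Writes the pair table (protein_id, compound_id, label, fold) as TSV and a
#' JSON audit report alongside it.
#'
#' @param fa a `fold_assignment`.
#' @param path TSV output path; the audit goes to `<path>.audit.json`.
#' @return `path`, invisibly.
#' @export
write_folds <- function(fa, path) {
  utils::write.table(as.data.frame(fa$pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  audit <- audit_leakage(fa)
  jsonlite::write_json(
    list(mode = fa$mode, k = fa$k, pass = audit$pass,
         offenders = audit$offenders),
    paste0(path, ".audit.json"), auto_unbox = TRUE)
  invisible(path)
}
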