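#' The fixed amino-acid alphabet of the one-hot encoding
#'
#' Row order of every one-hot matrix produced by [one_hot_encode()] and of
#' the k-mer index of [kmer_frequency()]. Part of the model contract: saved
#' checkpoints assume this ordering.
#' @format Character vector of the 20 standard residues.
#' @export
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' One-hot encode an amino-acid sequence
#'
#' Embeds a protein sequence as a 20 x `max_len` binary matrix (rows =
#' [AA_ALPHABET20], columns = positions). Nonstandard residue letters
#' (B, J, O, U, X, Z) give all-zero columns; sequences longer than `max_len`
#' are truncated with a warning; shorter ones are right-padded with zero
#' columns. `max_len` is typically the longest training sequence (5762 for
#' the full-scale STITCH/STRING corpus).
#'
#' @param sequence non-empty amino-acid string (A-Z).
#' @param max_len number of columns of the output matrix (>= 1).
#' @return Object of class `one_hot_sequence`: list with `matrix`
#'   (20 x max_len) and `true_length` (encoded length before padding).
#' @examples
#' oh <- one_hot_encode("ACD", max_len = 5)
#' colSums(oh$matrix)  # 1 1 1 0 0
#' @export
one_hot_encode <- function(sequence, max_len) {
  check_that(is.character(sequence) && length(sequence) == 1L &&
             nchar(sequence) > 0, "`sequence` must be a non-empty string")
  check_that(is.numeric(max_len) && max_len >= 1, "`max_len` must be >= 1")
  max_len <- as.integer(max_len)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (!all(grepl("^[A-Z]$", chars))) {
    bad <- unique(chars[!grepl("^[A-Z]$", chars)])
    stop(sprintf("sequence contains non-letter character(s): %s",
                 paste(bad, collapse = " ")), call. = FALSE)
  }
  if (length(chars) > max_len) {
    warning(sprintf("sequence of length %d truncated to max_len = %d",
                    length(chars), max_len))
    chars <- chars[seq_len(max_len)]
  }
  m <- matrix(0, nrow = 20L, ncol = max_len,
              dimnames = list(AA_ALPHABET20, NULL))
  row <- match(chars, AA_ALPHABET20)          # NA for nonstandard letters
  hit <- !is.na(row)
  m[cbind(row[hit], which(hit))] <- 1
  structure(list(matrix = m, true_length = length(chars)),
            class = "one_hot_sequence")
}

#' @export
print.one_hot_sequence <- function(x, ...) {
  cat(sprintf("one_hot_sequence: 20 x %d (true length %d)\n",
              ncol(x$matrix), x$true_length))
  invisible(x)
}

#' k-mer frequency features of a protein sequence
#'
#' Frequencies of all 20^k k-mers over the standard alphabet (8000 dimensions
#' for the default k = 3, the featurization consumed by classical SVM /
#' random-forest baselines). Windows containing a nonstandard residue are
#' skipped; counts are divided by the number of counted windows, so the
#' entries sum to 1 whenever at least one window counted.
#'
#' @param sequence amino-acid string with `nchar(sequence) >= k`.
#' @param k k-mer length (default 3).
#' @return Named numeric vector of length `20^k`.
#' @examples
#' f <- kmer_frequency("AAAA", 3)
#' f[["AAA"]]  # 1
#' @export
kmer_frequency <- function(sequence, k = 3L) {
  check_that(is.character(sequence) && length(sequence) == 1L,
             "`sequence` must be a single string")
  k <- as.integer(k)
  check_that(k >= 1, "`k` must be >= 1")
  n <- nchar(sequence)
  if (n < k) stop(sprintf("sequence length %d < k = %d", n, k), call. = FALSE)
  chars <- strsplit(toupper(sequence), "")[[1]]
  code <- match(chars, AA_ALPHABET20) - 1L    # 0..19, NA for nonstandard
  ## window index in base 20, most significant first
  n_win <- n - k + 1L
  idx <- rep(0, n_win)
  ok <- rep(TRUE, n_win)
  for (j in seq_len(k)) {
    c_j <- code[j:(j + n_win - 1L)]
    ok <- ok & !is.na(c_j)
    idx <- idx * 20 + ifelse(is.na(c_j), 0, c_j)
  }
  counts <- numeric(20^k)
  if (any(ok)) {
    tab <- table(idx[ok] + 1)
    counts[as.integer(names(tab))] <- as.integer(tab)
    counts <- counts / sum(ok)
  }
  names(counts) <- apply(
    expand.grid(rep(list(AA_ALPHABET20), k))[, k:1, drop = FALSE],
    1L, paste0, collapse = "")
  counts
}
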