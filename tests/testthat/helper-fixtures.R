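## Shared fixtures and independent oracles, built in code at test time.

## --- toy link tables ------------------------------------------------------

write_toy_links <- function(rows, header = "item_id_a item_id_b experimental",
                            path = tempfile(fileext = ".tsv")) {
  writeLines(c(header, rows), path)
  path
}

## --- small synthetic benchmark + cheap features ---------------------------

tiny_benchmark <- function(seed = 1, ...) {
  generate_benchmark(synthetic_config(
    n_proteins = 20L, n_compounds = 20L, n_pairs = 120L,
    seq_length = c(40L, 60L), n_protein_communities = 2L,
    n_compound_communities = 2L, seed = seed, ...))
}

## Random (non-node2vec) embeddings: sufficient wherever tests only need
## per-entity feature vectors, keeping model tests independent of the
## embedding module.
fake_embeddings <- function(ids, d = 8L, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(length(ids) * d), nrow = length(ids),
              dimnames = list(ids, NULL))
  m
}

bench_features <- function(bench, emb_dim = 8L, seed = 1,
                           real_embeddings = FALSE, walk_cfg = NULL) {
  if (real_embeddings) {
    wc <- walk_cfg %||% walk_config(dimensions = emb_dim, seed = seed)
    pe <- embed_network(bench$ppi, wc)
    ce <- embed_network(bench$cci, wc)
  } else {
    pe <- fake_embeddings(names(bench$sequences), emb_dim, seed)
    ce <- fake_embeddings(names(bench$smiles), emb_dim, seed + 1)
  }
  list(sequences = bench$sequences,
       fingerprints = ecfp_matrix(bench$smiles),
       protein_embeddings = pe, compound_embeddings = ce)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_training_config <- function(seed = 1, epochs = 30L, ...) {
  training_config(epochs = epochs, batch_size = 64L, latent_dim = 16L,
                  cnn_filters = c(8L, 8L), cnn_widths = c(5L, 3L),
                  dropout = 0.2, patience = 8L, seed = seed, ...)
}

## --- independent oracles --------------------------------------------------

## Brute-force CNN forward: direct summation convolution, bias, Leaky-ReLU,
## average pooling per layer, global max over valid positions. Works from
## the raw sequence matrix truncated to its true length.
brute_cnn <- function(onehot, params) {
  X <- onehot$matrix[, seq_len(onehot$true_length), drop = FALSE]
  slope <- params$leaky_slope
  for (l in seq_along(params$layers)) {
    W <- params$layers[[l]]$W
    b <- params$layers[[l]]$b
    r <- params$widths[l]
    n_f <- nrow(W)
    P <- ncol(X) - r + 1L
    stopifnot(P >= 1)
    Z <- matrix(0, n_f, P)
    for (k in seq_len(n_f)) {
      Wk <- matrix(W[k, ], nrow = nrow(X), ncol = r)   # column-major unfold
      for (i in seq_len(P)) {
        Z[k, i] <- sum(Wk * X[, i:(i + r - 1), drop = FALSE]) + b[k]
      }
    }
    A <- ifelse(Z > 0, Z, slope * Z)
    Pp <- P %/% params$pool
    stopifnot(Pp >= 1)
    X2 <- matrix(0, n_f, Pp)
    for (j in seq_len(Pp)) {
      X2[, j] <- rowMeans(A[, ((j - 1) * params$pool + 1):(j * params$pool),
                            drop = FALSE])
    }
    X <- X2
  }
  apply(X, 1, max)
}

## Brute-force AUROC: pairwise positive-over-negative counting, ties 1/2.
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

## Exact Wilcoxon signed-rank p by enumeration of all 2^n sign assignments.
brute_wilcoxon <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

## Smith-Waterman local alignment with affine gaps (open + len * extend),
## independent dynamic-programming oracle under BLOSUM62.
brute_smith_waterman <- function(a, b, gap_open = 11, gap_extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- get("BLOSUM62")
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1, m + 1)       # best ending in a match
  Ix <- matrix(-Inf, n + 1, m + 1)   # gap in y (vertical)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                      Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                      Iy[i, j - 1] - gap_extend)
      sc <- S[x[i - 1], y[j - 1]]
      M[i, j] <- max(0, sc + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                                 Iy[i - 1, j - 1]))
      best <- max(best, M[i, j])
    }
  }
  best
}

## Direct arithmetic oracle for the fusion output layer.
brute_fusion_score <- function(Wf, bf, Wg, bg, wh, bh, vp, vc) {
  x <- as.numeric(Wf %*% vp + bf)
  y <- as.numeric(Wg %*% vc + bg)
  1 / (1 + exp(-(sum(wh * x * y) + bh)))
}
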