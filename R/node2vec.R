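## node2vec feature learning on interaction networks: second-order biased
## random walks plus skip-gram with negative sampling (compiled inner loop).

#' node2vec walk and training configuration
#'
#' Defaults follow the standard node2vec parameterization used for
#' interactome embedding: 128 dimensions, 10 walks of length 80 per node,
#' return parameter p = 1 and in-out parameter q = 1 (with p = q = 1 the
#' biased walk reduces to a weighted first-order walk), edge weights
#' respected. Skip-gram settings (window 10, 5 negative samples, 5 epochs,
#' initial learning rate 0.025) are conventional word2vec defaults.
#'
#' @param dimensions embedding dimension d.
#' @param walk_length nodes visited per walk.
#' @param num_walks walks started per node.
#' @param p return (revisit) parameter; > 0.
#' @param q in-out parameter controlling search breadth; > 0.
#' @param use_weights use edge weights as transition propensities.
#' @param window skip-gram context window.
#' @param negative_samples negative samples per positive context.
#' @param epochs training passes over the walk corpus.
#' @param alpha initial skip-gram learning rate (linearly decayed).
#' @param seed integer seed for walks and training.
#' @return Object of class `walk_config`.
#' @export
walk_config <- function(dimensions = 128L, walk_length = 80L, num_walks = 10L,
                        p = 1, q = 1, use_weights = TRUE, window = 10L,
                        negative_samples = 5L, epochs = 5L, alpha = 0.025,
                        seed = 1L) {
  check_that(walk_length >= 1 && num_walks >= 1, "walk counts must be >= 1")
  check_that(p > 0 && q > 0, "p and q must be > 0")
  structure(list(dimensions = as.integer(dimensions),
                 walk_length = as.integer(walk_length),
                 num_walks = as.integer(num_walks), p = p, q = q,
                 use_weights = isTRUE(use_weights), window = as.integer(window),
                 negative_samples = as.integer(negative_samples),
                 epochs = as.integer(epochs), alpha = alpha,
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Generate second-order biased random walks
#'
#' Starts `num_walks` walks from every node. The first step follows edge
#' weights; subsequent steps are biased by the previous node: the transition
#' propensity to candidate x from v (previous node t) is
#' `w(v, x) * 1/p` if x = t, `w(v, x)` if x neighbours t, and `w(v, x) * 1/q`
#' otherwise. A walk stops early at a node with no neighbours.
#'
#' @param net an [interaction_network()].
#' @param cfg a [walk_config()].
#' @return List of character vectors of node IDs; each walk starts at its
#'   assigned node and has length at most `cfg$walk_length`.
#' @export
generate_walks <- function(net, cfg = walk_config()) {
  check_that(n_nodes(net) > 0, "network is empty")
  adj <- adjacency_list(net)
  if (!cfg$use_weights) {
    adj <- lapply(adj, function(a) list(ids = a$ids, w = rep(1, length(a$ids))))
  }
  nbr_sets <- lapply(adj, `[[`, "ids")
  with_seed(cfg$seed, {
    walks <- vector("list", cfg$num_walks * length(net$nodes))
    wi <- 0L
    for (rep_i in seq_len(cfg$num_walks)) {
      starts <- sample(net$nodes)
      for (s in starts) {
        walk <- character(cfg$walk_length)
        walk[1] <- s
        len <- 1L
        prev <- NA_character_
        cur <- s
        while (len < cfg$walk_length) {
          a <- adj[[cur]]
          if (!length(a$ids)) break
          w <- a$w
          if (!is.na(prev) && (cfg$p != 1 || cfg$q != 1)) {
            bias <- ifelse(a$ids == prev, 1 / cfg$p,
                           ifelse(a$ids %in% nbr_sets[[prev]], 1, 1 / cfg$q))
            w <- w * bias
          }
          nxt <- a$ids[sample.int(length(a$ids), 1L, prob = w)]
          len <- len + 1L
          walk[len] <- nxt
          prev <- cur
          cur <- nxt
        }
        wi <- wi + 1L
        walks[[wi]] <- walk[seq_len(len)]
      }
    }
    walks
  })
}

#' Embed an interaction network with node2vec
#'
#' Generates biased random walks ([generate_walks()]) and trains skip-gram
#' with negative sampling on them (single-threaded compiled loop, own seeded
#' RNG, hence fully reproducible). Nodes absent from the network are not
#' embedded.
#'
#' @inheritParams generate_walks
#' @return Numeric matrix `n_nodes x dimensions` with node IDs as rownames
#'   (the embedding table N).
#' @export
embed_network <- function(net, cfg = walk_config()) {
  walks <- generate_walks(net, cfg)
  ids <- net$nodes
  walk_idx <- lapply(walks, function(w) match(w, ids) - 1L)  # 0-based
  ## unigram^0.75 negative-sampling table
  freq <- table(factor(unlist(walks), levels = ids))
  pow <- as.numeric(freq)^0.75
  if (sum(pow) == 0) pow <- rep(1, length(ids))
  table_size <- 100000L
  neg_table <- rep(seq_along(ids) - 1L,
                   times = pmax(1L, round(table_size * pow / sum(pow))))
  emb <- sgns_train(walk_idx, length(ids), cfg$dimensions, cfg$window,
                    cfg$negative_samples, cfg$epochs, cfg$alpha,
                    neg_table, cfg$seed)
  rownames(emb) <- ids
  emb
}

#' Cosine similarity of two vectors
#'
#' `u . v / (||u|| ||v||)`; errors on zero vectors or length mismatch.
#'
#' @param u,v numeric vectors of equal length.
#' @return Real in [-1, 1].
#' @export
cosine <- function(u, v) {
  check_that(length(u) == length(v), "vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for zero vectors",
                               call. = FALSE)
  sum(u * v) / (nu * nv)
}

#' Write/read embeddings in word2vec text format
#'
#' Header line "count dim", then one line per node: id followed by the d
#' vector components.
#'
#' @param emb embedding matrix with rownames (from [embed_network()]).
#' @param path output path.
#' @return `path` invisibly / the embedding matrix.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb), ncol(emb)), con)
  for (i in seq_len(nrow(emb))) {
    writeLines(paste(rownames(emb)[i],
                     paste(sprintf("%.17g", emb[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " ")
  emb <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(emb) <- vapply(parts, `[`, "", 1L)
  emb
}
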