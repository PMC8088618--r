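#' Weighted undirected interaction network
#'
#' Container for a protein-protein or compound-compound interaction network:
#' a set of entity IDs plus undirected weighted edges. Edge weights are
#' confidence-derived reals in (0, 1] (STITCH/STRING channel score / 1000).
#' Each unordered pair is stored once, with `from < to` lexicographically.
#'
#' @param edges data.frame with columns `from`, `to` (character entity IDs)
#'   and `weight` (numeric in (0, 1]).
#' @param nodes optional character vector of node IDs; defaults to the edge
#'   endpoints. Extra isolated nodes are allowed.
#' @return An object of class `interaction_network` with elements `nodes`
#'   (character) and `edges` (data.frame `from`, `to`, `weight`).
#' @examples
#' net <- interaction_network(data.frame(
#'   from = c("p1", "p2"), to = c("p2", "p3"), weight = c(0.8, 0.9)))
#' net
#' @export
interaction_network <- function(edges, nodes = NULL) {
  check_that(is.data.frame(edges), "`edges` must be a data.frame")
  if (nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  check_that(all(c("from", "to", "weight") %in% names(edges)),
             "`edges` needs columns from, to, weight")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  check_that(!anyNA(edges$weight) && all(edges$weight > 0),
             "edge weights must be positive")
  check_that(!any(edges$from == edges$to), "self-loops are not allowed")
  ## canonical orientation + order
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  key <- paste(edges$from, edges$to, sep = "\r")
  check_that(!anyDuplicated(key), "duplicate edges are not allowed")
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(sprintf("  weight range: [%.3f, %.3f]\n",
                min(x$edges$weight), max(x$edges$weight)))
  }
  invisible(x)
}

#' Number of nodes/edges of a network
#' @param net an `interaction_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

## adjacency list: named list id -> list(ids = character, w = numeric),
## neighbours sorted by id for deterministic sampling
adjacency_list <- function(net) {
  adj <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (id in net$nodes) adj[[id]] <- list(ids = character(), w = numeric())
  e <- net$edges
  if (nrow(e)) {
    both <- data.frame(a = c(e$from, e$to), b = c(e$to, e$from),
                       w = c(e$weight, e$weight), stringsAsFactors = FALSE)
    both <- both[order(both$a, both$b), , drop = FALSE]
    sp <- split(seq_len(nrow(both)), both$a)
    for (id in names(sp)) {
      idx <- sp[[id]]
      adj[[id]] <- list(ids = both$b[idx], w = both$w[idx])
    }
  }
  adj
}

#' Write a network as a STITCH/STRING-style link table
#'
#' Emits one row per undirected edge with the channel score reconstructed as
#' `round(weight * 1000)`. Suitable for round-tripping through
#' [read_links()].
#'
#' @param net an `interaction_network`.
#' @param path output file path.
#' @param id_cols names of the two ID columns in the header.
#' @param score_channel name of the score column.
#' @return `path`, invisibly.
#' @export
write_links <- function(net, path, id_cols = c("item_id_a", "item_id_b"),
                        score_channel = "experimental") {
  df <- data.frame(a = net$edges$from, b = net$edges$to,
                   s = as.integer(round(net$edges$weight * 1000)))
  names(df) <- c(id_cols, score_channel)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
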