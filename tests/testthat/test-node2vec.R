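star_net <- function() {
  interaction_network(data.frame(from = c("hub", "hub"),
                                 to = c("a", "b"),
                                 weight = c(0.3, 0.1)))
}

test_that("walks start at their node and respect the length cap", {
  net <- tiny_benchmark(seed = 2)$ppi
  cfg <- walk_config(walk_length = 15, num_walks = 3, seed = 1)
  walks <- generate_walks(net, cfg)
  expect_length(walks, 3 * n_nodes(net))
  expect_true(all(lengths(walks) <= 15))
  starts <- vapply(walks, `[`, "", 1L)
  expect_equal(sort(table(starts)), sort(table(rep(net$nodes, 3))),
               ignore_attr = TRUE)
  ## determinism
  walks2 <- generate_walks(net, cfg)
  expect_identical(walks, walks2)
})

test_that("an isolated node yields length-1 walks", {
  net <- interaction_network(data.frame(from = "a", to = "b", weight = 1),
                             nodes = c("a", "b", "iso"))
  walks <- generate_walks(net, walk_config(num_walks = 4, walk_length = 10,
                                           seed = 1))
  iso_walks <- walks[vapply(walks, `[`, "", 1L) == "iso"]
  expect_length(iso_walks, 4L)
  expect_true(all(lengths(iso_walks) == 1L))
})

test_that("first-step frequencies follow edge weights on a star", {
  walks <- generate_walks(star_net(),
                          walk_config(walk_length = 2, num_walks = 10000,
                                      seed = 5))
  first <- vapply(walks[vapply(walks, `[`, "", 1L) == "hub"], `[`, "", 2L)
  n <- length(first)
  p_hat <- mean(first == "a")
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(p_hat - 0.75), 3 * se)
})

test_that("second-order transition frequencies match analytic probabilities", {
  ## triangle a-b-c plus pendant d on b; from b with previous node a:
  ## candidates a (return, w/p), c (shared neighbour of a and b, w),
  ## d (distance 2 from a, w/q)
  net <- interaction_network(data.frame(
    from = c("a", "b", "a", "b"), to = c("b", "c", "c", "d"),
    weight = c(0.5, 0.4, 0.6, 0.8)))
  p <- 2; q <- 0.5
  cfg <- walk_config(walk_length = 40, num_walks = 300, p = p, q = q,
                     seed = 9)
  walks <- generate_walks(net, cfg)
  ## collect transitions conditioned on (prev = a, cur = b)
  nxt <- character()
  for (w in walks) {
    if (length(w) < 3) next
    hit <- which(w[-c(length(w) - 1, length(w))] == "a" &
                 w[-c(1, length(w))] == "b")
    nxt <- c(nxt, w[hit + 2])
  }
  expect_gt(length(nxt), 500)
  probs <- c(a = 0.5 / p, c = 0.4, d = 0.8 / q)
  probs <- probs / sum(probs)
  obs <- table(factor(nxt, levels = names(probs)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.001)
})

test_that("p = q = 1 reduces to the weighted first-order walk", {
  ## on the star, steps from the hub must follow edge weights regardless of
  ## the previous node when p = q = 1
  walks <- generate_walks(star_net(),
                          walk_config(walk_length = 30, num_walks = 400,
                                      p = 1, q = 1, seed = 3))
  steps <- character()
  for (w in walks) {
    at_hub <- which(w == "hub")
    at_hub <- at_hub[at_hub < length(w)]
    steps <- c(steps, w[at_hub + 1])
  }
  p_hat <- mean(steps == "a")
  se <- sqrt(0.75 * 0.25 / length(steps))
  expect_lt(abs(p_hat - 0.75), 4 * se)
})

test_that("embeddings have the configured dimension and finite entries", {
  net <- interaction_network(data.frame(from = "a", to = "b", weight = 1))
  emb <- embed_network(net, walk_config(dimensions = 16, walk_length = 10,
                                        num_walks = 5, window = 3, seed = 1))
  expect_equal(dim(emb), c(2L, 16L))
  expect_setequal(rownames(emb), c("a", "b"))
  expect_true(all(is.finite(emb)))
})

test_that("planted-partition structure is recovered in embedding space", {
  wins <- 0L
  for (seed in 1:5) {
    set.seed(seed * 101)
    n <- 40
    block <- rep(1:2, each = 20)
    edges <- NULL
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      pr <- if (block[i] == block[j]) 0.3 else 0.01
      if (runif(1) < pr) edges <- rbind(edges, c(i, j))
    }
    net <- interaction_network(data.frame(
      from = sprintf("n%02d", edges[, 1]), to = sprintf("n%02d", edges[, 2]),
      weight = 1))
    emb <- embed_network(net, walk_config(dimensions = 32, walk_length = 40,
                                          num_walks = 8, window = 5,
                                          epochs = 3, seed = seed))
    bl <- block[as.integer(substring(rownames(emb), 2))]
    nm <- emb / sqrt(rowSums(emb^2))
    S <- nm %*% t(nm)
    same <- outer(bl, bl, "==") & upper.tri(S)
    diff <- (!outer(bl, bl, "==")) & upper.tri(S)
    if (mean(S[same]) > mean(S[diff])) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("cosine similarity follows its closed form", {
  expect_equal(cosine(c(3, 4), c(3, 4)), 1)
  expect_equal(cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine(c(1, 0), c(1, 1)), 0.7071, tolerance = 1e-4)
  expect_error(cosine(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine(c(1, 2), c(1, 2, 3)), "length")
})

test_that("embeddings round-trip through word2vec text format", {
  emb <- matrix(rnorm(6), nrow = 2, dimnames = list(c("x", "y"), NULL))
  path <- tempfile()
  write_embeddings(emb, path)
  back <- read_embeddings(path)
  expect_equal(back, emb, tolerance = 1e-12)
  hdr <- readLines(path, n = 1)
  expect_equal(hdr, "2 3")
})
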