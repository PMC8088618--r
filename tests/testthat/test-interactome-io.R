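test_that("read_links keeps edges at or above the channel threshold", {
  path <- write_toy_links(c("p1 p2 800", "p2 p3 650", "p1 p3 700"))
  net <- read_links(path, "experimental", 700)
  expect_s3_class(net, "interaction_network")
  expect_equal(n_edges(net), 2L)
  expect_setequal(net$nodes, c("p1", "p2", "p3"))

  path2 <- write_toy_links(c("a b 150", "b c 149"))
  net2 <- read_links(path2, "experimental", 150)
  expect_equal(n_edges(net2), 1L)
  expect_equal(net2$edges$weight, 0.15)

  expect_error(read_links(path, "database", 700), "database")
})

test_that("read_links drops self-loops and collapses reversed duplicates", {
  path <- write_toy_links(c("p1 p1 900", "p1 p2 800", "p2 p1 850"))
  expect_warning(expect_warning(net <- read_links(path, "experimental", 0),
                                "self-loop"), "duplicate")
  expect_equal(n_edges(net), 1L)
  expect_equal(net$edges$weight, 0.85)  # max of the two directions
})

test_that("read_links reports unreadable rows with a line number", {
  path <- write_toy_links(c("p1 p2 800", "p2 p3 oops"))
  expect_error(read_links(path, "experimental", 0), "line 3")
})

test_that("threshold filtering is monotone", {
  set.seed(42)
  rows <- sprintf("n%d n%d %d", 1:40, 41:80, sample(0:1000, 40))
  path <- write_toy_links(rows)
  sizes <- vapply(c(0, 150, 400, 700, 1000),
                  function(t) n_edges(read_links(path, "experimental", t)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("link tables round-trip through write_links/read_links", {
  net <- interaction_network(data.frame(
    from = c("p1", "p2", "a9"), to = c("p2", "p3", "p1"),
    weight = c(0.8, 0.153, 0.7)))
  path <- tempfile()
  write_links(net, path)
  back <- read_links(path, "experimental", 0)
  expect_equal(back$edges, net$edges)
  expect_equal(back$nodes, net$nodes)
})

test_that("read_positive_pairs labels, dedups and respects the threshold", {
  path <- write_toy_links(
    c("p1 c1 800", "p1 c2 650", "p2 c1 700", "p2 c1 900"),
    header = "protein chemical experimental")
  pp <- read_positive_pairs(path, "experimental", 700)
  expect_equal(nrow(pp), 2L)
  expect_true(all(pp$label == 1L))

  empty <- write_toy_links(character(), header = "protein chemical experimental")
  expect_equal(nrow(read_positive_pairs(empty, "experimental", 700)), 0L)
  expect_equal(nrow(read_positive_pairs(path, "experimental", 0)), 3L)
})

test_that("read_positive_pairs swaps chemical-first columns", {
  path <- write_toy_links(c("c1 p1 800"),
                          header = "chemical protein experimental")
  pp <- read_positive_pairs(path, "experimental", 700)
  expect_equal(pp$protein_id, "p1")
  expect_equal(pp$compound_id, "c1")
})

test_that("sample_negatives draws the exact complement count", {
  pos <- labeled_pairs(c("p1", "p2"), c("c1", "c2"), c(1L, 1L))
  out <- sample_negatives(pos, paste0("p", 1:3), paste0("c", 1:3),
                          ratio = 2, seed = 1)
  expect_equal(sum(out$label == 1), 2L)
  expect_equal(sum(out$label == 0), 4L)
  neg <- out[out$label == 0, ]
  expect_false(any(paste(neg$protein_id, neg$compound_id) %in%
                   paste(pos$protein_id, pos$compound_id)))
  ## determinism
  out2 <- sample_negatives(pos, paste0("p", 1:3), paste0("c", 1:3),
                           ratio = 2, seed = 1)
  expect_identical(out, out2)
  out3 <- sample_negatives(pos, paste0("p", 1:3), paste0("c", 1:3),
                           ratio = 2, seed = 2)
  expect_false(identical(out, out3))
})

test_that("sample_negatives errors when the complement is too small", {
  pos <- labeled_pairs(paste0("p", 1:2), paste0("c", c(1, 2)), c(1L, 1L))
  ## universe 2x2 = 4, complement 2, request 4
  expect_error(
    sample_negatives(pos, paste0("p", 1:2), paste0("c", 1:2), ratio = 2,
                     seed = 1),
    "maximum achievable")
})

test_that("negative sampling hits round-half-up counts", {
  pos <- labeled_pairs(paste0("p", 1:3), paste0("c", 1:3), rep(1L, 3))
  out <- sample_negatives(pos, paste0("p", 1:10), paste0("c", 1:10),
                          ratio = 0.5, seed = 1)
  expect_equal(sum(out$label == 0), 2L)  # round_half_up(1.5)
})

test_that("restrict_to_common_entities drops uncovered pairs", {
  pairs <- labeled_pairs(c("p1", "p2", "p3"), c("c1", "c2", "c3"),
                         c(1L, 0L, 1L))
  ppi <- interaction_network(data.frame(from = c("p1", "p2"),
                                        to = c("p2", "p3"),
                                        weight = c(0.5, 0.5)))
  cci <- interaction_network(data.frame(from = "c1", to = "c2",
                                        weight = 0.5))
  seqs <- c(p1 = "ACDE", p2 = "ACDF", p3 = "ACDG")
  smi <- c(c1 = "CCO", c2 = "CCC", c3 = "CCN")
  out <- suppressMessages(
    restrict_to_common_entities(pairs, ppi, cci, seqs, smi))
  expect_equal(nrow(out), 2L)  # c3 not in cci
  ## identity when everything is covered
  cci2 <- interaction_network(data.frame(from = c("c1", "c2"),
                                         to = c("c2", "c3"),
                                         weight = c(0.5, 0.5)))
  out2 <- restrict_to_common_entities(pairs, ppi, cci2, seqs, smi)
  expect_equal(nrow(out2), 3L)
  ## empty networks give an empty result
  empty <- interaction_network(data.frame(from = character(),
                                          to = character(),
                                          weight = numeric()))
  out3 <- suppressMessages(
    restrict_to_common_entities(pairs, empty, empty, seqs, smi))
  expect_equal(nrow(out3), 0L)
})

test_that("FASTA and compound tables round-trip", {
  seqs <- c(P1 = "ACDEFGHIKL", P2 = "MNPQRSTVWY")
  fp <- tempfile(fileext = ".fasta")
  write_sequences(seqs, fp)
  expect_equal(read_sequences(fp), seqs)
  smi <- c(C1 = "CCO", C2 = "c1ccccc1")
  tp <- tempfile(fileext = ".tsv")
  write_compound_table(smi, tp)
  expect_equal(read_compound_table(tp), smi)
})
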