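test_that("benchmark generation is reproducible and exposes ground truth", {
  b1 <- tiny_benchmark(seed = 42)
  b2 <- tiny_benchmark(seed = 42)
  expect_identical(b1$sequences, b2$sequences)
  expect_identical(b1$pairs, b2$pairs)
  expect_identical(ground_truth(b1), ground_truth(b2))
  tr <- ground_truth(b1)
  expect_length(tr$protein_community, 20L)
  expect_equal(dim(tr$compat_network), c(2L, 2L))
  expect_equal(dim(tr$compat_molecular), c(2L, 2L))
  expect_true(all(tr$compat_network %in% c(-1, 1)))
  b3 <- tiny_benchmark(seed = 43)
  expect_false(identical(b1$pairs, b3$pairs))
})

test_that("generated files round-trip through the interactome readers", {
  b <- tiny_benchmark(seed = 13)
  dir <- tempfile()
  write_benchmark(b, dir)
  ppi <- read_links(file.path(dir, "ppi.tsv"), "experimental", 150)
  cci <- read_links(file.path(dir, "cci.tsv"), "similarity", 150)
  expect_equal(ppi$edges, b$ppi$edges)
  expect_equal(cci$edges, b$cci$edges)
  pos <- read_positive_pairs(file.path(dir, "pci.tsv"), "experimental", 700)
  want <- b$pairs[b$pairs$label == 1, c("protein_id", "compound_id")]
  expect_setequal(paste(pos$protein_id, pos$compound_id),
                  paste(want$protein_id, want$compound_id))
  expect_equal(read_sequences(file.path(dir, "sequences.fasta")),
               b$sequences)
  expect_equal(read_compound_table(file.path(dir, "compounds.tsv")),
               b$smiles)
})

test_that("label prevalence tracks the configured positive rate", {
  cfg <- synthetic_config(n_proteins = 40L, n_compounds = 40L,
                          n_pairs = 600L, positive_rate = 1 / 3, seed = 7)
  b <- generate_benchmark(cfg)
  rate <- mean(b$pairs$label)
  expect_gt(rate, 1 / 3 * 0.8)
  expect_lt(rate, 1 / 3 * 1.2)
  expect_error(generate_benchmark(synthetic_config(positive_rate = 0)),
               "infeasible")
})

test_that("community motifs appear in the generated sequences", {
  b <- tiny_benchmark(seed = 21, motif_insert_prob = 1)
  tr <- ground_truth(b)
  carries <- vapply(names(b$sequences), function(id) {
    grepl(tr$motifs[tr$motif_group[id]], b$sequences[[id]], fixed = TRUE)
  }, TRUE)
  expect_true(all(carries))
})

test_that("compound SMILES come from the group's template family", {
  b <- tiny_benchmark(seed = 22)
  tr <- ground_truth(b)
  ok <- vapply(names(b$smiles), function(id) {
    b$smiles[[id]] %in% dtifuse:::SMILES_TEMPLATES[[tr$template_group[id]]]
  }, TRUE)
  expect_true(all(ok))
  ## every SMILES parses into a fingerprint
  fps <- ecfp_matrix(b$smiles)
  expect_true(all(rowSums(fps) >= 1))
})

test_that("channel scores clear the conventional thresholds", {
  b <- tiny_benchmark(seed = 23)
  expect_true(all(b$ppi$edges$weight >= 0.15))
  expect_true(all(b$cci$edges$weight >= 0.15))
  dir <- tempfile()
  write_benchmark(b, dir)
  pci <- read.table(file.path(dir, "pci.tsv"), header = TRUE)
  expect_true(all(pci$experimental >= 700))
})

test_that("modality ablations steer which channel carries the label signal", {
  ## construction-level check on the hidden variables: with alpha = 0 the
  ## molecular-channel oracle must outrank the network-channel oracle, and
  ## vice versa (the trained-model version of this property lives in the
  ## end-to-end acceptance tests)
  oracle_aurocs <- function(alpha, beta, seed) {
    b <- generate_benchmark(synthetic_config(alpha = alpha, beta = beta,
                                             seed = seed))
    tr <- ground_truth(b)
    p <- b$pairs
    k <- tr$protein_community[p$protein_id]
    l <- tr$compound_community[p$compound_id]
    m <- tr$motif_group[p$protein_id]
    t <- tr$template_group[p$compound_id]
    c(net = auroc(tr$compat_network[cbind(k, l)], p$label),
      mol = auroc(tr$compat_molecular[cbind(m, t)], p$label))
  }
  for (seed in 31:33) {
    mol_only <- oracle_aurocs(alpha = 0, beta = 2, seed)
    expect_gt(mol_only[["mol"]], mol_only[["net"]])
    net_only <- oracle_aurocs(alpha = 2, beta = 0, seed)
    expect_gt(net_only[["net"]], net_only[["mol"]])
  }
})

test_that("without any planted signal all models sit near chance", {
  b <- generate_benchmark(synthetic_config(
    n_proteins = 30L, n_compounds = 30L, n_pairs = 300L,
    seq_length = c(40L, 60L), alpha = 0, beta = 0, motif_insert_prob = 0,
    p_in = 0.15, p_out = 0.15, seed = 37))
  features <- bench_features(b, emb_dim = 8, seed = 37)
  fa <- split_baseline(b$pairs, 5, seed = 37)
  tr <- train_pairs(fa, 0); te <- test_pairs(fa, 0)
  cfg <- small_training_config(seed = 37, epochs = 15L)
  for (m in c("molecular", "network")) {
    fit <- train_fusion(tr, features, cfg, mode = m)
    a <- auroc(predict(fit, te, features)$score, te$label)
    expect_gt(a, 0.3)
    expect_lt(a, 0.7)
  }
})
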