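## Small deterministic fusion model with directly set weights.
toy_model <- function(mode = "network", pf = 3, pc = 3, d = 2, seed = 1) {
  cfg <- training_config(latent_dim = d, dropout = 0, seed = seed)
  m <- fusion_model(mode, a_dim = pf, b_dim = pc, np_dim = pf, nc_dim = pc,
                    cfg = cfg)
  m
}

test_that("output layer h reproduces its closed form", {
  m <- toy_model("network", pf = 2, pc = 2, d = 2)
  ## f, g = identity; h weights all 1, bias 0
  m$par$Wf <- diag(2); m$par$bf <- c(0, 0)
  m$par$Wg <- diag(2); m$par$bg <- c(0, 0)
  m$par$wh <- c(1, 1); m$par$bh <- 0
  ## x = y = e1 -> score = sigmoid(1)
  expect_equal(fusion_forward(m, c(1, 0), c(1, 0)), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  ## x = 0 -> sigmoid(bias) = 0.5
  expect_equal(fusion_forward(m, c(0, 0), c(1, 0)), 0.5)
  expect_error(fusion_forward(m, c(1, 0, 0), c(1, 0)), "dimension")
})

test_that("forward matches the direct matrix-arithmetic oracle", {
  set.seed(31)
  for (rep in 1:25) {
    pf <- sample(2:6, 1); pc <- sample(2:6, 1); d <- sample(2:5, 1)
    m <- toy_model("network", pf = pf, pc = pc, d = d, seed = rep)
    vp <- rnorm(pf); vc <- rnorm(pc)
    expect_equal(
      fusion_forward(m, vp, vc),
      brute_fusion_score(m$par$Wf, m$par$bf, m$par$Wg, m$par$bg,
                         m$par$wh, m$par$bh, vp, vc),
      tolerance = 1e-6)
  }
})

test_that("the model is not symmetric under swapping sides (f != g)", {
  m <- toy_model("network", pf = 3, pc = 3, d = 2, seed = 4)
  vp <- c(1, 2, 3); vc <- c(3, 1, 2)
  expect_false(isTRUE(all.equal(fusion_forward(m, vp, vc),
                                fusion_forward(m, vc, vp))))
  ## but symmetric when f = g by construction
  m$par$Wg <- m$par$Wf; m$par$bg <- m$par$bf
  expect_equal(fusion_forward(m, vp, vc), fusion_forward(m, vc, vp))
})

test_that("loss combines cross-entropy and the L2 term", {
  expect_equal(fusion_loss(0.5, 1, lambda = 0), -log(0.5), tolerance = 1e-4)
  ## penalty lambda/2 * sum(w^2): weights {1, 2}, lambda 0.1 -> 0.25
  expect_equal(fusion_loss(c(1e-12 + 0.5), c(1), lambda = 0.1,
                           weights = list(1, 2)) - fusion_loss(0.5, 1),
               0.25, tolerance = 1e-9)
  ## lambda 0 reduces to pure cross-entropy
  set.seed(1)
  s <- runif(10, 0.1, 0.9); y <- rbinom(10, 1, 0.5)
  expect_equal(fusion_loss(s, y, lambda = 0),
               -mean(y * log(s) + (1 - y) * log(1 - s)))
  expect_warning(fusion_loss(c(0, 0.5), c(0, 1)), "clipped")
})

test_that("numerical gradients validate the analytic backward pass", {
  ## finite differences on a tiny integrated model (no dropout; batch norm
  ## exercised in training mode)
  bench <- tiny_benchmark(seed = 12)
  feats_raw <- bench_features(bench, emb_dim = 4, seed = 12)
  cfg <- training_config(latent_dim = 3, dropout = 0, lambda = 0,
                         cnn_filters = c(3L, 2L), cnn_widths = c(3L, 2L),
                         batch_norm = TRUE, seed = 5)
  model <- fusion_model("integrated", b_dim = 1024, np_dim = 4, nc_dim = 4,
                        cfg = cfg)
  pairs <- bench$pairs[1:6, ]
  feats <- dtifuse:::assemble_features(model, pairs, feats_raw)
  labels <- pairs$label
  loss_at <- function(model) {
    fwd <- dtifuse:::model_forward_batch(model, feats, 1:6, training = TRUE)
    sc <- pmin(pmax(fwd$scores, 1e-12), 1 - 1e-12)
    -mean(labels * log(sc) + (1 - labels) * log(1 - sc))
  }
  fwd <- dtifuse:::model_forward_batch(model, feats, 1:6, training = TRUE)
  grads <- dtifuse:::model_backward_batch(model, feats, fwd, labels)
  eps <- 1e-5
  check_num <- function(get, set, g, label) {
    m1 <- set(model, get(model) + eps)
    m2 <- set(model, get(model) - eps)
    num <- (loss_at(m1) - loss_at(m2)) / (2 * eps)
    expect_equal(g, num, tolerance = 1e-4, info = label)
  }
  ## spot-check one coordinate of each parameter family
  check_num(function(m) m$par$wh[2],
            function(m, v) { m$par$wh[2] <- v; m },
            grads$par$wh[2], "wh")
  check_num(function(m) m$par$Wf[2, 3],
            function(m, v) { m$par$Wf[2, 3] <- v; m },
            grads$par$Wf[2, 3], "Wf")
  check_num(function(m) m$par$Wg[1, 5],
            function(m, v) { m$par$Wg[1, 5] <- v; m },
            grads$par$Wg[1, 5], "Wg")
  check_num(function(m) m$par$bh,
            function(m, v) { m$par$bh <- v; m },
            grads$par$bh, "bh")
  check_num(function(m) m$cnn$layers[[1]]$W[2, 7],
            function(m, v) { m$cnn$layers[[1]]$W[2, 7] <- v; m },
            grads$cnn[[1]]$W[2, 7], "conv W layer 1")
  check_num(function(m) m$cnn$layers[[2]]$W[1, 4],
            function(m, v) { m$cnn$layers[[2]]$W[1, 4] <- v; m },
            grads$cnn[[2]]$W[1, 4], "conv W layer 2")
  check_num(function(m) m$cnn$layers[[1]]$gamma[2],
            function(m, v) { m$cnn$layers[[1]]$gamma[2] <- v; m },
            grads$cnn[[1]]$gamma[2], "bn gamma")
  check_num(function(m) m$cnn$layers[[1]]$beta[1],
            function(m, v) { m$cnn$layers[[1]]$beta[1] <- v; m },
            grads$cnn[[1]]$beta[1], "bn beta")
})

test_that("training is reproducible and regularization shrinks weights", {
  bench <- tiny_benchmark(seed = 9)
  features <- bench_features(bench, emb_dim = 6, seed = 9)
  cfg <- small_training_config(seed = 2, epochs = 6L)
  f1 <- train_fusion(bench$pairs, features, cfg, mode = "network")
  f2 <- train_fusion(bench$pairs, features, cfg, mode = "network")
  expect_identical(f1$history, f2$history)
  expect_identical(f1$par, f2$par)
  ## heavy L2 leaves a smaller weight norm than no L2, same seed
  cfg0 <- small_training_config(seed = 2, epochs = 6L, lambda = 0)
  cfgL <- small_training_config(seed = 2, epochs = 6L, lambda = 10)
  w0 <- train_fusion(bench$pairs, features, cfg0, mode = "network")
  wL <- train_fusion(bench$pairs, features, cfgL, mode = "network")
  norm_of <- function(m) sqrt(sum(unlist(lapply(
    dtifuse:::weight_arrays(m), function(w) sum(w^2)))))
  expect_lt(norm_of(wL), norm_of(w0))
  expect_error(train_fusion(bench$pairs[0, ], features, cfg), "empty")
})

test_that("prediction applies a strict decision threshold", {
  df <- data.frame(score = c(0.51, 0.5, 0.49))
  expect_equal(as.integer(df$score > 0.5), c(1L, 0L, 0L))
  bench <- tiny_benchmark(seed = 10)
  features <- bench_features(bench, emb_dim = 6, seed = 10)
  cfg <- small_training_config(seed = 3, epochs = 4L)
  fit <- train_fusion(bench$pairs, features, cfg, mode = "network")
  pr0 <- predict(fit, bench$pairs, features, threshold = 1e-9)
  expect_true(all(pr0$predicted == 1L))
  ## missing features are reported by entity
  bad <- labeled_pairs("unknown_protein", bench$pairs$compound_id[1], 1L)
  expect_error(predict(fit, bad, features), "unknown_protein")
})
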