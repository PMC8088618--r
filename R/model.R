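## The integrated protein-compound interaction model and its two
## single-modality ablations.
##
## Protein side: v_protein = concat(a_protein, N_protein) where a_protein is
## the 1D-CNN encoding of the sequence and N_protein its node2vec embedding.
## Compound side: v_compound = concat(b_compound, N_compound) with b_compound
## the ECFP bit vector. Both sides are mapped into a shared latent space of
## dimension d by affine layers f and g; the output layer h scores the
## element-wise product (x1*y1, ..., xd*yd) — a learned extension of cosine
## similarity — and a sigmoid turns it into an interaction probability.
## Single-modality modes apply f/g to their sole feature vector.

#' Training configuration for the fusion model
#'
#' @param epochs maximum training epochs (default 200; convergence typically
#'   takes tens to hundreds).
#' @param batch_size mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param lambda L2 (weight-decay) strength on weight matrices.
#' @param dropout dropout rate applied after the fully connected latent maps
#'   during training.
#' @param latent_dim shared latent dimension d.
#' @param threshold decision threshold on the sigmoid output (default 0.5).
#' @param validation_split fraction of training pairs held out for early
#'   stopping (0 disables early stopping).
#' @param patience epochs without validation improvement before stopping.
#' @param min_epochs burn-in before early stopping may trigger; the fused
#'   model warms up slowly, so stopping is not meaningful in the first
#'   epochs.
#' @param cnn_filters,cnn_widths,pool 1D-CNN architecture (per layer).
#' @param batch_norm insert batch normalization after each conv layer.
#' @param max_len one-hot width; defaults to the longest training sequence.
#' @param seed RNG seed controlling initialization, batching and dropout.
#' @return Object of class `training_config`.
#' @export
training_config <- function(epochs = 200L, batch_size = 128L,
                            learning_rate = 1e-3, lambda = 1e-4,
                            dropout = 0.5, latent_dim = 128L,
                            threshold = 0.5, validation_split = 0.1,
                            patience = 20L, min_epochs = 20L,
                            cnn_filters = c(64L, 64L),
                            cnn_widths = c(7L, 5L), pool = 2L,
                            batch_norm = TRUE, max_len = NULL, seed = 1L) {
  check_that(threshold > 0 && threshold < 1, "`threshold` must be in (0,1)")
  check_that(lambda >= 0, "`lambda` must be >= 0")
  check_that(dropout >= 0 && dropout < 1, "`dropout` must be in [0,1)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lambda = lambda,
                 dropout = dropout, latent_dim = as.integer(latent_dim),
                 threshold = threshold, validation_split = validation_split,
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 cnn_filters = as.integer(cnn_filters),
                 cnn_widths = as.integer(cnn_widths), pool = as.integer(pool),
                 batch_norm = isTRUE(batch_norm), max_len = max_len,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Construct an (untrained) fusion model
#'
#' Initializes the latent maps f and g, the output layer h and, for
#' sequence-consuming modes, the 1D-CNN encoder. Input dimensions: `a_dim`
#' (CNN output / protein molecular feature), `b_dim` (fingerprint length),
#' `np_dim` / `nc_dim` (node2vec dimensions). Only the dimensions required
#' by `mode` are used.
#'
#' @param mode `"integrated"`, `"molecular"` or `"network"`.
#' @param a_dim,b_dim,np_dim,nc_dim feature dimensions (see above).
#' @param cfg a [training_config()].
#' @param cnn optional pre-built [cnn_params()]; by default one is created
#'   from `cfg` for modes that read sequences.
#' @return Object of class `fusion_model`.
#' @export
fusion_model <- function(mode = c("integrated", "molecular", "network"),
                         a_dim = NULL, b_dim = NULL, np_dim = NULL,
                         nc_dim = NULL, cfg = training_config(), cnn = NULL) {
  mode <- match.arg(mode)
  uses_cnn <- mode %in% c("integrated", "molecular")
  if (uses_cnn && is.null(cnn)) {
    cnn <- cnn_params(filters = cfg$cnn_filters, widths = cfg$cnn_widths,
                      pool = cfg$pool, batch_norm = cfg$batch_norm,
                      seed = cfg$seed)
  }
  if (uses_cnn) a_dim <- cnn$out_dim
  pf <- switch(mode, integrated = a_dim + np_dim, molecular = a_dim,
               network = np_dim)
  pc <- switch(mode, integrated = b_dim + nc_dim, molecular = b_dim,
               network = nc_dim)
  check_that(!is.null(pf) && !is.null(pc) && pf >= 1 && pc >= 1,
             "required feature dimensions missing for this mode")
  d <- cfg$latent_dim
  par <- with_seed(cfg$seed + 1L, {
    if (mode == "integrated") {
      ## modality-aligned initialization: each half of the latent space is
      ## wired to one modality (molecular | network), so at initialization
      ## the element-wise-product head decomposes into the sum of one
      ## bilinear score per modality — a late-fusion starting point that
      ## training is free to move away from (the off-blocks start at zero
      ## but receive gradients).
      d1 <- d %/% 2L
      blockwise <- function(rows_a, rows_b, cols_a, cols_b) {
        W <- matrix(0, nrow = d, ncol = cols_a + cols_b)
        W[seq_len(rows_a), seq_len(cols_a)] <-
          stats::rnorm(rows_a * cols_a, sd = sqrt(2 / cols_a))
        W[(rows_a + 1):d, cols_a + seq_len(cols_b)] <-
          stats::rnorm(rows_b * cols_b, sd = sqrt(2 / cols_b))
        W
      }
      list(Wf = blockwise(d1, d - d1, a_dim, np_dim),
           bf = numeric(d),
           Wg = blockwise(d1, d - d1, b_dim, nc_dim),
           bg = numeric(d),
           wh = stats::rnorm(d, sd = sqrt(1 / d)),
           bh = 0)
    } else {
      list(Wf = matrix(stats::rnorm(d * pf, sd = sqrt(2 / pf)), nrow = d),
           bf = numeric(d),
           Wg = matrix(stats::rnorm(d * pc, sd = sqrt(2 / pc)), nrow = d),
           bg = numeric(d),
           wh = stats::rnorm(d, sd = sqrt(1 / d)),
           bh = 0)
    }
  })
  structure(list(mode = mode, cnn = if (uses_cnn) cnn else NULL,
                 par = par, dims = list(a = a_dim, b = b_dim,
                                        np = np_dim, nc = nc_dim,
                                        pf = pf, pc = pc, d = d),
                 cfg = cfg, max_len = cfg$max_len, history = NULL),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("fusion_model (%s mode): latent d=%d, f: %d->%d, g: %d->%d%s\n",
              x$mode, x$dims$d, x$dims$pf, x$dims$d, x$dims$pc, x$dims$d,
              if (!is.null(x$cnn)) sprintf(", CNN out %d", x$cnn$out_dim)
              else ""))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, final train loss %.4f\n",
                nrow(x$history), x$history$train_loss[nrow(x$history)]))
  }
  invisible(x)
}

## ---- forward -------------------------------------------------------------

as_feature_vector <- function(input, model, side) {
  if (side == "protein" && inherits(input, "one_hot_sequence")) {
    check_that(!is.null(model$cnn), "model has no CNN encoder")
    return(cnn_encode(input, model$cnn))
  }
  if (is.list(input) && !is.null(input$a) && !is.null(input$N)) {
    a <- if (inherits(input$a, "one_hot_sequence")) {
      cnn_encode(input$a, model$cnn)
    } else {
      as.numeric(input$a)
    }
    return(c(a, as.numeric(input$N)))
  }
  if (is.list(input) && !is.null(input$b) && !is.null(input$N)) {
    b <- if (inherits(input$b, "compound_fingerprint")) input$b$bits
         else as.numeric(input$b)
    return(c(b, as.numeric(input$N)))
  }
  if (inherits(input, "compound_fingerprint")) return(as.numeric(input$bits))
  as.numeric(input)
}

#' Score one protein-compound pair
#'
#' Inference-mode forward pass: `score = sigmoid(h(x1*y1, ..., xd*yd))` with
#' `x = f(v_protein)` and `y = g(v_compound)`. Inputs per mode —
#' integrated: `list(a = , N = )` per side (`a` may be a `one_hot_sequence`,
#' `b` a `compound_fingerprint`); molecular: the molecular feature alone;
#' network: the embedding alone.
#'
#' @param model a [fusion_model()].
#' @param protein_input,compound_input feature input for each side.
#' @return Interaction score in (0, 1).
#' @export
fusion_forward <- function(model, protein_input, compound_input) {
  vp <- as_feature_vector(protein_input, model, "protein")
  vc <- as_feature_vector(compound_input, model, "compound")
  if (length(vp) != model$dims$pf) {
    stop(sprintf("protein input dimension %d does not match model (%d)",
                 length(vp), model$dims$pf), call. = FALSE)
  }
  if (length(vc) != model$dims$pc) {
    stop(sprintf("compound input dimension %d does not match model (%d)",
                 length(vc), model$dims$pc), call. = FALSE)
  }
  p <- model$par
  x <- drop(p$Wf %*% vp) + p$bf
  y <- drop(p$Wg %*% vc) + p$bg
  as.numeric(sigmoid(sum(p$wh * x * y) + p$bh))
}

#' Training objective: cross-entropy plus L2 penalty
#'
#' Mean binary cross-entropy of `scores` against `labels`, plus
#' `lambda/2 * sum(w^2)` over the model's weight matrices (conv filters and
#' f, g, h weights; biases and batch-norm parameters are not decayed).
#' Scores exactly 0 or 1 are clipped to `1e-12` away from the boundary with
#' a warning.
#'
#' @param scores predicted probabilities in (0, 1).
#' @param labels 0/1 labels, same length.
#' @param model optional [fusion_model()] supplying the penalized weights;
#'   alternatively `weights` may be a list of numeric arrays.
#' @param lambda L2 strength.
#' @param weights optional explicit list of weight arrays.
#' @return Non-negative scalar loss.
#' @export
fusion_loss <- function(scores, labels, model = NULL, lambda = 0,
                        weights = NULL) {
  check_that(length(scores) == length(labels),
             "`scores` and `labels` must have equal length")
  if (any(scores <= 0 | scores >= 1)) {
    warning("scores at the 0/1 boundary clipped to 1e-12")
    scores <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  }
  bce <- -mean(labels * log(scores) + (1 - labels) * log(1 - scores))
  if (lambda > 0) {
    if (is.null(weights) && !is.null(model)) weights <- weight_arrays(model)
    pen <- if (length(weights)) sum(vapply(weights, function(w) sum(w^2), 0))
           else 0
    bce <- bce + lambda * pen / 2
  }
  bce
}

weight_arrays <- function(model) {
  w <- list(model$par$Wf, model$par$Wg, model$par$wh)
  if (!is.null(model$cnn)) {
    w <- c(w, lapply(model$cnn$layers, `[[`, "W"))
  }
  w
}

## ---- feature assembly ----------------------------------------------------

## Check coverage and build per-pair fixed feature matrices; CNN inputs stay
## per-protein (variable length).
assemble_features <- function(model, pairs, features) {
  mode <- model$mode
  need_seq <- mode %in% c("integrated", "molecular")
  need_fp <- need_seq
  need_emb <- mode %in% c("integrated", "network")
  pids <- pairs$protein_id
  cids <- pairs$compound_id
  missing <- character()
  if (need_seq) {
    missing <- c(missing, setdiff(pids, names(features$sequences)))
  }
  if (need_fp) {
    missing <- c(missing, setdiff(cids, rownames(features$fingerprints)))
  }
  if (need_emb) {
    missing <- c(missing, setdiff(pids, rownames(features$protein_embeddings)),
                 setdiff(cids, rownames(features$compound_embeddings)))
  }
  missing <- unique(missing)
  if (length(missing)) {
    stop(sprintf("missing features for entities: %s",
                 paste(utils::head(missing, 10), collapse = ", ")),
         call. = FALSE)
  }
  uniq_prot <- unique(pids)
  out <- list(prot_index = match(pids, uniq_prot), uniq_prot = uniq_prot)
  ## balance the input blocks: each feature table is scaled to mean row
  ## norm 1 so that no modality dominates the concatenated input by sheer
  ## magnitude (fingerprints have ~sqrt(bits set), embeddings their own
  ## arbitrary scale). Deterministic given the feature tables.
  block_scale <- function(m) {
    s <- mean(sqrt(rowSums(m^2)))
    if (s > 0) m / s else m
  }
  if (need_fp) features$fingerprints <- block_scale(features$fingerprints)
  if (need_emb) {
    features$protein_embeddings <- block_scale(features$protein_embeddings)
    features$compound_embeddings <- block_scale(features$compound_embeddings)
  }
  if (need_seq) {
    max_len <- model$max_len %||%
      max(nchar(features$sequences[uniq_prot]))
    out$one_hots <- lapply(features$sequences[uniq_prot], one_hot_encode,
                           max_len = max_len)
    out$max_len <- max_len
    if (!is.null(model$cnn)) {
      r1 <- model$cnn$widths[1]
      out$cim1 <- lapply(out$one_hots, function(oh) {
        im2col(oh$matrix[, seq_len(oh$true_length), drop = FALSE], r1)
      })
    }
  }
  ## fixed (non-CNN) protein part
  out$Np <- if (need_emb) t(features$protein_embeddings[pids, , drop = FALSE])
  ## compound matrix pc x npairs
  out$Vc <- switch(mode,
    integrated = rbind(t(features$fingerprints[cids, , drop = FALSE]),
                       t(features$compound_embeddings[cids, , drop = FALSE])),
    molecular = t(features$fingerprints[cids, , drop = FALSE]),
    network = t(features$compound_embeddings[cids, , drop = FALSE]))
  out
}

## Batched forward. idx: pair indices. Returns scores + cache for backprop.
model_forward_batch <- function(model, feats, idx, training = FALSE,
                                dropout_masks = NULL) {
  mode <- model$mode
  p <- model$par
  cache <- list(idx = idx)
  if (!is.null(model$cnn)) {
    sub_prot <- unique(feats$prot_index[idx])
    local_ix <- match(feats$prot_index[idx], sub_prot)
    fwd <- cnn_forward_batch(feats$one_hots[sub_prot], model$cnn,
                             training = training,
                             cim1 = feats$cim1[sub_prot])
    A <- fwd$out                       # s x n_uniq
    cache$cnn_fwd <- fwd
    cache$sub_prot <- sub_prot
    cache$local_ix <- local_ix
    Vp <- A[, local_ix, drop = FALSE]
    if (mode == "integrated") Vp <- rbind(Vp, feats$Np[, idx, drop = FALSE])
  } else {
    Vp <- feats$Np[, idx, drop = FALSE]
  }
  Vc <- feats$Vc[, idx, drop = FALSE]
  X <- p$Wf %*% Vp + p$bf
  Y <- p$Wg %*% Vc + p$bg
  if (training && model$cfg$dropout > 0) {
    rate <- model$cfg$dropout
    Mx <- dropout_masks$Mx %||%
      (matrix(stats::rbinom(length(X), 1, 1 - rate), nrow = nrow(X)) / (1 - rate))
    My <- dropout_masks$My %||%
      (matrix(stats::rbinom(length(Y), 1, 1 - rate), nrow = nrow(Y)) / (1 - rate))
    Xd <- X * Mx
    Yd <- Y * My
    cache$Mx <- Mx; cache$My <- My
  } else {
    Xd <- X; Yd <- Y
  }
  P <- Xd * Yd
  logits <- drop(crossprod(P, p$wh)) + p$bh
  cache$Vp <- Vp; cache$Vc <- Vc; cache$Xd <- Xd; cache$Yd <- Yd; cache$P <- P
  list(scores = sigmoid(logits), cache = cache)
}

## Gradients of mean BCE + L2 wrt all trainable parameters.
model_backward_batch <- function(model, feats, fwd, labels) {
  p <- model$par
  ca <- fwd$cache
  n <- length(labels)
  dlogit <- (fwd$scores - labels) / n
  g <- list(
    Wf = NULL, bf = NULL, Wg = NULL, bg = NULL,
    wh = drop(ca$P %*% dlogit), bh = sum(dlogit))
  dP <- outer(p$wh, dlogit)
  dXd <- dP * ca$Yd
  dYd <- dP * ca$Xd
  dX <- if (!is.null(ca$Mx)) dXd * ca$Mx else dXd
  dY <- if (!is.null(ca$My)) dYd * ca$My else dYd
  g$Wf <- dX %*% t(ca$Vp)
  g$bf <- rowSums(dX)
  g$Wg <- dY %*% t(ca$Vc)
  g$bg <- rowSums(dY)
  lam <- model$cfg$lambda
  if (lam > 0) {
    g$Wf <- g$Wf + lam * p$Wf
    g$Wg <- g$Wg + lam * p$Wg
    g$wh <- g$wh + lam * p$wh
  }
  cnn_grads <- NULL
  if (!is.null(model$cnn)) {
    dVp <- t(p$Wf) %*% dX
    s <- model$cnn$out_dim
    dA_pairs <- dVp[seq_len(s), , drop = FALSE]
    n_uniq <- length(ca$sub_prot)
    dA <- matrix(0, nrow = s, ncol = n_uniq)
    for (j in seq_along(ca$local_ix)) {
      dA[, ca$local_ix[j]] <- dA[, ca$local_ix[j]] + dA_pairs[, j]
    }
    cnn_grads <- cnn_backward_batch(ca$cnn_fwd, dA, model$cnn)$layers
    if (lam > 0) {
      for (l in seq_along(cnn_grads)) {
        cnn_grads[[l]]$W <- cnn_grads[[l]]$W + lam * model$cnn$layers[[l]]$W
      }
    }
  }
  list(par = g, cnn = cnn_grads)
}

## ---- trainable-parameter plumbing (flatten for Adam) ---------------------

trainables <- function(model) {
  th <- model$par
  if (!is.null(model$cnn)) {
    th$cnn <- lapply(model$cnn$layers, function(l) {
      l[intersect(c("W", "b", "gamma", "beta"), names(l))]
    })
  }
  th
}

set_trainables <- function(model, th) {
  model$par <- th[c("Wf", "bf", "Wg", "bg", "wh", "bh")]
  if (!is.null(model$cnn)) {
    for (l in seq_along(model$cnn$layers)) {
      for (nm in names(th$cnn[[l]])) {
        model$cnn$layers[[l]][[nm]] <- th$cnn[[l]][[nm]]
      }
    }
  }
  model
}

grads_as_trainables <- function(model, grads) {
  th <- grads$par
  if (!is.null(model$cnn)) th$cnn <- grads$cnn
  th
}

## ---- training ------------------------------------------------------------

#' Train the fusion model
#'
#' Mini-batch Adam training of the sigmoid cross-entropy + L2 objective.
#' Batch normalization (batch statistics during training, running statistics
#' at inference) follows each convolutional layer; dropout follows the fully
#' connected latent maps and is disabled at inference. When
#' `cfg$validation_split > 0` a held-out slice of the training pairs drives
#' early stopping (best-validation weights are restored). Fully reproducible
#' from `cfg$seed`.
#'
#' @param pairs a [labeled_pairs()] training set.
#' @param features list with the entries required by the mode: `sequences`
#'   (named character), `fingerprints` (matrix, rownames = compound IDs),
#'   `protein_embeddings`, `compound_embeddings` (matrices, rownames = IDs).
#' @param cfg a [training_config()].
#' @param mode `"integrated"`, `"molecular"` or `"network"`.
#' @return A trained [fusion_model()]; `$history` holds per-epoch losses.
#' @export
train_fusion <- function(pairs, features, cfg = training_config(),
                         mode = c("integrated", "molecular", "network")) {
  mode <- match.arg(mode)
  check_that(nrow(pairs) > 0, "empty training set")
  model <- fusion_model(
    mode = mode,
    b_dim = if (mode != "network") ncol(features$fingerprints),
    np_dim = if (mode != "molecular") ncol(features$protein_embeddings),
    nc_dim = if (mode != "molecular") ncol(features$compound_embeddings),
    cfg = cfg)
  feats <- assemble_features(model, pairs, features)
  model$max_len <- feats$max_len %||% model$max_len
  labels <- pairs$label
  n <- nrow(pairs)

  with_seed(cfg$seed + 2L, {
    ## validation split for early stopping
    n_val <- floor(cfg$validation_split * n)
    val_idx <- if (n_val >= 1) sample(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)

    th <- trainables(model)
    flat <- unlist(th)
    m_adam <- numeric(length(flat))
    v_adam <- numeric(length(flat))
    t_adam <- 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    best_val <- Inf
    best_flat <- flat
    best_model <- model
    stall <- 0L

    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample(tr_idx)
      batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        fwd <- model_forward_batch(model, feats, bt, training = TRUE)
        if (!is.null(model$cnn)) model$cnn <- fwd$cache$cnn_fwd$params
        grads <- model_backward_batch(model, feats, fwd, labels[bt])
        gflat <- unlist(grads_as_trainables(model, grads))
        t_adam <- t_adam + 1
        m_adam <- b1 * m_adam + (1 - b1) * gflat
        v_adam <- b2 * v_adam + (1 - b2) * gflat^2
        mh <- m_adam / (1 - b1^t_adam)
        vh <- v_adam / (1 - b2^t_adam)
        flat <- unlist(trainables(model)) -
          cfg$learning_rate * mh / (sqrt(vh) + eps)
        model <- set_trainables(model, utils::relist(flat, th))
        sc <- pmin(pmax(fwd$scores, 1e-12), 1 - 1e-12)
        ep_loss <- ep_loss + sum(-(labels[bt] * log(sc) +
                                   (1 - labels[bt]) * log(1 - sc)))
      }
      train_loss <- ep_loss / length(tr_idx) +
        cfg$lambda * sum(vapply(weight_arrays(model),
                                function(w) sum(w^2), 0)) / 2
      val_loss <- NA_real_
      if (length(val_idx)) {
        vf <- model_forward_batch(model, feats, val_idx, training = FALSE)
        val_loss <- fusion_loss(pmin(pmax(vf$scores, 1e-12), 1 - 1e-12),
                                labels[val_idx], model = model,
                                lambda = cfg$lambda)
        ## early stopping tracks validation AUROC (the deployment metric);
        ## cross-entropy keeps rising with overconfidence even while the
        ## ranking still improves, so it is logged but not used to stop
        val_crit <- if (length(unique(labels[val_idx])) == 2) {
          -auroc(vf$scores, labels[val_idx])
        } else {
          val_loss
        }
        if (val_crit < best_val - 1e-6) {
          best_val <- val_crit
          best_model <- model
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (epoch > cfg$min_epochs && stall >= cfg$patience) {
            history <- rbind(history, data.frame(
              epoch = epoch, train_loss = train_loss, val_loss = val_loss))
            break
          }
        }
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = train_loss, val_loss = val_loss))
    }
    if (length(val_idx)) model <- best_model
    model$history <- unique(history)
    model
  })
}

#' Predict interactions for protein-compound pairs
#'
#' Inference-mode scoring; a pair is labelled interacting (1) iff its score
#' strictly exceeds `threshold` (a score equal to the threshold is negative).
#'
#' @param object a trained [fusion_model()].
#' @param pairs a [labeled_pairs()] set (labels ignored if present).
#' @param features as in [train_fusion()].
#' @param threshold decision threshold (default from the training config).
#' @param ... unused.
#' @return data.frame `protein_id`, `compound_id`, `score`, `predicted`.
#' @export
predict.fusion_model <- function(object, pairs, features,
                                 threshold = object$cfg$threshold, ...) {
  feats <- assemble_features(object, pairs, features)
  ## score in manageable chunks (CNN forward is per-protein)
  n <- nrow(pairs)
  scores <- numeric(n)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 512))
  for (ch in chunks) {
    scores[ch] <- model_forward_batch(object, feats, ch,
                                      training = FALSE)$scores
  }
  data.frame(protein_id = pairs$protein_id, compound_id = pairs$compound_id,
             score = scores, predicted = as.integer(scores > threshold),
             stringsAsFactors = FALSE)
}
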