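## 1D convolutional encoder for one-hot protein sequences.
##
## Architecture per layer: full-height 1-D convolution along the sequence
## axis, bias, (optional) batch normalization, Leaky-ReLU, average pooling;
## after the last layer a global max-pool over the remaining (valid,
## non-padding) positions yields one value per filter. Padding columns are
## never part of any retained position: each layer keeps only the positions
## computable from real residues, which makes the encoding invariant to the
## amount of right-padding.

#' Construct 1D-CNN encoder parameters
#'
#' Initializes filter weights (He-scaled Gaussian), biases and, when
#' `batch_norm = TRUE`, per-channel scale/shift plus running statistics. The
#' number of filters in the last layer is the output dimension of
#' [cnn_encode()].
#'
#' @param input_height rows of the input (20 for one-hot amino acids).
#' @param filters integer vector, filters per convolutional layer.
#' @param widths integer vector, filter width r per layer (same length).
#' @param pool average-pooling window and stride applied after every
#'   convolution (default 2).
#' @param leaky_slope negative-side slope of the Leaky-ReLU (default 0.01).
#' @param batch_norm logical; insert batch normalization after each
#'   convolution (used during model training; plain encoders default off).
#' @param seed RNG seed for weight initialization.
#' @return Object of class `cnn_params`.
#' @export
cnn_params <- function(input_height = 20L, filters = c(64L, 64L),
                       widths = c(7L, 5L), pool = 2L, leaky_slope = 0.01,
                       batch_norm = FALSE, seed = 1L) {
  check_that(length(filters) == length(widths) && length(filters) >= 1,
             "`filters` and `widths` must have equal length >= 1")
  check_that(all(widths >= 1), "filter widths must be >= 1")
  layers <- with_seed(seed, {
    n_in <- as.integer(input_height)
    lapply(seq_along(filters), function(l) {
      fan_in <- widths[l] * n_in
      W <- matrix(stats::rnorm(filters[l] * fan_in, sd = sqrt(2 / fan_in)),
                  nrow = filters[l])
      lay <- list(W = W, b = numeric(filters[l]))
      if (batch_norm) {
        lay$gamma <- rep(1, filters[l])
        lay$beta <- numeric(filters[l])
        lay$run_mean <- numeric(filters[l])
        lay$run_var <- rep(1, filters[l])
      }
      n_in <<- as.integer(filters[l])
      lay
    })
  })
  structure(list(input_height = as.integer(input_height),
                 filters = as.integer(filters), widths = as.integer(widths),
                 pool = as.integer(pool), leaky_slope = leaky_slope,
                 batch_norm = isTRUE(batch_norm), layers = layers,
                 out_dim = as.integer(filters[length(filters)])),
            class = "cnn_params")
}

#' @export
print.cnn_params <- function(x, ...) {
  cat(sprintf(
    "cnn_params: %d conv layer(s), filters [%s], widths [%s], pool %d, %s\n",
    length(x$filters), paste(x$filters, collapse = ","),
    paste(x$widths, collapse = ","), x$pool,
    if (x$batch_norm) "batch norm" else "no batch norm"))
  invisible(x)
}

## Unfold X (channels x positions) into (r*channels) x (P - r + 1) columns of
## stacked sliding windows.
im2col <- function(X, r) {
  n <- nrow(X); P <- ncol(X) - r + 1L
  out <- matrix(0, nrow = n * r, ncol = P)
  for (j in seq_len(r)) {
    out[((j - 1L) * n + 1L):(j * n), ] <- X[, j:(j + P - 1L), drop = FALSE]
  }
  out
}

## Adjoint of im2col: fold gradients back onto the input positions.
col2im <- function(dC, r, n, width) {
  P <- ncol(dC)
  dX <- matrix(0, nrow = n, ncol = width)
  for (j in seq_len(r)) {
    dX[, j:(j + P - 1L)] <- dX[, j:(j + P - 1L), drop = FALSE] +
      dC[((j - 1L) * n + 1L):(j * n), , drop = FALSE]
  }
  dX
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

avg_pool <- function(A, pool) {
  Pp <- ncol(A) %/% pool
  if (Pp < 1L) return(NULL)
  out <- matrix(0, nrow = nrow(A), ncol = Pp)
  for (j in seq_len(Pp)) {
    out[, j] <- rowMeans(A[, ((j - 1L) * pool + 1L):(j * pool), drop = FALSE])
  }
  out
}

## Forward pass for a batch of one-hot sequences. Only valid (non-padding)
## positions are propagated, so output is independent of padding length.
## training = TRUE uses batch statistics for BN (and updates running stats in
## the returned params); otherwise running statistics are applied.
## Returns list(out = matrix out_dim x n_items, cache, params).
cnn_forward_batch <- function(items, params, training = FALSE,
                              cim1 = NULL) {
  eps <- 1e-5
  n_items <- length(items)
  Xs <- lapply(items, function(it) {
    v <- it$true_length
    it$matrix[, seq_len(v), drop = FALSE]
  })
  cache <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    lay <- params$layers[[l]]
    r <- params$widths[l]
    lc <- list(X_in = Xs, Cim = vector("list", n_items),
               Z = vector("list", n_items), Zn = vector("list", n_items))
    for (i in seq_len(n_items)) {
      if (ncol(Xs[[i]]) < r) {
        stop(sprintf(
          "layer %d: filter width %d exceeds remaining sequence length %d",
          l, r, ncol(Xs[[i]])), call. = FALSE)
      }
      ## the layer-1 unfold depends only on the fixed one-hot input, so
      ## callers may supply it precomputed
      lc$Cim[[i]] <- if (l == 1L && !is.null(cim1)) cim1[[i]]
                     else im2col(Xs[[i]], r)
      lc$Z[[i]] <- lay$W %*% lc$Cim[[i]] + lay$b
    }
    if (params$batch_norm) {
      allZ <- do.call(cbind, lc$Z)
      if (training) {
        mu <- rowMeans(allZ)
        va <- rowMeans((allZ - mu)^2)
        params$layers[[l]]$run_mean <- 0.9 * lay$run_mean + 0.1 * mu
        params$layers[[l]]$run_var <- 0.9 * lay$run_var + 0.1 * va
      } else {
        mu <- lay$run_mean
        va <- lay$run_var
      }
      lc$mu <- mu; lc$va <- va; lc$m_bn <- ncol(allZ)
      inv <- 1 / sqrt(va + eps)
      for (i in seq_len(n_items)) {
        zhat <- (lc$Z[[i]] - mu) * inv
        lc$Zn[[i]] <- lay$gamma * zhat + lay$beta
      }
    } else {
      lc$Zn <- lc$Z
    }
    lc$A <- lapply(lc$Zn, leaky_relu, slope = params$leaky_slope)
    pooled <- lapply(lc$A, avg_pool, pool = params$pool)
    short <- vapply(pooled, is.null, TRUE)
    if (any(short)) {
      stop(sprintf("layer %d: sequence too short for pooling (item %d)",
                   l, which(short)[1]), call. = FALSE)
    }
    cache[[l]] <- lc
    Xs <- pooled
  }
  out <- matrix(0, nrow = params$out_dim, ncol = n_items)
  argmax <- matrix(0L, nrow = params$out_dim, ncol = n_items)
  for (i in seq_len(n_items)) {
    am <- max.col(Xs[[i]], ties.method = "first")
    out[, i] <- Xs[[i]][cbind(seq_len(nrow(Xs[[i]])), am)]
    argmax[, i] <- am
  }
  list(out = out, argmax = argmax, top = Xs, cache = cache, params = params)
}

## Backward pass matching cnn_forward_batch. dOut: out_dim x n_items.
## Returns list(grads = per-layer list(W, b[, gamma, beta])).
cnn_backward_batch <- function(fwd, dOut, params) {
  eps <- 1e-5
  n_items <- ncol(dOut)
  ## global max-pool backward
  dXs <- vector("list", n_items)
  for (i in seq_len(n_items)) {
    d <- matrix(0, nrow = nrow(fwd$top[[i]]), ncol = ncol(fwd$top[[i]]))
    d[cbind(seq_len(nrow(d)), fwd$argmax[, i])] <- dOut[, i]
    dXs[[i]] <- d
  }
  grads <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    lay <- params$layers[[l]]
    lc <- fwd$cache[[l]]
    r <- params$widths[l]
    pool <- params$pool
    dW <- matrix(0, nrow = nrow(lay$W), ncol = ncol(lay$W))
    db <- numeric(length(lay$b))
    dZn <- vector("list", n_items)
    for (i in seq_len(n_items)) {
      ## average-pool backward: spread each pooled column over its window
      A <- lc$A[[i]]
      dA <- matrix(0, nrow = nrow(A), ncol = ncol(A))
      Pp <- ncol(dXs[[i]])
      if (Pp > 0) for (j in seq_len(Pp)) {
        cols <- ((j - 1L) * pool + 1L):(j * pool)
        dA[, cols] <- dA[, cols] + dXs[[i]][, j] / pool
      }
      Zn <- lc$Zn[[i]]
      dZn[[i]] <- dA * ifelse(Zn > 0, 1, params$leaky_slope)
    }
    if (params$batch_norm) {
      inv <- 1 / sqrt(lc$va + eps)
      m <- lc$m_bn
      allZ <- do.call(cbind, lc$Z)
      allD <- do.call(cbind, dZn)
      xhat <- (allZ - lc$mu) * inv
      dgamma <- rowSums(allD * xhat)
      dbeta <- rowSums(allD)
      ## dZ = gamma*inv * (dy - mean(dy) - xhat * mean(dy*xhat))
      term <- allD - dbeta / m - xhat * (dgamma / m)
      allDZ <- (lay$gamma * inv) * term
      widths_i <- vapply(dZn, ncol, 0L)
      ends <- cumsum(widths_i)
      starts <- ends - widths_i + 1L
      dZ <- lapply(seq_len(n_items), function(i)
        allDZ[, starts[i]:ends[i], drop = FALSE])
    } else {
      dgamma <- dbeta <- NULL
      dZ <- dZn
    }
    dX_in <- vector("list", n_items)
    for (i in seq_len(n_items)) {
      dW <- dW + dZ[[i]] %*% t(lc$Cim[[i]])
      db <- db + rowSums(dZ[[i]])
      dCim <- t(lay$W) %*% dZ[[i]]
      dX_in[[i]] <- col2im(dCim, r, nrow(lc$X_in[[i]]), ncol(lc$X_in[[i]]))
    }
    grads[[l]] <- if (params$batch_norm) {
      list(W = dW, b = db, gamma = dgamma, beta = dbeta)
    } else {
      list(W = dW, b = db)
    }
    dXs <- dX_in
  }
  list(layers = grads)
}

#' Encode a one-hot protein sequence with the 1D-CNN
#'
#' Inference-mode forward pass: per layer a 1-D convolution with bias,
#' optional batch normalization (running statistics), Leaky-ReLU and average
#' pooling; finally a global max-pool over the valid positions of the last
#' feature maps. Padding columns never enter any retained position, so the
#' output does not depend on `max_len`.
#'
#' @param x a `one_hot_sequence` from [one_hot_encode()].
#' @param params a [cnn_params()] object.
#' @return Numeric vector of length `params$out_dim` (the protein feature
#'   vector a_protein).
#' @examples
#' p <- cnn_params(filters = c(4L, 3L), widths = c(3L, 2L), seed = 1)
#' a <- cnn_encode(one_hot_encode("ACDEFGHIKLMNPQRSTVWY", 30), p)
#' length(a)  # 3
#' @export
cnn_encode <- function(x, params) {
  check_that(inherits(x, "one_hot_sequence"), "`x` must be a one_hot_sequence")
  check_that(inherits(params, "cnn_params"), "`params` must be cnn_params")
  fwd <- cnn_forward_batch(list(x), params, training = FALSE)
  as.numeric(fwd$out[, 1])
}
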