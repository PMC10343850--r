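#' Stacked autoencoder for pair-feature compression
#'
#' Greedy layer-wise training: each autoencoder has a `tanh` encoder
#' `z = tanh(W x + b)` and a linear decoder `x~ = W' z + b'`, trained with
#' Adam to minimize the summed squared reconstruction error; layer `k` is
#' fitted on layer `k-1`'s codes. Default code dimensions are 1024, 512 and
#' 256 for 1756-dimensional input; for narrower inputs the dimensions shrink
#' proportionally (preserving the 1756:1024:512:256 ratios, minimum 2).
#'
#' @param X numeric training matrix (rows = samples).
#' @param dims integer vector of code dimensions; `NULL` (default) selects
#'   `c(1024, 512, 256)` scaled to the input width as described above.
#' @param epochs training epochs per layer (default 50).
#' @param batch minibatch size (default 128, capped at the sample count).
#' @param lr Adam learning rate (default 1e-3).
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param seed integer seed (weight init and batch shuffling).
#' @return An object of class `encoder_stack`: list with `layers` (each with
#'   `W`, `b`, `W2`, `b2`, `in_dim`, `code_dim`), `dims`, `training_log`
#'   (per-layer vector of end-of-epoch total losses), `seed`.
#' @export
fit_sae <- function(X, dims = NULL, epochs = 50, batch = 128, lr = 1e-3,
                    beta1 = 0.9, beta2 = 0.999, eps = 1e-8, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1) stopf("empty training matrix")
  in_dim <- ncol(X)
  if (is.null(dims)) dims <- sae_dims(in_dim)
  batch <- min(batch, n)
  layers <- vector("list", length(dims))
  logs <- vector("list", length(dims))
  H <- X
  for (k in seq_along(dims)) {
    fit <- fit_autoencoder_layer(H, dims[k], epochs, batch, lr, beta1, beta2,
                                 eps, derive_seed(seed, k))
    layers[[k]] <- fit$layer
    logs[[k]] <- fit$losses
    H <- encode_layer(fit$layer, H)
  }
  structure(list(layers = layers, dims = dims, training_log = logs,
                 seed = seed),
            class = "encoder_stack")
}

#' Default code dimensions for a given input width
#'
#' @param in_dim input feature count.
#' @return Integer vector of three code dimensions.
#' @export
sae_dims <- function(in_dim) {
  base <- c(1024L, 512L, 256L)
  if (in_dim >= 1024) return(base)
  pmax(2L, as.integer(round(in_dim * base / 1756)))
}

fit_autoencoder_layer <- function(X, code_dim, epochs, batch, lr,
                                  beta1, beta2, eps, seed) {
  n <- nrow(X); d <- ncol(X)
  withr::with_seed(seed, {
    # Glorot-uniform init
    r1 <- sqrt(6 / (d + code_dim))
    W <- matrix(runif(code_dim * d, -r1, r1), code_dim, d)
    b <- numeric(code_dim)
    W2 <- matrix(runif(code_dim * d, -r1, r1), d, code_dim)
    b2 <- numeric(d)
    params <- list(W = W, b = b, W2 = W2, b2 = b2)
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    t_step <- 0
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch)) {
        rows <- ord[start:min(start + batch - 1, n)]
        Xb <- X[rows, , drop = FALSE]
        nb <- nrow(Xb)
        Z <- tanh(tcrossprod(Xb, params$W) +
                    matrix(params$b, nb, code_dim, byrow = TRUE))
        Xhat <- tcrossprod(Z, params$W2) + matrix(params$b2, nb, d, byrow = TRUE)
        dXhat <- 2 * (Xhat - Xb) / nb
        gW2 <- crossprod(dXhat, Z)
        gb2 <- colSums(dXhat)
        dZ <- dXhat %*% params$W2
        dpre <- dZ * (1 - Z^2)
        gW <- crossprod(dpre, Xb)
        gb <- colSums(dpre)
        grads <- list(W = gW, b = gb, W2 = gW2, b2 = gb2)
        t_step <- t_step + 1
        for (nm in names(params)) {
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- m[[nm]] / (1 - beta1^t_step)
          vhat <- v[[nm]] / (1 - beta2^t_step)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      layer_now <- c(params, list(in_dim = d, code_dim = code_dim))
      losses[ep] <- reconstruction_loss(layer_now, X)
      if (!is.finite(losses[ep]))
        stopf("non-finite reconstruction loss at epoch %d", ep)
    }
    list(layer = c(params, list(in_dim = d, code_dim = code_dim)),
         losses = losses)
  })
}

encode_layer <- function(layer, X) {
  nb <- nrow(X)
  tanh(tcrossprod(X, layer$W) +
         matrix(layer$b, nb, layer$code_dim, byrow = TRUE))
}

#' Encode data with a fitted stack
#'
#' Applies each layer's `tanh(W x + b)` in sequence; output values lie
#' strictly inside (-1, 1).
#'
#' @param stack an `encoder_stack` from [fit_sae()].
#' @param X matrix with the stack's input width.
#' @return Matrix of codes (`nrow(X)` x final code dimension).
#' @export
encode <- function(stack, X) {
  X <- as.matrix(X)
  if (ncol(X) != stack$layers[[1]]$in_dim)
    stopf("input has %d columns; stack expects %d",
          ncol(X), stack$layers[[1]]$in_dim)
  for (layer in stack$layers) X <- encode_layer(layer, X)
  X
}

#' Reconstruction loss of one autoencoder layer
#'
#' Total summed squared error between `X` and its reconstruction through the
#' layer's encoder and decoder.
#'
#' @param layer a layer from an `encoder_stack` (fields `W`, `b`, `W2`, `b2`).
#' @param X input matrix with `layer$in_dim` columns.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(layer, X) {
  X <- as.matrix(X)
  if (ncol(X) != layer$in_dim) stopf("dimension mismatch")
  Z <- encode_layer(layer, X)
  Xhat <- tcrossprod(Z, layer$W2) + matrix(layer$b2, nrow(X), layer$in_dim,
                                           byrow = TRUE)
  sum((X - Xhat)^2)
}

#' @export
print.encoder_stack <- function(x, ...) {
  cat(sprintf("<encoder_stack> %d -> %s\n", x$layers[[1]]$in_dim,
              paste(x$dims, collapse = " -> ")))
  invisible(x)
}
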