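# Minimal multi-output feedforward network for multi-label classification.
# Plain R matrix ops: ReLU hidden layers with inverted dropout, per-label
# sigmoid outputs, binary cross-entropy (with-logits) loss, Adam updates on
# shuffled minibatches. Sized for fingerprint inputs at desk scale; no GPU,
# no early stopping.

mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                 nrow = fan_in),
      b = rep(0, sizes[l + 1L])
    )
  }
  layers
}

mlp_forward <- function(layers, x, dropout = 0, train = FALSE) {
  acts <- list(x)
  n_layers <- length(layers)
  masks <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    if (l < n_layers) {
      a <- pmax(z, 0)
      if (train && dropout > 0) {
        mask <- matrix(stats::rbinom(length(a), 1L, 1 - dropout) / (1 - dropout),
                       nrow = nrow(a))
        a <- a * mask
        masks[[l]] <- mask
      }
      acts[[l + 1L]] <- a
    } else {
      acts[[l + 1L]] <- z  # logits
    }
  }
  list(acts = acts, masks = masks)
}

#' Train the feedforward multi-label network
#'
#' @param x input matrix (samples x features).
#' @param y binary target matrix (samples x labels).
#' @param hidden hidden layer sizes.
#' @param dropout hidden-unit dropout probability.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param epochs passes over the data.
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @return an `mlp_model` (list of layer weights plus architecture).
#' @keywords internal
mlp_train <- function(x, y, hidden = c(512L, 256L), dropout = 0.2,
                      batch_size = 32L, lr = 1e-3, epochs = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  with_seed(seed, {
    layers <- mlp_init(ncol(x), hidden, ncol(y))
    mstate <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
    vstate <- mstate
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx, , drop = FALSE]
        fwd <- mlp_forward(layers, xb, dropout = dropout, train = TRUE)
        acts <- fwd$acts
        n_layers <- length(layers)
        # BCE-with-logits gradient at the output
        delta <- (stats::plogis(acts[[n_layers + 1L]]) - yb) / nrow(xb)
        grads <- vector("list", n_layers)
        for (l in rev(seq_len(n_layers))) {
          grads[[l]] <- list(
            W = crossprod(acts[[l]], delta),
            b = colSums(delta)
          )
          if (l > 1L) {
            delta <- delta %*% t(layers[[l]]$W)
            delta <- delta * (acts[[l]] > 0)
            if (!is.null(fwd$masks[[l - 1L]])) delta <- delta * fwd$masks[[l - 1L]]
          }
        }
        step <- step + 1L
        for (l in seq_len(n_layers)) {
          for (p in c("W", "b")) {
            g <- grads[[l]][[p]]
            mstate[[l]][[p]] <- beta1 * mstate[[l]][[p]] + (1 - beta1) * g
            vstate[[l]][[p]] <- beta2 * vstate[[l]][[p]] + (1 - beta2) * g^2
            mhat <- mstate[[l]][[p]] / (1 - beta1^step)
            vhat <- vstate[[l]][[p]] / (1 - beta2^step)
            layers[[l]][[p]] <- layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
          }
        }
      }
    }
    structure(list(layers = layers, hidden = hidden, n_in = ncol(x),
                   n_out = ncol(y)), class = "mlp_model")
  })
}

mlp_predict <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  fwd <- mlp_forward(model$layers, as.matrix(x), dropout = 0, train = FALSE)
  stats::plogis(fwd$acts[[length(model$layers) + 1L]])
}
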