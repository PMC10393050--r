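# Compact CNN -> LSTM sequence classifier for frame-difference stacks,
# implemented directly in R: each frame of a sequence is folded through a
# shared 3x3 valid convolution (im2col), ReLU and 2x2 average pooling, the
# per-frame feature maps are flattened back into a vector sequence, an LSTM
# consumes the sequence, and a softmax over the final hidden state yields
# the glucose class. Training is mini-batch gradient descent (Adam) with
# full backpropagation through time and global gradient-norm clipping.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training configuration for the CNN-LSTM
#'
#' Defaults follow the reference training recipe: initial learning rate
#' 1e-4, gradient threshold 2, mini-batch size 16, shuffling at every epoch,
#' and a 70/30 train/test split at the video level.
#'
#' @param learning_rate Adam step size; > 0.
#' @param gradient_threshold Global L2 gradient-norm clip.
#' @param batch_size Mini-batch size.
#' @param shuffle_each_epoch Logical; reshuffle sample order every epoch.
#' @param epochs Training epochs.
#' @param seed Integer seed for initialization and shuffling.
#' @param train_fraction Video-level training fraction, in (0, 1).
#' @param n_filters Convolution filters (capacity knob).
#' @param lstm_units LSTM hidden units (capacity knob).
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-4, gradient_threshold = 2,
                         batch_size = 16, shuffle_each_epoch = TRUE,
                         epochs = 30, seed = 1, train_fraction = 0.7,
                         n_filters = 8, lstm_units = 32) {
  check_finite_scalar(learning_rate, "learning_rate")
  check_finite_scalar(train_fraction, "train_fraction")
  if (learning_rate <= 0) stop_invalid("`learning_rate` must be > 0")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_invalid("`train_fraction` must be in (0, 1)")
  }
  if (batch_size < 1 || epochs < 1) {
    stop_invalid("`batch_size` and `epochs` must be >= 1")
  }
  structure(list(learning_rate = learning_rate,
                 gradient_threshold = gradient_threshold,
                 batch_size = as.integer(batch_size),
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 train_fraction = train_fraction,
                 n_filters = as.integer(n_filters),
                 lstm_units = as.integer(lstm_units)),
            class = "train_config")
}

# Geometry caches for a frame shape: im2col index matrix (patches x 9) for
# the 3x3 valid convolution and the 2x2 average-pool membership indices.
conv_geometry <- function(h, w) {
  if (h < 4 || w < 4) stop_invalid("frames must be at least 4x4")
  ho <- h - 2L
  wo <- w - 2L
  oi <- rep(seq_len(ho), times = wo)
  oj <- rep(seq_len(wo), each = ho)
  im2col <- matrix(0L, ho * wo, 9L)
  col <- 0L
  for (dc in 0:2) {
    for (dr in 0:2) {
      col <- col + 1L
      im2col[, col] <- (oj + dc - 1L) * h + (oi + dr)
    }
  }
  hp <- ho %/% 2L
  wp <- wo %/% 2L
  pi_ <- rep(seq_len(hp), times = wp)
  pj <- rep(seq_len(wp), each = hp)
  base_r <- 2L * (pi_ - 1L)
  base_c <- 2L * (pj - 1L)
  pool <- lapply(list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L)),
                 function(off) (base_c + off[2] - 1L) * ho + base_r + off[1])
  list(h = h, w = w, ho = ho, wo = wo, hp = hp, wp = wp,
       im2col = im2col, pool = pool, npool = hp * wp)
}

cnn_lstm_init <- function(h, w, n_classes, config) {
  geom <- conv_geometry(h, w)
  f <- config$n_filters
  m <- config$lstm_units
  d <- geom$npool * f
  ru <- function(nr, nc, scale) {
    matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
  }
  with_seed(derive_seed(config$seed, 21), {
    weights <- list(
      Wc = ru(9, f, sqrt(1 / 9)),
      bc = numeric(f),
      Wx = ru(4 * m, d, sqrt(1 / d)),
      Wh = ru(4 * m, m, sqrt(1 / m)),
      bl = numeric(4 * m),
      Wy = ru(n_classes, m, sqrt(1 / m)),
      by = numeric(n_classes)
    )
    # forget-gate bias starts at 1 for stable early training
    weights$bl[(m + 1):(2 * m)] <- 1
    weights
  })
}

# Forward pass over one sequence (h x w x t array). Returns softmax
# probabilities and, if requested, the caches needed for backprop.
cnn_lstm_forward <- function(weights, geom, frames, keep_cache = FALSE) {
  f <- ncol(weights$Wc)
  m <- ncol(weights$Wy)
  t_len <- dim(frames)[3]
  h_t <- numeric(m)
  c_t <- numeric(m)
  cache <- if (keep_cache) vector("list", t_len) else NULL
  for (t in seq_len(t_len)) {
    mat <- frames[, , t]
    p <- matrix(mat[geom$im2col], nrow(geom$im2col), 9L)
    apre <- p %*% weights$Wc
    apre <- sweep(apre, 2, weights$bc, "+")
    a <- pmax(apre, 0)
    pooled <- 0.25 * (a[geom$pool[[1]], , drop = FALSE] +
                      a[geom$pool[[2]], , drop = FALSE] +
                      a[geom$pool[[3]], , drop = FALSE] +
                      a[geom$pool[[4]], , drop = FALSE])
    x_t <- as.numeric(pooled)
    z <- as.numeric(weights$Wx %*% x_t + weights$Wh %*% h_t + weights$bl)
    ig <- sigmoid(z[1:m])
    fg <- sigmoid(z[(m + 1):(2 * m)])
    og <- sigmoid(z[(2 * m + 1):(3 * m)])
    gg <- tanh(z[(3 * m + 1):(4 * m)])
    c_prev <- c_t
    h_prev <- h_t
    c_t <- fg * c_prev + ig * gg
    tc <- tanh(c_t)
    h_t <- og * tc
    if (keep_cache) {
      cache[[t]] <- list(p = p, relu_mask = apre > 0, x = x_t,
                         i = ig, f = fg, o = og, g = gg,
                         c = c_t, c_prev = c_prev, h_prev = h_prev, tc = tc)
    }
  }
  logits <- as.numeric(weights$Wy %*% h_t + weights$by)
  logits <- logits - max(logits)
  prob <- exp(logits) / sum(exp(logits))
  list(prob = prob, h_final = h_t, cache = cache)
}

# Backprop through one sequence; returns the gradient list (same shapes as
# the weights) of the cross-entropy loss for true class `y_index`.
cnn_lstm_backward <- function(weights, geom, fwd, y_index) {
  m <- ncol(weights$Wy)
  f <- ncol(weights$Wc)
  cache <- fwd$cache
  t_len <- length(cache)
  grads <- lapply(weights, function(wt) wt * 0)
  dlogits <- fwd$prob
  dlogits[y_index] <- dlogits[y_index] - 1
  grads$Wy <- dlogits %o% fwd$h_final
  grads$by <- dlogits
  dh <- as.numeric(crossprod(weights$Wy, dlogits))
  dc <- numeric(m)
  for (t in rev(seq_len(t_len))) {
    cc <- cache[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dz <- c(di * cc$i * (1 - cc$i),
            df * cc$f * (1 - cc$f),
            do_ * cc$o * (1 - cc$o),
            dg * (1 - cc$g^2))
    grads$Wx <- grads$Wx + dz %o% cc$x
    grads$Wh <- grads$Wh + dz %o% cc$h_prev
    grads$bl <- grads$bl + dz
    dh <- as.numeric(crossprod(weights$Wh, dz))
    dc <- dc * cc$f
    dx <- as.numeric(crossprod(weights$Wx, dz))
    dpool <- matrix(dx, geom$npool, f)
    da <- matrix(0, nrow(geom$im2col), f)
    for (k in 1:4) {
      da[geom$pool[[k]], ] <- da[geom$pool[[k]], ] + 0.25 * dpool
    }
    dapre <- da * cc$relu_mask
    grads$Wc <- grads$Wc + crossprod(cc$p, dapre)
    grads$bc <- grads$bc + colSums(dapre)
  }
  grads
}

clip_gradients <- function(grads, threshold) {
  norm <- sqrt(sum(vapply(grads, function(gr) sum(gr^2), numeric(1))))
  if (is.finite(threshold) && norm > threshold) {
    grads <- lapply(grads, function(gr) gr * (threshold / norm))
  }
  grads
}

as_sequence_array <- function(s) {
  if (inherits(s, "difference_sequence")) s <- s$frames
  if (!is.array(s) || length(dim(s)) != 3) {
    stop_invalid("each sequence must be a difference_sequence or 3-d array")
  }
  if (any(!is.finite(s))) stop_invalid("sequences must be finite")
  s
}

#' Train the CNN-LSTM sequence classifier
#'
#' Each sample is a stack of normalized frame-difference images (see
#' [frame_difference_stack()]); a shared convolutional extractor folds the
#' sequence into per-frame feature vectors, an LSTM aggregates them over
#' time, and a softmax head predicts the glucose class. Optimized with Adam
#' under the mini-batch size, learning rate, shuffling and gradient clipping
#' of `config`; deterministic for a fixed `config$seed`.
#'
#' @param sequences List of `difference_sequence` objects or h x w x t
#'   arrays; all must share the same dimensions.
#' @param labels Class label per sequence.
#' @param config A [train_config()].
#' @return A `cnn_lstm` model: list with `weights`, `geom`, `classes`,
#'   `config` and `history` (data frame epoch / loss / accuracy on the
#'   training set).
#' @export
train_cnn_lstm <- function(sequences, labels, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  sequences <- lapply(sequences, as_sequence_array)
  if (length(sequences) == 0) stop_invalid("no sequences supplied")
  dims <- dim(sequences[[1]])
  same <- vapply(sequences, function(s) all(dim(s) == dims), logical(1))
  if (!all(same)) stop_invalid("inconsistent sequence dimensions")
  if (length(labels) != length(sequences)) {
    stop_invalid("`labels` length must match `sequences`")
  }
  labels <- as.factor(as.character(labels))
  y <- as.integer(labels)
  n_classes <- nlevels(labels)
  geom <- conv_geometry(dims[1], dims[2])
  weights <- cnn_lstm_init(dims[1], dims[2], n_classes, config)
  adam_m <- lapply(weights, function(wt) wt * 0)
  adam_v <- lapply(weights, function(wt) wt * 0)
  beta1 <- 0.9
  beta2 <- 0.999
  step <- 0
  n <- length(sequences)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  with_seed(derive_seed(config$seed, 22), {
    order_idx <- seq_len(n)
    for (epoch in seq_len(config$epochs)) {
      if (config$shuffle_each_epoch) order_idx <- sample(n)
      epoch_loss <- 0
      correct <- 0
      batch_starts <- seq(1, n, by = config$batch_size)
      for (bs in batch_starts) {
        idx <- order_idx[bs:min(bs + config$batch_size - 1, n)]
        grads <- NULL
        for (s in idx) {
          fwd <- cnn_lstm_forward(weights, geom, sequences[[s]],
                                  keep_cache = TRUE)
          epoch_loss <- epoch_loss - log(max(fwd$prob[y[s]], 1e-12))
          correct <- correct + (which.max(fwd$prob) == y[s])
          g <- cnn_lstm_backward(weights, geom, fwd, y[s])
          grads <- if (is.null(grads)) g else {
            Map(function(a, b) a + b, grads, g)
          }
        }
        grads <- lapply(grads, function(gr) gr / length(idx))
        grads <- clip_gradients(grads, config$gradient_threshold)
        step <- step + 1
        lr_t <- config$learning_rate *
          sqrt(1 - beta2^step) / (1 - beta1^step)
        for (nm in names(weights)) {
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grads[[nm]]
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * grads[[nm]]^2
          weights[[nm]] <- weights[[nm]] -
            lr_t * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + 1e-8)
        }
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = epoch_loss / n,
                                  accuracy = correct / n))
    }
  })
  structure(list(weights = weights, geom = geom, classes = levels(labels),
                 config = config, history = history),
            class = "cnn_lstm")
}

#' Predict with a trained CNN-LSTM
#'
#' @param object A `cnn_lstm` from [train_cnn_lstm()].
#' @param newdata List of sequences with the training frame shape.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix
#'   (rows sum to 1).
#' @param ... Unused.
#' @return Character labels or a probability matrix; empty input gives an
#'   empty result.
#' @export
predict.cnn_lstm <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  newdata <- lapply(newdata, as_sequence_array)
  if (length(newdata) == 0) {
    return(if (type == "class") character(0) else
      matrix(numeric(0), 0, length(object$classes)))
  }
  ok <- vapply(newdata, function(s) {
    all(dim(s)[1:2] == c(object$geom$h, object$geom$w))
  }, logical(1))
  if (!all(ok)) stop_invalid("sequence frame shape does not match training shape")
  probs <- t(vapply(newdata, function(s) {
    cnn_lstm_forward(object$weights, object$geom, s)$prob
  }, numeric(length(object$classes))))
  colnames(probs) <- object$classes
  if (type == "prob") probs else object$classes[max.col(probs, "first")]
}
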