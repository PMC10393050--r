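# Independent oracles used by the tests. These deliberately avoid the
# package's own estimation code paths.

# Dense upsampled correlation oracle: zero-pad the spectrum of a
# correlation surface by `factor`, invert, and take the argmax on the fine
# grid (1/factor px resolution).
oracle_upsampled_peak <- function(surface, factor = 16) {
  n <- nrow(surface)
  stopifnot(ncol(surface) == n, n %% 2 == 0)
  x <- stats::fft(surface)
  big_n <- factor * n
  big <- matrix(0i, big_n, big_n)
  ks <- 0:(n - 1)
  ksig <- ifelse(ks > n / 2, ks - n, ks)
  pos <- (ksig %% big_n) + 1
  big[pos, pos] <- x
  up <- Re(stats::fft(big, inverse = TRUE)) / (n * n)
  w <- which(up == max(up), arr.ind = TRUE)[1, ]
  wrap <- function(k) if (k > big_n / 2) k - big_n else k
  list(dy = wrap(w[1] - 1) / factor, dx = wrap(w[2] - 1) / factor)
}

# Raw periodogram frequencies/power of a real series (no windowing).
oracle_periodogram <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2 / n
  k <- 1:floor((n - 1) / 2)
  list(freq = k * fs / n, power = p[k + 1])
}

# Exhaustive recount of classification metrics by explicit loops over all
# (true, predicted) pairs.
oracle_recount <- function(true, pred, classes) {
  k <- length(classes)
  confusion <- matrix(0L, k, k)
  for (i in seq_along(true)) {
    r <- match(true[i], classes)
    c <- match(pred[i], classes)
    confusion[r, c] <- confusion[r, c] + 1L
  }
  precision <- recall <- f1 <- numeric(k)
  for (j in seq_len(k)) {
    tp <- confusion[j, j]
    fp <- sum(confusion[, j]) - tp
    fn <- sum(confusion[j, ]) - tp
    precision[j] <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall[j] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[j] <- if (precision[j] + recall[j] > 0) {
      2 * precision[j] * recall[j] / (precision[j] + recall[j])
    } else 0
  }
  list(confusion = confusion, accuracy = sum(diag(confusion)) / length(true),
       precision = precision, recall = recall, f1 = f1,
       macro_f1 = mean(f1))
}

# Apply an exact subpixel translation to an image by Fourier phase ramp
# (the same mathematical operation the simulator uses, re-derived here).
oracle_fourier_shift <- function(img, dx, dy) {
  n <- nrow(img)
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  kx <- matrix(k, n, n, byrow = TRUE)
  ky <- matrix(k, n, n)
  Re(stats::fft(stats::fft(img) * exp(-2i * pi * (kx * dx + ky * dy) / n),
                inverse = TRUE)) / n^2
}

# Small toy dataset for the sequence classifier: class A sequences are
# all-zero difference stacks, class B sequences contain a moving bright
# block. 8 sequences of `t_len` frames of 8x8 px.
make_toy_sequences <- function(t_len = 6, seed = 7) {
  set.seed(seed)
  seqs <- list()
  labels <- character(0)
  for (i in 1:4) {
    seqs[[length(seqs) + 1]] <- array(0, dim = c(8, 8, t_len))
    labels <- c(labels, "flat")
  }
  for (i in 1:4) {
    arr <- array(0, dim = c(8, 8, t_len))
    for (t in seq_len(t_len)) {
      r <- ((t + i) %% 6) + 1
      arr[r:(r + 2), 3:6, t] <- 1
    }
    arr <- arr + array(stats::rnorm(8 * 8 * t_len, 0, 0.05),
                       dim = c(8, 8, t_len))
    seqs[[length(seqs) + 1]] <- arr
    labels <- c(labels, "moving")
  }
  list(sequences = seqs, labels = labels)
}
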