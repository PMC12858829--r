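# Local 3x3x3 box mean via 27 shifted additions; edges padded with the
# nearest value (replication).
box_mean3 <- function(arr) {
  d <- dim(arr)
  pad <- array(0, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  pad[1, , ] <- pad[2, , ]; pad[d[1] + 2, , ] <- pad[d[1] + 1, , ]
  pad[, 1, ] <- pad[, 2, ]; pad[, d[2] + 2, ] <- pad[, d[2] + 1, ]
  pad[, , 1] <- pad[, , 2]; pad[, , d[3] + 2] <- pad[, , d[3] + 1]
  acc <- array(0, dim = d)
  for (sx in 0:2) for (sy in 0:2) for (sz in 0:2)
    acc <- acc + pad[sx + 1:d[1], sy + 1:d[2], sz + 1:d[3]]
  acc / 27
}

# Per-voxel features: centered/scaled intensity, 3^3 neighborhood mean,
# neighborhood SD, and a coarse smoothed-intensity context channel.
voxel_features <- function(image) {
  x <- image$values
  mu <- mean(x); sdv <- stats::sd(x)
  xs <- (x - mu) / sdv
  local_mean <- box_mean3(xs)
  local_sq <- box_mean3(xs^2)
  local_sd <- sqrt(pmax(local_sq - local_mean^2, 0))
  context <- gaussian_smooth3(xs, 2)
  cbind(int = as.numeric(xs), nmean = as.numeric(local_mean),
        nsd = as.numeric(local_sd), ctx = as.numeric(context))
}

# One linear head: Fisher discriminant direction on a bootstrap voxel
# sample, rescaled so the logit has a fixed gain (unit feature-space
# distance from the decision plane maps to `gain` logits). Fixing the
# scale keeps predictions moderately confident, so dropout-induced
# dispersion is expressed rather than crushed by saturation.
fit_head <- function(X, y, gain) {
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  S <- (stats::cov(X[y == 1, , drop = FALSE]) +
          stats::cov(X[y == 0, , drop = FALSE])) / 2
  S <- S + diag(1e-3, ncol(X))
  w <- solve(S, mu1 - mu0)
  w <- w / sqrt(sum(w^2))
  b <- -sum(w * (mu1 + mu0) / 2)
  c(b, w) * gain
}

#' Train a small MC-dropout voxel classifier on phantoms
#'
#' A one-hidden-layer stochastic classifier over local intensity
#' features (intensity, 3^3 neighborhood mean and SD, coarse smoothed
#' context). The hidden layer holds `heads` linear units, each a Fisher
#' discriminant fitted to an independent bootstrap voxel sample from
#' the training phantoms and rescaled to a fixed logit `gain`; the
#' output unit averages the head logits. At inference, Monte Carlo
#' dropout acts on the head layer: each stochastic pass keeps a head
#' with probability 1 - p (inverted-dropout scaling preserves the
#' expected logit), so the pass-to-pass variance of the combined logit
#' scales as p/(1 - p) — the uncertainty-floor law — while `p = 0`
#' makes every pass identical. Training never sees the dropout rate,
#' so predictors that differ only in `dropout_rate` share weights
#' under the same seed.
#'
#' @param phantoms list of phantom pairs (`list(image=, truth=)` as
#'   returned by [generate_phantom()]); at least 2.
#' @param dropout_rate dropout probability p in [0, 0.9].
#' @param seed training seed (bootstrap subsampling).
#' @param heads number of hidden linear heads.
#' @param gain fixed logit scale of each head.
#' @param min_train_dice abort training below this Dice on the
#'   training phantoms.
#' @return a predictor function `(image, m, seed) -> scalar_volume`
#'   with attributes `dropout_rate` and `train_dice`.
#' @export
toy_dropout_predictor <- function(phantoms, dropout_rate = 0.1, seed = 1L,
                                  heads = 6L, gain = 1,
                                  min_train_dice = 0.9) {
  if (length(phantoms) < 2L) stop("need at least 2 training phantoms")
  if (dropout_rate < 0 || dropout_rate > 0.9)
    stop("dropout_rate must be in [0, 0.9]")
  with_seed(seed, {
    feats <- list(); labs <- list()
    for (ph in phantoms) {
      X <- voxel_features(ph$image)
      y <- as.numeric(ph$truth$values)
      fg <- which(y == 1)
      bg <- sample(which(y == 0), min(3L * length(fg), sum(y == 0)))
      idx <- c(fg, bg)
      feats[[length(feats) + 1L]] <- X[idx, , drop = FALSE]
      labs[[length(labs) + 1L]] <- y[idx]
    }
    X <- do.call(rbind, feats); y <- unlist(labs)
    W <- vapply(seq_len(heads), function(h) {
      bs <- sample(nrow(X), nrow(X), replace = TRUE)
      fit_head(X[bs, , drop = FALSE], y[bs], gain)
    }, numeric(ncol(X) + 1L))       # (1 + n_features) x heads
    forward <- function(Xf, keep = NULL, p = 0) {
      L <- cbind(1, Xf) %*% W        # per-head logits
      if (is.null(keep)) stats::plogis(rowMeans(L))
      else stats::plogis(as.numeric(L %*% keep) / ((1 - p) * heads))
    }
    dices <- vapply(phantoms, function(ph) {
      pr <- forward(voxel_features(ph$image))
      dice(binary_mask(as.integer(pr >= 0.5), ph$image$grid), ph$truth)
    }, numeric(1))
    if (min(dices) < min_train_dice)
      stop(sprintf(
        "training failed: Dice %.3f below %.2f on a training phantom",
        min(dices), min_train_dice))
    p <- dropout_rate
    predictor <- function(image, m, seed) {
      Xf <- voxel_features(image)
      pr <- if (p > 0) {
        keep <- with_seed(seed, stats::rbinom(heads, 1, 1 - p))
        forward(Xf, keep, p)
      } else forward(Xf)
      scalar_volume(pr, image$grid, probability = TRUE)
    }
    attr(predictor, "dropout_rate") <- dropout_rate
    attr(predictor, "train_dice") <- dices
    predictor
  })
}
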