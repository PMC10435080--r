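#' Training control parameters
#'
#' @param epochs training epochs (the full-scale protocol uses 1000;
#'   desk-scale runs use far fewer).
#' @param batch_size minibatch size.
#' @param lr initial Adam learning rate.
#' @param milestones epochs (as fractions of `epochs` if < 1) at which the
#'   learning rate is multiplied by `gamma`.
#' @param gamma multi-step learning-rate decay factor.
#' @param beta1,beta2 Adam moment decay rates; short desk-scale schedules
#'   benefit from a faster-adapting second moment than the conventional
#'   0.999.
#' @param clip global gradient-norm clipping threshold (`Inf` disables).
#' @param seed seed controlling initialization and data order.
#' @param verbose print per-epoch losses.
#' @return A list of class `vt_control`.
#' @export
vt_control <- function(epochs = 1000, batch_size = 25, lr = 1e-3,
                       milestones = c(0.6, 0.85), gamma = 0.1,
                       beta1 = 0.9, beta2 = 0.99, clip = 5,
                       seed = 1, verbose = FALSE) {
  ms <- milestones
  ms[ms < 1] <- ceiling(ms[ms < 1] * epochs)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 milestones = sort(unique(ms)), gamma = gamma,
                 beta1 = beta1, beta2 = beta2, clip = clip,
                 seed = seed, verbose = verbose),
            class = "vt_control")
}

# Input conditioning statistics from the training rows only. Root-moment
# amplitudes span several orders of magnitude across plate positions
# (distant wakes induce far weaker loads), so every channel is first
# compressed with a signed-log transform, asinh(x / s), with s a low
# quantile of the channel's nonzero training amplitudes (linear below s,
# logarithmic above). The DC channels are then z-scored per pixel
# (statistics over training cases), equalizing the informative variation
# of weak and strong whiskers in the static spatial pattern; the AC
# channels are z-scored per channel so the oscillation waveforms keep a
# common scale across the array. Structural null pixels stay exactly zero
# (zero-variance pixels are pinned).
.norm_stats <- function(dataset, train_idx, q_scale = 0.05,
                        dc_channels = c(1, 3)) {
  dd <- dim(dataset$videos)
  n_ch <- dd[5]
  ch_scale <- ch_mean <- ch_sd <- numeric(n_ch)
  px_mean <- array(0, dd[3:5])
  px_sd <- array(1, dd[3:5])
  per_pixel <- logical(n_ch)
  for (ch in seq_len(n_ch)) {
    v <- dataset$videos[train_idx, , , , ch, drop = FALSE]
    nz <- abs(v[v != 0])
    ch_scale[ch] <- if (length(nz)) max(unname(quantile(nz, q_scale)), 1e-300) else 1
    vc <- asinh(v / ch_scale[ch])
    if (ch %in% dc_channels && dd[5] == 4) {
      per_pixel[ch] <- TRUE
      mu <- apply(vc, c(3, 4), mean)
      s <- sqrt(apply(vc, c(3, 4), var))
      dead <- !is.finite(s) | s < 1e-10
      mu[dead] <- 0
      s[dead] <- 1
      px_mean[, , ch] <- mu
      px_sd[, , ch] <- s
      ch_mean[ch] <- 0; ch_sd[ch] <- 1
    } else {
      ch_mean[ch] <- mean(vc)
      s <- sd(as.vector(vc))
      ch_sd[ch] <- if (is.finite(s) && s > 1e-12) s else 1
    }
  }
  y <- as.matrix(dataset$labels[train_idx, , drop = FALSE])
  y_mean <- colMeans(y)
  y_sd <- apply(y, 2, sd)
  y_sd[!is.finite(y_sd) | y_sd < 1e-12] <- 1
  list(ch_scale = ch_scale, ch_mean = ch_mean, ch_sd = ch_sd,
       per_pixel = per_pixel, px_mean = px_mean, px_sd = px_sd,
       y_mean = y_mean, y_sd = y_sd)
}

.standardize_videos <- function(videos, norm) {
  dd <- dim(videos)
  for (ch in seq_along(norm$ch_scale)) {
    v <- array(asinh(videos[, , , , ch, drop = FALSE] / norm$ch_scale[ch]),
               dd[1:4])
    if (isTRUE(norm$per_pixel[ch])) {
      mu <- aperm(array(norm$px_mean[, , ch], c(dd[3], dd[4], dd[1], dd[2])),
                  c(3, 4, 1, 2))
      sd_ <- aperm(array(norm$px_sd[, , ch], c(dd[3], dd[4], dd[1], dd[2])),
                   c(3, 4, 1, 2))
      videos[, , , , ch] <- (v - mu) / sd_
    } else {
      videos[, , , , ch] <- (v - norm$ch_mean[ch]) / norm$ch_sd[ch]
    }
  }
  videos
}

.standardize_labels <- function(y, norm)
  sweep(sweep(as.matrix(y), 2, norm$y_mean), 2, norm$y_sd, "/")

.destandardize_labels <- function(y, norm)
  sweep(sweep(y, 2, norm$y_sd, "*"), 2, norm$y_mean, "+")

.adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# rows of the precomputed token matrix belonging to the given samples
.token_rows <- function(idx, n_tok)
  rep((idx - 1) * n_tok, each = n_tok) + seq_len(n_tok)

.batched_predict_tokens <- function(params, cfg, tokens, idx, chunk = 32) {
  out <- matrix(0, length(idx), cfg$n_out)
  for (start in seq(1, length(idx), by = chunk)) {
    sel <- idx[start:min(start + chunk - 1, length(idx))]
    Xb <- tokens[.token_rows(sel, cfg$n_tok), , drop = FALSE]
    out[start:(start + length(sel) - 1), ] <-
      .vt_forward_tokens(params, cfg, Xb, length(sel))$out
  }
  out
}

#' Fit the video transformer to a sensing-video dataset
#'
#' Minimizes the mean squared error of the standardized plate parameters
#' with Adam and a multi-step learning-rate schedule. Channel and label
#' standardization statistics are computed on the training rows only and
#' stored with the model. The run is fully seeded (initialization and data
#' order) and deterministic on a given platform.
#'
#' @param dataset a [build_dataset()] result.
#' @param config a [vt_config()]; its video dimensions must match the
#'   dataset.
#' @param control a [vt_control()].
#' @param val_idx validation row indices (may be empty for a final fit on
#'   all rows).
#' @param train_idx training rows; defaults to all rows not in `val_idx`.
#' @param conditioning input conditioning: `"channel"` (default) applies
#'   the signed-log compression and z-score per channel; `"hybrid"`
#'   additionally z-scores the DC channels per pixel, equalizing weak and
#'   strong whiskers in the static pattern (slightly better parameter
#'   recovery, flatter spatial importance maps).
#' @return An object of class `wvt` with the trained parameters, the
#'   normalization statistics, per-epoch train/validation MSE history and
#'   held-out predictions.
#' @export
wvt_fit <- function(dataset, config = NULL, control = vt_control(),
                    val_idx = integer(0),
                    train_idx = setdiff(seq_len(nrow(dataset$labels)), val_idx),
                    conditioning = c("channel", "hybrid")) {
  conditioning = match.arg(conditioning)
  stopifnot(inherits(dataset, "wvt_dataset"))
  d <- dim(dataset$videos)
  if (is.null(config))
    config <- vt_config(T_prime = d[2], H = d[3], W = d[4], C = d[5])
  if (!all(d[-1] == c(config$T_prime, config$H, config$W, config$C)))
    stop("dataset video dimensions do not match the model configuration")
  if (control$batch_size > length(train_idx))
    stop("batch_size exceeds the training-set size")

  norm <- .norm_stats(dataset, train_idx,
                      dc_channels = if (conditioning == "hybrid") c(1, 3)
                      else integer(0))
  videos <- .standardize_videos(dataset$videos, norm)
  y_std <- .standardize_labels(dataset$labels, norm)
  tokens <- tubelet_tokens(videos, config)  # fixed across epochs

  set.seed(control$seed)
  params <- vt_init(config)
  adam <- .adam_init(params)
  lr <- control$lr
  hist_train <- hist_val <- numeric(control$epochs)

  for (epoch in seq_len(control$epochs)) {
    if (epoch %in% control$milestones) lr <- lr * control$gamma
    perm <- sample(train_idx)
    losses <- c()
    for (start in seq(1, length(perm), by = control$batch_size)) {
      sel <- perm[start:min(start + control$batch_size - 1, length(perm))]
      Xb <- tokens[.token_rows(sel, config$n_tok), , drop = FALSE]
      fw <- .vt_forward_tokens(params, config, Xb, length(sel), cache = TRUE)
      err <- fw$out - y_std[sel, , drop = FALSE]
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("non-finite loss at epoch ", epoch, ", lr ", lr,
             ", batch starting ", start)
      losses <- c(losses, loss)
      dOut <- 2 * err / length(err)
      bw <- vt_backward(params, config, fw$cache, dOut)
      if (is.finite(control$clip)) {
        gn <- sqrt(sum(vapply(bw$grads, function(g) sum(g * g), numeric(1))))
        if (gn > control$clip)
          bw$grads <- lapply(bw$grads, function(g) g * (control$clip / gn))
      }
      st <- .adam_step(params, bw$grads, adam, lr,
                       beta1 = control$beta1, beta2 = control$beta2)
      params <- st$params
      adam <- st$state
    }
    hist_train[epoch] <- mean(losses)
    hist_val[epoch] <- if (length(val_idx)) {
      pv <- .batched_predict_tokens(params, config, tokens, val_idx)
      mean((pv - y_std[val_idx, , drop = FALSE])^2)
    } else NA_real_
    if (control$verbose)
      message(sprintf("epoch %d  train %.5f  val %.5f  lr %.2g",
                      epoch, hist_train[epoch], hist_val[epoch], lr))
  }

  pred_val <- if (length(val_idx)) {
    .destandardize_labels(.batched_predict_tokens(params, config, tokens, val_idx),
                          norm)
  } else NULL
  structure(list(params = params, config = config, control = control,
                 norm = norm,
                 history = data.frame(epoch = seq_len(control$epochs),
                                      train_mse = hist_train,
                                      val_mse = hist_val),
                 train_idx = train_idx, val_idx = val_idx,
                 val_truth = if (length(val_idx))
                   as.matrix(dataset$labels[val_idx, , drop = FALSE]) else NULL,
                 val_pred = pred_val,
                 grid_map = dataset$grid_map,
                 dataset_hash = content_hash(dataset$labels)),
            class = "wvt")
}

#' Prediction accuracy on the plate-parameter scale
#'
#' `100 (1 - sum(|y_gt - y_pred|) / (Range N))`: 100% for perfect
#' prediction, and possibly negative for predictions worse than the
#' parameter range. `Range` is the span of the parameter's design grid.
#'
#' @param y_gt,y_pred ground-truth and predicted values.
#' @param value_range the parameter's range.
#' @return Accuracy in percent.
#' @export
accuracy <- function(y_gt, y_pred, value_range) {
  if (length(y_gt) != length(y_pred)) stop("length mismatch")
  if (!length(y_gt)) stop("empty input")
  if (value_range <= 0) stop("value_range must be > 0")
  100 * (1 - sum(abs(y_gt - y_pred)) / (value_range * length(y_gt)))
}

# per-parameter accuracies of a fitted fold on its validation rows
.fold_accuracies <- function(fit, spans = .grid_spans) {
  if (is.null(fit$val_pred)) stop("fit has no validation rows")
  vapply(seq_along(spans), function(j)
    accuracy(fit$val_truth[, j], fit$val_pred[, j], spans[j]), numeric(1)) |>
    setNames(names(spans))
}

#' Seeded k-fold split
#'
#' Partitions `n` samples into `k` near-equal disjoint validation folds
#' using a seeded permutation.
#'
#' @param n sample count; @param k folds (>= 2); @param seed RNG seed.
#' @return List of `k` integer index vectors.
#' @export
kfold_split <- function(n, k = 5, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of samples")
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  unname(split(perm, rep(seq_len(k), times = sizes)))
}

#' Cross-validated training over k folds
#'
#' Runs [wvt_fit()] once per fold and collects per-parameter accuracies
#' and loss histories, mirroring the 5-fold protocol of the full-scale
#' study.
#'
#' @param dataset,config,control as in [wvt_fit()].
#' @param k folds; @param seed seed for the fold split (fit seeds derive
#'   from `control$seed` plus the fold index).
#' @return An object of class `wvt_cv`: list of fold fits, the fold index
#'   sets and the accuracy table.
#' @export
wvt_cv <- function(dataset, config = NULL, control = vt_control(),
                   k = 5, seed = control$seed) {
  folds <- kfold_split(nrow(dataset$labels), k, seed)
  fits <- vector("list", k)
  acc <- matrix(NA_real_, k, 4, dimnames = list(NULL, names(.grid_spans)))
  for (i in seq_len(k)) {
    ctl <- control
    ctl$seed <- control$seed + i
    fits[[i]] <- wvt_fit(dataset, config, ctl, val_idx = folds[[i]])
    acc[i, ] <- .fold_accuracies(fits[[i]])
  }
  structure(list(fits = fits, folds = folds, accuracy = acc,
                 k = k, seed = seed),
            class = "wvt_cv")
}

#' Summarize cross-validated accuracies
#'
#' @param cv a [wvt_cv()] result (or a list of `wvt` fits with validation
#'   rows).
#' @return List with the per-fold accuracy matrix, per-parameter mean and
#'   sample standard deviation, the overall mean accuracy, and the pooled
#'   final validation MSE.
#' @export
evaluate <- function(cv) {
  acc <- if (inherits(cv, "wvt_cv")) cv$accuracy
  else t(vapply(cv, .fold_accuracies, numeric(4)))
  fits <- if (inherits(cv, "wvt_cv")) cv$fits else cv
  final_val <- vapply(fits, function(f) {
    v <- f$history$val_mse
    v[length(v)]
  }, numeric(1))
  list(accuracy = acc,
       mean = colMeans(acc),
       sd = apply(acc, 2, sd),
       overall = mean(colMeans(acc)),
       final_val_mse = final_val,
       best_fold = which.min(final_val))
}

#' Accuracy of the constant-mean predictor
#'
#' Baseline that always predicts the training mean of each parameter;
#' anything informative must beat it.
#'
#' @param labels data.frame of ground-truth parameters.
#' @param spans named parameter ranges.
#' @return Named accuracy vector in percent.
#' @export
baseline_accuracy <- function(labels, spans = .grid_spans) {
  vapply(seq_along(spans), function(j) {
    y <- labels[[j]]
    accuracy(y, rep(mean(y), length(y)), spans[j])
  }, numeric(1)) |> setNames(names(spans))
}

# ---- S3 methods for the fitted model ----

#' @export
print.wvt <- function(x, ...) {
  cat("Video-transformer wake-sensing model\n")
  cat("  tokens: ", x$config$n_t, " temporal x ", x$config$n_s,
      " spatial, G = ", x$config$G, ", L = ", x$config$L, "\n", sep = "")
  cat("  parameters:", vt_n_params(x$params), "\n")
  n <- x$control$epochs
  cat(sprintf("  final train MSE %.5f", x$history$train_mse[n]))
  if (length(x$val_idx))
    cat(sprintf(", val MSE %.5f (n_val = %d)", x$history$val_mse[n],
                length(x$val_idx)))
  cat("\n")
  invisible(x)
}

#' @export
summary.wvt <- function(object, ...) {
  out <- list(config = object$config,
              n_params = vt_n_params(object$params),
              final_train_mse = tail(object$history$train_mse, 1),
              final_val_mse = tail(object$history$val_mse, 1),
              accuracy = if (length(object$val_idx))
                .fold_accuracies(object) else NULL)
  class(out) <- "summary.wvt"
  out
}

#' @export
print.summary.wvt <- function(x, ...) {
  cat("Video transformer:", x$n_params, "parameters\n")
  cat(sprintf("Final train MSE: %.5f\n", x$final_train_mse))
  if (!is.null(x$accuracy)) {
    cat(sprintf("Final validation MSE: %.5f\n", x$final_val_mse))
    cat("Validation accuracy (%):\n")
    print(round(x$accuracy, 1))
  }
  invisible(x)
}

#' Predict plate parameters for new sensing videos
#'
#' @param object a fitted `wvt` model.
#' @param newdata a `wvt_dataset` or a video array
#'   `n x T' x 9 x 22 x 4` (a single video may drop the first dimension).
#' @param ... unused.
#' @return Data frame with predicted X, Y, alpha, beta.
#' @export
predict.wvt <- function(object, newdata, ...) {
  videos <- if (inherits(newdata, "wvt_dataset")) newdata$videos else newdata
  if (length(dim(videos)) == 4) dim(videos) <- c(1, dim(videos))
  videos <- .standardize_videos(videos, object$norm)
  out <- .batched_predict_tokens(object$params, object$config,
                                 tubelet_tokens(videos, object$config),
                                 seq_len(dim(videos)[1]))
  out <- .destandardize_labels(out, object$norm)
  setNames(as.data.frame(out), c("X", "Y", "alpha", "beta"))
}

#' @export
residuals.wvt <- function(object, ...) {
  if (is.null(object$val_pred))
    stop("model was fitted without validation rows; residuals unavailable")
  setNames(as.data.frame(object$val_truth - object$val_pred),
           c("X", "Y", "alpha", "beta"))
}

#' @export
coef.wvt <- function(object, ...) object$params

#' @export
plot.wvt <- function(x, ...) {
  h <- x$history
  ylim <- range(c(h$train_mse, h$val_mse), na.rm = TRUE, finite = TRUE)
  graphics::plot(h$epoch, h$train_mse, type = "l", log = "y",
                 xlab = "epoch", ylab = "MSE (standardized)",
                 ylim = ylim, ...)
  if (any(is.finite(h$val_mse)))
    graphics::lines(h$epoch, h$val_mse, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}

#' @export
print.wvt_cv <- function(x, ...) {
  ev <- evaluate(x)
  cat("Cross-validated video transformer (", x$k, " folds)\n", sep = "")
  cat("Per-parameter accuracy, mean (sd) %:\n")
  for (nm in colnames(x$accuracy))
    cat(sprintf("  %-6s %6.1f (%.1f)\n", nm, ev$mean[nm], ev$sd[nm]))
  cat(sprintf("Overall: %.1f%%; best fold by val MSE: %d\n",
              ev$overall, ev$best_fold))
  invisible(x)
}

#' Importance maps for a fitted model
#'
#' Convenience wrapper around [vt_importance()] that applies the model's
#' stored input standardization to a raw video.
#'
#' @param object a fitted `wvt`.
#' @param video raw video `T' x 9 x 22 x 4` (or a `wvt_dataset` plus
#'   `case` index).
#' @param case case index when `video` is a dataset.
#' @param backend see [vt_importance()].
#' @return An `importance_maps` object.
#' @export
importance <- function(object, video, case = NULL,
                       backend = c("rollout", "saliency")) {
  stopifnot(inherits(object, "wvt"))
  if (inherits(video, "wvt_dataset")) {
    if (is.null(case)) stop("give a case index with a dataset")
    video <- video$videos[case, , , , ]
  }
  arr <- array(video, c(1, dim(video)))
  arr <- .standardize_videos(arr, object$norm)
  # attribution reference: what a zero physical signal looks like after
  # the stored standardization
  null_arr <- .standardize_videos(array(0, dim(arr)), object$norm)
  dd <- dim(arr)[-1]
  vt_importance(object$params, object$config, array(arr[1, , , , ], dd),
                backend = match.arg(backend),
                null_video = array(null_arr[1, , , , ], dd))
}

#' Desk-scale study protocol
#'
#' The reduced problem sizes used throughout the examples, tests and the
#' reproduction script: a 3 x 3 x 3 x 3 sub-grid of the full parametric
#' space (81 cases), a compact transformer (t' = 8 frames by 3 x 11 pixel
#' tubelets, so 10 temporal patches of 3 x 2 muzzle-region tokens; L = 2,
#' G = 32, 2 heads, MLP ratio 2) and a short Adam schedule (150 epochs,
#' batch 16, learning rate 1e-2 decayed at 70% and 90%). The coarse
#' region-level spatial tokens are what makes a 900-step training budget
#' sufficient: with per-pixel tokens the pooled representation needs far
#' more steps to bind values to positions. A full dataset-plus-training
#' run takes a few minutes on one CPU core while preserving every
#' structural element of the full-scale protocol.
#'
#' @param seed seed for the training run.
#' @param epochs,batch_size overridable schedule.
#' @return List with `grid` ([param_grid()]), `config` ([vt_config()]) and
#'   `control` ([vt_control()]).
#' @export
desk_protocol <- function(seed = 1, epochs = 150, batch_size = 16) {
  list(grid = param_grid(X = seq(-120, 120, by = 120),
                         Y = seq(0, 200, by = 100),
                         alpha = seq(-45, 45, by = 45),
                         beta = seq(-45, 45, by = 45)),
       config = vt_config(T_prime = 80, H = 9, W = 22, C = 4,
                          t_prime = 8, h = 3, w = 11, L = 2, G = 32,
                          n_heads = 2, mlp_ratio = 2),
       control = vt_control(epochs = epochs, batch_size = batch_size,
                            lr = 1e-2, milestones = c(0.7, 0.9),
                            seed = seed))
}
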