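# Two-stage fully connected estimator: CBVE (18 -> 2048 -> 1024 -> 512 ->
# 256 -> 128 -> 64 -> 16 -> 8 -> 1, rectified output) predicts CBV from the
# GESFIDE signal ratio; VSDE (19 -> 2048 -> 1024 -> 512 -> 256 -> 128 -> 64
# -> 40, logistic output) predicts the 40-bin VSD from the signal plus the
# (frozen) CBVE prediction.  Both are trained with Adam (beta1 = 0.5,
# beta2 = 0.9, lr = 1e-4) on mean squared error, He-initialized.

#' Model architecture and training hyper-parameters
#'
#' @param cbve_hidden,vsde_hidden hidden layer widths of the two networks.
#' @param lr,beta1,beta2 Adam learning rate and moment decay rates.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs per stage.
#' @param patience early-stopping patience on the validation loss, in epochs
#'   ("trained until convergence" is operationalized as early stopping).
#' @param teacher_forcing use the true CBV (instead of the frozen CBVE
#'   prediction) as the 19th VSDE input during stage-2 training.
#' @param noise_augment_snr_db optional SNR (dB) at which Gaussian noise is
#'   added to training inputs each epoch (`NULL` = off, the main-experiment
#'   condition).
#' @return A `model_spec` list.
#' @export
model_spec <- function(cbve_hidden = c(2048, 1024, 512, 256, 128, 64, 16, 8),
                       vsde_hidden = c(2048, 1024, 512, 256, 128, 64),
                       lr = 1e-4, beta1 = 0.5, beta2 = 0.9,
                       batch_size = 256L, max_epochs = 500L, patience = 20L,
                       teacher_forcing = FALSE,
                       noise_augment_snr_db = NULL) {
  structure(list(cbve_hidden = cbve_hidden, vsde_hidden = vsde_hidden,
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 teacher_forcing = teacher_forcing,
                 noise_augment_snr_db = noise_augment_snr_db),
            class = "model_spec")
}

# ---- minimal dense network engine ------------------------------------------

mlp_init <- function(sizes, out_act) {
  layers <- vector("list", length(sizes) - 1)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1]),
      b = rep(0, sizes[l + 1]))
  }
  list(sizes = sizes, out_act = out_act, layers = layers)
}

act_code <- c(linear = 0L, relu = 1L, sigmoid = 2L)

mlp_forward <- function(net, X, cache = FALSE) {
  A <- list(X)
  nl <- length(net$layers)
  for (l in seq_len(nl)) {
    Z <- A[[l]] %*% net$layers[[l]]$W
    bias_act_cpp(Z, net$layers[[l]]$b,
                 if (l < nl) 1L else act_code[[net$out_act]])
    A[[l + 1]] <- Z
  }
  if (cache) A else A[[nl + 1]]
}

mlp_backward <- function(net, A, Y) {
  nl <- length(net$layers)
  Yhat <- A[[nl + 1]]
  n <- nrow(Y)
  # d MSE / d Yhat, MSE averaged over samples and output nodes
  delta <- 2 * (Yhat - Y) / (n * ncol(Y))
  delta <- switch(net$out_act,
                  relu = delta * (Yhat > 0),
                  sigmoid = delta * Yhat * (1 - Yhat),
                  linear = delta)
  grads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    grads[[l]] <- list(W = crossprod(A[[l]], delta), b = colSums(delta))
    if (l > 1)
      delta <- tcrossprod(delta, net$layers[[l]]$W) * (A[[l]] > 0)
  }
  grads
}

adam_init <- function(net) {
  lapply(net$layers, function(ly)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
}

# weights, gradients and moments are mutated in place by the fused C++
# kernel; `net` and `state` are private to the training loop (deep-copied
# snapshots are taken for early stopping)
adam_step <- function(net, grads, state, spec, t) {
  b1 <- spec$beta1; b2 <- spec$beta2; lr <- spec$lr; eps <- 1e-8
  corr1 <- 1 - b1^t
  corr2 <- 1 - b2^t
  for (l in seq_along(net$layers)) {
    adam_update_cpp(net$layers[[l]]$W, grads[[l]]$W, state[[l]]$mW,
                    state[[l]]$vW, lr, b1, b2, corr1, corr2, eps)
    adam_update_cpp(net$layers[[l]]$b, grads[[l]]$b, state[[l]]$mb,
                    state[[l]]$vb, lr, b1, b2, corr1, corr2, eps)
  }
  invisible(NULL)
}

copy_layers <- function(layers) {
  lapply(layers, function(ly) list(W = ly$W + 0, b = ly$b + 0))
}

mse <- function(Y, Yhat) mean((Y - Yhat)^2)

mlp_train <- function(net, X, Y, Xval, Yval, spec, noise_sigma = NULL) {
  net$layers <- copy_layers(net$layers) # private buffers: updates are in place
  state <- adam_init(net)
  best <- list(loss = Inf, net = net)
  history <- data.frame(epoch = integer(0), train = numeric(0),
                        val = numeric(0))
  t_adam <- 0
  stall <- 0
  n <- nrow(X)
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(n)
    Xe <- X[ord, , drop = FALSE]
    if (!is.null(noise_sigma))
      Xe <- Xe + matrix(rnorm(length(Xe), 0, noise_sigma), nrow(Xe))
    Ye <- Y[ord, , drop = FALSE]
    starts <- seq(1, n, by = spec$batch_size)
    batch_loss <- 0
    for (s in starts) {
      idx <- s:min(s + spec$batch_size - 1, n)
      A <- mlp_forward(net, Xe[idx, , drop = FALSE], cache = TRUE)
      batch_loss <- batch_loss + mse(Ye[idx, , drop = FALSE],
                                     A[[length(A)]]) * length(idx)
      grads <- mlp_backward(net, A, Ye[idx, , drop = FALSE])
      t_adam <- t_adam + 1
      adam_step(net, grads, state, spec, t_adam)
    }
    tr_loss <- batch_loss / n # running minibatch average
    val_loss <- mse(Yval, mlp_forward(net, Xval))
    if (!is.finite(tr_loss) || !is.finite(val_loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    history <- rbind(history,
                     data.frame(epoch = epoch, train = tr_loss,
                                val = val_loss))
    if (val_loss < best$loss) {
      snapshot <- net
      snapshot$layers <- copy_layers(net$layers)
      best <- list(loss = val_loss, net = snapshot)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= spec$patience) break
    }
  }
  list(net = best$net, history = history)
}

# ---- dataset ----------------------------------------------------------------

#' Filter VOIs by CBV bounds and split into train/validation/test
#'
#' VOIs with CBV below the lower bound or above the upper bound are removed
#' (they correspond to background or non-vascular samples); the remainder is
#' shuffled with the seed and split in the given ratio.  Partition sizes
#' follow `floor(N * 8 / 10)`, `floor(N / 10)`, remainder to test -- on
#' 31,320 kept VOIs this yields 25,056 / 3,132 / 3,132.
#'
#' @param signals N x 18 matrix of GESFIDE signal ratios.
#' @param cbv_labels N CBV fractions.
#' @param vsd_labels N x 40 matrix of max-normalized VSDs (or `NULL`).
#' @param bounds inclusion bounds on CBV (default 1% to 40%).
#' @param ratios integer split ratio (default `c(8, 1, 1)`).
#' @param seed shuffle seed.
#' @return A `signal_dataset`: list with `signals`, `cbv_labels`,
#'   `vsd_labels`, `partition` (factor train/val/test) and `provenance`.
#' @export
filter_and_split <- function(signals, cbv_labels, vsd_labels = NULL,
                             bounds = c(0.01, 0.40), ratios = c(8, 1, 1),
                             seed = 1L) {
  signals <- as.matrix(signals)
  stopifnot(nrow(signals) == length(cbv_labels))
  keep <- cbv_labels >= bounds[1] & cbv_labels <= bounds[2]
  if (!any(keep)) stop("no VOIs remain after CBV filtering")
  signals <- signals[keep, , drop = FALSE]
  cbv_labels <- cbv_labels[keep]
  if (!is.null(vsd_labels)) vsd_labels <- vsd_labels[keep, , drop = FALSE]
  n <- nrow(signals)
  tot <- sum(ratios)
  n_train <- floor(n * ratios[1] / tot)
  n_val <- floor(n * ratios[2] / tot)
  n_test <- n - n_train - n_val
  ord <- with_seed(seed, sample.int(n))
  part <- character(n)
  part[ord[seq_len(n_train)]] <- "train"
  part[ord[n_train + seq_len(n_val)]] <- "val"
  part[ord[n_train + n_val + seq_len(n_test)]] <- "test"
  structure(list(signals = signals, cbv_labels = cbv_labels,
                 vsd_labels = vsd_labels,
                 partition = factor(part, levels = c("train", "val", "test")),
                 provenance = list(bounds = bounds, ratios = ratios,
                                   seed = seed, n_removed = sum(!keep))),
            class = "signal_dataset")
}

#' @export
print.signal_dataset <- function(x, ...) {
  cat(sprintf("<signal_dataset> %d VOIs (%s), %d removed by CBV bounds\n",
              nrow(x$signals),
              paste(table(x$partition), collapse = "/"),
              x$provenance$n_removed))
  invisible(x)
}

ds_part <- function(ds, which) {
  i <- ds$partition == which
  list(X = ds$signals[i, , drop = FALSE], cbv = ds$cbv_labels[i],
       vsd = if (!is.null(ds$vsd_labels)) ds$vsd_labels[i, , drop = FALSE])
}

# ---- two-stage training -----------------------------------------------------

#' Train the CBV and VSD estimators in two stages
#'
#' Stage 1 trains the CBVE to minimize the MSE between true and predicted
#' CBV.  Stage 2 freezes the CBVE, appends its prediction (or the true CBV
#' under teacher forcing) as the 19th input, and trains the VSDE to minimize
#' the MSE between true and predicted VSD.  Early stopping monitors the
#' validation loss; the best-validation weights are kept.
#'
#' @param ds a [filter_and_split()] dataset with both label sets.
#' @param spec a [model_spec()].
#' @param seed integer seed controlling initialization and shuffling; two
#'   runs with the same seed, data and spec give identical histories.
#' @return A `model_pair`: list with `cbve`, `vsde`, `training_history`
#'   (per-epoch train/val losses for both stages), `spec` and `seed`.
#' @export
train_two_stage <- function(ds, spec = model_spec(), seed = 1L) {
  stopifnot(inherits(ds, "signal_dataset"), !is.null(ds$vsd_labels))
  tr <- ds_part(ds, "train")
  va <- ds_part(ds, "val")
  n_echo <- ncol(ds$signals)
  noise_sigma <- NULL
  if (!is.null(spec$noise_augment_snr_db)) {
    rms <- sqrt(mean(tr$X^2))
    noise_sigma <- rms * 10^(-spec$noise_augment_snr_db / 20)
  }
  with_seed(seed, {
    cbve <- mlp_init(c(n_echo, spec$cbve_hidden, 1), out_act = "relu")
    # start the rectified output at the mean training CBV: an output that
    # drifts negative early has zero gradient and would stay dead at 0
    cbve$layers[[length(cbve$layers)]]$b[] <- mean(tr$cbv)
    fit1 <- mlp_train(cbve, tr$X, matrix(tr$cbv, ncol = 1),
                      va$X, matrix(va$cbv, ncol = 1), spec, noise_sigma)
    cbve <- fit1$net
    cbv_tr <- if (spec$teacher_forcing) tr$cbv
      else as.numeric(mlp_forward(cbve, tr$X))
    cbv_va <- if (spec$teacher_forcing) va$cbv
      else as.numeric(mlp_forward(cbve, va$X))
    vsde <- mlp_init(c(n_echo + 1, spec$vsde_hidden, ncol(tr$vsd)),
                     out_act = "sigmoid")
    fit2 <- mlp_train(vsde, cbind(tr$X, cbv_tr), tr$vsd,
                      cbind(va$X, cbv_va), va$vsd, spec, noise_sigma)
    structure(list(cbve = cbve, vsde = fit2$net,
                   training_history = list(cbve = fit1$history,
                                           vsde = fit2$history),
                   spec = spec, seed = seed),
              class = "model_pair")
  })
}

#' @export
print.model_pair <- function(x, ...) {
  h <- x$training_history
  cat(sprintf(paste0("<model_pair> CBVE %d epochs (val MSE %.3g), ",
                     "VSDE %d epochs (val MSE %.3g)\n"),
              nrow(h$cbve), min(h$cbve$val), nrow(h$vsde), min(h$vsde$val)))
  invisible(x)
}

#' Predict CBV and VSD from GESFIDE signal ratios
#'
#' The CBVE maps the 18-echo ratio curve to a non-negative CBV; the VSDE
#' maps the curve plus that CBV to a 40-bin VSD with components in (0, 1).
#'
#' @param object a trained `model_pair`.
#' @param signals an 18-vector or N x 18 matrix of signal ratios.
#' @param ... unused.
#' @return List with `cbv` (length N) and `vsd` (N x 40 matrix).
#' @export
predict.model_pair <- function(object, signals, ...) {
  X <- if (is.null(dim(signals))) matrix(signals, nrow = 1)
    else as.matrix(signals)
  if (ncol(X) != object$cbve$sizes[1])
    stop("expected ", object$cbve$sizes[1], " signal values per VOI, got ",
         ncol(X))
  cbv <- as.numeric(mlp_forward(object$cbve, X))
  vsd <- mlp_forward(object$vsde, cbind(X, cbv))
  list(cbv = cbv, vsd = vsd)
}

#' Save / load a trained model pair
#'
#' Weights are serialized with a JSON sidecar recording the architecture and
#' a hash of the training configuration.
#'
#' @param models a `model_pair`.
#' @param path checkpoint path (`.rds`).
#' @return `path` (save) or the restored `model_pair` (load).
#' @export
save_model_pair <- function(models, path) {
  saveRDS(models, path)
  meta <- list(cbve_hidden = models$spec$cbve_hidden,
               vsde_hidden = models$spec$vsde_hidden,
               seed = models$seed,
               config_hash = digest_obj(models$spec))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model_pair
#' @export
load_model_pair <- function(path) {
  models <- readRDS(path)
  stopifnot(inherits(models, "model_pair"))
  models
}

digest_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
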