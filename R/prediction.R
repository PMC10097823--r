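# Waveform prediction: encoder-decoder network that maps 1-s theta-band Vm
# segments of 1-3 cells (500 bins at 2 ms) to the simultaneous theta-band
# LFP segment, evaluated by 10-fold contiguous cross-validation against
# within-cell segment-shuffle controls.

N_BINS <- 500L

#' Architecture and training hyperparameters of the LFP decoder
#'
#' The structural contract is fixed: the convolution output flattens to
#' 64 x 500 = 32,000, the encoder bottleneck is 100, and the output is a
#' 500-bin waveform. Encoder sizes taper 32,000 -> 2,000 -> 500 -> 200 ->
#' 100 (four fully connected layers); the decoder reconstructs via three
#' fully connected layers 100 -> 200 -> 500 -> 500 with a linear output.
#'
#' @param n_cells number of input Vm channels (1-3).
#' @param conv_filters convolution feature maps (64; fixed by the 32,000
#'   flatten size).
#' @param conv_kernel kernel length in bins (9 bins = 18 ms).
#' @param fc_encoder_sizes encoder layer widths ending at the bottleneck.
#' @param fc_decoder_sizes decoder layer widths ending at the output.
#' @param dropout dropout probability after the non-bottleneck encoder
#'   layers (0.5).
#' @param lr,beta1,beta2,eps,decay Adam settings (lr 0.001, beta1 0.9,
#'   beta2 0.999, eps 1e-7, decay 1e-4); parameter tuning found lr = 0.01
#'   with ~5 epochs equally workable, which short runs use.
#' @param epochs,batch training schedule (50 epochs, batch 256).
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(n_cells, conv_filters = 64, conv_kernel = 9,
                       fc_encoder_sizes = c(2000, 500, 200, 100),
                       fc_decoder_sizes = c(200, 500, 500),
                       dropout = 0.5, lr = 0.001, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-7, decay = 1e-4,
                       epochs = 50, batch = 256, seed = 1L) {
  stopifnot(n_cells %in% 1:3)
  if (conv_filters * N_BINS != 32000L)
    stop("flattened convolution output must be 32,000 (conv_filters x 500)")
  if (utils::tail(fc_encoder_sizes, 1) != 100L)
    stop("encoder bottleneck must be 100")
  if (utils::tail(fc_decoder_sizes, 1) != N_BINS)
    stop("decoder output must be 500")
  structure(list(n_cells = as.integer(n_cells),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 fc_encoder_sizes = as.integer(fc_encoder_sizes),
                 fc_decoder_sizes = as.integer(fc_decoder_sizes),
                 dropout = dropout, lr = lr, beta1 = beta1, beta2 = beta2,
                 eps = eps, decay = decay, epochs = as.integer(epochs),
                 batch = as.integer(batch), seed = as.integer(seed)),
            class = "model_spec")
}

#' Build an untrained LFP decoder
#'
#' Initializes the network weights (He-scaled Gaussian) deterministically
#' from `spec$seed`. Dropout is applied after each encoder layer except
#' the bottleneck; hidden activations are rectified-linear, the output is
#' linear.
#'
#' @param spec a [model_spec()].
#' @return object of class `lfp_decoder` holding the weights and spec.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(spec$seed)
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                sqrt(2 / nin)), nin, nout)
  Wc <- he(spec$conv_kernel * spec$n_cells, spec$conv_filters)
  fc <- list()
  sizes_in <- 32000L
  n_enc <- length(spec$fc_encoder_sizes)
  for (i in seq_len(n_enc)) {
    nout <- spec$fc_encoder_sizes[i]
    fc[[length(fc) + 1L]] <- list(W = he(sizes_in, nout),
                                  b = rep(0, nout), relu = TRUE,
                                  dropout = i < n_enc)
    sizes_in <- nout
  }
  n_dec <- length(spec$fc_decoder_sizes)
  for (i in seq_len(n_dec)) {
    nout <- spec$fc_decoder_sizes[i]
    # the linear output layer starts at 1/10 scale so the first Adam
    # updates move the output gently instead of overshooting the targets
    W <- he(sizes_in, nout)
    if (i == n_dec) W <- W * 0.1
    fc[[length(fc) + 1L]] <- list(W = W,
                                  b = rep(0, nout), relu = i < n_dec,
                                  dropout = FALSE)
    sizes_in <- nout
  }
  weights <- list(Wc = Wc, bc = rep(0, spec$conv_filters),
                  kernel = spec$conv_kernel, n_cells = spec$n_cells,
                  n_bins = as.integer(N_BINS), fc = fc)
  structure(list(spec = spec, weights = weights, trained = FALSE,
                 loss = numeric(0)),
            class = "lfp_decoder")
}

#' @export
print.lfp_decoder <- function(x, ...) {
  np <- length(x$weights$Wc) + length(x$weights$bc) +
    sum(vapply(x$weights$fc, function(l) length(l$W) + length(l$b),
               numeric(1)))
  cat(sprintf("<lfp_decoder> %d-cell input, %s parameters, %s\n",
              x$spec$n_cells, format(np, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Train an LFP decoder on segment pairs
#'
#' Mean-squared-error training with Adam; deterministic given
#' `seed` (initialization, shuffling and dropout all derive from it).
#'
#' @param model an `lfp_decoder` from [build_model()].
#' @param x segment array `[n, n_cells, 500]`.
#' @param y target matrix `[n, 500]`.
#' @param epochs,batch override the spec schedule if given.
#' @param seed training-loop seed (default `spec$seed`).
#' @param verbose print per-epoch loss.
#' @return the trained `lfp_decoder` (with `loss` history).
#' @export
train_decoder <- function(model, x, y, epochs = NULL, batch = NULL,
                          seed = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "lfp_decoder"))
  sp <- model$spec
  d <- dim(x)
  if (length(d) != 3 || d[2] != sp$n_cells || d[3] != N_BINS)
    stop("x must be an [n, n_cells, 500] array")
  if (!is.matrix(y) || nrow(y) != d[1] || ncol(y) != N_BINS)
    stop("y must be an [n, 500] matrix")
  # Per-channel standardization keeps training scale-free (the analyses
  # treat amplitudes as relative); the scales are stored in the model and
  # inverted at prediction time. Inputs are scaled to SD 0.01 rather than
  # 1: with 32,000-wide layers, Adam's near-sign-steps move the output by
  # ~lr * width * E|activation| per update, so unit-scale activations blow
  # the output past the targets in the first epoch and strand the ReLUs;
  # centimilli-scale inputs keep the early updates inside the target range.
  xscale <- vapply(seq_len(d[2]), function(c) stats::sd(x[, c, ]),
                   numeric(1)) / 0.01
  xscale[xscale == 0] <- 1
  yscale <- stats::sd(y)
  if (yscale == 0) yscale <- 1
  for (c in seq_len(d[2])) x[, c, ] <- x[, c, ] / xscale[c]
  res <- .cpp_nn_train(x, y / yscale, model$weights, sp$lr, sp$beta1,
                       sp$beta2, sp$eps, sp$decay, sp$dropout,
                       if (is.null(epochs)) sp$epochs else as.integer(epochs),
                       if (is.null(batch)) sp$batch else as.integer(batch),
                       if (is.null(seed)) sp$seed else as.integer(seed),
                       verbose)
  model$weights <- res$weights
  model$scales <- list(x = xscale, y = yscale)
  model$loss <- c(model$loss, as.numeric(res$loss))
  model$trained <- TRUE
  model
}

#' Predict LFP segments from Vm segments
#' @param object a trained `lfp_decoder`.
#' @param x segment array `[n, n_cells, 500]`.
#' @param ... unused.
#' @return `[n, 500]` matrix of predicted waveforms.
#' @export
predict.lfp_decoder <- function(object, x, ...) {
  if (!is.null(object$scales)) {
    for (c in seq_len(dim(x)[2])) x[, c, ] <- x[, c, ] / object$scales$x[c]
    return(.cpp_nn_predict(x, object$weights) * object$scales$y)
  }
  .cpp_nn_predict(x, object$weights)
}

#' Root mean squared error between two waveforms
#' @param pred,target equal-length numeric vectors.
#' @return `sqrt(mean((pred - target)^2))`.
#' @export
rmse <- function(pred, target) {
  if (length(pred) != length(target)) stop("length mismatch")
  sqrt(mean((pred - target)^2))
}

#' Contiguous cross-validation folds with band-filtered traces
#'
#' Downsamples (if needed) and bandpass-filters the LFP and Vm traces at
#' 500 Hz, then partitions the recording into `n_folds` contiguous,
#' equal-length, disjoint time blocks. Recordings shorter than 3 minutes
#' are rejected (too few training segments).
#'
#' @param dataset a `theta_dataset`.
#' @param lfp_label label of the target LFP channel.
#' @param cell_labels labels of 1-3 Vm channels (input order fixed).
#' @param band filter band in Hz (default theta, `c(3, 10)`).
#' @param n_folds number of blocks (default 10).
#' @param min_duration_s minimum accepted recording length (default 180).
#' @return list of class `decoder_folds`: filtered `lfp`/`vms` sample
#'   vectors, `fs`, `blocks` (per-fold sample index ranges), labels, band.
#' @export
make_folds <- function(dataset, lfp_label, cell_labels, band = c(3, 10),
                       n_folds = 10, min_duration_s = 180) {
  stopifnot(inherits(dataset, "theta_dataset"))
  if (dataset$duration_s < min_duration_s)
    stop("recording too short for prediction: ", dataset$duration_s,
         " s < ", min_duration_s, " s")
  labels <- c(lfp_label, cell_labels)
  missing_lb <- setdiff(labels, names(dataset$traces))
  if (length(missing_lb))
    stop("unknown channels: ", paste(missing_lb, collapse = ", "))
  prep <- function(lb) {
    tr <- dataset$traces[[lb]]
    if (tr$fs != 500) tr <- downsample_trace(tr, 500)
    bandpass_trace(tr, band[1], band[2])$samples
  }
  lfp <- prep(lfp_label)
  vms <- lapply(cell_labels, prep)
  n <- min(c(length(lfp), vapply(vms, length, integer(1))))
  lfp <- lfp[seq_len(n)]
  vms <- lapply(vms, function(v) v[seq_len(n)])
  bounds <- floor(seq(0, n, length.out = n_folds + 1))
  blocks <- lapply(seq_len(n_folds), function(i)
    c(start = bounds[i] + 1, end = bounds[i + 1]))
  structure(list(lfp = lfp, vms = vms, fs = 500, blocks = blocks,
                 lfp_label = lfp_label, cell_labels = cell_labels,
                 band = band),
            class = "decoder_folds")
}

#' Extract 1-s segment pairs from fold blocks
#'
#' Training segments slide at `stride_s` within each of the training
#' blocks (never crossing block boundaries); test segments slide at
#' `stride_s` within the held-out block. A cap subsamples training
#' segments uniformly at random (seeded) for desk-scale runs.
#'
#' @param folds a `decoder_folds`.
#' @param test_fold index of the held-out block (1-based).
#' @param role `"train"` or `"test"`.
#' @param stride_s segment stride in seconds (training default 0.002 = one
#'   bin; test default 0.1).
#' @param max_segments optional cap on the number of segments.
#' @param seed seed for the subsampling draw.
#' @return list with `x` array `[n, n_cells, 500]`, `y` matrix `[n, 500]`,
#'   `t0_s` segment starts, `fold_id`.
#' @export
extract_segments <- function(folds, test_fold, role = c("train", "test"),
                             stride_s = if (role == "train") 0.002 else 0.1,
                             max_segments = NULL, seed = 1) {
  role <- match.arg(role)
  fs <- folds$fs
  step <- max(1L, as.integer(round(stride_s * fs)))
  block_ids <- if (role == "test") test_fold
               else setdiff(seq_along(folds$blocks), test_fold)
  starts <- integer(0)
  for (b in block_ids) {
    blk <- folds$blocks[[b]]
    if (blk["end"] - blk["start"] + 1 < N_BINS) next  # block < one window
    s <- seq.int(blk["start"], blk["end"] - N_BINS + 1L, by = step)
    s <- s[s + N_BINS - 1L <= blk["end"]]
    starts <- c(starts, s)
  }
  if (!is.null(max_segments) && length(starts) > max_segments) {
    set.seed(seed)
    starts <- sort(sample(starts, max_segments))
  }
  n <- length(starts)
  ncell <- length(folds$vms)
  x <- array(0, dim = c(n, ncell, N_BINS))
  y <- matrix(0, n, N_BINS)
  for (i in seq_len(n)) {
    idx <- starts[i]:(starts[i] + N_BINS - 1L)
    for (c in seq_len(ncell)) x[i, c, ] <- folds$vms[[c]][idx]
    y[i, ] <- folds$lfp[idx]
  }
  list(x = x, y = y, t0_s = (starts - 1) / fs, fold_id = test_fold)
}

#' Within-cell segment shuffle of training data
#'
#' For each input channel independently, permutes which segment's trace
#' occupies each time label; targets stay put. The per-channel multiset of
#' traces is preserved exactly while the channel-to-target (and
#' channel-to-channel) alignment is destroyed -- the chance-level control
#' for the decoder.
#'
#' @param segments output of [extract_segments()].
#' @param seed RNG seed.
#' @return segments with shuffled `x`.
#' @export
shuffle_training <- function(segments, seed = 1) {
  x <- segments$x
  n <- dim(x)[1]
  if (n >= 2) {
    set.seed(seed)
    for (c in seq_len(dim(x)[2]))
      x[, c, ] <- x[sample(n), c, ]
  }
  segments$x <- x
  segments
}

#' Predict theta-band LFP waveforms from Vm traces
#'
#' Full evaluation pipeline: contiguous folds, per-fold training on real
#' segment pairs and prediction of the held-out segments, an independent
#' from-scratch training on within-cell shuffled segments, per-segment
#' RMSEs for both arms, and a pooled two-sample KS comparison of the RMSE
#' distributions. Real-trained RMSEs significantly below shuffle-trained
#' RMSEs indicate that the LFP waveform is predictable from the Vm
#' waveforms beyond segment-level chance.
#'
#' @param dataset a `theta_dataset` (>= 3 min).
#' @param lfp_label,cell_labels target and input channels.
#' @param band filter band (default theta `c(3, 10)`).
#' @param spec a [model_spec()]; default derives from `length(cell_labels)`.
#' @param n_folds number of contiguous folds (default 10).
#' @param folds_to_run subset of folds to evaluate (default: all).
#' @param train_stride_s,test_stride_s segment strides (defaults 0.002 and
#'   0.1 s).
#' @param max_train_segments optional per-fold cap on training segments.
#' @param epochs optional override of `spec$epochs`.
#' @param seed master seed; fold-level seeds derive from it.
#' @param verbose print progress.
#' @return object of class `lfp_prediction`: `rmse_real`, `rmse_shuffled`,
#'   `ks_d`, `p`, `folds` (per-fold summaries), `config`.
#' @export
predict_lfp <- function(dataset, lfp_label, cell_labels, band = c(3, 10),
                        spec = NULL, n_folds = 10, folds_to_run = NULL,
                        train_stride_s = 0.002, test_stride_s = 0.1,
                        max_train_segments = NULL, epochs = NULL,
                        seed = 1, verbose = FALSE) {
  if (is.null(spec)) spec <- model_spec(n_cells = length(cell_labels))
  folds <- make_folds(dataset, lfp_label, cell_labels, band = band,
                      n_folds = n_folds)
  if (is.null(folds_to_run)) folds_to_run <- seq_len(n_folds)
  rmse_real <- numeric(0); rmse_shuf <- numeric(0)
  fold_rows <- list()
  for (tf in folds_to_run) {
    fseed <- as.integer((seed * 1000L + tf) %% .Machine$integer.max)
    train <- extract_segments(folds, tf, "train", stride_s = train_stride_s,
                              max_segments = max_train_segments,
                              seed = fseed)
    test <- extract_segments(folds, tf, "test", stride_s = test_stride_s)
    if (!dim(train$x)[1] || !dim(test$x)[1]) next
    sp_real <- spec; sp_real$seed <- fseed
    m_real <- build_model(sp_real)
    m_real <- tryCatch(
      train_decoder(m_real, train$x, train$y, epochs = epochs,
                    seed = fseed, verbose = verbose),
      error = function(e) stop("fold ", tf, ": ", conditionMessage(e)))
    pr <- predict(m_real, test$x)
    rr <- vapply(seq_len(nrow(pr)), function(i) rmse(pr[i, ], test$y[i, ]),
                 numeric(1))
    shuf <- shuffle_training(train, seed = fseed + 1L)
    sp_shuf <- spec; sp_shuf$seed <- fseed + 2L  # fresh initialization
    m_shuf <- build_model(sp_shuf)
    m_shuf <- tryCatch(
      train_decoder(m_shuf, shuf$x, shuf$y, epochs = epochs,
                    seed = fseed + 2L, verbose = verbose),
      error = function(e) stop("fold ", tf, " (shuffled): ",
                               conditionMessage(e)))
    ps <- predict(m_shuf, test$x)
    rs <- vapply(seq_len(nrow(ps)), function(i) rmse(ps[i, ], test$y[i, ]),
                 numeric(1))
    rmse_real <- c(rmse_real, rr)
    rmse_shuf <- c(rmse_shuf, rs)
    fold_rows[[length(fold_rows) + 1L]] <-
      data.frame(fold = tf, n_train = dim(train$x)[1],
                 n_test = dim(test$x)[1],
                 rmse_real = stats::median(rr),
                 rmse_shuffled = stats::median(rs))
    if (verbose)
      message(sprintf("fold %d: median RMSE real %.4g shuffled %.4g",
                      tf, stats::median(rr), stats::median(rs)))
  }
  if (!length(rmse_real)) stop("no evaluable folds")
  kt <- ks_two_sample(rmse_real, rmse_shuf)
  structure(list(rmse_real = rmse_real, rmse_shuffled = rmse_shuf,
                 ks_d = kt$statistic, p = kt$p,
                 folds = do.call(rbind, fold_rows),
                 config = list(spec = spec, band = band, n_folds = n_folds,
                               folds_to_run = folds_to_run,
                               train_stride_s = train_stride_s,
                               test_stride_s = test_stride_s,
                               max_train_segments = max_train_segments,
                               epochs = epochs, seed = seed)),
            class = "lfp_prediction")
}

#' @export
print.lfp_prediction <- function(x, ...) {
  cat(sprintf("<lfp_prediction> %d segments/arm over %d fold(s)\n",
              length(x$rmse_real), nrow(x$folds)))
  cat(sprintf("  median RMSE: real %.4g, shuffled %.4g\n",
              stats::median(x$rmse_real), stats::median(x$rmse_shuffled)))
  cat(sprintf("  KS D = %.3g, p = %.3g\n", x$ks_d, x$p))
  invisible(x)
}

#' @export
summary.lfp_prediction <- function(object, ...) {
  out <- list(
    n_segments = length(object$rmse_real),
    median_rmse_real = stats::median(object$rmse_real),
    median_rmse_shuffled = stats::median(object$rmse_shuffled),
    ks_d = object$ks_d, p = object$p, folds = object$folds)
  class(out) <- "summary.lfp_prediction"
  out
}

#' @export
print.summary.lfp_prediction <- function(x, ...) {
  cat("LFP waveform prediction (real vs within-cell shuffle)\n")
  cat(sprintf("  segments per arm : %d\n", x$n_segments))
  cat(sprintf("  median RMSE real : %.4g\n", x$median_rmse_real))
  cat(sprintf("  median RMSE shuf : %.4g\n", x$median_rmse_shuffled))
  cat(sprintf("  KS D = %.3g, p = %.3g\n", x$ks_d, x$p))
  print(x$folds, row.names = FALSE)
  invisible(x)
}

#' @export
plot.lfp_prediction <- function(x, ...) {
  r <- sort(x$rmse_real); s <- sort(x$rmse_shuffled)
  plot(r, seq_along(r) / length(r), type = "s", col = "steelblue",
       xlab = "RMSE", ylab = "cumulative probability",
       main = "Prediction error: real vs shuffled training", ...)
  lines(s, seq_along(s) / length(s), type = "s", col = "gray50")
  legend("bottomright", legend = c("real", "shuffled"),
         col = c("steelblue", "gray50"), lty = 1, bty = "n")
  invisible(x)
}

#' Run the prediction pipeline across alternative frequency bands
#'
#' Repeats [predict_lfp()] for each band (the gamma and slow-oscillation
#' negative controls use `c(60, 100)`, `c(25, 55)`, `c(0.5, 1)`).
#'
#' @param dataset,lfp_label,cell_labels as in [predict_lfp()].
#' @param bands list of `c(lo, hi)` bands.
#' @param ... passed to [predict_lfp()].
#' @return named list of `lfp_prediction` objects.
#' @export
band_generalization <- function(dataset, lfp_label, cell_labels,
                                bands = list(theta = c(3, 10),
                                             high_gamma = c(60, 100),
                                             low_gamma = c(25, 55),
                                             slow = c(0.5, 1)), ...) {
  fs <- dataset$traces[[lfp_label]]$fs
  out <- lapply(bands, function(bd) {
    if (bd[2] >= fs / 2) stop("band exceeds Nyquist: ", bd[2], " Hz")
    predict_lfp(dataset, lfp_label, cell_labels, band = bd, ...)
  })
  names(out) <- names(bands)
  out
}
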