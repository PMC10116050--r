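#' Pattern-recognition configuration
#'
#' Windowing and training parameters of the gesture classifier: 250 ms
#' analysis windows sliding by 125 ms (so class decisions update at 8 Hz),
#' five motion classes, and a multilayer perceptron with one hidden layer of
#' ten logistic units.
#'
#' @param window_s analysis window length, seconds (default 0.250).
#' @param overlap_s window overlap = slide step, seconds (default 0.125);
#'   must satisfy 0 < overlap_s < window_s.
#' @param zc_ssc_deadband amplitude deadband (mV) for the ZC/SSC features.
#' @param mapping a [motion_mapping()].
#' @param seed RNG seed used for weight initialization when (re)training.
#' @param epochs maximum training iterations, default 500.
#' @return An object of class `pr_config`.
#' @export
pr_config <- function(window_s = 0.250, overlap_s = 0.125,
                      zc_ssc_deadband = 0.01,
                      mapping = motion_mapping("right_handed"),
                      seed = 1L, epochs = 500L) {
  stopifnot(overlap_s > 0, overlap_s < window_s)
  structure(list(window_s = window_s, overlap_s = overlap_s,
                 zc_ssc_deadband = zc_ssc_deadband, mapping = mapping,
                 seed = as.integer(seed), epochs = as.integer(epochs)),
            class = "pr_config")
}

#' Build a labeled training set from per-class contraction recordings
#'
#' Each repetition is high-pass filtered, cut into sliding windows (250 ms,
#' 125 ms step, windows never cross repetition boundaries) and reduced to the
#' five time-domain features per channel. The standard protocol — five 2 s
#' repetitions of each of the five motion classes — yields 15 windows per
#' repetition and 375 feature vectors in total.
#'
#' @param recordings named list: one entry per motion class (all five of
#'   [MOTION_CLASSES] required), each a list of raw [emg_recording()]s
#'   (>= 2 s each; 5 repetitions in the standard protocol).
#' @param cfg a [pr_config()].
#' @return `list(x = , y = )`: feature matrix (rows = windows) and a factor
#'   of class labels.
#' @export
build_training_set <- function(recordings, cfg = pr_config()) {
  missing <- setdiff(MOTION_CLASSES, names(recordings))
  if (length(missing) > 0)
    stop("missing training recordings for class(es): ",
         paste(missing, collapse = ", "))
  xs <- list(); ys <- character(0)
  for (cls in MOTION_CLASSES) {
    for (rec in recordings[[cls]]) {
      stopifnot(inherits(rec, "emg_recording"))
      if (duration(rec) < 2)
        stop(sprintf("a %s repetition is shorter than 2 s", cls))
      hp <- emg_highpass(rec)
      fore <- forearm_channels(rec$channel_roles)
      sig <- hp$samples[fore, , drop = FALSE]
      win <- round(cfg$window_s * rec$fs)
      step <- round(cfg$overlap_s * rec$fs)
      for (s in window_starts(ncol(sig), win, step)) {
        xs[[length(xs) + 1L]] <-
          extract_features(sig[, s:(s + win - 1L), drop = FALSE],
                           cfg$zc_ssc_deadband)
        ys <- c(ys, cls)
      }
    }
  }
  list(x = do.call(rbind, xs), y = factor(ys, levels = MOTION_CLASSES))
}

#' Train the gesture classifier
#'
#' Features are z-scored with training-set statistics (otherwise waveform
#' length dwarfs the count features), then a single-hidden-layer MLP
#' (30 -> 10 logistic units -> 5 softmax outputs) is fit. Training is
#' deterministic for a fixed seed. If the optimizer stops at the iteration
#' cap a convergence warning is recorded in the model metadata and the model
#' is returned anyway.
#'
#' @param training_set output of [build_training_set()].
#' @param cfg a [pr_config()]; `cfg$seed` fixes the weight initialization.
#' @return An object of class `pr_model`: scaler parameters, weight matrices
#'   `w1` (features x hidden), `b1`, `w2` (hidden x classes), `b2`, class
#'   levels and training metadata (seed, epochs, training accuracy,
#'   convergence flag).
#' @export
pr_train <- function(training_set, cfg = pr_config()) {
  x <- as.matrix(training_set$x)
  y <- training_set$y
  if (any(table(y) < 2)) stop("need at least 2 samples per class")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  fit <- withr::with_seed(cfg$seed,
    nnet::nnet(xs, nnet::class.ind(y), size = 10, softmax = TRUE,
               maxit = cfg$epochs, decay = 1e-4, trace = FALSE,
               MaxNWts = 5000))
  converged <- fit$convergence == 0
  nin <- ncol(xs)
  # nnet weight layout: per hidden unit (bias, inputs); then per output
  # unit (bias, hidden)
  wts <- fit$wts
  h <- 10L; k <- nlevels(y)
  w1 <- matrix(0, nin, h); b1 <- numeric(h)
  for (j in seq_len(h)) {
    off <- (j - 1L) * (nin + 1L)
    b1[j] <- wts[off + 1L]
    w1[, j] <- wts[off + 1L + seq_len(nin)]
  }
  w2 <- matrix(0, h, k); b2 <- numeric(k)
  base <- h * (nin + 1L)
  for (m in seq_len(k)) {
    off <- base + (m - 1L) * (h + 1L)
    b2[m] <- wts[off + 1L]
    w2[, m] <- wts[off + 1L + seq_len(h)]
  }
  model <- structure(
    list(center = center, scale = scale, w1 = w1, b1 = b1, w2 = w2, b2 = b2,
         classes = levels(y),
         meta = list(seed = cfg$seed, epochs = cfg$epochs,
                     converged = converged, training_accuracy = NA_real_)),
    class = "pr_model")
  model$meta$training_accuracy <-
    mean(pr_classify(model, x) == as.character(y))
  if (!converged)
    warning("MLP training stopped at the iteration cap without converging")
  model
}

#' Classify feature vectors
#'
#' Deterministic forward pass through the stored network: z-score with the
#' training scaler, logistic hidden layer, softmax output, argmax class.
#'
#' @param model a [pr_model][pr_train()].
#' @param features a feature vector (length = trained input size) or a matrix
#'   with one vector per row.
#' @return character vector of motion classes.
#' @export
pr_classify <- function(model, features) {
  x <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  stopifnot(ncol(x) == nrow(model$w1), all(is.finite(x)))
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  hid <- 1 / (1 + exp(-(xs %*% model$w1 +
                          matrix(model$b1, nrow(xs), length(model$b1), byrow = TRUE))))
  out <- hid %*% model$w2 +
    matrix(model$b2, nrow(hid), length(model$b2), byrow = TRUE)
  model$classes[max.col(out, ties.method = "first")]
}

#' Pattern-recognition proportional signal
#'
#' Overall contraction intensity: voluntary (rest-subtracted, clamped)
#' envelopes of the six forearm channels are averaged and normalized to the
#' mean forearm MVC envelope, clamped to \[0, 1\].
#'
#' @param envelopes numeric vector of current per-channel envelope samples
#'   (mV), matching the calibration layout.
#' @param calib a [calibration_profile()].
#' @return scalar in \[0, 1\].
#' @export
pr_proportional <- function(envelopes, calib) {
  stopifnot(length(envelopes) == length(calib$rest_env))
  fore <- forearm_channels(calib$channel_roles)
  vol <- pmax(envelopes[fore] - calib$rest_env[fore], 0)
  min(max(mean(vol) / calib$mvc_mean_env, 0), 1)
}

#' Pattern-recognition control output
#'
#' The decoded class selects the cursor direction (one axis, signed, per the
#' mapping preset); the proportional signal scales it. NO_MOTION yields
#' (0, 0).
#'
#' @param cls a motion class (one of [MOTION_CLASSES]).
#' @param U proportional signal in \[0, 1\].
#' @param mapping a [motion_mapping()].
#' @return numeric 2-vector (x, y), at most one nonzero component.
#' @export
pr_output <- function(cls, U, mapping) {
  stopifnot(cls %in% MOTION_CLASSES, U >= 0, U <= 1)
  mapping$pr[[cls]] * U
}

#' Serialize / load a trained classifier as JSON
#'
#' The stored weights fully determine [pr_classify()], so a round-tripped
#' model reproduces predictions exactly.
#'
#' @param model a [pr_model][pr_train()].
#' @param path JSON file path.
#' @return `write_pr_model` returns `path` invisibly; `read_pr_model` the
#'   model.
#' @export
write_pr_model <- function(model, path) {
  x <- unclass(model)
  x$w1 <- as.data.frame(x$w1); x$w2 <- as.data.frame(x$w2)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pr_model
#' @export
read_pr_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = x$center, scale = x$scale,
                 w1 = as.matrix(x$w1), b1 = x$b1,
                 w2 = as.matrix(x$w2), b2 = x$b2,
                 classes = x$classes, meta = x$meta),
            class = "pr_model")
}

#' @export
print.pr_model <- function(x, ...) {
  cat(sprintf("<pr_model> %d -> %d -> %d MLP; training accuracy %.3f%s\n",
              nrow(x$w1), ncol(x$w1), ncol(x$w2),
              x$meta$training_accuracy,
              if (isTRUE(x$meta$converged)) "" else " (not converged)"))
  invisible(x)
}
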