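#' MLP fusion-model configuration
#'
#' Architecture and optimization settings of the blood-pressure regressor:
#' two ReLU hidden layers of 80 and 12 neurons, each followed by 20%
#' dropout, a linear output unit, MSE loss, and the Adam optimizer with
#' learning rate 0.001. The schedule parameters (epochs, batch size, early
#' stopping) control desk-scale convergence and are exposed here.
#'
#' @param hiddenSizes two hidden-layer widths.
#' @param dropoutRate dropout probability after each hidden layer, in [0, 1).
#' @param learningRate Adam learning rate.
#' @param maxEpochs maximum training epochs.
#' @param batchSize minibatch size.
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping; the best-validation weights are retained.
#' @param seed integer; weight initialization, shuffling and dropout all
#'   derive from it, so training is deterministic.
#' @return an `mlpConfig` list.
#' @export
mlpConfig <- function(hiddenSizes = c(80, 12), dropoutRate = 0.2,
                      learningRate = 0.001, maxEpochs = 500, batchSize = 32,
                      earlyStopPatience = 30, seed = 1) {
  if (length(hiddenSizes) != 2 || any(hiddenSizes < 1))
    stopf("hiddenSizes must give two positive layer widths")
  if (dropoutRate < 0 || dropoutRate >= 1)
    stopf("dropoutRate must lie in [0, 1)")
  if (learningRate <= 0) stopf("learningRate must be positive")
  structure(list(hiddenSizes = as.integer(hiddenSizes),
                 dropoutRate = dropoutRate, learningRate = learningRate,
                 maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize),
                 earlyStopPatience = as.integer(earlyStopPatience),
                 seed = as.integer(seed)),
            class = "mlpConfig")
}

#' Per-feature z-score scaler fitted on training rows only
#'
#' @param X numeric matrix (rows = windows, columns = features) of training
#'   data; constant columns are rejected by name, since a zero-variance
#'   feature cannot be standardized.
#' @return a `featureScaler` with per-column means and standard deviations.
#' @export
fitScaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stopf("scaler needs at least 2 rows")
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  bad <- which(s <= 1e-12)
  if (length(bad))
    stopf("constant feature column(s): %s",
          paste(colnames(X)[bad] %||% bad, collapse = ", "))
  structure(list(mean = mu, sd = s), class = "featureScaler")
}

#' @rdname fitScaler
#' @param scaler a `featureScaler`.
#' @export
applyScaler <- function(scaler, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
}

#' @rdname fitScaler
#' @export
invertScaler <- function(scaler, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, scaler$sd, "*"), 2, scaler$mean, "+")
}

#' Train the MLP blood-pressure model
#'
#' Fits the feature scaler on the training rows only, then trains the MLP
#' with Adam and minibatch updates, monitoring MSE on the validation rows
#' each epoch and retaining the weights of the best validation epoch.
#' Dropout is active only during training. Deterministic given `cfg$seed`.
#'
#' @param X,y training feature matrix (columns named as in
#'   [featureNames()]) and target vector (mmHg).
#' @param Xval,yval validation rows used for early stopping.
#' @param cfg an [mlpConfig()].
#' @param target `"SBP"` or `"DBP"`; when given, the input width is checked
#'   against the target's feature count.
#' @return a `bpModel` with weights, scaler, config, training history and
#'   feature names.
#' @export
trainModel <- function(X, y, Xval, yval, cfg = mlpConfig(), target = NULL) {
  X <- as.matrix(X); Xval <- as.matrix(Xval)
  if (nrow(X) != length(y) || nrow(Xval) != length(yval))
    stopf("feature matrix and target length differ")
  if (ncol(Xval) != ncol(X))
    stopf("validation width %d does not match training width %d",
          ncol(Xval), ncol(X))
  if (!is.null(target)) {
    want <- length(featureNames(target))
    if (ncol(X) != want)
      stopf("%s model expects %d features, got %d", target, want, ncol(X))
  }
  scaler <- fitScaler(X)
  Xs <- applyScaler(scaler, X)
  Xvs <- applyScaler(scaler, Xval)
  fit <- mlp_train_cpp(Xs, as.numeric(y), Xvs, as.numeric(yval),
                       cfg$hiddenSizes[1], cfg$hiddenSizes[2],
                       cfg$dropoutRate, cfg$learningRate, cfg$maxEpochs,
                       cfg$batchSize, cfg$earlyStopPatience,
                       as.integer(cfg$seed) %% .Machine$integer.max)
  structure(list(target = target, weights = fit[c("W1", "b1", "W2", "b2",
                                                  "W3", "b3")],
                 scaler = scaler, config = cfg,
                 featureNames = colnames(X),
                 history = data.frame(epoch = seq_along(fit$trainLoss),
                                      trainLoss = fit$trainLoss,
                                      valLoss = fit$valLoss),
                 bestEpoch = fit$bestEpoch, bestValLoss = fit$bestValLoss),
            class = "bpModel")
}

#' Predict blood pressure from window features
#'
#' Deterministic inference (dropout disabled) with the stored scaler and
#' best-validation weights.
#'
#' @param model a `bpModel` from [trainModel()].
#' @param X feature matrix with the model's input width.
#' @return numeric vector of estimates, mmHg.
#' @export
predictBP <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$scaler$mean))
    stopf("input width %d does not match model width %d",
          ncol(X), length(model$scaler$mean))
  w <- model$weights
  as.numeric(mlp_predict_cpp(applyScaler(model$scaler, X), w$W1, w$b1,
                             w$W2, w$b2, w$W3, w$b3))
}

#' @export
print.bpModel <- function(x, ...) {
  cat(sprintf(
    "bpModel (%s): %d-%d-%d-1 MLP, best val MSE %.3f at epoch %d/%d\n",
    x$target %||% "?", length(x$scaler$mean), x$config$hiddenSizes[1],
    x$config$hiddenSizes[2], x$bestValLoss, x$bestEpoch, nrow(x$history)))
  invisible(x)
}
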