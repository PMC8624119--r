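# The trajectory network: a stacked bidirectional LSTM mapping a stride's
# 256 x 6 IMU window (3 accel + 3 gyro) to the 256 x 6 stride-frame target
# window (heel xyz + toe xyz). Both layers are bidirectional and sum-merged;
# the second layer has 6 units per direction and is itself the output head,
# so predictions are bounded by (-2, 2) in normalized units -- sufficient,
# since targets are scaled into [-1, 1].

#' Network configuration
#'
#' Defaults follow the tuned configuration of the full-scale model
#' (160 units, dropout 0.1, learning rate 1e-3, batch size 100); the
#' desk-scale preset used by the bundled experiments is 64 units / 60 epochs.
#'
#' @param units_layer1 hidden units per direction in the first layer.
#' @param dropout_rate dropout after the first bidirectional layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param lr_decay multiplicative learning-rate decay per epoch (1 = fixed
#'   rate; desk-scale runs benefit from a mild decay with a higher initial
#'   rate).
#' @param seed seed for initialization, shuffling and dropout.
#' @return a `net_config` list.
#' @export
net_config <- function(units_layer1 = 160L, dropout_rate = 0.1,
                       learning_rate = 1e-3, batch_size = 100L,
                       max_epochs = 350L, patience = 50L, lr_decay = 1,
                       seed = 1L) {
  stopifnot(units_layer1 >= 1L, dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, batch_size >= 1L, max_epochs >= 1L,
            patience >= 1L, lr_decay > 0, lr_decay <= 1)
  structure(list(units_layer1 = as.integer(units_layer1),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr_decay = lr_decay,
                 merge_mode = "sum", seed = as.integer(seed)),
            class = "net_config")
}

glorot_mat <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_cell <- function(n_in, n_units) {
  b <- rep(0, 4 * n_units)
  b[(n_units + 1):(2 * n_units)] <- 1          # forget-gate bias at 1
  list(W = glorot_mat(4 * n_units, n_in),
       U = glorot_mat(4 * n_units, n_units), b = b)
}

#' Build an untrained trajectory network
#'
#' @param config a [net_config()].
#' @param n_in,n_out input/output channel counts.
#' @return a `trajectory_net`: weights + config (no scaler yet).
#' @export
build_model <- function(config = net_config(), n_in = 6L, n_out = 6L) {
  h <- config$units_layer1
  with_seed(config$seed, {
    weights <- list(l1f = init_cell(n_in, h), l1b = init_cell(n_in, h),
                    l2f = init_cell(h, n_out), l2b = init_cell(h, n_out))
  })
  structure(list(weights = weights, config = config, scaler = NULL,
                 history = NULL), class = "trajectory_net")
}

#' Number of trainable parameters
#' @param model a `trajectory_net`.
#' @export
n_parameters <- function(model) {
  sum(vapply(unlist(model$weights, recursive = FALSE), length, numeric(1)))
}

#' Mean squared error of a flattened sequence pair
#'
#' Mean of squared element-wise differences over all elements of the
#' flattened sequences (for the standard 256 x 6 window, N = 1536). For a
#' batch, the loss is the mean of the per-sequence values.
#'
#' @param y,y_hat equal-shape numeric arrays.
#' @return scalar MSE.
#' @export
mse_loss <- function(y, y_hat) {
  if (!identical(dim(y) %||% length(y), dim(y_hat) %||% length(y_hat)))
    stop("shape mismatch between reference and estimate")
  mean((y - y_hat)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stack a list of L x C windows into the (C, B, T) cube the C++ core expects
windows_to_cube <- function(windows) {
  if (length(windows) == 0L) stop("no windows to stack")
  L <- nrow(windows[[1]]); C <- ncol(windows[[1]])
  arr <- array(0, dim = c(C, length(windows), L))
  for (i in seq_along(windows)) arr[, i, ] <- t(windows[[i]])
  arr
}

cube_to_windows <- function(cube) {
  lapply(seq_len(dim(cube)[2]), function(i) t(cube[, i, ]))
}

#' Train the trajectory network
#'
#' Mini-batch Adam with epoch-wise reshuffling and early stopping on the
#' validation loss; the returned model carries the weights of the best
#' validation epoch and the full training history. Deterministic given
#' `config$seed` (single-threaded BLAS assumed for bit reproducibility).
#'
#' @param model a `trajectory_net` from [build_model()].
#' @param train,val lists with elements `imu` and `target`, each a list of
#'   L x 6 normalized windows (see [prepare_batches()]).
#' @param scaler optional `scaling_params` pair (list `imu`, `target`)
#'   stored with the model for later prediction.
#' @param verbose print progress.
#' @return the trained `trajectory_net`.
#' @export
train_model <- function(model, train, val = NULL, scaler = NULL,
                        verbose = FALSE) {
  cfg <- model$config
  X <- windows_to_cube(train$imu)
  Y <- windows_to_cube(train$target)
  if (!is.null(val) && length(val$imu) > 0L) {
    Xv <- windows_to_cube(val$imu); Yv <- windows_to_cube(val$target)
  } else {
    Xv <- array(0, dim = c(dim(X)[1], 0, dim(X)[3]))
    Yv <- array(0, dim = c(dim(Y)[1], 0, dim(Y)[3]))
  }
  fit <- cpp_bilstm_train(model$weights, X, Y, Xv, Yv,
                          lr = cfg$learning_rate,
                          batch_size = cfg$batch_size,
                          max_epochs = cfg$max_epochs,
                          patience = cfg$patience,
                          dropout = cfg$dropout_rate,
                          seed = cfg$seed, verbose = verbose,
                          lr_decay = cfg$lr_decay %||% 1)
  model$weights <- fit$weights
  model$history <- data.frame(epoch = seq_along(fit$train_loss),
                              train_mse = fit$train_loss,
                              val_mse = fit$val_loss)
  model$best_epoch <- fit$best_epoch
  model$best_val_loss <- fit$best_val_loss
  if (!is.null(scaler)) model$scaler <- scaler
  model
}

#' Predict physical heel/toe stride trajectories from IMU segments
#'
#' Runs the network on normalized padded windows, applies the stored inverse
#' scaling, and strips the padding, returning per-stride trajectories in
#' meters. Inference is deterministic (no dropout).
#'
#' @param model a trained `trajectory_net` with a stored scaler.
#' @param segments list of stride segments (each with `imu_window`,
#'   `valid_length`), or a list of raw physical L x 6 IMU windows plus
#'   `valid_lengths`.
#' @param normalized set to TRUE if `segments` windows are already
#'   normalized.
#' @return list per stride with `heel` and `toe` (n x 3, m, stride frame).
#' @export
predict_trajectories <- function(model, segments, normalized = FALSE) {
  if (is.null(model$scaler))
    stop("model has no stored scaling parameters; train with `scaler =` first")
  imu_w <- lapply(segments, function(s) {
    w <- s$imu_window
    if (!normalized) scaler_transform(w, model$scaler$imu) else w
  })
  X <- windows_to_cube(imu_w)
  Yhat <- cpp_bilstm_forward(model$weights, X, 0, FALSE, 1L)
  out <- cube_to_windows(Yhat)
  lapply(seq_along(out), function(i) {
    phys <- scaler_inverse(out[[i]], model$scaler$target)
    vl <- segments[[i]]$valid_length
    w <- unpad(phys, vl)
    list(heel = w[, 1:3, drop = FALSE], toe = w[, 4:6, drop = FALSE])
  })
}

#' Trajectory-level evaluation metrics
#'
#' MSE (mm^2), MAE (mm), RMSE (mm) pooled over samples and axes, and mean
#' Euclidean distance (mm) pooled over samples, reported separately per
#' marker.
#'
#' @param pred,ref lists of per-stride trajectories (`heel`, `toe` n x 3, m).
#' @return data.frame with one row per marker.
#' @export
evaluate_trajectories <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("stride count mismatch")
  one <- function(marker) {
    d <- lapply(seq_along(pred), function(i) {
      p <- pred[[i]][[marker]]; r <- ref[[i]][[marker]]
      if (!all(dim(p) == dim(r))) stop("trajectory length mismatch")
      (p - r) * 1000
    })
    d <- do.call(rbind, d)
    data.frame(marker = marker, mse = mean(d^2), mae = mean(abs(d)),
               rmse = sqrt(mean(d^2)),
               euclidean = mean(sqrt(rowSums(d^2))))
  }
  rbind(one("heel"), one("toe"))
}

#' Save / load a trained model as plain text (JSON)
#'
#' @param model a `trajectory_net`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  obj <- list(weights = model$weights,
              config = unclass(model$config),
              scaler = lapply(model$scaler, unclass),
              history = model$history, best_epoch = model$best_epoch)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- lapply(obj$weights, function(cell)
    list(W = as.matrix(cell$W), U = as.matrix(cell$U), b = as.numeric(cell$b)))
  keep <- intersect(c("units_layer1", "dropout_rate", "learning_rate",
                      "batch_size", "max_epochs", "patience", "lr_decay",
                      "seed"), names(obj$config))
  cfg <- do.call(net_config, obj$config[keep])
  scaler <- NULL
  if (!is.null(obj$scaler))
    scaler <- lapply(obj$scaler, function(s)
      structure(as.numeric(s), class = "scaling_params"))
  structure(list(weights = w, config = cfg, scaler = scaler,
                 history = obj$history, best_epoch = obj$best_epoch),
            class = "trajectory_net")
}
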