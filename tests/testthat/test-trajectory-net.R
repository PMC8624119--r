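ns <- asNamespace("stridenet")

lstm_cell_params <- function(n_in, h) 4 * h * (n_in + h) + 4 * h

test_that("the model builds with the documented architecture", {
  m <- build_model(net_config(units_layer1 = 8, seed = 1))
  expect_equal(n_parameters(m),
               2 * lstm_cell_params(6, 8) + 2 * lstm_cell_params(8, 6))
  m2 <- build_model(net_config(units_layer1 = 16, seed = 1))
  expect_gt(n_parameters(m2), 2 * n_parameters(m))
  X <- array(0, c(6, 3, 256))
  Y <- ns$cpp_bilstm_forward(m$weights, X)
  expect_equal(dim(Y), c(6L, 3L, 256L))
  expect_true(all(is.finite(Y)))
  expect_error(net_config(dropout_rate = 1.2))
})

test_that("the sequence loss is the elementwise mean of squared errors", {
  y <- matrix(rnorm(12), 2); expect_equal(mse_loss(y, y), 0)
  expect_equal(mse_loss(c(1, 2), c(1, 0)), 2)
  set.seed(14)
  a <- array(rnorm(6 * 2 * 5), c(6, 2, 5))
  b <- array(rnorm(6 * 2 * 5), c(6, 2, 5))
  brute <- sum((a - b)^2) / length(a)
  expect_equal(mse_loss(a, b), brute, tolerance = 1e-12)
  expect_error(mse_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "mismatch")
})

test_that("backpropagation matches finite differences", {
  set.seed(15)
  m <- build_model(net_config(units_layer1 = 4, dropout_rate = 0, seed = 7),
                   n_in = 2, n_out = 3)
  X <- array(rnorm(2 * 2 * 6), c(2, 2, 6))
  Y <- array(rnorm(3 * 2 * 6), c(3, 2, 6))
  out <- ns$cpp_bilstm_loss_grad(m$weights, X, Y, 0, 1)
  eps <- 1e-6
  for (cell in c("l1f", "l1b", "l2f", "l2b")) for (p in c("W", "U", "b")) {
    g <- out$grad[[cell]][[p]]
    for (i in sample(length(g), min(6, length(g)))) {
      wp <- m$weights; wp[[cell]][[p]][i] <- wp[[cell]][[p]][i] + eps
      wm <- m$weights; wm[[cell]][[p]][i] <- wm[[cell]][[p]][i] - eps
      fd <- (ns$cpp_bilstm_loss_grad(wp, X, Y, 0, 1)$loss -
             ns$cpp_bilstm_loss_grad(wm, X, Y, 0, 1)$loss) / (2 * eps)
      expect_lt(abs(g[i] - fd), 1e-7)
    }
  }
})

test_that("training overfits a tiny stride set and honours early stopping", {
  set.seed(16)
  tr <- simulate_trial(sim_config(n_strides = 10, seed = 21))
  segs <- trial_segments(tr, "A")
  b <- prepare_batches(segs, fractions = c(train = 1), k_augment = 0)
  cfg <- net_config(units_layer1 = 32, dropout_rate = 0, batch_size = 10,
                    max_epochs = 220, patience = 220, seed = 3)
  m <- train_model(build_model(cfg), b$train, b$train, scaler = b$scaler)
  expect_lt(min(m$history$train_mse), 1e-3)
  expect_lte(nrow(m$history), cfg$max_epochs)
  # selected checkpoint is never worse than the final epoch
  expect_lte(m$best_val_loss, m$history$val_mse[nrow(m$history)])
  # patience contract: a zero learning rate cannot improve the validation
  # loss, so training stops right after the patience window
  m0 <- build_model(net_config(units_layer1 = 8, seed = 3))
  X <- ns$windows_to_cube(b$train$imu)
  Y <- ns$windows_to_cube(b$train$target)
  fit0 <- ns$cpp_bilstm_train(m0$weights, X, Y, X, Y, 0, 10L, 50L, 3L, 0,
                              1L, FALSE)
  expect_length(fit0$train_loss, 1L + 3L)
})

test_that("prediction strips padding, rescales, and is deterministic", {
  set.seed(17)
  tr <- simulate_trial(sim_config(n_strides = 6, seed = 22))
  segs <- trial_segments(tr, "A")
  b <- prepare_batches(segs, fractions = c(train = 1), k_augment = 0)
  m <- build_model(net_config(units_layer1 = 8, seed = 5))
  m$scaler <- b$scaler
  pred <- predict_trajectories(m, segs)
  expect_length(pred, length(segs))
  for (i in seq_along(pred))
    expect_equal(nrow(pred[[i]]$heel), segs[[i]]$valid_length)
  pred2 <- predict_trajectories(m, segs)
  expect_identical(pred, pred2)
  m$scaler <- NULL
  expect_error(predict_trajectories(m, segs), "scal")
})

test_that("trajectory metrics follow their definitions", {
  ref <- list(list(heel = matrix(0, 10, 3), toe = matrix(0, 10, 3)))
  expect_equal(evaluate_trajectories(ref, ref)$mae, c(0, 0))
  # 3 mm offset on one of three axes
  off <- list(list(heel = cbind(0.003, matrix(0, 10, 2)),
                   toe = matrix(0, 10, 3)))
  ev <- evaluate_trajectories(off, ref)
  expect_equal(ev$mae[1], 1)          # axis-pooled
  expect_equal(ev$euclidean[1], 3)    # sample-pooled distance
  set.seed(18)
  a <- list(list(heel = matrix(rnorm(30), 10), toe = matrix(rnorm(30), 10)))
  b2 <- list(list(heel = matrix(rnorm(30), 10), toe = matrix(rnorm(30), 10)))
  ev <- evaluate_trajectories(a, b2)
  expect_equal(ev$rmse^2, ev$mse, tolerance = 1e-12)
})

test_that("models survive a save/load round trip", {
  set.seed(19)
  m <- build_model(net_config(units_layer1 = 6, seed = 2))
  m$scaler <- list(imu = structure(rep(8, 6), class = "scaling_params"),
                   target = structure(rep(1.5, 6), class = "scaling_params"))
  segs <- list(list(imu_window = matrix(rnorm(256 * 6), 256, 6),
                    valid_length = 100L))
  p1 <- predict_trajectories(m, segs)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  p2 <- predict_trajectories(load_model(path), segs)
  expect_equal(p1, p2, tolerance = 1e-12)
  unlink(path)
})
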