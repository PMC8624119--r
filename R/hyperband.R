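# Hyperband hyperparameter search with successive halving (reduction
# factor eta = 3), scoring each trial by the mean validation loss over
# `n_executions` trainings.

#' Hyperband bracket schedule
#'
#' Bracket and rung sizes for a maximum resource `max_resource` (epochs)
#' and reduction factor `eta`: bracket s (s_max..0) starts
#' ceil((s_max+1)/(s+1) * eta^s) configurations at max_resource/eta^s
#' epochs, keeping the best third at each rung.
#'
#' @param max_resource maximum epochs per configuration.
#' @param eta reduction factor.
#' @return list of brackets, each a data.frame with `n_configs`, `epochs`.
#' @export
hyperband_schedule <- function(max_resource, eta = 3) {
  s_max <- floor(log(max_resource) / log(eta))
  budget <- (s_max + 1) * max_resource
  lapply(s_max:0, function(s) {
    n <- ceiling((budget / max_resource) * eta^s / (s + 1))
    r <- max_resource * eta^(-s)
    data.frame(rung = 0:s,
               n_configs = floor(n * eta^(-(0:s))),
               epochs = pmin(max_resource, floor(r * eta^(0:s))))
  })
}

#' Sample a network configuration from the search space
#'
#' Bounds follow the tuned model's search space: units 32-160, dropout
#' 0-0.30, learning rate 1e-6 to 1e-2 (log-uniform), batch size 100-400.
#'
#' @param space list of ranges (`units`, `dropout`, `learning_rate`,
#'   `batch_size`).
#' @return a [net_config()].
#' @export
sample_net_config <- function(space = list(units = c(32L, 160L),
                                           dropout = c(0, 0.30),
                                           learning_rate = c(1e-6, 1e-2),
                                           batch_size = c(100L, 400L))) {
  net_config(
    units_layer1 = sample(space$units[1]:space$units[2], 1),
    dropout_rate = stats::runif(1, space$dropout[1], space$dropout[2]),
    learning_rate = exp(stats::runif(1, log(space$learning_rate[1]),
                                     log(space$learning_rate[2]))),
    batch_size = sample(space$batch_size[1]:space$batch_size[2], 1),
    seed = sample.int(2^31 - 1, 1))
}

#' Hyperband search over network configurations
#'
#' Runs successive-halving brackets; each trial's score is the mean best
#' validation loss over `n_executions` trainings with different seeds.
#' A desk-scale search is obtained by lowering `max_resource`.
#'
#' @param train,val normalized batches (as in [train_model()]).
#' @param max_resource maximum epochs per configuration.
#' @param eta reduction factor.
#' @param n_executions trainings per trial (scores averaged).
#' @param n_iterations hyperband iterations (full schedule repeats).
#' @param space search space (see [sample_net_config()]).
#' @param configs optional explicit candidate list (overrides sampling).
#' @param verbose print progress.
#' @return list with `best_config`, `best_score`, `history`.
#' @export
tune_hyperparameters <- function(train, val, max_resource = 27L, eta = 3,
                                 n_executions = 3L, n_iterations = 2L,
                                 space = NULL, configs = NULL,
                                 verbose = FALSE) {
  if (!is.null(space) && !length(space)) stop("empty search space")
  if (!is.null(configs) && !length(configs)) stop("empty search space")
  sched <- hyperband_schedule(max_resource, eta)
  history <- list()
  best <- NULL; best_score <- Inf
  score_config <- function(cfg, epochs) {
    losses <- vapply(seq_len(n_executions), function(e) {
      cfg_e <- cfg
      cfg_e$max_epochs <- as.integer(epochs)
      cfg_e$patience <- max(cfg$patience, as.integer(epochs))
      cfg_e$seed <- cfg$seed + e - 1L
      fit <- train_model(build_model(cfg_e), train, val)
      fit$best_val_loss
    }, numeric(1))
    mean(losses)
  }
  for (it in seq_len(n_iterations)) {
    for (br in sched) {
      n0 <- br$n_configs[1]
      cand <- if (!is.null(configs)) {
        configs[rep_len(seq_along(configs), n0)]
      } else {
        lapply(seq_len(n0), function(i)
          if (is.null(space)) sample_net_config() else
            sample_net_config(space))
      }
      for (rung in seq_len(nrow(br))) {
        epochs <- br$epochs[rung]
        keep_n <- br$n_configs[rung]
        cand <- cand[seq_len(min(keep_n, length(cand)))]
        scores <- vapply(cand, score_config, numeric(1), epochs = epochs)
        history[[length(history) + 1L]] <- data.frame(
          iteration = it, epochs = epochs,
          units = vapply(cand, `[[`, integer(1), "units_layer1"),
          score = scores)
        ord <- order(scores)
        cand <- cand[ord]
        if (scores[ord[1]] < best_score) {
          best_score <- scores[ord[1]]
          best <- cand[[1]]
        }
        if (verbose)
          message(sprintf("iter %d rung %d: best %.5g", it, rung,
                          best_score))
      }
    }
  }
  list(best_config = best, best_score = best_score,
       history = do.call(rbind, history))
}
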