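# Successive-halving hyperparameter search (HyperBand-style): a large pool
# of randomly drawn configurations is trained for a small epoch budget, the
# worst two thirds are dropped, and the survivors continue with a doubled
# budget until a single configuration remains.

#' Default hyperparameter space for the predictor
#'
#' Candidate values for the tunable architecture dimensions: number and size
#' of convolution kernels, GRU width, number and width of dense blocks, and
#' the activation function.
#'
#' @param desk If `TRUE`, return a reduced space suited to desk-scale
#'   experiments (identical structure, fewer candidates).
#' @return Named list of candidate vectors.
#' @export
hyperband_space <- function(desk = FALSE) {
  if (desk) {
    list(conv_filters = c(16L, 32L), conv_kernel = c(3L, 7L),
         gru_dim = c(16L, 32L), n_dense_blocks = c(2L, 3L),
         dense_units = c(16L, 32L), activation = c("relu", "elu"))
  } else {
    list(conv_filters = c(16L, 32L, 64L, 128L),
         conv_kernel = c(3L, 5L, 7L, 9L),
         gru_dim = c(16L, 32L, 64L, 128L),
         n_dense_blocks = c(1L, 2L, 3L, 4L),
         dense_units = c(16L, 32L, 64L, 128L),
         activation = c("relu", "elu", "tanh"))
  }
}

sample_config <- function(space, input_len) {
  pick <- lapply(space, function(v) v[[sample.int(length(v), 1L)]])
  do.call(predictor_config, c(pick, list(input_len = input_len)))
}

#' Successive-halving search over predictor configurations
#'
#' Draws `pool_size` random configurations from `space`, trains every
#' survivor for the current epoch budget (resuming from its weights), ranks
#' by validation MSE, keeps the best `ceiling(n * (1 - drop_ratio))`, and
#' repeats with a doubled budget until one configuration remains.
#'
#' @param space Named list of candidate vectors (see [hyperband_space()]).
#' @param data List with `train` and `val` libraries (data.frames with
#'   `seq`, `mrl`).
#' @param pool_size Number of initial configurations (default 8000; use a
#'   small pool such as 27 for desk-scale runs).
#' @param drop_ratio Fraction dropped per round (default 2/3).
#' @param epoch_schedule Integer vector of per-round epoch budgets; the
#'   default starts at 2 and doubles (2, 4, 8, ...), extended as needed.
#' @param input_len Encoded length for all candidate models.
#' @param seed Integer seed (configuration draws, initialisation, shuffling).
#' @return The winning `predictor_config`; attributes `history` (data.frame
#'   with one row per round: `round`, `n_configs`, `epochs`, `best_val`) and
#'   `model` (the winning trained model).
#' @export
hyperband_search <- function(space, data, pool_size = 8000L,
                             drop_ratio = 2 / 3, epoch_schedule = NULL,
                             input_len = 100L, seed = 1L) {
  if (length(space) == 0L) stop("empty hyperparameter space", call. = FALSE)
  if (pool_size < 1L) stop("`pool_size` must be >= 1", call. = FALSE)
  if (drop_ratio <= 0 || drop_ratio >= 1) {
    stop("`drop_ratio` must lie in (0, 1)", call. = FALSE)
  }
  train <- encode_library(data$train, input_len)
  val <- encode_library(data$val, input_len)
  configs <- with_seed(seed, replicate(pool_size,
                                       sample_config(space, input_len),
                                       simplify = FALSE))
  models <- lapply(seq_along(configs), function(i) {
    build_predictor(configs[[i]], seed = child_seed(seed, i))
  })
  alive <- seq_len(pool_size)
  budget_for <- function(r) {
    if (!is.null(epoch_schedule) && r <= length(epoch_schedule)) {
      epoch_schedule[r]
    } else {
      base <- if (is.null(epoch_schedule)) 2L
              else epoch_schedule[length(epoch_schedule)]
      extra <- if (is.null(epoch_schedule)) r - 1L
               else r - length(epoch_schedule)
      as.integer(base * 2^max(0L, extra))
    }
  }
  history <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    budget <- budget_for(round)
    val_losses <- rep(NA_real_, length(alive))
    for (j in seq_along(alive)) {
      i <- alive[j]
      models[[i]] <- train_predictor(models[[i]], train, val,
                                     sched = train_schedule(),
                                     seed = child_seed(seed, 1000L + i),
                                     epochs = budget)
      val_losses[j] <- predictor_loss(models[[i]]$params,
                                      models[[i]]$cfg, val$x, val$y)
    }
    history[[round]] <- data.frame(round = round,
                                   n_configs = length(alive),
                                   epochs = budget,
                                   best_val = min(val_losses))
    if (length(alive) == 1L) break
    # round before ceiling so 9 * (1 - 2/3) keeps 3, not 4, despite
    # floating-point representation of the drop ratio
    n_keep <- ceiling(round(length(alive) * (1 - drop_ratio), 9L))
    alive <- alive[order(val_losses)][seq_len(n_keep)]
  }
  winner <- alive[1L]
  structure(configs[[winner]],
            history = do.call(rbind, history),
            model = models[[winner]])
}
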