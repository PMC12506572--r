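# Discriminative model: residual 1-D convolutions -> GRU -> residual dense
# blocks -> linear MRL output, trained with mean squared error under a
# reduce-on-plateau learning-rate schedule with early stopping.

#' Predictor architecture configuration
#'
#' The architecture is three residual-connected convolutional blocks, one GRU
#' layer whose number of units equals the length of the convolutional feature
#' sequence, and three residual-connected fully connected blocks feeding a
#' single linear output. Convolutions preserve sequence length; residual
#' skips are identity where widths match and learned 1x1 / linear projections
#' where they differ.
#'
#' @param n_conv_blocks Number of residual conv blocks (default 3).
#' @param conv_filters Filters per conv layer (default 32).
#' @param conv_kernel Convolution kernel width (default 7).
#' @param gru_dim GRU hidden width (default 32).
#' @param n_dense_blocks Number of residual dense blocks (default 3).
#' @param dense_units Units per dense block (default 32).
#' @param activation One of `"relu"`, `"elu"`, `"tanh"`.
#' @param input_len Encoded input length, 50 or 100 (default 100).
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(n_conv_blocks = 3L, conv_filters = 32L,
                             conv_kernel = 7L, gru_dim = 32L,
                             n_dense_blocks = 3L, dense_units = 32L,
                             activation = "elu", input_len = 100L) {
  cfg <- list(n_conv_blocks = as.integer(n_conv_blocks),
              conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(conv_kernel),
              gru_dim = as.integer(gru_dim),
              n_dense_blocks = as.integer(n_dense_blocks),
              dense_units = as.integer(dense_units),
              activation = match.arg(activation, ACTIVATIONS),
              input_len = as.integer(input_len))
  counts <- cfg[c("n_conv_blocks", "conv_filters", "conv_kernel", "gru_dim",
                  "n_dense_blocks", "dense_units")]
  if (any(unlist(counts) <= 0L)) {
    stop("all architecture sizes must be positive", call. = FALSE)
  }
  if (!cfg$input_len %in% c(50L, 100L)) {
    stop("`input_len` must be 50 or 100", call. = FALSE)
  }
  structure(cfg, class = "predictor_config")
}

#' Training schedule for the predictor
#'
#' Mean-squared-error loss; the learning rate starts at `initial_lr` and is
#' multiplied by `lr_factor` whenever the validation loss fails to improve
#' for `plateau_patience` consecutive epochs; training stops after
#' `stop_patience` epochs without improvement (the best-validation weights
#' are restored).
#'
#' @param initial_lr Initial learning rate (default 0.001).
#' @param lr_factor Multiplicative decay on plateau (default 0.1).
#' @param plateau_patience Epochs without improvement before decay
#'   (default 5).
#' @param stop_patience Epochs without improvement before stopping
#'   (default 12).
#' @param batch_size Minibatch size (default 128).
#' @param max_epochs Hard cap on epochs (default 100).
#' @return A `train_schedule` list.
#' @export
train_schedule <- function(initial_lr = 0.001, lr_factor = 0.1,
                           plateau_patience = 5L, stop_patience = 12L,
                           batch_size = 128L, max_epochs = 100L) {
  if (lr_factor <= 0 || lr_factor >= 1) {
    stop("`lr_factor` must lie in (0, 1)", call. = FALSE)
  }
  if (stop_patience <= plateau_patience) {
    stop("`stop_patience` must exceed `plateau_patience`", call. = FALSE)
  }
  structure(list(initial_lr = initial_lr, lr_factor = lr_factor,
                 plateau_patience = as.integer(plateau_patience),
                 stop_patience = as.integer(stop_patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs)),
            class = "train_schedule")
}

predictor_init_params <- function(cfg) {
  F <- cfg$conv_filters; k <- cfg$conv_kernel
  G <- cfg$gru_dim; D <- cfg$dense_units
  p <- list()
  c_in <- 5L
  for (i in seq_len(cfg$n_conv_blocks)) {
    p[[sprintf("conv%d.W", i)]] <- glorot(k * c_in, F, c(k * c_in, F))
    p[[sprintf("conv%d.b", i)]] <- numeric(F)
    if (c_in != F) {
      p[[sprintf("conv%d.pW", i)]] <- glorot(c_in, F)
      p[[sprintf("conv%d.pb", i)]] <- numeric(F)
    }
    c_in <- F
  }
  for (nm in names(g <- gru_init(F, G))) p[[paste0("gru.", nm)]] <- g[[nm]]
  d_in <- G
  for (j in seq_len(cfg$n_dense_blocks)) {
    p[[sprintf("dense%d.W", j)]] <- glorot(d_in, D)
    p[[sprintf("dense%d.b", j)]] <- numeric(D)
    if (d_in != D) {
      p[[sprintf("dense%d.pW", j)]] <- glorot(d_in, D)
      p[[sprintf("dense%d.pb", j)]] <- numeric(D)
    }
    d_in <- D
  }
  p[["out.W"]] <- glorot(D, 1L)
  p[["out.b"]] <- 0
  p
}

#' Build an untrained MRL predictor
#'
#' @param cfg A [predictor_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `mrl_predictor`.
#' @export
build_predictor <- function(cfg = predictor_config(), seed = 1L) {
  stopifnot(inherits(cfg, "predictor_config"))
  params <- with_seed(seed, predictor_init_params(cfg))
  structure(list(cfg = cfg, params = params, trained = FALSE,
                 opt_state = NULL, history = NULL),
            class = "mrl_predictor")
}

#' @export
print.mrl_predictor <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("<mrl_predictor> input %d nt | %d conv blocks ",
                     "(%d filters, kernel %d) | GRU %d | %d dense blocks ",
                     "(%d units, %s) | %s\n"),
              cfg$input_len, cfg$n_conv_blocks, cfg$conv_filters,
              cfg$conv_kernel, cfg$gru_dim, cfg$n_dense_blocks,
              cfg$dense_units, cfg$activation,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

gru_param_list <- function(params) {
  nm <- c("Wz", "Wr", "Wh", "Uz", "Ur", "Uh", "bz", "br", "bh")
  stats::setNames(lapply(paste0("gru.", nm), function(k) params[[k]]), nm)
}

predictor_forward <- function(params, cfg, x, keep_cache = FALSE) {
  act <- cfg$activation
  cache <- if (keep_cache) list(conv = vector("list", cfg$n_conv_blocks),
                                dense = vector("list", cfg$n_dense_blocks))
  h <- x
  for (i in seq_len(cfg$n_conv_blocks)) {
    W <- params[[sprintf("conv%d.W", i)]]
    b <- params[[sprintf("conv%d.b", i)]]
    pre <- conv_forward(h, W, b)
    a <- act_forward(pre, act)
    pW <- params[[sprintf("conv%d.pW", i)]]
    skip <- if (is.null(pW)) h
            else conv_forward(h, pW, params[[sprintf("conv%d.pb", i)]])
    out <- a + skip
    if (keep_cache) cache$conv[[i]] <- list(x = h, pre = pre, a = a)
    h <- out
  }
  gfwd <- gru_forward(h, gru_param_list(params), keep_cache = keep_cache)
  if (keep_cache) cache$gru <- gfwd
  v <- gfwd$h
  for (j in seq_len(cfg$n_dense_blocks)) {
    W <- params[[sprintf("dense%d.W", j)]]
    b <- params[[sprintf("dense%d.b", j)]]
    pre <- dense_forward(v, W, b)
    a <- act_forward(pre, act)
    pW <- params[[sprintf("dense%d.pW", j)]]
    skip <- if (is.null(pW)) v
            else dense_forward(v, pW, params[[sprintf("dense%d.pb", j)]])
    out <- a + skip
    if (keep_cache) cache$dense[[j]] <- list(x = v, pre = pre, a = a)
    v <- out
  }
  if (keep_cache) cache$head_in <- v
  pred <- drop(dense_forward(v, params[["out.W"]], params[["out.b"]]))
  list(pred = pred, cache = cache)
}

predictor_backward <- function(params, cfg, cache, dpred,
                               need_dx = FALSE) {
  act <- cfg$activation
  grads <- list()
  dpred <- matrix(dpred, ncol = 1L)
  bw <- dense_backward(dpred, cache$head_in, params[["out.W"]])
  grads[["out.W"]] <- bw$dW; grads[["out.b"]] <- bw$db
  dv <- bw$dx
  for (j in rev(seq_len(cfg$n_dense_blocks))) {
    cc <- cache$dense[[j]]
    W <- params[[sprintf("dense%d.W", j)]]
    da <- act_backward(dv, cc$pre, cc$a, act)
    bw <- dense_backward(da, cc$x, W)
    grads[[sprintf("dense%d.W", j)]] <- bw$dW
    grads[[sprintf("dense%d.b", j)]] <- bw$db
    pW <- params[[sprintf("dense%d.pW", j)]]
    if (is.null(pW)) {
      dv <- bw$dx + dv
    } else {
      bs <- dense_backward(dv, cc$x, pW)
      grads[[sprintf("dense%d.pW", j)]] <- bs$dW
      grads[[sprintf("dense%d.pb", j)]] <- bs$db
      dv <- bw$dx + bs$dx
    }
  }
  gbw <- gru_backward(dv, cache$gru, gru_param_list(params))
  for (nm in names(gbw$grads)) grads[[paste0("gru.", nm)]] <- gbw$grads[[nm]]
  dh <- gbw$dx
  for (i in rev(seq_len(cfg$n_conv_blocks))) {
    cc <- cache$conv[[i]]
    W <- params[[sprintf("conv%d.W", i)]]
    b <- params[[sprintf("conv%d.b", i)]]
    da <- act_backward(dh, cc$pre, cc$a, act)
    bw <- conv_backward(da, cc$x, W, b)
    grads[[sprintf("conv%d.W", i)]] <- bw$dW
    grads[[sprintf("conv%d.b", i)]] <- bw$db
    pW <- params[[sprintf("conv%d.pW", i)]]
    if (is.null(pW)) {
      dh <- bw$dx + dh
    } else {
      bs <- conv_backward(dh, cc$x, pW, params[[sprintf("conv%d.pb", i)]])
      grads[[sprintf("conv%d.pW", i)]] <- bs$dW
      grads[[sprintf("conv%d.pb", i)]] <- bs$db
      dh <- bw$dx + bs$dx
    }
  }
  list(grads = grads, dx = if (need_dx) dh)
}

#' Predict MRL scores for a batch of encoded sequences
#'
#' @param model An `mrl_predictor`.
#' @param x Either a 3-D array of dim (N, input_len, 5), a single
#'   input_len x 5 matrix, or a character vector of sequences (encoded
#'   internally).
#' @param batch_size Internal forward batch size.
#' @return Numeric vector of predicted MRL scores, one per input, in input
#'   order.
#' @export
predict_mrl <- function(model, x, batch_size = 512L) {
  stopifnot(inherits(model, "mrl_predictor"))
  if (is.character(x) || is.list(x)) {
    x <- encode_batch(x, model$cfg$input_len)
  }
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  if (length(dim(x)) != 3L || dim(x)[2L] != model$cfg$input_len ||
      dim(x)[3L] != 5L) {
    stop(sprintf("input must be (N, %d, 5); got (%s)", model$cfg$input_len,
                 paste(dim(x), collapse = ", ")), call. = FALSE)
  }
  n <- dim(x)[1L]
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    out[s:e] <- predictor_forward(model$params, model$cfg,
                                  x[s:e, , , drop = FALSE])$pred
  }
  out
}

predictor_loss <- function(params, cfg, x, y, batch_size = 512L) {
  n <- dim(x)[1L]
  sse <- 0
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    pred <- predictor_forward(params, cfg, x[s:e, , , drop = FALSE])$pred
    sse <- sse + sum((pred - y[s:e])^2)
  }
  sse / n
}

encode_library <- function(lib, input_len) {
  list(x = encode_batch(lib$seq, input_len), y = lib$mrl)
}

#' Train an MRL predictor
#'
#' Minimises mean squared error with Adam. The learning rate is cut by
#' `sched$lr_factor` after `plateau_patience` epochs without validation-loss
#' improvement, and training stops after `stop_patience` such epochs; the
#' weights with the best validation loss are kept.
#'
#' @param model An `mrl_predictor` (fresh or partially trained; the optimiser
#'   state is carried within the model, so repeated calls resume training).
#' @param train,val Libraries: data.frames with columns `seq`, `mrl`, or
#'   pre-encoded lists `list(x = array, y = numeric)`.
#' @param sched A [train_schedule()].
#' @param seed Integer seed controlling shuffling.
#' @param epochs Optional fixed number of epochs; when given, the plateau /
#'   early-stop logic is disabled and exactly `epochs` epochs are run (used
#'   for successive-halving budgets).
#' @param verbose Print per-epoch losses.
#' @return The trained model; `$history` holds a per-epoch data.frame with
#'   `epoch`, `train_loss`, `val_loss`, `lr`.
#' @export
train_predictor <- function(model, train, val, sched = train_schedule(),
                            seed = 1L, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "mrl_predictor"), inherits(sched,
                                                       "train_schedule"))
  if (is.data.frame(train)) {
    if (nrow(train) == 0L) stop("empty training library", call. = FALSE)
    train <- encode_library(train, model$cfg$input_len)
  }
  if (is.data.frame(val)) {
    if (nrow(val) == 0L) stop("empty validation library", call. = FALSE)
    val <- encode_library(val, model$cfg$input_len)
  }
  if (length(train$y) == 0L || length(val$y) == 0L) {
    stop("training and validation libraries must be non-empty",
         call. = FALSE)
  }
  params <- model$params
  opt <- model$opt_state %||% adam_init(params)
  lr <- model$lr %||% sched$initial_lr
  n <- dim(train$x)[1L]
  fixed_epochs <- !is.null(epochs)
  n_epochs <- if (fixed_epochs) epochs else sched$max_epochs
  best_val <- Inf
  best_params <- params
  since_improve <- 0L
  since_decay <- 0L
  hist <- list()
  with_seed(seed, {
    for (ep in seq_len(n_epochs)) {
      idx <- sample.int(n)
      tl <- 0
      for (s in seq(1L, n, by = sched$batch_size)) {
        e <- min(n, s + sched$batch_size - 1L)
        b <- idx[s:e]
        xb <- train$x[b, , , drop = FALSE]
        yb <- train$y[b]
        fw <- predictor_forward(params, model$cfg, xb, keep_cache = TRUE)
        resid <- fw$pred - yb
        tl <- tl + sum(resid^2)
        dpred <- 2 * resid / length(b)
        bw <- predictor_backward(params, model$cfg, fw$cache, dpred)
        st <- adam_step(params, bw$grads, opt, lr)
        params <- st$params; opt <- st$state
      }
      vl <- predictor_loss(params, model$cfg, val$x, val$y)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = tl / n,
                               val_loss = vl, lr = lr)
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f  lr %g",
                        ep, tl / n, vl, lr))
      }
      if (vl < best_val - 1e-12) {
        best_val <- vl
        best_params <- params
        since_improve <- 0L
        since_decay <- 0L
      } else {
        since_improve <- since_improve + 1L
        since_decay <- since_decay + 1L
      }
      if (!fixed_epochs) {
        if (since_improve >= sched$stop_patience) break
        if (since_decay >= sched$plateau_patience) {
          lr <- lr * sched$lr_factor
          since_decay <- 0L
        }
      }
    }
  })
  model$params <- if (fixed_epochs) params else best_params
  model$opt_state <- opt
  model$lr <- lr
  model$trained <- TRUE
  model$history <- rbind(model$history, do.call(rbind, hist))
  model
}

#' Split a library into train / validation / test sets
#'
#' `test_frac` of the records (default 10%) are held out as the test set;
#' the remainder is split `1 - val_frac` : `val_frac` (default 80:20) into
#' training and validation sets. The three parts are disjoint and exhaustive
#' and fully determined by `seed`.
#'
#' @param lib Library data.frame.
#' @param test_frac Fraction reserved for the test set (default 0.10).
#' @param val_frac Fraction of the remainder used for validation
#'   (default 0.20).
#' @param seed Integer seed.
#' @return List with elements `train`, `val`, `test`.
#' @export
split_library <- function(lib, test_frac = 0.10, val_frac = 0.20,
                          seed = 1L) {
  n <- nrow(lib)
  n_test <- round(n * test_frac)
  n_val <- round((n - n_test) * val_frac)
  if (n_test < 1L || n_val < 1L || n - n_test - n_val < 1L) {
    stop("library too small for a three-way split", call. = FALSE)
  }
  with_seed(seed, {
    test_idx <- sample.int(n, n_test)
    rest <- setdiff(seq_len(n), test_idx)
    val_idx <- sample(rest, n_val)
    train_idx <- setdiff(rest, val_idx)
    list(train = lib[train_idx, , drop = FALSE],
         val = lib[val_idx, , drop = FALSE],
         test = lib[test_idx, , drop = FALSE])
  })
}

#' Spearman correlation between predictions and labels
#'
#' Rank correlation with average-rank tie handling.
#'
#' @param model An `mrl_predictor`.
#' @param test Library data.frame with `seq` and `mrl`.
#' @return Spearman's rho in [-1, 1].
#' @export
evaluate_spearman <- function(model, test) {
  if (nrow(test) == 0L) stop("empty test library", call. = FALSE)
  pred <- predict_mrl(model, test$seq)
  if (stats::sd(pred) == 0 || stats::sd(test$mrl) == 0) {
    stop("correlation undefined: constant predictions or labels",
         call. = FALSE)
  }
  stats::cor(pred, test$mrl, method = "spearman")
}
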