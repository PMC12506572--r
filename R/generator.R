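# Generative autoencoder: strided convolutional encoder -> dense latent
# (length 128) -> dense + transposed-convolution decoder ending in row-wise
# softmax probabilities over the five channels. Trained with a composite
# loss: masked categorical cross-entropy reconstruction + binary
# cross-entropy on the pad channel + lambda * exp(MRL(input) - MRL(output)),
# where MRL() is a frozen, previously trained predictor. The ribosome-loading
# term's gradient flows through the predictor into the decoder's continuous
# softmax output; discrete decoding happens only at inference.

#' Generator architecture configuration
#'
#' @param latent_dim Length of the latent vector (default 128).
#' @param n_conv Encoder convolutional layers (default 3), each stride 2.
#' @param n_deconv Decoder transposed-convolution layers (default 3); must
#'   equal `n_conv` so the decoder mirrors the encoder's lengths exactly.
#' @param conv_filters Channels per hidden conv layer (default 32).
#' @param conv_kernel Kernel width (default 7).
#' @param lambda_rl Weight of the ribosome-loading loss term (default 100).
#' @param input_len Encoded sequence length, 50 or 100 (default 100).
#' @param activation Hidden activation (default `"relu"`).
#' @return A `generator_config` list.
#' @export
generator_config <- function(latent_dim = 128L, n_conv = 3L, n_deconv = 3L,
                             conv_filters = 32L, conv_kernel = 7L,
                             lambda_rl = 100, input_len = 100L,
                             activation = "elu") {
  if (latent_dim < 1L) stop("`latent_dim` must be >= 1", call. = FALSE)
  if (lambda_rl < 0) stop("`lambda_rl` must be nonnegative", call. = FALSE)
  if (n_deconv != n_conv) {
    stop("`n_deconv` must equal `n_conv` (mirrored architecture)",
         call. = FALSE)
  }
  if (!input_len %in% c(50L, 100L)) {
    stop("`input_len` must be 50 or 100", call. = FALSE)
  }
  structure(list(latent_dim = as.integer(latent_dim),
                 n_conv = as.integer(n_conv),
                 n_deconv = as.integer(n_deconv),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 lambda_rl = lambda_rl, input_len = as.integer(input_len),
                 activation = match.arg(activation, ACTIVATIONS)),
            class = "generator_config")
}

generator_lengths <- function(cfg) {
  lens <- integer(cfg$n_conv + 1L)
  lens[1L] <- cfg$input_len
  for (i in seq_len(cfg$n_conv)) lens[i + 1L] <- conv_out_len(lens[i], 2L)
  lens
}

generator_init_params <- function(cfg) {
  F <- cfg$conv_filters; k <- cfg$conv_kernel
  lens <- generator_lengths(cfg)
  inner <- lens[length(lens)]
  p <- list()
  c_in <- 5L
  for (i in seq_len(cfg$n_conv)) {
    p[[sprintf("enc%d.W", i)]] <- glorot(k * c_in, F, c(k * c_in, F))
    p[[sprintf("enc%d.b", i)]] <- numeric(F)
    c_in <- F
  }
  p[["encd.W"]] <- glorot(inner * F, cfg$latent_dim)
  p[["encd.b"]] <- numeric(cfg$latent_dim)
  p[["decd.W"]] <- glorot(cfg$latent_dim, inner * F)
  p[["decd.b"]] <- numeric(inner * F)
  for (i in seq_len(cfg$n_deconv)) {
    c_out <- if (i == cfg$n_deconv) 5L else F
    p[[sprintf("dec%d.W", i)]] <- glorot(k * F, c_out, c(k * F, c_out))
    p[[sprintf("dec%d.b", i)]] <- numeric(c_out)
  }
  p
}

#' Build a generative autoencoder
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed for weight initialisation.
#' @param identity If `TRUE`, build a pass-through "null" generator whose
#'   output equals its input (useful as a baseline and for plumbing tests).
#' @return An object of class `utr_generator`.
#' @export
build_generator <- function(cfg = generator_config(), seed = 1L,
                            identity = FALSE) {
  stopifnot(inherits(cfg, "generator_config"))
  params <- if (identity) list()
            else with_seed(seed, generator_init_params(cfg))
  structure(list(cfg = cfg, params = params, trained = identity,
                 identity = identity, opt_state = NULL, history = NULL),
            class = "utr_generator")
}

#' @export
print.utr_generator <- function(x, ...) {
  cat(sprintf(paste0("<utr_generator> input %d nt | latent %d | %d conv / ",
                     "%d deconv (%d filters, kernel %d) | lambda = %g%s\n"),
              x$cfg$input_len, x$cfg$latent_dim, x$cfg$n_conv,
              x$cfg$n_deconv, x$cfg$conv_filters, x$cfg$conv_kernel,
              x$cfg$lambda_rl,
              if (x$identity) " | identity pass-through" else ""))
  invisible(x)
}

generator_forward <- function(params, cfg, x, keep_cache = FALSE) {
  if (length(params) == 0L) {  # identity generator
    return(list(p = x, cache = NULL))
  }
  act <- cfg$activation
  lens <- generator_lengths(cfg)
  F <- cfg$conv_filters
  N <- dim(x)[1L]
  cache <- if (keep_cache) list(enc = vector("list", cfg$n_conv),
                                dec = vector("list", cfg$n_deconv))
  h <- x
  for (i in seq_len(cfg$n_conv)) {
    pre <- conv_forward(h, params[[sprintf("enc%d.W", i)]],
                        params[[sprintf("enc%d.b", i)]], stride = 2L)
    a <- act_forward(pre, act)
    if (keep_cache) cache$enc[[i]] <- list(x = h, pre = pre, a = a)
    h <- a
  }
  inner <- lens[length(lens)]
  flat <- matrix(h, N, inner * F)
  latent <- dense_forward(flat, params[["encd.W"]], params[["encd.b"]])
  dpre <- dense_forward(latent, params[["decd.W"]], params[["decd.b"]])
  dact <- act_forward(dpre, act)
  g <- array(dact, dim = c(N, inner, F))
  if (keep_cache) {
    cache$flat <- flat; cache$latent <- latent
    cache$dpre <- dpre; cache$dact <- dact
  }
  for (i in seq_len(cfg$n_deconv)) {
    L_out <- lens[cfg$n_conv + 1L - i]
    pre <- tconv_forward(g, params[[sprintf("dec%d.W", i)]],
                         params[[sprintf("dec%d.b", i)]], stride = 2L,
                         L_out = L_out)
    a <- if (i == cfg$n_deconv) pre else act_forward(pre, act)
    if (keep_cache) cache$dec[[i]] <- list(x = g, pre = pre, a = a,
                                           L_out = L_out)
    g <- a
  }
  p <- softmax_rows(g)
  if (keep_cache) cache$logits <- g
  list(p = p, latent = latent, cache = cache)
}

generator_backward <- function(params, cfg, cache, dp, p) {
  act <- cfg$activation
  lens <- generator_lengths(cfg)
  F <- cfg$conv_filters
  inner <- lens[length(lens)]
  grads <- list()
  dg <- softmax_rows_backward(dp, p)
  for (i in rev(seq_len(cfg$n_deconv))) {
    cc <- cache$dec[[i]]
    if (i != cfg$n_deconv) dg <- act_backward(dg, cc$pre, cc$a, act)
    bw <- tconv_backward(dg, cc$x, params[[sprintf("dec%d.W", i)]],
                         params[[sprintf("dec%d.b", i)]], stride = 2L,
                         L_out = cc$L_out)
    grads[[sprintf("dec%d.W", i)]] <- bw$dW
    grads[[sprintf("dec%d.b", i)]] <- bw$db
    dg <- bw$dx
  }
  N <- dim(dg)[1L]
  ddact <- matrix(dg, N, inner * F)
  ddpre <- act_backward(ddact, cache$dpre, cache$dact, act)
  bw <- dense_backward(ddpre, cache$latent, params[["decd.W"]])
  grads[["decd.W"]] <- bw$dW; grads[["decd.b"]] <- bw$db
  bw <- dense_backward(bw$dx, cache$flat, params[["encd.W"]])
  grads[["encd.W"]] <- bw$dW; grads[["encd.b"]] <- bw$db
  dh <- array(bw$dx, dim = c(N, inner, F))
  for (i in rev(seq_len(cfg$n_conv))) {
    cc <- cache$enc[[i]]
    da <- act_backward(dh, cc$pre, cc$a, act)
    bw <- conv_backward(da, cc$x, params[[sprintf("enc%d.W", i)]],
                        params[[sprintf("enc%d.b", i)]], stride = 2L)
    grads[[sprintf("enc%d.W", i)]] <- bw$dW
    grads[[sprintf("enc%d.b", i)]] <- bw$db
    dh <- bw$dx
  }
  grads
}

## ---- losses ------------------------------------------------------------

CLIP_EPS <- 1e-12

#' Reconstruction loss (masked CCE + pad-channel BCE)
#'
#' Categorical cross-entropy between the true one-hot encoding and the
#' reconstructed row probabilities, averaged over non-pad positions, plus
#' binary cross-entropy on the pad channel averaged over all positions.
#'
#' @param y_true One-hot encoding: L x 5 matrix or (N, L, 5) array.
#' @param y_pred Reconstruction with valid probability rows, same shape.
#' @param mask_pad Exclude pad positions from the CCE average
#'   (default `TRUE`).
#' @return Nonnegative scalar loss.
#' @export
reconstruction_loss <- function(y_true, y_pred, mask_pad = TRUE) {
  if (is.matrix(y_true)) y_true <- array(y_true, dim = c(1L, dim(y_true)))
  if (is.matrix(y_pred)) y_pred <- array(y_pred, dim = c(1L, dim(y_pred)))
  if (!identical(dim(y_true), dim(y_pred))) {
    stop("`y_true` and `y_pred` must have identical shapes", call. = FALSE)
  }
  pm <- matrix(y_pred, ncol = dim(y_pred)[3L])
  if (any(pm < -1e-9) || any(abs(rowSums(pm) - 1) > 1e-6)) {
    stop("`y_pred` rows must be probability vectors", call. = FALSE)
  }
  comp <- recon_loss_components(y_true, y_pred, mask_pad = mask_pad)
  comp$cce + comp$bce
}

recon_loss_components <- function(y_true, y_pred, mask_pad = TRUE) {
  p <- pmin(pmax(y_pred, CLIP_EPS), 1 - CLIP_EPS)
  d <- dim(y_true)
  mask <- if (mask_pad) 1 - y_true[, , 5L] else array(1, dim = d[1:2])
  npos <- sum(mask)
  p_true <- rowSums(matrix(y_true * log(p), d[1L] * d[2L], d[3L]))
  cce <- if (npos > 0) -sum(mask * p_true) / npos else 0
  q <- p[, , 5L]
  t <- y_true[, , 5L]
  bce <- -mean(t * log(q) + (1 - t) * log(1 - q))
  list(cce = cce, bce = bce, npos = npos)
}

# Gradient of the reconstruction loss wrt the probability output.
recon_loss_grad <- function(y_true, p, mask_pad = TRUE) {
  pc <- pmin(pmax(p, CLIP_EPS), 1 - CLIP_EPS)
  d <- dim(p)
  mask <- if (mask_pad) 1 - y_true[, , 5L] else array(1, dim = d[1:2])
  npos <- sum(mask)
  dp <- array(0, dim = d)
  if (npos > 0) {
    dp <- -(y_true / pc) * array(rep(mask, d[3L]), dim = d) / npos
  }
  nall <- d[1L] * d[2L]
  q <- pc[, , 5L]; t <- y_true[, , 5L]
  dp[, , 5L] <- dp[, , 5L] + (-t / q + (1 - t) / (1 - q)) / nall
  dp
}

#' Ribosome-loading loss
#'
#' `exp(mrl_true - mrl_pred)`: strictly decreasing in the predicted MRL of
#' the reconstructed sequence, so minimising it pushes the generator toward
#' outputs that the predictor scores higher than the input.
#'
#' @param mrl_true Predicted MRL of the input sequence.
#' @param mrl_pred Predicted MRL of the reconstructed sequence.
#' @return Positive value(s), elementwise over vectors.
#' @export
rl_loss <- function(mrl_true, mrl_pred) exp(mrl_true - mrl_pred)

#' Composite generator loss
#'
#' @param re Reconstruction loss value.
#' @param rl Ribosome-loading loss value.
#' @param lambda_rl Weight of the RL term (default 100).
#' @return `re + lambda_rl * rl`.
#' @export
total_loss <- function(re, rl, lambda_rl = 100) re + lambda_rl * rl

## ---- training ----------------------------------------------------------

#' Train the generative autoencoder against a frozen predictor
#'
#' Minimises the batch mean of `reconstruction + lambda_rl * rl_loss`.
#' Only generator weights are updated; the predictor is used for scoring and
#' for routing the RL-loss gradient into the decoder's softmax output, and
#' its weights are left untouched.
#'
#' @param generator A `utr_generator`.
#' @param predictor A trained `mrl_predictor` with matching `input_len`.
#' @param train_seqs Character vector of training sequences (or a library
#'   data.frame with a `seq` column).
#' @param epochs Training epochs (default 40).
#' @param batch_size Minibatch size (default 128).
#' @param lr Adam learning rate (default 0.005); cut to one fifth for the
#'   final 30\% of epochs to stabilise late training.
#' @param seed Integer seed (shuffling).
#' @param verbose Print per-epoch loss components.
#' @return The trained generator; `$history` holds per-epoch mean
#'   reconstruction and RL loss components.
#' @export
train_generator <- function(generator, predictor, train_seqs, epochs = 40L,
                            batch_size = 128L, lr = 0.005, seed = 1L,
                            verbose = FALSE) {
  stopifnot(inherits(generator, "utr_generator"),
            inherits(predictor, "mrl_predictor"))
  if (generator$identity) {
    stop("identity generators are fixed pass-throughs and cannot be trained",
         call. = FALSE)
  }
  if (!isTRUE(predictor$trained)) {
    stop("the predictor must be trained before it can guide the generator",
         call. = FALSE)
  }
  if (predictor$cfg$input_len != generator$cfg$input_len) {
    stop("generator and predictor `input_len` must match", call. = FALSE)
  }
  if (is.data.frame(train_seqs)) train_seqs <- train_seqs$seq
  if (length(train_seqs) == 0L) stop("no training sequences", call. = FALSE)
  cfg <- generator$cfg
  lambda <- cfg$lambda_rl
  x_all <- encode_batch(train_seqs, cfg$input_len)
  n <- dim(x_all)[1L]
  # Input-sequence MRL scores are constants of the run (frozen predictor).
  mrl_in_all <- if (lambda > 0) predict_mrl(predictor, x_all)
  params <- generator$params
  opt <- generator$opt_state %||% adam_init(params)
  hist <- list()
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      lr_ep <- if (ep > 0.7 * epochs) lr / 5 else lr
      idx <- sample.int(n)
      re_sum <- 0; rl_sum <- 0
      for (s in seq(1L, n, by = batch_size)) {
        e <- min(n, s + batch_size - 1L)
        b <- idx[s:e]
        nb <- length(b)
        xb <- x_all[b, , , drop = FALSE]
        gf <- generator_forward(params, cfg, xb, keep_cache = TRUE)
        p <- gf$p
        comp <- recon_loss_components(xb, p)
        dp <- recon_loss_grad(xb, p)
        rl_mean <- 0
        if (lambda > 0) {
          mrl_in <- mrl_in_all[b]
          pf <- predictor_forward(predictor$params, predictor$cfg, p,
                                  keep_cache = TRUE)
          rl <- rl_loss(mrl_in, pf$pred)
          rl_mean <- mean(rl)
          dpred <- -lambda * rl / nb
          pb <- predictor_backward(predictor$params, predictor$cfg,
                                   pf$cache, dpred, need_dx = TRUE)
          dp <- dp + pb$dx
        }
        grads <- generator_backward(params, cfg, gf$cache, dp, p)
        st <- adam_step(params, grads, opt, lr_ep)
        params <- st$params; opt <- st$state
        re_sum <- re_sum + (comp$cce + comp$bce) * nb
        rl_sum <- rl_sum + rl_mean * nb
      }
      hist[[ep]] <- data.frame(epoch = ep, recon_loss = re_sum / n,
                               rl_loss = rl_sum / n,
                               total_loss = re_sum / n +
                                 lambda * rl_sum / n)
      if (verbose) {
        message(sprintf("epoch %3d  recon %.4f  rl %.4f", ep, re_sum / n,
                        rl_sum / n))
      }
    }
  })
  generator$params <- params
  generator$opt_state <- opt
  generator$trained <- TRUE
  generator$history <- rbind(generator$history, do.call(rbind, hist))
  generator
}

## ---- inference ---------------------------------------------------------

# Decode generator probabilities while preserving the input's length: pad
# rows stay pad; non-pad rows take the argmax over the four nucleotide
# channels only (pad can never be introduced inside the sequence).
masked_decode <- function(p, n_pad) {
  L <- nrow(p)
  if (n_pad >= L) return("")
  rows <- (n_pad + 1L):L
  arg <- max.col(p[rows, 1:4, drop = FALSE], ties.method = "first")
  paste(UTR_CHANNELS[arg], collapse = "")
}

#' Optimize a 5' UTR sequence
#'
#' Encodes the query, passes it through the generator, decodes the output
#' with pad positions masked (so the optimized sequence always has exactly
#' the query's length), scores both sequences with the predictor, and
#' enumerates the substitutions in upstream coordinates (position 1 = first
#' nucleotide upstream of the start codon).
#'
#' For generators whose `input_len` is shorter than the query (fixed-length
#' 50 nt mode with a longer query), only the last `input_len` nucleotides are
#' rewritten; the untouched 5' prefix is retained.
#'
#' @param generator A trained `utr_generator`.
#' @param predictor A trained `mrl_predictor`.
#' @param s Query sequence (`utr_sequence`, or string validated internally).
#' @return An `optimization_result`: list with `original`, `optimized`
#'   (`utr_sequence`s), `mrl_orig`, `mrl_opt`, and a `substitutions`
#'   data.frame with columns `position`, `from`, `to`.
#' @export
optimize_utr <- function(generator, predictor, s) {
  stopifnot(inherits(generator, "utr_generator"),
            inherits(predictor, "mrl_predictor"))
  if (!inherits(s, "utr_sequence")) s <- validate_utr(s)
  L <- generator$cfg$input_len
  seq <- s$seq
  n <- nchar(seq)
  prefix <- if (n > L) substr(seq, 1L, n - L) else ""
  x <- encode_utr(seq, L)
  p <- generator_forward(generator$params, generator$cfg,
                         array(x, dim = c(1L, dim(x))))$p[1L, , ]
  core <- masked_decode(p, max(0L, L - n))
  optimized <- paste0(prefix, core)
  orig_chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  opt_chars <- strsplit(optimized, "", fixed = TRUE)[[1L]]
  diff <- which(orig_chars != opt_chars)
  subs <- data.frame(position = n - diff + 1L,
                     from = orig_chars[diff], to = opt_chars[diff],
                     stringsAsFactors = FALSE)
  subs <- subs[order(subs$position), , drop = FALSE]
  rownames(subs) <- NULL
  structure(list(original = s,
                 optimized = structure(list(seq = optimized, id =
                                              paste0(s$id, "_opt")),
                                       class = "utr_sequence"),
                 mrl_orig = predict_mrl(predictor, seq),
                 mrl_opt = predict_mrl(predictor, optimized),
                 substitutions = subs),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> %s\n  original : %s (MRL %.3f)\n",
              x$original$id, x$original$seq, x$mrl_orig))
  cat(sprintf("  optimized: %s (MRL %.3f)\n  %d substitution(s)\n",
              x$optimized$seq, x$mrl_opt, nrow(x$substitutions)))
  invisible(x)
}
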