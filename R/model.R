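# Transformer classifier: configuration, initialization, training (Adam on
# cross-entropy) and inference. The numerical core (forward + backprop)
# lives in src/transformer.cpp; everything here is bookkeeping.

#' Transformer model configuration
#'
#' Defaults mirror the reference architecture: 48 input channels embedded to
#' a model width of 48 (the embedding is a learned linear map), fixed
#' sinusoidal positional encoding, five post-norm encoder blocks, flattening
#' over time and model dimensions (width `seq_len * d_model`, 13248 at the
#' default shape) and a fully connected softmax classifier with two classes.
#' Head count, feed-forward width and dropout are free parameters of this
#' implementation.
#'
#' @param seq_len input length after padding (default 276).
#' @param n_channels input channels (default 48).
#' @param d_model embedding width; must be divisible by `n_heads`.
#' @param n_blocks number of encoder blocks (default 5).
#' @param n_heads attention heads.
#' @param ff_dim feed-forward hidden width.
#' @param dropout dropout probability on each sub-layer output.
#' @param n_classes output classes.
#' @return List of class `model_config`.
#' @export
model_config <- function(seq_len = 276L, n_channels = 48L, d_model = 48L,
                         n_blocks = 5L, n_heads = 4L, ff_dim = 128L,
                         dropout = 0.1, n_classes = 2L) {
  stopifnot(seq_len >= 2, n_channels >= 1, n_blocks >= 1,
            dropout >= 0, dropout < 1, n_classes >= 2)
  if (d_model %% n_heads != 0)
    stop("d_model must be divisible by n_heads")
  structure(list(seq_len = as.integer(seq_len),
                 n_channels = as.integer(n_channels),
                 d_model = as.integer(d_model),
                 n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 ff_dim = as.integer(ff_dim),
                 dropout = dropout,
                 n_classes = as.integer(n_classes)),
            class = "model_config")
}

#' Training configuration
#'
#' Reference protocol defaults: 130 epochs, batch size 64, learning rate
#' 1e-5 (Adam, no scheduler, no early stopping; the final-epoch model is
#' kept).
#'
#' @param epochs number of epochs (0 returns the model unchanged).
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param warmup_steps linear learning-rate warm-up over this many steps
#'   (0 = constant rate, the reference behavior). Post-norm encoders train
#'   through an initial plateau; at the reference rate of 1e-5 over 130
#'   epochs no warm-up is needed, but short runs at higher rates converge
#'   much faster and more stably with a brief warm-up.
#' @param seed optional seed controlling shuffling, dropout and any
#'   initialization performed during training.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 130L, batch_size = 64L,
                         learning_rate = 1e-5, warmup_steps = 0L,
                         seed = NULL) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0,
            warmup_steps >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 warmup_steps = as.integer(warmup_steps), seed = seed),
            class = "train_config")
}

# fixed sinusoidal positional encoding, positions 0-based
.positional_encoding <- function(seq_len, d_model) {
  pos <- matrix(0:(seq_len - 1L), seq_len, d_model)
  i2 <- matrix(rep(seq(0L, d_model - 1L) %/% 2L * 2L, each = seq_len),
               seq_len, d_model)
  angle <- pos / 10000^(i2 / d_model)
  odd <- rep(seq_len(d_model) %% 2 == 0, each = seq_len)  # 1-based even cols
  out <- matrix(0, seq_len, d_model)
  out[!odd] <- sin(angle[!odd])
  out[odd] <- cos(angle[odd])
  out
}

.glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
}

#' Build an (untrained) Transformer classifier
#'
#' @param config a [model_config()].
#' @param seed optional seed for the parameter initialization.
#' @return Object of class `imu_transformer` with fields `params`, `config`,
#'   `history` (empty), `trained`.
#' @export
build_model <- function(config = model_config(), seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- config$d_model
  p <- list(W_emb = .glorot(config$n_channels, d), b_emb = numeric(d))
  for (i in seq_len(config$n_blocks)) {
    s <- paste0("_", i)
    p[[paste0("Wq", s)]] <- .glorot(d, d); p[[paste0("bq", s)]] <- numeric(d)
    p[[paste0("Wk", s)]] <- .glorot(d, d); p[[paste0("bk", s)]] <- numeric(d)
    p[[paste0("Wv", s)]] <- .glorot(d, d); p[[paste0("bv", s)]] <- numeric(d)
    p[[paste0("Wo", s)]] <- .glorot(d, d); p[[paste0("bo", s)]] <- numeric(d)
    p[[paste0("g1", s)]] <- rep(1, d); p[[paste0("be1", s)]] <- numeric(d)
    p[[paste0("W1", s)]] <- .glorot(d, config$ff_dim)
    p[[paste0("b1f", s)]] <- numeric(config$ff_dim)
    p[[paste0("W2", s)]] <- .glorot(config$ff_dim, d)
    p[[paste0("b2f", s)]] <- numeric(d)
    p[[paste0("g2", s)]] <- rep(1, d); p[[paste0("be2", s)]] <- numeric(d)
  }
  p$W_fc <- .glorot(config$seq_len * d, config$n_classes)
  p$b_fc <- numeric(config$n_classes)
  p$pe <- .positional_encoding(config$seq_len, d)
  structure(list(params = p, config = config,
                 history = data.frame(), trained = FALSE),
            class = "imu_transformer")
}

#' @export
print.imu_transformer <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params[names(x$params) != "pe"], length, numeric(1)))
  cat(sprintf(paste0("<imu_transformer> %s: seq_len %d x %d channels, ",
                     "d_model %d, %d blocks x %d heads, %d parameters\n"),
              if (x$trained) "trained" else "untrained",
              cfg$seq_len, cfg$n_channels, cfg$d_model, cfg$n_blocks,
              cfg$n_heads, n_par))
  if (nrow(x$history))
    cat(sprintf("  final epoch: loss %.4f, train acc %.3f%s\n",
                utils::tail(x$history$loss, 1),
                utils::tail(x$history$train_accuracy, 1),
                if (!all(is.na(x$history$val_accuracy)))
                  sprintf(", val acc %.3f",
                          utils::tail(x$history$val_accuracy, 1)) else ""))
  invisible(x)
}

.model_cfg_list <- function(config) {
  list(d_model = config$d_model, n_blocks = config$n_blocks,
       n_heads = config$n_heads, ff_dim = config$ff_dim,
       dropout = config$dropout, n_classes = config$n_classes)
}

# labels -> 0-based class integers (WA = 0, NA = 1, the positive class)
.y_int <- function(y) {
  stopifnot(is.factor(y), identical(levels(y), c("WA", "NA")))
  as.integer(y) - 1L
}

#' Train a Transformer classifier
#'
#' Minimizes softmax cross-entropy with Adam. The sample order is shuffled
#' every epoch; per-epoch mean training loss and accuracy (and validation
#' accuracy, if a validation set is given) are recorded in the model's
#' `history`. With a fixed `config$seed` the run is reproducible on a fixed
#' platform.
#'
#' @param model an `imu_transformer`.
#' @param train_samples list of `norm_sample` (both classes present).
#' @param val_samples optional validation samples.
#' @param config a [train_config()].
#' @return The trained model.
#' @export
train_model <- function(model, train_samples, val_samples = NULL,
                        config = train_config()) {
  stopifnot(inherits(model, "imu_transformer"),
            inherits(config, "train_config"))
  if (config$epochs == 0L) return(model)
  tr <- samples_to_array(train_samples)
  if (length(unique(tr$y)) < 2L)
    stop("training set contains a single class")
  if (dim(tr$x)[1L] != model$config$seq_len)
    stop("sample length ", dim(tr$x)[1L], " does not match model seq_len ",
         model$config$seq_len)
  y <- .y_int(tr$y)
  va <- if (!is.null(val_samples) && length(val_samples))
    samples_to_array(val_samples) else NULL
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- .model_cfg_list(model$config)
  params <- model$params
  opt_names <- setdiff(names(params), "pe")
  m_st <- lapply(params[opt_names], function(x) x * 0)
  v_st <- lapply(params[opt_names], function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0L
  n <- length(y)
  hist <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    correct <- 0L; loss_sum <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      res <- .tf_pass(params, tr$x[, , idx, drop = FALSE], y[idx], cfg,
                      TRUE, TRUE)
      loss_sum <- loss_sum + res$loss * length(idx)
      correct <- correct +
        sum(max.col(res$probs, ties.method = "first") - 1L == y[idx])
      t_step <- t_step + 1L
      lr_t <- config$learning_rate *
        sqrt(1 - beta2^t_step) / (1 - beta1^t_step)
      if (config$warmup_steps > 0L && t_step <= config$warmup_steps)
        lr_t <- lr_t * t_step / config$warmup_steps
      for (nm in opt_names) {
        g <- res$grads[[nm]]
        m_st[[nm]] <- beta1 * m_st[[nm]] + (1 - beta1) * g
        v_st[[nm]] <- beta2 * v_st[[nm]] + (1 - beta2) * g^2
        params[[nm]] <- params[[nm]] -
          lr_t * m_st[[nm]] / (sqrt(v_st[[nm]]) + eps)
      }
    }
    val_acc <- NA_real_
    if (!is.null(va)) {
      pv <- .tf_pass(params, va$x, integer(0), cfg, FALSE, FALSE)
      val_acc <- mean(max.col(pv$probs, ties.method = "first") - 1L ==
                        .y_int(va$y))
    }
    hist[[epoch]] <- data.frame(epoch = epoch, loss = loss_sum / n,
                                train_accuracy = correct / n,
                                val_accuracy = val_acc)
  }
  model$params <- params
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

#' Predict class probabilities and labels
#'
#' Inference is deterministic (dropout off) and batch-order preserving.
#'
#' @param object a trained `imu_transformer`.
#' @param samples list of `norm_sample`, or an array of dim
#'   `(seq_len, n_channels, n)`.
#' @param ... unused.
#' @return List with `prob` (`n x 2` matrix, columns `WA`, `NA`) and `label`
#'   (factor with levels `WA`, `NA`).
#' @export
predict.imu_transformer <- function(object, samples, ...) {
  x <- if (is.array(samples) && length(dim(samples)) == 3L) samples
       else samples_to_array(samples)$x
  res <- .tf_pass(object$params, x, integer(0),
                  .model_cfg_list(object$config), FALSE, FALSE)
  prob <- res$probs
  colnames(prob) <- c("WA", "NA")
  label <- factor(c("WA", "NA")[max.col(prob, ties.method = "first")],
                  levels = c("WA", "NA"))
  list(prob = prob, label = label, flat_width = res$flat_width)
}
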