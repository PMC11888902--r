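# Shared numerical machinery for the hand-rolled neural classifiers:
# seeded initialisation, softmax cross-entropy, inverted dropout, Adam with
# the two learning-rate schedules used by the models.

# uniform(-k, k) init with k = 1/sqrt(fan_in)
init_mat <- function(nrow, ncol, fan_in = ncol) {
  k <- 1 / sqrt(fan_in)
  matrix(stats::runif(nrow * ncol, -k, k), nrow, ncol)
}
init_vec <- function(n, fan_in) {
  k <- 1 / sqrt(fan_in)
  stats::runif(n, -k, k)
}

# row-wise numerically stable softmax
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy and the gradient wrt the scores (already averaged)
ce_loss_grad <- function(scores, y_idx) {
  p <- softmax_rows(scores)
  n <- nrow(scores)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y_idx)] + eps))
  g <- p
  g[cbind(seq_len(n), y_idx)] <- g[cbind(seq_len(n), y_idx)] - 1
  list(loss = loss, grad = g / n)
}

# inverted dropout: mask already scaled by 1/(1-p); identity when not training
dropout_mask <- function(dim, p, training) {
  if (!training || p <= 0) return(NULL)
  array(stats::rbinom(prod(dim), 1, 1 - p) / (1 - p), dim = dim)
}
apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- Adam over an arbitrary named list (possibly nested) of arrays ---
# Parameters are flattened to one numeric vector for the moment updates
# (fast elementwise math) and re-folded into the original structure.

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(skeleton, v) {
  pos <- 0L
  refold <- function(p) {
    if (is.list(p)) return(lapply(p, refold))
    n <- length(p)
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(p))) dim(out) <- dim(p)
    out
  }
  refold(skeleton)
}

# the optimizer state lives in an environment so the compiled kernel can
# update the moment vectors in place
adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- numeric(length(flatten_params(params)))
  st$v <- numeric(length(st$m))
  st$t <- 0L
  st
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  p <- flatten_params(params)
  g <- flatten_params(grads)
  adam_update_inplace(p, state$m, state$v, g, lr, 0.9, 0.999, 1e-8, state$t)
  unflatten_params(params, p)
}

# --- learning-rate schedules ---

# step schedule: lr0 * factor^floor((epoch-1)/step); factor 0.1 every 10
# epochs reproduces "decrease the learning rate by 0.1 every ten epochs"
lr_step <- function(lr0, epoch, step = 10L, factor = 0.1) {
  lr0 * factor^(floor((epoch - 1L) / step))
}

# plateau schedule state machine: halve when the monitored loss has not
# improved for `patience` consecutive epochs
plateau_state <- function(lr0, factor = 0.5, patience = 3L) {
  list(lr = lr0, best = Inf, wait = 0L, factor = factor, patience = patience)
}
plateau_update <- function(st, loss) {
  if (loss < st$best - 1e-12) {
    st$best <- loss
    st$wait <- 0L
  } else {
    st$wait <- st$wait + 1L
    if (st$wait > st$patience) {
      st$lr <- st$lr * st$factor
      st$wait <- 0L
    }
  }
  st
}

#' Training configuration for the neural classifiers
#'
#' Defaults follow the published training schedules: cross-entropy loss,
#' Adam, 50 epochs, batch size 32; the FC+LSTM model uses lr 0.001 with a
#' step schedule (x0.1 every 10 epochs), the Transformer lr 0.0005 with a
#' plateau schedule (x0.5 after 3 epochs without improvement of the
#' training loss).
#'
#' @param model `"fclstm"` or `"transformer"` (sets the defaults).
#' @param lr initial learning rate.
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialisation, shuffling, dropout.
#' @param scheduler `"step"` or `"plateau"`.
#' @param lstm_seq_len for the FC+LSTM model: the 256-unit projection is
#'   reshaped into a sequence of this length (must divide 256) before the
#'   LSTM; default 1 (the whole projection as one step).
#' @param tokenize for the Transformer: `"single"` (the feature vector is
#'   one token) or `"per_feature"` (one token per input feature).
#' @return A list of class `train_config`.
#' @export
train_config <- function(model = c("fclstm", "transformer"), lr = NULL,
                         epochs = 50L, batch_size = 32L, seed = 1L,
                         scheduler = NULL, lstm_seq_len = 1L,
                         tokenize = c("single", "per_feature")) {
  model <- match.arg(model)
  tokenize <- match.arg(tokenize)
  lr <- lr %||% if (model == "fclstm") 0.001 else 0.0005
  scheduler <- scheduler %||% if (model == "fclstm") "step" else "plateau"
  if (lr <= 0) stop_bcg("lr must be positive")
  if (epochs < 1) stop_bcg("epochs must be >= 1")
  if (256L %% as.integer(lstm_seq_len) != 0L)
    stop_bcg("lstm_seq_len must divide 256")
  structure(list(model = model, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 scheduler = scheduler, lstm_seq_len = as.integer(lstm_seq_len),
                 tokenize = tokenize),
            class = "train_config")
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2L)
    stop_bcg("training labels must contain both classes")
}

minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}
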