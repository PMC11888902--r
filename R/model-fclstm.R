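# Fully connected + LSTM classifier, implemented from scratch:
# x -> FC(512) -> ReLU -> FC(256) -> reshape to a length-T sequence ->
# 2-layer LSTM (hidden 128) -> FC(64) -> Dropout(0.1) -> FC(C).
# Trained with softmax cross-entropy, Adam, and a step LR schedule.

fclstm_init <- function(d, C = 2L, seq_len = 1L) {
  H <- 128L
  in1 <- 256L %/% seq_len
  kl <- 128L  # torch-style LSTM init: uniform(-1/sqrt(H), 1/sqrt(H))
  lstm_layer <- function(in_sz) list(
    Wx = init_mat(4L * H, in_sz, fan_in = kl),
    Wh = init_mat(4L * H, H, fan_in = kl),
    b = init_vec(4L * H, kl)
  )
  list(
    W1 = init_mat(512L, d, fan_in = d), b1 = init_vec(512L, d),
    W2 = init_mat(256L, 512L, fan_in = 512L), b2 = init_vec(256L, 512L),
    l1 = lstm_layer(in1), l2 = lstm_layer(H),
    W3 = init_mat(64L, H, fan_in = H), b3 = init_vec(64L, H),
    W4 = init_mat(C, 64L, fan_in = 64L), b4 = init_vec(C, 64L)
  )
}

# xs: list over time of [B x In] inputs
lstm_layer_forward <- function(xs, layer) {
  B <- nrow(xs[[1]])
  H <- nrow(layer$Wh) %/% 4L
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  hs <- vector("list", length(xs)); cache <- vector("list", length(xs))
  gi <- 1:H; gf <- H + gi; gg <- 2L * H + gi; go <- 3L * H + gi
  for (t in seq_along(xs)) {
    pre <- tcrossprod(xs[[t]], layer$Wx) + tcrossprod(h, layer$Wh) +
      matrix(layer$b, B, 4L * H, byrow = TRUE)
    i <- sigmoid(pre[, gi, drop = FALSE])
    f <- sigmoid(pre[, gf, drop = FALSE])
    g <- tanh(pre[, gg, drop = FALSE])
    o <- sigmoid(pre[, go, drop = FALSE])
    c_prev <- cc; h_prev <- h
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    hs[[t]] <- h
    cache[[t]] <- list(x = xs[[t]], h_prev = h_prev, c_prev = c_prev,
                       i = i, f = f, g = g, o = o, tc = tc)
  }
  list(hs = hs, cache = cache)
}

# dhs: list over time of external gradients wrt h_t (zero matrices allowed)
lstm_layer_backward <- function(cache, dhs, layer) {
  T_ <- length(cache)
  B <- nrow(dhs[[T_]])
  H <- nrow(layer$Wh) %/% 4L
  dWx <- layer$Wx * 0; dWh <- layer$Wh * 0; db <- layer$b * 0
  dxs <- vector("list", T_)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in T_:1) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dh_next
    do <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dpre <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                  dg * (1 - cc$g^2), do * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(dpre, cc$x)
    dWh <- dWh + crossprod(dpre, cc$h_prev)
    db <- db + colSums(dpre)
    dxs[[t]] <- dpre %*% layer$Wx
    dh_next <- dpre %*% layer$Wh
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dxs = dxs)
}

split_sequence <- function(h2, n_tokens) {
  in1 <- ncol(h2) %/% n_tokens
  lapply(seq_len(n_tokens), function(t)
    h2[, ((t - 1L) * in1 + 1L):(t * in1), drop = FALSE])
}

#' Forward pass of the FC+LSTM classifier
#'
#' @param params a parameter list as produced by training (or `fclstm_init`).
#' @param x numeric matrix `[n x d]` (a single feature vector may be passed
#'   as a vector).
#' @param training logical; when `TRUE` the 0.1-rate dropout before the
#'   output layer is active (stochastic), otherwise the pass is
#'   deterministic.
#' @param seq_len sequence length the 256-unit projection is reshaped to.
#' @return A numeric matrix `[n x C]` of class scores (logits).
#' @export
fclstm_forward <- function(params, x, training = FALSE, seq_len = 1L) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  fwd <- fclstm_forward_cache(params, x, training, seq_len)
  fwd$scores
}

fclstm_forward_cache <- function(params, X, training, seq_len) {
  B <- nrow(X)
  H1 <- tcrossprod(X, params$W1) + matrix(params$b1, B, 512L, byrow = TRUE)
  A1 <- pmax(H1, 0)
  H2 <- tcrossprod(A1, params$W2) + matrix(params$b2, B, 256L, byrow = TRUE)
  xs <- split_sequence(H2, seq_len)
  l1 <- lstm_layer_forward(xs, params$l1)
  l2 <- lstm_layer_forward(l1$hs, params$l2)
  h_final <- l2$hs[[length(l2$hs)]]
  H4 <- tcrossprod(h_final, params$W3) + matrix(params$b3, B, 64L, byrow = TRUE)
  mask <- dropout_mask(dim(H4), 0.1, training)
  A2 <- apply_mask(H4, mask)
  scores <- tcrossprod(A2, params$W4) + matrix(params$b4, B, nrow(params$W4), byrow = TRUE)
  list(scores = scores,
       cache = list(X = X, H1 = H1, A1 = A1, xs = xs, l1 = l1, l2 = l2,
                    h_final = h_final, H4 = H4, mask = mask, A2 = A2,
                    seq_len = seq_len))
}

fclstm_backward <- function(params, cache, dscores) {
  B <- nrow(dscores)
  gW4 <- crossprod(dscores, cache$A2)
  gb4 <- colSums(dscores)
  dA2 <- dscores %*% params$W4
  dH4 <- apply_mask(dA2, cache$mask)
  gW3 <- crossprod(dH4, cache$h_final)
  gb3 <- colSums(dH4)
  dh_final <- dH4 %*% params$W3
  T_ <- cache$seq_len
  zero <- matrix(0, B, 128L)
  dhs2 <- c(rep(list(zero), T_ - 1L), list(dh_final))
  bl2 <- lstm_layer_backward(cache$l2$cache, dhs2, params$l2)
  bl1 <- lstm_layer_backward(cache$l1$cache, bl2$dxs, params$l1)
  dH2 <- do.call(cbind, bl1$dxs)
  gW2 <- crossprod(dH2, cache$A1)
  gb2 <- colSums(dH2)
  dA1 <- dH2 %*% params$W2
  dH1 <- dA1 * (cache$H1 > 0)
  gW1 <- crossprod(dH1, cache$X)
  gb1 <- colSums(dH1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       l1 = bl1$grads, l2 = bl2$grads,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

#' Train the FC+LSTM classifier
#'
#' Minimises softmax cross-entropy with Adam; the learning rate follows a
#' step schedule (multiplied by 0.1 every 10 epochs). Deterministic given
#' `cfg$seed`: initialisation, epoch shuffling and dropout all derive from
#' it.
#'
#' @param X numeric feature matrix `[n x d]`, expected standardised (see
#'   [standardize_features()]).
#' @param y integer labels, hypertensive = 1, normotensive = 0 (both must
#'   be present).
#' @param cfg a [train_config()] for model `"fclstm"`.
#' @return An object of class `bcg_fclstm` with elements `params`,
#'   `loss_history` (one entry per epoch), `lr_history`, `cfg`.
#' @export
train_fclstm <- function(X, y, cfg = train_config("fclstm")) {
  X <- as.matrix(X)
  y <- label_to_int(y)
  check_two_classes(y)
  y_idx <- y + 1L
  seq_len_ <- cfg$lstm_seq_len
  with_seed(cfg$seed, {
    params <- fclstm_init(ncol(X), C = 2L, seq_len = seq_len_)
    opt <- adam_init(params)
    loss_hist <- numeric(cfg$epochs)
    lr_hist <- numeric(cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_step(cfg$lr, epoch)
      lr_hist[epoch] <- lr
      batch_losses <- c()
      for (idx in minibatches(nrow(X), cfg$batch_size)) {
        fwd <- fclstm_forward_cache(params, X[idx, , drop = FALSE],
                                    training = TRUE, seq_len = seq_len_)
        lg <- ce_loss_grad(fwd$scores, y_idx[idx])
        grads <- fclstm_backward(params, fwd$cache, lg$grad)
        params <- adam_step(params, grads, opt, lr)
        batch_losses <- c(batch_losses, lg$loss)
      }
      loss_hist[epoch] <- mean(batch_losses)
    }
    structure(list(params = params, cfg = cfg, d = ncol(X),
                   loss_history = loss_hist, lr_history = lr_hist),
              class = c("bcg_fclstm", "bcg_model"))
  })
}

#' @export
predict_proba.bcg_fclstm <- function(model, X, ...) {
  X <- as.matrix(X)
  scores <- fclstm_forward(model$params, X, training = FALSE,
                           seq_len = model$cfg$lstm_seq_len)
  p <- softmax_rows(scores)
  colnames(p) <- c("0", "1")
  p
}
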