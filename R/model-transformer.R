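# Transformer encoder classifier, implemented from scratch:
# x -> linear embedding to 256 -> Dropout(0.1) -> 3 encoder layers
# (4-head self-attention + 512-unit feed-forward, post-norm residuals) ->
# mean pooling over tokens -> linear map to C classes.
# By default the whole feature vector is a single token (T = 1, where the
# attention weights collapse to 1); `tokenize = "per_feature"` instead
# feeds one token per input feature (T = d).

TF_D <- 256L   # model width
TF_H <- 4L     # attention heads
TF_F <- 512L   # feed-forward width
TF_L <- 3L     # encoder layers
TF_P <- 0.1    # dropout rate

transformer_init <- function(din, C = 2L) {
  D <- TF_D
  layer <- function() list(
    Wq = init_mat(D, D), bq = init_vec(D, D),
    Wk = init_mat(D, D), bk = init_vec(D, D),
    Wv = init_mat(D, D), bv = init_vec(D, D),
    Wo = init_mat(D, D), bo = init_vec(D, D),
    Wf1 = init_mat(TF_F, D), bf1 = init_vec(TF_F, D),
    Wf2 = init_mat(D, TF_F), bf2 = init_vec(D, TF_F),
    ln1_g = rep(1, D), ln1_b = rep(0, D),
    ln2_g = rep(1, D), ln2_b = rep(0, D)
  )
  list(
    Wemb = init_mat(D, din, fan_in = din), bemb = init_vec(D, din),
    layers = lapply(seq_len(TF_L), function(i) layer()),
    Wout = init_mat(C, D), bout = init_vec(C, D)
  )
}

layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  gamma <- as.numeric(gamma)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv_std <- 1 / sqrt(v + eps)
  xhat <- xc * inv_std
  list(y = sweep(xhat * gamma[col(xhat)], 2, beta, `+`),
       xhat = xhat, inv_std = inv_std)
}

layernorm_bwd <- function(dy, cache, gamma) {
  gamma <- as.numeric(gamma)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * gamma[col(dy)]
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv_std
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

addb <- function(x, b) sweep(x, 2, b, `+`)

# multi-head self-attention over tokens grouped in blocks of T rows
attention_fwd <- function(X, ly, T_) {
  N <- nrow(X); B <- N %/% T_
  dk <- TF_D %/% TF_H
  Q <- addb(tcrossprod(X, ly$Wq), ly$bq)
  K <- addb(tcrossprod(X, ly$Wk), ly$bk)
  V <- addb(tcrossprod(X, ly$Wv), ly$bv)
  if (T_ == 1L) {
    O <- V  # softmax over one key is identically 1
    A_all <- NULL
  } else {
    O <- matrix(0, N, TF_D)
    A_all <- array(0, c(T_, T_, TF_H, B))
    for (s in seq_len(B)) {
      rows <- ((s - 1L) * T_ + 1L):(s * T_)
      for (h in seq_len(TF_H)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) / sqrt(dk)
        A <- softmax_rows(S)
        A_all[, , h, s] <- A
        O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      }
    }
  }
  out <- addb(tcrossprod(O, ly$Wo), ly$bo)
  list(out = out, Q = Q, K = K, V = V, O = O, A = A_all)
}

attention_bwd <- function(dout, cache, X, ly, T_) {
  N <- nrow(X); B <- N %/% T_
  dk <- TF_D %/% TF_H
  gWo <- crossprod(dout, cache$O)
  gbo <- colSums(dout)
  dO <- dout %*% ly$Wo
  if (T_ == 1L) {
    dV <- dO
    dQ <- matrix(0, N, TF_D)
    dK <- matrix(0, N, TF_D)
  } else {
    dQ <- matrix(0, N, TF_D); dK <- matrix(0, N, TF_D); dV <- matrix(0, N, TF_D)
    for (s in seq_len(B)) {
      rows <- ((s - 1L) * T_ + 1L):(s * T_)
      for (h in seq_len(TF_H)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        A <- cache$A[, , h, s]
        dOh <- dO[rows, cols, drop = FALSE]
        Vh <- cache$V[rows, cols, drop = FALSE]
        dA <- tcrossprod(dOh, Vh)
        dV[rows, cols] <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- (dS %*% cache$K[rows, cols, drop = FALSE]) / sqrt(dk)
        dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) / sqrt(dk)
      }
    }
  }
  dX <- dQ %*% ly$Wq + dK %*% ly$Wk + dV %*% ly$Wv
  list(dX = dX,
       grads = list(Wq = crossprod(dQ, X), bq = colSums(dQ),
                    Wk = crossprod(dK, X), bk = colSums(dK),
                    Wv = crossprod(dV, X), bv = colSums(dV),
                    Wo = gWo, bo = gbo))
}

encoder_layer_fwd <- function(X, ly, T_, training) {
  at <- attention_fwd(X, ly, T_)
  m1 <- dropout_mask(dim(at$out), TF_P, training)
  ln1 <- layernorm_fwd(X + apply_mask(at$out, m1), ly$ln1_g, ly$ln1_b)
  X1 <- ln1$y
  F1 <- addb(tcrossprod(X1, ly$Wf1), ly$bf1)
  R <- pmax(F1, 0)
  F2 <- addb(tcrossprod(R, ly$Wf2), ly$bf2)
  m2 <- dropout_mask(dim(F2), TF_P, training)
  ln2 <- layernorm_fwd(X1 + apply_mask(F2, m2), ly$ln2_g, ly$ln2_b)
  list(out = ln2$y,
       cache = list(X = X, at = at, m1 = m1, ln1 = ln1, X1 = X1,
                    relu_mask = F1 > 0, R = R, m2 = m2, ln2 = ln2))
}

encoder_layer_bwd <- function(dout, cache, ly, T_) {
  b2 <- layernorm_bwd(dout, cache$ln2, ly$ln2_g)
  dF2 <- apply_mask(b2$dx, cache$m2)
  gWf2 <- crossprod(dF2, cache$R)
  gbf2 <- colSums(dF2)
  dR <- dF2 %*% ly$Wf2
  dF1 <- dR * cache$relu_mask
  gWf1 <- crossprod(dF1, cache$X1)
  gbf1 <- colSums(dF1)
  dX1 <- b2$dx + dF1 %*% ly$Wf1
  b1 <- layernorm_bwd(dX1, cache$ln1, ly$ln1_g)
  dattn <- apply_mask(b1$dx, cache$m1)
  ab <- attention_bwd(dattn, cache$at, cache$X, ly, T_)
  dX <- b1$dx + ab$dX
  grads <- c(ab$grads,
             list(Wf1 = gWf1, bf1 = gbf1, Wf2 = gWf2, bf2 = gbf2,
                  ln1_g = b1$dgamma, ln1_b = b1$dbeta,
                  ln2_g = b2$dgamma, ln2_b = b2$dbeta))
  # order grads like the parameter list
  list(dX = dX, grads = grads[c("Wq", "bq", "Wk", "bk", "Wv", "bv",
                                "Wo", "bo", "Wf1", "bf1", "Wf2", "bf2",
                                "ln1_g", "ln1_b", "ln2_g", "ln2_b")])
}

tokens_from_features <- function(X, tokenize) {
  if (tokenize == "per_feature")
    list(Xin = matrix(as.vector(t(X)), ncol = 1L), T_ = ncol(X))
  else
    list(Xin = X, T_ = 1L)
}

transformer_forward_cache <- function(params, X, training, tokenize) {
  tk <- tokens_from_features(X, tokenize)
  B <- nrow(X); T_ <- tk$T_
  E <- addb(tcrossprod(tk$Xin, params$Wemb), params$bemb)
  m0 <- dropout_mask(dim(E), TF_P, training)
  H <- apply_mask(E, m0)
  caches <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    st <- encoder_layer_fwd(H, params$layers[[l]], T_, training)
    H <- st$out
    caches[[l]] <- st$cache
  }
  group <- rep(seq_len(B), each = T_)
  H3 <- unname(rowsum(H, group)) / T_         # mean pool over tokens
  scores <- addb(tcrossprod(H3, params$Wout), params$bout)
  list(scores = scores,
       cache = list(Xin = tk$Xin, T_ = T_, B = B, m0 = m0,
                    caches = caches, H = H, H3 = H3))
}

transformer_backward <- function(params, cache, dscores) {
  T_ <- cache$T_; B <- cache$B
  gWout <- crossprod(dscores, cache$H3)
  gbout <- colSums(dscores)
  dH3 <- dscores %*% params$Wout
  dH <- dH3[rep(seq_len(B), each = T_), , drop = FALSE] / T_
  layer_grads <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    bl <- encoder_layer_bwd(dH, cache$caches[[l]], params$layers[[l]], T_)
    dH <- bl$dX
    layer_grads[[l]] <- bl$grads
  }
  dE <- apply_mask(dH, cache$m0)
  list(Wemb = crossprod(dE, cache$Xin), bemb = colSums(dE),
       layers = layer_grads,
       Wout = gWout, bout = gbout)
}

#' Forward pass of the Transformer classifier
#'
#' @param params a parameter list as produced by training.
#' @param x numeric matrix `[n x d]` of feature vectors.
#' @param training logical; activates the 0.1-rate dropout layers.
#' @param tokenize `"single"` (default: the feature vector is one token) or
#'   `"per_feature"`.
#' @return A numeric matrix `[n x C]` of class scores.
#' @export
transformer_forward <- function(params, x, training = FALSE,
                                tokenize = "single") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  transformer_forward_cache(params, x, training, tokenize)$scores
}

#' Train the Transformer classifier
#'
#' Minimises softmax cross-entropy with Adam (initial lr 0.0005); the
#' learning rate is halved whenever the training loss has not improved for
#' 3 consecutive epochs (plateau schedule). Deterministic given `cfg$seed`.
#'
#' @inheritParams train_fclstm
#' @param cfg a [train_config()] for model `"transformer"`.
#' @return An object of class `bcg_transformer` with `params`,
#'   `loss_history`, `lr_history`, `cfg`.
#' @export
train_transformer <- function(X, y, cfg = train_config("transformer")) {
  X <- as.matrix(X)
  y <- label_to_int(y)
  check_two_classes(y)
  y_idx <- y + 1L
  din <- if (cfg$tokenize == "per_feature") 1L else ncol(X)
  with_seed(cfg$seed, {
    params <- transformer_init(din, C = 2L)
    opt <- adam_init(params)
    sched <- plateau_state(cfg$lr)
    loss_hist <- numeric(cfg$epochs)
    lr_hist <- numeric(cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      lr_hist[epoch] <- sched$lr
      batch_losses <- c()
      for (idx in minibatches(nrow(X), cfg$batch_size)) {
        fwd <- transformer_forward_cache(params, X[idx, , drop = FALSE],
                                         training = TRUE, cfg$tokenize)
        lg <- ce_loss_grad(fwd$scores, y_idx[idx])
        grads <- transformer_backward(params, fwd$cache, lg$grad)
        params <- adam_step(params, grads, opt, sched$lr)
        batch_losses <- c(batch_losses, lg$loss)
      }
      loss_hist[epoch] <- mean(batch_losses)
      sched <- plateau_update(sched, loss_hist[epoch])
    }
    structure(list(params = params, cfg = cfg, d = ncol(X),
                   loss_history = loss_hist, lr_history = lr_hist),
              class = c("bcg_transformer", "bcg_model"))
  })
}

#' @export
predict_proba.bcg_transformer <- function(model, X, ...) {
  X <- as.matrix(X)
  scores <- transformer_forward(model$params, X, training = FALSE,
                                tokenize = model$cfg$tokenize)
  p <- softmax_rows(scores)
  colnames(p) <- c("0", "1")
  p
}
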