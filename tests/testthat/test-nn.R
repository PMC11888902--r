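# white-box checks of the hand-rolled neural machinery via the package
# namespace (forward caches, analytic gradients, optimiser, schedules)
ns <- asNamespace("bcgscreen")

flatten <- function(p) unlist(p, use.names = FALSE)
unflatten <- function(template, v) {
  refold <- function(p) {
    if (is.list(p)) return(lapply(p, refold))
    n <- length(p); out <- v[1:n]; v <<- v[-(1:n)]
    if (!is.null(dim(p))) dim(out) <- dim(p)
    out
  }
  refold(template)
}

numeric_grad <- function(loss_fn, v0, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    vp <- v0; vp[i] <- vp[i] + eps
    vm <- v0; vm[i] <- vm[i] - eps
    (loss_fn(vp) - loss_fn(vm)) / (2 * eps)
  }, numeric(1))
}

test_that("FC+LSTM analytic gradients match finite differences", {
  set.seed(42)
  B <- 3; d <- 5
  X <- matrix(rnorm(B * d), B, d)
  y_idx <- c(1L, 2L, 1L)
  for (seq_len_ in c(1L, 2L)) {
    params <- ns$fclstm_init(d, 2L, seq_len = seq_len_)
    fwd <- ns$fclstm_forward_cache(params, X, training = FALSE, seq_len_)
    lg <- ns$ce_loss_grad(fwd$scores, y_idx)
    grads <- ns$fclstm_backward(params, fwd$cache, lg$grad)
    v0 <- flatten(params)
    g <- flatten(grads)
    expect_length(g, length(v0))
    set.seed(7)
    idx <- sample(length(v0), 40)
    loss_fn <- function(v) {
      f <- ns$fclstm_forward_cache(unflatten(params, v), X, FALSE, seq_len_)
      ns$ce_loss_grad(f$scores, y_idx)$loss
    }
    expect_lt(max(abs(numeric_grad(loss_fn, v0, idx) - g[idx])), 1e-7)
  }
})

test_that("Transformer analytic gradients match finite differences", {
  set.seed(42)
  B <- 2; d <- 4
  X <- matrix(rnorm(B * d), B, d)
  y_idx <- c(1L, 2L)
  for (mode in c("single", "per_feature")) {
    din <- if (mode == "per_feature") 1L else d
    set.seed(1)
    params <- ns$transformer_init(din, 2L)
    fwd <- ns$transformer_forward_cache(params, X, FALSE, mode)
    lg <- ns$ce_loss_grad(fwd$scores, y_idx)
    grads <- ns$transformer_backward(params, fwd$cache, lg$grad)
    v0 <- flatten(params)
    g <- flatten(grads)
    expect_length(g, length(v0))
    set.seed(7)
    idx <- sample(length(v0), 30)
    loss_fn <- function(v) {
      f <- ns$transformer_forward_cache(unflatten(params, v), X, FALSE, mode)
      ns$ce_loss_grad(f$scores, y_idx)$loss
    }
    expect_lt(max(abs(numeric_grad(loss_fn, v0, idx) - g[idx])), 1e-7)
  }
})

test_that("zero weights give zero scores and uniform probabilities", {
  d <- 6
  params <- ns$fclstm_init(d, 2L, 1L)
  zeroed <- unflatten(params, rep(0, length(flatten(params))))
  s <- fclstm_forward(zeroed, rnorm(d))
  expect_equal(unname(s), matrix(0, 1, 2))
  expect_equal(unname(ns$softmax_rows(s)), matrix(0.5, 1, 2))

  # transformer: zeroing the output layer suffices (layernorm keeps the
  # trunk nonzero, but the class scores collapse)
  set.seed(2)
  tp <- ns$transformer_init(d, 2L)
  tp$Wout[] <- 0
  tp$bout[] <- 0
  st <- transformer_forward(tp, rnorm(d))
  expect_equal(unname(st), matrix(0, 1, 2))
})

test_that("eval-mode forward passes are deterministic pure functions", {
  set.seed(3)
  d <- 8
  x <- rnorm(d)
  params <- ns$fclstm_init(d, 2L, 1L)
  expect_identical(fclstm_forward(params, x), fclstm_forward(params, x))
  tp <- ns$transformer_init(d, 2L)
  expect_identical(transformer_forward(tp, x), transformer_forward(tp, x))
})

test_that("the forward map is nonlinear in its input", {
  set.seed(4)
  d <- 8
  x <- rnorm(d)
  params <- ns$fclstm_init(d, 2L, 1L)
  s1 <- fclstm_forward(params, x)
  s2 <- fclstm_forward(params, 2 * x)
  expect_gt(max(abs(s2 - 2 * s1)), 1e-6)
})

test_that("permuting features with matching embedding columns is invariant", {
  set.seed(5)
  d <- 6
  x <- rnorm(d)
  params <- ns$transformer_init(d, 2L)
  perm <- sample(d)
  params_p <- params
  params_p$Wemb <- params$Wemb[, perm]
  expect_equal(transformer_forward(params_p, x[perm]),
               transformer_forward(params, x), tolerance = 1e-12)
})

test_that("softmax, dropout and the Adam kernel behave as specified", {
  expect_equal(ns$softmax_rows(matrix(0, 1, 2))[1, ], c(0.5, 0.5))
  z <- matrix(c(1, 3), 1, 2)
  p <- ns$softmax_rows(z)
  expect_lt(p[1, 1], p[1, 2])
  expect_equal(sum(p), 1)

  expect_null(ns$dropout_mask(c(4, 4), 0.1, training = FALSE))
  set.seed(1)
  m <- ns$dropout_mask(c(1000, 10), 0.1, training = TRUE)
  expect_true(all(m %in% c(0, 1 / 0.9)))
  expect_equal(mean(m > 0), 0.9, tolerance = 0.02)

  # one Adam step against the closed-form first update: p1 = p0 - lr*sign(g)
  p <- c(1, -2, 0.5); m0 <- numeric(3); v0 <- numeric(3); g <- c(0.3, -0.1, 2)
  ns$adam_update_inplace(p, m0, v0, g, 0.01, 0.9, 0.999, 1e-8, 1L)
  expect_equal(p, c(1, -2, 0.5) - 0.01 * sign(g), tolerance = 1e-4)
})

test_that("learning-rate schedules follow their published rules", {
  lrs <- vapply(1:35, function(e) ns$lr_step(0.001, e), numeric(1))
  expect_equal(unique(lrs), c(1e-3, 1e-4, 1e-5, 1e-6))
  expect_equal(lrs[10], 1e-3)   # change takes effect after epoch 10
  expect_equal(lrs[11], 1e-4)

  st <- ns$plateau_state(0.0005)
  losses <- rep(1, 7)
  trace <- numeric(length(losses))
  for (i in seq_along(losses)) {
    trace[i] <- st$lr
    st <- ns$plateau_update(st, losses[i])
  }
  # the rate halves once the loss has stagnated beyond the 3-epoch patience
  expect_equal(trace, c(rep(5e-4, 5), 2.5e-4, 2.5e-4))

  # an improving loss never triggers a cut
  st2 <- ns$plateau_state(0.0005)
  for (l in seq(1, 0.4, by = -0.1)) st2 <- ns$plateau_update(st2, l)
  expect_equal(st2$lr, 5e-4)
})
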