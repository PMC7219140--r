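# LSTM cell, bidirectional stack, and feed-forward engines.

test_that("lstm_step reproduces the gate equations in closed form", {
  # zero weights: sigmoid(0) = 0.5 gates, zero cell and hidden state
  p0 <- lstm_layer_params(2, 3)
  for (g in c("input_gate", "forget_gate", "output_gate", "cell")) {
    p0[[g]]$W[] <- 0; p0[[g]]$V[] <- 0; p0[[g]]$b[] <- 0
  }
  st <- lstm_step(c(1, -1), numeric(3), numeric(3), p0)
  expect_equal(st$c, rep(0, 3))
  expect_equal(st$h, rep(0, 3))

  # scalar case, W = 1, V = 0, b = 0, x = 1: hand-composed sigmoid/tanh
  p1 <- lstm_layer_params(1, 1)
  for (g in c("input_gate", "forget_gate", "output_gate", "cell")) {
    p1[[g]]$W[] <- 1; p1[[g]]$V[] <- 0; p1[[g]]$b[] <- 0
  }
  st <- lstm_step(1, 0, 0, p1)
  sig1 <- 1 / (1 + exp(-1))
  c_expect <- sig1 * tanh(1)          # f * 0 + i * tanh(candidate)
  h_expect <- sig1 * tanh(c_expect)
  expect_equal(st$c, c_expect, tolerance = 1e-10)
  expect_equal(st$h, h_expect, tolerance = 1e-10)
  # the 4-decimal reference values of this composition
  expect_equal(st$c, 0.5568, tolerance = 1e-3)
  expect_equal(st$h, 0.3697, tolerance = 1e-3)

  # hidden state is always strictly inside (-1, 1)
  p <- bilstm_params(3, hidden = 5, depth = 1, bidirectional = FALSE, seed = 2)
  st <- lstm_step(rnorm(3) * 10, rnorm(5), rnorm(5) * 5, p$layers[[1]]$fwd)
  expect_true(all(abs(st$h) < 1))

  expect_error(lstm_step(c(1, 2, 3, 4), numeric(5), numeric(5), p$layers[[1]]$fwd),
               "length 3")
  expect_error(lstm_step(rnorm(3), numeric(2), numeric(2), p$layers[[1]]$fwd),
               "hidden size")
})

test_that("bilstm_predict agrees with a manual composition of lstm_step", {
  set.seed(31)
  p <- bilstm_params(2, hidden = 4, depth = 1, bidirectional = TRUE, seed = 5)
  win <- matrix(rnorm(12), nrow = 6, ncol = 2)

  # forward stack left->right, backward stack right->left, readout at the
  # centre-flanking positions (p_f = 3, p_b = 4 for T = 6)
  run_dir <- function(lay, rows) {
    h <- numeric(4); cc <- numeric(4); hs <- list()
    for (r in rows) {
      st <- lstm_step(win[r, ], h, cc, lay)
      h <- st$h; cc <- st$c
      hs[[r]] <- h
    }
    hs
  }
  hf <- run_dir(p$layers[[1]]$fwd, 1:6)
  hb <- run_dir(p$layers[[1]]$bwd, 6:1)
  manual <- sum(p$readout$w * c(hf[[3]], hb[[4]])) + p$readout$b
  expect_equal(bilstm_predict(win, p), manual, tolerance = 1e-12)

  # zero parameters everywhere -> prediction 0 for any window
  pz <- p
  for (l in seq_along(pz$layers)) {
    for (d in names(pz$layers[[l]])) {
      for (g in c("input_gate", "forget_gate", "output_gate", "cell")) {
        pz$layers[[l]][[d]][[g]]$W[] <- 0
        pz$layers[[l]][[d]][[g]]$V[] <- 0
        pz$layers[[l]][[d]][[g]]$b[] <- 0
      }
    }
  }
  pz$readout$w[] <- 0; pz$readout$b <- 0
  expect_equal(bilstm_predict(win, pz), 0)

  # backward stack zeroed + readout ignoring the backward half reduces to
  # the unidirectional engine on the same window
  pu <- bilstm_params(2, hidden = 4, depth = 1, bidirectional = FALSE, seed = 5)
  pr <- p
  pr$layers[[1]]$fwd <- pu$layers[[1]]$fwd
  pr$readout$w <- c(pu$readout$w, rep(0, 4))
  pr$readout$b <- pu$readout$b
  expect_equal(bilstm_predict(win, pr, p_f = 6),
               bilstm_predict(win, pu), tolerance = 1e-12)

  # single-timestep window: both stacks see the same single input
  w1 <- win[1, , drop = FALSE]
  stf <- lstm_step(w1[1, ], numeric(4), numeric(4), p$layers[[1]]$fwd)
  stb <- lstm_step(w1[1, ], numeric(4), numeric(4), p$layers[[1]]$bwd)
  expect_equal(bilstm_predict(w1, p),
               sum(p$readout$w * c(stf$h, stb$h)) + p$readout$b,
               tolerance = 1e-12)

  expect_error(bilstm_predict(matrix(numeric(0), 0, 2), p), "non-empty")
})

test_that("analytic gradients match finite differences", {
  fx <- random_windows(C = 2, T_len = 5, B = 3)
  p <- bilstm_params(2, hidden = 3, depth = 2, bidirectional = TRUE, seed = 17)
  pk <- bilstmgc:::pack_params(p)
  g <- bilstmgc:::cpp_lstm_grad(pk, fx$X, fx$y, 2L, 3L)
  loss_at <- function(pp) {
    pr <- bilstmgc:::cpp_lstm_predict(pp, fx$X, 2L, 3L)
    mean((pr - fx$y)^2)
  }
  eps <- 1e-6
  set.seed(4)
  worst <- 0
  for (l in 1:2) for (d in c("fwd", "bwd")) for (m in c("W", "V", "b")) {
    M <- pk$layers[[l]][[d]][[m]]
    for (k in sample(length(M), 4)) {
      up <- pk; up$layers[[l]][[d]][[m]][k] <- M[k] + eps
      dn <- pk; dn$layers[[l]][[d]][[m]][k] <- M[k] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      ana <- g$grad$layers[[l]][[d]][[m]][k]
      worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("forward passes are pure and training is seed-reproducible", {
  fx <- random_windows(C = 3, T_len = 6, B = 8)
  p <- bilstm_params(3, hidden = 4, depth = 1, bidirectional = TRUE, seed = 3)
  pk <- bilstmgc:::pack_params(p)
  a <- bilstmgc:::cpp_lstm_predict(pk, fx$X, 3L, 4L)
  b <- bilstmgc:::cpp_lstm_predict(pk, fx$X, 3L, 4L)
  expect_identical(a, b)

  cfg <- predictor_config(epochs = 5, batch_size = 4, validation = 0, seed = 1)
  t1 <- bilstmgc:::train_windows(p, fx$X, fx$y, cfg, 3L, 4L, 21L)
  t2 <- bilstmgc:::train_windows(p, fx$X, fx$y, cfg, 3L, 4L, 21L)
  expect_identical(t1$params, t2$params)
  t3 <- bilstmgc:::train_windows(p, fx$X, fx$y, cfg, 3L, 4L, 22L)
  expect_false(identical(t1$params, t3$params))
})

test_that("a small bi-LSTM driven to convergence fits a noiseless AR(2)", {
  # deterministic resonant AR(2); 200 training samples
  n <- 260
  x <- numeric(n)
  x[1:2] <- c(0.5, -0.3)
  for (t in 3:n) x[t] <- 0.952 * x[t - 1] - 0.9025 * x[t - 2]
  xs <- matrix(x / sd(x), ncol = 1)
  S <- 8
  pos <- (S / 2 + 1):(n - S / 2)
  w <- bilstmgc:::lstm_windows(cbind(xs, xs), pos, S, TRUE)   # 2 identical channels
  y <- xs[pos, 1]
  p <- bilstm_params(2, hidden = 10, depth = 1, bidirectional = TRUE, seed = 8)
  cfg <- predictor_config(epochs = 300, learning_rate = 0.02, batch_size = Inf,
                          validation = 0, patience = 0, weight_decay = 0, seed = 8)
  tr <- bilstmgc:::train_windows(p, w$X, y, cfg, w$p_f, w$p_b, 8L)
  pred <- bilstmgc:::predict_windows(tr$params, w$X, w$p_f, w$p_b)
  expect_lt(mean((pred - y)^2), 0.01 * var(y))
})

test_that("the feed-forward engine has the stated shape and linear limit", {
  # hidden size = ceil(2/3 * input): 25 inputs -> 17 hidden units
  p <- feedforward_params(25, seed = 1)
  expect_equal(p$hidden, 17L)
  expect_equal(dim(p$W1), c(17L, 25L))

  # zero weights -> prediction equals the output bias
  p$W1[] <- 0; p$w2[] <- 0; p$b2 <- 1.5
  expect_equal(feedforward_predict(rnorm(25), p), 1.5)

  # linear activation + training reproduces an OLS autoregression fit
  set.seed(12)
  n <- 400
  x <- as.numeric(arima.sim(list(ar = 0.8), n + 3))
  X <- cbind(x[3:(n + 2)], x[2:(n + 1)], x[1:n])
  y <- x[4:(n + 3)]
  pl <- feedforward_params(3, hidden = 4, activation = "linear", seed = 2)
  cfg <- predictor_config(epochs = 400, learning_rate = 0.02, batch_size = Inf,
                          validation = 0, patience = 0, seed = 2)
  pl <- bilstmgc:::train_ffnn(pl, X, y, cfg, 2L)
  ols <- lm(y ~ X)
  expect_equal(mean((feedforward_predict(X, pl) - y)^2),
               mean(residuals(ols)^2), tolerance = 1e-3)
  expect_error(feedforward_predict(rnorm(4), pl), "3 values")
})

test_that("parameters survive a JSON round trip", {
  p <- bilstm_params(3, hidden = 4, depth = 2, bidirectional = TRUE, seed = 10)
  js <- params_to_json(p)
  q <- params_from_json(js)
  expect_equal(q, p, tolerance = 1e-12)
  win <- matrix(rnorm(18), 6, 3)
  expect_equal(bilstm_predict(win, q), bilstm_predict(win, p))

  f <- feedforward_params(5, seed = 3)
  f2 <- params_from_json(params_to_json(f))
  expect_equal(f2, f, tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".json")
  params_to_json(p, path)
  expect_equal(params_from_json(path), p, tolerance = 1e-12)
})
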