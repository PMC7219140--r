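# Granger-causality core: fitting, pair scores, matrices, detection.

test_that("the linear oracle reproduces an lm-based Granger computation", {
  sim <- sim_a_short()
  x <- sim$series
  cfg <- gc_config("linear_gc_oracle", model_order = 5, n_trials = 1, seed = 3)

  fit <- fit_full_model(x, "x2", cfg)
  expect_s3_class(fit, "gc_predictor")

  # independent route: lm() on a hand-assembled lagged data frame with the
  # same train/eval split and standardization
  x_std <- scale(x)
  pos <- 6:nrow(x_std)
  df <- data.frame(y = x_std[pos, 2])
  for (ch in 1:5) for (l in 1:5) {
    df[[paste0("c", ch, "l", l)]] <- x_std[pos - l, ch]
  }
  n_eval <- max(8, floor(length(pos) * 0.2))
  idx_eval <- (nrow(df) - n_eval + 1):nrow(df)
  # match the evaluation-window cap used by the package
  idx_eval <- idx_eval[round(seq(1, length(idx_eval), length.out = min(256, length(idx_eval))))]
  idx_train <- 1:(nrow(df) - n_eval)
  idx_train <- idx_train[round(seq(1, length(idx_train), length.out = min(1600, length(idx_train))))]
  ols <- lm(y ~ ., data = df[idx_train, ])
  pred <- predict(ols, newdata = df[idx_eval, ])
  err_full_lm <- mean((pred - df$y[idx_eval])^2)
  expect_equal(fit$err_full, err_full_lm, tolerance = 1e-8)

  # restricted model dropping channel 1's lags, retrain restriction
  cfg_rt <- gc_config("linear_gc_oracle", model_order = 5, n_trials = 1,
                      restriction = "retrain_without_channel", seed = 3)
  ols_r <- lm(y ~ ., data = df[idx_train, !grepl("^c1l", names(df))])
  pred_r <- predict(ols_r, newdata = df[idx_eval, ])
  err_res_lm <- mean((pred_r - df$y[idx_eval])^2)
  expect_equal(gc_pair(x, 1, 2, cfg_rt, signed = TRUE),
               log(err_res_lm / err_full_lm), tolerance = 1e-7)
})

test_that("a pure-noise target is unpredictable and irrelevant sources score ~0", {
  set.seed(9)
  x <- cbind(sim_a_short()$series[, 1:2], noise = rnorm(800))
  cfg <- gc_config("linear_gc_oracle", model_order = 5, n_trials = 1, seed = 2)
  fit <- fit_full_model(x, "noise", cfg)
  # residual variance ~ raw variance (standardized target: raw var = 1)
  expect_gt(fit$err_full, 0.85)
  expect_lt(fit$err_full, 1.25)
  # an independent noise channel scores near zero for a real target
  expect_lt(gc_pair(x, "noise", "x2", cfg), 0.05)
})

test_that("gc_pair validates inputs and flags perfect fits", {
  x <- sim_a_short()$series
  cfg <- linear_cfg()
  expect_error(gc_pair(x, 2, 2, cfg), "must differ")
  expect_error(fit_full_model(cbind(x, const = 1), "const", cfg), "constant")
  expect_error(fit_full_model(x[1:12, ], 1, cfg), "too short")

  # a target that equals another channel's lag-1 value is perfectly
  # predictable from the past window -> (numerically) zero residual
  det <- cbind(x[, 1:2], copy = c(0, x[-nrow(x), 1]))[-1, ]
  fit <- fit_full_model(det, "copy", gc_config("linear_gc_oracle", n_trials = 1))
  expect_error(bilstmgc:::gc_score(0.5, fit$err_full), "Perfect fit")
})

test_that("model A linear GC is directional: 1->2 positive, 2->1 not", {
  x <- simulate_gc_benchmark("A", n = 3000, seed = 15)$series
  cfg <- gc_config("linear_gc_oracle", model_order = 5, n_trials = 1,
                   restriction = "retrain_without_channel", seed = 15)
  s12 <- gc_pair(x, 1, 2, cfg, signed = TRUE)
  s21 <- gc_pair(x, 2, 1, cfg, signed = TRUE)
  expect_gt(s12, 0.2)
  expect_lt(s21, 0.05)

  # reversing time swaps the dominant direction
  xr <- x[nrow(x):1, ]
  expect_gt(gc_pair(xr, 2, 1, cfg, signed = TRUE), 0.2)
  expect_lt(gc_pair(xr, 1, 2, cfg, signed = TRUE), 0.05)
})

test_that("estimate_gc averages trials and respects channel relabelling", {
  cfg <- linear_cfg(n_trials = 2)
  x <- sim_a_short()$series
  gcm <- estimate_gc(x, cfg)
  expect_s3_class(gcm, "gc_matrix")
  expect_true(all(is.na(diag(gcm$values))))
  off <- gcm$values[row(gcm$values) != col(gcm$values)]
  expect_true(all(off >= 0))
  # averaging identical per-trial matrices returns that matrix
  expect_equal(gcm$values[1, 2], mean(pmax(gcm$per_trial[, 1, 2], 0)))

  # permuting channel order permutes rows/columns identically
  perm <- c(3, 1, 5, 2, 4)
  gcm_p <- estimate_gc(x[, perm], cfg)
  expect_equal(gcm_p$values, gcm$values[perm, perm], tolerance = 1e-10)

  td <- tidy(gcm)
  expect_equal(nrow(td), 20L)
  expect_equal(td$score[1], max(off))
  gl <- glance(gcm)
  expect_equal(gl$n_trials, 2L)
  expect_s3_class(autoplot(gcm), "ggplot")
})

test_that("fresh realisations per trial only happen for sim_spec inputs", {
  cfg <- linear_cfg(n_trials = 2)
  gcm_fixed <- estimate_gc(sim_a_short()$series, cfg)
  # fixed input + linear fits: trials are identical
  expect_equal(gcm_fixed$per_trial[1, , ], gcm_fixed$per_trial[2, , ])
  gcm_spec <- estimate_gc(sim_spec("A", n = 600), cfg)
  expect_false(isTRUE(all.equal(gcm_spec$per_trial[1, , ],
                                gcm_spec$per_trial[2, , ])))
})

test_that("edge detection modes behave: thresholds, nulls, empty matrices", {
  x <- sim_a_short()$series
  cfg <- linear_cfg(n_trials = 1)
  gcm <- estimate_gc(x, cfg)

  thr <- detect_edges(gcm, gc_config("linear_gc_oracle", n_trials = 1, seed = 7,
                                     detection = detection_spec("fixed_threshold",
                                                                threshold = 1e6)))
  expect_equal(sum(tidy(thr)$detected), 0L)

  det <- detect_edges(gcm)
  tb <- tidy(det)
  expect_true(all(tb$p_value > 0 & tb$p_value <= 1))
  expect_true(all(tb$detected == (tb$p_value <= 0.05)))
  expect_s3_class(glance(det), "tbl_df")
  expect_s3_class(autoplot(det), "ggplot")

  expect_error(detection_spec(n_permutations = 10), ">= 20")
  expect_error(detection_spec(alpha = 1.2))
  expect_error(detection_spec("fixed_threshold"), "threshold")

  gcm$trials <- NULL
  expect_error(detect_edges(gcm), "keep_models")
})

test_that("linear GC on model A recovers the true edges via the permutation null", {
  cfg <- gc_config("linear_gc_oracle", model_order = 5, n_trials = 6,
                   restriction = "retrain_without_channel",
                   detection = detection_spec(n_permutations = 59), seed = 31)
  det <- detect_edges(estimate_gc(sim_spec("A", n = 2500), cfg))
  sc <- score_detection(det, ground_truth_edges("A"))
  expect_equal(sc$true_positives, 5L)
  expect_lte(sc$false_positives, 1L)
})

test_that("score_detection counts hits against ground truth", {
  tab <- tibble::tibble(source = c(1L, 1L, 2L), target = c(2L, 3L, 1L),
                        source_label = "s", target_label = "t",
                        score = 1, log_ratio = 1, null_q = 0, p_value = 0.01,
                        detected = c(TRUE, TRUE, FALSE))
  fake <- bilstmgc:::new_gc_detection(tab, list(estimator = "x"), detection_spec())
  truth <- tibble::tibble(source = c(1L, 2L), target = c(2L, 1L))
  sc <- score_detection(fake, truth)
  expect_equal(sc$true_positives, 1L)
  expect_equal(sc$false_positives, 1L)
  expect_equal(sc$false_negatives, 1L)
  expect_equal(sc$recall, 0.5)
})
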