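# Band filtering, stationarity preprocessing, montage, stable dependencies,
# region summaries, synthetic cohorts.

test_that("the montage has 34 electrodes in 10 regions with the printed assignments", {
  m <- montage_1020()
  expect_equal(nrow(m), 34L)
  expect_equal(anyDuplicated(tolower(m$electrode)), 0L)
  expect_equal(dplyr::n_distinct(m$region), 10L)

  by_region <- split(m$electrode, m$region)
  expect_setequal(by_region$prefrontal, c("Fp1", "Fp2"))
  expect_setequal(by_region$frontal, c("F7", "F3", "Fz", "F4", "F8"))
  expect_setequal(by_region$central, c("C3", "Cz", "C4"))
  expect_setequal(by_region$`frontal-central`,
                  c("FT9", "FT7", "FC3", "FCz", "FC4", "FT8", "FT10"))
  expect_setequal(by_region$temporal, c("T3", "T4", "T5", "T6"))
  expect_setequal(by_region$`temporal-parietal`, c("TP7", "TP8"))
  expect_setequal(by_region$parietal, c("P3", "Pz", "P4"))
  expect_setequal(by_region$`central-parietal`, c("CP3", "CPz", "CP4"))
  expect_setequal(by_region$`parietal-occipital`, c("PO1", "PO2"))
  expect_setequal(by_region$occipital, c("O1", "O2", "Oz"))
})

test_that("electrode-to-region lookup is case-insensitive and strict", {
  expect_equal(map_electrode_region("FP1"), "prefrontal")
  expect_equal(map_electrode_region("Fp1"), "prefrontal")
  expect_equal(map_electrode_region("CPz"), "central-parietal")
  expect_equal(map_electrode_region(c("PZ", "oz")), c("parietal", "occipital"))
  expect_error(map_electrode_region("XX9"), "XX9")
})

test_that("the default filter bank has the five printed bands below Nyquist", {
  bk <- band_defaults()
  expect_equal(bk$band, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(bk$low, c(0.5, 4, 8, 13, 31))
  expect_equal(bk$high, c(3, 7, 13, 30, 50))
  for (fs in c(128, 1000)) {
    expect_true(all(bk$high < fs / 2), label = paste("fs", fs))
  }
})

test_that("the alpha bandpass passes 10 Hz, kills 45 Hz, and matches theory", {
  fs <- 128
  t <- (0:2047) / fs
  tone <- function(f) sin(2 * pi * f * t)

  y10 <- chebyshev_bandpass(tone(10), "alpha", fs)
  # two zero-phase passes square the 0.5 dB ripple: amplitude >= ~0.89
  expect_gt(max(abs(y10[500:1500])), 0.85)
  expect_lt(max(abs(y10[500:1500])), 1.05)

  y45 <- chebyshev_bandpass(tone(45), "alpha", fs)
  expect_lt(max(abs(y45[500:1500])) / max(abs(tone(45))), 10^(-40 / 20))

  expect_equal(chebyshev_bandpass(numeric(300), "alpha", fs), numeric(300))

  # single-pass response vs the analytic Chebyshev-I magnitude, within 3 dB
  for (f in c(10, 45)) {
    designed <- band_filter_gain_db(f, "alpha", fs)
    analytic <- 20 * log10(bilstmgc:::cheby1_analytic_gain(f, 8, 13, fs))
    expect_lt(abs(designed - analytic), 3)
  }

  expect_error(chebyshev_bandpass(tone(10), "gamma", 90), "Nyquist")
  expect_error(chebyshev_bandpass(tone(10), "omega", fs), "Unknown band")
})

test_that("filtering a matrix preserves shape and channel independence", {
  fs <- 128
  x <- matrix(rnorm(512 * 3), 512, 3, dimnames = list(NULL, c("Fp1", "C3", "O1")))
  y <- chebyshev_bandpass(x, "theta", fs)
  expect_equal(dim(y), dim(x))
  expect_equal(colnames(y), colnames(x))
  expect_equal(y[, 2], chebyshev_bandpass(x[, 2], "theta", fs))
})

test_that("preprocess removes trend and mean and flags unit roots", {
  set.seed(21)
  n <- 600
  x <- cbind(stationary = 5 + 0.01 * seq_len(n) + as.numeric(arima.sim(list(ar = 0.5), n)),
             walk = cumsum(rnorm(n)))
  out <- preprocess(x)
  v <- out$series[, "stationary"]
  expect_lt(abs(mean(v)), 1e-8)
  expect_lt(abs(coef(lm(v ~ seq_len(n)))[2]), 1e-3)
  rep <- out$report
  expect_false(rep$differenced[rep$channel == "stationary"])
  expect_true(rep$differenced[rep$channel == "walk"])
  expect_true(all(rep$stationary))

  expect_error(preprocess(x[1:50, ]), "at least 100")
})

test_that("a simulated AR(2) benchmark channel passes stationarity directly", {
  fails <- 0
  for (s in 1:20) {
    x1 <- simulate_gc_benchmark("A", n = 1000, seed = s)$series[, 1, drop = FALSE]
    rep <- preprocess(x1)$report
    fails <- fails + rep$differenced[1]
  }
  expect_lte(fails, 1)
})

test_that("stable_edges applies the count and t-test rules", {
  rec <- tibble::tibble(
    source = "Fp1", target = "C3", band = "theta",
    strength = rep(0.5, 12), detected = TRUE,
    subject = 1:12, segment = 1L
  )
  # constant strengths have zero sd: no t-test, dropped
  expect_equal(nrow(stable_edges(rec)), 0L)

  rec$strength <- 0.5 + rnorm(12, sd = 0.05)
  tab <- stable_edges(rec)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$occurrences, 12L)
  expect_lt(tab$p_value, 1e-6)

  # count rule is strict: > min_count
  expect_equal(nrow(stable_edges(rec, min_count = 12)), 0L)
  rec3 <- rec[1:3, ]
  rec3$strength <- rec3$strength + 10   # hugely significant but only 3 occurrences
  expect_equal(nrow(stable_edges(rec3, min_count = 10)), 0L)

  expect_error(stable_edges(rec[0, ]), "empty")
})

test_that("stable_edges recovers exactly a planted group from a noisy cohort table", {
  # brute-force oracle: construct records where one (source, target, band)
  # group has elevated strengths in 15 of 25 subjects, all others are
  # zero-mean noise, then recount by hand
  set.seed(77)
  pairs <- tidyr::expand_grid(source = c("Fp1", "F3", "P3"),
                              target = c("C3", "Cz", "O1"), band = c("theta", "alpha"))
  rec <- dplyr::cross_join(tibble::tibble(subject = 1:25), pairs)
  rec$strength <- rnorm(nrow(rec), 0, 0.2)
  rec$detected <- rec$strength > 0.35
  planted <- rec$source == "Fp1" & rec$target == "C3" & rec$band == "theta" &
    rec$subject <= 15
  rec$strength[planted] <- rec$strength[planted] + 1.2
  rec$detected[planted] <- TRUE

  tab <- stable_edges(rec, alpha = 1e-4, min_count = 10)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$source, "Fp1")
  expect_equal(tab$target, "C3")
  expect_equal(tab$band, "theta")
  expect_equal(tab$occurrences, sum(rec$detected[rec$source == "Fp1" &
                                                  rec$target == "C3" &
                                                  rec$band == "theta"]))
})

test_that("region flow fractions are normalised and match hand counts", {
  one <- tibble::tibble(source = "F3", target = "C3", band = "theta")
  s1 <- region_flow_summary(one)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$source_region, "frontal")
  expect_equal(s1$target_region, "central")
  expect_equal(s1$fraction, 1)

  ten <- tibble::tibble(
    source = c("F3", "F4", "Fz", "F7", "Fp1", "Fp2", "Fp1", "T3", "P3", "O1"),
    target = c("C3", "C4", "Cz", "C3", "CP3", "CPz", "CP4", "F3", "Fp1", "Oz"),
    band = "alpha"
  )
  s10 <- region_flow_summary(ten)
  expect_equal(sum(s10$fraction), 1, tolerance = 1e-9)
  expect_equal(s10$fraction[s10$source_region == "frontal" &
                              s10$target_region == "central"], 0.4)
  expect_equal(s10$fraction[s10$source_region == "prefrontal" &
                              s10$target_region == "central-parietal"], 0.3)
  expect_equal(s10$percent[1], 40)
  expect_error(region_flow_summary(one[0, ]), "no stable")
})

test_that("synthetic cohorts are reproducible and validate their inputs", {
  co1 <- synthesize_eeg_cohort(n_subjects = 2, n_segments = 2, seg_length = 256, seed = 4)
  co2 <- synthesize_eeg_cohort(n_subjects = 2, n_segments = 2, seg_length = 256, seed = 4)
  expect_identical(co1$series, co2$series)
  expect_equal(nrow(co1), 4L)
  expect_equal(dim(co1$series[[1]]), c(256L, 6L))

  bad <- tibble::tibble(source = "Fp1", target = "T6", band = "theta",
                        coefficient = 0.5, lag = 3)
  expect_error(synthesize_eeg_cohort(2, 1, planted_edges = bad, seg_length = 256),
               "T6")
  loop <- tibble::tibble(source = "Fp1", target = "Fp1", band = "theta",
                         coefficient = 0.5, lag = 3)
  expect_error(synthesize_eeg_cohort(2, 1, planted_edges = loop, seg_length = 256),
               "source != target")
})

test_that("a planted band-limited coupling is visible in the right band", {
  edge <- tibble::tibble(source = "Fp1", target = "C3", band = "theta",
                         coefficient = 0.8, lag = 3)
  co <- synthesize_eeg_cohort(n_subjects = 1, n_segments = 1, planted_edges = edge,
                              seg_length = 1024, seed = 6)
  x <- co$series[[1]]
  th <- chebyshev_bandpass(x, "theta", attr(co, "fs"))
  n <- nrow(th)
  lagged_cor <- function(m, lag) cor(m[1:(n - lag), "Fp1"], m[(1 + lag):n, "C3"])
  expect_gt(abs(lagged_cor(th, 3)), 0.3)
  al <- chebyshev_bandpass(x, "alpha", attr(co, "fs"))
  expect_lt(abs(lagged_cor(al, 3)), 0.15)
})
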