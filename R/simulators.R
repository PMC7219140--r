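#' Gaussian innovation specification for the benchmark simulators
#'
#' The benchmark generators drive every recursion with Gaussian innovations.
#' `noise_spec()` bundles their mean, variance, and the noise-stream policy
#' used by model C, whose printed equations reuse the innovation streams of
#' channels `x2` and `x4` inside the forward channels `y1` and `y2`.
#'
#' @param mean Innovation mean. Default 0.
#' @param variance Innovation variance, `>= 0`. Default 1. A variance of 0
#'   gives deterministic (noise-free) recursions, useful for fixed-point
#'   checks.
#' @param stream_policy `"independent_per_equation"` draws a fresh innovation
#'   stream for every equation, including the forward channels of model C;
#'   `"shared_as_written"` reuses the `x2`/`x4` streams inside `y1`/`y2`,
#'   following the model C equations literally. Shared streams induce
#'   instantaneous correlation between `x2` and `y1` (and `x4` and `y2`) on
#'   top of the lagged dependencies, so the independent policy is the
#'   default.
#' @return A list of class `noise_spec`.
#' @export
#' @examples
#' noise_spec()
#' noise_spec(variance = 0.5, stream_policy = "shared_as_written")
noise_spec <- function(mean = 0, variance = 1,
                       stream_policy = c("independent_per_equation", "shared_as_written")) {
  stream_policy <- match.arg(stream_policy)
  if (!is.numeric(variance) || length(variance) != 1 || !is.finite(variance) || variance < 0) {
    abort("`variance` must be a single finite number >= 0.")
  }
  if (!is.numeric(mean) || length(mean) != 1 || !is.finite(mean)) {
    abort("`mean` must be a single finite number.")
  }
  structure(list(mean = mean, variance = variance, stream_policy = stream_policy),
            class = "noise_spec")
}

# Coefficients of the three printed benchmark models, exposed as overridable
# constants (see simulate_gc_benchmark(coefficients=)).
benchmark_coefficients <- function() {
  list(
    x1_ar  = c(0.952, -0.9025),
    x2_a   = 0.5,   # model A: linear, lag 2
    x2_b   = 0.5,   # models B/C: quadratic, lag 10
    x3     = -0.4,  # lag 3
    x4_x1  = -0.5,  # lag 2
    x4_ar  = 0.252, # lag 1 (self)
    x4_x5  = 0.252, # lag 1
    x5_x4  = -0.252,
    x5_ar  = 0.252,
    y1_x1  = 0.6,   # forward, x1(t + 2)
    y2_x1  = -0.5,  # forward, x1(t + 2)
    y2_x4  = 0.252, # forward, x4(t + 1)
    y2_x5  = 0.252  # forward, x5(t + 1)
  )
}

#' Ground-truth directed dependencies of the benchmark models
#'
#' Returns the directed dependency set each simulator realises, excluding
#' self-dependencies. Negative lags denote forward (future) dependencies:
#' the source channel's *future* values determine the target's present.
#'
#' @param model `"A"`, `"B"`, or `"C"`.
#' @return A tibble with columns `source`, `target` (1-based channel
#'   indices), `source_label`, `target_label`, `lag` (samples; negative =
#'   forward), `form` (`"linear"`/`"quadratic"`), and `coefficient`.
#' @export
#' @examples
#' ground_truth_edges("A")
#' ground_truth_edges("C")
ground_truth_edges <- function(model = c("A", "B", "C")) {
  model <- match.arg(toupper(model), c("A", "B", "C"))
  cf <- benchmark_coefficients()
  base <- tibble(
    source = c(1L, 1L, 1L, 4L, 5L),
    target = c(2L, 3L, 4L, 5L, 4L),
    lag = c(2L, 3L, 2L, 1L, 1L),
    form = "linear",
    coefficient = c(cf$x2_a, cf$x3, cf$x4_x1, cf$x5_x4, cf$x4_x5)
  )
  edges <- switch(model,
    A = base,
    B = {
      b <- base
      b$lag[1] <- 10L
      b$form[1] <- "quadratic"
      b$coefficient[1] <- cf$x2_b
      b
    },
    C = {
      b <- base
      b$lag[1] <- 10L
      b$form[1] <- "quadratic"
      b$coefficient[1] <- cf$x2_b
      fwd <- tibble(
        source = c(1L, 1L, 4L, 5L),
        target = c(6L, 7L, 7L, 7L),
        lag = c(-2L, -2L, -1L, -1L),
        form = "linear",
        coefficient = c(cf$y1_x1, cf$y2_x1, cf$y2_x4, cf$y2_x5)
      )
      dplyr::bind_rows(b, fwd)
    }
  )
  labels <- channel_labels(model)
  edges$source_label <- labels[edges$source]
  edges$target_label <- labels[edges$target]
  dplyr::relocate(edges, "source", "target", "source_label", "target_label")
}

channel_labels <- function(model) {
  if (model == "C") c(paste0("x", 1:5), "y1", "y2") else paste0("x", 1:5)
}

#' Simulate a ground-truthed benchmark dataset
#'
#' Generates one realisation of the three benchmark dependency models used to
#' validate directed-connectivity estimators:
#'
#' * **Model A** — five channels with purely linear lagged dependencies;
#'   `x1` is a resonant AR(2) driver (`0.952, -0.9025`), feeding `x2`, `x3`,
#'   `x4` at lags 2-3, with a weak `x4`/`x5` feedback loop (`+-0.252`).
#' * **Model B** — as A, but the `1 -> 2` dependency becomes quadratic with a
#'   10-sample delay: `x2(t) = 0.5 x1^2(t - 10) + e2(t)`.
#' * **Model C** — model B plus two *forward* channels: `y1(t) = 0.6 x1(t+2)
#'   + e(t)` and `y2(t) = -0.5 x1(t+2) + 0.252 x4(t+1) + 0.252 x5(t+1) +
#'   e(t)`. Their dependence on future samples is only detectable by an
#'   acausal (bidirectional) regressor. The final samples of `y1`/`y2` have
#'   no future source available and are filled with standard-normal draws;
#'   the count is recorded in the result.
#'
#' All recursions start from zero initial conditions and a burn-in of
#' `burn_in` samples is generated and discarded so the returned window is
#' near-stationary. A fixed seed gives bit-identical output.
#'
#' @param model `"A"`, `"B"`, or `"C"`.
#' @param n Number of returned samples. Defaults to 5000 (A/B) or 5020 (C).
#'   Minimum 50 (52 for model C, which needs two future samples).
#' @param seed Integer seed.
#' @param noise A [noise_spec()].
#' @param burn_in Discarded leading samples (default 100).
#' @param coefficients Optional named list overriding entries of the printed
#'   model coefficients (see `bilstmgc:::benchmark_coefficients()`).
#' @return An object of class `sim_dataset`: a list with `series` (an
#'   `n x channels` numeric matrix, labelled columns), `truth` (the
#'   [ground_truth_edges()] tibble), `model`, `seed`, `n_random_fill`
#'   (model C terminal fills), and the `noise` spec.
#' @export
#' @examples
#' sim <- simulate_gc_benchmark("A", n = 500, seed = 1)
#' dim(sim$series)
#' sim$truth
simulate_gc_benchmark <- function(model = c("A", "B", "C"), n = NULL, seed = 1,
                                  noise = noise_spec(), burn_in = 100,
                                  coefficients = NULL) {
  model <- match.arg(toupper(model), c("A", "B", "C"))
  if (is.null(n)) n <- if (model == "C") 5020L else 5000L
  n <- as.integer(n)
  min_n <- if (model == "C") 52L else 50L
  if (!is_count(n, min = min_n)) {
    abort(sprintf("`n` must be an integer >= %d for model %s.", min_n, model))
  }
  if (!inherits(noise, "noise_spec")) abort("`noise` must be created by noise_spec().")
  if (!is_count(burn_in, min = 0)) abort("`burn_in` must be a non-negative integer.")
  cf <- benchmark_coefficients()
  if (!is.null(coefficients)) {
    unknown <- setdiff(names(coefficients), names(cf))
    if (length(unknown)) abort(paste0("Unknown coefficient name(s): ", paste(unknown, collapse = ", ")))
    cf <- modifyList(cf, coefficients)
  }

  total <- n + as.integer(burn_in)
  sdv <- sqrt(noise$variance)

  series <- with_seed(seed, {
    # Innovations for the five x equations, drawn up-front column-major so
    # the x block is identical across models B and C under the same seed.
    E <- matrix(rnorm(total * 5L, mean = noise$mean, sd = sdv), total, 5L)
    x <- matrix(0, total, 5L)
    quad <- model %in% c("B", "C")
    start <- if (quad) 11L else 4L
    if (start > 1L) for (t in seq_len(start - 1L)) x[t, ] <- E[t, ]
    for (t in start:total) {
      x[t, 1] <- cf$x1_ar[1] * x[t - 1, 1] + cf$x1_ar[2] * x[t - 2, 1] + E[t, 1]
      x[t, 2] <- if (quad) cf$x2_b * x[t - 10, 1]^2 + E[t, 2] else cf$x2_a * x[t - 2, 1] + E[t, 2]
      x[t, 3] <- cf$x3 * x[t - 3, 1] + E[t, 3]
      x[t, 4] <- cf$x4_x1 * x[t - 2, 1] + cf$x4_ar * x[t - 1, 4] + cf$x4_x5 * x[t - 1, 5] + E[t, 4]
      x[t, 5] <- cf$x5_x4 * x[t - 1, 4] + cf$x5_ar * x[t - 1, 5] + E[t, 5]
    }
    if (model == "C") {
      y <- matrix(0, total, 2L)
      shared <- noise$stream_policy == "shared_as_written"
      Ey <- if (shared) E[, c(2L, 4L)] else
        matrix(rnorm(total * 2L, mean = noise$mean, sd = sdv), total, 2L)
      fill1 <- (total - 1L):total    # y1 needs x1(t + 2)
      fill2 <- (total - 1L):total    # y2 needs x1(t + 2) as its longest lead
      ok1 <- seq_len(total - 2L)
      y[ok1, 1] <- cf$y1_x1 * x[ok1 + 2L, 1] + Ey[ok1, 1]
      y[ok1, 2] <- cf$y2_x1 * x[ok1 + 2L, 1] + cf$y2_x4 * x[ok1 + 1L, 4] +
        cf$y2_x5 * x[ok1 + 1L, 5] + Ey[ok1, 2]
      y[fill1, 1] <- rnorm(length(fill1))
      y[fill2, 2] <- rnorm(length(fill2))
      cbind(x, y)
    } else {
      x
    }
  })

  keep <- (total - n + 1L):total
  out <- series[keep, , drop = FALSE]
  colnames(out) <- channel_labels(model)
  structure(
    list(series = out,
         truth = ground_truth_edges(model),
         model = model, n = n, seed = as.integer(seed),
         noise = noise,
         n_random_fill = if (model == "C") 4L else 0L),
    class = "sim_dataset"
  )
}

#' A simulator specification for trial-resampled estimation
#'
#' [estimate_gc()] averages dependency scores over independent trials. When
#' the input is a `sim_spec` rather than a fixed matrix, every trial draws a
#' fresh realisation of the benchmark model (in addition to a fresh training
#' seed), mimicking repeated experiments on the generating process.
#'
#' @inheritParams simulate_gc_benchmark
#' @return An object of class `sim_spec`.
#' @export
#' @examples
#' sim_spec("B", n = 2000)
sim_spec <- function(model = c("A", "B", "C"), n = NULL, noise = noise_spec(),
                     burn_in = 100, coefficients = NULL) {
  model <- match.arg(toupper(model), c("A", "B", "C"))
  structure(list(model = model, n = n, noise = noise, burn_in = burn_in,
                 coefficients = coefficients),
            class = "sim_spec")
}

realise_spec <- function(spec, seed) {
  simulate_gc_benchmark(spec$model, n = spec$n, seed = seed, noise = spec$noise,
                        burn_in = spec$burn_in, coefficients = spec$coefficients)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> model %s: %d channels x %d samples (seed %d)\n",
              x$model, ncol(x$series), nrow(x$series), x$seed))
  cat(sprintf("  ground truth: %d directed dependencies (%d forward)\n",
              nrow(x$truth), sum(x$truth$lag < 0)))
  invisible(x)
}

#' @export
as_tibble.sim_dataset <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$series))
  dplyr::bind_cols(tibble(time = seq_len(nrow(out))), out)
}

#' @rdname simulate_gc_benchmark
#' @param object A `sim_dataset`.
#' @param ... Unused.
#' @export
autoplot.sim_dataset <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"time",
                            names_to = "channel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "sample", y = NULL,
                  title = sprintf("Benchmark model %s", object$model))
}
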