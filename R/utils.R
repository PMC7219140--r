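# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All user-facing randomness funnels
# through this so that fixed seeds give bit-identical output without
# clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible child seed from a root seed and a named substream,
# kept inside 32-bit integer range.
substream_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  val <- (as.double(seed) * 69069 + h * 9973 + as.double(index) * 101) %% 2147483629
  as.integer(val) + 1L
}

# Center and scale columns of a samples x channels matrix to unit variance.
# Constant columns are left centered with scale 1 (they carry no signal).
standardize_series <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[!is.finite(sdv) | sdv < .Machine$double.eps] <- 1
  out <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

# Validate a samples x channels numeric matrix with channel labels.
as_series_matrix <- function(x, arg = "series") {
  if (inherits(x, "sim_dataset")) x <- x$series
  if (is.data.frame(x)) {
    time_cols <- intersect(names(x), c("time", ".time"))
    x <- as.matrix(x[setdiff(names(x), time_cols)])
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric samples x channels matrix or data frame.", arg))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("ch", seq_len(ncol(x)))
  x
}
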