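# Internal helpers shared across the pipeline.

#' @importFrom stats rnorm runif median sd prcomp fft predict glm binomial
#'   as.formula complete.cases quantile cor filter aggregate
NULL

# Evaluate `expr` under a private RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministically fold a master seed and a stream index into a child seed
# below 2^31 (R integers are 32-bit). Multiplicative hash keeps streams with
# adjacent indices decorrelated.
derive_seed <- function(master, index) {
  m <- as.numeric(master) %% 2147483647
  i <- as.numeric(index) %% 2147483647
  as.integer((m * 48271 + i * 16807 + 12345) %% 2147483629 + 1)
}

# Centred moving average with reflected edges: zero phase, length preserving.
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L || length(x) < 2L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  n <- length(x)
  pad <- c(x[pmin(half:1, n)], x, x[pmax(n - seq_len(half) + 1L, 1L)])
  as.numeric(stats::filter(pad, rep(1 / width, width), sides = 2))[(half + 1L):(half + n)]
}

# Smooth each column of an n x 3 position matrix.
smooth_positions <- function(pos, width) {
  apply(pos, 2L, moving_average, width = width)
}

# Per-sample speed (m/s) from an n x 3 position matrix sampled at `fs` Hz.
# `halfwidth` > 1 uses a central difference over +/- halfwidth samples,
# trading a little temporal resolution for much lower velocity noise.
position_speed <- function(pos, fs, halfwidth = 1L) {
  n <- nrow(pos)
  h <- min(as.integer(halfwidth), n - 1L)
  hi <- pmin(seq_len(n) + h, n)
  lo <- pmax(seq_len(n) - h, 1L)
  d <- pos[hi, , drop = FALSE] - pos[lo, , drop = FALSE]
  sqrt(rowSums(d^2)) * fs / (hi - lo)
}

# Zero-phase Butterworth low-pass with odd-reflection padding at both ends,
# which suppresses the start/end transients plain filtfilt leaves on signals
# with non-zero boundary slope.
lowpass_zerophase <- function(x, cutoff_hz, fs, order = 2L) {
  n <- length(x)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  pad <- min(n - 1L, as.integer(3 * fs))
  head_pad <- 2 * x[1] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(pad + 1L):(pad + n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
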