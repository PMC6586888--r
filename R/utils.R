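# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
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
  expr
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / (n - 1L)))
}

# Analytic-signal magnitude via frequency-domain Hilbert transform.
analytic_envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Band-limited unit-variance Gaussian noise built in the frequency domain:
# independent complex-Gaussian coefficients on in-band bins, zero elsewhere.
band_limited_noise <- function(n, fs, f_low, f_high, n_series = 1L) {
  freqs <- (0:(n - 1L)) / n * fs
  half <- seq_len(floor(n / 2))                 # positive-frequency bins 1..n/2
  fpos <- freqs[half + 1L]
  in_band <- fpos >= f_low & fpos <= f_high
  k <- which(in_band)
  if (length(k) == 0L) {
    stop("band contains no Fourier bins at this length/sampling rate",
         call. = FALSE)
  }
  out <- matrix(0, nrow = n, ncol = n_series)
  nk <- length(k)
  for (j in seq_len(n_series)) {
    spec <- complex(real = stats::rnorm(nk), imaginary = stats::rnorm(nk))
    X <- complex(real = numeric(n), imaginary = numeric(n))
    X[k + 1L] <- spec
    X[n - k + 1L] <- Conj(spec)
    x <- Re(stats::fft(X, inverse = TRUE)) / n
    out[, j] <- x / stats::sd(x)
  }
  if (n_series == 1L) drop(out) else out
}

# Reflect-pad a vector by `pad` samples at each end.
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad <= 0L) return(x)
  c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
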