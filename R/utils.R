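# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so simulation functions are pure in (args, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Inverse FFT normalized so ifft(fft(x)) == x.
ifft <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Circular convolution of equal-length real vectors via the FFT.
circular_convolve <- function(x, h) {
  stopifnot(length(x) == length(h))
  Re(ifft(stats::fft(x) * stats::fft(h)))
}

# Roll a vector right by k samples (circular).
roll_right <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}

rms <- function(x) sqrt(mean(x^2))

# Zero-phase (forward-backward) IIR filtering with odd-reflection padding at
# both ends, so constant signals pass exactly and edge transients stay out
# of the signal proper.
zero_phase_filter <- function(flt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad > 0) {
    front <- 2 * x[1] - x[(pad + 1):2]
    back <- 2 * x[n] - x[(n - 1):(n - pad)]
    x <- c(front, x, back)
  }
  y <- as.numeric(signal::filter(flt, x))
  y <- rev(as.numeric(signal::filter(flt, rev(y))))
  y[(pad + 1):(pad + n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
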