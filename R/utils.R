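# Internal numerical helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the ambient RNG stream".
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of child seeds from one base seed; keeps values < 2^31.
deriveSeeds <- function(seed, n) {
  (as.numeric(seed) * 7919 + seq_len(n) * 104729) %% 2147483629 + 1
}

# Pink (1/f power) noise by spectral shaping: white Gaussian spectrum with
# amplitude ~ f^(-1/2) and random phases, rescaled to the requested sd.
pinkNoise <- function(n, sd) {
  if (sd <= 0 || n < 2) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)              # two-sided frequency index
  shape <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd
}

# Ongoing narrow-band Gaussian process: white noise restricted to [lo, hi] Hz
# by a hard spectral mask, rescaled so that its RMS matches a sinusoid of
# amplitude `amp` (sd = amp / sqrt(2)).  Linear in `amp` for a fixed RNG
# state, so band power scales exactly as amp^2.
narrowbandNoise <- function(n, sampleRate, band, amp) {
  w <- stats::rnorm(n)               # always consume RNG so seeds line up
  if (amp <= 0 || n < 4) return(numeric(n))
  W <- stats::fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * sampleRate / n
  W[f < band[1] | f > band[2]] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * (amp / sqrt(2))
}

# von Mises sampler (Best & Fisher rejection scheme).  kappa = 0 gives the
# uniform circular distribution; kappa = Inf degenerates to the mean angle.
rVonMises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (!is.finite(kappa)) return(rep(mu, n))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f)))
    }
  }
  out
}

# Cumulative event times of a homogeneous Poisson process on [0, duration).
rPoissonProcess <- function(rate, duration) {
  if (rate <= 0) return(numeric(0))
  n <- stats::rpois(1, rate * duration)
  sort(stats::runif(n, 0, duration))
}
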