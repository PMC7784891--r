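# Time-frequency decomposition: complex Morlet wavelet transform (power
# path) and Hann-window short-time Fourier transform with 60% overlap
# (intertrial-coherence path).  Both return aligned freq x time grids of
# complex coefficients.
#
# Normalization: the Morlet filter has unit gain at its centre frequency,
# so a sinusoid A*cos(2*pi*f*t) yields |W| = A/2 (analytic signal) and
# power A^2/4 at f; absolute power is only ever used in ratios and
# differences computed with the same estimator, so the gain convention
# cancels.

# cached-wavelet Morlet transform of the COLUMNS of a sample x segment
# matrix; returns list of complex [nSamples x nSegments] per frequency.
.morletMany <- function(segs, sampleRate, freqs, nCycles = 7) {
  n <- nrow(segs)
  hws <- integer(length(freqs))
  for (k in seq_along(freqs)) {
    sigma <- nCycles / (2 * pi * freqs[k])
    hws[k] <- ceiling(4 * sigma * sampleRate)
  }
  N <- stats::nextn(n + 2 * max(hws), 2)
  segPad <- rbind(segs, matrix(0, N - n, ncol(segs)))
  X <- stats::mvfft(segPad)
  out <- vector("list", length(freqs))
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sigma <- nCycles / (2 * pi * f)
    hw <- hws[k]
    tw <- (-hw:hw) / sampleRate
    env <- exp(-tw^2 / (2 * sigma^2))
    w <- env * exp(2i * pi * f * tw) / sum(env)
    wPad <- c(w, rep(0 + 0i, N - length(w)))
    Wf <- stats::fft(wPad)
    conv <- stats::mvfft(X * Wf, inverse = TRUE) / N
    out[[k]] <- conv[(hw + 1):(hw + n), , drop = FALSE]
  }
  out
}

# mean band power of each 200-ms-scale segment (columns of `segs`),
# Morlet estimator on an integer-Hz grid spanning `band`.
.bandSegmentPower <- function(segs, sampleRate, band, nCycles = 7) {
  freqs <- seq(ceiling(band[1]), floor(band[2]), by = 1)
  coef <- .morletMany(segs, sampleRate, freqs, nCycles)
  p <- 0
  for (k in seq_along(coef)) p <- p + colMeans(Mod(coef[[k]])^2)
  p / length(coef)
}

# Hann STFT of the COLUMNS of a sample x segment matrix.  Zero-padded to an
# nfft that puts the grid at 1-Hz spacing (nfft = sampleRate samples).
# Returns complex array [nFreq x nFrames x nSegments] plus grids.
.stftMany <- function(segs, sampleRate, windowSec = 0.2, overlap = 0.6,
                      freqRange = c(0, 100)) {
  n <- nrow(segs)
  win <- round(windowSec * sampleRate)
  if (win > n) stop("trace shorter than one STFT window")
  hop <- max(1L, round(win * (1 - overlap)))
  starts <- seq(1L, n - win + 1L, by = hop)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  nfft <- max(win, round(sampleRate))       # 1-Hz grid
  fAll <- (seq_len(nfft) - 1) * sampleRate / nfft
  keep <- which(fAll >= freqRange[1] & fAll <= min(freqRange[2], sampleRate / 2))
  nSeg <- ncol(segs)
  out <- array(0 + 0i, c(length(keep), length(starts), nSeg))
  frame <- matrix(0, nfft, nSeg)
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + win - 1L)
    frame[] <- 0
    frame[seq_len(win), ] <- segs[idx, , drop = FALSE] * hann
    F <- stats::mvfft(frame)
    out[, j, ] <- F[keep, ]
  }
  list(coef = out, freqs = fAll[keep],
       times = (starts - 1 + (win - 1) / 2) / sampleRate)
}

#' Time-frequency decomposition of a single trace
#'
#' Decomposes a trace with either a complex Morlet wavelet (7 cycles,
#' integer-Hz frequency steps; the power path) or a Hann-window STFT with
#' 60\% overlapping windows zero-padded to a 1-Hz grid (the phase /
#' intertrial-coherence path).
#'
#' @param trace numeric vector.
#' @param sampleRate sampling rate (Hz).
#' @param freqs frequency grid (Hz) for \code{method = "morlet"}; for
#'   "stft" it is interpreted as a range and the grid is the 1-Hz STFT
#'   grid inside it.
#' @param method "morlet" or "stft".
#' @param nCycles Morlet cycles (default 7).
#' @param windowSec,overlap STFT window length (s) and fractional overlap.
#' @return a [Spectrogram-class]; power is \code{specPower(x)}.
#' @examples
#' t <- seq(0, 1, by = 1/500)[-1]
#' sg <- tfDecompose(sin(2*pi*40*t), 500, freqs = 30:50)
#' which.max(rowMeans(specPower(sg)))   # peaks at 40 Hz
#' @export
tfDecompose <- function(trace, sampleRate, freqs = 1:100,
                        method = c("morlet", "stft"), nCycles = 7,
                        windowSec = 0.2, overlap = 0.6) {
  method <- match.arg(method)
  if (any(freqs > sampleRate / 2))
    stop("requested frequency above Nyquist (", sampleRate / 2, " Hz)")
  x <- matrix(as.numeric(trace), ncol = 1)
  if (method == "morlet") {
    fpos <- freqs[freqs > 0]
    if (length(trace) / sampleRate < 2 / min(fpos))
      stop("trace must cover at least 2 cycles of the lowest frequency")
    coef <- .morletMany(x, sampleRate, fpos, nCycles)
    vals <- t(vapply(coef, function(m) m[, 1], complex(length(trace))))
    new("Spectrogram", freqs = fpos,
        times = (seq_along(trace) - 1) / sampleRate, values = vals,
        method = "morlet", sampleRate = sampleRate)
  } else {
    s <- .stftMany(x, sampleRate, windowSec, overlap,
                   freqRange = range(freqs))
    vals <- matrix(s$coef[, , 1], nrow = length(s$freqs))
    new("Spectrogram", freqs = s$freqs, times = s$times, values = vals,
        method = "stft", sampleRate = sampleRate)
  }
}
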