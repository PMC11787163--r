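#' Generate a fractal (power-law) time series with a prescribed DFA exponent
#'
#' Spectral synthesis of a zero-mean, unit-variance Gaussian series whose
#' power spectral density follows \eqn{S(f) \propto f^{-\beta}} with
#' \eqn{\beta = 2\alpha - 1}, so that first-order detrended fluctuation
#' analysis of the series recovers scaling exponent \eqn{\alpha}.
#' \eqn{\alpha = 0.5} is white noise; \eqn{\alpha = 1.5} is ordinary Brownian
#' motion; the band \eqn{1 < \alpha < 1.5} is anti-persistent fractional
#' Brownian motion, the regime characteristic of healthy postural sway.
#'
#' The series is synthesised at twice the requested length with randomised
#' phases and a half-length segment is returned, which breaks the circular
#' periodicity of the inverse FFT and removes most of the finite-size bias in
#' the recovered exponent.
#'
#' @param n_samples Series length (at least 256 for a stable scaling regime).
#' @param alpha Target DFA exponent, in \[0.2, 1.8\].
#' @param seed RNG seed.
#' @return Numeric vector of length `n_samples`, zero mean, unit SD.
#' @examples
#' x <- generate_fractal_series(4096, alpha = 1.25, seed = 1)
#' dfa(x)$alpha
#' @export
generate_fractal_series <- function(n_samples, alpha, seed) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 256L) {
    stop("`n_samples` must be at least 256 for stable scaling", call. = FALSE)
  }
  if (alpha < 0.2 || alpha > 1.8) {
    stop("`alpha` must lie in [0.2, 1.8]", call. = FALSE)
  }
  beta <- 2 * alpha - 1
  local_rng(seed)
  m <- 2L * n_samples
  nf <- m %/% 2L
  f <- seq_len(nf) / m
  amp <- f^(-beta / 2)
  phase <- runif(nf - 1L, 0, 2 * pi)
  pos <- complex(modulus = amp[-nf], argument = phase)
  # Hermitian-symmetric spectrum: zero DC, real Nyquist bin.
  spec <- c(0 + 0i, pos, complex(real = amp[nf]), Conj(rev(pos)))
  x <- Re(fft(spec, inverse = TRUE)) / m
  x <- x[seq_len(n_samples)]
  x <- x - mean(x)
  x / sd(x)
}

#' Generate a white-noise auditory stimulus
#'
#' Gaussian noise with constant spectral density, the stimulus class used for
#' additive auditory stimulation in posturography experiments. Samples are
#' scaled to a stated RMS fraction of digital full scale; the physical
#' playback level (e.g. a nominal 75 dB SPL) is a property of the playback
#' chain and is carried as a metadata label only.
#'
#' @param duration Duration in seconds (> 0).
#' @param sampling_rate Audio sampling rate in Hz.
#' @param seed RNG seed.
#' @param rms_fraction Target RMS as a fraction of full scale (default 0.125,
#'   leaving ample headroom against clipping).
#' @param nominal_db_spl Nominal playback level label stored in the result.
#' @return A list of class `noise_audio` with elements `samples` (numeric,
#'   clipped to \[-1, 1\]), `sampling_rate`, `rms_fraction`, `nominal_db_spl`.
#' @export
generate_white_noise_audio <- function(duration, sampling_rate = 44100,
                                       seed = 1L, rms_fraction = 0.125,
                                       nominal_db_spl = 75) {
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  n <- round(duration * sampling_rate)
  local_rng(seed)
  x <- rnorm(n) * rms_fraction
  x[x > 1] <- 1; x[x < -1] <- -1
  structure(list(samples = x, sampling_rate = sampling_rate,
                 rms_fraction = rms_fraction, nominal_db_spl = nominal_db_spl),
            class = "noise_audio")
}

#' Write audio samples as a 16-bit PCM WAV file
#'
#' Minimal single-channel RIFF/WAVE writer for stimulus export.
#'
#' @param audio A `noise_audio` object or a numeric vector in \[-1, 1\].
#' @param path Output file path.
#' @param sampling_rate Sampling rate in Hz; taken from `audio` when it is a
#'   `noise_audio` object.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, sampling_rate = NULL) {
  if (inherits(audio, "noise_audio")) {
    sampling_rate <- audio$sampling_rate
    samples <- audio$samples
  } else {
    samples <- audio
    if (is.null(sampling_rate)) stop("`sampling_rate` required", call. = FALSE)
  }
  pcm <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sampling_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sampling_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
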