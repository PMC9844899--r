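# Acoustic feature extraction for diarisation.
#
# The diariser works on non-overlapping 0.2 s windows described by 35
# features: 13 MFCC means + 13 MFCC standard deviations aggregated over
# 25 ms / 10 ms sub-frames, plus mean fundamental frequency, frame energy,
# zero-crossing rate, spectral centroid, rolloff, flux, flatness, bandwidth
# and harmonic ratio computed on the window spectrum.  The exact feature
# list of ear-tuned toolchains varies; this set is fixed here as the
# documented default and can be subset via the model's feature spec.

mel_of <- function(f) 2595 * log10(1 + f / 700)
hz_of <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank: nfilt x (nfft/2 + 1)
mel_filterbank <- function(nfilt, nfft, sr, fmin = 50, fmax = sr / 2) {
  pts <- hz_of(seq(mel_of(fmin), mel_of(fmax), length.out = nfilt + 2))
  bins <- floor((nfft + 1) * pts / sr)
  fb <- matrix(0, nfilt, nfft / 2 + 1)
  for (m in seq_len(nfilt)) {
    lo <- bins[m]; ce <- bins[m + 1]; hi <- bins[m + 2]
    if (ce > lo) for (k in lo:ce) fb[m, k + 1] <- (k - lo) / (ce - lo)
    if (hi > ce) for (k in ce:hi) fb[m, k + 1] <- (hi - k) / (hi - ce)
  }
  fb
}

dct_matrix <- function(ncoef, nfilt) {
  outer(seq_len(ncoef), seq_len(nfilt) - 0.5,
        function(k, n) sqrt(2 / nfilt) * cos(pi * k * n / nfilt))
}

# power spectra of the columns of a frame matrix, chunked to bound memory
frame_power_spectra <- function(frames, nfft) {
  nf <- ncol(frames)
  out <- matrix(0, nfft / 2 + 1, nf)
  pad <- matrix(0, nfft - nrow(frames), ncol = 1)
  chunk <- max(1L, floor(2e6 / nfft))
  i <- 1L
  while (i <= nf) {
    j <- min(i + chunk - 1L, nf)
    block <- rbind(frames[, i:j, drop = FALSE],
                   matrix(0, nfft - nrow(frames), j - i + 1L))
    sp <- stats::mvfft(block)
    out[, i:j] <- Mod(sp[seq_len(nfft / 2 + 1), , drop = FALSE])^2
    i <- j + 1L
  }
  out
}

#' Extract per-window acoustic features
#'
#' @param w a [waveform()].
#' @param window analysis window in seconds (non-overlapping; 0.2 default).
#' @param n_mfcc number of cepstral coefficients (13).
#' @param n_mel number of mel filters (26).
#' @return an object of class `feature_matrix`: numeric matrix with one row
#'   per window and 35 named columns, plus attributes `times` (window
#'   centres, seconds), `window` and `sample_rate`.
#' @export
extract_features <- function(w, window = 0.2, n_mfcc = 13, n_mel = 26) {
  stop_if_not(inherits(w, "waveform"), "w must be a waveform")
  sr <- w$sample_rate
  stop_if_not(sr >= 4000, "sample_rate too low for the MFCC band")
  stop_if_not(w$duration >= window, "waveform shorter than one analysis window")
  wlen <- round(window * sr)
  nwin <- floor(length(w$samples) / wlen)
  x <- w$samples[seq_len(nwin * wlen)]
  M <- matrix(x, nrow = wlen)

  energy <- colMeans(M^2)
  sgn <- sign(M); sgn[sgn == 0] <- 1
  zcr <- colMeans(abs(diff(sgn)) > 0)
  zcr[energy < 1e-12] <- 0

  # window-level spectra
  nfft_w <- 2^ceiling(log2(wlen))
  P <- frame_power_spectra(M * (0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / wlen)),
                           nfft_w)
  freq <- (seq_len(nrow(P)) - 1) * sr / nfft_w
  tot <- colSums(P) + 1e-12
  centroid <- colSums(P * freq) / tot
  bandwidth <- sqrt(colSums(P * sweep(matrix(freq, nrow(P), ncol(P)), 2,
                                      centroid, "-")^2) / tot)
  cum <- apply(P, 2, cumsum)
  rolloff <- freq[max.col(t(cum >= 0.85 * rep(tot, each = nrow(P))) * 1,
                          ties.method = "first")]
  flatness <- exp(colMeans(log(P + 1e-12))) / (colMeans(P) + 1e-12)
  Pn <- sweep(P, 2, tot, "/")
  flux <- c(0, sqrt(colSums((Pn[, -1, drop = FALSE] -
                               Pn[, -ncol(Pn), drop = FALSE])^2)))
  # F0 by spectral peak in the voice band
  band <- which(freq >= 60 & freq <= 400)
  f0 <- freq[band][max.col(t(P[band, , drop = FALSE]), ties.method = "first")]
  f0[energy < 1e-10] <- 0
  # harmonic ratio: energy near the first four harmonics of f0
  hr <- numeric(nwin)
  db <- sr / nfft_w
  for (h in 1:4) {
    kb <- round(h * f0 / db) + 1
    for (dk in -1:1) {
      k <- pmin(pmax(kb + dk, 1), nrow(P))
      hr <- hr + P[cbind(k, seq_len(nwin))]
    }
  }
  hr <- hr / tot
  hr[f0 == 0] <- 0

  # MFCCs over 25 ms frames, 10 ms hop
  flen <- round(0.025 * sr); hop <- round(0.010 * sr)
  nframes <- max(1L, floor((length(x) - flen) / hop) + 1L)
  idx <- outer(seq_len(flen), (seq_len(nframes) - 1L) * hop, "+")
  frames <- matrix(x[idx], nrow = flen) *
    (0.54 - 0.46 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1)))
  nfft_f <- 2^ceiling(log2(flen))
  Pf <- frame_power_spectra(frames, nfft_f)
  fb <- mel_filterbank(n_mel, nfft_f, sr)
  mf <- dct_matrix(n_mfcc, n_mel) %*% log(fb %*% Pf + 1e-10)  # n_mfcc x nframes
  centre <- ((seq_len(nframes) - 1L) * hop + flen / 2) / sr
  wid <- pmin(floor(centre / window) + 1L, nwin)
  mfcc_mean <- t(vapply(seq_len(n_mfcc), function(k)
    as.numeric(tapply(mf[k, ], wid, mean)[as.character(seq_len(nwin))]),
    numeric(nwin)))
  mfcc_sd <- t(vapply(seq_len(n_mfcc), function(k) {
    v <- tapply(mf[k, ], wid, stats::sd)[as.character(seq_len(nwin))]
    as.numeric(v)
  }, numeric(nwin)))
  mfcc_mean[is.na(mfcc_mean)] <- 0
  mfcc_sd[is.na(mfcc_sd)] <- 0

  feats <- cbind(t(mfcc_mean), t(mfcc_sd), f0, energy, zcr, centroid,
                 rolloff, flux, flatness, bandwidth, harmonic_ratio = hr)
  colnames(feats) <- c(paste0("mfcc_mean_", seq_len(n_mfcc)),
                       paste0("mfcc_sd_", seq_len(n_mfcc)),
                       "f0_mean", "energy", "zcr", "centroid", "rolloff",
                       "flux", "flatness", "bandwidth", "harmonic_ratio")
  structure(feats,
            times = (seq_len(nwin) - 0.5) * window,
            window = window, sample_rate = sr,
            class = c("feature_matrix", "matrix", "array"))
}
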