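#' Least-squares linear-phase FIR design
#'
#' Classic band-integral least-squares design of a type-I (even order,
#' symmetric) FIR filter: minimizes the integrated squared error between
#' the zero-phase response and a piecewise-constant desired response over
#' the specified bands, leaving transition regions unconstrained. The
#' normal equations have the closed Toeplitz-plus-Hankel form in the
#' cosine basis.
#'
#' @param order filter order (even); the filter has `order + 1` taps.
#' @param bands matrix with rows `(f1, f2, desired, weight)` in Hz.
#' @param fs sampling rate in Hz.
#' @return numeric vector of `order + 1` taps (symmetric).
#' @export
design_firls <- function(order, bands, fs) {
  if (order %% 2 != 0) stop("order must be even (type-I design)")
  M <- order / 2
  w <- 2 * pi * bands[, 1:2, drop = FALSE] / fs  # radian edges
  # I(d) = integral of cos(d w) over each band
  dvec <- 0:(2 * M)
  Ifun <- function(d, w1, w2) {
    if (d == 0) return(w2 - w1)
    (sin(d * w2) - sin(d * w1)) / d
  }
  Iacc <- numeric(2 * M + 1)
  bacc <- numeric(M + 1)
  for (r in seq_len(nrow(bands))) {
    wt <- bands[r, 4]; des <- bands[r, 3]
    Ib <- vapply(dvec, Ifun, numeric(1), w1 = w[r, 1], w2 = w[r, 2])
    Iacc <- Iacc + wt * Ib
    bacc <- bacc + wt * des * Ib[seq_len(M + 1)]
  }
  k <- 0:M
  Q <- 0.5 * (matrix(Iacc[abs(outer(k, k, "-")) + 1], M + 1) +
                matrix(Iacc[outer(k, k, "+") + 1], M + 1))
  a <- solve(Q, bacc)
  h <- c(rev(a[-1]) / 2, a[1], a[-1] / 2)
  h
}

#' Zero-phase frequency response of a symmetric FIR
#' @param h taps (odd length, symmetric).
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return real amplitude response at `f`.
#' @export
fir_response <- function(h, f, fs) {
  M <- (length(h) - 1) / 2
  n <- -M:M
  vapply(f, function(fi) sum(h * cos(2 * pi * fi / fs * n)), numeric(1))
}

# FFT-based convolution with a symmetric FIR, delay-compensated
# (zero-phase per pass); x is a vector.
fft_filt <- function(x, h) {
  n <- length(x); L <- length(h); M <- (L - 1) / 2
  nfft <- stats::nextn(n + L - 1, 2)
  X <- fft(c(x, numeric(nfft - n)))
  H <- fft(c(h, numeric(nfft - L)))
  y <- Re(fft(X * H, inverse = TRUE)) / nfft
  y[(M + 1):(M + n)]
}

# cache FIR designs (keyed by parameters) to avoid re-solving
.fir_cache <- new.env(parent = emptyenv())

design_cached <- function(order, bands, fs) {
  key <- paste(c(order, as.vector(bands), fs), collapse = "_")
  if (is.null(.fir_cache[[key]]))
    .fir_cache[[key]] <- design_firls(order, bands, fs)
  .fir_cache[[key]]
}

#' Common-average reference
#'
#' Subtracts the instantaneous mean across channels from every channel.
#'
#' @param eeg a `continuous_eeg`.
#' @return re-referenced `continuous_eeg`.
#' @export
rereference_common_average <- function(eeg) {
  if (nrow(eeg$data) < 2) stop("need at least 2 channels")
  eeg$data <- sweep(eeg$data, 2, colMeans(eeg$data))
  eeg
}

#' Band-limit EEG with least-squares FIR filters
#'
#' High-pass (pass 0.5 Hz / stop 0.45 Hz) and low-pass (pass 25 Hz /
#' stop 27.5 Hz) least-squares FIR filters of the given orders, applied
#' zero-phase (forward-backward, so the effective attenuation is
#' squared and epoch latencies are untouched).
#'
#' @param eeg a `continuous_eeg`.
#' @param highpass `list(pass=, stop=, order=)` in Hz, or `NULL` to skip.
#' @param lowpass `list(pass=, stop=, order=)` in Hz, or `NULL` to skip.
#' @return filtered `continuous_eeg`.
#' @export
fir_bandlimit <- function(eeg,
                          highpass = list(pass = 0.5, stop = 0.45, order = 2000),
                          lowpass = list(pass = 25, stop = 27.5, order = 2000)) {
  fs <- eeg$sfreq
  n <- ncol(eeg$data)
  hs <- list()
  if (!is.null(highpass)) {
    if (highpass$order >= n) stop("high-pass order >= signal length")
    hs <- c(hs, list(design_cached(
      highpass$order,
      rbind(c(0, highpass$stop, 0, 1), c(highpass$pass, fs / 2, 1, 1)), fs)))
  }
  if (!is.null(lowpass)) {
    if (lowpass$order >= n) stop("low-pass order >= signal length")
    if (fs <= 2 * lowpass$stop) stop("sampling rate too low for the low-pass band")
    hs <- c(hs, list(design_cached(
      lowpass$order,
      rbind(c(0, lowpass$pass, 1, 1), c(lowpass$stop, fs / 2, 0, 1)), fs)))
  }
  for (h in hs) {
    P <- min(n - 1, length(h))
    for (ch in seq_len(nrow(eeg$data))) {
      x <- eeg$data[ch, ]
      xp <- c(2 * x[1] - rev(x[2:(P + 1)]), x, 2 * x[n] - rev(x[(n - P):(n - 1)]))
      y <- fft_filt(xp, h)          # forward
      y <- rev(fft_filt(rev(y), h)) # backward
      eeg$data[ch, ] <- y[(P + 1):(P + n)]
    }
  }
  eeg
}

#' Anti-aliased resampling to a lower rate
#'
#' Integer-factor decimation with a least-squares FIR anti-alias filter
#' (zero-phase), keeping sample 0 so event onsets in seconds are
#' unchanged. Upsampling and non-integer ratios are refused.
#'
#' @param eeg a `continuous_eeg`.
#' @param target_hz target sampling rate (default 128).
#' @return resampled `continuous_eeg`.
#' @export
resample_eeg <- function(eeg, target_hz = 128) {
  fs <- eeg$sfreq
  if (target_hz > fs) stop("upsampling is not supported")
  if (target_hz == fs) return(eeg)
  q <- fs / target_hz
  if (abs(q - round(q)) > 1e-9)
    stop("target rate must divide the current rate (integer decimation)")
  q <- as.integer(round(q))
  nyq <- target_hz / 2
  h <- design_cached(64L * q, rbind(c(0, 0.8 * nyq, 1, 1),
                                    c(nyq, fs / 2, 0, 1)), fs)
  n <- ncol(eeg$data)
  keep <- seq(1L, n, by = q)
  out <- matrix(0, nrow(eeg$data), length(keep))
  P <- min(n - 1, length(h))
  for (ch in seq_len(nrow(eeg$data))) {
    x <- eeg$data[ch, ]
    xp <- c(2 * x[1] - rev(x[2:(P + 1)]), x, 2 * x[n] - rev(x[(n - P):(n - 1)]))
    y <- fft_filt(xp, h)[(P + 1):(P + n)]
    out[ch, ] <- y[keep]
  }
  eeg$data <- out
  eeg$sfreq <- target_hz
  eeg
}

#' Normalize each channel over the whole recording
#'
#' Subtracts the per-channel mean and divides by the per-channel standard
#' deviation (z-units); later stages apply no further normalization.
#'
#' @param eeg a `continuous_eeg`.
#' @return normalized `continuous_eeg`.
#' @export
normalize_eeg <- function(eeg) {
  m <- rowMeans(eeg$data)
  s <- apply(eeg$data, 1, sd)
  flat <- which(s == 0)
  if (length(flat))
    stop("flat channel(s): ", paste(eeg$labels[flat], collapse = ", "))
  eeg$data <- (eeg$data - m) / s
  eeg
}

#' Phoneme-locked epoching
#'
#' Cuts fixed-length windows around phoneme onsets (default -0.2 to
#' 0.6 s; 103 samples at 128 Hz). Onsets are rounded to the nearest
#' sample; events whose window leaves the recording are dropped and
#' counted. No baseline correction and no post-epoch normalization.
#'
#' @param eeg a `continuous_eeg`.
#' @param events event data.frame with `onset_s`.
#' @param window `c(start, end)` seconds relative to onset.
#' @return object of class `eeg_epochs`: `data` (events x channels x
#'   times), `times_s`, `sfreq`, `events` (metadata of surviving rows),
#'   `labels`, `montage`.
#' @export
epoch_eeg <- function(eeg, events, window = c(-0.2, 0.6)) {
  fs <- eeg$sfreq
  n <- ncol(eeg$data)
  start_off <- round(window[1] * fs)
  n_t <- round((window[2] - window[1]) * fs) + 1
  onset_smp <- round(events$onset_s * fs)  # 0-based
  first <- onset_smp + start_off
  ok <- first >= 0 & (first + n_t - 1) < n
  if (sum(!ok))
    message(sum(!ok), " events dropped (epoch window outside recording)")
  if (!any(ok)) stop("no events survive epoching")
  first <- first[ok]
  data <- array(0, dim = c(sum(ok), nrow(eeg$data), n_t))
  for (i in seq_along(first))
    data[i, , ] <- eeg$data[, (first[i] + 1):(first[i] + n_t)]
  structure(list(data = data,
                 times_s = (start_off + 0:(n_t - 1)) / fs,
                 sfreq = fs,
                 events = events[ok, , drop = FALSE],
                 labels = eeg$labels, montage = eeg$montage),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("<eeg_epochs> ", dim(x$data)[1], " events x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " times (",
      signif(min(x$times_s), 3), " to ", signif(max(x$times_s), 3),
      " s @ ", x$sfreq, " Hz)\n", sep = "")
  invisible(x)
}

#' Evoked average of an epoch set
#' @param epochs an `eeg_epochs`.
#' @return channels x times matrix of the mean over events.
#' @export
evoked_average <- function(epochs) {
  if (dim(epochs$data)[1] < 1) stop("need at least one epoch")
  apply(epochs$data, c(2, 3), mean)
}

#' The full conditioning chain
#'
#' Fixed stage order: common-average reference, high-pass, low-pass,
#' resample to 128 Hz, per-channel normalization, phoneme-locked
#' epoching.
#'
#' @param eeg a `continuous_eeg`.
#' @param events phoneme events.
#' @param target_hz analysis rate (default 128).
#' @param filter_order FIR order for both filters. The default scales the
#'   study-standard order-2000-at-512-Hz design to the current rate so
#'   the impulse-response extent (~3.9 s) is rate-invariant.
#' @param window epoch window (default `c(-0.2, 0.6)`).
#' @return an `eeg_epochs`.
#' @export
preprocess_chain <- function(eeg, events, target_hz = 128,
                             filter_order = NULL, window = c(-0.2, 0.6)) {
  if (is.null(filter_order))
    filter_order <- 2L * round(2000 * eeg$sfreq / 512 / 2)
  eeg <- rereference_common_average(eeg)
  eeg <- fir_bandlimit(eeg,
                       highpass = list(pass = 0.5, stop = 0.45, order = filter_order),
                       lowpass = list(pass = 25, stop = 27.5, order = filter_order))
  eeg <- resample_eeg(eeg, target_hz)
  eeg <- normalize_eeg(eeg)
  epoch_eeg(eeg, events, window)
}
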