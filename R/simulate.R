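#' Simulation configuration
#'
#' Conditions for the synthetic continuous-speech EEG generator. The
#' defaults mirror the dynamics reported for natural story listening:
#' phonetic information is encoded for about 0.3 s after phoneme onset
#' (`encode_duration_s`), handed between neural ensembles every 0.08 s
#' (`dwell_tau_s`), with the cortical response starting ~0.05 s after
#' acoustic onset (`response_onset_s`).
#'
#' @param n_channels number of EEG channels (default 64).
#' @param sampling_rate_hz sampling rate (default 128).
#' @param n_subjects_per_group subjects per group (default 6).
#' @param n_words word tokens per subject recording (default 600).
#' @param dwell_tau_s pattern dwell time in seconds (default 0.08).
#' @param encode_duration_s total encoding duration D (default 0.3).
#' @param response_onset_s latency of the first response pattern (default 0.05).
#' @param snr response amplitude divided by noise standard deviation.
#' @param group_gain_profile named list of per-group step functions, each
#'   `list(times = <breaks, s since phoneme onset>, gains = <values in [0,1]>)`.
#' @param entropy_duration_bonus_s spread of encoding duration across the
#'   entropy range: realized duration is
#'   `D + bonus * (entropy quantile - 0.5)`, so high-uncertainty phonemes
#'   are encoded up to `bonus/2` longer and the mean stays D (default 0).
#'   A named list/vector gives a per-group bonus (groups absent from it
#'   get 0), which is how a group lacking the adaptive-encoding mechanism
#'   is simulated.
#' @param lead_in_s silent (noise-only) padding before the first and after
#'   the last phoneme, protecting filter edges (default 3).
#' @param seed master seed; per-subject seeds derive via [derive_seed()].
#' @return list of class `pd_sim_config`.
#' @export
sim_config <- function(n_channels = 64L, sampling_rate_hz = 128,
                       n_subjects_per_group = 6L, n_words = 600L,
                       dwell_tau_s = 0.08, encode_duration_s = 0.3,
                       response_onset_s = 0.05, snr = 2,
                       group_gain_profile = list(
                         control = list(times = 0, gains = 1)),
                       entropy_duration_bonus_s = 0,
                       lead_in_s = 3, seed = 1L) {
  stopifnot(dwell_tau_s <= encode_duration_s, dwell_tau_s > 0,
            sampling_rate_hz > 55)  # > 2x the 27.5 Hz low-pass stopband
  for (g in group_gain_profile)
    if (any(g$gains < 0 | g$gains > 1)) stop("gains must lie in [0, 1]")
  structure(list(n_channels = n_channels,
                 sampling_rate_hz = sampling_rate_hz,
                 n_subjects_per_group = n_subjects_per_group,
                 n_words = n_words,
                 dwell_tau_s = dwell_tau_s,
                 encode_duration_s = encode_duration_s,
                 response_onset_s = response_onset_s,
                 snr = snr,
                 group_gain_profile = group_gain_profile,
                 entropy_duration_bonus_s = entropy_duration_bonus_s,
                 lead_in_s = lead_in_s,
                 seed = seed),
            class = "pd_sim_config")
}

#' Ground-truth spatial patterns for the simulator
#'
#' One unit-norm spatial pattern per dwell interval per feature;
#' consecutive patterns are constructed mutually orthogonal, so the code
#' is dynamic by construction (|cosine| = 0 < 0.3 between neighbours).
#'
#' @param n_features number of decodable features.
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return list of class `pd_ground_truth` with `patterns` (list of
#'   channels x n_intervals matrices), `dwell_tau_s`, `encode_duration_s`.
#' @export
make_ground_truth <- function(n_features, cfg, seed = cfg$seed) {
  set.seed(seed)
  d_max <- cfg$encode_duration_s +
    0.5 * max(abs(unlist(cfg$entropy_duration_bonus_s)))
  K <- ceiling(d_max / cfg$dwell_tau_s - 1e-9)
  if (K > cfg$n_channels)
    stop("more dwell intervals than channels; cannot build distinct ensembles")
  patterns <- lapply(seq_len(n_features), function(f) {
    P <- matrix(0, cfg$n_channels, K)
    for (k in seq_len(K)) {
      v <- rnorm(cfg$n_channels)
      # distinct neural ensembles: orthogonalize against all previous
      # patterns of this feature so handoffs move to fresh populations
      if (k > 1) v <- v - P[, 1:(k - 1), drop = FALSE] %*%
          crossprod(P[, 1:(k - 1), drop = FALSE], v)
      P[, k] <- v / sqrt(sum(v^2))
    }
    P
  })
  structure(list(patterns = patterns, dwell_tau_s = cfg$dwell_tau_s,
                 encode_duration_s = cfg$encode_duration_s,
                 n_intervals = K),
            class = "pd_ground_truth")
}

# 1/f ("pink") noise via spectral shaping, unit variance per channel.
pink_noise <- function(n_channels, n_samples) {
  out <- matrix(0, n_channels, n_samples)
  f <- c(1, seq_len(n_samples - 1))   # avoid DC blow-up
  f <- pmin(f, n_samples - f + 1)     # symmetric (two-sided spectrum)
  amp <- 1 / sqrt(f)
  for (ch in seq_len(n_channels)) {
    spec <- fft(rnorm(n_samples)) * amp
    x <- Re(fft(spec, inverse = TRUE)) / n_samples
    out[ch, ] <- x / sd(x)
  }
  out
}

step_gain <- function(profile, u) {
  profile$gains[pmax(1L, findInterval(u, profile$times))]
}

#' Simulate one subject's continuous EEG
#'
#' Forward model: for every phoneme event and every phonetic feature
#' active on it, the feature's dwell-interval patterns are emitted in
#' sequence, each under a smooth half-sine amplitude envelope, scaled by
#' the group's gain profile (a step function of time since phoneme onset)
#' and the configured SNR; additive noise is an equal-power pink (1/f)
#' plus white mixture, iid across channels.
#'
#' @param events phoneme events (annotated if `entropy_duration_bonus_s`
#'   is nonzero).
#' @param features a `pd_feature_table` aligned with `events`.
#' @param truth a [make_ground_truth()] result.
#' @param cfg a [sim_config()].
#' @param group group label (must name an entry of
#'   `cfg$group_gain_profile`; unknown labels fall back to gain 1).
#' @param seed RNG seed for the noise (signal is deterministic given
#'   events/truth).
#' @return object of class `continuous_eeg`; the realized per-event
#'   encoding durations are attached as `$realized_duration_s`.
#' @export
simulate_subject <- function(events, features, truth, cfg, group = "control",
                             seed = cfg$seed) {
  if (nrow(features$matrix) != nrow(events))
    stop("feature table rows must match event count")
  set.seed(seed)
  fs <- cfg$sampling_rate_hz
  tau <- cfg$dwell_tau_s
  r0 <- cfg$response_onset_s
  gain <- cfg$group_gain_profile[[group]]
  if (is.null(gain)) gain <- list(times = 0, gains = 1)

  # realized encoding duration per event
  bonus <- cfg$entropy_duration_bonus_s
  if (length(bonus) > 1 || !is.null(names(bonus)))
    bonus <- if (group %in% names(bonus)) bonus[[group]] else 0
  D <- rep(cfg$encode_duration_s, nrow(events))
  if (bonus != 0) {
    e <- events$entropy_bits
    ok <- !is.na(e)
    if (any(ok)) {
      q <- rep(NA_real_, length(e))
      q[ok] <- (rank(e[ok], ties.method = "average") - 0.5) / sum(ok)
      D[ok] <- D[ok] + bonus * (q[ok] - 0.5)
    }
  }
  D <- pmax(D, tau)

  t_end <- max(events$onset_s + events$duration_s)
  n_samples <- ceiling((t_end + cfg$lead_in_s) * fs)
  n_trunc <- 0L

  K <- truth$n_intervals
  data <- matrix(0, cfg$n_channels, n_samples)
  for (f in seq_along(truth$patterns)) {
    active <- which(features$matrix[, f] == 1L)
    if (!length(active)) next
    src <- matrix(0, K, n_samples)
    smoothstep <- function(x) sin(pi / 2 * pmin(pmax(x, 0), 1))^2
    for (i in active) {
      on <- events$onset_s[i]
      # each pattern holds a plateau over its dwell interval
      # [k*tau, (k+1)*tau) with raised-cosine crossfades of width rho at
      # the handoffs (complementary, so total power stays constant) and
      # smooth onset/offset ramps at the edges of the encoding span
      rho <- min(tau / 2, 0.04)
      Ki <- ceiling(D[i] / tau - 1e-9)
      for (k in seq_len(Ki) - 1L) {
        lo <- k * tau
        hi <- min((k + 1) * tau, D[i])
        u0 <- r0 + if (k == 0) 0 else lo - rho / 2
        u1 <- r0 + if (k == Ki - 1L) D[i] else hi + rho / 2
        s0 <- round((on + u0) * fs)
        s1 <- round((on + u1) * fs) - 1L
        if (s0 >= n_samples) { n_trunc <- n_trunc + 1L; break }
        if (s1 >= n_samples) { s1 <- n_samples - 1L; n_trunc <- n_trunc + 1L }
        if (s1 < s0) next
        smp <- s0:s1
        u <- smp / fs - on          # time since phoneme onset
        ph <- u - r0                # phase within the encoding span
        rise <- if (k == 0) smoothstep(ph / rho) else
          smoothstep((ph - lo + rho / 2) / rho)
        fall <- if (k == Ki - 1L) smoothstep((D[i] - ph) / rho) else
          smoothstep((hi + rho / 2 - ph) / rho)
        src[k + 1L, smp + 1L] <- src[k + 1L, smp + 1L] +
          rise * fall * step_gain(gain, u)
      }
    }
    data <- data + cfg$snr * (truth$patterns[[f]] %*% src)
  }
  if (n_trunc) warning(n_trunc, " response segments truncated at signal end")

  noise <- (pink_noise(cfg$n_channels, n_samples) +
              matrix(rnorm(cfg$n_channels * n_samples), cfg$n_channels)) /
    sqrt(2)
  data <- data + noise

  montage <- synthetic_montage(cfg$n_channels)
  eeg <- continuous_eeg(data, fs, labels = montage$label, montage = montage)
  eeg$realized_duration_s <- D
  eeg$group <- group
  eeg
}

#' Continuous multichannel EEG container
#'
#' @param data channels x samples numeric matrix (finite values).
#' @param sfreq sampling rate in Hz.
#' @param labels channel labels.
#' @param montage optional montage data.frame ([synthetic_montage()]).
#' @return object of class `continuous_eeg`.
#' @export
continuous_eeg <- function(data, sfreq, labels = NULL, montage = NULL) {
  if (!all(is.finite(data))) stop("EEG data contains non-finite samples")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("channel labels must match channel count")
  structure(list(data = data, sfreq = sfreq, labels = labels,
                 montage = montage),
            class = "continuous_eeg")
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat("<continuous_eeg> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$sfreq, " Hz (", signif(ncol(x$data) / x$sfreq, 4),
      " s)\n", sep = "")
  invisible(x)
}

#' Simulate a full multi-subject dataset
#'
#' Generates a lexicon, samples each subject's phoneme stream, annotates
#' it (positions, cohort entropy, tertiles), builds and prunes the
#' feature table, and simulates continuous EEG per subject and group.
#'
#' @param cfg a [sim_config()].
#' @param groups character vector of group labels (defaults to the names
#'   of `cfg$group_gain_profile`).
#' @param lexicon optional fixed lexicon (generated from the master seed
#'   otherwise).
#' @param n_lexicon_words lexicon size when generating (default 250).
#' @param lexicon_zipf Zipf exponent of the generated lexicon (default 1).
#'   Flatter exponents reduce word-token repetition and with it the
#'   phoneme-label autocorrelation of the stimulus, which is the right
#'   regime when measuring recovery of the injected encoding duration.
#' @param feature_subset optional character vector restricting which
#'   pruned features are simulated and decoded (smaller = faster).
#' @return list of subject records: `eeg`, `events`, `features`, `truth`,
#'   `group`, `subject`.
#' @export
simulate_dataset <- function(cfg, groups = names(cfg$group_gain_profile),
                             lexicon = NULL, n_lexicon_words = 250L,
                             lexicon_zipf = 1, feature_subset = NULL) {
  if (is.null(lexicon))
    lexicon <- generate_lexicon(n_lexicon_words, zipf_exponent = lexicon_zipf,
                                seed = derive_seed(cfg$seed, 0L))
  subjects <- list()
  sid <- 0L
  for (g in groups) {
    for (s in seq_len(cfg$n_subjects_per_group)) {
      sid <- sid + 1L
      sd_i <- derive_seed(cfg$seed, sid)
      ev <- sample_utterance(lexicon, cfg$n_words, seed = sd_i,
                             t0 = cfg$lead_in_s)
      # tertiles can be degenerate on small/flat lexica; only analyses
      # that request entropy subsets actually need them
      ev <- suppressMessages(tryCatch(
        annotate_events(ev, lexicon),
        error = function(e) annotate_events(ev, lexicon, tertiles = FALSE)))
      ft <- prune_rare_features(build_feature_table(ev))
      if (!is.null(feature_subset))
        ft <- new_feature_table(
          ft$matrix[, intersect(feature_subset, ft$feature_names),
                    drop = FALSE])
      truth <- make_ground_truth(ncol(ft$matrix), cfg,
                                 seed = derive_seed(cfg$seed, 0L) + 1L)
      eeg <- simulate_subject(ev, ft, truth, cfg, group = g, seed = sd_i + 1L)
      subjects[[sid]] <- list(eeg = eeg, events = ev, features = ft,
                              truth = truth, group = g, subject = sid)
    }
  }
  subjects
}

#' Write / read ground truth as JSON
#'
#' Serializes the simulator's ground truth (per-feature spatial
#' patterns, dwell time, encoding duration) so a recovery analysis can
#' be compared against what was injected.
#'
#' @param truth a [make_ground_truth()] result.
#' @param path JSON file path.
#' @return `path` (writer) or a `pd_ground_truth` (reader).
#' @export
write_ground_truth <- function(truth, path) {
  n_channels <- nrow(truth$patterns[[1]])
  jsonlite::write_json(
    list(dwell_tau_s = truth$dwell_tau_s,
         encode_duration_s = truth$encode_duration_s,
         n_intervals = truth$n_intervals,
         n_channels = n_channels,
         patterns = lapply(truth$patterns, as.vector)),  # column-major
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pats <- if (is.list(x$patterns)) x$patterns else if (is.matrix(x$patterns))
    lapply(seq_len(nrow(x$patterns)), function(i) x$patterns[i, ]) else
    list(as.vector(x$patterns))
  structure(list(patterns = lapply(pats, function(v)
                   matrix(v, nrow = x$n_channels)),
                 dwell_tau_s = x$dwell_tau_s,
                 encode_duration_s = x$encode_duration_s,
                 n_intervals = x$n_intervals),
            class = "pd_ground_truth")
}

#' Write / read the continuous-EEG array container
#'
#' The container is a raw little-endian float64 array (`<prefix>.bin`,
#' column-major channels x samples) with a JSON sidecar
#' (`<prefix>.json`: channel count, sample count, rate, labels, montage
#' name). Events and lexica travel as TSV beside it.
#'
#' @param eeg a `continuous_eeg`.
#' @param prefix output path prefix (no extension).
#' @return `prefix` (writer) or a `continuous_eeg` (reader).
#' @export
write_eeg <- function(eeg, prefix) {
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(eeg$data), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(n_channels = nrow(eeg$data), n_samples = ncol(eeg$data),
         sampling_rate_hz = eeg$sfreq, labels = eeg$labels,
         montage = if (is.null(eeg$montage)) "none" else "synthetic-64"),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = meta$n_channels * meta$n_samples,
               size = 8, endian = "little")
  continuous_eeg(matrix(x, meta$n_channels, meta$n_samples),
                 meta$sampling_rate_hz, labels = meta$labels)
}
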