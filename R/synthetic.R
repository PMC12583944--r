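#' Specification of one synthetic hyperscanning session
#'
#' Describes a session of simultaneously recorded multi-subject EEG with
#' known ground truth: band-limited pairwise coherence between subjects,
#' planted large-amplitude artifacts, a communication-event schedule, and
#' per-subject recording-start lags (visible in the audio envelopes and in
#' the EEG sample alignment).
#'
#' Coherence is requested through \code{band_coherence}, a list of
#' components.  Each component is a list with fields \code{band}
#' (\code{"all"}, \code{"alpha"}, or \code{c(lo, hi)} in Hz), \code{coherence}
#' (target magnitude-squared coherence in \[0, 1)), \code{region}
#' (\code{"all"} or one of \code{"anterior"}, \code{"central"},
#' \code{"posterior"}), and \code{pairs} (\code{"all"} for a source shared by
#' every subject, or a list of 2-vectors of subject indices, each pair
#' receiving its own shared source).  Components must cover disjoint
#' frequency bins within a region.
#'
#' @param n_subjects number of subjects (default 6).
#' @param channel_labels montage (default \code{\link{default_montage}}).
#' @param fs sampling rate, Hz (default 125).
#' @param duration session length, seconds.
#' @param band_coherence list of coherence components (see Details).
#' @param artifact_rate expected artifacts per minute per channel.
#' @param artifact_amplitude artifact size as a multiple of the channel's
#'   baseline SD; must exceed 6 so planted artifacts trip the 6x golden-SD
#'   rule (default 10).
#' @param comm_schedule data.frame with columns \code{sender},
#'   \code{receiver} (subject indices), \code{start}, \code{end} (seconds
#'   from session start); default one event spanning most of the session.
#' @param audio_lags per-subject recording-start lag in ms (reference
#'   subject 1 should be 0); default all zero.
#' @param baseline_sd baseline channel SD in microvolts (default 10).
#' @param seed RNG seed.
#' @return An object of class \code{session_spec}.
#' @export
session_spec <- function(n_subjects = 6, channel_labels = default_montage(),
                         fs = 125, duration = 120, band_coherence = list(),
                         artifact_rate = 1, artifact_amplitude = 10,
                         comm_schedule = NULL, audio_lags = NULL,
                         baseline_sd = 10, seed = 1) {
  if (fs <= 0) stop("fs must be positive")
  if (duration < 1) stop("duration shorter than one epoch")
  if (artifact_amplitude <= 6)
    stop("artifact_amplitude must exceed 6 (the rejection threshold)")
  band_coherence <- lapply(band_coherence, normalize_coh_component,
                           n_subjects = n_subjects)
  for (comp in band_coherence)
    if (comp$coherence < 0 || comp$coherence >= 1)
      stop("coherence targets must lie in [0, 1)")
  if (is.null(comm_schedule))
    comm_schedule <- data.frame(sender = 1, receiver = 2,
                                start = 5, end = max(6, duration - 5))
  with(comm_schedule, {
    if (any(end <= start)) stop("communication events must have end > start")
    if (any(sender == receiver)) stop("schedule pairs must be distinct subjects")
    if (any(start < 0 | end > duration))
      stop("communication windows must lie within [0, duration]")
  })
  if (is.null(audio_lags)) audio_lags <- numeric(n_subjects)
  if (length(audio_lags) != n_subjects)
    stop("audio_lags must have one entry per subject")
  structure(list(n_subjects = n_subjects, channel_labels = channel_labels,
                 fs = fs, duration = duration, band_coherence = band_coherence,
                 artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude,
                 comm_schedule = comm_schedule, audio_lags = audio_lags,
                 baseline_sd = baseline_sd, seed = seed),
            class = "session_spec")
}

normalize_coh_component <- function(comp, n_subjects) {
  if (is.null(comp$band)) stop("coherence component needs a 'band'")
  rng <- if (is.character(comp$band))
    band_spec(comp$band)$bins[c(1, length(band_spec(comp$band)$bins))]
  else as.numeric(comp$band)
  comp$band_range <- rng
  if (is.null(comp$region)) comp$region <- "all"
  if (is.null(comp$pairs)) comp$pairs <- "all"
  if (!identical(comp$pairs, "all")) {
    subj <- unlist(comp$pairs)
    if (anyDuplicated(subj))
      stop("pair-specific coherence groups must involve disjoint subjects")
    if (any(subj < 1 | subj > n_subjects))
      stop("pair subject index out of range")
  }
  comp
}

# mixing weight from target magnitude-squared coherence: each subject's
# in-band content is w*shared + (1-w)*own with unit-variance parts, so the
# complex correlation between subjects is w^2/(w^2+(1-w)^2) and the
# magnitude-SQUARED coherence is its square; calibrate on sqrt(C).
coh_weight <- function(C) {
  if (C <= 0) return(0)
  b <- sqrt(C)
  rho <- sqrt(b / (1 - b))
  rho / (1 + rho)
}

# Spatial injection patterns.  The pipeline rereferences to the common
# average, which forces every source's region means to satisfy
# sum_r m_r * mean_r = 0 -- content cannot live in one region's mean alone.
# A component targeting one region therefore uses a zero-sum pattern: the
# target region carries the mixture at weight 1, a balancing region carries
# the counter-phase part, and the balancing region is masked by
# high-variance independent noise routed through a second zero-sum pattern
# (mask region iid, balancing region minus the mask-region sum), which
# leaves the target region untouched and keeps the mask region incoherent.
component_geometry <- function(region, rmap, channel_labels) {
  sizes <- lengths(rmap)
  idx <- lapply(rmap, match, table = channel_labels)
  p <- numeric(length(channel_labels))
  if (identical(region, "all")) {
    p[idx$anterior] <- 1
    p[idx$central] <- 1
    p[idx$posterior] <- -(sizes[["anterior"]] + sizes[["central"]]) /
      sizes[["posterior"]]
    return(list(pattern = p, mask_idx = integer(0), bal_idx = integer(0),
                mask_scale = 0))
  }
  others <- setdiff(names(rmap), region)
  bal <- others[which.max(sizes[others])]   # balancing region: the larger
  msk <- setdiff(others, bal)
  p[idx[[region]]] <- 1
  p[idx[[bal]]] <- -sizes[[region]] / sizes[[bal]]
  list(pattern = p, mask_idx = idx[[msk]], bal_idx = idx[[bal]],
       mask_m = sizes[[msk]], bal_m = sizes[[bal]],
       target_m = sizes[[region]])
}

#' Generate a synthetic EEG session
#'
#' Synthesizes per-subject 15-channel recordings with a 1/f (pink) baseline
#' spectrum and controllable band-limited pairwise coherence, then plants
#' high-amplitude artifacts (short spikes and 0.5-s square drifts) at
#' recorded epochs.  Coherence is injected spectrally: within a component's
#' band, every channel of a participating subject carries
#' \code{w*shared + (1-w)*subject-specific} complex spectra with matched
#' variance, so the pairwise magnitude-squared coherence equals
#' \code{w^2/(w^2+(1-w)^2)} per bin -- both per channel and after
#' region-averaging.  Recording-start lags shift each subject's sampling
#' window over a common underlying "world" signal, emulating devices started
#' at slightly different moments.
#'
#' @param spec a \code{\link{session_spec}}.
#' @param t0_unix nominal start timestamp written on every recording.
#' @return List with \code{recordings} (list of \code{eeg_recording}),
#'   \code{events} (data.frame \code{id, sender, receiver, start_unix,
#'   end_unix}), and \code{ground_truth} (planted coherence components,
#'   per-subject artifact epoch indices, true lags in ms and samples).
#' @export
generate_eeg_session <- function(spec, t0_unix = 0) {
  stopifnot(inherits(spec, "session_spec"))
  old <- mistate_save(); on.exit(mistate_restore(old))
  set.seed(as.integer(spec$seed %% .Machine$integer.max))

  fs <- spec$fs; n_sub <- spec$n_subjects
  lag_samples <- round(spec$audio_lags / 1000 * fs)
  pad <- max(0, max(lag_samples)) - min(0, min(lag_samples))
  # FFT-friendly world grid (truncated after synthesis)
  N <- stats::nextn(round(spec$duration * fs) + pad, 2)
  M <- (N - 1) %/% 2                            # usable half-spectrum bins
  freq <- seq_len(M) / (N / fs)                 # Hz of world FFT bins
  amp <- 1 / sqrt(pmax(freq, 0.25))             # pink baseline amplitude

  rmap <- region_map()
  cplx <- function(n) complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) /
    sqrt(2)

  # half-spectra: list over subjects of M x n_channels complex matrices
  n_ch <- length(spec$channel_labels)
  H <- lapply(seq_len(n_sub), function(s)
    matrix(cplx(M * n_ch), M, n_ch) * amp)

  covered <- rep(FALSE, M)           # bins replaced by a coherent component
  for (comp in spec$band_coherence) {
    rng <- comp$band_range
    bins <- which(freq >= rng[1] - 0.5 & freq < rng[2] + 0.5)
    if (any(covered[bins]))
      stop("coherence components overlap in band")
    covered[bins] <- TRUE
    nb <- length(bins)
    w <- coh_weight(comp$coherence)
    s0 <- sqrt(w^2 + (1 - w)^2)      # SD of the mixture
    geo <- component_geometry(comp$region, rmap, spec$channel_labels)
    groups <- if (identical(comp$pairs, "all")) list(seq_len(n_sub))
              else comp$pairs
    in_group <- unlist(groups)
    mixtures <- vector("list", n_sub)
    for (g in groups) {
      S <- cplx(nb)                            # shared source
      for (s in g)
        mixtures[[s]] <- w * S + (1 - w) * cplx(nb)
    }
    for (s in setdiff(seq_len(n_sub), in_group))
      mixtures[[s]] <- s0 * cplx(nb)           # matched-variance, unshared
    for (s in seq_len(n_sub)) {
      Hb <- outer(mixtures[[s]], geo$pattern) * amp[bins]
      if (length(geo$mask_idx)) {
        # masking noise: iid on the mask region, balanced on the balancing
        # region; variance set so the balancing region's coherent leak is
        # diluted to ~1/20 in amplitude
        sigma <- sqrt(19 * geo$target_m^2 * s0^2 / geo$mask_m)
        eta <- matrix(cplx(nb * geo$mask_m), nb, geo$mask_m) * sigma
        Hb[, geo$mask_idx] <- eta * amp[bins]
        Hb[, geo$bal_idx] <- Hb[, geo$bal_idx] -
          (rowSums(eta) / geo$bal_m) * amp[bins]
      }
      H[[s]][bins, ] <- Hb
    }
  }

  # world time series per subject, then per-subject sampling window by lag
  n_rec <- round(spec$duration * fs)
  offset0 <- -min(0, min(lag_samples))  # so every window stays in 1..N
  recordings <- vector("list", n_sub)
  artifact_epochs <- vector("list", n_sub)
  art_amp_mult <- spec$artifact_amplitude
  for (s in seq_len(n_sub)) {
    full <- matrix(0 + 0i, N, n_ch)
    full[1 + seq_len(M), ] <- H[[s]]
    full[N + 1 - seq_len(M), ] <- Conj(H[[s]])
    x <- Re(stats::mvfft(full, inverse = TRUE)) / N
    # one global scale to the baseline SD: per-channel scaling would break
    # the zero-sum spatial patterns that survive average rereferencing
    x <- x * spec$baseline_sd / mean(apply(x, 2, stats::sd))
    i0 <- offset0 + lag_samples[s]
    xs <- x[(i0 + 1):(i0 + n_rec), , drop = FALSE]

    # plant artifacts on the recorded window
    ep <- integer(0)
    n_art <- stats::rpois(n_ch, spec$artifact_rate * spec$duration / 60)
    for (ch in seq_len(n_ch)) {
      if (n_art[ch] == 0) next
      base <- stats::mad(xs[, ch])
      for (a in seq_len(n_art[ch])) {
        square <- stats::runif(1) < 0.2
        width <- if (square) round(0.5 * fs) else sample(3:5, 1)
        pos <- sample.int(n_rec - width, 1)
        ampl <- art_amp_mult * base * stats::runif(1, 1.0, 1.4) *
          sample(c(-1, 1), 1)
        xs[pos:(pos + width - 1), ch] <- xs[pos:(pos + width - 1), ch] + ampl
        ep <- c(ep, unique((pos:(pos + width - 1) - 1L) %/% as.integer(fs) + 1L))
      }
    }
    artifact_epochs[[s]] <- sort(unique(ep[ep <= n_rec %/% fs]))
    recordings[[s]] <- eeg_recording(xs, spec$channel_labels, fs = fs,
                                     subject = paste0("sub-", s),
                                     t0_unix = t0_unix, reference = "CPz")
  }
  names(recordings) <- paste0("sub-", seq_len(n_sub))
  names(artifact_epochs) <- names(recordings)

  events <- data.frame(id = seq_len(nrow(spec$comm_schedule)),
                       sender = spec$comm_schedule$sender,
                       receiver = spec$comm_schedule$receiver,
                       start_unix = t0_unix + spec$comm_schedule$start,
                       end_unix = t0_unix + spec$comm_schedule$end)

  list(recordings = recordings, events = events,
       ground_truth = list(coherence = spec$band_coherence,
                           artifact_epochs = artifact_epochs,
                           audio_lags_ms = spec$audio_lags,
                           audio_lag_samples = lag_samples))
}

#' Generate per-subject audio envelopes
#'
#' One shared broadband envelope (smoothed rectified noise) sampled by each
#' subject's device with its recording-start lag, plus small independent
#' measurement noise -- the signal used to recover inter-recording lags by
#' cross-correlation.
#'
#' @param spec a \code{\link{session_spec}}.
#' @param noise_sd measurement noise relative to the envelope's SD.
#' @return Numeric matrix, samples by subjects, at the EEG sampling rate.
#' @export
generate_audio_envelopes <- function(spec, noise_sd = 0.05) {
  stopifnot(inherits(spec, "session_spec"))
  old <- mistate_save(); on.exit(mistate_restore(old))
  set.seed(as.integer((spec$seed + 77003) %% .Machine$integer.max))
  fs <- spec$fs
  lag_samples <- round(spec$audio_lags / 1000 * fs)
  pad <- max(abs(lag_samples)) + 1
  n_rec <- round(spec$duration * fs)
  N <- n_rec + 2 * pad
  raw <- abs(stats::rnorm(N))
  win <- round(0.08 * fs)                     # ~80 ms smoothing
  e <- as.numeric(stats::filter(raw, rep(1 / win, win), sides = 2))
  e[is.na(e)] <- mean(e, na.rm = TRUE)
  out <- vapply(seq_len(spec$n_subjects), function(s) {
    i0 <- pad + lag_samples[s]
    e[(i0 + 1):(i0 + n_rec)] + stats::rnorm(n_rec, 0, noise_sd * stats::sd(e))
  }, numeric(n_rec))
  colnames(out) <- paste0("sub-", seq_len(spec$n_subjects))
  out
}
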