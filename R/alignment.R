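#' Estimate the lag between two recordings from audio envelopes
#'
#' Normalized cross-correlation between the reference subject's envelope and
#' another subject's, maximized over integer sample lags within
#' \code{±max_lag}.  A positive lag means the other device started recording
#' later than the reference (so shared content appears at earlier sample
#' indices in its file).
#'
#' @param env_ref,env_other numeric envelope series on a common sampling
#'   grid, at least 10 s long.
#' @param fs_audio envelope sampling rate, Hz.
#' @param max_lag search half-window in seconds (default 5).
#' @return Lag in milliseconds, with attributes \code{peak_corr} and
#'   \code{unreliable} (TRUE, with a warning, when the peak correlation is
#'   below 0.2).
#' @export
estimate_lag <- function(env_ref, env_other, fs_audio = 125, max_lag = 5) {
  n <- min(length(env_ref), length(env_other))
  if (n < 10 * fs_audio) stop("envelopes must be at least 10 s long")
  x <- env_ref[seq_len(n)]; y <- env_other[seq_len(n)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance envelope")
  L <- min(as.integer(round(max_lag * fs_audio)), n - 2)
  ks <- -L:L
  cc <- norm_xcorr(x, y, L)
  best <- which.max(cc)
  # device-start lag: content appearing earlier in `other` (negative shift
  # of the peak) means `other` started later
  lag_ms <- -ks[best] / fs_audio * 1000
  peak <- cc[best]
  unreliable <- peak < 0.2
  if (unreliable)
    warning("unreliable lag estimate: peak cross-correlation ",
            round(peak, 3), " < 0.2")
  structure(lag_ms, peak_corr = peak, unreliable = unreliable)
}

# Normalized (per-overlap Pearson) cross-correlation at integer lags
# -L..L, FFT for the lagged inner products and cumulative sums for the
# per-lag means/variances.  Index k+L+1 holds cor(x[t], y[t+k]).
norm_xcorr <- function(x, y, L) {
  n <- length(x)
  m <- stats::nextn(n + L + 1)
  X <- stats::fft(c(x, numeric(m - n)))
  Y <- stats::fft(c(y, numeric(m - n)))
  raw <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / m
  # raw[k+1] = sum_t x[t] y[t+k] for k >= 0; negative lags wrap at the end
  sxy <- c(raw[(m - L + 1):m], raw[1:(L + 1)])        # k = -L..L
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2)
  tot <- function(cs, a, b) cs[b] - if (a > 1) cs[a - 1] else 0
  vapply(-L:L, function(k) {
    if (k >= 0) { ax <- 1; bx <- n - k; ay <- 1 + k; by <- n }
    else        { ax <- 1 - k; bx <- n; ay <- 1; by <- n + k }
    nk <- bx - ax + 1
    sx <- tot(cx, ax, bx); sy <- tot(cy, ay, by)
    vx <- tot(cx2, ax, bx) - sx^2 / nk
    vy <- tot(cy2, ay, by) - sy^2 / nk
    if (vx <= 0 || vy <= 0) return(0)
    (sxy[k + L + 1] - sx * sy / nk) / sqrt(vx * vy)
  }, numeric(1))
}

#' Lag table for a session
#'
#' Estimates every subject's recording-start lag relative to the reference
#' subject (lag 0 by construction).
#'
#' @param envelopes matrix, samples by subjects (column names are subject
#'   ids).
#' @param fs_audio sampling rate, Hz.
#' @param reference reference column (index or name; default the first).
#' @param max_lag search half-window, seconds.
#' @return data.frame \code{subject, lag_ms, peak_corr, unreliable}.
#' @export
lag_table <- function(envelopes, fs_audio = 125, reference = 1, max_lag = 5) {
  subs <- colnames(envelopes)
  if (is.null(subs)) subs <- paste0("sub-", seq_len(ncol(envelopes)))
  ref_i <- if (is.character(reference)) match(reference, subs) else reference
  out <- lapply(seq_len(ncol(envelopes)), function(j) {
    if (j == ref_i)
      return(data.frame(subject = subs[j], lag_ms = 0, peak_corr = 1,
                        unreliable = FALSE))
    lg <- suppressWarnings(
      estimate_lag(envelopes[, ref_i], envelopes[, j], fs_audio, max_lag))
    data.frame(subject = subs[j], lag_ms = as.numeric(lg),
               peak_corr = attr(lg, "peak_corr"),
               unreliable = attr(lg, "unreliable"))
  })
  do.call(rbind, out)
}

#' Map events into one subject's recording timeline
#'
#' Shifts event start/end times by minus the subject's lag, converting
#' common-timeline (reference) annotations into positions on that subject's
#' own recording clock: a device that started \code{L} ms late sees a common
#' event \code{L} ms earlier on its local axis.
#'
#' @param events data.frame with \code{start_unix}, \code{end_unix} and
#'   subject columns \code{sender}/\code{receiver}.
#' @param lags a \code{\link{lag_table}} (or data.frame \code{subject,
#'   lag_ms}).
#' @param subject the subject whose timeline to map into.
#' @return The events with shifted \code{start_unix}/\code{end_unix};
#'   ordering is preserved.
#' @export
apply_lags <- function(events, lags, subject) {
  i <- match(subject, lags$subject)
  if (is.na(i)) stop("subject ", subject, " missing from lag table")
  shift <- lags$lag_ms[i] / 1000
  events$start_unix <- events$start_unix - shift
  events$end_unix <- events$end_unix - shift
  events
}

#' Align a session's recordings onto a common sample grid
#'
#' Trims the front of every recording according to its estimated lag so that
#' sample \code{i} refers to the same instant in all recordings, and trims
#' all to a common length.  The returned recordings carry an adjusted
#' \code{t0_unix} so event segmentation against the common timeline stays
#' correct.
#'
#' @param recordings named list of \code{eeg_recording}s.
#' @param lags a \code{\link{lag_table}} for the same subjects.
#' @return Named list of aligned \code{eeg_recording}s.
#' @export
align_recordings <- function(recordings, lags) {
  shifts <- round(lags$lag_ms[match(names(recordings), lags$subject)] / 1000 *
                  vapply(recordings, `[[`, 0, "fs"))
  if (anyNA(shifts)) stop("lag table missing some recorded subjects")
  t0_shift <- max(shifts)          # latest-starting device defines grid start
  offs <- t0_shift - shifts        # samples to drop from each front
  n_keep <- min(vapply(recordings, function(r) nrow(r$samples), 0L) - offs)
  out <- lapply(seq_along(recordings), function(j) {
    r <- recordings[[j]]
    r$samples <- r$samples[(offs[j] + 1):(offs[j] + n_keep), , drop = FALSE]
    r$t0_unix <- r$t0_unix + t0_shift / r$fs
    r
  })
  names(out) <- names(recordings)
  out
}

#' Sample window of a communication event within a recording
#'
#' Converts an event's time window into a 1-based half-open sample window
#' \code{[first, last+1)} on the recording grid.  Events that fall outside
#' the recording, or are shorter than one 1-s epoch after clipping, are
#' reported invalid rather than raising an error.
#'
#' @param rec an \code{eeg_recording}.
#' @param event one-row data.frame (or list) with \code{start_unix},
#'   \code{end_unix}.
#' @return List \code{first}, \code{last} (1-based inclusive sample bounds),
#'   \code{valid}.
#' @export
segment_eeg <- function(rec, event) {
  fs <- rec$fs
  n <- nrow(rec$samples)
  first <- ceiling((event$start_unix - rec$t0_unix) * fs) + 1
  last <- floor((event$end_unix - rec$t0_unix) * fs)     # half-open upper end
  first <- max(first, 1)
  last <- min(last, n)
  valid <- (last - first + 1) >= fs
  list(first = as.integer(first), last = as.integer(last), valid = valid)
}
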