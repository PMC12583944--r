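#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (\code{signal::filtfilt}), so the net response is zero-phase -- phase
#' preservation matters because cross-spectra downstream are phase sensitive.
#' The default 1-40 Hz passband is the standard broadband EEG range for this
#' pipeline.
#'
#' @param rec an \code{eeg_recording}.
#' @param lo,hi band edges in Hz; must satisfy \code{0 < lo < hi < fs/2}.
#' @param order Butterworth prototype order (default 4).
#' @return The filtered \code{eeg_recording}.
#' @export
bandpass <- function(rec, lo = 1, hi = 40, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi))
    stop("band edges must satisfy 0 < lo < hi")
  if (hi >= nyq)
    stop("upper band edge ", hi, " Hz is at or above the Nyquist frequency of ",
         format(nyq), " Hz (fs = ", format(rec$fs), " Hz)")
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  out <- rec$samples
  for (j in seq_len(ncol(out)))
    out[, j] <- signal::filtfilt(bf, out[, j])
  rec$samples <- out
  rec
}

#' Nyquist frequency
#' @param fs sampling rate in Hz.
#' @return \code{fs/2}.
#' @export
nyquist <- function(fs) fs / 2

#' Rereference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' each sample's channel mean is zero.  Requires at least 2 channels.
#'
#' @param rec an \code{eeg_recording} (reference \code{"CPz"}).
#' @return The rereferenced \code{eeg_recording} with
#'   \code{reference = "average"}.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$reference == "average") {
    warning("recording is already average-referenced; returning unchanged")
    return(rec)
  }
  if (ncol(rec$samples) < 2)
    stop("average reference undefined for a single-channel recording")
  rec$samples <- rec$samples - rowMeans(rec$samples)
  rec$reference <- "average"
  rec
}

#' Region map: channels grouped into three scalp regions
#'
#' Default lobe partition of the 15-channel montage: anterior (frontal),
#' central, posterior (parietal + occipital).  Subsets must be disjoint,
#' non-empty and drawn from the montage.
#'
#' @param anterior,central,posterior character vectors of channel labels.
#' @return A named list of class \code{region_map}.
#' @export
region_map <- function(anterior = c("Fp1", "Fp2", "F3", "Fz", "F4"),
                       central = c("C3", "Cz", "C4"),
                       posterior = c("P7", "P3", "Pz", "P4", "P8", "O1", "O2")) {
  m <- list(anterior = anterior, central = central, posterior = posterior)
  all_ch <- unlist(m)
  if (anyDuplicated(all_ch))
    stop("region subsets must be disjoint")
  if (any(lengths(m) == 0))
    stop("each region must contain at least one channel")
  structure(m, class = "region_map")
}

#' Average channels within each region
#'
#' Reduces a multichannel recording to one series per region by averaging the
#' member channels sample-wise, producing the per-region signals that enter
#' coherence estimation.
#'
#' @param rec an \code{eeg_recording}.
#' @param map a \code{\link{region_map}}.
#' @return Numeric matrix, time by region.
#' @export
region_signals <- function(rec, map = region_map()) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- vapply(map, function(ch) {
    absent <- setdiff(ch, rec$channel_labels)
    if (length(absent))
      stop("region channel(s) not in recording: ", paste(absent, collapse = ", "))
    rowMeans(rec$samples[, ch, drop = FALSE])
  }, numeric(nrow(rec$samples)))
  colnames(out) <- names(map)
  out
}

#' Golden SD: robust per-channel amplitude scale
#'
#' A per-channel variability estimate that is unbiased for Gaussian data and
#' resistant to artifact contamination: 1.4826 times the median absolute
#' deviation of the (filtered) recording.  It anchors the amplitude threshold
#' used to reject artifact epochs.
#'
#' @param rec an \code{eeg_recording}, ideally band-passed first.
#' @return Named numeric vector of per-channel robust SDs (class
#'   \code{golden_sd}).
#' @export
golden_sd <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  sds <- apply(rec$samples, 2, stats::mad)  # mad() already scales by 1.4826
  flat <- names(sds)[sds == 0]
  if (length(flat))
    stop("flat channel(s) with zero robust SD: ", paste(flat, collapse = ", "))
  structure(sds, class = "golden_sd")
}

#' Epoch a recording and flag artifact epochs
#'
#' Cuts the recording into contiguous non-overlapping 1-second epochs
#' (trailing partial epoch dropped) and flags an epoch as unclean when any
#' sample in any channel exceeds \code{mult} times that channel's golden SD
#' in absolute amplitude.
#'
#' @param rec an \code{eeg_recording} (filtered).
#' @param gsd a \code{\link{golden_sd}} vector for the same channels.
#' @param mult amplitude threshold multiplier (default 6).
#' @return An object of class \code{epoch_set}: list with \code{n_epochs},
#'   \code{fs}, \code{clean} (logical vector), \code{starts} (1-based first
#'   sample of each epoch).
#' @export
epoch_and_flag <- function(rec, gsd, mult = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- as.integer(round(rec$fs))
  n_ep <- nrow(rec$samples) %/% fs
  if (n_ep < 1) stop("recording shorter than one epoch")
  thr <- mult * as.numeric(gsd)[match(rec$channel_labels, names(gsd))]
  if (anyNA(thr)) stop("golden SD missing for some channels")
  exceed <- sweep(abs(rec$samples[seq_len(n_ep * fs), , drop = FALSE]),
                  2, thr, ">")
  ep_id <- rep(seq_len(n_ep), each = fs)
  bad <- rowsum(exceed + 0, ep_id) > 0
  clean <- rowSums(bad) == 0
  structure(list(n_epochs = n_ep, fs = fs, clean = unname(clean),
                 starts = (seq_len(n_ep) - 1L) * fs + 1L),
            class = "epoch_set")
}

#' Commonly clean epochs of a subject pair
#'
#' Epochs that pass the artifact rule simultaneously for both subjects; only
#' these enter pairwise coherence estimation.
#'
#' @param epochs_a,epochs_b \code{epoch_set}s on the same epoch grid.
#' @return Integer vector of (1-based) commonly clean epoch indices.
#' @export
common_clean <- function(epochs_a, epochs_b) {
  stopifnot(inherits(epochs_a, "epoch_set"), inherits(epochs_b, "epoch_set"))
  if (epochs_a$n_epochs != epochs_b$n_epochs || epochs_a$fs != epochs_b$fs)
    stop("mismatched epoch grids (", epochs_a$n_epochs, " vs ",
         epochs_b$n_epochs, " epochs)")
  which(epochs_a$clean & epochs_b$clean)
}

#' Extract epoch matrix from a signal
#'
#' Internal helper: given a single series and an epoch grid, return a
#' K-by-fs matrix whose rows are the selected epochs.
#'
#' @param x numeric series.
#' @param epochs integer vector of 1-based epoch indices.
#' @param fs samples per epoch.
#' @return numeric matrix, one row per epoch.
#' @export
epoch_matrix <- function(x, epochs, fs) {
  fs <- as.integer(round(fs))
  t(vapply(epochs, function(e) x[((e - 1L) * fs + 1L):(e * fs)],
           numeric(fs)))
}
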