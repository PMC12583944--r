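#' Standard 15-channel montage
#'
#' Electrode labels of the 10-20 montage used throughout the package, in
#' canonical order.
#'
#' @return Character vector of 15 channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F3", "Fz", "F4", "C3", "Cz", "C4",
    "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

#' Construct an EEG recording
#'
#' Container for one subject's continuous multichannel EEG: a samples-by-
#' channels matrix in microvolts with a uniform sampling rate and a start
#' timestamp.
#'
#' @param samples numeric matrix, time by channel, microvolts.
#' @param channel_labels character vector naming the columns.
#' @param fs sampling rate in Hz (default 125).
#' @param subject subject identifier.
#' @param t0_unix start time in seconds (unix epoch).
#' @param reference reference scheme: \code{"CPz"} (acquisition reference) or
#'   \code{"average"}.
#' @return An object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(samples, channel_labels = colnames(samples),
                          fs = 125, subject = "sub-1", t0_unix = 0,
                          reference = c("CPz", "average")) {
  reference <- match.arg(reference)
  samples <- as.matrix(samples)
  if (is.null(channel_labels))
    stop("channel_labels must be supplied")
  channel_labels <- as.character(channel_labels)
  if (ncol(samples) != length(channel_labels))
    stop("number of columns (", ncol(samples), ") does not match number of labels (",
         length(channel_labels), ")")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (anyNA(samples))
    stop("samples contain missing values")
  colnames(samples) <- channel_labels
  structure(list(samples = samples, channel_labels = channel_labels,
                 fs = fs, subject = subject, t0_unix = t0_unix,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> subject", x$subject, "\n")
  cat("  ", nrow(x$samples), "samples x", ncol(x$samples), "channels @",
      x$fs, "Hz (", round(nrow(x$samples) / x$fs, 2), "s )\n")
  cat("  reference:", x$reference, " t0:", format(x$t0_unix), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an \code{eeg_recording}.
#' @return length in seconds.
#' @export
rec_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Read / write EEG recordings as CSV
#'
#' The on-disk dialect is a plain CSV with a \code{unix_time} column followed
#' by one column per channel (microvolts).  Reading validates that every
#' expected channel is present and that timestamps are uniform.
#'
#' @param path file path.
#' @param expected_labels channel labels the file must contain (default the
#'   standard 15-channel montage); \code{NULL} to accept any.
#' @param subject subject id to attach; defaults to the file name stem.
#' @param reference reference scheme recorded in the file's metadata
#'   side-channel (not stored in the CSV; defaults to \code{"CPz"}).
#' @return \code{read_eeg_csv} returns an \code{eeg_recording};
#'   \code{write_eeg_csv} returns \code{path} invisibly.
#' @export
read_eeg_csv <- function(path, expected_labels = default_montage(),
                         subject = NULL, reference = "CPz") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"unix_time" %in% names(df))
    stop("missing 'unix_time' column in ", path)
  labs <- setdiff(names(df), "unix_time")
  if (!is.null(expected_labels)) {
    absent <- setdiff(expected_labels, labs)
    if (length(absent))
      stop("missing channel(s) in ", path, ": ", paste(absent, collapse = ", "))
    labs <- expected_labels
  }
  tt <- df$unix_time
  if (length(tt) < 2) stop("fewer than 2 samples in ", path)
  dt <- diff(tt)
  if (any(dt <= 0))
    stop("timestamps not strictly increasing at row ", which(dt <= 0)[1] + 1)
  med_dt <- stats::median(dt)
  bad <- which(abs(dt - med_dt) > 0.01 * med_dt)
  if (length(bad))
    stop("non-uniform sampling: gap of ", signif(dt[bad[1]], 6),
         " s at row ", bad[1] + 1, " (expected ", signif(med_dt, 6), " s)")
  if (is.null(subject))
    subject <- sub("_eeg\\.csv$", "", basename(path))
  fs <- 1 / med_dt
  # timestamps round-trip through decimal text; snap to an integer rate
  if (abs(fs - round(fs)) < 1e-3 * fs) fs <- round(fs)
  eeg_recording(as.matrix(df[labs]), labs, fs = fs,
                subject = subject, t0_unix = tt[1], reference = reference)
}

#' @rdname read_eeg_csv
#' @param rec an \code{eeg_recording} to write.
#' @export
write_eeg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  tt <- rec$t0_unix + (seq_len(nrow(rec$samples)) - 1) / rec$fs
  df <- data.frame(unix_time = tt, check.names = FALSE)
  df[rec$channel_labels] <- as.data.frame(rec$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
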