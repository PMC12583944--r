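#' Specification of a synthetic multi-session study
#'
#' A study is a set of sessions sharing one template \code{\link{session_spec}}.
#' Across sessions the target coherence of one designated component (band x
#' region, default anterior alpha) is drawn uniformly from \code{coh_range},
#' and the latent group teamwork score is coupled to that session-level
#' coherence through \code{link_slope}, so downstream correlation analyses
#' have a known planted effect (or a known null when the slope is 0).
#'
#' Rater scores follow the two-way random-effects model the ICC assumes:
#' score = subject effect + rater effect + error, with the supplied variance
#' components, mapped linearly into each (profession, topic) range and
#' clipped.  The implied single-rater ICC is
#' \code{var_subject / (var_subject + var_rater + var_error)} (plus the
#' planted link's share of subject variance).
#'
#' @param n_sessions number of sessions (>= 2).
#' @param session template \code{\link{session_spec}}.
#' @param coh_range range of the linked component's target coherence across
#'   sessions.
#' @param link list with \code{band} and \code{region} of the linked
#'   coherence component.
#' @param link_slope signed coupling between a session's planted coherence
#'   and its latent group score, in latent-SD units per unit coherence.
#' @param var_subject,var_rater,var_error variance components of the score
#'   generator (all >= 0).
#' @param random_lags draw per-session recording-start lags (reference
#'   subject 1 stays 0)?
#' @param lag_range_ms range of the random lags.
#' @param seed RNG seed.
#' @return An object of class \code{study_spec}.
#' @export
study_spec <- function(n_sessions = 10, session = session_spec(),
                       coh_range = c(0.05, 0.6),
                       link = list(band = "alpha", region = "anterior"),
                       link_slope = 0, var_subject = 0.5, var_rater = 0.1,
                       var_error = 0.4, random_lags = TRUE,
                       lag_range_ms = c(-400, 400), seed = 1) {
  if (n_sessions < 2) stop("need at least 2 sessions")
  if (any(c(var_subject, var_rater, var_error) < 0))
    stop("variance components must be nonnegative")
  if (any(coh_range < 0) || any(coh_range >= 1))
    stop("coherence range must lie in [0, 1)")
  structure(list(n_sessions = n_sessions, session = session,
                 coh_range = coh_range, link = link, link_slope = link_slope,
                 var_subject = var_subject, var_rater = var_rater,
                 var_error = var_error, random_lags = random_lags,
                 lag_range_ms = lag_range_ms, seed = seed),
            class = "study_spec")
}

#' Generate two-rater TeamSTEPPS scores with known reliability
#'
#' Draws scores from the two-way random-effects model (see
#' \code{\link{study_spec}}), optionally coupling every profession's subject
#' effect in a session to that session's planted coherence.
#'
#' @param study a \code{\link{study_spec}}.
#' @param session_coherence per-session planted coherence values driving the
#'   latent group score (default none: null link).
#' @param ranges topic range table (\code{\link{default_topic_ranges}}).
#' @return List: \code{table} (long data.frame \code{session, profession,
#'   rater, topic, score}) and \code{ground_truth} (latent group scores,
#'   implied single-rater ICC, link sign).
#' @export
generate_rater_scores <- function(study, session_coherence = NULL,
                                  ranges = default_topic_ranges()) {
  stopifnot(inherits(study, "study_spec"))
  old <- mistate_save(); on.exit(mistate_restore(old))
  set.seed(as.integer((study$seed + 40087) %% .Machine$integer.max))
  n <- study$n_sessions
  if (is.null(session_coherence)) session_coherence <- numeric(n)
  if (length(session_coherence) != n)
    stop("session_coherence must have one value per session")
  g <- study$link_slope * (session_coherence - mean(session_coherence))
  sd_g <- stats::sd(g)
  sd_lat <- sqrt(study$var_subject + study$var_rater + study$var_error +
                 if (is.na(sd_g)) 0 else sd_g^2)
  if (sd_lat == 0) sd_lat <- 1
  prof <- unique(ranges$profession)
  topics <- teamstepps_topics()
  rows <- list()
  for (p in prof) {
    for (tp in topics) {
      rg <- ranges[ranges$profession == p & ranges$topic == tp, ]
      a <- stats::rnorm(n, 0, sqrt(study$var_subject)) + g
      b <- stats::rnorm(2, 0, sqrt(study$var_rater))
      for (r in 1:2) {
        e <- stats::rnorm(n, 0, sqrt(study$var_error))
        latent <- a + b[r] + e
        mid <- (rg$min + rg$max) / 2
        val <- mid + (rg$max - rg$min) / 2 * latent / (3 * sd_lat)
        val <- pmin(pmax(val, rg$min), rg$max)
        rows[[length(rows) + 1]] <-
          data.frame(session = seq_len(n), profession = p, rater = r,
                     topic = tp, score = val)
      }
    }
  }
  table <- do.call(rbind, rows)
  icc_true <- study$var_subject /
    (study$var_subject + study$var_rater + study$var_error)
  list(table = table,
       ground_truth = list(latent_group = g,
                           icc_implied = icc_true,
                           link_sign = sign(study$link_slope)))
}

#' Generate a full synthetic study
#'
#' Generates \code{n_sessions} sessions (EEG, audio envelopes, events) plus
#' one study-wide two-rater score table, with the designated coherence
#' component varying across sessions and coupled to the latent group score
#' via \code{link_slope}.  Optionally writes the study to disk in the
#' package's session-folder layout.
#'
#' @param study a \code{\link{study_spec}}.
#' @param out_dir optional directory; when given the study is written with
#'   \code{\link{write_study}}.
#' @return Object of class \code{hyperti_study_data}: \code{sessions} (list
#'   of per-session lists with \code{recordings}, \code{envelopes},
#'   \code{events}, \code{ground_truth}), \code{scores} (long table),
#'   \code{ground_truth} (session coherence targets, latent group scores,
#'   link sign), \code{spec}.
#' @export
generate_study <- function(study, out_dir = NULL) {
  stopifnot(inherits(study, "study_spec"))
  old <- mistate_save(); on.exit(mistate_restore(old))
  set.seed(as.integer(study$seed %% .Machine$integer.max))
  n <- study$n_sessions
  C <- stats::runif(n, study$coh_range[1], study$coh_range[2])
  lag_draws <- lapply(seq_len(n), function(s) {
    if (!study$random_lags) return(study$session$audio_lags)
    c(0, stats::runif(study$session$n_subjects - 1,
                      study$lag_range_ms[1], study$lag_range_ms[2]))
  })
  sessions <- vector("list", n)
  for (s in seq_len(n)) {
    tmpl <- study$session
    comp <- list(band = study$link$band, region = study$link$region,
                 pairs = "all", coherence = C[s])
    sp <- session_spec(n_subjects = tmpl$n_subjects,
                       channel_labels = tmpl$channel_labels,
                       fs = tmpl$fs, duration = tmpl$duration,
                       band_coherence = c(tmpl$band_coherence, list(comp)),
                       artifact_rate = tmpl$artifact_rate,
                       artifact_amplitude = tmpl$artifact_amplitude,
                       comm_schedule = tmpl$comm_schedule,
                       audio_lags = lag_draws[[s]],
                       baseline_sd = tmpl$baseline_sd,
                       seed = (study$seed * 131 + s * 9973) %% 2147483647)
    ses <- generate_eeg_session(sp, t0_unix = 1.6e9 + (s - 1) * 3600)
    ses$envelopes <- generate_audio_envelopes(sp)
    ses$id <- s
    sessions[[s]] <- ses
  }
  sc <- generate_rater_scores(study, session_coherence = C)
  out <- structure(list(sessions = sessions, scores = sc$table,
                        ground_truth = list(
                          session_coherence = C,
                          latent_group = sc$ground_truth$latent_group,
                          icc_implied = sc$ground_truth$icc_implied,
                          link_sign = sc$ground_truth$link_sign),
                        spec = study),
                   class = "hyperti_study_data")
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

#' @export
print.hyperti_study_data <- function(x, ...) {
  cat("<hyperti_study_data>", length(x$sessions), "sessions,",
      x$spec$session$n_subjects, "subjects each\n")
  cat("  planted coherence range:",
      paste(round(range(x$ground_truth$session_coherence), 3), collapse = " - "),
      " link slope:", x$spec$link_slope, "\n")
  invisible(x)
}

#' Write / read a study in the session-folder layout
#'
#' Layout: \code{sess-<k>/sub-<j>_eeg.csv} (\code{unix_time} + channel
#' columns, microvolts), \code{sess-<k>/events.json},
#' \code{sess-<k>/audio_sub-<j>.csv}, plus study-level \code{scores.csv} and
#' \code{ground_truth.json}.
#'
#' @param study_data a \code{hyperti_study_data}.
#' @param dir target directory (created if needed).
#' @return \code{dir} (write) or a \code{hyperti_study_data} (read),
#'   invisibly for the writer.
#' @export
write_study <- function(study_data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ses in study_data$sessions) {
    sd_dir <- file.path(dir, sprintf("sess-%02d", ses$id))
    dir.create(sd_dir, showWarnings = FALSE)
    for (nm in names(ses$recordings))
      write_eeg_csv(ses$recordings[[nm]],
                    file.path(sd_dir, paste0(nm, "_eeg.csv")))
    jsonlite::write_json(ses$events,
                         file.path(sd_dir, "events.json"), digits = NA)
    fs <- ses$recordings[[1]]$fs
    t0 <- ses$recordings[[1]]$t0_unix
    tt <- t0 + (seq_len(nrow(ses$envelopes)) - 1) / fs
    for (j in seq_len(ncol(ses$envelopes)))
      utils::write.csv(data.frame(unix_time = tt,
                                  envelope = ses$envelopes[, j]),
                       file.path(sd_dir, sprintf("audio_sub-%d.csv", j)),
                       row.names = FALSE)
    jsonlite::write_json(ses$ground_truth,
                         file.path(sd_dir, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  utils::write.csv(study_data$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study_data$ground_truth,
                       file.path(dir, "ground_truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  sess_dirs <- sort(list.dirs(dir, recursive = FALSE))
  sess_dirs <- sess_dirs[grepl("sess-", basename(sess_dirs))]
  sessions <- lapply(sess_dirs, function(sd) {
    eeg_files <- sort(list.files(sd, pattern = "_eeg\\.csv$", full.names = TRUE))
    recs <- lapply(eeg_files, read_eeg_csv)
    names(recs) <- vapply(recs, `[[`, "", "subject")
    env_files <- sort(list.files(sd, pattern = "^audio_sub-", full.names = TRUE))
    env <- vapply(env_files,
                  function(f) utils::read.csv(f)$envelope,
                  numeric(nrow(recs[[1]]$samples)))
    colnames(env) <- sub("^audio_(sub-\\d+)\\.csv$", "\\1", basename(env_files))
    events <- as.data.frame(jsonlite::read_json(file.path(sd, "events.json"),
                                                simplifyVector = TRUE))
    gt <- if (file.exists(file.path(sd, "ground_truth.json")))
      jsonlite::read_json(file.path(sd, "ground_truth.json"),
                          simplifyVector = TRUE) else NULL
    list(recordings = recs, envelopes = env, events = events,
         ground_truth = gt,
         id = as.integer(sub("sess-", "", basename(sd))))
  })
  scores <- utils::read.csv(file.path(dir, "scores.csv"))
  gt <- if (file.exists(file.path(dir, "ground_truth.json")))
    jsonlite::read_json(file.path(dir, "ground_truth.json"),
                        simplifyVector = TRUE) else NULL
  structure(list(sessions = sessions, scores = scores, ground_truth = gt,
                 spec = NULL),
            class = "hyperti_study_data")
}
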