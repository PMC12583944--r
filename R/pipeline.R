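#' Pipeline configuration
#'
#' Fixed analysis constants of the pipeline, all overridable: the 1-40 Hz
#' band-pass, the three-region channel map, the 6x golden-SD artifact rule,
#' the minimum commonly clean epoch count for a valid pair TI (K_min = 10,
#' below which the coherence estimate is dominated by its 1/K bias), 1000
#' permutations for the TI null, MCD outlier screening at 75\% support and
#' alpha = .001, and Benjamini-Hochberg significance at adjusted p < .05.
#'
#' @param bands list of \code{\link{band_spec}}s analyzed.
#' @param regions a \code{\link{region_map}}.
#' @param filter_lo,filter_hi band-pass edges, Hz.
#' @param golden_mult golden-SD multiplier for epoch rejection.
#' @param k_min minimum commonly clean epochs per valid pair TI.
#' @param n_perm permutations for the TI null.
#' @param mcd_support,mcd_alpha MCD screening parameters.
#' @param bh_alpha adjusted-p significance threshold.
#' @param max_lag lag search half-window, seconds.
#' @param seed master seed; per-communication substreams are derived from it
#'   deterministically.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(bands = list(band_spec("all"), band_spec("alpha")),
                            regions = region_map(), filter_lo = 1,
                            filter_hi = 40, golden_mult = 6, k_min = 10,
                            n_perm = 1000, mcd_support = 0.75,
                            mcd_alpha = 0.001, bh_alpha = 0.05,
                            max_lag = 5, seed = 1) {
  structure(list(bands = bands, regions = regions, filter_lo = filter_lo,
                 filter_hi = filter_hi, golden_mult = golden_mult,
                 k_min = k_min, n_perm = n_perm, mcd_support = mcd_support,
                 mcd_alpha = mcd_alpha, bh_alpha = bh_alpha,
                 max_lag = max_lag, seed = seed),
            class = "pipeline_config")
}

# deterministic per-communication substream seed
comm_seed <- function(master, session, comm, pair) {
  as.integer((master * 7919 + session * 104729 + comm * 1299709 +
                pair * 15485863) %% 2147483629)
}

#' TI analysis of one session
#'
#' Preprocesses (average rereference, zero-phase 1-40 Hz band-pass), aligns
#' recordings by audio-envelope lags, flags artifact epochs with the
#' golden-SD rule, and computes permutation-normalized TI for every subject
#' pair, region and band within each communication window.
#'
#' @param session one session of a \code{hyperti_study_data} (list with
#'   \code{recordings}, \code{envelopes}, \code{events}, \code{id}).
#' @param config a \code{\link{pipeline_config}}.
#' @return List: \code{pair_ti} (tidy data.frame: session, comm_id,
#'   subject_a, subject_b, region, band, K, raw_ti, z, ks_flag, n_perm,
#'   valid), \code{lags}, and per-stage counts.
#' @export
run_session <- function(session, config = pipeline_config()) {
  recs <- lapply(session$recordings, function(r)
    bandpass(rereference_average(r), config$filter_lo, config$filter_hi))
  lags <- lag_table(session$envelopes, fs_audio = recs[[1]]$fs,
                    max_lag = config$max_lag)
  recs <- align_recordings(recs, lags)
  fs <- as.integer(round(recs[[1]]$fs))

  gsd <- lapply(recs, golden_sd)
  epochs <- mapply(function(r, g) epoch_and_flag(r, g, config$golden_mult),
                   recs, gsd, SIMPLIFY = FALSE)
  rsig <- lapply(recs, region_signals, map = config$regions)
  subs <- names(recs)
  pairs <- utils::combn(seq_along(subs), 2)
  region_names <- names(config$regions)
  band_names <- vapply(config$bands, `[[`, "", "name")

  rows <- list(); n_invalid <- 0L
  for (ev in seq_len(nrow(session$events))) {
    event <- session$events[ev, ]
    seg <- segment_eeg(recs[[1]], event)
    e_min <- ceiling((seg$first - 1) / fs) + 1
    e_max <- floor(seg$last / fs)
    for (pi in seq_len(ncol(pairs))) {
      i <- pairs[1, pi]; j <- pairs[2, pi]
      cc <- integer(0)
      if (seg$valid && e_max >= e_min)
        cc <- intersect(common_clean(epochs[[i]], epochs[[j]]), e_min:e_max)
      K <- length(cc)
      valid <- K >= config$k_min
      if (!valid) {
        n_invalid <- n_invalid + 1L
        for (rg in region_names) for (bd in band_names)
          rows[[length(rows) + 1]] <- data.frame(
            session = session$id, comm_id = event$id, subject_a = subs[i],
            subject_b = subs[j], region = rg, band = bd, K = K,
            raw_ti = NA_real_, z = NA_real_, ks_flag = NA,
            n_perm = config$n_perm, valid = FALSE)
        next
      }
      sd_seed <- comm_seed(config$seed, session$id, event$id, pi)
      for (rg in region_names) {
        x_ep <- epoch_matrix(rsig[[i]][, rg], cc, fs)
        y_ep <- epoch_matrix(rsig[[j]][, rg], cc, fs)
        Fx <- epoch_spectra(x_ep); Fy <- epoch_spectra(y_ep)
        C <- coherence_from_spectra(Fx, Fy)
        nulls <- perm_null_ti(Fx, Fy, config$bands, config$n_perm, sd_seed)
        for (b in seq_along(config$bands)) {
          raw <- band_ti(C, config$bands[[b]])
          res <- normalize_ti(raw, null_summary(nulls[[b]], config$n_perm))
          rows[[length(rows) + 1]] <- data.frame(
            session = session$id, comm_id = event$id, subject_a = subs[i],
            subject_b = subs[j], region = rg, band = band_names[b], K = K,
            raw_ti = res$raw_ti, z = res$z, ks_flag = res$ks_flag,
            n_perm = config$n_perm, valid = TRUE)
        }
      }
    }
  }
  list(pair_ti = do.call(rbind, rows), lags = lags,
       counts = list(epochs_rejected = sum(!vapply(epochs, `[[`,
                       logical(epochs[[1]]$n_epochs), "clean")),
                     pair_communications_invalid = n_invalid))
}

#' Run the full analysis pipeline over a study
#'
#' Chains every stage for all sessions: preprocessing, lag alignment, pair
#' TI with permutation normalization, aggregation to student and group TI,
#' TeamSTEPPS score scaling and group scores, ICC(2,1) interrater report,
#' and the two 36-case correlation grids (individual and group level) with
#' MCD outlier screening and Benjamini-Hochberg correction.  The run is a
#' pure function of the inputs and the configuration: rerunning with the
#' same seed reproduces every number.
#'
#' @param study a \code{hyperti_study_data} (from \code{\link{generate_study}}
#'   or \code{\link{read_study}}), or a path to a study directory.
#' @param config a \code{\link{pipeline_config}}.
#' @param roster profession of each subject, in subject order (default the
#'   six simulated professions).
#' @return Object of class \code{hyperti_study}.
#' @export
run_study <- function(study, config = pipeline_config(),
                      roster = unique(default_topic_ranges()$profession)) {
  if (is.character(study)) study <- read_study(study)
  stopifnot(inherits(study, "hyperti_study_data"))
  per_session <- lapply(study$sessions, run_session, config = config)
  pair_ti <- do.call(rbind, lapply(per_session, `[[`, "pair_ti"))
  agg <- aggregate_ti(pair_ti)

  scaled <- scale_scores(study$scores)
  gscore <- group_score(scaled, roster)
  icc <- icc_report(study$scores)

  # subject <-> profession mapping for the individual-level grid
  subj_ids <- sort(unique(c(pair_ti$subject_a, pair_ti$subject_b)))
  prof_of <- roster[as.integer(sub("sub-", "", subj_ids))]
  scaled$subject <- subj_ids[match(scaled$profession, prof_of)]

  ti_ind <- agg$student
  grid_ind <- correlation_grid(ti_ind, scaled, level = "individual",
                               support = config$mcd_support,
                               alpha = config$mcd_alpha,
                               bh_alpha = config$bh_alpha,
                               seed = config$seed)
  gsc <- gscore; gsc$topic <- "overall"; gsc$scaled <- gsc$value
  # group-level scores per topic: session mean of the six scaled topic scores
  topic_group <- stats::aggregate(scaled ~ session + topic,
                                  data = scaled[scaled$topic != "overall", ],
                                  FUN = function(v) if (length(v) == 6) mean(v) else NA_real_)
  group_scores_long <- rbind(topic_group, gsc[c("session", "topic", "scaled")])
  grid_grp <- correlation_grid(agg$group, group_scores_long, level = "group",
                               support = config$mcd_support,
                               alpha = config$mcd_alpha,
                               bh_alpha = config$bh_alpha,
                               seed = config$seed)
  structure(list(pair_ti = pair_ti, student_ti = agg$student,
                 group_ti = agg$group, scores_scaled = scaled,
                 group_scores = gscore, icc = icc,
                 grid_individual = grid_ind, grid_group = grid_grp,
                 lags = lapply(per_session, `[[`, "lags"),
                 counts = lapply(per_session, `[[`, "counts"),
                 config = config),
            class = "hyperti_study")
}

#' @export
print.hyperti_study <- function(x, ...) {
  ns <- length(unique(x$pair_ti$session))
  cat("<hyperti_study>", ns, "sessions;",
      sum(x$pair_ti$valid, na.rm = TRUE), "valid pair-communication TIs\n")
  comp <- x$group_ti[x$group_ti$complete & x$group_ti$band == "alpha" &
                       x$group_ti$region == "anterior", ]
  cat("  complete group TIs (anterior alpha):", nrow(comp), "of", ns,
      "sessions\n")
  cat("  group-level grid:", sum(x$grid_group$significant, na.rm = TRUE),
      "of", nrow(x$grid_group), "cases significant after BH\n")
  invisible(x)
}

#' @export
summary.hyperti_study <- function(object, ...) {
  cat("Normalized TI pipeline summary\n")
  cat("------------------------------\n")
  v <- object$pair_ti$z[object$pair_ti$valid]
  cat("pair TI z: mean", round(mean(v, na.rm = TRUE), 3), " sd",
      round(stats::sd(v, na.rm = TRUE), 3), " n", sum(!is.na(v)), "\n")
  cat("KS non-normal null rate:",
      round(100 * mean(object$pair_ti$ks_flag[object$pair_ti$valid],
                       na.rm = TRUE), 2), "%\n")
  cat("mean interrater ICC(2,1):", round(mean(object$icc$icc), 3), "\n\n")
  cat("Group-level correlation grid:\n")
  print(object$grid_group)
  invisible(object)
}

#' @export
plot.hyperti_study <- function(x, score = "overall", region = "anterior",
                               band = "alpha", ...) {
  ti <- x$group_ti[x$group_ti$region == region & x$group_ti$band == band, ]
  sc <- if (score == "overall") x$group_scores[c("session", "value")]
  else {
    s <- x$scores_scaled[x$scores_scaled$topic == score, ]
    stats::aggregate(scaled ~ session, data = s, FUN = mean)
  }
  names(sc)[2] <- "score"
  mg <- merge(ti, sc, by = "session")
  mg <- mg[is.finite(mg$value) & is.finite(mg$score), ]
  graphics::plot(mg$value, mg$score,
                 xlab = paste("group TI (", region, ",", band, "band )"),
                 ylab = paste("group TeamSTEPPS:", score),
                 pch = 19, ...)
  if (nrow(mg) >= 3) graphics::abline(stats::lm(score ~ value, data = mg))
  invisible(mg)
}

#' Validate a study directory
#'
#' Per-file sanity report: EEG readability, sampling uniformity and channel
#' set; event-window sanity; two raters per (session, profession, topic).
#' Reports only -- never raises.
#'
#' @param dir study directory in the \code{\link{write_study}} layout.
#' @return data.frame \code{item}, \code{check}, \code{pass}, \code{note}.
#' @export
validate_inputs <- function(dir) {
  out <- list()
  add <- function(item, check, pass, note = "")
    out[[length(out) + 1]] <<- data.frame(item = item, check = check,
                                          pass = pass, note = note)
  sess_dirs <- sort(list.dirs(dir, recursive = FALSE))
  sess_dirs <- sess_dirs[grepl("sess-", basename(sess_dirs))]
  for (sd in sess_dirs) {
    for (f in list.files(sd, pattern = "_eeg\\.csv$", full.names = TRUE)) {
      r <- try(read_eeg_csv(f), silent = TRUE)
      if (inherits(r, "try-error"))
        add(f, "eeg readable/uniform/channels", FALSE,
            conditionMessage(attr(r, "condition")))
      else add(f, "eeg readable/uniform/channels", TRUE)
    }
    evf <- file.path(sd, "events.json")
    if (file.exists(evf)) {
      ev <- as.data.frame(jsonlite::read_json(evf, simplifyVector = TRUE))
      bad <- which(ev$end_unix <= ev$start_unix)
      add(evf, "event windows end after start", length(bad) == 0,
          if (length(bad)) paste("event id", paste(ev$id[bad], collapse = ",")) else "")
      badp <- which(ev$sender == ev$receiver)
      add(evf, "event pairs distinct", length(badp) == 0,
          if (length(badp)) paste("event id", paste(ev$id[badp], collapse = ",")) else "")
    } else add(evf, "events.json present", FALSE, "missing")
  }
  scf <- file.path(dir, "scores.csv")
  if (file.exists(scf)) {
    sc <- utils::read.csv(scf)
    cnt <- stats::aggregate(rater ~ session + profession + topic, data = sc,
                            FUN = function(v) length(unique(v)))
    bad <- cnt[cnt$rater != 2, ]
    add(scf, "two raters per profession/topic", nrow(bad) == 0,
        if (nrow(bad)) paste0("session ", bad$session[1], " ",
                              bad$profession[1], " has ", bad$rater[1],
                              " rater(s)") else "")
  } else add(scf, "scores.csv present", FALSE, "missing")
  do.call(rbind, out)
}
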