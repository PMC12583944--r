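# measured pairwise region coherence after the real preprocessing path,
# using the package pipeline for preprocessing but the brute-force DFT
# oracle is exercised separately in test-ti
measure_msc <- function(ses, subjects = 1:2, bins = 8:12) {
  recs <- lapply(ses$recordings[subjects],
                 function(r) bandpass(rereference_average(r)))
  eps <- lapply(recs, function(r) epoch_and_flag(r, golden_sd(r)))
  cc <- common_clean(eps[[1]], eps[[2]])
  rs <- lapply(recs, region_signals)
  fs <- recs[[1]]$fs
  vapply(c("anterior", "central", "posterior"), function(rg) {
    C <- coherence_epochs(epoch_matrix(rs[[1]][, rg], cc, fs),
                          epoch_matrix(rs[[2]][, rg], cc, fs))
    mean(C$coh[bins])
  }, numeric(1))
}

test_that("spec validation rejects impossible sessions", {
  expect_error(session_spec(band_coherence = list(list(band = "alpha",
                                                       coherence = 1))),
               "\\[0, 1\\)")
  expect_error(session_spec(duration = 0.5), "one epoch")
  expect_error(session_spec(comm_schedule = data.frame(
    sender = 1, receiver = 1, start = 5, end = 10)), "distinct")
  expect_error(session_spec(comm_schedule = data.frame(
    sender = 1, receiver = 2, start = 5, end = 300), duration = 100),
    "within")
  expect_error(session_spec(artifact_amplitude = 5), "exceed 6")
})

test_that("zero planted coherence stays at the 1/K bias level", {
  sp <- session_spec(duration = 80, artifact_rate = 0.5, seed = 21,
                     band_coherence = list(list(band = "alpha",
                                                coherence = 0)))
  msc <- measure_msc(generate_eeg_session(sp))
  expect_true(all(msc < 0.15))
})

test_that("planted pairwise coherence is recovered within 0.1", {
  sp <- session_spec(duration = 120, artifact_rate = 0.5, seed = 22,
                     band_coherence = list(list(band = "alpha",
                                                coherence = 0.8,
                                                pairs = list(c(1, 2)))))
  ses <- generate_eeg_session(sp)
  msc12 <- measure_msc(ses, 1:2)
  expect_true(all(abs(msc12 - 0.8) < 0.1))
  # a pair outside the planted group stays incoherent
  msc34 <- measure_msc(ses, 3:4)
  expect_true(all(msc34 < 0.15))
})

test_that("region-targeted coherence leaves the other regions incoherent", {
  sp <- session_spec(duration = 120, artifact_rate = 0.5, seed = 23,
                     band_coherence = list(list(band = "alpha",
                                                coherence = 0.6,
                                                region = "anterior")))
  msc <- measure_msc(generate_eeg_session(sp))
  expect_lt(abs(msc[["anterior"]] - 0.6), 0.1)
  expect_lt(msc[["central"]], 0.15)
  expect_lt(msc[["posterior"]], 0.15)
})

test_that("measured coherence is monotone in the planted level", {
  msc <- vapply(c(0.1, 0.4, 0.7), function(C0) {
    sp <- session_spec(duration = 80, artifact_rate = 0, seed = 24,
                       band_coherence = list(list(band = "alpha",
                                                  coherence = C0)))
    measure_msc(generate_eeg_session(sp))[["anterior"]]
  }, numeric(1))
  expect_true(all(diff(msc) > 0))
})

test_that("artifact ground truth matches the flagging rule", {
  sp0 <- session_spec(duration = 60, artifact_rate = 0, seed = 25)
  ses0 <- generate_eeg_session(sp0)
  expect_true(all(lengths(ses0$ground_truth$artifact_epochs) == 0))
  sp <- session_spec(duration = 120, artifact_rate = 2,
                     artifact_amplitude = 10, seed = 26)
  ses <- generate_eeg_session(sp)
  for (s in c(1, 4)) {
    r <- bandpass(rereference_average(ses$recordings[[s]]))
    e <- epoch_and_flag(r, golden_sd(r), 6)
    planted <- ses$ground_truth$artifact_epochs[[s]]
    flagged <- which(!e$clean)
    expect_gt(length(planted), 0)
    # every planted epoch is caught
    expect_length(setdiff(planted, flagged), 0)
    # epochs away from any artifact (beyond filter ringing reach) stay clean
    halo <- unique(c(planted - 1, planted, planted + 1))
    expect_length(setdiff(flagged, halo), 0)
  }
})

test_that("audio envelopes carry the planted lags with sign", {
  sp <- session_spec(duration = 80, seed = 27,
                     audio_lags = c(0, 250, -80, 0, 0, 0))
  expect_equal(generate_eeg_session(sp)$ground_truth$audio_lag_samples,
               c(0, 31, -10, 0, 0, 0))
  env <- generate_audio_envelopes(sp)
  lt <- lag_table(env)
  expect_equal(lt$lag_ms[1], 0)
  expect_lt(abs(lt$lag_ms[2] - 250), 1000 / 125 + 1e-9)  # within 1 sample
  expect_lt(abs(lt$lag_ms[3] - (-80)), 1000 / 125 + 1e-9)
  expect_true(all(lt$peak_corr[2:3] > 0.9))
})

test_that("rater-score generator honours ranges, reliability and agreement", {
  # perfect agreement when rater and error variance vanish
  st0 <- study_spec(n_sessions = 12, var_subject = 1, var_rater = 0,
                    var_error = 0, seed = 5)
  tab0 <- generate_rater_scores(st0)$table
  w0 <- reshape(tab0, idvar = c("session", "profession", "topic"),
                timevar = "rater", direction = "wide")
  expect_equal(w0$score.1, w0$score.2)
  rep0 <- icc_report(tab0)
  expect_true(all(rep0$icc == 1))
  # implied ICC 0.5 realized within 0.05 at n = 500
  st <- study_spec(n_sessions = 500, var_subject = 1, var_rater = 0,
                   var_error = 1, seed = 6)
  rep1 <- icc_report(generate_rater_scores(st)$table)
  expect_lt(abs(mean(rep1$icc) - 0.5), 0.05)
  # declared ranges enforced (team structure 2-10 for the radiological
  # technologist)
  tab <- generate_rater_scores(study_spec(n_sessions = 200, seed = 7))$table
  ts <- tab[tab$profession == "radiological technologist" &
              tab$topic == "team structure", ]
  expect_true(all(ts$score >= 2 & ts$score <= 10))
  expect_error(study_spec(var_subject = -1), "nonnegative")
})

test_that("study generator plants the score-synchrony link", {
  small_session <- session_spec(duration = 20, artifact_rate = 0,
                                comm_schedule = data.frame(
                                  sender = 1, receiver = 2,
                                  start = 2, end = 18))
  # null link: realized correlation small
  st0 <- generate_study(study_spec(n_sessions = 20, session = small_session,
                                   link_slope = 0, seed = 8))
  g0 <- group_score(scale_scores(st0$scores))
  r0 <- cor(g0$value, st0$ground_truth$session_coherence)
  expect_lte(abs(r0), 0.3)
  # strong negative link, low noise: correlation near -1
  st1 <- generate_study(study_spec(n_sessions = 20, session = small_session,
                                   link_slope = -3, var_subject = 0.01,
                                   var_rater = 0.01, var_error = 0.01,
                                   seed = 9))
  g1 <- group_score(scale_scores(st1$scores))
  r1 <- cor(g1$value, st1$ground_truth$session_coherence)
  expect_lte(r1, -0.9)
})

test_that("generation is deterministic and the folder layout round-trips", {
  st <- study_spec(n_sessions = 2,
                   session = session_spec(duration = 20, artifact_rate = 2,
                                          comm_schedule = data.frame(
                                            sender = 1, receiver = 2,
                                            start = 2, end = 18)),
                   seed = 10)
  a <- generate_study(st)
  b <- generate_study(st)
  expect_identical(a, b)
  d1 <- file.path(tempdir(), "study_rt")
  unlink(d1, recursive = TRUE)
  write_study(a, d1)
  back <- read_study(d1)
  expect_equal(back$sessions[[1]]$recordings[["sub-1"]]$samples,
               a$sessions[[1]]$recordings[["sub-1"]]$samples,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$scores$score, a$scores$score, tolerance = 1e-9)
  expect_equal(back$sessions[[1]]$events$start_unix,
               a$sessions[[1]]$events$start_unix)
  unlink(d1, recursive = TRUE)
})
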