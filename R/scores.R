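#' Default per-profession TeamSTEPPS topic ranges
#'
#' Instrument metadata: minimum and maximum attainable score per profession
#' and topic (the item counts differ by profession), plus the overall range
#' (sum of the five topic ranges).  Used to min-max scale rater-averaged
#' scores into \[0, 1\].
#'
#' @return data.frame with columns \code{profession}, \code{topic},
#'   \code{min}, \code{max}.
#' @export
default_topic_ranges <- function() {
  prof <- c("radiological technologist", "medical technologist",
            "medical doctor", "pharmacist", "circulation nurse",
            "airway nurse")
  topics <- teamstepps_topics()
  lo <- rbind(c(2, 4, 5, 5, 4, 20),
              c(2, 4, 5, 4, 3, 18),
              c(4, 4, 6, 5, 4, 23),
              c(2, 4, 5, 2, 4, 17),
              c(3, 4, 5, 5, 4, 21),
              c(3, 4, 5, 5, 4, 21))
  hi <- rbind(c(10, 20, 25, 25, 20, 100),
              c(10, 20, 25, 20, 15, 90),
              c(20, 20, 30, 25, 20, 115),
              c(10, 20, 25, 10, 20, 85),
              c(15, 20, 25, 25, 20, 105),
              c(15, 20, 25, 25, 20, 105))
  data.frame(profession = rep(prof, each = 6),
             topic = rep(c(topics, "overall"), times = 6),
             min = as.vector(t(lo)), max = as.vector(t(hi)),
             stringsAsFactors = FALSE)
}

#' @rdname default_topic_ranges
#' @export
teamstepps_topics <- function() {
  c("team structure", "communication", "leadership",
    "situation monitoring", "mutual support")
}

#' Scale two-rater TeamSTEPPS scores
#'
#' Averages the two raters per (session, profession, topic), then min-max
#' scales by the declared topic range so the minimum attainable score maps
#' to 0 and the maximum to 1.  The overall score is the sum of the five raw
#' topic scores, scaled by the overall range (not the mean of the five
#' scaled topics).
#'
#' @param table long data.frame with columns \code{session},
#'   \code{profession}, \code{rater}, \code{topic}, \code{score}.
#' @param ranges range table as \code{\link{default_topic_ranges}}.
#' @return data.frame with columns \code{session}, \code{profession},
#'   \code{topic} (five topics plus \code{"overall"}), \code{scaled}.
#' @export
scale_scores <- function(table, ranges = default_topic_ranges()) {
  need <- c("session", "profession", "rater", "topic", "score")
  if (!all(need %in% names(table)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  tab <- merge(table, ranges, by = c("profession", "topic"))
  if (nrow(tab) < nrow(table))
    stop("no declared range for some (profession, topic) records")
  bad <- tab$score < tab$min | tab$score > tab$max
  if (any(bad))
    stop("score outside declared range: session ", tab$session[bad][1],
         ", ", tab$profession[bad][1], ", ", tab$topic[bad][1],
         " = ", tab$score[bad][1])
  avg <- stats::aggregate(score ~ session + profession + topic + min + max,
                          data = tab, FUN = mean)
  avg$scaled <- (avg$score - avg$min) / (avg$max - avg$min)

  # overall: sum of the five rater-mean topic scores, scaled by overall range
  tot <- stats::aggregate(score ~ session + profession, data = avg, FUN = sum)
  orng <- ranges[ranges$topic == "overall", ]
  tot <- merge(tot, orng[c("profession", "min", "max")], by = "profession")
  tot$scaled <- (tot$score - tot$min) / (tot$max - tot$min)
  tot$topic <- "overall"

  cols <- c("session", "profession", "topic", "scaled")
  out <- rbind(avg[cols], tot[cols])
  out[order(out$session, out$profession, out$topic), ]
}

#' Group TeamSTEPPS score
#'
#' Session-level teamwork score: the mean of the six professions' scaled
#' overall scores, defined only when all six are present.
#'
#' @param scaled output of \code{\link{scale_scores}}.
#' @param roster professions expected per session (default the six
#'   simulated professions).
#' @return data.frame with \code{session}, \code{value}, \code{complete};
#'   \code{value} is \code{NA} when any roster member is missing.
#' @export
group_score <- function(scaled, roster = unique(default_topic_ranges()$profession)) {
  ov <- scaled[scaled$topic == "overall", ]
  sessions <- sort(unique(ov$session))
  out <- do.call(rbind, lapply(sessions, function(s) {
    v <- ov$scaled[ov$session == s][match(roster, ov$profession[ov$session == s])]
    complete <- !anyNA(v) && length(v) == length(roster)
    data.frame(session = s, value = if (complete) mean(v) else NA_real_,
               complete = complete)
  }))
  out
}

#' Interrater reliability: ICC(2,1), absolute agreement
#'
#' Intraclass correlation from the two-way random-effects model (both raters
#' and subjects random), single-rater, absolute-agreement form:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} the subject, rater and error mean
#' squares of the two-way ANOVA, \eqn{k} raters and \eqn{n} subjects.
#' Absolute agreement penalizes systematic rater offsets, unlike the
#' consistency form.
#'
#' @param mat numeric matrix, subjects by raters (no missing cells;
#'   at least 3 subjects).
#' @return The ICC estimate (scalar); attribute \code{uninformative} is TRUE
#'   when between-subject variance is zero.
#' @export
icc21 <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3) stop("need at least 3 subjects")
  if (anyNA(mat)) stop("missing cells not allowed")
  gm <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ms_r <- k * sum((row_m - gm)^2) / (n - 1)
  ms_c <- n * sum((col_m - gm)^2) / (k - 1)
  resid <- mat - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + gm
  ms_e <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + k / n * (ms_c - ms_e)
  val <- if (denom == 0) 0 else (ms_r - ms_e) / denom
  attr(val, "uninformative") <- ms_r <= ms_e
  val
}

#' Qualitative interpretation of an ICC value
#'
#' Labels under two published conventions: Cicchetti (poor < 0.40, fair
#' 0.40-0.59, good 0.60-0.74, excellent 0.75-1.00) and Koo-Li (poor < 0.5,
#' moderate 0.5-0.75, good 0.75-0.9, excellent > 0.9).  Band edges are
#' assigned to the band whose printed range starts there.
#'
#' @param value an ICC estimate (<= 1).
#' @return Named character vector with \code{cicchetti} and \code{koo_li}
#'   labels.
#' @export
icc_interpret <- function(value) {
  if (value > 1) stop("ICC cannot exceed 1")
  cic <- if (value >= 0.75) "excellent" else if (value >= 0.60) "good"
         else if (value >= 0.40) "fair" else "poor"
  koo <- if (value > 0.9) "excellent" else if (value >= 0.75) "good"
         else if (value >= 0.5) "moderate" else "poor"
  c(cicchetti = cic, koo_li = koo)
}

#' Interrater reliability report for a score table
#'
#' Computes ICC(2,1) per (profession, topic) across sessions, with labels.
#'
#' @param table long score table as in \code{\link{scale_scores}}.
#' @return data.frame with \code{profession}, \code{topic}, \code{n},
#'   \code{icc}, \code{cicchetti}, \code{koo_li}.
#' @export
icc_report <- function(table) {
  combos <- unique(table[c("profession", "topic")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- table[table$profession == combos$profession[i] &
                 table$topic == combos$topic[i], ]
    wide <- stats::reshape(sub[c("session", "rater", "score")],
                           idvar = "session", timevar = "rater",
                           direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    keep <- stats::complete.cases(m)
    m <- m[keep, , drop = FALSE]
    if (nrow(m) < 3 || ncol(m) != 2) return(NULL)
    v <- icc21(m)
    lab <- icc_interpret(as.numeric(v))
    data.frame(profession = combos$profession[i], topic = combos$topic[i],
               n = nrow(m), icc = as.numeric(v),
               cicchetti = lab[["cicchetti"]], koo_li = lab[["koo_li"]])
  })
  do.call(rbind, out)
}
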