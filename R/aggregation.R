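#' Aggregate pair-level TI to student and group levels
#'
#' Three-step unweighted averaging of normalized TI:
#' \enumerate{
#'   \item a student's communication TI is the mean over all valid pair TIs
#'     involving that student for that communication;
#'   \item the student TI is the mean of the student's communication TIs over
#'     all valid communications;
#'   \item the group TI is the mean of the six student TIs, defined only when
#'     every roster member has one (\code{complete = TRUE}).
#' }
#'
#' @param pair_ti data.frame with columns \code{session}, \code{comm_id},
#'   \code{subject_a}, \code{subject_b}, \code{region}, \code{band},
#'   \code{z}, \code{valid}.
#' @param roster subject ids forming a complete group (default the six
#'   subjects present in the table).
#' @return List with data.frames \code{student_comm} (session, comm_id,
#'   subject, region, band, value), \code{student} (adds
#'   \code{n_communications}), \code{group} (session, region, band, value,
#'   complete).
#' @export
aggregate_ti <- function(pair_ti, roster = NULL) {
  need <- c("session", "comm_id", "subject_a", "subject_b", "region",
            "band", "z", "valid")
  if (!all(need %in% names(pair_ti)))
    stop("pair_ti must have columns: ", paste(need, collapse = ", "))
  if (is.null(roster))
    roster <- sort(unique(c(pair_ti$subject_a, pair_ti$subject_b)))
  ok <- pair_ti[pair_ti$valid & !is.na(pair_ti$z), ]
  long <- rbind(
    data.frame(ok[c("session", "comm_id", "region", "band", "z")],
               subject = ok$subject_a),
    data.frame(ok[c("session", "comm_id", "region", "band", "z")],
               subject = ok$subject_b))
  if (nrow(long) == 0)
    return(list(student_comm = NULL, student = NULL,
                group = data.frame(session = integer(0), region = character(0),
                                   band = character(0), value = numeric(0),
                                   complete = logical(0))))
  student_comm <- stats::aggregate(
    z ~ session + comm_id + subject + region + band, data = long, FUN = mean)
  names(student_comm)[names(student_comm) == "z"] <- "value"

  student <- stats::aggregate(value ~ session + subject + region + band,
                              data = student_comm,
                              FUN = function(v) c(mean(v), length(v)))
  student <- do.call(data.frame, student)
  names(student)[(ncol(student) - 1):ncol(student)] <-
    c("value", "n_communications")

  combos <- unique(student[c("session", "region", "band")])
  group <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- student[student$session == combos$session[i] &
                   student$region == combos$region[i] &
                   student$band == combos$band[i], ]
    v <- sub$value[match(roster, sub$subject)]
    complete <- !anyNA(v)
    data.frame(session = combos$session[i], region = combos$region[i],
               band = combos$band[i],
               value = if (complete) mean(v) else NA_real_,
               complete = complete)
  }))
  list(student_comm = student_comm, student = student,
       group = group[order(group$session, group$region, group$band), ])
}

#' Student communication TI (single communication)
#'
#' Mean of the valid pair TIs that include the subject, for one
#' communication; \code{NA} when the subject appears in no valid pair.
#'
#' @param pair_z numeric vector of pair TI z-scores.
#' @param members list of length-2 vectors naming the subjects of each pair.
#' @param subject the subject of interest.
#' @return Scalar mean or \code{NA}.
#' @export
student_communication_ti <- function(pair_z, members, subject) {
  inc <- vapply(members, function(m) subject %in% m, logical(1))
  if (!any(inc)) return(NA_real_)
  mean(pair_z[inc])
}

#' Student TI across communications
#'
#' Unweighted mean of per-communication values; \code{NA} if none defined.
#'
#' @param comm_values numeric vector (may contain \code{NA}).
#' @return Scalar mean or \code{NA}.
#' @export
student_ti <- function(comm_values) {
  v <- comm_values[!is.na(comm_values)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Group TI from student TIs
#'
#' Mean of the roster's student TIs; undefined (with \code{complete = FALSE})
#' when any member's value is missing.
#'
#' @param student_values named numeric vector of student TIs.
#' @param roster subject ids forming the group (default the names of
#'   \code{student_values}).
#' @return List \code{value}, \code{complete}.
#' @export
group_ti <- function(student_values, roster = names(student_values)) {
  v <- if (is.null(roster)) student_values
       else student_values[match(roster, names(student_values))]
  if (is.null(roster)) roster <- seq_along(v)
  if (anyNA(v) || length(v) < length(roster))
    return(list(value = NA_real_, complete = FALSE))
  list(value = mean(v), complete = TRUE)
}
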