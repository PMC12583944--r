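#' Bivariate outlier flags from the Minimum Covariance Determinant
#'
#' Robust location/scatter of the 2-column point cloud by FastMCD
#' (\code{MASS::cov.rob}) with a 75\% support fraction and up to 500 random
#' starts (exhaustive enumeration of elemental subsets when there are fewer
#' than 500); points with extreme robust squared Mahalanobis distances are
#' flagged at level \code{alpha}.
#'
#' The asymptotic rule compares distances with the chi-square quantile at
#' \code{1 - alpha} with 2 df (13.816 at \code{alpha = 0.001}).  At the
#' sample sizes of session-level analyses (n of order 10-30) raw MCD
#' distances are strongly inflated relative to that reference -- the
#' estimator's well-known small-sample bias -- and the chi-square rule
#' over-flags by more than an order of magnitude, which in turn inflates the
#' type-I error of any test run on the survivors.  The default
#' \code{cutoff = "calibrated"} therefore draws the cutoff from a
#' Monte-Carlo null: robust distances of clean bivariate-normal samples of
#' the same n (400 replicates, fixed internal seed, memoized per n), taking
#' their \code{1 - alpha} quantile.  \code{cutoff = "chisq"} gives the
#' asymptotic rule.
#'
#' @param points numeric matrix or data.frame, n by 2, finite values,
#'   n >= 10.
#' @param support minimum fraction of "good" samples (default 0.75).
#' @param alpha flagging level (default 0.001).
#' @param nsamp number of random starts for FastMCD (default 500).
#' @param seed RNG seed (FastMCD subset search is randomized).
#' @param cutoff \code{"calibrated"} (default) or \code{"chisq"}.
#' @return Logical vector of outlier flags, with attributes \code{md2}
#'   (robust squared distances) and \code{cutoff} (the threshold used).
#' @export
mcd_outliers <- function(points, support = 0.75, alpha = 0.001,
                         nsamp = 500, seed = 1,
                         cutoff = c("calibrated", "chisq")) {
  cutoff <- match.arg(cutoff)
  X <- as.matrix(points)
  if (ncol(X) != 2) stop("points must have exactly 2 columns")
  n <- nrow(X)
  if (n < 10) stop("need at least 10 points for MCD screening (got ", n, ")")
  if (!all(is.finite(X))) stop("points must be finite")
  if (qr(sweep(X, 2, colMeans(X)))$rank < 2)
    stop("rank-deficient point cloud: MCD scatter undefined")
  old <- mistate_save(); on.exit(mistate_restore(old))
  md2 <- mcd_distances(X, support, nsamp, seed)
  thr <- if (cutoff == "chisq") stats::qchisq(1 - alpha, df = 2)
         else mcd_calibrated_cutoff(n, support, alpha, nsamp)
  flags <- md2 > thr
  attr(flags, "md2") <- md2
  attr(flags, "cutoff") <- thr
  flags
}

# raw FastMCD robust squared distances (seeded; exhaustive search when the
# number of elemental subsets is below nsamp, which also silences the
# explorative-sampling warning)
mcd_distances <- function(X, support, nsamp, seed) {
  n <- nrow(X)
  h <- ceiling(support * n)
  if (choose(n, 3) <= nsamp) nsamp <- "best"
  set.seed(as.integer(seed %% .Machine$integer.max))
  fit <- MASS::cov.rob(X, method = "mcd", quantile.used = h, nsamp = nsamp)
  stats::mahalanobis(X, fit$center, fit$cov)
}

# Monte-Carlo null cutoff for MCD distances, memoized per (n, support,
# alpha); its RNG stream is fixed and isolated from the caller's.
.mcd_cal_cache <- new.env(parent = emptyenv())
mcd_calibrated_cutoff <- function(n, support = 0.75, alpha = 0.001,
                                  nsamp = 500, B = 400) {
  key <- paste(n, support, alpha, sep = "_")
  hit <- .mcd_cal_cache[[key]]
  if (!is.null(hit)) return(hit)
  old <- mistate_save(); on.exit(mistate_restore(old))
  pool <- unlist(lapply(seq_len(B), function(b) {
    set.seed(76543 + b)
    X <- matrix(stats::rnorm(2 * n), n, 2)
    mcd_distances(X, support, nsamp, seed = 76543 + b)
  }))
  out <- stats::quantile(pool, 1 - alpha, names = FALSE)
  .mcd_cal_cache[[key]] <- out
  out
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; p from the exact t reference with n-2 df.
#'
#' @param x,y numeric vectors, length >= 3, nonzero variance.
#' @return List \code{r}, \code{p}, \code{n}.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the variables")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sorted p-values are scaled by
#' \code{m/i} with a cumulative-minimum enforcement and capped at 1.  Missing
#' entries stay missing but still count toward \code{m}.
#'
#' @param p numeric vector of raw p-values in \[0, 1\] (NAs allowed).
#' @param m number of comparisons (default the number of non-missing
#'   p-values).
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p, m = sum(!is.na(p))) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Minimum detectable correlation for a given sample size
#'
#' Smallest Pearson r detectable with the requested power at a two-sided
#' level \code{alpha}, under the Fisher-z approximation:
#' \deqn{r = \tanh\!\big((z_{1-\alpha/2} + z_{power}) / \sqrt{n - 3}\big).}
#'
#' @param n sample size (> 3).
#' @param power desired power (default 0.8).
#' @param alpha two-sided significance level (default 0.05).
#' @return The minimum detectable r.
#' @export
min_detectable_r <- function(n, power = 0.8, alpha = 0.05) {
  if (n <= 3) stop("n must exceed 3")
  tanh((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n - 3))
}

#' Correlation grid: TI against TeamSTEPPS scores
#'
#' The 36-case grid of Pearson correlations -- 6 scores (five topics plus
#' overall) x 3 brain regions x 2 frequency bands -- at the individual
#' (subject-session) or group (session) level.  Per case the bivariate
#' (TI, score) cloud is screened with \code{\link{mcd_outliers}} (skipped
#' when fewer than 10 observations are available), Pearson r and its raw p
#' are computed on the survivors, and Benjamini-Hochberg adjustment is
#' applied across exactly the 36 cases of the grid.  Cases with fewer than
#' 3 surviving observations or degenerate variance are reported undefined
#' but still count toward the correction.
#'
#' @param ti data.frame of TI values: columns \code{session},
#'   (\code{subject} at individual level), \code{region}, \code{band},
#'   \code{value}.
#' @param scores data.frame of scaled scores: at individual level columns
#'   \code{session}, \code{subject}, \code{topic}, \code{scaled}; at group
#'   level \code{session}, \code{topic}, \code{scaled} (topic includes
#'   \code{"overall"}).
#' @param level \code{"individual"} or \code{"group"}.
#' @param support,alpha MCD parameters (defaults 0.75 and 0.001).
#' @param bh_alpha significance threshold on the adjusted p (default 0.05).
#' @param seed seed for the MCD subset search.
#' @return data.frame of class \code{ti_cor_grid} with 36 rows: \code{level},
#'   \code{score}, \code{region}, \code{band}, \code{n_total},
#'   \code{n_after_outliers}, \code{r}, \code{p_raw}, \code{p_adjusted},
#'   \code{significant}.
#' @export
correlation_grid <- function(ti, scores, level = c("group", "individual"),
                             support = 0.75, alpha = 0.001, bh_alpha = 0.05,
                             seed = 1) {
  level <- match.arg(level)
  key <- if (level == "individual") c("session", "subject") else "session"
  score_names <- c(teamstepps_topics(), "overall")
  regions <- c("anterior", "central", "posterior")
  bands <- c("all", "alpha")
  grid <- expand.grid(score = score_names, region = regions, band = bands,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ti_sub <- ti[ti$region == grid$region[i] & ti$band == grid$band[i],
                 c(key, "value")]
    sc_sub <- scores[scores$topic == grid$score[i], c(key, "scaled")]
    mg <- merge(ti_sub, sc_sub, by = key)
    mg <- mg[is.finite(mg$value) & is.finite(mg$scaled), ]
    n_total <- nrow(mg)
    res <- list(r = NA_real_, p = NA_real_, n = n_total)
    n_after <- n_total
    if (n_total >= 3) {
      keep <- rep(TRUE, n_total)
      if (n_total >= 10) {
        fl <- try(mcd_outliers(cbind(mg$value, mg$scaled),
                               support = support, alpha = alpha,
                               seed = seed + i), silent = TRUE)
        if (!inherits(fl, "try-error")) keep <- !as.logical(fl)
      }
      n_after <- sum(keep)
      if (n_after >= 3 &&
          stats::sd(mg$value[keep]) > 0 && stats::sd(mg$scaled[keep]) > 0)
        res <- pearson_r(mg$value[keep], mg$scaled[keep])
    }
    rows[[i]] <- data.frame(level = level, score = grid$score[i],
                            region = grid$region[i], band = grid$band[i],
                            n_total = n_total, n_after_outliers = n_after,
                            r = res$r, p_raw = res$p)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_raw, m = nrow(out))
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < bh_alpha
  class(out) <- c("ti_cor_grid", "data.frame")
  attr(out, "m") <- nrow(out)
  out
}

#' @export
print.ti_cor_grid <- function(x, ...) {
  cat("Correlation grid (", x$level[1], " level): ", nrow(x),
      " cases, BH-corrected (m = ", attr(x, "m"), ")\n", sep = "")
  sig <- x[which(x$significant), ]
  if (nrow(sig)) {
    cat("significant cases (adjusted p < .05):\n")
    print.data.frame(sig[c("score", "region", "band", "n_after_outliers",
                           "r", "p_adjusted")],
                     row.names = FALSE, digits = 3)
  } else cat("no significant cases after correction\n")
  invisible(x)
}
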