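#' Build a tidy measurement table
#'
#' One row per (subject, cohort, rater, repeat, metric, value); duplicate
#' (subject, rater, repeat, metric) keys are rejected.
#'
#' @param subject,cohort,rater,repeat_id,metric,value column vectors
#'   (recycled where length 1).
#' @return data.frame of class \code{measurement_table}.
#' @export
measurement_table <- function(subject, cohort = "all", rater = "rater1",
                              repeat_id = 1L, metric = "mtr_asym", value) {
  df <- data.frame(subject = as.character(subject), cohort = as.character(cohort),
                   rater = as.character(rater), repeat_id = repeat_id,
                   metric = as.character(metric), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  key <- paste(df$subject, df$rater, df$repeat_id, df$metric)
  if (anyDuplicated(key))
    stop("duplicate (subject, rater, repeat, metric) keys", call. = FALSE)
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Per-cohort descriptive summary of a metric
#'
#' Mean, standard deviation, median, range and the t-based 95\% confidence
#' interval of the mean, per cohort.
#'
#' @param table a \code{\link{measurement_table}} (or compatible data.frame).
#' @param metric metric name to summarise.
#' @param conf confidence level for the CI on the mean.
#' @return data.frame, one row per cohort.
#' @export
cohort_summary <- function(table, metric = "mtr_asym", conf = 0.95) {
  d <- table[table$metric == metric, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for metric '", metric, "'", call. = FALSE)
  out <- lapply(split(d$value, d$cohort), function(v) {
    n <- length(v); m <- mean(v); s <- if (n > 1) sd(v) else NA_real_
    half <- if (n > 1) qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n) else 0
    data.frame(n = n, mean = m, sd = s, median = median(v),
               min = min(v), max = max(v),
               ci_low = m - half, ci_high = m + half)
  })
  res <- do.call(rbind, out)
  res <- cbind(cohort = names(out), res)
  rownames(res) <- NULL
  res
}

#' Welch's t-test between two phantom cohorts
#'
#' Convenience comparison of a metric between the two cohorts of a synthetic
#' study. This is plumbing for phantom experiments, not the linear mixed
#' model used for in-vivo cohorts.
#'
#' @inheritParams cohort_summary
#' @return htest object from \code{t.test}.
#' @export
compare_cohorts <- function(table, metric = "mtr_asym") {
  d <- table[table$metric == metric, , drop = FALSE]
  co <- unique(d$cohort)
  if (length(co) != 2L) stop("exactly two cohorts required", call. = FALSE)
  t.test(value ~ cohort, data = d)
}

# two-way ANOVA mean squares for a complete subjects x raters matrix
anova_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  list(n = n, k = k, msr = msr, msc = msc, mse = mse)
}

#' Two-way random-effects intraclass correlation (single and average measure)
#'
#' Computes ICC(2,1) (single measure) and ICC(2,k) (average measure) from the
#' two-way ANOVA mean squares of a complete subjects-by-raters layout.
#' Default form is absolute agreement (the standard inter-rater choice);
#' consistency is available via \code{type}. Confidence bounds follow the
#' standard F-based construction with a Satterthwaite degrees-of-freedom
#' approximation for the agreement form; average-measure bounds are obtained
#' from the single-measure bounds by the Spearman-Brown relation.
#'
#' @param table a \code{\link{measurement_table}} with >= 2 raters; every
#'   subject must be measured by every rater (incomplete layouts are rejected
#'   with a report of the missing cells).
#' @param metric metric name.
#' @param type \code{"agreement"} (default) or \code{"consistency"}.
#' @param conf confidence level.
#' @return list with \code{sICC}, \code{aICC}, \code{sICC_ci}, \code{aICC_ci},
#'   \code{F}, \code{p}, \code{n_subjects}, \code{n_raters}.
#' @export
icc_two_way <- function(table, metric = "mtr_asym",
                        type = c("agreement", "consistency"), conf = 0.95) {
  type <- match.arg(type)
  d <- table[table$metric == metric, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for metric '", metric, "'", call. = FALSE)
  # collapse repeats within (subject, rater) by averaging
  agg <- stats::aggregate(value ~ subject + rater, data = d, FUN = mean)
  subjects <- sort(unique(agg$subject)); raters <- sort(unique(agg$rater))
  if (length(raters) < 2L) stop("need >= 2 raters for ICC", call. = FALSE)
  m <- matrix(NA_real_, length(subjects), length(raters),
              dimnames = list(subjects, raters))
  m[cbind(match(agg$subject, subjects), match(agg$rater, raters))] <- agg$value
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("incomplete two-way layout; missing cells: ",
         paste(sprintf("(%s, %s)", subjects[miss[, 1]], raters[miss[, 2]]),
               collapse = ", "), call. = FALSE)
  }
  ms <- anova_ms(m)
  n <- ms$n; k <- ms$k
  alpha <- 1 - conf
  eps <- .Machine$double.eps
  if (type == "agreement") {
    sicc <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
    aicc <- (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n)
    # F-based CI with Satterthwaite df (McGraw & Wong form)
    a <- (k * sicc) / (n * (1 - sicc) + eps)
    b <- 1 + (k * sicc * (n - 1)) / (n * (1 - sicc) + eps)
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms$msr - fl * (a * ms$msc + b * ms$mse)) /
      (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    hi <- n * (fu * ms$msr - a * ms$msc - b * ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
    sci <- c(lo, hi)
  } else {
    sicc <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    aicc <- (ms$msr - ms$mse) / ms$msr
    f0 <- ms$msr / ms$mse
    fl <- f0 / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f0 * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    sci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  sb <- function(r) k * r / (1 + (k - 1) * r)
  fstat <- ms$msr / ms$mse
  pval <- pf(fstat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(sICC = sicc, aICC = aicc, sICC_ci = sci, aICC_ci = sb(sci),
       F = fstat, p = pval, n_subjects = n, n_raters = k, type = type)
}
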