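# Pearson correlation structure of selected features and survival
# characterization: expression dichotomization (median or density valley),
# Kaplan-Meier curves and log-rank tests.

#' Pairwise Pearson correlations with two-sided p-values
#'
#' Standard product-moment correlations; p-values from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` df, two-sided.
#' Zero-variance features yield `NA` rows/columns (with a warning).
#'
#' @param x samples-by-features numeric matrix (>= 3 samples).
#' @return List of class `"correlation_result"` with `r`, `p` and `n`
#'   (samples used per pair).
#' @export
pearson_matrix <- function(x) {
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples")
  sds <- col_sds(x)
  if (any(sds == 0)) {
    warning("zero-variance feature(s); correlations reported as NA")
  }
  r <- suppressWarnings(stats::cor(x))
  r[, sds == 0] <- NA_real_
  r[sds == 0, ] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  nmat <- matrix(n, ncol(x), ncol(x), dimnames = dimnames(r))
  structure(list(r = r, p = p, n = nmat), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Pearson correlation over", ncol(x$r), "features,", x$n[1L],
      "samples\n")
  invisible(x)
}

#' Split expression values into low/high groups
#'
#' If the Gaussian kernel density (Silverman bandwidth, 512-point grid)
#' shows at least two peaks with prominence at least `prominence_frac`
#' times the density maximum, the cutoff is the density minimum between
#' the two most prominent peaks; otherwise the median is used. Values
#' `<= cutoff` are `"low"`.
#'
#' @param values numeric vector (>= 10 samples, non-constant).
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   density maximum (default 0.05).
#' @return List with `groups` (factor low/high), `cutoff` and `method`
#'   (`"median"` or `"density_valley"`).
#' @export
dichotomize_expression <- function(values, prominence_frac = 0.05) {
  if (length(values) < 10L) stop("need at least 10 samples")
  if (stats::sd(values) == 0) stop("constant values cannot be dichotomized")
  dens <- stats::density(values, bw = "nrd0", n = 512L)
  y <- dens$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  prominence <- vapply(peaks, function(i) {
    higher <- peaks[y[peaks] > y[i]]
    saddle <- 0
    if (length(higher)) {
      left <- higher[higher < i]
      right <- higher[higher > i]
      sl <- if (length(left)) min(y[max(left):i]) else NA_real_
      sr <- if (length(right)) min(y[i:min(right)]) else NA_real_
      saddle <- max(sl, sr, na.rm = TRUE)
    }
    y[i] - saddle
  }, numeric(1L))
  keep <- peaks[prominence >= prominence_frac * max(y)]
  if (length(keep) >= 2L) {
    top2 <- sort(keep[order(-prominence[match(keep, peaks)])][1:2])
    valley <- seq(top2[1L], top2[2L])
    cutoff <- dens$x[valley[which.min(y[valley])]]
    method <- "density_valley"
  } else {
    cutoff <- stats::median(values)
    method <- "median"
  }
  groups <- factor(ifelse(values <= cutoff, "low", "high"),
                   levels = c("low", "high"))
  list(groups = groups, cutoff = cutoff, method = method)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive event/censoring times.
#' @param event event indicator (1 = event, 0 = censored).
#' @return List of class `"km_curve"` with `time` (distinct observed
#'   times), `n_risk`, `n_event`, `n_censor` and `surv` (the step-function
#'   estimate S(t)).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("empty input")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = fit$surv),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", sum(x$n_event), "events over",
      length(x$time), "time points\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = "time", ylab = "S(t)", ylim = c(0, 1),
                 main = "Kaplan-Meier estimate", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' The standard hypergeometric-moment form: at each event time the
#' observed minus expected events in group 1 are summed and squared over
#' the variance, referred to a chi-squared distribution with 1 df. When a
#' group has no events the statistic is reported as `NA` with a warning.
#'
#' @param time positive times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param groups two-level group vector.
#' @return List with `statistic` (chi-squared) and `p`.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("exactly 2 groups are required")
  if (any(tapply(event, groups, sum) == 0)) {
    warning("a group has no events; log-rank statistic undefined")
    return(list(statistic = NA_real_, p = NA_real_))
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ groups)
  stat <- sd_fit$chisq
  list(statistic = stat, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Survival screen of selected features
#'
#' For each feature (and optionally within each cohort), dichotomizes the
#' expression values into low/high groups and runs the log-rank test.
#'
#' @param x samples-by-features matrix of expression values.
#' @param time,event survival outcome per sample.
#' @param cohort optional cohort vector; the screen runs separately within
#'   each cohort.
#' @param prominence_frac passed to [dichotomize_expression()].
#' @return Data frame with `feature`, `cohort`, `cutoff`, `method`,
#'   `statistic`, `p`.
#' @export
survival_screen <- function(x, time, event, cohort = NULL,
                            prominence_frac = 0.05) {
  if (is.null(cohort)) cohort <- rep("all", length(time))
  cohort <- as.factor(cohort)
  rows <- list()
  for (co in levels(cohort)) {
    idx <- cohort == co
    for (j in seq_len(ncol(x))) {
      feat <- colnames(x)[j] %||% paste0("V", j)
      res <- tryCatch({
        d <- dichotomize_expression(x[idx, j], prominence_frac)
        lr <- suppressWarnings(logrank_test(time[idx], event[idx], d$groups))
        data.frame(feature = feat, cohort = co, cutoff = d$cutoff,
                   method = d$method, statistic = lr$statistic, p = lr$p,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(feature = feat, cohort = co, cutoff = NA_real_,
                   method = NA_character_, statistic = NA_real_, p = NA_real_,
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
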