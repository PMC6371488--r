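# Method-agreement statistics for paired measurements: Bland-Altman limits
# of agreement, relative percent differences, Spearman correlation, the
# two-way absolute-agreement single-measure ICC, and the power of the
# one-sided ICC F test.

#' Paired measurements from two methods or observers
#'
#' @param a,b equal-length numeric vectors (method A vs method B), no
#'   missing values, length >= 2.
#' @param label description for reports.
#' @return object of class `paired_measurements`.
#' @export
paired_measurements <- function(a, b, label = "") {
  stopifnot(length(a) == length(b), length(a) >= 2,
            !anyNA(a), !anyNA(b))
  structure(list(a = as.numeric(a), b = as.numeric(b), label = label),
            class = "paired_measurements")
}

.as_paired <- function(p, b = NULL, label = "") {
  if (inherits(p, "paired_measurements")) p else paired_measurements(p, b, label)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b`; limits of agreement are the mean difference
#' +/- 1.96 sample standard deviations (the conventional 95% LOA). Relative
#' percent differences use the pairwise mean as denominator,
#' `100 * (a - b) / ((a + b) / 2)`, and are summarized the same way; pairs
#' with `a + b = 0` are excluded from the relative summary with a warning.
#'
#' @param p a [paired_measurements] (or the `a` vector, with `b` given).
#' @param b optional second vector when `p` is numeric.
#' @return object of class `agreement_report` with `n`, `mean_diff`,
#'   `sd_diff`, `loa_lo`, `loa_hi`, `mean_rel_pct`, `sd_rel_pct`,
#'   `rel_loa_lo`, `rel_loa_hi`.
#' @export
bland_altman <- function(p, b = NULL) {
  p <- .as_paired(p, b)
  d <- p$a - p$b
  m <- mean(d)
  s <- stats::sd(d)
  denom <- (p$a + p$b) / 2
  keep <- denom != 0
  if (!all(keep)) {
    warning(sprintf("%d pair(s) with a + b = 0 excluded from relative %% summary",
                    sum(!keep)), call. = FALSE)
  }
  rel <- 100 * d[keep] / denom[keep]
  mr <- if (length(rel)) mean(rel) else NA_real_
  sr <- if (length(rel) >= 2) stats::sd(rel) else NA_real_
  structure(list(
    label = p$label, n = length(d),
    mean_diff = m, sd_diff = s,
    loa_lo = m - 1.96 * s, loa_hi = m + 1.96 * s,
    mean_rel_pct = mr, sd_rel_pct = sr,
    rel_loa_lo = mr - 1.96 * sr, rel_loa_hi = mr + 1.96 * sr
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report>%s n = %d\n",
              if (nzchar(x$label)) paste0(" ", x$label, ",") else "", x$n))
  cat(sprintf("  mean diff %.4g (95%% LOA %.4g to %.4g)\n",
              x$mean_diff, x$loa_lo, x$loa_hi))
  if (!is.na(x$mean_rel_pct)) {
    cat(sprintf("  relative %% %.3g (LOA %.3g to %.3g)\n",
                x$mean_rel_pct, x$rel_loa_lo, x$rel_loa_hi))
  }
  if (!is.null(x$spearman_rho)) cat(sprintf("  Spearman rho %.4f\n", x$spearman_rho))
  if (!is.null(x$icc)) cat(sprintf("  ICC(2,1) %.4f\n", x$icc))
  invisible(x)
}

#' Spearman rank correlation of paired measurements
#'
#' Pearson correlation of the ranks (average ranks for ties).
#'
#' @inheritParams bland_altman
#' @return the correlation coefficient, between -1 and 1.
#' @export
spearman_rho <- function(p, b = NULL) {
  p <- .as_paired(p, b)
  stopifnot(length(p$a) >= 3)
  if (stats::var(rank(p$a)) == 0 || stats::var(rank(p$b)) == 0) {
    stop("Spearman correlation undefined: zero rank variance", call. = FALSE)
  }
  stats::cor(p$a, p$b, method = "spearman")
}

#' Intraclass correlation, two-way absolute agreement, single measure
#'
#' ICC(2,1): subjects and methods both random, absolute agreement, from the
#' mean squares of the subjects x methods table:
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))}
#' where MS_R, MS_C, MS_E are the subject, method and residual mean squares.
#' Systematic bias between methods lowers the coefficient.
#'
#' @inheritParams bland_altman
#' @return the ICC (<= 1).
#' @export
icc_absolute <- function(p, b = NULL) {
  p <- .as_paired(p, b)
  n <- length(p$a)
  stopifnot(n >= 3)
  k <- 2
  y <- cbind(p$a, p$b)
  grand <- mean(y)
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((y - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (!is.finite(denom) || denom <= 0) {
    stop("degenerate variance: ICC undefined", call. = FALSE)
  }
  (msr - mse) / denom
}

#' Power of the one-sided ICC hypothesis test
#'
#' For the test of H0: ICC = `icc0` against H1: ICC = `icc1` based on the
#' between/within mean-square F ratio of a one-way design with `n` subjects
#' and `k` measurements each, using
#' \deqn{\theta(\rho) = (1 + (k-1)\rho) / (1-\rho)}
#' the statistic divided by \eqn{\theta} of the true ICC follows
#' F(n-1, n(k-1)), so
#' \deqn{power = P\left(F > \frac{\theta(icc0)}{\theta(icc1)} F_{1-\alpha}\right)}
#'
#' @param icc0 null ICC (0 <= icc0 <= icc1).
#' @param icc1 alternative ICC (< 1); when equal to `icc0` the power is the
#'   test size `alpha`.
#' @param n number of subjects (>= 2).
#' @param k measurements per subject (>= 2).
#' @param alpha one-sided type-1 error rate.
#' @return the power, a fraction in (0, 1].
#' @export
icc_power <- function(icc0, icc1, n, k = 2, alpha = 0.05) {
  stopifnot(icc0 >= 0, icc0 <= icc1, icc1 < 1, n >= 2, k >= 2,
            alpha > 0, alpha < 1)
  theta <- function(rho) (1 + (k - 1) * rho) / (1 - rho)
  df1 <- n - 1
  df2 <- n * (k - 1)
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(theta(icc0) / theta(icc1) * crit, df1, df2, lower.tail = FALSE)
}

#' Full method-agreement report
#'
#' Bland-Altman difference summary plus Spearman correlation and ICC(2,1)
#' in one object.
#'
#' @inheritParams bland_altman
#' @return an `agreement_report` with `spearman_rho` and `icc` fields added.
#' @export
agreement_report <- function(p, b = NULL) {
  p <- .as_paired(p, b)
  rep <- bland_altman(p)
  rep$spearman_rho <- tryCatch(spearman_rho(p), error = function(e) NA_real_)
  rep$icc <- tryCatch(icc_absolute(p), error = function(e) NA_real_)
  rep
}

#' Compare a measurement column between two CSV exports
#'
#' Joins two [write_measurements_csv] files on marker id and slice, and runs
#' [agreement_report] on the chosen column.
#'
#' @param path_a,path_b measurement CSV paths.
#' @param column column to compare (default `area_cm2`).
#' @return an `agreement_report`.
#' @export
compare_measurements <- function(path_a, path_b, column = "area_cm2") {
  a <- read_measurements_csv(path_a)
  b <- read_measurements_csv(path_b)
  key <- function(d) paste(d$marker_id, d$slice_series_uid, d$slice_instance)
  m <- merge(data.frame(k = key(a), va = a[[column]]),
             data.frame(k = key(b), vb = b[[column]]), by = "k")
  if (nrow(m) < 2) stop("fewer than 2 matched rows between the two files",
                        call. = FALSE)
  agreement_report(paired_measurements(m$va, m$vb,
                                       label = sprintf("%s (%d rows)",
                                                       column, nrow(m))))
}
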