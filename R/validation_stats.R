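#' Bland-Altman agreement analysis
#'
#' Differences are taken as `test - reference`. Bias is the mean
#' difference; limits of agreement are bias +/- 1.96 times the sample SD
#' (n - 1) of the differences.
#'
#' @param test_values,reference_values Equal-length numeric vectors,
#'   n >= 3.
#' @return List: n, bias, sd_diff, loa_lower, loa_upper, and a `points`
#'   data.frame with per-pair (mean, diff) for plotting.
#' @export
#' @examples
#' bland_altman(c(2, 3, 4), c(1, 2, 3))
bland_altman <- function(test_values, reference_values) {
  if (length(test_values) != length(reference_values))
    stop("vectors must have equal length")
  ok <- complete.cases(test_values, reference_values)
  x <- test_values[ok]; y <- reference_values[ok]
  if (length(x) < 3) stop("need at least 3 paired values")
  d <- x - y
  bias <- mean(d)
  sdd <- sd(d)
  list(n = length(x), bias = bias, sd_diff = sdd,
       loa_lower = bias - 1.96 * sdd, loa_upper = bias + 1.96 * sdd,
       points = data.frame(mean = (x + y) / 2, diff = d))
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both with nonzero
#'   variance.
#' @return Correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  cor(x, y)
}

#' Paired Student t test
#'
#' Two-sided one-sample t test on the differences `x - y` with
#' `df = n - 1`. Zero-variance differences with a nonzero mean cannot be
#' tested parametrically; the result carries `degenerate = TRUE` with a
#' p-value of 0.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return List: t, p, df, mean_diff, degenerate.
#' @export
paired_t <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired values")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, df = length(d) - 1, mean_diff = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}

#' Passing-Bablok method-comparison regression
#'
#' Nonparametric regression for method comparison: the slope is the
#' shifted median of all pairwise slopes S_ij = (y_j - y_i)/(x_j - x_i),
#' i < j. Following the original procedure, slopes equal to -1 are
#' discarded, pairs with identical x and y are skipped, vertical pairs
#' contribute infinite slopes with the sign of dy, and the median index is
#' shifted by K, the number of slopes below -1, making the estimate
#' invariant to exchanging the methods. Confidence intervals use the
#' conventional rank-based normal approximation; the intercept is
#' median(y - slope * x) with its CI evaluated at the slope CI bounds.
#'
#' @param x,y Equal-length numeric vectors, n >= 10; x not all equal.
#' @return Object of class `pb_fit`: slope, intercept, slope_ci,
#'   intercept_ci, n.
#' @export
#' @examples
#' x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
#' passing_bablok(x, 2 * x + 1)$slope
passing_bablok <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 paired values")
  if (length(unique(x)) == 1) stop("x values are all identical")
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- !(dx == 0 & dy == 0)
  dx <- dx[keep]; dy <- dy[keep]
  S <- ifelse(dx == 0, sign(dy) * Inf, dy / dx)
  S <- S[S != -1]
  S <- sort(S)
  N <- length(S)
  K <- sum(S < -1)
  slope <- if (N %% 2 == 1) S[(N + 1) / 2 + K]
           else mean(S[c(N / 2 + K, N / 2 + 1 + K)])
  w <- qnorm(0.975) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- max(1L, as.integer(round((N - w) / 2)))
  M2 <- min(N, as.integer(N - M1 + 1))
  lo <- S[min(max(M1 + K, 1L), N)]
  hi <- S[min(max(M2 + K, 1L), N)]
  intercept <- median(y - slope * x)
  int_ci <- sort(c(median(y - hi * x), median(y - lo * x)))
  structure(list(slope = slope, intercept = intercept,
                 slope_ci = c(lo, hi), intercept_ci = int_ci, n = n),
            class = "pb_fit")
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf("<pb_fit> n = %d\n  slope %.4f (95%% CI %.4f-%.4f)\n  intercept %.4f (95%% CI %.4f-%.4f)\n",
              x$n, x$slope, x$slope_ci[1], x$slope_ci[2],
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}

#' Kolmogorov-Smirnov normality check
#'
#' KS distance of the sample against a normal with the sample mean and SD,
#' with the standard asymptotic p-value. (The fitted-parameter version the
#' field's standard software reports; it is anti-conservative relative to
#' Lilliefors.)
#'
#' @param x Numeric vector, n >= 5, nonconstant.
#' @return List: statistic, p.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("need at least 5 values")
  if (sd(x) == 0) stop("constant vector")
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Precision summary against EFLM goals
#'
#' Within-run precision per concentration range: mean, sample SD (n - 1)
#' and CV; per analyte the mean CV over its ranges is compared with the
#' EFLM allowable-imprecision goal.
#'
#' @param replicate_table data.frame with columns analyte, range
#'   (label), value (replicate measurements; NA rows mark a missing
#'   range).
#' @param goals Named CV goals in percent, see [eflm_goals()].
#' @return Object of class `precision_report`: `ranges` (per analyte x
#'   range: n, mean, sd, cv, pass) and `analytes` (mean_cv, goal,
#'   pass_mean = mean CV within goal, pass_all = every range within goal).
#' @export
#' @examples
#' tab <- data.frame(analyte = "rbc", range = "4.0",
#'                   value = c(4.0, 4.1, 3.9, 4.0))
#' precision_summary(tab)$ranges
precision_summary <- function(replicate_table, goals = eflm_goals()) {
  stopifnot(all(c("analyte", "range", "value") %in% names(replicate_table)))
  keys <- unique(replicate_table[, c("analyte", "range")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    v <- replicate_table$value[replicate_table$analyte == keys$analyte[i] &
                                 replicate_table$range == keys$range[i]]
    v <- v[is.finite(v)]
    if (length(v) < 2)
      return(data.frame(analyte = keys$analyte[i], range = keys$range[i],
                        n = length(v), mean = NA_real_, sd = NA_real_,
                        cv = NA_real_, pass = NA))
    m <- mean(v); s <- sd(v); cv <- 100 * s / m
    goal <- goals[[keys$analyte[i]]]
    data.frame(analyte = keys$analyte[i], range = keys$range[i],
               n = length(v), mean = m, sd = s, cv = cv,
               pass = if (is.null(goal)) NA else cv <= goal)
  })
  ranges <- do.call(rbind, rows)
  analytes <- do.call(rbind, lapply(unique(ranges$analyte), function(a) {
    cvs <- ranges$cv[ranges$analyte == a]
    goal <- goals[[a]]
    mean_cv <- mean(cvs)  # NA if any range missing: not dropped silently
    data.frame(analyte = a, mean_cv = mean_cv,
               goal = if (is.null(goal)) NA_real_ else goal,
               pass_mean = if (is.null(goal)) NA else mean_cv <= goal,
               pass_all = if (is.null(goal)) NA else
                 all(cvs <= goal))
  }))
  structure(list(ranges = ranges, analytes = analytes),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("<precision_report>\n")
  print(x$analytes, row.names = FALSE)
  invisible(x)
}

#' Mean CV per analyte from a table of published per-range CVs
#'
#' Worked-example helper: averages already-computed per-range CVs (for
#' instance the repeatability and reproducibility columns of a published
#' precision study) into the per-analyte mean CV that is compared with the
#' EFLM goal.
#'
#' @param cv_table data.frame with columns analyte and cv (%).
#' @param goals Named CV goals in percent.
#' @return data.frame: analyte, mean_cv, goal, pass.
#' @export
summarize_range_cvs <- function(cv_table, goals = eflm_goals()) {
  stopifnot(all(c("analyte", "cv") %in% names(cv_table)))
  out <- do.call(rbind, lapply(unique(cv_table$analyte), function(a) {
    m <- mean(cv_table$cv[cv_table$analyte == a])
    goal <- goals[[a]]
    data.frame(analyte = a, mean_cv = m,
               goal = if (is.null(goal)) NA_real_ else goal,
               pass = if (is.null(goal)) NA else m <= goal)
  }))
  rownames(out) <- NULL
  out
}

#' In/out-of-reference-range concordance
#'
#' Each paired value is binarized by the sex-specific reference interval;
#' "outside the range" is the positive (disease-predictive) class. One
#' confusion matrix per analyte compares the test method's classification
#' with the reference method's.
#'
#' @param test_panels,reference_panels data.frames with columns analyte,
#'   value, sex, and a shared sample identity (row-aligned).
#' @param ranges Reference intervals, see [reference_ranges()].
#' @return Named list of [confusion_metrics()] per analyte.
#' @export
range_concordance <- function(test_panels, reference_panels,
                              ranges = reference_ranges()) {
  stopifnot(nrow(test_panels) == nrow(reference_panels))
  if (any(!test_panels$sex %in% c("F", "M")))
    stop("unknown sex label in panels")
  out <- list()
  for (a in unique(test_panels$analyte)) {
    ti <- test_panels$analyte == a
    tv <- test_panels$value[ti]; tsex <- test_panels$sex[ti]
    rv <- reference_panels$value[reference_panels$analyte == a]
    ok <- is.finite(tv) & is.finite(rv)
    if (!any(ok)) next
    outside <- function(v, s) {
      lo <- hi <- numeric(length(v))
      for (sx in c("F", "M")) {
        rr <- reference_range(a, sx, ranges)
        lo[s == sx] <- rr[["low"]]; hi[s == sx] <- rr[["high"]]
      }
      v < lo | v > hi
    }
    p <- outside(tv[ok], tsex[ok])
    t <- outside(rv[ok], tsex[ok])
    out[[a]] <- confusion_metrics(tp = sum(p & t), fp = sum(p & !t),
                                  tn = sum(!p & !t), fn = sum(!p & t))
  }
  out
}

#' Full method-comparison battery on a paired dataset
#'
#' Per analyte: Pearson correlation, paired t test, Bland-Altman bias and
#' limits of agreement, Passing-Bablok regression (when n >= 10), and
#' in/out-of-range concordance.
#'
#' @param paired A data.frame with columns sample_id, analyte, test,
#'   reference, sex (long format, one row per sample x analyte), e.g. from
#'   [make_validation_dataset()] measurements renamed, or read from CSV.
#' @param ranges Reference intervals for the concordance step.
#' @return List of class `comparison_report`: `comparison` (per-analyte
#'   data.frame with n, r, bias, sd_diff, loa, t, p, pb_slope,
#'   pb_intercept) and `concordance` (per-analyte confusion metrics
#'   table).
#' @export
run_method_comparison <- function(paired, ranges = reference_ranges()) {
  stopifnot(all(c("analyte", "test", "reference", "sex") %in% names(paired)))
  analytes <- unique(paired$analyte)
  rows <- list()
  conc_rows <- list()
  for (a in analytes) {
    sub <- paired[paired$analyte == a, ]
    sub <- sub[complete.cases(sub$test, sub$reference), ]
    if (nrow(sub) < 3)
      stop("need at least 3 complete pairs for analyte ", a)
    ba <- bland_altman(sub$test, sub$reference)
    # a degenerate analyte (e.g. a vanishing cell population counted as
    # zero throughout) reports NA rather than aborting the battery
    r <- tryCatch(pearson_r(sub$test, sub$reference),
                  error = function(e) NA_real_)
    tt <- paired_t(sub$test, sub$reference)
    pb <- if (nrow(sub) >= 10 && length(unique(sub$reference)) > 1)
      tryCatch(passing_bablok(sub$reference, sub$test),
               error = function(e) NULL) else NULL
    rows[[a]] <- data.frame(
      analyte = a, n = ba$n, r = r, bias = ba$bias, sd_diff = ba$sd_diff,
      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
      t = tt$t, p = tt$p,
      pb_slope = if (is.null(pb)) NA_real_ else pb$slope,
      pb_intercept = if (is.null(pb)) NA_real_ else pb$intercept)
    if (a %in% ranges$analyte) {
      cm <- range_concordance(
        data.frame(analyte = a, value = sub$test, sex = sub$sex),
        data.frame(analyte = a, value = sub$reference, sex = sub$sex),
        ranges)[[a]]
      conc_rows[[a]] <- data.frame(
        analyte = a, tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
        accuracy = cm$accuracy, sensitivity = cm$sensitivity,
        specificity = cm$specificity, kappa = cm$kappa,
        balanced_accuracy = cm$balanced_accuracy)
    }
  }
  structure(list(comparison = do.call(rbind, c(rows,
                                               list(make.row.names = FALSE))),
                 concordance = if (length(conc_rows))
                   do.call(rbind, c(conc_rows, list(make.row.names = FALSE)))
                 else NULL),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$comparison, row.names = FALSE, digits = 3)
  invisible(x)
}
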