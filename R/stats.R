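# Statistical battery for volumetric reliability and outcome analysis:
# descriptive stats in the clinical table layout, paired Wilcoxon
# signed-rank (normal approximation), Spearman rank correlation, and
# two-way absolute-agreement intraclass correlation (McGraw-Wong forms)
# with 95% F-based confidence intervals.

#' Descriptive statistics (mean, sample SD, CV)
#'
#' @param values numeric vector (e.g. per-segment delta-V in mm^3).
#' @return List with `mean`, `sd` (n-1 denominator), `cv` (= sd/mean), `n`.
#' @export
descriptive <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stopf("sample SD needs at least 2 values (got %d)", n)
  m <- mean(values)
  s <- sd(values)
  if (m == 0) stopf("CV undefined for zero mean")
  list(mean = m, sd = s, cv = s / m, n = n)
}

test_result <- function(statistic, p_value, method, n, ci = NULL, extra = list()) {
  structure(c(list(statistic = statistic, p_value = p_value, method = method,
                   n = n, ci = ci), extra),
            class = "canal3d_test")
}

#' @export
print.canal3d_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.6g, p = %.4g (n = %d)\n",
              x$method, x$statistic, x$p_value, x$n))
  if (!is.null(x$ci))
    cat(sprintf("  95%% CI [%.4g, %.4g]\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test on `post - pre`. Zero differences are
#' dropped (Wilcoxon convention; the count is reported). Ranks of the
#' absolute differences use average ranks for ties; the test statistic is
#' the positive-rank sum W, and the default p-value comes from the normal
#' approximation `z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` without
#' continuity correction. Exact enumeration over all 2^n sign patterns is
#' available for small samples.
#'
#' @param pre,post paired numeric vectors of equal length (n >= 5 after
#'   dropping zeros is recommended).
#' @param exact use exact enumeration (only allowed for n <= 12 pairs).
#' @return A test result with `statistic` (W), `p_value`, `z`, and
#'   `n_zero_dropped`.
#' @export
wilcoxon_signed_rank <- function(pre, post, exact = FALSE) {
  if (length(pre) != length(post)) stopf("pre and post must have equal length")
  d <- as.numeric(post) - as.numeric(pre)
  nz <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stopf("all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (exact) {
    if (n > 12) stopf("exact enumeration limited to n <= 12 (got %d)", n)
    # distribution of W over all 2^n sign assignments with these ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.numeric(signs %*% r)
    mu <- n * (n + 1) / 4
    p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
    z <- NA_real_
    method <- "Paired Wilcoxon signed-rank (exact enumeration), two-sided"
  } else {
    z <- (W - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
    p <- 2 * pnorm(-abs(z))
    method <- "Paired Wilcoxon signed-rank (normal approximation, no continuity correction), two-sided"
  }
  test_result(W, p, method, n, extra = list(z = z, n_zero_dropped = nz))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks; the p-value uses the
#' t approximation `t = rho sqrt((n-2)/(1-rho^2))` with n-2 degrees of
#' freedom (two-sided). Invariant under strictly monotone transforms of
#' either variable.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @return A test result with `statistic` (rho) and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 4) stopf("Spearman correlation needs n >= 4 (got %d)", n)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stopf("Spearman correlation undefined for a constant vector")
  rho <- cor(rank(x), rank(y))
  if (1 - abs(rho) < 1e-12) rho <- sign(rho) # exact ranks, exact +/-1
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  test_result(rho, p, "Spearman rank correlation (t approximation), two-sided", n)
}

#' Intraclass correlation, two-way model, absolute agreement
#'
#' ICC for a complete subjects x raters matrix under the two-way model with
#' absolute agreement (McGraw-Wong), either the single-measurement form
#' ICC(A,1) or the mean-of-k-raters form ICC(A,k). Point estimates for the
#' two-way mixed and two-way random models coincide (standard result); 95%
#' confidence bounds come from the corresponding F-distribution quantiles.
#'
#' @param data numeric matrix or data.frame, rows = subjects/segments,
#'   columns = raters or rater-timepoint combinations (no missing cells).
#' @param form `"single"` for ICC(A,1) or `"mean_k"` for ICC(A,k).
#' @param conf_level confidence level (default 0.95).
#' @return A test result with `statistic` (the ICC) and `ci`.
#' @export
icc_absolute <- function(data, form = c("single", "mean_k"), conf_level = 0.95) {
  form <- match.arg(form)
  x <- as.matrix(data)
  if (anyNA(x)) stopf("ICC requires a complete matrix")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) stopf("ICC needs >= 2 subjects and >= 2 raters")
  grand <- mean(x)
  if (sum((x - grand)^2) == 0) stopf("ICC undefined: zero total variance")
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)                  # rows (subjects)
  msc <- n * sum((cm - grand)^2) / (k - 1)                   # columns (raters)
  sse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # Satterthwaite dof for the A,1 bounds (McGraw & Wong)
  a <- (k * icc1) / (n * (1 - icc1))
  b <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lb1 <- n * (msr - FL * mse) / (FL * (k * msc + (k * n - k - n) * mse) + n * msr)
  ub1 <- n * (FU * msr - mse) / (k * msc + (k * n - k - n) * mse + n * FU * msr)
  if (form == "single") {
    return(test_result(icc1, NA_real_,
                       sprintf("ICC(A,1), two-way, absolute agreement (k = %d)", k),
                       n, ci = c(lb1, ub1)))
  }
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  sb <- function(r) r * k / (1 + (k - 1) * r) # Spearman-Brown step-up
  test_result(icck, NA_real_,
              sprintf("ICC(A,%d), two-way, absolute agreement, mean rating", k),
              n, ci = c(sb(lb1), sb(ub1)))
}

#' Correlate per-patient delta-V with outcome changes
#'
#' Averages delta-V over segments within each patient (multi-segment
#' procedures contribute one patient-level value), joins on patient ID, and
#' runs a Spearman correlation of delta-V against every outcome column.
#'
#' @param delta_v data.frame with columns `patient` and `delta_v_mm3`
#'   (one row per treated segment).
#' @param outcomes data.frame with a `patient` column and one column per
#'   outcome change score (e.g. change in disability or pain scores).
#' @return Named list of test results, one per outcome column.
#' @export
correlate_outcomes <- function(delta_v, outcomes) {
  if (!all(c("patient", "delta_v_mm3") %in% names(delta_v)))
    stopf("delta_v needs columns patient, delta_v_mm3")
  if (!"patient" %in% names(outcomes))
    stopf("outcomes needs a patient column")
  per_patient <- aggregate(delta_v_mm3 ~ patient, data = delta_v, FUN = mean)
  merged <- merge(per_patient, outcomes, by = "patient")
  if (nrow(merged) < 4)
    stopf("fewer than 4 matched patients (%d)", nrow(merged))
  cols <- setdiff(names(outcomes), "patient")
  setNames(lapply(cols, function(cl) spearman_rho(merged$delta_v_mm3, merged[[cl]])),
           cols)
}

#' Published per-segment volumetry table
#'
#' The packaged per-segment measurement table of the PCD cohort (16 treated
#' segments in 10 patients): cylinder geometry, rater-averaged V_preop,
#' V_postop and delta-V, with the across-rater SD and CV of delta-V.
#'
#' @return data.frame with one row per treated segment.
#' @export
pcd_table2 <- function() {
  read.csv(system.file("extdata", "pcd_table2.csv", package = "canal3d",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}
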