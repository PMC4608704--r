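#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by the point-probability rule: with margins
#' fixed, sum the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (ties included up
#' to a 1e-7 relative tolerance). A zero margin returns p = 1.
#'
#' @param table 2x2 matrix of non-negative integer cells `[[a,b],[c,d]]`.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  if (a + b + c + d == 0) stopf("empty table")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) return(1)
  kk <- max(0L, (a + b) - (b + d)):min(a + b, a + c)
  pk <- dhyper(kk, a + b, c + d, a + c)
  p_obs <- dhyper(a, a + b, c + d, a + c)
  min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
}

#' qPCR relative quantification (delta-Ct)
#'
#' Relative quantity against the reference (housekeeping) gene:
#' `2^-(Ct_target - Ct_reference) * 1e6`. Targets whose Ct exceeds the
#' cut-off (default 32) are called not expressed and return `NA`.
#'
#' @param ct_target numeric vector of target Ct values.
#' @param ct_reference numeric vector of reference-gene Ct values.
#' @param cutoff Ct cut-off above which the target is not expressed.
#' @return numeric vector of relative quantities (`NA` = not expressed).
#' @export
qpcr_relative_quantity <- function(ct_target, ct_reference, cutoff = 32) {
  stopifnot(all(ct_target > 0), all(ct_reference > 0))
  q <- 2^(-(ct_target - ct_reference)) * 1e6
  q[ct_target > cutoff] <- NA_real_
  q
}

#' Quantify a qPCR Ct table
#'
#' Applies [qpcr_relative_quantity()] row-wise; useful for building the
#' heat-map-ready matrix with not-expressed cells blanked.
#'
#' @param ct_table data.frame from [read_ct_table()].
#' @param cutoff Ct cut-off (default 32).
#' @return the table with `quantity` and `expressed` columns added.
#' @export
quantify_ct_table <- function(ct_table, cutoff = 32) {
  ct_table$quantity <- qpcr_relative_quantity(ct_table$ct_target,
                                              ct_table$ct_reference, cutoff)
  ct_table$expressed <- !is.na(ct_table$quantity)
  ct_table
}

#' Estimate qPCR amplification efficiency (window of linearity)
#'
#' The baseline is the mean of the first three cycles. When the curve has
#' reached a plateau (the last three cycles rise by under 5% of the curve
#' maximum), the saturation is inverted before fitting: with plateau `P`,
#' the underlying exponential is `x = s * P / (P - s)` for baseline-
#' subtracted signal `s`, which removes the slope compression that the
#' approach to plateau otherwise causes. Candidate windows of `window_size`
#' consecutive cycles must sit above the baseline noise floor (5 baseline
#' standard deviations) and below half the plateau; among candidates, the
#' window maximizing the R-squared of the linear fit to `log10(x)` is
#' selected and efficiency = 10^slope (reported to 1e-6). When no window
#' qualifies, any above-baseline window is used without correction.
#' Efficiencies strictly above 1.8 are flagged acceptable.
#'
#' @param fluorescence numeric vector of per-cycle fluorescence.
#' @param window_size window length in cycles (default 6; the
#'   window-of-linearity approach typically uses 4-6 points, and the longer
#'   window keeps the slope variance low on noisy curves).
#' @return list with `efficiency`, `window` (cycle indices), `r_squared`,
#'   `acceptable` (`efficiency > 1.8`).
#' @export
estimate_efficiency <- function(fluorescence, window_size = 6L) {
  n <- length(fluorescence)
  stopifnot(n >= window_size + 3L)
  baseline <- mean(fluorescence[1:3])
  noise_sd <- stats::sd(fluorescence[1:3])
  signal <- fluorescence - baseline
  smax <- max(signal)
  saturated <- (signal[n] - signal[n - 3L]) < 0.05 * smax
  x <- signal
  ok_hi <- rep(TRUE, n)
  if (saturated) {
    ok_hi <- signal < 0.5 * smax
    x <- ifelse(signal > 0 & signal < 0.8 * smax,
                signal * smax / (smax - signal), NA_real_)
  }
  lo <- max(5 * noise_sd, 1e-12)
  pick <- function(ok, xv) {
    best <- NULL
    for (s in seq_len(n - window_size + 1L)) {
      win <- s:(s + window_size - 1L)
      if (!all(ok[win]) || anyNA(xv[win])) next
      y <- log10(xv[win])
      fit <- lm(y ~ win)
      r2 <- summary(fit)$r.squared
      if (is.null(best) || r2 > best$r2) {
        best <- list(r2 = r2, slope = coef(fit)[2], window = win)
      }
    }
    best
  }
  best <- pick(signal > lo & ok_hi, x)
  if (is.null(best)) best <- pick(signal > 0, signal)
  if (is.null(best)) stopf("no above-baseline window of %d cycles",
                           window_size)
  eff <- round(unname(10^best$slope), 6L)
  list(efficiency = eff, window = best$window, r_squared = best$r2,
       acceptable = eff > 1.8)
}
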