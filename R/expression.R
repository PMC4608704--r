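#' Reads-per-million normalization
#'
#' `rpm[i,s] = counts[i,s] / total[s] * 1e6`, where the per-sample total is
#' the column sum over the supplied loci unless per-sample mapped-read
#' totals are given.
#'
#' @param counts integer matrix (loci x samples).
#' @param totals optional named per-sample mapped-read totals.
#' @return numeric matrix of RPM values.
#' @export
rpm_normalize <- function(counts, totals = NULL) {
  if (is.null(totals)) totals <- colSums(counts)
  else totals <- totals[colnames(counts)]
  if (any(totals <= 0)) stopf("zero column total in RPM normalization")
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Flag expressed loci
#'
#' A locus is expressed when its RPM reaches `threshold` in at least
#' `min_samples` samples (across all supplied sample sets).
#'
#' @param rpm matrix from [rpm_normalize()] (several matrices may be
#'   column-bound beforehand).
#' @param threshold RPM threshold (default 1, inclusive).
#' @param min_samples minimum number of qualifying samples (default 1).
#' @return named logical vector per locus.
#' @export
flag_expressed <- function(rpm, threshold = 1, min_samples = 1L) {
  setNames(rowSums(rpm >= threshold) >= min_samples, rownames(rpm))
}

#' Median-of-ratios size factors
#'
#' `factor_s = median_i counts[i,s] / geomean_i` over loci whose geometric
#' mean is positive.
#'
#' @param counts integer matrix (loci x samples).
#' @return named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  ok <- is.finite(log_geo)
  if (!any(ok)) stopf("no locus with all-positive counts")
  f <- apply(counts[ok, , drop = FALSE], 2L, function(col) {
    median(exp(log(col) - log_geo[ok]))
  })
  setNames(f, colnames(counts))
}

#' Negative-binomial two-group differential expression test
#'
#' A per-locus NB model with size-factor offsets: group means are estimated
#' as `q_g = sum(counts) / sum(size factors)` within each group, dispersion
#' by pooled method of moments (floored at 1e-8), and the Wald statistic on
#' the log fold change is referred to a t distribution with `n - 2` degrees
#' of freedom (the residual df of the dispersion estimate), which keeps the
#' raw test close to nominal at small group sizes. Loci with mean raw count
#' below `min_mean_reads` are excluded before testing; adjusted p-values are
#' Benjamini-Hochberg over the tested loci.
#'
#' @param counts integer matrix (loci x samples).
#' @param group_labels named character vector (sample -> group); exactly two
#'   groups with >= 2 samples each. The first group encountered is the
#'   reference; fold changes are tested group over reference.
#' @param min_mean_reads low-coverage exclusion threshold (default 50).
#' @param sf optional size factors; estimated from `counts` when `NULL`.
#' @return data.frame with `locus`, `mean_norm_count`, `log2fc`,
#'   `fold_change`, `se`, `pvalue`, `padj`, `skipped` (reason or `NA`).
#' @export
nb_differential_test <- function(counts, group_labels, min_mean_reads = 50,
                                 sf = NULL) {
  group_labels <- group_labels[colnames(counts)]
  lev <- unique(unname(group_labels))
  stopifnot(length(lev) == 2L, all(table(group_labels) >= 2L))
  if (is.null(sf)) sf <- size_factors(counts)
  sf <- sf[colnames(counts)]
  keep <- rowMeans(counts) >= min_mean_reads
  tested <- counts[keep, , drop = FALSE]
  idx1 <- which(group_labels == lev[1])
  idx2 <- which(group_labels == lev[2])
  res <- data.frame(locus = rownames(tested),
                    mean_norm_count = NA_real_, log2fc = NA_real_,
                    fold_change = NA_real_, se = NA_real_,
                    pvalue = NA_real_, padj = NA_real_,
                    skipped = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tested))) {
    k <- tested[i, ]
    q1 <- sum(k[idx1]) / sum(sf[idx1])
    q2 <- sum(k[idx2]) / sum(sf[idx2])
    res$mean_norm_count[i] <- mean(k / sf)
    if (q1 <= 0 || q2 <= 0) {
      res$skipped[i] <- "degenerate_group"
      next
    }
    # pooled method-of-moments dispersion on normalized counts
    z <- k / sf
    resid2 <- c((z[idx1] - q1)^2, (z[idx2] - q2)^2)
    v <- sum(resid2) / (length(k) - 2L)
    qj <- c(rep(q1, length(idx1)), rep(q2, length(idx2)))
    sj <- sf[c(idx1, idx2)]
    alpha <- (v - mean(qj / sj)) / mean(qj^2)
    alpha <- max(alpha, 1e-8)
    beta <- log(q2 / q1)
    var_log_q <- function(q, ii) {
      sum(sf[ii] * q + alpha * (sf[ii] * q)^2) / (sum(sf[ii])^2 * q^2)
    }
    se <- sqrt(var_log_q(q1, idx1) + var_log_q(q2, idx2))
    z_stat <- beta / se
    res$log2fc[i] <- beta / log(2)
    res$fold_change[i] <- q2 / q1
    res$se[i] <- se / log(2)
    res$pvalue[i] <- 2 * stats::pt(-abs(z_stat), df = length(k) - 2L)
  }
  ok <- is.na(res$skipped)
  res$padj[ok] <- p.adjust(res$pvalue[ok], method = "BH")
  attr(res, "groups") <- lev
  res
}

#' Call significant differential expression
#'
#' Significant loci show at least a `min_fold_change`-fold expression change
#' in either direction (|log2FC| >= log2(min_fold_change)) with adjusted
#' p-value below `max_adjusted_p`. Fold changes are reported on the linear
#' scale with direction preserved (values below 1 are down in the tested
#' group).
#'
#' @param results data.frame from [nb_differential_test()].
#' @param min_fold_change fold-change threshold (default 2).
#' @param max_adjusted_p adjusted-p threshold (default 0.05, strict).
#' @return the significant subset of `results`.
#' @export
call_differential <- function(results, min_fold_change = 2,
                              max_adjusted_p = 0.05) {
  ok <- !is.na(results$padj) &
    abs(results$log2fc) >= log2(min_fold_change) &
    results$padj < max_adjusted_p
  results[ok, , drop = FALSE]
}
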