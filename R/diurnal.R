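#' Relative quantification by the 2^-ddCt method
#'
#' dCt = Ct(target) - Ct(reference); ddCt = dCt(sample) - dCt(calibrator);
#' relative expression = 2^-ddCt. The calibrator's own fold change is 1 by
#' construction.
#'
#' @param ct_target,ct_reference Ct values in the sample of interest.
#' @param ct_target_cal,ct_reference_cal Ct values in the calibrator.
#' @return fold change(s), dimensionless.
#' @examples
#' ddct(24, 18, 24, 18)  # 1
#' ddct(25, 18, 24, 18)  # 0.5
#' @export
ddct <- function(ct_target, ct_reference, ct_target_cal,
                 ct_reference_cal) {
  2^-((ct_target - ct_reference) - (ct_target_cal - ct_reference_cal))
}

#' Summary of a 4-point diurnal series
#'
#' Peak and nadir are the argmax/argmin of the per-ZT replicate means;
#' amplitude is max - min of those means and relative amplitude is
#' amplitude over the series mean (scale-invariant). Ties break toward the
#' earlier ZT and are flagged.
#'
#' @param series data.frame with columns `zt` and `value` (replicate-level
#'   relative expression) for one gene and group.
#' @return list: `peak_zt`, `nadir_zt`, `amplitude`, `relative_amplitude`,
#'   `tie` (logical).
#' @export
diurnal_summary <- function(series) {
  if (any(series$value <= 0)) stop("relative expression must be positive")
  zts <- sort(unique(series$zt))
  mu <- vapply(zts, function(z) mean(series$value[series$zt == z]),
               numeric(1))
  amp <- max(mu) - min(mu)
  tie <- sum(mu == max(mu)) > 1L || sum(mu == min(mu)) > 1L
  list(peak_zt = zts[which.max(mu)], nadir_zt = zts[which.min(mu)],
       amplitude = amp, relative_amplitude = amp / mean(mu), tie = tie)
}

#' Per-timepoint comparison of two diurnal series
#'
#' At each ZT, a two-sided Welch t-test (or Wilcoxon rank-sum) on the
#' replicate values of the two series, with the conventional star tiers
#' (* / ** / *** at 0.05 / 0.01 / 0.001, ns otherwise). With fewer than two
#' replicates on either side at a ZT, p is NA and the tier ns.
#'
#' @param seriesA,seriesB data.frames with `zt`, `value`.
#' @param test "welch" (default) or "wilcoxon".
#' @return data.frame: zt, p, star.
#' @export
reciprocal_timepoint_tests <- function(seriesA, seriesB,
                                       test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  zts <- sort(intersect(unique(seriesA$zt), unique(seriesB$zt)))
  rows <- lapply(zts, function(z) {
    xa <- seriesA$value[seriesA$zt == z]
    xb <- seriesB$value[seriesB$zt == z]
    p <- if (length(xa) < 2L || length(xb) < 2L) NA_real_
    else if (identical(xa, xb)) 1
    else if (test == "welch") {
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0 &&
          mean(xa) == mean(xb)) 1
      else stats::t.test(xa, xb)$p.value
    } else suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
    star <- if (is.na(p) || p >= 0.05) "ns" else if (p < 0.001) "***"
      else if (p < 0.01) "**" else "*"
    data.frame(zt = z, p = p, star = star)
  })
  do.call(rbind, rows)
}
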