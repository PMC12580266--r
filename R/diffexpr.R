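#' Library-size normalization
#'
#' Default is median-of-ratios: a reference pseudo-sample is the per-gene
#' geometric mean over samples (genes expressed in every sample), and each
#' sample's size factor is the median ratio of its counts to the reference.
#' `totals` mode uses the library total relative to the mean total. Values
#' are divided by the size factor.
#'
#' @param counts an [expression_matrix()] of raw counts (or plain matrix).
#' @param method "median_ratio" (default) or "totals".
#' @return list: `normalized` ([expression_matrix()], normalized = TRUE),
#'   `size_factors` (named numeric).
#' @export
normalize_library <- function(counts, method = c("median_ratio", "totals")) {
  method <- match.arg(method)
  m <- unclass(as.matrix(counts))
  tot <- colSums(m)
  if (any(tot == 0))
    stop("all-zero sample: ", colnames(m)[which(tot == 0)[1L]])
  if (method == "totals") {
    sf <- tot / mean(tot)
  } else {
    pos <- rowSums(m > 0) == ncol(m)
    if (!any(pos))
      stop("median-of-ratios needs at least one gene expressed in every ",
           "sample")
    logref <- rowMeans(log(m[pos, , drop = FALSE]))
    sf <- apply(m[pos, , drop = FALSE], 2, function(col)
      exp(stats::median(log(col) - logref)))
  }
  names(sf) <- colnames(m)
  norm <- sweep(m, 2, sf, "/")
  list(normalized = expression_matrix(norm, normalized = TRUE),
       size_factors = sf)
}

#' Two-group differential expression (negative-binomial Wald test)
#'
#' A dependency-light substitute for a full DE framework: per-gene
#' method-of-moments dispersion pooled across the two groups (floored at
#' 1e-8), a Wald test on the difference of log group means with delta-method
#' standard errors, and the conventional significance rule
#' |log2FC| >= `lfc_threshold` AND p < `alpha` on the raw p-value.
#' A pseudocount of 1 enters the fold change only when a group mean is zero.
#'
#' @param countsA,countsB numeric matrices (genes x replicates), same genes,
#'   normalized values.
#' @param lfc_threshold minimum absolute log2 fold change (default 1).
#' @param alpha p-value threshold (default 0.05).
#' @return data.frame: gene_id, mean_a, mean_b, log2FC, p, significant.
#'   With < 2 replicates on either side p is NA and nothing is significant;
#'   genes at zero in both groups get log2FC 0.
#' @export
test_differential <- function(countsA, countsB,
                              lfc_threshold = 1, alpha = 0.05) {
  countsA <- as.matrix(countsA); countsB <- as.matrix(countsB)
  if (nrow(countsA) != nrow(countsB))
    stop("count matrices must have the same genes")
  nA <- ncol(countsA); nB <- ncol(countsB)
  mA <- rowMeans(countsA); mB <- rowMeans(countsB)
  # computed as a difference of logs so lfc(A,B) == -lfc(B,A) exactly
  lfc <- ifelse(mA == 0 | mB == 0,
                log2(mA + 1) - log2(mB + 1),
                log2(mA) - log2(mB))
  lfc[mA == 0 & mB == 0] <- 0
  if (nA < 2L || nB < 2L) {
    p <- rep(NA_real_, length(lfc))
  } else {
    vA <- apply(countsA, 1, stats::var)
    vB <- apply(countsB, 1, stats::var)
    # method-of-moments NB dispersion, pooled over both groups
    phi_g <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
    phi <- rowMeans(cbind(phi_g(vA, mA), phi_g(vB, mB)), na.rm = TRUE)
    phi <- pmax(ifelse(is.nan(phi), 1e-8, phi), 1e-8)
    # delta method: Var(log mean) ~ (mu + phi mu^2) / (n mu^2)
    se2 <- ifelse(mA > 0, (1 / mA + phi) / nA, Inf) +
           ifelse(mB > 0, (1 / mB + phi) / nB, Inf)
    z <- (log(pmax(mA, 1e-300)) - log(pmax(mB, 1e-300))) / sqrt(se2)
    p <- 2 * stats::pnorm(-abs(z))
    p[mA == 0 & mB == 0] <- NA_real_
    p[is.infinite(se2) & !(mA == 0 & mB == 0)] <- 1
  }
  sig <- !is.na(p) & p < alpha & abs(lfc) >= lfc_threshold
  data.frame(gene_id = rownames(countsA), mean_a = mA, mean_b = mB,
             log2FC = lfc, p = p, significant = sig, row.names = NULL)
}

contrast_classes <- list(
  poe     = list(a = "3x_paternal_excess", b = "3x_maternal_excess"),
  ploidy2 = list(a = c("3x_paternal_excess", "3x_maternal_excess"),
                 b = "self2x"),
  ploidy4 = list(a = c("3x_paternal_excess", "3x_maternal_excess"),
                 b = "self4x"),
  hyb2    = list(a = "2x_hybrid", b = "self2x"),
  hyb4    = list(a = "4x_hybrid", b = "self4x"))

contrast_groups <- function(design, side) {
  if (identical(side, "self2x")) {
    g <- design$groups
    g$group[g$group_class == "parental_self" & g$maternal_ploidy == 2L]
  } else if (identical(side, "self4x")) {
    g <- design$groups
    g$group[g$group_class == "parental_self" & g$maternal_ploidy == 4L]
  } else groups_of_class(design, side)
}

#' Run one factorial contrast
#'
#' Named contrasts separate the three factors of the factorial design:
#' * `poe` — paternal-excess vs maternal-excess triploids;
#' * `ploidy2` / `ploidy4` — all triploids vs diploid / tetraploid selfs;
#' * `hyb2` / `hyb4` — diploid / tetraploid hybrids vs same-ploidy selfs;
#' * `distance` — triploids of genetically close vs distant parents, via a
#'   user-supplied `distance_map` (named vector group -> "h"/"l").
#'
#' `mode = "pooled"` pools all samples of each side; `"per_pair"` tests every
#' (group A, group B) pair and flags a gene significant if it is significant
#' in any pair (log2FC reported from the largest-|log2FC| pair).
#'
#' @param expr normalized [expression_matrix()] (all design samples).
#' @param design a [cross_design()].
#' @param contrast one of poe, ploidy2, ploidy4, hyb2, hyb4, distance.
#' @param distance_map named character vector (groups -> "h"/"l"),
#'   required for `contrast = "distance"`.
#' @param mode "pooled" or "per_pair".
#' @param ... thresholds passed to [test_differential()].
#' @return [test_differential()] data.frame plus attributes `contrast`,
#'   `mode`.
#' @export
run_contrast <- function(expr, design, contrast, distance_map = NULL,
                         mode = c("pooled", "per_pair"), ...) {
  mode <- match.arg(mode)
  if (contrast == "distance") {
    if (is.null(distance_map))
      stop("contrast 'distance' needs a distance_map (group -> h/l)")
    ga <- names(distance_map)[distance_map == "h"]
    gb <- names(distance_map)[distance_map == "l"]
  } else {
    spec <- contrast_classes[[contrast]]
    if (is.null(spec)) stop("unknown contrast: ", contrast)
    ga <- contrast_groups(design, spec$a)
    gb <- contrast_groups(design, spec$b)
  }
  if (!length(ga) || !length(gb))
    stop("contrast ", contrast, ": a side has no groups in this design")
  cols <- function(groups) unlist(lapply(groups, replicates_of,
                                         design = design))
  if (mode == "pooled") {
    res <- test_differential(unclass(expr)[, cols(ga), drop = FALSE],
                             unclass(expr)[, cols(gb), drop = FALSE], ...)
  } else {
    pair_res <- list()
    for (a in ga) for (b in gb)
      pair_res[[paste(a, b)]] <-
        test_differential(unclass(expr)[, cols(a), drop = FALSE],
                          unclass(expr)[, cols(b), drop = FALSE], ...)
    res <- pair_res[[1L]]
    for (r in pair_res[-1L]) {
      take <- abs(r$log2FC) > abs(res$log2FC)
      res$log2FC[take] <- r$log2FC[take]
      res$p[take] <- r$p[take]
      res$mean_a[take] <- r$mean_a[take]
      res$mean_b[take] <- r$mean_b[take]
      res$significant <- res$significant | r$significant
    }
  }
  attr(res, "contrast") <- contrast
  attr(res, "mode") <- mode
  res
}

#' Factorial DEG summary and factor ranking
#'
#' Tallies significant genes (split up/down by log2FC sign) per contrast and
#' ranks the experimental factors (POE, ploidy, hybridity, distance) by their
#' largest contrast's DEG count; ties break alphabetically.
#'
#' @param results named list of [run_contrast()] / [test_differential()]
#'   data.frames; names are contrast labels.
#' @return list: `summary` (data.frame contrast, factor, up, down, total),
#'   `factor_ranking` (character vector, most DEGs first), `mode`.
#' @export
factorial_deg_summary <- function(results) {
  if (is.null(names(results)) || any(names(results) == ""))
    stop("results must be a named list of contrast results")
  factor_of <- c(poe = "POE", ploidy2 = "ploidy", ploidy4 = "ploidy",
                 hyb2 = "hybridity", hyb4 = "hybridity",
                 distance = "distance")
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    sig <- r[r$significant, , drop = FALSE]
    data.frame(contrast = nm,
               factor = if (nm %in% names(factor_of)) factor_of[[nm]]
                        else nm,
               up = sum(sig$log2FC > 0), down = sum(sig$log2FC < 0),
               total = nrow(sig))
  })
  s <- do.call(rbind, rows)
  by_factor <- tapply(s$total, s$factor, max)
  ord <- order(-by_factor, tolower(names(by_factor)))
  modes <- unique(unlist(lapply(results, attr, "mode")))
  list(summary = s,
       factor_ranking = names(by_factor)[ord],
       mode = if (length(modes)) modes else "pooled")
}
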