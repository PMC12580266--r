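#' Strand-aware gene regions (upstream flank, body, downstream flank)
#'
#' Builds the three analysis regions of each gene in genomic coordinates:
#' upstream = `flank` bp before the TSS in transcription orientation,
#' body = TSS..TTS, downstream = `flank` bp after the TTS. The partition is
#' contiguous and non-overlapping for any single gene.
#'
#' @param annotation data.frame from [read_annotation()] /
#'   [sim_annotation()].
#' @param flank flank length in bp (default 2000).
#' @return data.frame: gene_id, chrom, strand, region, start, end
#'   (start <= end, genomic coordinates).
#' @export
gene_regions <- function(annotation, flank = 2000L) {
  a <- annotation
  plus <- a$strand == "+"
  lo <- pmin(a$tss, a$tts); hi <- pmax(a$tss, a$tts)
  up <- data.frame(gene_id = a$gene_id, chrom = a$chrom,
                   strand = a$strand, region = "upstream",
                   start = ifelse(plus, a$tss - flank, a$tss + 1L),
                   end = ifelse(plus, a$tss - 1L, a$tss + flank))
  body <- data.frame(gene_id = a$gene_id, chrom = a$chrom,
                     strand = a$strand, region = "body",
                     start = lo, end = hi)
  dn <- data.frame(gene_id = a$gene_id, chrom = a$chrom,
                   strand = a$strand, region = "downstream",
                   start = ifelse(plus, a$tts + 1L, a$tts - flank),
                   end = ifelse(plus, a$tts + flank, a$tts - 1L))
  out <- rbind(up, body, dn)
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out[order(match(out$gene_id, a$gene_id)), ]
}

#' Per-cytosine methylation level
#'
#' Level = methylated reads / total reads, computed only for cytosines
#' covered by at least `min_reads` reads (the conventional 5); otherwise NA.
#'
#' @param meth_reads,total_reads integer vectors.
#' @param min_reads minimum coverage.
#' @return numeric vector of levels in `[0, 1]`, NA where coverage fails.
#' @export
site_level <- function(meth_reads, total_reads, min_reads = 5L) {
  if (any(meth_reads > total_reads, na.rm = TRUE))
    stop("meth_reads exceeds total_reads")
  ifelse(total_reads >= min_reads, meth_reads / total_reads, NA_real_)
}

# pool replicate calls per (chrom, pos, context, allele) by read summation,
# then apply the site-level coverage filter
pooled_sites <- function(calls, min_reads = 5L) {
  key <- paste(calls$chrom, calls$pos, calls$context, calls$allele,
               sep = "\r")
  first <- !duplicated(key)
  meth <- rowsum(calls$meth_reads, key)[key[first], 1L]
  tot <- rowsum(calls$total_reads, key)[key[first], 1L]
  data.frame(chrom = calls$chrom[first], pos = calls$pos[first],
             context = calls$context[first], allele = calls$allele[first],
             level = site_level(meth, tot, min_reads))
}

#' Mean methylation level of one region
#'
#' Unweighted mean of qualifying per-site levels (replicates pooled by read
#' summation before the coverage filter) for one region, context and
#' allele; fewer than `min_sites` qualifying sites gives NA.
#'
#' @param calls methylation calls ([read_methyl_calls()] layout).
#' @param region one row of [gene_regions()].
#' @param context CG, CHG or CHH.
#' @param allele genotype allele label.
#' @param min_sites minimum qualifying cytosines (default 3).
#' @param min_reads minimum pooled coverage per cytosine (default 5).
#' @return list: `mean` (or NA), `n_sites`.
#' @export
region_mean <- function(calls, region, context, allele,
                        min_sites = 3L, min_reads = 5L) {
  s <- pooled_sites(calls[calls$context == context &
                            calls$allele == allele, , drop = FALSE],
                    min_reads)
  s <- s[s$chrom == region$chrom & s$pos >= region$start &
           s$pos <= region$end & !is.na(s$level), , drop = FALSE]
  n <- nrow(s)
  list(mean = if (n >= min_sites) mean(s$level) else NA_real_, n_sites = n)
}

#' Region mean methylation for all genes, regions, contexts and alleles
#'
#' Vectorized companion of [region_mean()]: pools replicates, applies the
#' coverage and site-count filters, and returns the full long table the ASM
#' statistics consume.
#'
#' @param calls methylation calls (one cross).
#' @param annotation gene annotation data.frame.
#' @param flank flank length in bp.
#' @param min_sites,min_reads filters as in [region_mean()].
#' @return data.frame: gene_id, region, context, allele, mean_level,
#'   n_sites.
#' @export
region_means <- function(calls, annotation, flank = 2000L,
                         min_sites = 3L, min_reads = 5L) {
  regs <- gene_regions(annotation, flank)
  sites <- pooled_sites(calls, min_reads)
  sites <- sites[!is.na(sites$level), , drop = FALSE]
  combos <- unique(sites[, c("context", "allele")])
  nr <- nrow(regs) * nrow(combos)
  mean_level <- rep(NA_real_, nr)
  n_sites <- integer(nr)
  by_chrom <- split(sites, sites$chrom)
  by_chrom <- lapply(by_chrom, function(s) s[order(s$pos), , drop = FALSE])
  k <- 0L
  for (i in seq_len(nrow(regs))) {
    s <- by_chrom[[regs$chrom[i]]]
    if (!is.null(s)) {
      lo <- findInterval(regs$start[i] - 1L, s$pos) + 1L
      hi <- findInterval(regs$end[i], s$pos)
      s <- if (hi >= lo) s[lo:hi, , drop = FALSE] else NULL
    }
    for (j in seq_len(nrow(combos))) {
      k <- k + 1L
      if (is.null(s)) next
      sel <- s$context == combos$context[j] & s$allele == combos$allele[j]
      n <- sum(sel)
      n_sites[k] <- n
      if (n >= min_sites) mean_level[k] <- mean(s$level[sel])
    }
  }
  data.frame(
    gene_id = rep(regs$gene_id, each = nrow(combos)),
    region = rep(regs$region, each = nrow(combos)),
    context = rep(combos$context, nrow(regs)),
    allele = rep(combos$allele, nrow(regs)),
    mean_level = mean_level, n_sites = n_sites)
}

#' Allele-specific methylation difference per gene region
#'
#' The ASM difference is the absolute difference in mean methylation level
#' between the two parental genotype alleles for one gene region and
#' context. Rows where either allele's mean is missing get NA and are
#' excluded from downstream tests.
#'
#' @param means output of [region_means()] (one cross; exactly two allele
#'   labels).
#' @return data.frame: gene_id, region, context, allele_1, mean_1,
#'   allele_2, mean_2, asm_diff, n_sites_1, n_sites_2.
#' @export
asm_difference <- function(means) {
  alleles <- sort(unique(means$allele))
  if (length(alleles) != 2L)
    stop("expected exactly 2 allele labels, got ",
         paste(alleles, collapse = ", "))
  a <- means[means$allele == alleles[1L], ]
  b <- means[means$allele == alleles[2L], ]
  key <- function(d) paste(d$gene_id, d$region, d$context, sep = "\r")
  b <- b[match(key(a), key(b)), ]
  data.frame(gene_id = a$gene_id, region = a$region, context = a$context,
             allele_1 = alleles[1L], mean_1 = a$mean_level,
             allele_2 = alleles[2L], mean_2 = b$mean_level,
             asm_diff = abs(a$mean_level - b$mean_level),
             n_sites_1 = a$n_sites, n_sites_2 = b$n_sites)
}

#' Compare ASM differences between reciprocal crosses
#'
#' Two-sided Wilcoxon rank-sum test on the ASM-difference distributions of
#' the two reciprocal crosses for one region and context; exact when both
#' sides have at most 25 values, normal approximation with tie correction
#' otherwise. Annotation tiers mirror the conventional display: *** / ** / *
#' at 0.001 / 0.01 / 0.05, a dagger at 0.1, ns above.
#'
#' @param diffsA,diffsB [asm_difference()] tables for the two crosses.
#' @param region region label (upstream / body / downstream).
#' @param context CG, CHG or CHH.
#' @param paired set TRUE for a gene-paired signed-rank comparison.
#' @return list: `statistic`, `p`, `annotation`, `n_a`, `n_b`.
#' @export
compare_reciprocal_asm <- function(diffsA, diffsB, region, context,
                                   paired = FALSE) {
  pick <- function(d) {
    x <- d[d$region == region & d$context == context, ]
    if (paired) x else x$asm_diff[!is.na(x$asm_diff)]
  }
  if (paired) {
    a <- pick(diffsA); b <- pick(diffsB)
    b <- b[match(a$gene_id, b$gene_id), ]
    keep <- !is.na(a$asm_diff) & !is.na(b$asm_diff)
    xa <- a$asm_diff[keep]; xb <- b$asm_diff[keep]
  } else {
    xa <- pick(diffsA); xb <- pick(diffsB)
  }
  if (length(xa) == 0L || length(xb) == 0L)
    stop("no ASM values on one side for ", region, "/", context)
  wt <- suppressWarnings(stats::wilcox.test(
    xa, xb, paired = paired,
    exact = length(xa) <= 25L && length(xb) <= 25L))
  ann <- if (wt$p.value < 0.001) "***" else if (wt$p.value < 0.01) "**"
    else if (wt$p.value < 0.05) "*" else if (wt$p.value < 0.1) "†"
    else "ns"
  list(statistic = unname(wt$statistic), p = wt$p.value,
       annotation = ann, n_a = length(xa), n_b = length(xb))
}

#' Metagene methylation profile (TSS to TTS plus flanks)
#'
#' Averages per-site methylation levels into a fixed-length profile: the
#' 2-kb (by default) flanks in fixed-width bins, the gene body rescaled into
#' `body_bins` proportional bins. Minus-strand genes are reversed so every
#' profile runs 5' to 3'. Per gene the mean level per bin is taken first,
#' then bins are averaged across genes (unweighted, NA-dropped).
#'
#' @param calls methylation calls (one cross).
#' @param annotation gene annotation.
#' @param context CG, CHG or CHH.
#' @param allele genotype allele label.
#' @param body_bins,flank_bins bin counts (defaults 40 / 20).
#' @param flank flank length in bp.
#' @param min_reads per-site pooled coverage filter.
#' @return numeric vector of length `2 * flank_bins + body_bins` with a
#'   `segment` attribute labelling each bin upstream/body/downstream.
#' @export
metagene_profile <- function(calls, annotation, context, allele,
                             body_bins = 40L, flank_bins = 20L,
                             flank = 2000L, min_reads = 5L) {
  sites <- pooled_sites(calls[calls$context == context &
                                calls$allele == allele, , drop = FALSE],
                        min_reads)
  sites <- sites[!is.na(sites$level), , drop = FALSE]
  nb <- 2L * flank_bins + body_bins
  acc <- matrix(NA_real_, nrow(annotation), nb)
  bw <- flank / flank_bins
  by_chrom <- split(sites, sites$chrom)
  by_chrom <- lapply(by_chrom, function(s) s[order(s$pos), , drop = FALSE])
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    s <- by_chrom[[a$chrom]]
    if (is.null(s)) next
    lo <- min(a$tss, a$tts) - flank; hi <- max(a$tss, a$tts) + flank
    i1 <- findInterval(lo - 1L, s$pos) + 1L
    i2 <- findInterval(hi, s$pos)
    if (i2 < i1) next
    p <- s$pos[i1:i2]; lev <- s$level[i1:i2]
    sense <- if (a$strand == "+") p - a$tss else a$tss - p
    len <- abs(a$tts - a$tss) + 1L
    bin <- integer(length(p))
    upstream <- sense < 0
    body <- sense >= 0 & sense < len
    down <- sense >= len
    bin[upstream] <- flank_bins + 1L + floor(sense[upstream] / bw)
    bin[body] <- flank_bins + 1L + floor(sense[body] / len * body_bins)
    bin[down] <- flank_bins + body_bins + 1L +
      floor((sense[down] - len) / bw)
    ok <- bin >= 1L & bin <= nb
    if (!any(ok)) next
    acc[i, ] <- tapply(lev[ok], factor(bin[ok], levels = seq_len(nb)),
                       mean)
  }
  prof <- colMeans(acc, na.rm = TRUE)
  prof[is.nan(prof)] <- NA_real_
  attr(prof, "segment") <- rep(c("upstream", "body", "downstream"),
                               c(flank_bins, body_bins, flank_bins))
  prof
}

#' Gene-body methylation vs allelic expression association
#'
#' Spearman correlation between the per-gene paternal-minus-maternal
#' body-mCG level difference and the paternal allelic expression fraction,
#' over genes with both measures — the statistic behind the observation
#' that paternal gene-body hypermethylation tracks enhanced paternal-allele
#' expression.
#'
#' @param means [region_means()] table for the cross (body/CG rows used).
#' @param ase [aggregate_gene_ase()] results for the same cross.
#' @param design a [cross_design()].
#' @return list: `rho`, `p`, `n`. `rho`/`p` are NA when either measure is
#'   constant (correlation undefined); fewer than 3 complete pairs is an
#'   error.
#' @export
gbm_expression_association <- function(means, ase, design) {
  grp <- group_row(design, ase$group[1L])
  body <- means[means$region == "body" & means$context == "CG", ]
  pat <- body[body$allele == grp$paternal_parent, ]
  mat <- body[body$allele == grp$maternal_parent, ]
  mat <- mat[match(pat$gene_id, mat$gene_id), ]
  diff <- pat$mean_level - mat$mean_level
  names(diff) <- pat$gene_id
  i <- match(names(diff), ase$gene_id)
  pfrac <- 1 - ase$maternal_fraction[i]
  keep <- !is.na(diff) & !is.na(pfrac)
  if (sum(keep) < 3L)
    stop("fewer than 3 genes with both methylation and ASE measures")
  x <- diff[keep]; y <- pfrac[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = sum(keep)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}
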