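#' Exact binomial test for allelic imbalance at one SNP
#'
#' Two-sided exact binomial p-value for observing `reads_parent1` of
#' `reads_parent1 + reads_parent2` reads when the parent-1 allele is
#' expected at fraction `f_null` — 2/3 for the tetraploid parent in a
#' triploid, 1/2 in balanced crosses. Two-sidedness follows the
#' minimum-likelihood convention: the p-value sums the probabilities of all
#' outcomes no more likely than the observed one, so an observation at the
#' modal expectation gives p = 1.
#'
#' @param reads_parent1,reads_parent2 nonnegative integer read counts
#'   (vectorized).
#' @param f_null expected fraction of the parent-1 allele.
#' @return p-values; NA where the total is zero (such SNPs are excluded
#'   upstream).
#' @examples
#' snp_ase_test(20, 10, 2/3)   # 1: exactly the modal 2:1 expectation
#' @export
snp_ase_test <- function(reads_parent1, reads_parent2, f_null) {
  stopifnot(length(f_null) == 1L, f_null > 0, f_null < 1)
  n <- reads_parent1 + reads_parent2
  if (any(n < 0 | reads_parent1 < 0 | reads_parent2 < 0, na.rm = TRUE))
    stop("negative read counts")
  vapply(seq_along(n), function(i) {
    if (is.na(n[i]) || n[i] == 0L) return(NA_real_)
    stats::binom.test(reads_parent1[i], n[i], p = f_null)$p.value
  }, numeric(1))
}

resolve_parents <- function(records, design, group) {
  g <- group_row(design, group)
  samples <- replicates_of(design, group)
  r <- records[records$sample %in% samples, , drop = FALSE]
  if (nrow(r) == 0L) return(r)
  ok_a <- r$allele_a %in% c(g$maternal_parent, g$paternal_parent)
  ok_b <- r$allele_b %in% c(g$maternal_parent, g$paternal_parent)
  if (!all(ok_a & ok_b))
    stop("allele labels outside the parental genotypes of cross ", group)
  a_mat <- r$allele_a == g$maternal_parent
  r$maternal_reads <- ifelse(a_mat, r$reads_a, r$reads_b)
  r$paternal_reads <- ifelse(a_mat, r$reads_b, r$reads_a)
  r
}

#' Gene-level allele-specific expression calls for one cross
#'
#' Implements the dosage-aware ASE procedure: allele labels are resolved to
#' maternal/paternal through the design; biological replicates are pooled by
#' summation per SNP; SNPs with fewer than `min_reads` pooled reads are
#' dropped; each remaining SNP is tested against the cross's dosage null
#' with [snp_ase_test()]; Benjamini-Hochberg correction is applied across
#' all tested SNPs of the cross (or within each gene with
#' `fdr_scope = "per_gene"`). A gene is a significant ASE gene (ASEG) when
#' at least one of its SNPs has FDR < `alpha`; its direction comes from the
#' pooled gene-level counts, and genes whose significant SNPs disagree in
#' direction are classed `conflicting`.
#'
#' @param records allele count records ([read_allele_counts()] layout).
#' @param design a [cross_design()].
#' @param group the cross (group label) to analyse.
#' @param alpha FDR threshold for significance.
#' @param min_reads minimum pooled reads per SNP (the conventional 10,
#'   summed across all biological replicates).
#' @param fdr_scope "per_cross" (BH over all SNPs of the cross, default) or
#'   "per_gene".
#' @return data.frame, one row per gene with any record in the cross:
#'   gene_id, group, n_snps (passing the filter), maternal_reads,
#'   paternal_reads, maternal_fraction, f_null_maternal, min_fdr,
#'   bias_class in {maternal_biased, paternal_biased, unbiased, conflicting,
#'   filtered}.
#' @export
aggregate_gene_ase <- function(records, design, group, alpha = 0.05,
                               min_reads = 10L,
                               fdr_scope = c("per_cross", "per_gene")) {
  fdr_scope <- match.arg(fdr_scope)
  null <- dosage_null(design, group)
  r <- resolve_parents(records, design, group)
  all_genes <- unique(records$gene_id[records$sample %in%
                                        replicates_of(design, group)])
  empty <- function() data.frame(
    gene_id = character(0), group = character(0), n_snps = integer(0),
    maternal_reads = integer(0), paternal_reads = integer(0),
    maternal_fraction = numeric(0), f_null_maternal = numeric(0),
    min_fdr = numeric(0), bias_class = character(0))
  if (nrow(r) == 0L) return(empty())

  key <- paste(r$gene_id, r$chrom, r$pos, sep = "\r")
  mat <- rowsum(r$maternal_reads, key)
  pat <- rowsum(r$paternal_reads, key)
  first <- !duplicated(key)
  snp <- data.frame(gene_id = r$gene_id[first],
                    key = key[first],
                    maternal = mat[key[first], 1L],
                    paternal = pat[key[first], 1L])
  snp$total <- snp$maternal + snp$paternal
  tested <- snp[snp$total >= min_reads, , drop = FALSE]
  if (nrow(tested)) {
    tested$p <- snp_ase_test(tested$maternal, tested$paternal,
                             null$f_maternal)
    tested$fdr <- if (fdr_scope == "per_cross")
      stats::p.adjust(tested$p, method = "BH")
    else stats::ave(tested$p, tested$gene_id,
                    FUN = function(p) stats::p.adjust(p, method = "BH"))
    tested$dir <- sign(tested$maternal / tested$total - null$f_maternal)
  }

  res <- lapply(all_genes, function(gn) {
    tg <- tested[tested$gene_id == gn, , drop = FALSE]
    if (nrow(tg) == 0L)
      return(data.frame(gene_id = gn, group = group, n_snps = 0L,
                        maternal_reads = 0L, paternal_reads = 0L,
                        maternal_fraction = NA_real_,
                        f_null_maternal = null$f_maternal,
                        min_fdr = NA_real_, bias_class = "filtered"))
    mr <- sum(tg$maternal); pr <- sum(tg$paternal)
    frac <- mr / (mr + pr)
    min_fdr <- min(tg$fdr)
    sig <- tg[tg$fdr < alpha, , drop = FALSE]
    cls <- if (nrow(sig) == 0L) "unbiased" else {
      dirs <- unique(sig$dir[sig$dir != 0])
      pooled_dir <- sign(frac - null$f_maternal)
      if (length(dirs) != 1L || pooled_dir != dirs) "conflicting"
      else if (dirs > 0) "maternal_biased" else "paternal_biased"
    }
    data.frame(gene_id = gn, group = group, n_snps = nrow(tg),
               maternal_reads = mr, paternal_reads = pr,
               maternal_fraction = frac,
               f_null_maternal = null$f_maternal,
               min_fdr = min_fdr, bias_class = cls)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

favored_allele <- function(res, design) {
  g <- group_row(design, res$group[1L])
  ifelse(res$bias_class == "maternal_biased", g$maternal_parent,
         ifelse(res$bias_class == "paternal_biased", g$paternal_parent,
                NA_character_))
}

#' Reciprocal-cross ASE summary
#'
#' Collates the two reciprocal crosses' gene-level ASE results into
#' (i) per-cross biased-gene counts with the informative-gene denominator,
#' (ii) a per-gene allelic-contribution scatter table — for every ASEG
#' present (unfiltered) in both crosses, the favoured genotype allele's
#' percentage of transcripts when maternally vs paternally inherited — and
#' (iii) the quantity-vs-magnitude asymmetry: the fraction of biased calls
#' that are maternal, and the mean uplift in allelic percentage when the
#' allele is paternally inherited.
#'
#' @param resultsA,resultsB [aggregate_gene_ase()] outputs for the two
#'   reciprocal crosses.
#' @param design a [cross_design()].
#' @return list: `counts` (per cross: maternal, paternal, informative),
#'   `scatter` (gene_id, allele, pct_when_maternal, pct_when_paternal,
#'   biased_in), `asymmetry` (maternal_call_fraction,
#'   mean_paternal_uplift_pct, n_scatter).
#' @export
reciprocal_summary <- function(resultsA, resultsB, design) {
  counts <- do.call(rbind, lapply(list(resultsA, resultsB), function(r) {
    data.frame(group = r$group[1L],
               maternal = sum(r$bias_class == "maternal_biased"),
               paternal = sum(r$bias_class == "paternal_biased"),
               informative = sum(r$bias_class != "filtered"))
  }))
  gA <- group_row(design, resultsA$group[1L])
  scatter <- NULL
  both <- intersect(resultsA$gene_id[resultsA$bias_class != "filtered"],
                    resultsB$gene_id[resultsB$bias_class != "filtered"])
  if (length(both)) {
    a <- resultsA[match(both, resultsA$gene_id), ]
    b <- resultsB[match(both, resultsB$gene_id), ]
    fa <- favored_allele(a, design)
    fb <- favored_allele(b, design)
    allele <- ifelse(!is.na(fa), fa, fb)
    keep <- !is.na(allele)
    if (any(keep)) {
      a <- a[keep, ]; b <- b[keep, ]; allele <- allele[keep]
      pct_in <- function(res, grow, allele) {
        mat_frac <- res$maternal_fraction
        100 * ifelse(allele == grow$maternal_parent, mat_frac,
                     1 - mat_frac)
      }
      gB <- group_row(design, resultsB$group[1L])
      pctA <- pct_in(a, gA, allele)
      pctB <- pct_in(b, gB, allele)
      a_is_mat <- allele == gA$maternal_parent
      scatter <- data.frame(
        gene_id = a$gene_id, allele = allele,
        pct_when_maternal = ifelse(a_is_mat, pctA, pctB),
        pct_when_paternal = ifelse(a_is_mat, pctB, pctA),
        biased_in = paste0(ifelse(!is.na(favored_allele(a, design)),
                                  a$group[1L], ""),
                           ifelse(!is.na(favored_allele(b, design)),
                                  paste0("|", b$group[1L]), "")))
    }
  }
  if (is.null(scatter))
    scatter <- data.frame(gene_id = character(0), allele = character(0),
                          pct_when_maternal = numeric(0),
                          pct_when_paternal = numeric(0),
                          biased_in = character(0))
  n_mat <- sum(counts$maternal); n_pat <- sum(counts$paternal)
  asymmetry <- data.frame(
    maternal_call_fraction = if (n_mat + n_pat > 0)
      n_mat / (n_mat + n_pat) else NA_real_,
    mean_paternal_uplift_pct = if (nrow(scatter))
      mean(scatter$pct_when_paternal - scatter$pct_when_maternal)
    else NA_real_,
    n_scatter = nrow(scatter))
  list(counts = counts, scatter = scatter, asymmetry = asymmetry)
}

#' Call imprinted (PEG/MEG) versus cis-biased genes from reciprocal crosses
#'
#' A gene is a PEG (paternally expressed imprinted gene) when it is
#' significantly paternally biased in BOTH reciprocal crosses, a MEG when
#' maternally biased in both — parent-of-origin-attached bias. A gene whose
#' bias points to the SAME genotype allele in both crosses (maternal in one
#' direction, paternal in the other) is cis-biased: a sequence-attached
#' effect that must never be counted as imprinted. Everything else is
#' `none`.
#'
#' @param resultsA,resultsB [aggregate_gene_ase()] outputs for the two
#'   reciprocal crosses.
#' @param design a [cross_design()].
#' @return data.frame over genes present in both crosses: gene_id, status in
#'   {PEG, MEG, cis_biased, none}, favored_allele (genotype, for cis),
#'   class_a, fdr_a, class_b, fdr_b.
#' @export
call_imprinting <- function(resultsA, resultsB, design) {
  both <- intersect(resultsA$gene_id, resultsB$gene_id)
  a <- resultsA[match(both, resultsA$gene_id), ]
  b <- resultsB[match(both, resultsB$gene_id), ]
  fa <- favored_allele(a, design)
  fb <- favored_allele(b, design)
  status <- rep("none", length(both))
  peg <- a$bias_class == "paternal_biased" & b$bias_class == "paternal_biased"
  meg <- a$bias_class == "maternal_biased" & b$bias_class == "maternal_biased"
  cis <- !is.na(fa) & !is.na(fb) & fa == fb & !peg & !meg
  status[cis] <- "cis_biased"
  status[peg] <- "PEG"
  status[meg] <- "MEG"
  data.frame(gene_id = both, status = status,
             favored_allele = ifelse(cis, fa, NA_character_),
             class_a = a$bias_class, fdr_a = a$min_fdr,
             class_b = b$bias_class, fdr_b = b$min_fdr)
}
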