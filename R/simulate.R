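#' Simulation parameters with planted ground truth
#'
#' Bundles every knob of the synthetic-data generators. The defaults emulate
#' the study conditions the analysis is designed for: a reciprocal
#' 2x/3x/4x hybrid series with 3 replicates per group, negative-binomial
#' counts at bulk RNA-seq depth, allelic counts under the triploid 2:1
#' parental-dosage null, allele-resolved methylomes with gene-body mCG
#' asymmetry, and 4-point diurnal series at ZT0/6/12/18.
#'
#' Expression effects are planted as group-mean multipliers:
#' parent-of-origin genes are shifted antisymmetrically (up `2^(lfc/2)` in
#' paternal-excess, down `2^(-lfc/2)` in maternal-excess triploids) so that a
#' POE never leaks into the pooled-triploid ploidy contrasts; ploidy genes
#' are shifted in all triploids; hybridity genes in all hybrids.
#'
#' ASE truth distinguishes three planted classes: PEGs/MEGs are
#' parent-of-origin-attached (the same *parent*'s allele is favoured in both
#' reciprocal crosses), cis genes are genotype-attached (the same *genotype*
#' allele is favoured in both crosses); per-cross biased genes model ordinary
#' one-cross allelic bias. PEG/MEG/cis sets must be disjoint — they are the
#' positive and negative controls for the imprinting caller.
#'
#' @param n_genes number of genes.
#' @param seed integer seed; identical params + seed give byte-identical
#'   outputs from every generator.
#' @param lib_mean expected reads per sample (library size).
#' @param dispersion negative-binomial dispersion, shared across groups.
#' @param base_lsd log-normal sd of per-gene baseline means.
#' @param poe_genes,ploidy_genes,hybridity_genes character vectors of planted
#'   effect genes (NULL = sized defaults `n_poe`, `n_ploidy`, `n_hybridity`).
#' @param n_poe,n_ploidy,n_hybridity planted effect-set sizes.
#' @param poe_lfc,ploidy_lfc,hybridity_lfc planted log2 effect sizes.
#' @param n_snps_mean Poisson mean of informative SNPs per gene.
#' @param snp_depth_mean Poisson mean read depth per SNP per sample.
#' @param n_pegs,n_megs,n_cis planted imprinted / cis gene-set sizes.
#' @param imprint_fraction allelic fraction of the favoured allele for
#'   planted PEG/MEG/cis genes.
#' @param n_maternal_bias,n_paternal_bias planted biased gene counts per
#'   cross direction (ordinary, non-imprinted bias; distinct gene sets are
#'   active in paternal- vs maternal-excess crosses).
#' @param bias_delta fraction shift of the favoured parent over its dosage
#'   null for planted biased genes (capped at 0.95).
#' @param meth_sites_per_region named vector, sites per region per context.
#' @param meth_coverage_mean Poisson mean read coverage per cytosine.
#' @param meth_baseline 3x3 matrix of baseline levels,
#'   rows upstream/body/downstream, cols CG/CHG/CHH.
#' @param n_gbm planted gene-body-mCG-asymmetry gene count.
#' @param gbm_delta methylation offset added to the paternal allele's
#'   body-CG level for planted gbM genes.
#' @param gbm_couple_ase logical; give planted gbM genes a paternal
#'   expression bias too (the coupling the association statistic targets).
#' @param diurnal_noise_sd additive replicate noise sd for diurnal series.
#' @param n_reps replicates per group.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 2000L,
                       seed = 1L,
                       lib_mean = 1e6,
                       dispersion = 0.05,
                       base_lsd = 1,
                       poe_genes = NULL, ploidy_genes = NULL,
                       hybridity_genes = NULL,
                       n_poe = 400L, n_ploidy = 150L, n_hybridity = 30L,
                       poe_lfc = 3, ploidy_lfc = 2, hybridity_lfc = 2,
                       n_snps_mean = 3,
                       snp_depth_mean = 30,
                       n_pegs = 10L, n_megs = 0L, n_cis = 10L,
                       imprint_fraction = 0.9,
                       n_maternal_bias = 100L, n_paternal_bias = 20L,
                       bias_delta = 0.25,
                       meth_sites_per_region = c(CG = 8L, CHG = 6L,
                                                 CHH = 10L),
                       meth_coverage_mean = 10,
                       meth_baseline = NULL,
                       n_gbm = 50L,
                       gbm_delta = 0.3,
                       gbm_couple_ase = TRUE,
                       diurnal_noise_sd = 0.1,
                       n_reps = 3L) {
  genes <- sprintf("g%05d", seq_len(n_genes))
  pick <- function(x, n, pool) {
    if (!is.null(x)) {
      if (!all(x %in% genes)) stop("effect applied to unknown gene: ",
                                   setdiff(x, genes)[1L])
      return(x)
    }
    pool[seq_len(min(n, length(pool)))]
  }
  poe_genes <- pick(poe_genes, n_poe, genes)
  ploidy_genes <- pick(ploidy_genes, n_ploidy, setdiff(genes, poe_genes))
  hybridity_genes <- pick(hybridity_genes, n_hybridity,
                          setdiff(genes, c(poe_genes, ploidy_genes)))
  # imprinting/cis/bias genes drawn from the tail so classes stay disjoint
  tail_pool <- rev(genes)
  pegs <- tail_pool[seq_len(n_pegs)]
  megs <- if (n_megs > 0L) tail_pool[n_pegs + seq_len(n_megs)] else character(0)
  cis  <- tail_pool[n_pegs + n_megs + seq_len(n_cis)]
  used <- length(pegs) + length(megs) + length(cis)
  # ordinary (non-imprinted) bias is planted per cross direction: distinct
  # gene sets are active in paternal- vs maternal-excess crosses, so these
  # genes never mimic the both-cross consistency that defines imprinting
  take <- function(n) {
    out <- tail_pool[used + seq_len(n)]
    used <<- used + n
    out
  }
  mat_bias <- list("3x_paternal_excess" = take(n_maternal_bias),
                   "3x_maternal_excess" = take(n_maternal_bias))
  pat_bias <- list("3x_paternal_excess" = take(n_paternal_bias),
                   "3x_maternal_excess" = take(n_paternal_bias))
  if (used + n_gbm > n_genes)
    stop("planted ASE/methylation gene sets exceed n_genes")
  gbm <- if (n_gbm > 0L) tail_pool[used + seq_len(n_gbm)] else character(0)
  if (is.null(meth_baseline)) {
    meth_baseline <- rbind(upstream  = c(CG = 0.15, CHG = 0.08, CHH = 0.04),
                           body      = c(CG = 0.30, CHG = 0.10, CHH = 0.05),
                           downstream = c(CG = 0.15, CHG = 0.08, CHH = 0.04))
  }
  stopifnot(imprint_fraction >= 0, imprint_fraction <= 1,
            all(meth_baseline >= 0), all(meth_baseline <= 1),
            bias_delta >= 0, bias_delta <= 1)
  if (length(intersect(pegs, cis)) || length(intersect(megs, cis)) ||
      length(intersect(pegs, megs)))
    stop("planted PEG/MEG/cis sets must be disjoint")
  structure(list(
    n_genes = n_genes, genes = genes, seed = as.integer(seed),
    lib_mean = lib_mean, dispersion = dispersion, base_lsd = base_lsd,
    poe_genes = poe_genes, ploidy_genes = ploidy_genes,
    hybridity_genes = hybridity_genes,
    poe_lfc = poe_lfc, ploidy_lfc = ploidy_lfc,
    hybridity_lfc = hybridity_lfc,
    n_snps_mean = n_snps_mean, snp_depth_mean = snp_depth_mean,
    pegs = pegs, megs = megs, cis_genes = cis,
    imprint_fraction = imprint_fraction,
    maternal_bias_genes = mat_bias, paternal_bias_genes = pat_bias,
    bias_delta = bias_delta,
    meth_sites_per_region = meth_sites_per_region,
    meth_coverage_mean = meth_coverage_mean,
    meth_baseline = meth_baseline,
    gbm_genes = gbm, gbm_delta = gbm_delta,
    gbm_couple_ase = isTRUE(gbm_couple_ase),
    diurnal_noise_sd = diurnal_noise_sd,
    n_reps = as.integer(n_reps)), class = "sim_params")
}

#' Synthetic gene annotation matching the simulators
#'
#' Genes are laid out on 5 chromosomes, 3-kb bodies spaced 10 kb apart,
#' alternating strands, so upstream/body/downstream regions never overlap.
#'
#' @param params a [sim_params()].
#' @return annotation data.frame as from [read_annotation()].
#' @export
sim_annotation <- function(params) {
  n <- params$n_genes
  i <- seq_len(n)
  chrom <- paste0("chr", ((i - 1L) %% 5L) + 1L)
  offset <- ((i - 1L) %/% 5L) * 10000L + 5000L
  strand <- ifelse(i %% 2L == 0L, "-", "+")
  start <- offset
  end <- offset + 2999L
  data.frame(gene_id = params$genes, chrom = chrom, strand = strand,
             tss = ifelse(strand == "+", start, end),
             tts = ifelse(strand == "+", end, start))
}

hybrid_groups <- function(design) {
  design$groups$group[design$groups$group_class != "parental_self"]
}

#' Simulate a raw count matrix with planted POE/ploidy/hybridity effects
#'
#' Counts are negative binomial with a per-gene baseline mean (log-normal
#' across genes, scaled so expected library size is `lib_mean`) and a shared
#' dispersion. Effect multipliers by group class as documented in
#' [sim_params()].
#'
#' @param design a [cross_design()].
#' @param params a [sim_params()].
#' @return list: `expr` (raw-count [expression_matrix()]), `truth`
#'   (data.frame gene_id, class, lfc; class "null" for unplanted genes).
#' @export
simulate_expression <- function(design, params) {
  set.seed(params$seed)
  genes <- params$genes
  n <- length(genes)
  base <- stats::rlnorm(n, meanlog = 0, sdlog = params$base_lsd)
  base <- base / sum(base) * params$lib_mean
  cls <- design$groups$group_class
  names(cls) <- design$groups$group
  mult <- matrix(1, n, nrow(design$groups),
                 dimnames = list(genes, design$groups$group))
  ip <- match(params$poe_genes, genes)
  mult[ip, cls == "3x_paternal_excess"] <- 2^(params$poe_lfc / 2)
  mult[ip, cls == "3x_maternal_excess"] <- 2^(-params$poe_lfc / 2)
  i3 <- cls %in% c("3x_paternal_excess", "3x_maternal_excess")
  mult[match(params$ploidy_genes, genes), i3] <-
    mult[match(params$ploidy_genes, genes), i3] * 2^params$ploidy_lfc
  ih <- cls != "parental_self"
  mult[match(params$hybridity_genes, genes), ih] <-
    mult[match(params$hybridity_genes, genes), ih] * 2^params$hybridity_lfc

  counts <- matrix(0L, n, nrow(design$samples),
                   dimnames = list(genes, design$samples$sample))
  for (j in seq_len(nrow(design$samples))) {
    mu <- base * mult[, design$samples$group[j]]
    counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / params$dispersion)
  }
  truth <- data.frame(gene_id = genes, class = "null", lfc = 0)
  truth$class[truth$gene_id %in% params$poe_genes] <- "poe"
  truth$lfc[truth$class == "poe"] <- params$poe_lfc
  truth$class[truth$gene_id %in% params$ploidy_genes] <- "ploidy"
  truth$lfc[truth$class == "ploidy"] <- params$ploidy_lfc
  truth$class[truth$gene_id %in% params$hybridity_genes] <- "hybridity"
  truth$lfc[truth$class == "hybridity"] <- params$hybridity_lfc
  list(expr = expression_matrix(counts, normalized = FALSE), truth = truth)
}

# Expected fraction of the maternal-parent allele for one gene in one cross,
# applying planted truth classes in priority order PEG/MEG > cis > biased.
truth_maternal_fraction <- function(gene, group, design, params) {
  g <- group_row(design, group)
  f_null <- g$maternal_ploidy / (g$maternal_ploidy + g$paternal_ploidy)
  fr <- params$imprint_fraction
  if (gene %in% params$pegs) return(1 - fr)          # paternal allele at fr
  if (gene %in% params$megs) return(fr)
  if (gene %in% params$cis_genes) {
    # genotype-attached: the alphabetically-last parent genotype is favoured
    fav <- max(g$maternal_parent, g$paternal_parent)
    return(if (g$maternal_parent == fav) fr else 1 - fr)
  }
  cls <- g$group_class
  if (gene %in% params$maternal_bias_genes[[cls]])
    return(min(f_null + params$bias_delta, 0.95))
  if (gene %in% params$paternal_bias_genes[[cls]])
    return(1 - min((1 - f_null) + params$bias_delta, 0.95))
  if (params$gbm_couple_ase && gene %in% params$gbm_genes)
    return(1 - min((1 - f_null) + params$bias_delta, 0.95))
  f_null
}

#' Simulate per-SNP allelic read counts under the parental-dosage null
#'
#' For every hybrid group, every gene gets a Poisson number of informative
#' SNPs; per SNP and sample the total depth is Poisson and the reads of the
#' maternal-parent allele are binomial with the gene's true maternal
#' fraction: the dosage null (2/3 for the tetraploid parent in triploids,
#' 1/2 in balanced crosses) unless the gene is planted as PEG/MEG (parent-
#' of-origin-attached), cis (genotype-attached) or per-cross biased.
#' Records store genotype allele labels in alphabetical order; parent of
#' origin is never stored.
#'
#' @param design a [cross_design()].
#' @param params a [sim_params()].
#' @param groups groups to simulate (default: all hybrid groups).
#' @return list: `records` (data.frame as from [read_allele_counts()]),
#'   `truth` (gene_id, group, f_maternal, class).
#' @export
simulate_allele_counts <- function(design, params,
                                   groups = hybrid_groups(design)) {
  set.seed(params$seed + 1L)
  anno <- sim_annotation(params)
  n_snps <- pmax(stats::rpois(params$n_genes, params$n_snps_mean), 0L)
  keep <- n_snps > 0L
  out <- vector("list", length(groups))
  truth <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    grp <- groups[k]
    g <- group_row(design, grp)
    samples <- replicates_of(design, grp)
    gi <- which(keep)
    reps <- rep.int(gi, n_snps[gi])
    gene <- params$genes[reps]
    a <- anno[reps, ]
    lo <- pmin(a$tss, a$tts)
    hi <- pmax(a$tss, a$tts)
    pos <- lo + (stats::runif(length(reps)) * (hi - lo)) %/% 1
    f_m <- vapply(params$genes, truth_maternal_fraction, 0,
                  group = grp, design = design, params = params)
    cls <- rep("null", params$n_genes)
    cls[params$genes %in% params$pegs] <- "peg"
    cls[params$genes %in% params$megs] <- "meg"
    cls[params$genes %in% params$cis_genes] <- "cis"
    gcls <- g$group_class
    cls[params$genes %in% params$maternal_bias_genes[[gcls]]] <-
      "maternal_bias"
    cls[params$genes %in% params$paternal_bias_genes[[gcls]]] <-
      "paternal_bias"
    if (params$gbm_couple_ase)
      cls[cls == "null" & params$genes %in% params$gbm_genes] <-
        "paternal_bias"
    truth[[k]] <- data.frame(gene_id = params$genes, group = grp,
                             f_maternal = unname(f_m), class = cls)
    pair <- sort(c(g$maternal_parent, g$paternal_parent))
    mat_is_a <- g$maternal_parent == pair[1L]
    blocks <- lapply(samples, function(s) {
      tot <- stats::rpois(length(reps), params$snp_depth_mean)
      m <- stats::rbinom(length(reps), tot, f_m[reps])
      data.frame(gene_id = gene, chrom = a$chrom, pos = as.integer(pos),
                 allele_a = pair[1L], allele_b = pair[2L],
                 reads_a = if (mat_is_a) m else tot - m,
                 reads_b = if (mat_is_a) tot - m else m,
                 sample = s)
    })
    out[[k]] <- do.call(rbind, blocks)
  }
  list(records = do.call(rbind, out), truth = do.call(rbind, truth))
}

#' Simulate allele-resolved methylomes with planted gene-body mCG asymmetry
#'
#' Cytosines are placed uniformly in the upstream flank, gene body and
#' downstream flank of each gene at per-context densities; read coverage is
#' Poisson, methylated reads binomial at the region/context baseline level.
#' Planted gbM genes get `gbm_delta` added to the body-CG level of the
#' paternal allele of each cross (parent-of-origin-attached, like the
#' expression coupling it models).
#'
#' @param design a [cross_design()].
#' @param annotation annotation data.frame (default [sim_annotation()]).
#' @param params a [sim_params()].
#' @param groups crosses to simulate (default: reciprocal triploid pair
#'   formed from the first 3x(p) and first 3x(m) group).
#' @param flank flank length in bp.
#' @return list: `calls` (data.frame per cross, as [read_methyl_calls()],
#'   with a `group` column), `truth` (gene_id, group, gbm logical).
#' @export
simulate_methylomes <- function(design, params,
                                annotation = sim_annotation(params),
                                groups = NULL, flank = 2000L) {
  set.seed(params$seed + 2L)
  if (is.null(groups))
    groups <- c(groups_of_class(design, "3x_paternal_excess")[1L],
                groups_of_class(design, "3x_maternal_excess")[1L])
  contexts <- names(params$meth_sites_per_region)
  out <- list(); truth <- list()
  for (grp in groups) {
    g <- group_row(design, grp)
    samples <- replicates_of(design, grp)
    alleles <- c(g$maternal_parent, g$paternal_parent)
    pat <- g$paternal_parent
    regs <- gene_regions(annotation, flank = flank)
    is_gbm <- regs$gene_id %in% params$gbm_genes & regs$region == "body"
    blocks <- list()
    for (ctx in contexts) {
      nsite <- params$meth_sites_per_region[[ctx]]
      ridx <- rep(seq_len(nrow(regs)), each = nsite)
      width <- regs$end[ridx] - regs$start[ridx]
      pos <- regs$start[ridx] +
        as.integer((stats::runif(length(ridx)) * (width + 1L)) %/% 1)
      lev0 <- params$meth_baseline[regs$region[ridx], ctx]
      strand <- sample(c("+", "-"), length(ridx), replace = TRUE)
      for (al in alleles) {
        lev <- lev0
        bump <- is_gbm[ridx] & al == pat & ctx == "CG"
        lev[bump] <- pmin(lev[bump] + params$gbm_delta, 1)
        for (s in samples) {
          tot <- stats::rpois(length(ridx), params$meth_coverage_mean)
          meth <- stats::rbinom(length(ridx), tot, lev)
          blocks[[length(blocks) + 1L]] <- data.frame(
            chrom = regs$chrom[ridx], pos = pos, strand = strand,
            context = ctx, allele = al, meth_reads = meth,
            total_reads = tot, sample = s, group = grp)
        }
      }
    }
    out[[grp]] <- do.call(rbind, blocks)
    truth[[grp]] <- data.frame(gene_id = annotation$gene_id, group = grp,
                               gbm = annotation$gene_id %in% params$gbm_genes)
  }
  list(calls = do.call(rbind, out), truth = do.call(rbind, truth))
}

#' Simulate diurnal expression series
#'
#' Cosinor-shaped relative expression sampled at ZT0/6/12/18 with additive
#' replicate noise, clamped at a small positive floor (relative expression
#' is a positive fold change).
#'
#' @param truth data.frame with columns `gene_id, group, mesor, amplitude,
#'   peak_zt` (peak-to-trough amplitude = 2 x the cosinor amplitude used;
#'   here `amplitude` is the cosinor half-amplitude).
#' @param params a [sim_params()] (supplies `n_reps`, `diurnal_noise_sd`,
#'   `seed`).
#' @return data.frame gene_id, group, zt, rep, value.
#' @export
simulate_diurnal <- function(truth, params) {
  set.seed(params$seed + 3L)
  zts <- c(0, 6, 12, 18)
  grid <- merge(truth, expand.grid(zt = zts, rep = seq_len(params$n_reps)))
  mu <- grid$mesor + grid$amplitude *
    cos(2 * pi * (grid$zt - grid$peak_zt) / 24)
  val <- mu + stats::rnorm(nrow(grid), 0, params$diurnal_noise_sd)
  grid$value <- pmax(val, 1e-3)
  grid[order(grid$gene_id, grid$group, grid$zt, grid$rep),
       c("gene_id", "group", "zt", "rep", "value")]
}

#' Default diurnal truth table for the synthetic clock genes
#'
#' Four clock-like genes over the triploid reciprocal pairs of a design:
#' CCA1-like (nadir ZT6), LHY-like (nadir ZT12), GI-like and TOC1-like
#' (peak ZT6). The TOC1-like gene's amplitude is reduced by 40% in
#' paternal-excess groups, emulating the dampened rhythm paternal genome
#' excess induces.
#'
#' @param design a [cross_design()].
#' @return truth data.frame for [simulate_diurnal()].
#' @export
default_diurnal_truth <- function(design) {
  grps <- groups_of_class(design, c("3x_paternal_excess",
                                    "3x_maternal_excess"))
  cls <- design$groups$group_class[match(grps, design$groups$group)]
  genes <- data.frame(
    gene_id = c("CCA1like", "LHYlike", "GIlike", "TOC1like"),
    peak_zt = c(18, 0, 6, 6),
    amplitude = c(0.8, 0.8, 0.6, 1.0))
  out <- merge(genes, data.frame(group = grps, class = cls))
  out$mesor <- 1.5
  damp <- out$gene_id == "TOC1like" & out$class == "3x_paternal_excess"
  out$amplitude[damp] <- out$amplitude[damp] * 0.6
  out[, c("gene_id", "group", "mesor", "amplitude", "peak_zt")]
}
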