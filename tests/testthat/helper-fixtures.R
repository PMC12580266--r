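# Shared fixtures, built in code at test time.

# minimal reciprocal triploid design: L2xL4 (paternal excess), L4xL2
# (maternal excess), plus both parental selfs
tiny_design <- function(n_reps = 3L) {
  groups <- data.frame(
    group = c("L2self", "L4self", "L2xL4", "L4xL2"),
    maternal_parent = c("L2", "L4", "L2", "L4"),
    paternal_parent = c("L2", "L4", "L4", "L2"))
  samples <- do.call(rbind, lapply(groups$group, function(g)
    data.frame(sample = paste0(g, "_r", seq_len(n_reps)), group = g)))
  cross_design(groups, samples, c(L2 = 2L, L4 = 4L))
}

# allele-count records for one SNP across replicates of a group
snp_records <- function(design, group, gene, chrom = "chr1", pos = 100L,
                        reads_maternal, reads_paternal) {
  g <- design$groups[design$groups$group == group, ]
  pair <- sort(c(g$maternal_parent, g$paternal_parent))
  mat_is_a <- g$maternal_parent == pair[1L]
  samples <- replicates_of(design, group)
  stopifnot(length(reads_maternal) == length(samples))
  data.frame(gene_id = gene, chrom = chrom, pos = pos,
             allele_a = pair[1L], allele_b = pair[2L],
             reads_a = if (mat_is_a) reads_maternal else reads_paternal,
             reads_b = if (mat_is_a) reads_paternal else reads_maternal,
             sample = samples)
}

# brute-force two-sided minimum-likelihood exact binomial p-value: sums the
# probabilities of all outcomes whose pmf does not exceed the observed
# one's (standard relative tolerance guards floating-point ties)
enum_binom_p <- function(k, n, f) {
  d <- stats::dbinom(0:n, n, f)
  min(1, sum(d[d <= d[k + 1L] * (1 + 1e-7)]))
}

# methylation calls at explicit sites: one row per site x sample
meth_calls_at <- function(pos, chrom = "chr1", context = "CG",
                          allele = "L2", meth, total,
                          sample = "s1", strand = "+") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             context = context, allele = allele,
             meth_reads = as.integer(meth), total_reads = as.integer(total),
             sample = sample)
}

# small simulation params with all planted set sizes scaled coherently
small_params <- function(seed = 1L, ...) {
  sim_params(n_genes = 600L, seed = seed, lib_mean = 3e5,
             n_poe = 60L, n_ploidy = 30L, n_hybridity = 10L,
             n_pegs = 5L, n_cis = 5L,
             n_maternal_bias = 30L, n_paternal_bias = 10L,
             n_gbm = 15L, ...)
}
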