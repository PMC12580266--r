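#!/usr/bin/env Rscript
# Stage 5 — allele-specific methylation around the ASE genes.
#
# Regenerates allele-resolved methylomes (same seed as stage 1) for the
# ASE genes plus a background set, computes per-region (2-kb upstream /
# body / 2-kb downstream) mean levels per allele and context, the ASM
# difference |mean(L2) - mean(L4)|, the reciprocal-cross Wilcoxon
# comparison per region and context, metagene profiles, and the
# gene-body-mCG vs paternal-expression association.

suppressPackageStartupMessages(library(triploase))
out <- "results/analysis"
seed <- 1L
design <- read_design(file.path(out, "design.yaml"))
params <- sim_params(seed = seed)

ase_p <- read_table_tsv(file.path(out, "ase_L2xL4.tsv"))
ase_m <- read_table_tsv(file.path(out, "ase_L4xL2.tsv"))
biased <- function(a) a$gene_id[a$bias_class %in%
                                  c("maternal_biased", "paternal_biased")]
targets <- unique(c(biased(ase_p), biased(ase_m), params$gbm_genes))
anno <- sim_annotation(params)
bg <- setdiff(anno$gene_id, targets)[1:200]
anno <- anno[anno$gene_id %in% c(targets, bg), ]
message("profiling ", nrow(anno), " genes (",
        length(targets), " ASE/gbM targets + ", length(bg),
        " background)")

meth <- simulate_methylomes(design, params, annotation = anno,
                            groups = c("L2xL4", "L4xL2"))
means_p <- region_means(meth$calls[meth$calls$group == "L2xL4", ], anno)
means_m <- region_means(meth$calls[meth$calls$group == "L4xL2", ], anno)
diffs_p <- asm_difference(means_p)
diffs_m <- asm_difference(means_m)
write_table(diffs_p, file.path(out, "asm_L2xL4.tsv"))
write_table(diffs_m, file.path(out, "asm_L4xL2.tsv"))

tests <- do.call(rbind, lapply(c("upstream", "body", "downstream"),
  function(rg) do.call(rbind, lapply(c("CG", "CHG", "CHH"), function(ctx) {
    w <- compare_reciprocal_asm(diffs_m, diffs_p, rg, ctx)
    data.frame(region = rg, context = ctx, statistic = w$statistic,
               p = signif(w$p, 4), annotation = w$annotation)
  }))))
write_table(tests, file.path(out, "asm_reciprocal_tests.tsv"))
print(tests)

# metagene profiles of the paternal allele in each cross, body mCG focus
profs <- do.call(rbind, lapply(
  list(c("L2xL4", "L4"), c("L4xL2", "L2")), function(ga) {
    pr <- metagene_profile(meth$calls[meth$calls$group == ga[1], ], anno,
                           context = "CG", allele = ga[2])
    data.frame(group = ga[1], allele = ga[2],
               bin = seq_along(pr), segment = attr(pr, "segment"),
               level = round(pr, 4))
  }))
write_table(profs, file.path(out, "metagene_cg_paternal.tsv"))

gbm <- gbm_expression_association(means_p, ase_p, design)
message(sprintf("gbM body-mCG vs paternal expression: Spearman rho = %.3f (p = %.2g, n = %d)",
                gbm$rho, gbm$p, gbm$n))
body_cg <- diffs_p[diffs_p$region == "body" & diffs_p$context == "CG", ]
top <- body_cg$gene_id[order(-body_cg$asm_diff)][seq_along(params$gbm_genes)]
message(sprintf("planted gbM-asymmetry genes in the top-%d body-mCG ASM list: %d",
                length(params$gbm_genes),
                sum(top %in% params$gbm_genes)))
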