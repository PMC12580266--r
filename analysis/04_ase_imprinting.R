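#!/usr/bin/env Rscript
# Stage 4 — allele-specific expression and imprinting calls.
#
# Tests every informative SNP of the reciprocal triploid pair against the
# 2:1 parental-dosage null (the tetraploid parent contributes two of three
# genome copies), aggregates to genes with BH correction across each
# cross's SNPs, summarizes the reciprocal pattern, and separates true
# parent-of-origin bias (PEG/MEG: same PARENT's allele favoured in both
# crosses) from cis effects (same GENOTYPE allele favoured in both).

suppressPackageStartupMessages(library(triploase))
out <- "results/analysis"
design <- read_design(file.path(out, "design.yaml"))
records <- read_allele_counts(file.path(out, "allele_counts.tsv"))

ase_m <- aggregate_gene_ase(records, design, "L4xL2")  # maternal excess
ase_p <- aggregate_gene_ase(records, design, "L2xL4")  # paternal excess
write_table(ase_m, file.path(out, "ase_L4xL2.tsv"))
write_table(ase_p, file.path(out, "ase_L2xL4.tsv"))

rs <- reciprocal_summary(ase_m, ase_p, design)
write_table(rs$counts, file.path(out, "ase_counts.tsv"))
write_table(rs$scatter, file.path(out, "ase_scatter.tsv"))
print(rs$counts)
message(sprintf("fraction of biased calls that are maternal: %.2f",
                rs$asymmetry$maternal_call_fraction))

imp <- call_imprinting(ase_p, ase_m, design)
write_table(imp, file.path(out, "imprinting.tsv"))
message("imprinting calls: ", sum(imp$status == "PEG"), " PEG, ",
        sum(imp$status == "MEG"), " MEG, ",
        sum(imp$status == "cis_biased"),
        " cis-biased (excluded from imprinting)")

truth <- read_table_tsv(file.path(out, "ase_truth.tsv"))
planted_peg <- unique(truth$gene_id[truth$class == "peg"])
planted_cis <- unique(truth$gene_id[truth$class == "cis"])
message(sprintf("planted-truth check: %d/%d informative PEGs recovered; %d cis genes miscalled PEG",
                sum(imp$status == "PEG" & imp$gene_id %in% planted_peg),
                sum(imp$gene_id %in% planted_peg),
                sum(imp$status == "PEG" & imp$gene_id %in% planted_cis)))
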