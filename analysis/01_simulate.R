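#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Builds the reciprocal hybrid series (parental selfs, 2x/3x/4x hybrids,
# 3 replicates each), then generates every input table the downstream
# stages consume: a raw RNA-seq count matrix with planted POE, ploidy and
# hybridity effects, and per-SNP allelic read counts for the reciprocal
# triploid pair with planted imprinted (PEG), cis-biased and per-cross
# biased genes. Everything is written under results/analysis/ so stages
# 02-06 run from files, exactly as they would on real data.

suppressPackageStartupMessages(library(triploase))
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

seed <- 1L
design <- default_design()
params <- sim_params(seed = seed)

write_design(design, file.path(out, "design.yaml"))
message("design: ", nrow(design$groups), " groups / ",
        nrow(design$samples), " samples")

sim <- simulate_expression(design, params)
write_counts(sim$expr, file.path(out, "counts.tsv"))
write_table(sim$truth, file.path(out, "expression_truth.tsv"))
message("expression: ", params$n_genes, " genes; planted ",
        sum(sim$truth$class == "poe"), " POE / ",
        sum(sim$truth$class == "ploidy"), " ploidy / ",
        sum(sim$truth$class == "hybridity"), " hybridity genes")

ac <- simulate_allele_counts(design, params,
                             groups = c("L2xL4", "L4xL2"))
write_table(ac$records, file.path(out, "allele_counts.tsv"))
write_table(ac$truth, file.path(out, "ase_truth.tsv"))
message("allelic counts: ", nrow(ac$records), " SNP x sample records; ",
        "planted ", length(params$pegs), " PEGs, ",
        length(params$cis_genes), " cis genes, ",
        length(params$maternal_bias_genes[[1]]),
        " maternal- and ", length(params$paternal_bias_genes[[1]]),
        " paternal-biased genes per cross direction")

# methylomes and diurnal series are regenerated by stages 05/06 from the
# same seed (they are large relative to what they add as intermediates)
message("done: inputs in ", out)
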