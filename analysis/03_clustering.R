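#!/usr/bin/env Rscript
# Stage 3 — expression-profile clustering of the DEGs.
#
# Z-scores each DEG's group-mean profile, partitions the profiles with
# fuzzy c-means (c = 5, fuzzifier 2, membership threshold 0.7), picks the
# cluster peaking in the paternal-excess triploids — the profile of
# interest for vigor-associated genes — and splits it into 10 k-means
# sub-clusters.

suppressPackageStartupMessages(library(triploase))
out <- "results/analysis"
seed <- 1L
design <- read_design(file.path(out, "design.yaml"))
counts <- read_counts(file.path(out, "counts.tsv"), design = design)
norm <- normalize_library(counts)

de_files <- list.files(out, pattern = "^de_(poe|ploidy|hyb)", full.names = TRUE)
degs <- unique(unlist(lapply(de_files, function(f) {
  d <- read_table_tsv(f)
  d$gene_id[d$significant == "TRUE" | d$significant == TRUE]
})))
message(length(degs), " DEGs pooled over contrasts")

prof <- standardize_profiles(norm$normalized, design)
keep <- setdiff(degs, prof$flagged)
if (length(prof$flagged))
  message(length(prof$flagged), " constant genes flagged and excluded")
x <- prof$profiles[keep, , drop = FALSE]

fcm <- fuzzy_cmeans(x, c = 5L, m = 2, seed = seed)
memb <- assign_members(fcm, threshold = 0.7)
message("fuzzy c-means: ", fcm$iterations, " iterations; ",
        sum(!is.na(memb)), "/", length(memb),
        " genes pass the 0.7 membership threshold")

pk <- peak_cluster(fcm, groups_of_class(design, "3x_paternal_excess")[1L])
# sub-cluster the argmax members of the peak cluster: synthetic DEGs have
# few distinct profile shapes, so memberships split across near-duplicate
# centers and the 0.7 threshold retains few of them
sel <- max.col(fcm$membership) == pk
message("cluster ", pk, " peaks in the paternal-excess triploids (",
        sum(sel), " member genes, ",
        sum(!is.na(memb) & memb == pk), " above the 0.7 threshold)")

sub <- rep(NA_integer_, length(memb))
names(sub) <- names(memb)
if (sum(sel) >= 10L) {
  km <- kmeans_subcluster(x[sel, , drop = FALSE], k = 10L, seed = seed)
  sub[names(km$labels)] <- km$labels
  message("k-means sub-clusters C1-C10 sized: ",
          paste(tabulate(km$labels, 10), collapse = ", "))
}
write_table(data.frame(gene_id = names(memb), cluster = unname(memb),
                       subcluster = unname(sub)),
            file.path(out, "clusters.tsv"))
write_table(data.frame(cluster = seq_len(nrow(fcm$centers)),
                       as.data.frame(fcm$centers)),
            file.path(out, "cluster_centers.tsv"))
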