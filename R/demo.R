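#' Run the full synthetic pipeline end to end
#'
#' Simulates the complete study structure from planted ground truth, then
#' runs every analysis stage — library normalization, factorial DE
#' contrasts and summary, fuzzy c-means clustering with k-means
#' sub-clustering, dosage-aware ASE per reciprocal triploid cross,
#' imprinting calls, allele-specific methylation statistics, and diurnal
#' summaries — and writes one TSV per stage plus a planted-truth recovery
#' summary and a run manifest. Logging goes to standard error; results only
#' to files.
#'
#' @param out_dir output directory (created if missing).
#' @param params a [sim_params()]; its seed drives all randomness.
#' @param design a [cross_design()].
#' @param asm_background number of non-ASE genes to carry through the
#'   methylation stage alongside the planted/called ASE genes.
#' @return (invisibly) a list with every stage's in-memory result.
#' @export
run_demo <- function(out_dir, params = sim_params(),
                     design = default_design(params$n_reps),
                     asm_background = 200L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message("[demo] ", ...)
  tsv <- function(df, name) write_table(df, file.path(out_dir, name))

  log("simulating expression (", params$n_genes, " genes, ",
      nrow(design$samples), " samples, seed ", params$seed, ")")
  sim <- simulate_expression(design, params)
  norm <- normalize_library(sim$expr)

  log("factorial DE contrasts")
  contrasts <- c("poe", "ploidy2", "ploidy4", "hyb2", "hyb4")
  de <- lapply(stats::setNames(contrasts, contrasts), function(ct)
    run_contrast(norm$normalized, design, ct))
  fsum <- factorial_deg_summary(de)
  for (ct in contrasts) tsv(de[[ct]], paste0("de_", ct, ".tsv"))
  tsv(fsum$summary, "de_summary.tsv")

  log("clustering DEG profiles")
  degs <- unique(unlist(lapply(de, function(r) r$gene_id[r$significant])))
  prof <- standardize_profiles(norm$normalized, design)
  cl_genes <- setdiff(degs, prof$flagged)
  clu <- NULL
  if (length(cl_genes) >= 20L) {
    p <- prof$profiles[cl_genes, , drop = FALSE]
    fcm <- fuzzy_cmeans(p, c = 5L, m = 2, seed = params$seed)
    memb <- assign_members(fcm, 0.7)
    pk <- peak_cluster(fcm, groups_of_class(design,
                                            "3x_paternal_excess")[1L])
    sub <- rep(NA_integer_, length(memb)); names(sub) <- names(memb)
    # sub-cluster the peak cluster's argmax members: with few distinct
    # profile shapes, memberships split across near-duplicate centers and
    # the 0.7 threshold retains few genes
    in_pk <- max.col(fcm$membership) == pk
    if (!is.na(pk) && sum(in_pk) >= 10L) {
      ks <- kmeans_subcluster(p[in_pk, , drop = FALSE], k = 10L,
                              seed = params$seed)
      sub[names(ks$labels)] <- ks$labels
    }
    clu <- data.frame(gene_id = names(memb), cluster = unname(memb),
                      subcluster = unname(sub))
    tsv(clu, "clusters.tsv")
  } else log("too few DEGs to cluster; skipping stage output")

  log("allele-specific expression on the reciprocal triploid pair")
  cr_p <- groups_of_class(design, "3x_paternal_excess")[1L]
  cr_m <- groups_of_class(design, "3x_maternal_excess")[1L]
  ac <- simulate_allele_counts(design, params, groups = c(cr_p, cr_m))
  ase_p <- aggregate_gene_ase(ac$records, design, cr_p)
  ase_m <- aggregate_gene_ase(ac$records, design, cr_m)
  tsv(ase_p, paste0("ase_", cr_p, ".tsv"))
  tsv(ase_m, paste0("ase_", cr_m, ".tsv"))
  rsum <- reciprocal_summary(ase_m, ase_p, design)
  tsv(rsum$counts, "ase_counts.tsv")
  tsv(rsum$scatter, "ase_scatter.tsv")
  imp <- call_imprinting(ase_p, ase_m, design)
  tsv(imp, "imprinting.tsv")

  log("allele-specific methylation")
  asegs <- unique(c(ase_p$gene_id[ase_p$bias_class %in%
                                    c("maternal_biased", "paternal_biased")],
                    ase_m$gene_id[ase_m$bias_class %in%
                                    c("maternal_biased", "paternal_biased")],
                    params$gbm_genes))
  anno <- sim_annotation(params)
  bg <- setdiff(anno$gene_id, asegs)[seq_len(asm_background)]
  anno_sub <- anno[anno$gene_id %in% c(asegs, bg), , drop = FALSE]
  meth <- simulate_methylomes(design, params, annotation = anno_sub,
                              groups = c(cr_p, cr_m))
  means_p <- region_means(meth$calls[meth$calls$group == cr_p, ], anno_sub)
  means_m <- region_means(meth$calls[meth$calls$group == cr_m, ], anno_sub)
  diffs_p <- asm_difference(means_p)
  diffs_m <- asm_difference(means_m)
  tsv(diffs_p, paste0("asm_", cr_p, ".tsv"))
  tsv(diffs_m, paste0("asm_", cr_m, ".tsv"))
  asm_tests <- do.call(rbind, lapply(
    c("upstream", "body", "downstream"), function(rg)
      do.call(rbind, lapply(c("CG", "CHG", "CHH"), function(ctx) {
        w <- compare_reciprocal_asm(diffs_m, diffs_p, rg, ctx)
        data.frame(region = rg, context = ctx, statistic = w$statistic,
                   p = w$p, annotation = w$annotation)
      }))))
  tsv(asm_tests, "asm_reciprocal_tests.tsv")
  gbm <- gbm_expression_association(means_p, ase_p, design)

  log("diurnal series")
  dtruth <- default_diurnal_truth(design)
  dser <- simulate_diurnal(dtruth, params)
  dsum <- do.call(rbind, lapply(split(dser, list(dser$gene_id,
                                                 dser$group),
                                      drop = TRUE), function(s) {
    z <- diurnal_summary(s)
    data.frame(gene_id = s$gene_id[1L], group = s$group[1L],
               peak_zt = z$peak_zt, nadir_zt = z$nadir_zt,
               amplitude = z$amplitude,
               relative_amplitude = z$relative_amplitude, tie = z$tie)
  }))
  tsv(dsum, "diurnal_summary.tsv")
  tt <- do.call(rbind, lapply(unique(dser$gene_id), function(gn) {
    r <- reciprocal_timepoint_tests(
      dser[dser$gene_id == gn & dser$group == cr_p, ],
      dser[dser$gene_id == gn & dser$group == cr_m, ])
    cbind(gene_id = gn, r)
  }))
  tsv(tt, "diurnal_timepoint_tests.tsv")

  log("planted-truth recovery summary")
  de_truth <- sim$truth
  rec_row <- function(stage, metric, value)
    data.frame(stage = stage, metric = metric, value = value)
  poe_sig <- de$poe$gene_id[de$poe$significant]
  null_genes <- de_truth$gene_id[de_truth$class == "null"]
  recovery <- rbind(
    rec_row("de", "poe_sensitivity",
            mean(de_truth$gene_id[de_truth$class == "poe"] %in% poe_sig)),
    rec_row("de", "null_fp_rate_poe_contrast",
            mean(null_genes %in% poe_sig)),
    rec_row("de", "factor_rank_1", match("POE", fsum$factor_ranking)),
    rec_row("ase", "peg_recovered",
            sum(imp$status == "PEG" & imp$gene_id %in% params$pegs)),
    rec_row("ase", "pegs_planted_informative",
            sum(imp$gene_id %in% params$pegs)),
    rec_row("ase", "cis_called_peg",
            sum(imp$status == "PEG" & imp$gene_id %in% params$cis_genes)),
    rec_row("asm", "gbm_expression_rho", gbm$rho),
    rec_row("diurnal", "toc1_amplitude_ratio_p_over_m",
            dsum$amplitude[dsum$gene_id == "TOC1like" &
                             dsum$group == cr_p] /
              dsum$amplitude[dsum$gene_id == "TOC1like" &
                               dsum$group == cr_m]))
  tsv(recovery, "recovery_summary.tsv")

  manifest <- data.frame(
    key = c("seed", "n_genes", "n_reps", "lib_mean", "dispersion",
            "package_version", "r_version"),
    value = c(params$seed, params$n_genes, params$n_reps, params$lib_mean,
              params$dispersion,
              as.character(utils::packageVersion("triploase")),
              paste(R.version$major, R.version$minor, sep = ".")))
  tsv(manifest, "run_manifest.tsv")
  log("done; outputs in ", out_dir)

  invisible(list(sim = sim, norm = norm, de = de, de_summary = fsum,
                 clusters = clu, allele_counts = ac,
                 ase = list(paternal_excess = ase_p,
                            maternal_excess = ase_m),
                 reciprocal = rsum, imprinting = imp,
                 asm = list(means_p = means_p, means_m = means_m,
                            diffs_p = diffs_p, diffs_m = diffs_m,
                            tests = asm_tests, gbm = gbm),
                 diurnal = list(series = dser, summary = dsum,
                                timepoint_tests = tt),
                 recovery = recovery))
}
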