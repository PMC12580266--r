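test_that("SNP binomial test matches the enumeration oracle", {
  # spot grid here; the exhaustive n <= 60 sweep lives with the
  # calibration checks in test-acceptance.R
  for (f in c(1 / 3, 1 / 2, 2 / 3))
    for (n in c(1, 7, 23, 60))
      for (k in unique(c(0, 1, n %/% 3, n %/% 2, n))) {
        expect_equal(snp_ase_test(k, n - k, f), enum_binom_p(k, n, f),
                     tolerance = 1e-12,
                     label = sprintf("k=%d n=%d f=%.3f", k, n, f))
      }
  # modal expectation under the 2:1 null -> p exactly 1
  expect_equal(snp_ase_test(20, 10, 2 / 3), 1.0)
  # frozen oracle values
  expect_equal(snp_ase_test(30, 0, 2 / 3), 6.68974308406261e-06,
               tolerance = 1e-12)
  # monoallelic-grade bias like the 95.5%-paternal exemplar locus
  p_ext <- snp_ase_test(191, 9, 1 / 3)
  expect_lt(p_ext, 1e-10)
  expect_equal(p_ext, enum_binom_p(191, 200, 1 / 3), tolerance = 1e-12)
  expect_true(is.na(snp_ase_test(0, 0, 2 / 3)))
})

test_that("relabelling maternal/paternal flips classes, not p-values", {
  expect_equal(snp_ase_test(25, 9, 2 / 3), snp_ase_test(9, 25, 1 / 3),
               tolerance = 1e-12)
  d <- tiny_design()
  rec <- rbind(
    snp_records(d, "L4xL2", "gA", pos = 10L,
                reads_maternal = c(30L, 28L, 35L),
                reads_paternal = c(2L, 4L, 1L)),
    snp_records(d, "L4xL2", "gB", pos = 50L,
                reads_maternal = c(3L, 2L, 2L),
                reads_paternal = c(30L, 31L, 29L)))
  res <- aggregate_gene_ase(rec, d, "L4xL2")
  # same counts attached to the reciprocal cross: maternal<->paternal swap
  rec2 <- rec
  rec2$sample <- sub("L4xL2", "L2xL4", rec2$sample)
  res2 <- aggregate_gene_ase(rec2, d, "L2xL4")
  expect_equal(res$min_fdr, res2$min_fdr)
  flip <- c(maternal_biased = "paternal_biased",
            paternal_biased = "maternal_biased")
  expect_equal(unname(flip[res$bias_class]), res2$bias_class)
})

test_that("gene aggregation applies the 10-read filter and BH scope", {
  d <- tiny_design()
  # one SNP with 6+3 = 9 pooled reads -> filtered
  rec <- snp_records(d, "L4xL2", "thin", pos = 5L,
                     reads_maternal = c(2L, 2L, 2L),
                     reads_paternal = c(1L, 1L, 1L))
  res <- aggregate_gene_ase(rec, d, "L4xL2")
  expect_equal(res$bias_class, "filtered")
  expect_equal(res$n_snps, 0L)

  # exactly the null ratio at every SNP -> unbiased
  rec2 <- rbind(
    snp_records(d, "L4xL2", "nullg", pos = 7L,
                reads_maternal = c(20L, 20L, 20L),
                reads_paternal = c(10L, 10L, 10L)),
    snp_records(d, "L4xL2", "nullg", pos = 9L,
                reads_maternal = c(40L, 40L, 40L),
                reads_paternal = c(20L, 20L, 20L)))
  res2 <- aggregate_gene_ase(rec2, d, "L4xL2")
  expect_equal(res2$bias_class, "unbiased")
  expect_equal(res2$n_snps, 2L)
  expect_equal(res2$maternal_fraction, 2 / 3)

  # replicates pool by summation before testing
  expect_equal(res2$maternal_reads, 180L)
  expect_equal(res2$paternal_reads, 90L)

  # per-gene FDR scope adjusts within genes only
  rec3 <- rbind(rec2,
                snp_records(d, "L4xL2", "biased", pos = 11L,
                            reads_maternal = c(66L, 60L, 70L),
                            reads_paternal = c(1L, 2L, 1L)))
  a <- aggregate_gene_ase(rec3, d, "L4xL2", fdr_scope = "per_cross")
  b <- aggregate_gene_ase(rec3, d, "L4xL2", fdr_scope = "per_gene")
  expect_true(all(c("nullg", "biased") %in% a$gene_id))
  expect_equal(b$min_fdr[b$gene_id == "biased"],
               snp_ase_test(196, 4, 2 / 3))
  expect_equal(a$bias_class[a$gene_id == "biased"], "maternal_biased")
})

test_that("conflicting SNP directions are classed as conflicting", {
  d <- tiny_design()
  rec <- rbind(
    snp_records(d, "L4xL2", "confl", pos = 3L,
                reads_maternal = c(40L, 40L, 40L),
                reads_paternal = c(1L, 1L, 1L)),
    snp_records(d, "L4xL2", "confl", pos = 8L,
                reads_maternal = c(1L, 1L, 1L),
                reads_paternal = c(40L, 40L, 40L)))
  res <- aggregate_gene_ase(rec, d, "L4xL2")
  expect_equal(res$bias_class, "conflicting")
})

test_that("null simulation keeps the false-ASEG proportion at bay", {
  d <- tiny_design()
  p <- sim_params(n_genes = 700, seed = 19, snp_depth_mean = 10,
                  n_pegs = 0, n_cis = 0, n_maternal_bias = 0,
                  n_paternal_bias = 0, n_gbm = 0,
                  n_poe = 0, n_ploidy = 0, n_hybridity = 0)
  ac <- simulate_allele_counts(d, p, groups = "L4xL2")
  res <- aggregate_gene_ase(ac$records, d, "L4xL2")
  informative <- res[res$bias_class != "filtered", ]
  fp <- mean(informative$min_fdr < 0.05)
  expect_lte(fp, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(informative)))
})

test_that("reciprocal summary counts planted bias and builds the scatter", {
  d <- tiny_design()
  p <- sim_params(n_genes = 800, seed = 29, snp_depth_mean = 40,
                  n_maternal_bias = 60, n_paternal_bias = 15,
                  n_pegs = 0, n_cis = 0, n_gbm = 0,
                  n_poe = 0, n_ploidy = 0, n_hybridity = 0)
  ac <- simulate_allele_counts(d, p)
  rm_ <- aggregate_gene_ase(ac$records, d, "L4xL2")
  rp <- aggregate_gene_ase(ac$records, d, "L2xL4")
  s <- reciprocal_summary(rm_, rp, d)
  # planted 60 maternal / 15 paternal per cross, recovered within
  # binomial sampling error (some genes draw zero SNPs)
  expect_true(all(abs(s$counts$maternal - 60) <= 15))
  expect_true(all(abs(s$counts$paternal - 15) <= 10))
  expect_gt(s$asymmetry$maternal_call_fraction, 0.6)
  expect_true(all(s$scatter$pct_when_maternal >= 0 &
                    s$scatter$pct_when_maternal <= 100))

  # no ASEGs -> zero counts, empty scatter
  un <- rm_; un$bias_class[un$bias_class != "filtered"] <- "unbiased"
  un2 <- rp; un2$bias_class[un2$bias_class != "filtered"] <- "unbiased"
  s0 <- reciprocal_summary(un, un2, d)
  expect_equal(s0$counts$maternal, c(0, 0))
  expect_equal(nrow(s0$scatter), 0)

  # a gene absent from one cross is dropped from the scatter, kept in counts
  drop1 <- rm_$gene_id[rm_$bias_class == "maternal_biased"][1]
  s1 <- reciprocal_summary(rm_[rm_$gene_id != drop1, ], rp, d)
  expect_false(drop1 %in% s1$scatter$gene_id)
  expect_equal(s1$counts$maternal[1],
               sum(rm_$bias_class == "maternal_biased") - 1)
})

test_that("imprinting caller separates PEGs from cis bias", {
  d <- tiny_design()
  p <- sim_params(n_genes = 500, seed = 37, snp_depth_mean = 50,
                  n_pegs = 20, n_cis = 20, imprint_fraction = 0.9,
                  n_maternal_bias = 0, n_paternal_bias = 0, n_gbm = 0,
                  n_poe = 0, n_ploidy = 0, n_hybridity = 0)
  ac <- simulate_allele_counts(d, p)
  rp <- aggregate_gene_ase(ac$records, d, "L2xL4")
  rm_ <- aggregate_gene_ase(ac$records, d, "L4xL2")
  imp <- call_imprinting(rp, rm_, d)
  planted_peg <- imp$gene_id %in% p$pegs
  planted_cis <- imp$gene_id %in% p$cis_genes
  expect_gte(mean(imp$status[planted_peg] == "PEG"), 0.95)
  expect_equal(sum(imp$status[planted_cis] == "PEG"), 0)
  expect_true(all(imp$status[planted_cis] %in% c("cis_biased", "none")))
  expect_equal(unique(imp$favored_allele[imp$status == "cis_biased"]),
               "L4")
  # bias in only one cross -> none
  one_cross <- imp$gene_id[imp$class_a == "maternal_biased" &
                             imp$class_b == "unbiased"]
  expect_true(all(imp$status[imp$gene_id %in% one_cross] == "none"))
})

test_that("SNP p-values are uniform under the null at adequate depth", {
  set.seed(41)
  n_snps <- 4000
  tot <- rpois(n_snps, 60)
  tot <- tot[tot > 0]
  k <- rbinom(length(tot), tot, 2 / 3)
  p <- snp_ase_test(k, tot - k, 2 / 3)
  # discrete exact test: p-values are super-uniform (conservative);
  # check the empirical CDF never exceeds uniform materially
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_p <- ecdf(p)(grid)
  expect_true(all(ecdf_p <= grid + 3 * sqrt(grid * (1 - grid) /
                                              length(p))))
})
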