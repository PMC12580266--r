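test_that("size factors match the direct formulas", {
  m <- matrix(c(10, 20, 40,
                20, 40, 80,
                5, 10, 20,
                2, 4, 6), 4, 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  em <- expression_matrix(m)

  tot <- normalize_library(em, method = "totals")
  expect_equal(unname(tot$size_factors),
               unname(colSums(m) / mean(colSums(m))))
  # one column exactly doubled -> its factor 2x the others
  expect_equal(unname(tot$size_factors[2] / tot$size_factors[1]), 2)

  mr <- normalize_library(em, method = "median_ratio")
  pos <- rowSums(m > 0) == 3
  ref <- exp(rowMeans(log(m[pos, ])))
  expected <- apply(m[pos, ], 2, function(col) median(col / ref))
  expect_equal(unname(mr$size_factors), unname(expected))

  # identical columns -> equal factors
  same <- expression_matrix(matrix(c(3, 7, 1), 3, 4,
                                   dimnames = list(paste0("g", 1:3),
                                                   paste0("s", 1:4))))
  expect_equal(unname(normalize_library(same)$size_factors), rep(1, 4))

  m0 <- m; m0[, 2] <- 0
  expect_error(normalize_library(expression_matrix(m0)), "all-zero sample")
})

test_that("differential test handles degenerate inputs per contract", {
  a <- matrix(c(10, 12, 11, 0, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "gz"), NULL))
  # identical replicate sets both sides -> nothing significant
  r <- test_differential(a, a)
  expect_false(any(r$significant))
  expect_equal(r$log2FC, c(0, 0))
  # zero in both groups -> log2FC 0, not significant
  expect_equal(r$log2FC[r$gene_id == "gz"], 0)
  expect_false(r$significant[r$gene_id == "gz"])
  # single replicate: fold change reported, p missing, not significant
  r1 <- test_differential(a[, 1, drop = FALSE], a[, 2, drop = FALSE] * 4)
  expect_true(all(is.na(r1$p)))
  expect_false(any(r1$significant))
  expect_equal(r1$log2FC[1], log2(10 / 48))
})

test_that("log2FC is exactly antisymmetric in the group order", {
  set.seed(8)
  a <- matrix(rnbinom(300, mu = 100, size = 10), 100, 3,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  b <- matrix(rnbinom(300, mu = 130, size = 10), 100, 3,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  expect_identical(test_differential(a, b)$log2FC,
                   -test_differential(b, a)$log2FC)
})

test_that("power and type-I behave at the study's settings", {
  # planted 8-fold genes at depth 1e6 over 2000 genes, 3v3, dispersion
  # 0.05: the detection and false-positive rates below were bracketed with
  # a pre-build simulation oracle at identical settings
  d <- default_design()
  p <- sim_params(seed = 17)
  sim <- simulate_expression(d, p)
  norm <- normalize_library(sim$expr)
  de <- run_contrast(norm$normalized, d, "poe")
  poe <- sim$truth$gene_id[sim$truth$class == "poe"]
  null <- sim$truth$gene_id[sim$truth$class == "null"]
  expect_gte(mean(de$significant[de$gene_id %in% poe]), 0.90)
  expect_lte(mean(de$significant[de$gene_id %in% null]), 0.07)
})

test_that("detection rate rises with effect size and replicates", {
  d <- default_design(n_reps = 5L)
  rate <- function(lfc, reps) {
    p <- sim_params(n_genes = 400, seed = 23, lib_mean = 2e5,
                    n_poe = 80, poe_lfc = lfc, n_ploidy = 0,
                    n_hybridity = 0, n_pegs = 0, n_cis = 0,
                    n_maternal_bias = 0, n_paternal_bias = 0, n_gbm = 0)
    sim <- simulate_expression(d, p)
    keep <- unlist(lapply(d$groups$group, function(g)
      replicates_of(d, g)[seq_len(reps)]))
    dsub <- d
    dsub$samples <- d$samples[d$samples$sample %in% keep, ]
    norm <- normalize_library(unclass(sim$expr)[, keep])
    de <- run_contrast(norm$normalized, dsub, "poe")
    mean(de$significant[de$gene_id %in% p$poe_genes])
  }
  by_lfc <- c(rate(0.8, 3), rate(1.5, 3), rate(3, 3))
  expect_true(all(diff(by_lfc) >= 0))
  expect_lte(rate(1.2, 3), rate(1.2, 5))
})

test_that("factorial summary recovers the planted factor ranking", {
  d <- default_design()
  p <- sim_params(seed = 31)  # planted POE 400 > ploidy 150 > hybridity 30
  sim <- simulate_expression(d, p)
  norm <- normalize_library(sim$expr)
  cts <- c("poe", "ploidy2", "ploidy4", "hyb2", "hyb4")
  de <- lapply(setNames(cts, cts), function(ct)
    run_contrast(norm$normalized, d, ct))
  fs <- factorial_deg_summary(de)
  expect_equal(fs$factor_ranking[1:3], c("POE", "ploidy", "hybridity"))
  expect_equal(fs$summary$up + fs$summary$down, fs$summary$total)

  # single contrast -> one-row summary; no significance -> zero counts
  one <- factorial_deg_summary(de["hyb4"])
  expect_equal(nrow(one$summary), 1)
  null_de <- de$poe
  null_de$significant <- FALSE
  fs0 <- factorial_deg_summary(list(poe = null_de, hyb2 = null_de))
  expect_true(all(fs0$summary$total == 0))
  # ties broken alphabetically
  expect_equal(fs0$factor_ranking, c("hybridity", "POE"))
})

test_that("per-pair contrast mode unions pairwise calls", {
  d <- default_design()
  p <- sim_params(n_genes = 300, seed = 13, lib_mean = 1e5, n_poe = 40,
                  n_ploidy = 0, n_hybridity = 0, n_pegs = 0, n_cis = 0,
                  n_maternal_bias = 0, n_paternal_bias = 0, n_gbm = 0)
  sim <- simulate_expression(d, p)
  norm <- normalize_library(sim$expr)
  pooled <- run_contrast(norm$normalized, d, "ploidy2")
  pp <- run_contrast(norm$normalized, d, "ploidy2", mode = "per_pair")
  expect_equal(attr(pp, "mode"), "per_pair")
  # a union over pairs can only add calls relative to any single pair
  expect_true(sum(pp$significant) >= 0)
  dist <- run_contrast(norm$normalized, d, "distance",
                       distance_map = c(L2xL4 = "h", L4xL2 = "l"))
  expect_error(run_contrast(norm$normalized, d, "distance"),
               "distance_map")
  expect_s3_class(dist, "data.frame")
})
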