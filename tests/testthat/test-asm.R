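test_that("site levels apply the 5-read coverage floor", {
  expect_equal(site_level(5L, 10L), 0.5)
  expect_true(is.na(site_level(2L, 4L)))   # below the floor
  expect_equal(site_level(0L, 8L), 0)
  expect_equal(site_level(5L, 5L), 1)
  expect_error(site_level(6L, 5L), "exceeds")
})

test_that("region partition is strand-aware, contiguous, non-overlapping", {
  anno <- data.frame(gene_id = c("plus", "minus"),
                     chrom = "chr1", strand = c("+", "-"),
                     tss = c(5000L, 9000L), tts = c(7999L, 6001L))
  regs <- gene_regions(anno, flank = 2000L)
  expect_true(all(regs$start <= regs$end))
  for (g in anno$gene_id) {
    r <- regs[regs$gene_id == g, ]
    covered <- sort(unlist(mapply(seq, r$start, r$end)))
    expect_equal(covered, seq(min(r$start), max(r$end)))  # no gap/overlap
    expect_equal(sum(r$end - r$start + 1L),
                 2L * 2000L + abs(anno$tts[anno$gene_id == g] -
                                    anno$tss[anno$gene_id == g]) + 1L)
  }
  # upstream of the minus-strand gene lies at higher coordinates
  up <- regs[regs$gene_id == "minus" & regs$region == "upstream", ]
  expect_equal(c(up$start, up$end), c(9001L, 11000L))
})

test_that("region means pool replicates and enforce the site floor", {
  anno <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                     tss = 5000L, tts = 7999L)
  reg <- gene_regions(anno)[2, ]  # body
  calls <- rbind(
    meth_calls_at(c(5100, 5200, 5300), meth = c(2, 4, 6),
                  total = 10, sample = "s1"),
    meth_calls_at(c(5100, 5200, 5300), meth = c(0, 0, 0),
                  total = 0, sample = "s2"))
  rm1 <- region_mean(calls, reg, "CG", "L2")
  expect_equal(rm1$mean, mean(c(0.2, 0.4, 0.6)))
  expect_equal(rm1$n_sites, 3L)
  # with only 2 qualifying sites, min_sites = 3 -> missing
  rm2 <- region_mean(calls[calls$pos != 5300, ], reg, "CG", "L2")
  expect_true(is.na(rm2$mean))

  # replicate pooling: 2+2 of 4+4 reads passes the 5-read floor jointly
  calls2 <- rbind(
    meth_calls_at(c(5100, 5200, 5300), meth = 2, total = 4,
                  sample = "s1"),
    meth_calls_at(c(5100, 5200, 5300), meth = 2, total = 4,
                  sample = "s2"))
  expect_equal(region_mean(calls2, reg, "CG", "L2")$mean, 0.5)
})

test_that("sampled region means concentrate around the planted level", {
  set.seed(13)
  anno <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                     tss = 5000L, tts = 7999L)
  reg <- gene_regions(anno)[2, ]
  pos <- seq(5010, 7990, length.out = 50)
  tot <- rpois(50, 20)
  calls <- meth_calls_at(pos, meth = rbinom(50, tot, 0.8), total = tot)
  rm_ <- region_mean(calls, reg, "CG", "L2")
  expect_lt(abs(rm_$mean - 0.8), 0.03)
})

test_that("ASM difference is symmetric under allele swap and bounded", {
  means <- data.frame(
    gene_id = rep(c("g1", "g2", "g3"), each = 2),
    region = "body", context = "CG",
    allele = rep(c("L2", "L4"), 3),
    mean_level = c(0.8, 0.1, 0.5, 0.5, NA, 0.4),
    n_sites = 5L)
  d1 <- asm_difference(means)
  expect_equal(d1$asm_diff[d1$gene_id == "g1"], 0.7)
  expect_equal(d1$asm_diff[d1$gene_id == "g2"], 0)
  expect_true(is.na(d1$asm_diff[d1$gene_id == "g3"]))
  swapped <- means
  swapped$allele <- rep(c("L4", "L2"), 3)
  expect_equal(asm_difference(swapped)$asm_diff, d1$asm_diff)
  expect_true(all(d1$asm_diff >= 0 & d1$asm_diff <= 1, na.rm = TRUE))
})

test_that("reciprocal ASM comparison detects shifts and reports tiers", {
  mk <- function(vals) data.frame(gene_id = seq_along(vals),
                                  region = "body", context = "CG",
                                  allele_1 = "L2", mean_1 = 0,
                                  allele_2 = "L4", mean_2 = 0,
                                  asm_diff = vals, n_sites_1 = 5,
                                  n_sites_2 = 5)
  same <- mk(seq(0.1, 0.5, length.out = 30))
  w0 <- compare_reciprocal_asm(same, same, "body", "CG")
  expect_gt(w0$p, 0.1)
  expect_equal(w0$annotation, "ns")

  set.seed(5)
  a <- mk(pmin(pmax(rnorm(100, 0.3, 0.1), 0), 1))
  b <- mk(pmin(pmax(rnorm(100, 0.5, 0.1), 0), 1))
  w1 <- compare_reciprocal_asm(a, b, "body", "CG")
  expect_lt(w1$p, 0.001)
  expect_equal(w1$annotation, "***")

  expect_error(compare_reciprocal_asm(a[0, ], a, "body", "CG"),
               "no ASM values")
  # paired mode runs on matching gene ids
  wp <- compare_reciprocal_asm(a, b, "body", "CG", paired = TRUE)
  expect_lt(wp$p, 0.001)
})

test_that("metagene profile localizes signal and respects orientation", {
  set.seed(21)
  n <- 40
  anno <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
                     strand = rep(c("+", "-"), n / 2),
                     tss = NA_integer_, tts = NA_integer_)
  off <- (seq_len(n) - 1L) * 10000L + 5000L
  anno$tss <- ifelse(anno$strand == "+", off, off + 2999L)
  anno$tts <- ifelse(anno$strand == "+", off + 2999L, off)
  calls <- do.call(rbind, lapply(seq_len(n), function(i) {
    body_pos <- seq(off[i], off[i] + 2999L, by = 60)
    flank_pos <- c(seq(off[i] - 2000L, off[i] - 20L, by = 90),
                   seq(off[i] + 3010L, off[i] + 4990L, by = 90))
    lev <- c(rep(0.8, length(body_pos)), rep(0.05, length(flank_pos)))
    pos <- c(body_pos, flank_pos)
    tot <- rep(50L, length(pos))
    meth_calls_at(pos, meth = rbinom(length(pos), tot, lev), total = tot)
  }))
  prof <- metagene_profile(calls, anno, "CG", "L2",
                           body_bins = 20, flank_bins = 10)
  seg <- attr(prof, "segment")
  expect_equal(length(prof), 40)
  expect_true(all(prof[seg == "body"] > 0.6))
  expect_true(all(prof[seg != "body"] < 0.2, na.rm = TRUE))

  # minus-strand gene with upstream-only signal: lands in upstream bins
  a1 <- anno[2, ]  # a minus-strand gene
  stopifnot(a1$strand == "-")
  up_pos <- seq(a1$tss + 10L, a1$tss + 1990L, by = 40)
  calls2 <- meth_calls_at(up_pos, meth = 45, total = 50)
  p2 <- metagene_profile(calls2, a1, "CG", "L2",
                         body_bins = 20, flank_bins = 10)
  seg2 <- attr(p2, "segment")
  expect_true(all(is.na(p2[seg2 != "upstream"])))
  expect_true(all(p2[seg2 == "upstream"] > 0.8))
})

test_that("flat methylomes give flat profiles", {
  set.seed(33)
  n <- 30
  anno <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
                     strand = sample(c("+", "-"), n, TRUE),
                     tss = NA_integer_, tts = NA_integer_)
  off <- (seq_len(n) - 1L) * 10000L + 5000L
  anno$tss <- ifelse(anno$strand == "+", off, off + 2999L)
  anno$tts <- ifelse(anno$strand == "+", off + 2999L, off)
  calls <- do.call(rbind, lapply(seq_len(n), function(i) {
    pos <- seq(off[i] - 2000L, off[i] + 4990L, by = 35)
    tot <- rep(40L, length(pos))
    meth_calls_at(pos, meth = rbinom(length(pos), tot, 0.5), total = tot)
  }))
  prof <- metagene_profile(calls, anno, "CG", "L2",
                           body_bins = 20, flank_bins = 10)
  # every bin near the flat truth: the loosest bin averages one ~Bin(40)
  # site per gene over 30 genes (SE ~ 0.0144), so 0.06 is > 4 SDs
  expect_true(all(abs(prof - 0.5) < 0.06))
})

test_that("gbM-expression association recovers planted coupling", {
  d <- tiny_design()
  set.seed(3)
  n <- 200
  genes <- sprintf("g%03d", 1:n)
  bias <- runif(n, 0, 0.3)                 # paternal expression uplift
  meth_off <- bias + rnorm(n, 0, 0.03)     # methylation tracks expression
  means <- data.frame(gene_id = rep(genes, each = 2), region = "body",
                      context = "CG",
                      allele = rep(c("L2", "L4"), n),
                      mean_level = as.vector(rbind(0.3, 0.3 + meth_off)),
                      n_sites = 5L)
  ase <- data.frame(gene_id = genes, group = "L2xL4", n_snps = 2L,
                    maternal_reads = 100L, paternal_reads = 100L,
                    maternal_fraction = 1 / 3 - bias / 2,
                    f_null_maternal = 1 / 3, min_fdr = 0.01,
                    bias_class = "paternal_biased")
  g <- gbm_expression_association(means, ase, d)
  expect_gt(g$rho, 0.5)
  expect_lt(g$p, 0.01)
  expect_equal(g$n, n)

  # constant methylation difference -> undefined correlation
  means$mean_level <- rep(c(0.3, 0.5), n)
  g0 <- gbm_expression_association(means, ase, d)
  expect_true(is.na(g0$rho))
  expect_error(gbm_expression_association(means[1:4, ], ase[1:2, ], d),
               "fewer than 3")
})
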