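test_that("fold enrichment reproduces the published 40-fold figure", {
  fold <- fold_enrichment(2, 1610, 1, 32647)
  expect_equal(fold, (2 / 1610) / (1 / 32647))
  expect_equal(round(fold, -1), 40)
  expect_equal(fold_enrichment(5, 100, 5, 100), 1.0)
  # scale invariance in both cohort sizes
  expect_equal(fold_enrichment(4, 3220, 2, 65294), fold)
  expect_identical(fold_enrichment(1, 10, 0, 10), Inf)
})

test_that("Hardy-Weinberg homozygote frequency is the squared MAF", {
  expect_equal(hwe_homozygote_frequency(0.01), 1e-4)
  expect_equal(hwe_homozygote_frequency(0), 0)
  expect_equal(hwe_homozygote_frequency(1), 1)
})

test_that("tolerability verdicts compare homozygote frequency to prevalence", {
  res <- tolerability_assessment(29, 104220)
  expect_equal(res$hom_frequency, 29 / 104220)
  expect_equal(round(100 * res$hom_frequency, 3), 0.028)
  expect_equal(res$verdict, "cannot_exclude")

  high <- tolerability_assessment(9160, 100000)
  expect_equal(high$verdict, "unlikely_penetrant")
  expect_equal(tolerability_assessment(0, 1000)$verdict,
               "cannot_exclude")
  # equality resolves to cannot_exclude
  expect_equal(tolerability_assessment(41, 100000,
                                       prevalence = 41e-5)$verdict,
               "cannot_exclude")
})

test_that("identical-variant matching requires position, alleles and genotype", {
  cand <- rbind(
    variant_record("14", 76644266, "C", "T", gene = "GPATCH2L",
                   effect_class = "stopgain",
                   transcript_id = "NM_017972"))
  rep_v <- rbind(
    cand,
    variant_record("14", 76644266, "C", "G", gene = "GPATCH2L",
                   effect_class = "stopgain",
                   transcript_id = "NM_017972"))
  g <- matrix(c(2L, 0L, 1L,
                0L, 2L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(variant_key(rep_v), NULL))
  rep_gt <- cohort_genotypes(c("p1", "p2", "p3"),
                             c("case", "control", "case"), g)
  m <- match_identical_variant(cand, rep_v, rep_gt)
  # homozygote matches; same position different alt does not;
  # a lone heterozygote is not a recessive genotype
  expect_equal(nrow(m), 1L)
  expect_equal(m$sample_id, "p1")
  expect_equal(m$mode, "homozygous")

  # trans-annotated het pair on one transcript matches as compound het
  rep_v2 <- rbind(
    variant_record("8", 124195352, "G", "T", gene = "FAM83A",
                   effect_class = "stopgain",
                   transcript_id = "NM_032899"),
    variant_record("8", 124200000, "C", "T", gene = "FAM83A",
                   effect_class = "stopgain",
                   transcript_id = "NM_032899"))
  keys2 <- variant_key(rep_v2)
  g2 <- matrix(c(1L, 1L), ncol = 1,
               dimnames = list(keys2, NULL))
  ph <- data.frame(sample_id = "q1", key_a = keys2[1],
                   key_b = keys2[2], phase = "trans")
  gt2 <- cohort_genotypes("q1", "case", g2, ph)
  m2 <- match_identical_variant(rep_v2[1, ], rep_v2, gt2)
  expect_equal(m2$mode, "compound_het")

  # declared build mismatch is a hard error
  a <- cand
  attr(a, "build") <- "hg19"
  b <- rep_v
  attr(b, "build") <- "hg38"
  expect_error(match_identical_variant(a, b, rep_gt), "build")
})

test_that("shared-heterozygote scan needs 2+ index cases and no controls", {
  v <- rbind(
    variant_record("7", 80302000, "G", "T", gene = "CD36",
                   effect_class = "missense",
                   transcript_id = "NM_001127444", cadd = 23.3),
    variant_record("7", 80303000, "C", "T", gene = "CD36",
                   effect_class = "missense",
                   transcript_id = "NM_001127444", cadd = 22),
    variant_record("7", 80304000, "A", "G", gene = "CD36",
                   effect_class = "missense",
                   transcript_id = "NM_001127444", cadd = 22),
    variant_record("7", 80305000, "A", "C", gene = "CD36",
                   effect_class = "missense",
                   transcript_id = "NM_001127444", cadd = 22,
                   maf_exac_nfe = 0.01))
  #        3 idx cases   1 idx case    case+control   too common
  g <- rbind(c(1, 1, 1, 0, 0),
             c(1, 0, 0, 0, 0),
             c(1, 1, 0, 0, 1),
             c(1, 1, 0, 1, 0))
  rownames(g) <- variant_key(v)
  gt <- cohort_genotypes(paste0("i", 1:5),
                         c(rep("case", 4), "control"), g)
  hits <- shared_het_scan(v, gt)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$key, variant_key(v[1, ]))
  expect_equal(hits$n_index_cases, 3L)
})

test_that("GWAS windows apply the 1-Mb and p-value rules", {
  genes <- data.frame(gene = "VPS13C", chrom = "15",
                      start = 62144000, end = 62340000)
  ss <- data.frame(
    snp = c("rs2414739", "rs_weak", "rs_far"),
    chrom = "15",
    pos = c(62490000, 62500000, 63700000),
    p = c(3.59e-12, 2e-4, 1e-8))
  hits <- gwas_window(genes, ss)
  expect_equal(hits$snp, "rs2414739")   # weak p and 1.2-Mb SNP excluded
  expect_equal(hits$peak, 1L)

  # two significant SNPs 400 kb apart form two peaks
  ss2 <- data.frame(snp = c("a", "b"), chrom = "15",
                    pos = c(62400000, 62800000), p = c(1e-6, 1e-6))
  expect_equal(gwas_window(genes, ss2)$peak, c(1L, 2L))
})

test_that("pairwise relatedness matches its definition and null behaviour", {
  # centred genotypes: x = 2p at every SNP gives exactly zero
  p <- c(0.5, 0.25, 0.4)
  expect_equal(grm_pair(2 * p, 2 * p, p), 0)
  # single-SNP hand evaluation
  expect_equal(grm_pair(2, 2, 0.5), (2 - 1)^2 / (2 * 0.25))
  # brute-force sum on a 10-SNP instance
  set.seed(23)
  p10 <- runif(10, 0.05, 0.5)
  xj <- rbinom(10, 2, p10)
  xk <- rbinom(10, 2, p10)
  manual <- mean((xj - 2 * p10) * (xk - 2 * p10) /
                   (2 * p10 * (1 - p10)))
  expect_equal(grm_pair(xj, xk, p10), manual)
  # unrelated pair at many SNPs: near zero
  set.seed(24)
  pm <- runif(5000, 0.05, 0.5)
  a <- rbinom(5000, 2, pm)
  b <- rbinom(5000, 2, pm)
  expect_lt(abs(grm_pair(a, b, pm)), 0.05)
  # the MAF floor excludes rare SNPs
  expect_true(is.na(grm_pair(c(1, 1), c(1, 1), c(0.001, 0.005))))
})

test_that("prioritization reproduces the published gene sets and counts", {
  fx <- discovery_table_fixture(decoys = FALSE)
  pr <- prioritize(fx$evidence)
  expect_identical(pr$prioritized,
                   c("ARSB", "GPATCH2L", "PTPRH", "UHRF1BP1L",
                     "VPS13C"))
  expect_length(pr$genetic, 7L)
  expect_true(all(c("CD36", "FAM83A") %in% pr$genetic))
  expect_equal(unname(pr$counts["mito_any"]), 15L)
  expect_equal(unname(pr$counts["Mm"]), 13L)
  expect_equal(unname(pr$counts["Mp"]), 6L)
  expect_equal(unname(pr$counts["S"]), 4L)

  none <- evidence_table(c("X", "Y"), c(NA, NA), c(NA, NA))
  pr0 <- prioritize(none)
  expect_length(pr0$functional, 0L)
  expect_length(pr0$genetic, 0L)
  expect_length(pr0$prioritized, 0L)

  # monotone in evidence: switching on a flag never shrinks the set
  ev2 <- fx$evidence
  ev2$GWAS[ev2$gene == "TMEM134"] <- TRUE
  pr2 <- prioritize(ev2)
  expect_true(all(pr$prioritized %in% pr2$prioritized))
  expect_true("TMEM134" %in% pr2$prioritized)
})
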