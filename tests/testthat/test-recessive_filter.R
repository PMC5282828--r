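test_that("public rarity filter handles present, common and absent sources", {
  cfg <- filter_config()
  near <- variant_record("10", 27688101, "G", "A", gene = "PTCHD3",
                         rsid = "rs142646098",
                         effect_class = "stopgain",
                         maf_exac_nfe = 0.0097)
  expect_true(rare_by_public_maf(near, cfg)$pass)

  common <- variant_record("1", 10, "A", "T",
                           effect_class = "stopgain",
                           maf_exac_nfe = 0.015)
  res <- rare_by_public_maf(common, cfg)
  expect_false(res$pass)
  expect_equal(res$provenance, "maf_exac_nfe")

  # one source rare, another common: every available source must pass
  split <- variant_record("1", 10, "A", "T",
                          effect_class = "stopgain",
                          maf_kg_eur = 0.002, maf_exac_nfe = 0.02)
  expect_false(rare_by_public_maf(split, cfg)$pass)

  novel <- variant_record("12", 100433523, "T", "A",
                          gene = "UHRF1BP1L",
                          effect_class = "stopgain")
  res <- rare_by_public_maf(novel, cfg)
  expect_true(res$pass)
  expect_true(res$novel)
  expect_equal(res$provenance, "novel")
})

test_that("homozygous rules: case carriers, control comparison, exception", {
  fx <- discovery_table_fixture(decoys = TRUE)
  v <- attach_lof_calls(fx$variants)

  cands <- suppressWarnings(
    homozygous_candidates(v, fx$genotypes))
  genes <- vapply(cands, `[[`, character(1), "gene")
  expect_true("GPATCH2L" %in% genes)
  expect_equal(length(cands[[which(genes == "ARSB")]]$carriers), 4L)

  # the splice gene fails internal-control rules but is database-absent
  expect_warning(homozygous_candidates(v, fx$genotypes),
                 "exception")
  arsb <- cands[[which(genes == "ARSB")]]
  expect_true("exception" %in% arsb$filter_trail$status)

  # control-only homozygote and control-common decoys never qualify
  expect_false("DECOY_CTRLONLY" %in% genes)
  expect_false("DECOY_CTRLHOM" %in% genes)
  expect_false("DECOY_COMMON" %in% genes)
  expect_false("DECOY_NONLOF" %in% genes)
})

test_that("compound-het rules: anchor, partner, transcript and phase", {
  fx <- discovery_table_fixture(decoys = TRUE)
  v <- attach_lof_calls(fx$variants)
  cands <- compound_het_candidates(v, fx$genotypes)
  genes <- vapply(cands, `[[`, character(1), "gene")

  # two LoF alleles (stopgain + immediate-stop frameshift)
  expect_true("VPS13C" %in% genes)
  # LoF anchor + deleterious dbSNP-absent missense partner
  expect_true("CD36" %in% genes)
  # under-threshold missense partner and split transcripts never pair
  expect_false("DECOY_LOWCADD" %in% genes)
  expect_false("DECOY_DIFFTX" %in% genes)

  # near pair (154 bp apart) with declared trans phase is confirmed
  fam <- cands[[which(genes == "FAM83A")]]
  expect_equal(fam$status, "confirmed")

  # the same near pair with phase removed needs review
  gt2 <- fx$genotypes
  gt2$phase <- NULL
  cands2 <- compound_het_candidates(v, gt2)
  genes2 <- vapply(cands2, `[[`, character(1), "gene")
  status2 <- vapply(cands2, `[[`, character(1), "status")
  expect_equal(status2[genes2 == "FAM83A"], "needs_review")
  # distant pairs with unknown phase stay putative
  expect_equal(status2[genes2 == "VPS13C"], "putative")

  # a cis-phased pair is not a candidate
  gt3 <- fx$genotypes
  gt3$phase$phase[gt3$phase$sample_id %in% fam$carriers &
                    grepl("^8:", gt3$phase$key_a)] <- "cis"
  cands3 <- compound_het_candidates(v, gt3)
  expect_false("FAM83A" %in%
                 vapply(cands3, `[[`, character(1), "gene"))

  # two rare deleterious missense hets without a LoF anchor: no pair
  vv <- rbind(
    variant_record("5", 100, "A", "T", gene = "NOLOF",
                   effect_class = "missense", transcript_id = "TXN",
                   cadd = 25),
    variant_record("5", 900, "G", "C", gene = "NOLOF",
                   effect_class = "missense", transcript_id = "TXN",
                   cadd = 25))
  vv <- attach_lof_calls(vv)
  g <- matrix(c(1L, 0L, 1L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(variant_key(vv), NULL))
  gt <- cohort_genotypes(c("c1", "c2"), c("case", "control"), g)
  expect_length(compound_het_candidates(vv, gt), 0L)
})

test_that("cascade is monotone in thresholds and stage counts decrease", {
  fx <- discovery_table_fixture(decoys = TRUE)
  base <- suppressWarnings(run_cascade(fx$variants, fx$genotypes))
  expect_true(all(diff(base$counts[c("input", "qc_pass", "lof",
                                     "lof_rare")]) <= 0))

  tight_maf <- suppressWarnings(run_cascade(
    fx$variants, fx$genotypes, filter_config(maf_threshold = 0.004)))
  expect_true(all(unique(tight_maf$summary$gene) %in%
                    unique(base$summary$gene)))
  expect_lte(nrow(tight_maf$summary), nrow(base$summary))

  tight_cadd <- suppressWarnings(run_cascade(
    fx$variants, fx$genotypes, filter_config(cadd_threshold = 26)))
  expect_true(all(unique(tight_cadd$summary$gene) %in%
                    unique(base$summary$gene)))
  # the CADD screen applies to missense partners only
  expect_false("CD36" %in% tight_cadd$summary$gene)
  expect_true("VPS13C" %in% tight_cadd$summary$gene)
})

test_that("cascade on an empty cohort yields nothing", {
  v <- tiny_variants()[0, ]
  g <- matrix(integer(0), nrow = 0, ncol = 2)
  gt <- cohort_genotypes(c("a", "b"), c("case", "control"), g)
  res <- run_cascade(v, gt)
  expect_length(res$candidates, 0L)
  expect_true(all(res$counts == 0))
})

test_that("planted recessive genes are recovered exactly on synthetic cohorts", {
  spec <- cohort_spec(n_cases = 150, n_controls = 80,
                      n_background_genes = 60, planted_hom = 3,
                      planted_comphet = 2, decoys = TRUE)
  sim <- generate_cohort(spec, seed = 7)
  res <- run_cascade(sim$variants, sim$genotypes)
  found <- sort(unique(res$summary$gene))
  planted <- sort(sim$truth$gene[sim$truth$expected_candidate])
  expect_identical(found, planted)

  modes <- res$summary$mode[match(planted, res$summary$gene)]
  expect_identical(modes, ifelse(grepl("^PLH", planted),
                                 "homozygous", "compound_het"))
  # every decoy is rejected
  decoys <- sim$truth$gene[grepl("^decoy", sim$truth$category)]
  expect_false(any(decoys %in% found))
})
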