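test_that("cell QC filters and per-well medians match a sort oracle", {
  set.seed(2)
  n <- 100
  cells <- data.frame(
    mito_count = rpois(n, 30),
    roundness = runif(n),
    axial_length_ratio = runif(n, 1, 3),
    cmxros_intensity = rnorm(n, 500, 50),
    interphase = TRUE, in_focus = TRUE, well_segmented = TRUE,
    border = rep(c(TRUE, FALSE), c(9, 91)))
  well <- qc_and_summarize(cells)
  expect_equal(well$n_cells, 91L)
  expect_true(well$valid)
  kept <- cells[!cells$border, ]
  # odd count: the median is the middle order statistic
  expect_equal(well$roundness, sort(kept$roundness)[46])
  expect_equal(well$mito_count, sort(kept$mito_count)[46])

  # all cells excluded -> invalid well
  cells$interphase <- FALSE
  empty <- qc_and_summarize(cells)
  expect_equal(empty$n_cells, 0L)
  expect_false(empty$valid)
  expect_true(is.na(empty$roundness))

  # a low-cell well falls below the validity floor
  few <- qc_and_summarize(cells[1:30, ] |>
                            transform(interphase = TRUE),
                          min_cells = 50)
  expect_false(few$valid)
})

test_that("translocation ratio uses the strict more-than-two-spots rule", {
  cells <- data.frame(spot_count = rep(c(5, 0), each = 50))
  expect_equal(translocation_ratio(cells)$ratio, 1.0)

  cells <- data.frame(spot_count = c(rep(4, 30), rep(1, 10)))
  expect_equal(translocation_ratio(cells)$ratio, 3.0)

  # exactly two spots is negative
  res <- translocation_ratio(data.frame(spot_count = c(2, 2, 3)))
  expect_equal(res$n_positive, 1L)
  expect_equal(res$n_negative, 2L)

  # zero negatives: continuity offset, flagged
  res <- translocation_ratio(data.frame(spot_count = c(3, 4, 5)))
  expect_true(res$continuity_corrected)
  expect_equal(res$ratio, 3.5 / 0.5)
})

test_that("plate normalization centres negative controls and removes offsets", {
  wells <- data.frame(
    plate = 1, well = c("A1", "A2", "B1"),
    role = c("neg_control", "neg_control", "sample"),
    value = c(180, 220, 100))
  norm <- normalize_plate(wells)
  expect_equal(norm$normalized[3], 0.5)
  expect_equal(stats::median(norm$normalized[1:2]), 1)

  flat <- data.frame(plate = 1, well = c("A1", "B1"),
                     role = c("neg_control", "sample"),
                     value = c(7, 7))
  expect_true(all(normalize_plate(flat)$normalized == 1))

  # a global 2x offset between plates cancels after normalization
  p1 <- data.frame(plate = 1, well = c("A1", "A2", "B1", "B2"),
                   role = c("neg_control", "neg_control",
                            "sample", "sample"),
                   value = c(100, 110, 55, 75))
  p2 <- p1
  p2$plate <- 2
  p2$value <- p1$value * 2
  norm <- normalize_plate(rbind(p1, p2))
  expect_equal(norm$normalized[norm$plate == 1 & norm$role == "sample"],
               norm$normalized[norm$plate == 2 & norm$role == "sample"])

  no_neg <- data.frame(plate = 1, well = "B1", role = "sample",
                       value = 1)
  expect_error(normalize_plate(no_neg), "negative-control")
})

test_that("robust SSMD follows its formula, sign and invariances", {
  expect_equal(robust_ssmd(c(1, 2, 3), c(1, 2, 3)), 0)

  # direct formula evaluation with non-degenerate spread
  tr <- c(10, 10.5, 9.5, 10.5, 9.5, 10)
  ct <- c(0, 0.5, -0.5, 0.5, -0.5, 0)
  want <- (10 - 0) / (1.4826 * sqrt(0.5^2 + 0.5^2))
  expect_equal(robust_ssmd(tr, ct), want)
  # antisymmetry under group swap
  expect_equal(robust_ssmd(ct, tr), -want)
  # invariance under common affine rescaling
  expect_equal(robust_ssmd(3 * tr + 7, 3 * ct + 7), want)

  # zero MADs on both sides: 0 or signed infinity
  tr0 <- c(10, 10, 10, 11, 9, 10)   # raw MAD 0
  ct0 <- c(0, 0, 0, 1, -1, 0)
  expect_identical(robust_ssmd(tr0, ct0), Inf)
  expect_identical(robust_ssmd(ct0, tr0), -Inf)
  expect_identical(robust_ssmd(rep(5, 3), rep(5, 3)), 0)
})

test_that("robust Z' follows its formula and degrades with spread", {
  expect_equal(robust_zprime(c(10, 10, 10), c(0, 0, 0)), 1)

  pos <- c(10, 10.5, 9.5, 10.5, 9.5)   # median 10, raw MAD 0.5
  neg <- c(0, 0.5, -0.5, 0.5, -0.5)
  expect_equal(robust_zprime(pos, neg),
               1 - 3 * 1.4826 * (0.5 + 0.5) / 10)

  wider <- c(0, 1.2, -1.2, 1.2, -1.2)  # raw MAD 1.2
  expect_lt(robust_zprime(pos, wider), robust_zprime(pos, neg))
  expect_true(is.na(robust_zprime(c(1, 2, 3), c(1, 2, 3))))
})

test_that("Mann-Whitney p-values match exact enumeration at small n", {
  set.seed(8)
  for (i in 1:6) {
    x <- rnorm(sample(4:6, 1))
    y <- rnorm(sample(4:6, 1), mean = i / 4)
    expect_equal(mann_whitney_p(x, y), oracle_mw_p(x, y),
                 tolerance = 1e-10,
                 info = paste("case", i))
  }
})

test_that("BH adjustment agrees with the step-up definition", {
  set.seed(9)
  for (i in 1:5) {
    p <- runif(sample(3:12, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
  }
})

test_that("hit calling enforces the strict two-clone rule", {
  clones <- data.frame(
    gene = c("A", "A", "B", "B", "C"),
    clone = paste0("sh", 1:5),
    ssmd = c(5.1, -4.8, 6.0, 3.9, 7.0),
    mw_p = c(1e-4, 2e-4, 1e-4, 1e-4, 1e-4))
  hits <- call_hits(clones)
  expect_true(hits$hit[hits$gene == "A"])    # two clones past cutoff
  expect_false(hits$hit[hits$gene == "B"])   # 3.9 fails the strict > 4
  expect_false(hits$hit[hits$gene == "C"])   # single clone

  # FDR requirement can veto an SSMD-passing clone under rule "both"
  clones$mw_p <- c(1e-4, 0.9, 1e-4, 1e-4, 1e-4)
  expect_false(call_hits(clones)$hit[1])
  expect_true(call_hits(clones, hit_rule = "ssmd_only")$hit[1])

  # identical 7-mer seed across significant clones is flagged
  clones <- data.frame(
    gene = "D", clone = c("sh1", "sh2"),
    ssmd = c(5, 6), mw_p = c(1e-4, 1e-4),
    guide_seq = c("ACGTACGTACGTACGTACGTA",
                  "TCGTACGTATTTTTTTTTTTT"))  # same positions 2-8
  expect_true(call_hits(clones)$seed_confounded)
})

test_that("a null screen yields no hits and a strong screen is recovered", {
  spec0 <- plate_spec(genes = sprintf("G%02d", 1:12),
                      clones_per_gene = 5, replicates = 6)
  sim0 <- generate_plates(spec0, seed = 101)
  res0 <- analyze_screen(sim0$wells)
  expect_false(any(res0$hits$hit))

  spec1 <- plate_spec(genes = sprintf("G%02d", 1:12),
                      effect_sizes = c(G01 = 8, G02 = -8))
  sim1 <- generate_plates(spec1, seed = 102)
  res1 <- analyze_screen(sim1$wells)
  expect_true(res1$hits$hit[res1$hits$gene == "G01"])
  expect_true(res1$hits$hit[res1$hits$gene == "G02"])
  expect_false(any(res1$hits$hit[!res1$hits$gene %in% c("G01", "G02")]))
  # separated controls give a high assay-quality score
  expect_gt(res1$zprime, 0)
})
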