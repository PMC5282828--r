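test_that("stop-affecting effect classes are LoF, others are not", {
  stopgain <- variant_record("14", 76644266, "C", "T",
                             gene = "GPATCH2L",
                             effect_class = "stopgain",
                             aa_change = "p.R362X")
  call <- classify_stop_variant(stopgain)
  expect_true(call$is_lof)
  expect_equal(call$reason, "stopgain")

  stoploss <- variant_record("13", 73333935, "A", "G", gene = "DIS3",
                             effect_class = "stoploss",
                             aa_change = "p.X959Q")
  expect_equal(classify_stop_variant(stoploss)$reason, "stoploss")

  silent <- variant_record("1", 10, "A", "G", effect_class = "other")
  expect_false(classify_stop_variant(silent)$is_lof)
  missense <- variant_record("1", 10, "A", "G",
                             effect_class = "missense")
  expect_false(classify_stop_variant(missense)$is_lof)
})

test_that("frameshift immediate-stop rule matches the worked examples", {
  # insertion of T after offset 3: ATG|T AA... -> codon 2 is TAA
  call <- classify_frameshift("ATGAAAGGG", 3, "", "T")
  expect_true(call$is_lof)
  expect_equal(call$reason, "frameshift_immediate_stop")

  # insertion of G after offset 3: first affected codon GAA, no stop
  expect_false(classify_frameshift("ATGAAAGGGCCC", 3, "", "G")$is_lof)

  # in-frame deletion preserves the reading frame
  expect_false(classify_frameshift("ATGAAAGGGCCC", 3, "AAA", "")$is_lof)

  expect_error(classify_frameshift("ATGAAA", 7, "", "T"), "range")
  expect_error(classify_frameshift("ATGNNN", 1, "", "T"), "non-ACGT")
  expect_error(classify_frameshift("ATGAAA", 1, "T", "A"), "indel")
})

test_that("frameshift rule agrees with a full-translation oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:200) {
    len <- 3 * sample(3:8, 1)
    cds <- paste(sample(bases, len, replace = TRUE), collapse = "")
    off <- sample(0:(len - 2), 1)
    if (runif(1) < 0.5) {
      ref <- ""
      alt <- paste(sample(bases, sample(c(1, 2, 4), 1),
                          replace = TRUE), collapse = "")
    } else {
      del_len <- sample(c(1, 2, 4), 1)
      if (off + del_len > len) next
      ref <- substr(cds, off + 1, off + del_len)
      alt <- ""
    }
    got <- classify_frameshift(cds, off, ref, alt)$is_lof
    want <- oracle_frameshift(cds, off, ref, alt)
    expect_identical(got, want,
                     info = paste(cds, off, ref, alt, sep = "/"))
  }
})

test_that("splice rule requires <= 2 bp intronic and a coding exon", {
  tx <- two_exon_tx()
  # acceptor -2 of the second (coding) exon
  hit <- variant_record("1", 298, "T", "TA", effect_class = "splice",
                        transcript_id = "TXS")
  call <- classify_splice(hit, tx)
  expect_true(call$is_lof)
  expect_equal(call$reason, "splice_2bp_coding")
  # donor +1 of the first exon (which has CDS)
  donor <- variant_record("1", 200, "G", "A", effect_class = "splice",
                          transcript_id = "TXS")
  expect_true(classify_splice(donor, tx)$is_lof)

  far <- variant_record("1", 295, "G", "A", effect_class = "splice",
                        transcript_id = "TXS")
  expect_false(classify_splice(far, tx)$is_lof)
  exonic <- variant_record("1", 350, "G", "A", effect_class = "splice",
                           transcript_id = "TXS")
  expect_false(classify_splice(exonic, tx)$is_lof)

  # UTR-only neighbouring exon does not qualify
  utr_tx <- transcript_model("TXU", exons = list(c(100L, 199L),
                                                 c(300L, 399L)),
                             cds = list(NULL, c(300L, 380L)))
  near_utr <- variant_record("1", 201, "G", "A",
                             effect_class = "splice",
                             transcript_id = "TXU")
  expect_false(classify_splice(near_utr, utr_tx)$is_lof)

  outside <- variant_record("1", 5000, "G", "A",
                            effect_class = "splice",
                            transcript_id = "TXS")
  expect_error(classify_splice(outside, tx), "span")
})

test_that("splice calls are symmetric under strand reflection", {
  tx_fwd <- two_exon_tx("+")
  # reflect coordinates around 500: exon [100,199] -> [301,400] etc.
  reflect <- function(iv) if (is.null(iv)) NULL else
    c(500L - iv[2L], 500L - iv[1L])
  tx_rev <- transcript_model("TXR", strand = "-",
                             exons = rev(lapply(tx_fwd$exons, reflect)),
                             cds = rev(lapply(tx_fwd$cds, reflect)))
  for (pos in c(198L, 200L, 201L, 202L, 203L, 298L, 299L, 305L)) {
    fwd <- variant_record("1", pos, "G", "A", effect_class = "splice",
                          transcript_id = "TXS")
    rev_ <- variant_record("1", 500L - pos, "G", "A",
                           effect_class = "splice",
                           transcript_id = "TXR")
    expect_identical(classify_splice(fwd, tx_fwd)$is_lof,
                     classify_splice(rev_, tx_rev)$is_lof,
                     info = paste("pos", pos))
  }
})

test_that("attach_lof_calls combines rules and annotation evidence", {
  fx <- discovery_table_fixture(decoys = FALSE)
  v <- attach_lof_calls(fx$variants)
  expected_lof <- sum(v$effect_class %in% c("stopgain", "stoploss")) +
    sum(v$effect_class == "frameshift" &
          !is.na(v$immediate_stop) & v$immediate_stop) +
    sum(v$effect_class == "splice" &
          !is.na(v$splice_coding_2bp) & v$splice_coding_2bp)
  expect_equal(sum(v$is_lof), expected_lof)
  expect_equal(sum(v$is_lof), 33L)  # 30 stop-affecting + 2 fs + 1 splice
  # splice row carried by annotation evidence
  expect_true(v$is_lof[v$gene == "ARSB"])
  expect_equal(v$lof_reason[v$gene == "ARSB"], "splice_2bp_coding")
  # missense partners are never LoF
  expect_false(any(v$is_lof[v$effect_class == "missense"]))
})
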