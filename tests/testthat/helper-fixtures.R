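# Shared builders for small in-code fixtures.

# minimal variant table: three annotated variants on two genes
tiny_variants <- function() {
  rbind(
    variant_record("1", 1000, "A", "T", gene = "GENE1",
                   effect_class = "stopgain", transcript_id = "TX1",
                   cadd = 35, maf_exac_nfe = 0.001),
    variant_record("1", 2000, "C", "G", gene = "GENE1",
                   effect_class = "missense", transcript_id = "TX1",
                   cadd = 25),
    variant_record("2", 500, "G", "A", gene = "GENE2", rsid = "rs1",
                   effect_class = "missense", transcript_id = "TX2",
                   cadd = 10, maf_exac_nfe = 0.2)
  )
}

# four-sample cohort (2 cases, 2 controls) over tiny_variants()
tiny_cohort <- function(phase = NULL) {
  geno <- matrix(c(1L, 0L, 0L, 0L,
                   1L, 0L, 0L, 0L,
                   0L, 1L, 2L, 0L),
                 nrow = 3L, byrow = TRUE)
  rownames(geno) <- variant_key(tiny_variants())
  cohort_genotypes(c("s1", "s2", "s3", "s4"),
                   c("case", "case", "control", "control"),
                   geno, phase)
}

# two-exon coding transcript with a UTR-only first exon variant
two_exon_tx <- function(strand = "+") {
  transcript_model("TXS", strand = strand,
                   exons = list(c(100L, 199L), c(300L, 399L)),
                   cds = list(c(150L, 199L), c(300L, 380L)))
}

# brute-force frameshift oracle: apply the edit, translate the whole
# edited sequence with Biostrings, and inspect the codon containing
# the first edited base
oracle_frameshift <- function(cds, off, ref, alt) {
  if (abs(nchar(alt) - nchar(ref)) %% 3 == 0) return(FALSE)
  edited <- paste0(substr(cds, 1, off), alt,
                   substr(cds, off + nchar(ref) + 1, nchar(cds)))
  n_codon <- nchar(edited) %/% 3
  if (n_codon == 0) return(FALSE)
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(edited, 1, 3 * n_codon)),
    no.init.codon = TRUE)))
  idx <- off %/% 3 + 1
  idx <= nchar(aa) && substr(aa, idx, idx) == "*"
}

# exact two-sided Mann-Whitney p by full enumeration of group
# assignments (feasible for n <= 8 per group)
oracle_mw_p <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- u_stat(x, y)
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(ix) {
    u_stat(pooled[ix], pooled[-ix])
  })
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# Benjamini-Hochberg step-up by the textbook definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
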