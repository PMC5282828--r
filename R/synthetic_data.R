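#' @title Synthetic cohorts and screen plates with known ground truth
#' @name synthetic_data
#' @description
#' Generators for every input the pipeline consumes: annotated
#' case/control exome cohorts with a realistic rare-allele frequency
#' spectrum and planted recessive loss-of-function genotypes, decoy
#' variants that each violate exactly one cascade rule, and screen
#' plates with planted effects in SSMD* units. All outputs are
#' deterministic given a seed, and each generator returns a truth
#' table for comparison against pipeline output.
NULL

#' Cohort simulation specification
#'
#' Defaults emulate the discovery cohort structure: 1148 cases and
#' 503 controls, a frequency spectrum dominated by singleton-scale
#' alleles (70\% singleton-scale, 25\% rare tail below 1\%, 5\%
#' common, so every MAF filter of the cascade is exercised), and a
#' handful of planted recessive genes among neutral background genes.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param n_background_genes Neutral background genes (2 non-LoF
#'   variants each).
#' @param planted_hom,planted_comphet Numbers of planted recessive
#'   genes by mode.
#' @param carrier_count Case carriers per planted gene.
#' @param spectrum Named proportions `singleton`, `rare`, `common`
#'   (must sum to 1).
#' @param p_missing_maf Annotation-noise rate: probability a public
#'   frequency is dropped to missing.
#' @param decoys Include the standard decoy set (one gene per
#'   violated rule)?
#' @return A list with class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 1148, n_controls = 503,
                        n_background_genes = 500,
                        planted_hom = 3, planted_comphet = 2,
                        carrier_count = 1,
                        spectrum = c(singleton = 0.70, rare = 0.25,
                                     common = 0.05),
                        p_missing_maf = 0, decoys = TRUE) {
  stopifnot(carrier_count <= n_cases,
            abs(sum(spectrum) - 1) < 1e-8,
            p_missing_maf >= 0, p_missing_maf <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

ref_panel_n <- 32647L  # reference-panel size used for singleton MAFs

spectrum_maf <- function(n, spectrum) {
  cls <- sample(names(spectrum), n, replace = TRUE, prob = spectrum)
  maf <- numeric(n)
  maf[cls == "singleton"] <- 1 / (2 * ref_panel_n)
  maf[cls == "rare"] <- 0.01 * stats::rbeta(sum(cls == "rare"), 0.8, 2)
  maf[cls == "common"] <- stats::runif(sum(cls == "common"), 0.05, 0.4)
  maf
}

new_variant_row <- function(gene, chrom, pos, ref, alt, effect_class,
                            transcript_id, cadd = NA_real_,
                            rsid = NA_character_,
                            maf_exac_nfe = NA_real_,
                            immediate_stop = NA) {
  data.frame(gene = gene, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, rsid = rsid,
             effect_class = effect_class,
             transcript_id = transcript_id, aa_change = NA_character_,
             cadd = cadd, maf_esp6500_ea = NA_real_,
             maf_kg_eur = NA_real_, maf_exac_nfe = maf_exac_nfe,
             hom_ref_count = NA_integer_, hom_ref_n = NA_integer_,
             immediate_stop = immediate_stop,
             splice_coding_2bp = NA, stringsAsFactors = FALSE)
}

#' Generate a synthetic annotated cohort
#'
#' Background genotypes are drawn under Hardy-Weinberg equilibrium at
#' each variant's spectrum-assigned frequency; planted genes receive
#' their recessive genotypes (homozygous, or trans-phased compound
#' het) in randomly chosen cases; each standard decoy gene violates
#' exactly one named cascade rule. Deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List with `variants`, `genotypes`
#'   ([cohort_genotypes()]) and `truth` (data frame: `gene`,
#'   `category`, `expected_candidate`).
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_cases + spec$n_controls
  sample_ids <- c(sprintf("case_%04d", seq_len(spec$n_cases)),
                  sprintf("control_%04d", seq_len(spec$n_controls)))
  phenotype <- rep(c("case", "control"),
                   c(spec$n_cases, spec$n_controls))

  vlist <- list()
  glist <- list()
  truth <- list()
  phase <- list()
  pos_counter <- 1e6L

  add_variant <- function(row, genos) {
    vlist[[length(vlist) + 1L]] <<- row
    glist[[length(glist) + 1L]] <<- genos
  }
  next_pos <- function(step = 5000L) {
    pos_counter <<- pos_counter + step
    pos_counter
  }

  # neutral background: HWE draws at spectrum frequencies, non-LoF
  n_bg_var <- 2L * spec$n_background_genes
  bg_maf <- spectrum_maf(n_bg_var, spec$spectrum)
  for (i in seq_len(n_bg_var)) {
    gene <- sprintf("BG%04d", (i + 1L) %/% 2L)
    maf_pub <- if (stats::runif(1) < spec$p_missing_maf) NA_real_
               else bg_maf[i]
    add_variant(
      new_variant_row(gene, chrom = "1", pos = next_pos(), ref = "A",
                      alt = "G",
                      effect_class = sample(c("missense", "other"), 1L),
                      transcript_id = paste0("TX_", gene),
                      cadd = round(stats::rnorm(1, 12, 6), 1),
                      rsid = sprintf("rs9%06d", i),
                      maf_exac_nfe = maf_pub),
      stats::rbinom(n, 2L, bg_maf[i])
    )
    truth[[gene]] <- "background"
  }

  plant_carriers <- function() sample(spec$n_cases, spec$carrier_count)

  for (i in seq_len(spec$planted_hom)) {
    gene <- sprintf("PLH%02d", i)
    g <- integer(n)
    g[plant_carriers()] <- 2L
    add_variant(
      new_variant_row(gene, "2", next_pos(), "C", "T", "stopgain",
                      paste0("TX_", gene), cadd = 38),
      g)
    truth[[gene]] <- "planted_hom"
  }

  for (i in seq_len(spec$planted_comphet)) {
    gene <- sprintf("PLC%02d", i)
    carriers <- plant_carriers()
    p1 <- next_pos(); p2 <- next_pos()
    g1 <- integer(n); g2 <- integer(n)
    g1[carriers] <- 1L; g2[carriers] <- 1L
    tx <- paste0("TX_", gene)
    add_variant(new_variant_row(gene, "3", p1, "G", "T", "stopgain",
                                tx, cadd = 36), g1)
    add_variant(new_variant_row(gene, "3", p2, "A", "C", "missense",
                                tx, cadd = 28), g2)
    k1 <- paste("3", p1, "G", "T", sep = ":")
    k2 <- paste("3", p2, "A", "C", sep = ":")
    for (s in carriers) {
      phase[[length(phase) + 1L]] <- data.frame(
        sample_id = sample_ids[s], key_a = k1, key_b = k2,
        phase = "trans", stringsAsFactors = FALSE)
    }
    truth[[gene]] <- "planted_comphet"
  }

  if (spec$decoys) {
    dec <- standard_decoys(spec$n_cases, spec$n_controls,
                           base_pos = pos_counter + 1e6L)
    for (i in seq_len(nrow(dec$variants))) {
      add_variant(dec$variants[i, ], dec$geno[i, ])
    }
    for (g in unique(dec$variants$gene)) {
      truth[[g]] <- dec$category[[g]]
    }
  }

  variants <- do.call(rbind, vlist)
  rownames(variants) <- NULL
  geno <- do.call(rbind, glist)
  rownames(geno) <- variant_key(variants)
  phase_df <- if (length(phase) > 0L) do.call(rbind, phase) else NULL
  genotypes <- cohort_genotypes(sample_ids, phenotype, geno, phase_df)
  truth_df <- data.frame(
    gene = names(truth),
    category = unlist(truth),
    expected_candidate = grepl("^planted", unlist(truth)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(variants = variants, genotypes = genotypes, truth = truth_df)
}

# one decoy gene per cascade rule; deterministic (no RNG)
standard_decoys <- function(n_cases, n_controls, base_pos = 9e6L) {
  n <- n_cases + n_controls
  rows <- list(); genos <- list(); category <- list()
  pos <- base_pos
  bump <- function(step = 10000L) {
    pos <<- pos + step
    pos
  }
  add <- function(gene, rule, row, g) {
    rows[[length(rows) + 1L]] <<- row
    genos[[length(genos) + 1L]] <<- g
    category[[gene]] <<- paste0("decoy:", rule)
  }

  g <- integer(n); g[5L] <- 2L
  add("DECOY_COMMON", "public_maf",
      new_variant_row("DECOY_COMMON", "9", bump(), "A", "T",
                      "stopgain", "TX_DECOY_COMMON", cadd = 35,
                      maf_exac_nfe = 0.05), g)

  g <- integer(n); g[6L] <- 2L
  add("DECOY_NONLOF", "lof_class",
      new_variant_row("DECOY_NONLOF", "9", bump(), "C", "G",
                      "missense", "TX_DECOY_NONLOF", cadd = 30,
                      maf_exac_nfe = 1e-4), g)

  # rare in public databases but common in the internal controls
  g <- integer(n)
  g[7L] <- 2L
  ctrl_het <- n_cases + seq_len(max(3L, round(0.02 * 2 * n_controls)))
  g[ctrl_het] <- 1L
  add("DECOY_CTRLHOM", "internal_control",
      new_variant_row("DECOY_CTRLHOM", "9", bump(), "G", "A",
                      "stopgain", "TX_DECOY_CTRLHOM", cadd = 33,
                      maf_exac_nfe = 1e-4), g)

  # LoF anchor with an under-threshold missense partner
  g1 <- integer(n); g1[8L] <- 1L
  g2 <- integer(n); g2[8L] <- 1L
  add("DECOY_LOWCADD", "cadd_partner",
      new_variant_row("DECOY_LOWCADD", "9", bump(), "T", "C",
                      "stopgain", "TX_DECOY_LOWCADD", cadd = 34,
                      maf_exac_nfe = 1e-4), g1)
  rows[[length(rows) + 1L]] <- new_variant_row(
    "DECOY_LOWCADD", "9", bump(), "A", "G", "missense",
    "TX_DECOY_LOWCADD", cadd = 10, maf_exac_nfe = 1e-4)
  genos[[length(genos) + 1L]] <- g2

  # two LoF hets in one case but on different transcripts
  g1 <- integer(n); g1[9L] <- 1L
  g2 <- integer(n); g2[9L] <- 1L
  add("DECOY_DIFFTX", "same_transcript",
      new_variant_row("DECOY_DIFFTX", "9", bump(), "C", "T",
                      "stopgain", "TX_DECOY_DIFFTX_A", cadd = 36,
                      maf_exac_nfe = 1e-4), g1)
  rows[[length(rows) + 1L]] <- new_variant_row(
    "DECOY_DIFFTX", "9", bump(), "G", "C", "stopgain",
    "TX_DECOY_DIFFTX_B", cadd = 35, maf_exac_nfe = 1e-4)
  genos[[length(genos) + 1L]] <- g2

  # rare LoF homozygous only in a control
  g <- integer(n); g[n_cases + 1L] <- 2L
  add("DECOY_CTRLONLY", "case_zygosity",
      new_variant_row("DECOY_CTRLONLY", "9", bump(), "A", "C",
                      "stopgain", "TX_DECOY_CTRLONLY", cadd = 37,
                      maf_exac_nfe = 1e-4), g)

  list(variants = do.call(rbind, rows), geno = do.call(rbind, genos),
       category = category)
}

#' Screen-plate simulation specification
#'
#' Defaults follow the screening design: at least five shRNA clones
#' per gene, six replicate wells per clone, and per-plate scrambled
#' negative controls. Effects are specified in SSMD* units on the
#' normalized scale; well noise is Gaussian with standard deviation
#' `noise_sd` around a per-plate multiplicative offset, so a planted
#' effect `e` shifts the clone median by `e * sqrt(2) * noise_sd`
#' (the expected SSMD* denominator for normal noise).
#'
#' @param genes Character vector of screened genes.
#' @param effect_sizes Named numeric vector of planted SSMD* effects
#'   (genes not named get 0).
#' @param clones_per_gene Clones per gene (default 5).
#' @param replicates Replicate wells per clone (default 6).
#' @param n_neg,n_pos Control wells per plate (default 6 each).
#' @param pos_effect Positive-control effect in SSMD* units
#'   (default 8).
#' @param noise_sd Well noise standard deviation on the normalized
#'   scale (default 0.05).
#' @param wells_per_plate Plate capacity (default 96).
#' @return A list with class `plate_spec`.
#' @export
plate_spec <- function(genes, effect_sizes = numeric(0),
                       clones_per_gene = 5, replicates = 6,
                       n_neg = 6, n_pos = 6, pos_effect = 8,
                       noise_sd = 0.05, wells_per_plate = 96) {
  stopifnot(replicates >= 2, n_neg >= 1, clones_per_gene >= 1)
  structure(as.list(environment()), class = "plate_spec")
}

#' Generate synthetic screen plates
#'
#' Lays clones out over plates (each plate carries its own negative
#' and positive control wells plus a random multiplicative offset
#' that per-plate normalization must remove) and draws one normalized
#' well median per replicate. Returns the well table and a per-clone
#' truth table of intended SSMD* values.
#'
#' @param spec A [plate_spec()].
#' @param seed Integer seed.
#' @return List with `wells` (data frame: `plate`, `well`, `role`,
#'   `gene`, `clone`, `replicate`, `value`) and `truth` (`gene`,
#'   `clone`, `true_ssmd`).
#' @export
generate_plates <- function(spec, seed) {
  stopifnot(inherits(spec, "plate_spec"))
  set.seed(seed)
  shift_unit <- sqrt(2) * spec$noise_sd
  clone_rows <- expand.grid(clone_idx = seq_len(spec$clones_per_gene),
                            gene = spec$genes,
                            stringsAsFactors = FALSE)
  clone_rows$clone <- paste0(clone_rows$gene, "_sh",
                             clone_rows$clone_idx)
  effects <- rep(0, nrow(clone_rows))
  named <- intersect(names(spec$effect_sizes), spec$genes)
  for (g in named) {
    effects[clone_rows$gene == g] <- spec$effect_sizes[[g]]
  }
  clone_rows$effect <- effects

  sample_wells_per_plate <- spec$wells_per_plate - spec$n_neg -
    spec$n_pos
  clones_per_plate <- max(1L,
                          sample_wells_per_plate %/% spec$replicates)
  clone_rows$plate <- (seq_len(nrow(clone_rows)) - 1L) %/%
    clones_per_plate + 1L

  wells <- list()
  for (p in unique(clone_rows$plate)) {
    offset <- exp(stats::rnorm(1, 0, 0.3))  # plate-to-plate variation
    widx <- 0L
    emit <- function(role, gene, clone, k, effect) {
      widx <<- widx + 1L
      base <- 1 + effect * shift_unit +
        stats::rnorm(1, 0, spec$noise_sd)
      data.frame(plate = p, well = sprintf("W%03d", widx),
                 role = role, gene = gene, clone = clone,
                 replicate = k, value = offset * base,
                 stringsAsFactors = FALSE)
    }
    for (k in seq_len(spec$n_neg)) {
      wells[[length(wells) + 1L]] <-
        emit("neg_control", "SCR", "SCR", k, 0)
    }
    for (k in seq_len(spec$n_pos)) {
      wells[[length(wells) + 1L]] <-
        emit("pos_control", "POS", "POS", k, spec$pos_effect)
    }
    on_plate <- clone_rows[clone_rows$plate == p, , drop = FALSE]
    for (i in seq_len(nrow(on_plate))) {
      for (k in seq_len(spec$replicates)) {
        wells[[length(wells) + 1L]] <-
          emit("sample", on_plate$gene[i], on_plate$clone[i], k,
               on_plate$effect[i])
      }
    }
  }
  truth <- clone_rows[, c("gene", "clone", "effect")]
  names(truth)[3L] <- "true_ssmd"
  list(wells = do.call(rbind, wells), truth = truth)
}

#' Analyze a screen-well table end to end
#'
#' Normalizes wells per plate, computes each clone's SSMD* and
#' Mann-Whitney p-value against the pooled normalized negative
#' controls, and applies the two-clone hit rule.
#'
#' @param wells Well table as produced by [generate_plates()].
#' @param fdr_alpha,ssmd_cutoff,hit_rule Passed to [call_hits()].
#' @return List with `clones` (per-clone statistics), `hits` (gene
#'   table) and `zprime` (robust Z' from the pooled normalized
#'   controls, `NA` if no positive controls).
#' @export
analyze_screen <- function(wells, fdr_alpha = 0.05, ssmd_cutoff = 4,
                           hit_rule = "both") {
  wells <- normalize_plate(wells)
  negs <- wells$normalized[wells$role == "neg_control"]
  poss <- wells$normalized[wells$role == "pos_control"]
  samp <- wells[wells$role == "sample", , drop = FALSE]
  clones <- do.call(rbind, lapply(split(samp, samp$clone), function(cl) {
    data.frame(gene = cl$gene[1L], clone = cl$clone[1L],
               n = nrow(cl),
               ssmd = robust_ssmd(cl$normalized, negs),
               mw_p = mann_whitney_p(cl$normalized, negs),
               stringsAsFactors = FALSE)
  }))
  rownames(clones) <- NULL
  hits <- call_hits(clones, fdr_alpha = fdr_alpha,
                    ssmd_cutoff = ssmd_cutoff, hit_rule = hit_rule)
  zp <- if (length(poss) >= 2L) robust_zprime(poss, negs) else NA_real_
  list(clones = clones, hits = hits, zprime = zp)
}

#' The published recessive LoF variant table as a packaged fixture
#'
#' Encodes each row of the published discovery table verbatim
#' (coordinates, alleles, dbSNP ids, effect classes, ExAC European
#' frequencies, CADD scores, transcripts, zygosity modes, and the
#' Functional/Genetic validation flags), and builds a deterministic
#' synthetic carrier structure: one case homozygote per homozygous
#' gene, one trans-phased compound-het case per compound-het gene,
#' and for the splice gene the published four case homozygotes plus
#' one control homozygote with heterozygote counts matching the
#' printed case/control allele frequencies (0.073 / 0.052). The
#' genotypes are synthetic: no individual-level data from any cohort
#' are redistributed.
#'
#' @param decoys Append the standard decoy set (default `TRUE`)?
#' @return List with `variants` (table rows plus any decoys),
#'   `genotypes`, `evidence` (per-gene flag table) and
#'   `expected_genes` (data frame: `gene`, `mode`).
#' @export
discovery_table_fixture <- function(decoys = TRUE) {
  path <- system.file("extdata", "discovery_table_variants.tsv",
                      package = "lofprio", mustWork = TRUE)
  variants <- read_variant_tsv(path)
  validate_variants(variants)
  n_cases <- 1148L
  n_controls <- 503L
  n <- n_cases + n_controls
  sample_ids <- c(sprintf("case_%04d", seq_len(n_cases)),
                  sprintf("control_%04d", seq_len(n_controls)))
  phenotype <- rep(c("case", "control"), c(n_cases, n_controls))

  geno <- matrix(0L, nrow = nrow(variants), ncol = n)
  keys <- variant_key(variants)
  rownames(geno) <- keys
  phase <- list()

  hz <- which(variants$mode == "HZ" & variants$gene != "ARSB")
  # one distinct case homozygote per homozygous gene
  for (j in seq_along(hz)) {
    geno[hz[j], 200L + j] <- 2L
  }

  # splice gene: published case/control frequencies and homozygotes
  arsb <- which(variants$gene == "ARSB")
  geno[arsb, 1:4] <- 2L                      # 4 case homozygotes
  geno[arsb, 5:164] <- 1L                    # 160 case heterozygotes
  geno[arsb, n_cases + 1L] <- 2L             # 1 control homozygote
  geno[arsb, n_cases + 2:51] <- 1L           # 50 control heterozygotes

  ch_genes <- unique(variants$gene[variants$mode == "CH"])
  for (j in seq_along(ch_genes)) {
    idx <- which(variants$gene == ch_genes[j])
    carrier <- 400L + j
    geno[idx, carrier] <- 1L
    phase[[length(phase) + 1L]] <- data.frame(
      sample_id = sample_ids[carrier], key_a = keys[idx[1L]],
      key_b = keys[idx[2L]], phase = "trans",
      stringsAsFactors = FALSE)
  }

  tab <- variants
  if (decoys) {
    dec <- standard_decoys(n_cases, n_controls)
    dv <- dec$variants
    for (col in setdiff(names(variants), names(dv))) dv[[col]] <- NA
    dv$functional <- "."
    dv$genetic <- "."
    dv <- dv[, names(variants)]
    variants <- rbind(variants, dv)
    geno <- rbind(geno, dec$geno)
    rownames(geno) <- variant_key(variants)
  }

  phase_df <- do.call(rbind, phase)
  genotypes <- cohort_genotypes(sample_ids, phenotype, geno, phase_df)

  evidence <- evidence_table(tab$gene, tab$functional, tab$genetic)
  expected <- unique(tab[, c("gene", "mode")])
  rownames(expected) <- NULL
  list(variants = variants, genotypes = genotypes,
       evidence = evidence, expected_genes = expected)
}
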