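#' @title Cross-cohort arithmetic and evidence integration
#' @name enrichment_evidence
#' @description
#' Fold enrichment against reference cohorts, Hardy-Weinberg
#' homozygote frequencies, tolerability verdicts against disease
#' prevalence, replication matching (identical variants, shared
#' heterozygotes, GWAS windows, pairwise relatedness), and the final
#' rule that combines functional-assay and genetic-replication flags
#' into a prioritized gene set.
NULL

#' Fold enrichment of a genotype between cohorts
#'
#' `(k_cases / n_cases) / (k_ref / n_ref)`: the ratio of carrier
#' frequencies in the study cohort versus a reference cohort. Scale
#' invariant in both cohort sizes.
#'
#' @param k_cases,n_cases Carrier count and size of the study cohort.
#' @param k_ref,n_ref Carrier count and size of the reference cohort.
#' @return The fold enrichment; `Inf` (not estimable) when
#'   `k_ref = 0`.
#' @export
fold_enrichment <- function(k_cases, n_cases, k_ref, n_ref) {
  stopifnot(k_cases >= 0, k_ref >= 0, n_cases > 0, n_ref > 0)
  if (k_ref == 0) return(Inf)
  (k_cases / n_cases) / (k_ref / n_ref)
}

#' Homozygote frequency under Hardy-Weinberg equilibrium
#'
#' @param maf Allele frequency in \[0, 1\].
#' @return `maf^2`, the expected homozygote frequency.
#' @export
hwe_homozygote_frequency <- function(maf) {
  stopifnot(all(maf >= 0 & maf <= 1))
  maf^2
}

#' Tolerability of an observed homozygote frequency
#'
#' An observed population homozygote frequency at or below the disease
#' prevalence cannot exclude the gene as a highly penetrant risk
#' locus (`"cannot_exclude"`, equality included); a frequency above
#' the prevalence makes high penetrance unlikely
#' (`"unlikely_penetrant"`).
#'
#' @param hom_count Homozygote count in the reference population.
#' @param cohort_n Reference population size.
#' @param prevalence Disease prevalence for the relevant age band
#'   (default 0.00041, young-onset parkinsonism at ages 40-49).
#' @return List with `hom_frequency` and `verdict`.
#' @export
tolerability_assessment <- function(hom_count, cohort_n,
                                    prevalence = 0.00041) {
  stopifnot(cohort_n > 0, hom_count >= 0,
            prevalence > 0, prevalence < 1)
  f <- hom_count / cohort_n
  list(hom_frequency = f,
       verdict = if (f <= prevalence) "cannot_exclude"
                 else "unlikely_penetrant")
}

recessive_in_sample <- function(variants, genotypes, sample_idx,
                                window_genes = NULL) {
  # homozygous, or >= 2 het variants on one transcript
  g <- genotypes$geno[, sample_idx]
  hom <- which(!is.na(g) & g == 2L)
  het <- which(!is.na(g) & g == 1L)
  comphet <- integer(0)
  if (length(het) >= 2L) {
    for (tx in unique(variants$transcript_id[het])) {
      if (is.na(tx)) next
      idx <- het[variants$transcript_id[het] == tx]
      if (length(idx) >= 2L) comphet <- c(comphet, idx)
    }
  }
  list(hom = hom, comphet = comphet)
}

#' Match candidate variants in a replication cohort
#'
#' Finds candidates' variants again in an independent cohort by exact
#' (chrom, pos, ref, alt) identity, requiring a qualifying recessive
#' genotype there: a homozygous carrier, or a heterozygous carrier
#' with a second qualifying allele on the same transcript whose phase
#' is annotated trans (or unknown, reported as putative).
#'
#' @param candidates Variant table of discovery candidates.
#' @param rep_variants Replication-cohort variant table (same genome
#'   build; a `build` attribute mismatch between the two tables is a
#'   hard error).
#' @param rep_genotypes Replication-cohort [cohort_genotypes()].
#' @return Data frame of matches: `gene`, `key`, `sample_id`,
#'   `phenotype`, `mode`.
#' @export
match_identical_variant <- function(candidates, rep_variants,
                                    rep_genotypes) {
  b1 <- attr(candidates, "build")
  b2 <- attr(rep_variants, "build")
  if (!is.null(b1) && !is.null(b2) && !identical(b1, b2)) {
    stop("genome build mismatch between discovery (", b1,
         ") and replication (", b2, ") tables")
  }
  keys_c <- variant_key(candidates)
  keys_r <- variant_key(rep_variants)
  hits <- list()
  for (i in which(keys_r %in% keys_c)) {
    ci <- match(keys_r[i], keys_c)
    g <- rep_genotypes$geno[i, ]
    for (s in which(!is.na(g) & g > 0L)) {
      rec <- recessive_in_sample(rep_variants, rep_genotypes, s)
      mode <- if (i %in% rec$hom) {
        "homozygous"
      } else if (i %in% rec$comphet) {
        partners <- setdiff(rec$comphet[
          rep_variants$transcript_id[rec$comphet] ==
            rep_variants$transcript_id[i]], i)
        ph <- if (length(partners) > 0L) {
          pair_phase(rep_genotypes,
                     rep_genotypes$samples$sample_id[s],
                     keys_r[i], keys_r[partners[1L]])
        } else "unknown"
        if (ph == "cis") next
        "compound_het"
      } else {
        next
      }
      hits[[length(hits) + 1L]] <- data.frame(
        gene = candidates$gene[ci], key = keys_r[i],
        sample_id = rep_genotypes$samples$sample_id[s],
        phenotype = rep_genotypes$samples$phenotype[s],
        mode = mode, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(gene = character(0), key = character(0),
                      sample_id = character(0),
                      phenotype = character(0), mode = character(0)))
  }
  do.call(rbind, hits)
}

#' Shared-heterozygote scan in a small index-case cohort
#'
#' Reports heterozygous missense/LoF variants carried by at least
#' `min_cases` index cases, absent from all cohort controls, with
#' every available public frequency below `maf_cap`.
#'
#' @param variants Variant table.
#' @param genotypes A [cohort_genotypes()] (cases are index cases).
#' @param min_cases Minimum index-case carriers (default 2).
#' @param maf_cap Public-frequency ceiling (default 0.001).
#' @return Data frame of reported variants with carrier counts.
#' @export
shared_het_scan <- function(variants, genotypes, min_cases = 2,
                            maf_cap = 0.001) {
  is_case <- genotypes$samples$phenotype == "case"
  lof <- if ("is_lof" %in% names(variants)) variants$is_lof else
    variants$effect_class %in% c("stopgain", "stoploss", "frameshift",
                                 "splice")
  classes_ok <- lof | variants$effect_class == "missense"
  out <- list()
  for (i in seq_len(nrow(variants))) {
    if (!classes_ok[i]) next
    freqs <- unlist(variants[i, MAF_SOURCES])
    if (any(!is.na(freqs) & freqs >= maf_cap)) next
    g <- genotypes$geno[i, ]
    n_case <- sum(is_case & !is.na(g) & g == 1L)
    n_ctrl <- sum(!is_case & !is.na(g) & g >= 1L)
    if (n_case >= min_cases && n_ctrl == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        gene = variants$gene[i], key = variant_key(variants[i, ]),
        effect_class = variants$effect_class[i],
        n_index_cases = n_case, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene = character(0), key = character(0),
                      effect_class = character(0),
                      n_index_cases = integer(0)))
  }
  do.call(rbind, out)
}

#' GWAS association signals near candidate genes
#'
#' Reports summary-statistic SNPs below `p_threshold` within `window`
#' bp up- or downstream of each gene, grouped into peaks: SNPs closer
#' than `merge_dist` bp join the same peak.
#'
#' @param genes Data frame with columns `gene`, `chrom`, `start`,
#'   `end` (1-based).
#' @param sumstats Data frame with columns `snp`, `chrom`, `pos`, `p`.
#' @param window Flank size in bp (default 1e6 each side).
#' @param p_threshold Suggestive-association threshold (default 1e-4).
#' @param merge_dist Peak-grouping distance in bp (default 2.5e5).
#' @return Data frame: `gene`, `snp`, `pos`, `p`, `peak` (index within
#'   gene).
#' @export
gwas_window <- function(genes, sumstats, window = 1e6,
                        p_threshold = 1e-4, merge_dist = 2.5e5) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gn <- genes[i, ]
    sel <- sumstats$chrom == gn$chrom &
      sumstats$pos >= gn$start - window &
      sumstats$pos <= gn$end + window &
      sumstats$p < p_threshold
    if (!any(sel)) next
    hits <- sumstats[sel, , drop = FALSE]
    hits <- hits[order(hits$pos), , drop = FALSE]
    peak <- cumsum(c(1, diff(hits$pos) > merge_dist))
    out[[length(out) + 1L]] <- data.frame(
      gene = gn$gene, snp = hits$snp, pos = hits$pos, p = hits$p,
      peak = peak, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(gene = character(0), snp = character(0),
                      pos = integer(0), p = numeric(0),
                      peak = integer(0)))
  }
  do.call(rbind, out)
}

#' Pairwise genetic relatedness from common SNPs
#'
#' The standardized genotype covariance between two individuals,
#' `A_jk = mean_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over SNPs with minor allele frequency at or above `maf_floor`.
#' Near zero for unrelated pairs.
#'
#' @param x_j,x_k Genotype vectors (0/1/2) for the two individuals.
#' @param p Allele frequencies of the counted allele, per SNP.
#' @param maf_floor Minor-allele-frequency floor (default 0.01).
#' @return `A_jk`, or `NA` when no SNP passes the floor.
#' @export
grm_pair <- function(x_j, x_k, p, maf_floor = 0.01) {
  stopifnot(length(x_j) == length(p), length(x_k) == length(p))
  keep <- !is.na(x_j) & !is.na(x_k) & pmin(p, 1 - p) >= maf_floor
  if (!any(keep)) return(NA_real_)
  x_j <- x_j[keep]; x_k <- x_k[keep]; p <- p[keep]
  mean((x_j - 2 * p) * (x_k - 2 * p) / (2 * p * (1 - p)))
}

FUNCTIONAL_FLAGS <- c("Mp", "Mm", "S")
GENETIC_FLAGS <- c("PPMI", "neuroX", "GRIP", "GWAS")

#' Build an evidence table from flag strings
#'
#' Expands the compact per-gene `functional` and `genetic` columns
#' (comma-separated flag codes: Mp = Parkin translocation, Mm =
#' mitochondrial morphology, S = alpha-synuclein enhancer; PPMI,
#' neuroX, GRIP, GWAS replication sources) into one boolean column per
#' flag.
#'
#' @param genes Character vector of gene symbols.
#' @param functional,genetic Character vectors of comma-separated flag
#'   codes (`NA` or `"."` for none), parallel to `genes`.
#' @return Data frame: `gene` plus a logical column per flag.
#' @export
evidence_table <- function(genes, functional, genetic) {
  parse_flags <- function(x, flags) {
    x[is.na(x) | x == "."] <- ""
    parts <- strsplit(x, ",", fixed = TRUE)
    vapply(flags, function(f) {
      vapply(parts, function(p) f %in% trimws(p), logical(1))
    }, logical(length(x)))
  }
  fun <- parse_flags(functional, FUNCTIONAL_FLAGS)
  gen <- parse_flags(genetic, GENETIC_FLAGS)
  if (length(genes) == 1L) {
    fun <- matrix(fun, nrow = 1L, dimnames = list(NULL,
                                                  FUNCTIONAL_FLAGS))
    gen <- matrix(gen, nrow = 1L, dimnames = list(NULL, GENETIC_FLAGS))
  }
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(fun), as.data.frame(gen))
  # aggregate duplicate gene rows (e.g. per-variant flag columns)
  if (anyDuplicated(out$gene)) {
    agg <- stats::aggregate(out[-1L], by = list(gene = out$gene), any)
    out <- agg[order(agg$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Prioritize genes by combined functional and genetic evidence
#'
#' Returns three deterministic, alphabetically ordered gene sets: the
#' functionally supported genes (>= 1 functional flag), the
#' genetically replicated genes (>= 1 genetic flag), and the
#' prioritized intersection (>= 1 functional AND >= 1 genetic flag).
#' The conjunction rule is the package default and can be overridden
#' by supplying a different `rule` function over the two flag counts.
#'
#' @param evidence Data frame from [evidence_table()].
#' @param rule Function `(n_functional, n_genetic) -> logical` for the
#'   prioritized set (default: both at least 1).
#' @return List with `functional`, `genetic`, `prioritized` (gene
#'   character vectors) and `counts` (per-flag gene counts).
#' @export
prioritize <- function(evidence,
                       rule = function(nf, ng) nf >= 1 & ng >= 1) {
  nf <- rowSums(evidence[, FUNCTIONAL_FLAGS, drop = FALSE])
  ng <- rowSums(evidence[, GENETIC_FLAGS, drop = FALSE])
  counts <- c(
    vapply(c(FUNCTIONAL_FLAGS, GENETIC_FLAGS), function(f)
      sum(evidence[[f]]), integer(1)),
    mito_any = sum(evidence$Mp | evidence$Mm),
    functional_any = sum(nf >= 1),
    genetic_any = sum(ng >= 1)
  )
  list(
    functional = sort(evidence$gene[nf >= 1]),
    genetic = sort(evidence$gene[ng >= 1]),
    prioritized = sort(evidence$gene[rule(nf, ng)]),
    counts = counts
  )
}
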