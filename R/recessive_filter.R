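#' @title Recessive LoF filter cascade
#' @name recessive_filter
#' @description
#' The candidate-discovery cascade: LoF classification, multi-database
#' minor-allele-frequency filtering, homozygous candidate selection
#' with case/control comparison, and putative compound-heterozygote
#' detection with explicit phase handling. Each candidate carries a
#' filter trail recording every rule it passed, failed or was excepted
#' from.
NULL

#' Filter cascade configuration
#'
#' @param maf_threshold Public minor-allele-frequency ceiling for rare
#'   variants (default 0.01, chosen so the implied homozygote
#'   frequency under Hardy-Weinberg, 0.01\%, stays below the disease
#'   prevalence of interest).
#' @param cadd_threshold CADD floor for the missense partner of a
#'   compound het (default 20: the predicted 1\% most damaging
#'   variants genome-wide).
#' @param comphet_window Distance in bp within which a variant pair
#'   needs explicit phase evidence (default 200; near pairs can sit on
#'   single sequencing reads and demand read-level scrutiny).
#' @param control_common_threshold Internal-control allele-frequency
#'   ceiling for homozygous candidates (default 0.01).
#' @return A list with class `filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.01, cadd_threshold = 20,
                          comphet_window = 200,
                          control_common_threshold = 0.01) {
  stopifnot(maf_threshold > 0, maf_threshold < 0.5,
            cadd_threshold > 0, comphet_window > 0,
            control_common_threshold > 0)
  structure(list(maf_threshold = maf_threshold,
                 cadd_threshold = cadd_threshold,
                 comphet_window = comphet_window,
                 control_common_threshold = control_common_threshold),
            class = "filter_config")
}

#' Public-database rarity filter
#'
#' A variant passes when every public source that reports it gives a
#' frequency below `maf_threshold`. A variant absent from all sources
#' passes and is flagged novel (absence from the databases is treated
#' as evidence of rarity, not as frequency zero).
#'
#' @param record A variant record row.
#' @param config A [filter_config()].
#' @return List with `pass` (logical), `novel` (logical) and
#'   `provenance` (the deciding source, or `"novel"`).
#' @export
rare_by_public_maf <- function(record, config = filter_config()) {
  freqs <- unlist(record[MAF_SOURCES])
  avail <- !is.na(freqs)
  if (!any(avail)) {
    return(list(pass = TRUE, novel = TRUE, provenance = "novel"))
  }
  failing <- avail & freqs >= config$maf_threshold
  if (any(failing)) {
    src <- names(freqs)[which(failing)[1L]]
    list(pass = FALSE, novel = FALSE, provenance = src)
  } else {
    src <- names(freqs)[avail][which.max(freqs[avail])]
    list(pass = TRUE, novel = FALSE, provenance = src)
  }
}

# allele frequency of the alternate allele among called alleles
allele_freq <- function(genos) {
  called <- !is.na(genos)
  if (!any(called)) return(NA_real_)
  sum(genos[called]) / (2 * sum(called))
}

cohort_allele_freqs <- function(genotypes) {
  is_case <- genotypes$samples$phenotype == "case"
  geno <- genotypes$geno
  list(
    case = apply(geno[, is_case, drop = FALSE], 1L, allele_freq),
    control = apply(geno[, !is_case, drop = FALSE], 1L, allele_freq)
  )
}

#' Homozygous recessive candidates
#'
#' A gene becomes a homozygous-mode candidate when at least one case
#' sample is homozygous (genotype 2) for a rare LoF variant. Variants
#' are excluded when the internal-control allele frequency exceeds
#' `control_common_threshold` or exceeds the case frequency (ties
#' pass); variants that fail these internal-control rules but are
#' absent from every public database are retained with an "exception"
#' entry in the filter trail and a warning, since for such variants
#' the in-house controls are the only frequency reference available.
#'
#' @param variants Variant table with `is_lof`/`lof_reason` attached
#'   (see [attach_lof_calls()]).
#' @param genotypes A [cohort_genotypes()] object whose matrix rows
#'   correspond to `variants` rows.
#' @param config A [filter_config()].
#' @return List of [gene_candidate()] objects (mode `"homozygous"`).
#' @export
homozygous_candidates <- function(variants, genotypes,
                                  config = filter_config()) {
  stopifnot("is_lof" %in% names(variants))
  is_case <- genotypes$samples$phenotype == "case"
  geno <- genotypes$geno
  freqs <- cohort_allele_freqs(genotypes)
  out <- list()
  for (i in seq_len(nrow(variants))) {
    rec <- variants[i, ]
    if (!rec$is_lof) next
    maf <- rare_by_public_maf(rec, config)
    if (!maf$pass) next
    hom_cases <- which(is_case & !is.na(geno[i, ]) & geno[i, ] == 2L)
    if (length(hom_cases) == 0L) next
    trail <- data.frame(
      filter = c("lof_class", "public_maf"),
      status = c("pass", "pass"), stringsAsFactors = FALSE
    )
    f_ctrl <- freqs$control[i]
    f_case <- freqs$case[i]
    ctrl_ok <- is.na(f_ctrl) ||
      (f_ctrl <= config$control_common_threshold && f_ctrl <= f_case)
    if (ctrl_ok) {
      trail <- rbind(trail, data.frame(filter = "internal_control",
                                       status = "pass"))
    } else if (maf$novel) {
      warning("variant ", variant_key(rec), " in ", rec$gene,
              " fails the internal-control rule but is absent from ",
              "all public sources; retained with an exception flag")
      trail <- rbind(trail, data.frame(filter = "internal_control",
                                       status = "exception"))
    } else {
      next
    }
    if (maf$novel) {
      trail <- rbind(trail, data.frame(filter = "novel",
                                       status = "pass"))
    }
    out[[length(out) + 1L]] <- gene_candidate(
      gene = rec$gene, mode = "homozygous", variants = rec,
      carriers = genotypes$samples$sample_id[hom_cases],
      filter_trail = trail
    )
  }
  out
}

pair_phase <- function(genotypes, sample_id, key_a, key_b) {
  ph <- genotypes$phase
  if (is.null(ph)) return("unknown")
  hit <- ph$sample_id == sample_id &
    ((ph$key_a == key_a & ph$key_b == key_b) |
       (ph$key_a == key_b & ph$key_b == key_a))
  if (!any(hit)) "unknown" else ph$phase[which(hit)[1L]]
}

#' Putative compound-heterozygous candidates
#'
#' For each case sample and transcript, enumerates heterozygous
#' variant pairs in which one allele is LoF and the partner is either
#' LoF or a deleterious missense variant (no dbSNP id and CADD above
#' `cadd_threshold`); both must pass the public rarity filter. Pairs
#' closer than `comphet_window` bp require explicit trans phase:
#' unknown phase there yields a `"needs_review"` candidate, excluded
#' from the confirmed set. Distant pairs with unknown phase are
#' accepted as `"putative"`; cis pairs are never candidates.
#'
#' @inheritParams homozygous_candidates
#' @return List of [gene_candidate()] objects (mode `"compound_het"`),
#'   including any with status `"needs_review"`.
#' @export
compound_het_candidates <- function(variants, genotypes,
                                    config = filter_config()) {
  stopifnot("is_lof" %in% names(variants))
  is_case <- genotypes$samples$phenotype == "case"
  geno <- genotypes$geno
  keys <- variant_key(variants)
  maf_pass <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    maf_pass[i] <- rare_by_public_maf(variants[i, ], config)$pass
  }
  partner_ok <- variants$is_lof |
    (variants$effect_class == "missense" & is.na(variants$rsid) &
       !is.na(variants$cadd) & variants$cadd > config$cadd_threshold)

  out <- list()
  seen <- character(0)  # gene/pair dedupe across carriers
  for (s in which(is_case)) {
    sid <- genotypes$samples$sample_id[s]
    het <- which(!is.na(geno[, s]) & geno[, s] == 1L & maf_pass)
    if (length(het) < 2L) next
    for (tx in unique(variants$transcript_id[het])) {
      if (is.na(tx)) next
      idx <- het[variants$transcript_id[het] == tx]
      if (length(idx) < 2L) next
      for (a in seq_along(idx)) {
        for (b in seq_along(idx)) {
          if (a >= b) next
          ia <- idx[a]; ib <- idx[b]
          # anchor rule: at least one LoF allele, partner qualifying
          anchored <- (variants$is_lof[ia] && partner_ok[ib]) ||
            (variants$is_lof[ib] && partner_ok[ia])
          if (!anchored) next
          pair_id <- paste(variants$gene[ia], keys[ia], keys[ib])
          status <- "putative"
          phase <- pair_phase(genotypes, sid, keys[ia], keys[ib])
          if (phase == "cis") next
          near <- abs(variants$pos[ia] - variants$pos[ib]) <=
            config$comphet_window
          if (phase == "trans") {
            status <- "confirmed"
          } else if (near) {
            status <- "needs_review"
          }
          if (pair_id %in% seen) {
            # append carrier to the existing candidate
            for (j in seq_along(out)) {
              if (identical(attr(out[[j]], "pair_id"), pair_id)) {
                out[[j]]$carriers <- union(out[[j]]$carriers, sid)
              }
            }
            next
          }
          seen <- c(seen, pair_id)
          trail <- data.frame(
            filter = c("lof_anchor", "public_maf", "same_transcript",
                       "phase"),
            status = c("pass", "pass", "pass",
                       if (status == "needs_review") "fail" else "pass"),
            stringsAsFactors = FALSE
          )
          cand <- gene_candidate(
            gene = variants$gene[ia], mode = "compound_het",
            variants = variants[c(ia, ib), ], carriers = sid,
            filter_trail = trail, status = status
          )
          attr(cand, "pair_id") <- pair_id
          out[[length(out) + 1L]] <- cand
        }
      }
    }
  }
  out
}

#' Run the full filter cascade
#'
#' Applies LoF classification, the public rarity filter, homozygous
#' zygosity rules, and compound-het rules, returning candidates
#' partitioned by mode plus the per-stage variant counts that form the
#' cascade's audit trail. An optional `vqsr_pass` column acts as an
#' upstream-QC pre-filter (rows with `vqsr_pass == FALSE` are dropped
#' first).
#'
#' @param variants Variant table (LoF calls are attached internally if
#'   absent).
#' @param genotypes A [cohort_genotypes()] object.
#' @param config A [filter_config()].
#' @param transcripts Optional transcript models for
#'   [attach_lof_calls()].
#' @return List with `candidates` (confirmed/putative only),
#'   `needs_review`, `counts` (named per-stage variant counts) and
#'   `summary` (data frame of candidate genes by mode).
#' @export
run_cascade <- function(variants, genotypes, config = filter_config(),
                        transcripts = NULL) {
  counts <- c(input = nrow(variants))
  keep <- rep(TRUE, nrow(variants))
  if ("vqsr_pass" %in% names(variants)) {
    keep <- is.na(variants$vqsr_pass) | variants$vqsr_pass
  }
  variants <- variants[keep, , drop = FALSE]
  genotypes$geno <- genotypes$geno[keep, , drop = FALSE]
  counts["qc_pass"] <- nrow(variants)

  if (!"is_lof" %in% names(variants)) {
    variants <- attach_lof_calls(variants, transcripts)
  }
  counts["lof"] <- sum(variants$is_lof)

  maf_pass <- vapply(seq_len(nrow(variants)), function(i) {
    rare_by_public_maf(variants[i, ], config)$pass
  }, logical(1))
  counts["lof_rare"] <- sum(variants$is_lof & maf_pass)

  hom <- homozygous_candidates(variants, genotypes, config)
  ch_all <- compound_het_candidates(variants, genotypes, config)
  review <- Filter(function(x) x$status == "needs_review", ch_all)
  ch <- Filter(function(x) x$status != "needs_review", ch_all)

  # a gene already carried by a homozygous candidate is reported there
  hom_genes <- vapply(hom, `[[`, character(1), "gene")
  ch <- Filter(function(x) !(x$gene %in% hom_genes), ch)

  counts["hom_candidates"] <- length(hom)
  counts["comphet_candidates"] <- length(ch)

  candidates <- c(hom, ch)
  summary <- data.frame(
    gene = vapply(candidates, `[[`, character(1), "gene"),
    mode = vapply(candidates, `[[`, character(1), "mode"),
    status = vapply(candidates, `[[`, character(1), "status"),
    n_carriers = vapply(candidates, function(x)
      length(x$carriers), integer(1)),
    stringsAsFactors = FALSE
  )
  if (nrow(summary) > 0L) {
    summary <- summary[order(summary$gene), , drop = FALSE]
    rownames(summary) <- NULL
  }
  list(candidates = candidates, needs_review = review,
       counts = counts, summary = summary)
}
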