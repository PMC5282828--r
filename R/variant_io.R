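#' @title Annotated cohort variant I/O and shared data model
#' @name variant_io
#' @description
#' Readers and writers for annotated case/control variant tables, the
#' cohort genotype matrix, and candidate-gene reports. The canonical
#' on-disk format is a flat TSV with a fixed header (one row per
#' biallelic variant); VCF 4.x input is also accepted for variant
#' tables, with annotations taken from INFO keys. Coordinates are
#' 1-based inclusive throughout.
NULL

# Public allele-frequency sources recognised by the filter cascade.
MAF_SOURCES <- c("maf_esp6500_ea", "maf_kg_eur", "maf_exac_nfe")

VARIANT_COLUMNS <- c(
  "gene", "chrom", "pos", "ref", "alt", "rsid", "effect_class",
  "transcript_id", "aa_change", "cadd", MAF_SOURCES
)

EFFECT_CLASSES <- c("stopgain", "stoploss", "frameshift", "splice",
                    "missense", "other")

#' Construct a single annotated variant record
#'
#' A `VariantRecord` is a one-row data frame carrying the annotation
#' fields the filter cascade consumes: coordinates, alleles, dbSNP id,
#' functional effect class, transcript, protein notation, CADD
#' deleteriousness score, and per-source public minor allele
#' frequencies. Missing public frequencies are `NA` (explicitly
#' distinct from 0: the cascade treats "absent from databases"
#' specially).
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position (>= 1).
#' @param ref,alt Reference and alternate allele strings (`ref != alt`).
#' @param gene Gene symbol.
#' @param rsid dbSNP identifier or `NA`.
#' @param effect_class One of `r paste(EFFECT_CLASSES, collapse = ", ")`.
#' @param transcript_id Annotation transcript (required for splice
#'   variants).
#' @param aa_change Protein/cDNA notation or `NA`.
#' @param cadd PHRED-like deleteriousness score (>= 0) or `NA`.
#' @param maf_esp6500_ea,maf_kg_eur,maf_exac_nfe Public allele
#'   frequencies in \[0, 1\] or `NA` when the variant is absent from
#'   that source.
#' @param hom_ref_count,hom_ref_n Optional homozygote count and cohort
#'   size in a reference population.
#' @return A one-row data frame with class `variant_record`.
#' @export
variant_record <- function(chrom, pos, ref, alt, gene = NA_character_,
                           rsid = NA_character_,
                           effect_class = "other",
                           transcript_id = NA_character_,
                           aa_change = NA_character_, cadd = NA_real_,
                           maf_esp6500_ea = NA_real_,
                           maf_kg_eur = NA_real_,
                           maf_exac_nfe = NA_real_,
                           hom_ref_count = NA_integer_,
                           hom_ref_n = NA_integer_) {
  rec <- data.frame(
    gene = as.character(gene), chrom = as.character(chrom),
    pos = as.integer(pos), ref = as.character(ref),
    alt = as.character(alt), rsid = as.character(rsid),
    effect_class = as.character(effect_class),
    transcript_id = as.character(transcript_id),
    aa_change = as.character(aa_change), cadd = as.numeric(cadd),
    maf_esp6500_ea = as.numeric(maf_esp6500_ea),
    maf_kg_eur = as.numeric(maf_kg_eur),
    maf_exac_nfe = as.numeric(maf_exac_nfe),
    hom_ref_count = as.integer(hom_ref_count),
    hom_ref_n = as.integer(hom_ref_n),
    stringsAsFactors = FALSE
  )
  validate_variants(rec)
  class(rec) <- c("variant_record", class(rec))
  rec
}

#' Validate a table of variant records
#'
#' Enforces the shared data-model invariants: positions >= 1, `ref !=
#' alt`, public frequencies in \[0, 1\], a declared effect class, and a
#' transcript id for every splice variant. Multi-allelic rows (comma in
#' the alternate allele) are rejected; all filter rules are
#' per-allele, so sites must be pre-split into biallelic records.
#'
#' @param variants Data frame with at least the columns of
#'   [variant_record()].
#' @return The input, invisibly, if valid; otherwise an error naming
#'   the offending row.
#' @export
validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  missing_cols <- setdiff(VARIANT_COLUMNS, names(variants))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0L) {
      stop("invalid variant record (row ", idx[1L], "): ", what,
           call. = FALSE)
    }
  }
  bad(is.na(variants$pos) | variants$pos < 1L, "pos must be >= 1")
  bad(grepl(",", variants$alt, fixed = TRUE),
      "multi-allelic rows must be pre-split into biallelic records")
  bad(variants$ref == variants$alt, "ref and alt alleles are identical")
  bad(!(variants$effect_class %in% EFFECT_CLASSES),
      "unknown effect_class")
  for (src in MAF_SOURCES) {
    f <- variants[[src]]
    bad(!is.na(f) & (f < 0 | f > 1), paste(src, "outside [0, 1]"))
  }
  bad(variants$effect_class == "splice" & is.na(variants$transcript_id),
      "splice variant without a transcript_id")
  invisible(variants)
}

#' Build a variant key string ("chrom:pos:ref:alt")
#'
#' Used to tie genotype-matrix columns back to the variant table and
#' for identical-variant replication matching.
#'
#' @param variants Variant table.
#' @return Character vector of keys.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt,
        sep = ":")
}

#' Assemble cohort genotypes
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param phenotype Character vector, `"case"` or `"control"`, one per
#'   sample.
#' @param geno Integer matrix of alternate-allele counts, variants in
#'   rows (rownames are variant keys), samples in columns; codes 0, 1,
#'   2 or `NA`.
#' @param phase Optional data frame of per-sample phase annotations for
#'   variant pairs with columns `sample_id`, `key_a`, `key_b`, `phase`
#'   (`"cis"`, `"trans"` or `"unknown"`).
#' @return A list with class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(sample_ids, phenotype, geno, phase = NULL) {
  sample_ids <- as.character(sample_ids)
  phenotype <- as.character(phenotype)
  if (length(phenotype) != length(sample_ids)) {
    stop("phenotype must be assigned for every sample")
  }
  if (!all(phenotype %in% c("case", "control"))) {
    stop("phenotype codes must be 'case' or 'control'")
  }
  geno <- as.matrix(geno)
  if (ncol(geno) != length(sample_ids)) {
    stop("genotype matrix has ", ncol(geno), " columns but ",
         length(sample_ids), " samples are declared")
  }
  ok <- is.na(geno) | geno %in% c(0L, 1L, 2L)
  if (!all(ok)) {
    stop("invalid genotype code '", geno[which(!ok)[1L]],
         "': codes must be 0, 1, 2 or missing")
  }
  colnames(geno) <- sample_ids
  if (!is.null(phase)) {
    stopifnot(all(c("sample_id", "key_a", "key_b", "phase") %in%
                    names(phase)))
    if (!all(phase$phase %in% c("cis", "trans", "unknown"))) {
      stop("phase codes must be 'cis', 'trans' or 'unknown'")
    }
  }
  structure(
    list(samples = data.frame(sample_id = sample_ids,
                              phenotype = phenotype,
                              stringsAsFactors = FALSE),
         geno = geno, phase = phase),
    class = "cohort_genotypes"
  )
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat("cohort_genotypes:", nrow(x$geno), "variants x",
      ncol(x$geno), "samples (",
      sum(x$samples$phenotype == "case"), "cases /",
      sum(x$samples$phenotype == "control"), "controls )\n")
  invisible(x)
}

#' Construct a transcript model
#'
#' Exon and CDS coordinates used by splice and frameshift
#' classification. Coordinates are 1-based inclusive genomic
#' intervals; exons must be non-overlapping and ordered by start. A
#' coding-sequence length not divisible by 3 is tolerated (truncated
#' annotations occur) but recorded as a warning.
#'
#' @param transcript_id Transcript identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons List of `c(start, end)` integer pairs.
#' @param cds List parallel to `exons`: `c(start, end)` coding
#'   subinterval, or `NULL` for UTR-only exons.
#' @param cds_sequence Optional coding nucleotide string.
#' @return A list with class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, strand = "+", exons,
                             cds = NULL, cds_sequence = NA_character_) {
  stopifnot(strand %in% c("+", "-"), length(exons) >= 1L)
  starts <- vapply(exons, `[`, numeric(1), 1L)
  ends <- vapply(exons, `[`, numeric(1), 2L)
  if (any(starts > ends)) stop("exon start beyond exon end")
  if (is.unsorted(starts, strictly = TRUE) ||
      any(starts[-1L] <= ends[-length(ends)])) {
    stop("exons must be ordered and non-overlapping")
  }
  if (is.null(cds)) cds <- vector("list", length(exons))
  if (length(cds) != length(exons)) {
    stop("cds list must parallel the exon list")
  }
  if (!is.na(cds_sequence) && nchar(cds_sequence) %% 3L != 0L) {
    warning("cds_sequence length not divisible by 3 ",
            "(truncated annotation?)")
  }
  structure(list(transcript_id = transcript_id, strand = strand,
                 exons = exons, cds = cds,
                 cds_sequence = cds_sequence),
            class = "transcript_model")
}

#' Construct a gene candidate
#'
#' A gene plus the recessive genotype(s) and filter provenance that
#' implicated it.
#'
#' @param gene Gene symbol.
#' @param mode `"homozygous"` or `"compound_het"`.
#' @param variants Variant table rows implicating the gene: 1 row for
#'   homozygous, 2 rows (same transcript) for compound het.
#' @param carriers Character vector of carrier sample ids.
#' @param filter_trail Data frame with columns `filter` and `status`
#'   (`"pass"`, `"fail"` or `"exception"`); never empty.
#' @param status Candidate status: `"confirmed"`, `"putative"` or
#'   `"needs_review"`.
#' @return A list with class `gene_candidate`.
#' @export
gene_candidate <- function(gene, mode, variants, carriers, filter_trail,
                           status = "confirmed") {
  stopifnot(mode %in% c("homozygous", "compound_het"))
  n_expected <- if (mode == "homozygous") 1L else 2L
  if (nrow(variants) != n_expected) {
    stop(mode, " candidate must carry exactly ", n_expected,
         " variant(s)")
  }
  if (mode == "compound_het" &&
      length(unique(variants$transcript_id)) != 1L) {
    stop("compound-het variants must share a transcript")
  }
  if (nrow(filter_trail) == 0L) stop("filter trail must not be empty")
  structure(list(gene = gene, mode = mode, variants = variants,
                 carriers = carriers, filter_trail = filter_trail,
                 status = status),
            class = "gene_candidate")
}

parse_dot <- function(x, as = as.numeric) {
  x[x %in% c(".", "", "NA")] <- NA
  as(x)
}

#' Read an annotated cohort (variant table + genotypes)
#'
#' The variant table may be the canonical TSV (fixed header, `.` for
#' missing values) or a VCF 4.x file (extension `.vcf`; biallelic
#' records only, annotations read from INFO keys named as in the TSV
#' header). Genotypes are a TSV with columns `sample_id`, `phenotype`,
#' then one column per variant key holding codes 0/1/2 or `.`.
#'
#' @param variant_path Path to the variant table.
#' @param genotype_path Path to the genotype table.
#' @param phase_path Optional path to a phase-annotation TSV
#'   (`sample_id`, `key_a`, `key_b`, `phase`).
#' @return A list with elements `variants` (validated data frame) and
#'   `genotypes` ([cohort_genotypes()]).
#' @export
read_annotated_cohort <- function(variant_path, genotype_path,
                                  phase_path = NULL) {
  if (!file.exists(variant_path)) stop("no such file: ", variant_path)
  if (!file.exists(genotype_path)) stop("no such file: ", genotype_path)
  variants <- if (grepl("\\.vcf(\\.gz)?$", variant_path)) {
    read_variant_vcf(variant_path)
  } else {
    read_variant_tsv(variant_path)
  }
  validate_variants(variants)

  gt <- utils::read.delim(genotype_path, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("sample_id", "phenotype") %in% names(gt))) {
    stop("genotype table must declare sample_id and phenotype columns")
  }
  keys <- setdiff(names(gt), c("sample_id", "phenotype"))
  vkeys <- variant_key(variants)
  if (!setequal(keys, vkeys)) {
    stop("sample/variant mismatch between files: genotype columns do ",
         "not match the variant table keys")
  }
  gmat <- t(vapply(keys, function(k) {
    col <- gt[[k]]
    col[col == "."] <- NA
    v <- suppressWarnings(as.integer(col))
    if (any(!is.na(col) & is.na(v))) {
      stop("malformed genotype code in column ", k)
    }
    v
  }, integer(nrow(gt))))
  rownames(gmat) <- keys
  gmat <- gmat[vkeys, , drop = FALSE]

  phase <- NULL
  if (!is.null(phase_path)) {
    phase <- utils::read.delim(phase_path, colClasses = "character")
  }
  genotypes <- cohort_genotypes(gt$sample_id, gt$phenotype, gmat, phase)
  message("read ", nrow(variants), " variant records and ",
          nrow(gt), " samples")
  list(variants = variants, genotypes = genotypes)
}

read_variant_tsv <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  n <- nrow(raw)
  out <- data.frame(
    gene = raw$gene,
    chrom = raw$chrom,
    pos = parse_dot(raw$pos, as.integer),
    ref = raw$ref, alt = raw$alt,
    rsid = parse_dot(raw$rsid, as.character),
    effect_class = raw$effect_class,
    transcript_id = parse_dot(raw$transcript_id, as.character),
    aa_change = parse_dot(raw$aa_change, as.character),
    cadd = parse_dot(raw$cadd),
    maf_esp6500_ea = parse_dot(raw$maf_esp6500_ea),
    maf_kg_eur = parse_dot(raw$maf_kg_eur),
    maf_exac_nfe = parse_dot(raw$maf_exac_nfe),
    stringsAsFactors = FALSE
  )
  # optional columns are preserved when present
  for (col in c("hom_ref_count", "hom_ref_n")) {
    out[[col]] <- if (col %in% names(raw)) {
      parse_dot(raw[[col]], as.integer)
    } else {
      rep(NA_integer_, n)
    }
  }
  for (col in c("immediate_stop", "splice_coding_2bp", "vqsr_pass")) {
    if (col %in% names(raw)) {
      out[[col]] <- parse_dot(raw[[col]], as.logical)
    }
  }
  for (col in setdiff(names(raw), c(names(out), "mode"))) {
    out[[col]] <- raw[[col]]  # unknown annotations kept as opaque extras
  }
  if ("mode" %in% names(raw)) out$mode <- raw$mode
  if (any(is.na(out$pos))) {
    stop("malformed coordinate at line ",
         which(is.na(out$pos))[1L] + 1L)
  }
  out
}

read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic rows must be pre-split into biallelic records")
  }
  info_get <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else x
  }
  data.frame(
    gene = info_get("GENE"),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    rsid = ifelse(fix$ID %in% c(".", ""), NA_character_, fix$ID),
    effect_class = info_get("EFFECT"),
    transcript_id = info_get("TRANSCRIPT"),
    aa_change = info_get("AACHANGE"),
    cadd = parse_dot(info_get("CADD")),
    maf_esp6500_ea = parse_dot(info_get("MAF_ESP6500_EA")),
    maf_kg_eur = parse_dot(info_get("MAF_KG_EUR")),
    maf_exac_nfe = parse_dot(info_get("MAF_EXAC_NFE")),
    hom_ref_count = parse_dot(info_get("HOM_REF_COUNT"), as.integer),
    hom_ref_n = parse_dot(info_get("HOM_REF_N"), as.integer),
    stringsAsFactors = FALSE
  )
}

#' Write cohort variants + genotypes in the canonical TSV dialect
#'
#' Inverse of [read_annotated_cohort()]; `read(write(x))` reproduces
#' the input field-for-field.
#'
#' @param variants Variant table.
#' @param genotypes A [cohort_genotypes()] object.
#' @param variant_path,genotype_path,phase_path Output paths
#'   (`phase_path` only written when phase annotations are present).
#' @return Invisibly, the paths written.
#' @export
write_annotated_cohort <- function(variants, genotypes, variant_path,
                                   genotype_path, phase_path = NULL) {
  validate_variants(variants)
  fmt <- as.data.frame(lapply(variants, function(col) {
    out <- as.character(col)
    out[is.na(out)] <- "."
    out
  }), stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(fmt, variant_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- t(genotypes$geno)
  gdf <- data.frame(sample_id = genotypes$samples$sample_id,
                    phenotype = genotypes$samples$phenotype,
                    stringsAsFactors = FALSE)
  for (k in colnames(g)) {
    col <- as.character(g[, k])
    col[is.na(col)] <- "."
    gdf[[k]] <- col
  }
  utils::write.table(gdf, genotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(genotypes$phase) && !is.null(phase_path)) {
    utils::write.table(genotypes$phase, phase_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(variant_path, genotype_path))
}

#' Write a candidate-gene report
#'
#' One row per candidate, with columns mirroring the published variant
#' table (gene, type HZ/CH, chr:bp, alleles, effect, MAF, CADD) plus
#' the carrier list and serialized filter trail. [read_candidate_report()]
#' reconstructs the candidate list.
#'
#' @param candidates List of [gene_candidate()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidate_report <- function(candidates, path) {
  rows <- lapply(candidates, function(cand) {
    v <- cand$variants
    data.frame(
      gene = cand$gene,
      type = if (cand$mode == "homozygous") "HZ" else "CH",
      status = cand$status,
      chr_bp = paste(paste0(v$chrom, ":", v$pos), collapse = ";"),
      alleles = paste(paste0(v$ref, "/", v$alt), collapse = ";"),
      effect = paste(v$effect_class, collapse = ";"),
      transcript = paste(v$transcript_id, collapse = ";"),
      aa_change = paste(ifelse(is.na(v$aa_change), ".", v$aa_change),
                        collapse = ";"),
      maf_exac_nfe = paste(ifelse(is.na(v$maf_exac_nfe), ".",
                                  v$maf_exac_nfe), collapse = ";"),
      cadd = paste(ifelse(is.na(v$cadd), ".", v$cadd), collapse = ";"),
      carriers = paste(cand$carriers, collapse = ";"),
      filter_trail = paste(paste0(cand$filter_trail$filter, ":",
                                  cand$filter_trail$status),
                           collapse = "|"),
      stringsAsFactors = FALSE
    )
  })
  header <- c("gene", "type", "status", "chr_bp", "alleles", "effect",
              "transcript", "aa_change", "maf_exac_nfe", "cadd",
              "carriers", "filter_trail")
  out <- if (length(rows) == 0L) {
    as.data.frame(setNames(rep(list(character(0)), length(header)),
                           header), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a candidate-gene report
#'
#' @param path Report TSV written by [write_candidate_report()].
#' @return A list of [gene_candidate()] objects.
#' @export
read_candidate_report <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character")
  lapply(seq_len(nrow(raw)), function(i) {
    row <- raw[i, ]
    split1 <- function(x) strsplit(x, ";", fixed = TRUE)[[1L]]
    chrbp <- strsplit(split1(row$chr_bp), ":", fixed = TRUE)
    alleles <- strsplit(split1(row$alleles), "/", fixed = TRUE)
    v <- data.frame(
      gene = row$gene,
      chrom = vapply(chrbp, `[`, character(1), 1L),
      pos = as.integer(vapply(chrbp, `[`, character(1), 2L)),
      ref = vapply(alleles, `[`, character(1), 1L),
      alt = vapply(alleles, `[`, character(1), 2L),
      rsid = NA_character_,
      effect_class = split1(row$effect),
      transcript_id = split1(row$transcript),
      aa_change = parse_dot(split1(row$aa_change), as.character),
      cadd = parse_dot(split1(row$cadd)),
      maf_esp6500_ea = NA_real_, maf_kg_eur = NA_real_,
      maf_exac_nfe = parse_dot(split1(row$maf_exac_nfe)),
      stringsAsFactors = FALSE
    )
    trail_parts <- strsplit(strsplit(row$filter_trail, "|",
                                     fixed = TRUE)[[1L]],
                            ":", fixed = TRUE)
    trail <- data.frame(
      filter = vapply(trail_parts, `[`, character(1), 1L),
      status = vapply(trail_parts, `[`, character(1), 2L),
      stringsAsFactors = FALSE
    )
    gene_candidate(
      gene = row$gene,
      mode = if (row$type == "HZ") "homozygous" else "compound_het",
      variants = v,
      carriers = split1(row$carriers),
      filter_trail = trail,
      status = row$status
    )
  })
}
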