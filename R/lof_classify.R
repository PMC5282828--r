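#' @title Loss-of-function classification
#' @name lof_classify
#' @description
#' Decides whether a variant is loss-of-function (LoF): SNVs affecting
#' the position of the stop codon (stopgain/stoploss), frameshift
#' indels that create an immediate stop codon at the position of the
#' indel, and intronic variants within 2 bp of a splice junction
#' adjacent to a coding exon. Annotator-supplied effect classes for
#' SNVs are taken at face value; the frameshift and splice rules are
#' recomputed here.
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

LOF_REASONS <- c("stopgain", "stoploss", "frameshift_immediate_stop",
                 "splice_2bp_coding", "not_lof")

effect_call <- function(reason, detail = NA_character_) {
  stopifnot(reason %in% LOF_REASONS)
  list(is_lof = reason != "not_lof", reason = reason, detail = detail)
}

#' Classify a stop-codon-affecting SNV
#'
#' Stopgain and stoploss effect classes are LoF; everything else
#' (missense, synonymous/other) is not.
#'
#' @param record A [variant_record()] row (or any data frame row with
#'   an `effect_class` field).
#' @return An effect call: list with `is_lof`, `reason`, `detail`.
#' @export
classify_stop_variant <- function(record) {
  ec <- record$effect_class
  stopifnot(length(ec) == 1L)
  if (ec %in% c("stopgain", "stoploss")) {
    effect_call(ec, detail = record$aa_change)
  } else {
    effect_call("not_lof")
  }
}

#' Classify a frameshift indel by the immediate-stop rule
#'
#' Applies the edit to the coding sequence and asks whether the codon
#' containing the first edited base becomes a stop codon (TAA/TAG/TGA)
#' in the shifted frame. Only such "immediate stop at the position of
#' the indel" frameshifts count as LoF; in-frame indels (length
#' difference divisible by 3) never do. The edit is anchored at
#' `cds_offset`: the reference allele (possibly empty for a pure
#' insertion) starts at that 0-based offset and is replaced by the
#' alternate allele.
#'
#' @param cds_sequence Coding nucleotide string (A/C/G/T).
#' @param cds_offset 0-based offset into the coding sequence where the
#'   edit applies.
#' @param ref Reference allele within the CDS (may be `""`).
#' @param alt Alternate allele.
#' @return An effect call; `reason` is `"frameshift_immediate_stop"`
#'   when LoF.
#' @export
classify_frameshift <- function(cds_sequence, cds_offset, ref, alt) {
  cds_sequence <- toupper(cds_sequence)
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (grepl("[^ACGT]", cds_sequence) ||
      (nchar(ref) > 0L && grepl("[^ACGT]", ref)) ||
      (nchar(alt) > 0L && grepl("[^ACGT]", alt))) {
    stop("non-ACGT characters in sequence or alleles")
  }
  n <- nchar(cds_sequence)
  if (cds_offset < 0L || cds_offset + nchar(ref) > n) {
    stop("cds_offset out of range for the coding sequence")
  }
  if (nchar(ref) == nchar(alt)) {
    stop("classify_frameshift expects an indel (length(ref) != length(alt))")
  }
  if (nchar(ref) > 0L &&
      substr(cds_sequence, cds_offset + 1L,
             cds_offset + nchar(ref)) != ref) {
    stop("reference allele does not match the coding sequence at offset ",
         cds_offset)
  }
  if (abs(nchar(alt) - nchar(ref)) %% 3L == 0L) {
    return(effect_call("not_lof", detail = "in-frame indel"))
  }
  edited <- paste0(substr(cds_sequence, 1L, cds_offset), alt,
                   substr(cds_sequence, cds_offset + nchar(ref) + 1L, n))
  # first affected codon: the codon containing the first edited base
  codon_idx <- cds_offset %/% 3L
  codon <- substr(edited, 3L * codon_idx + 1L, 3L * codon_idx + 3L)
  if (nchar(codon) == 3L && codon %in% STOP_CODONS) {
    effect_call("frameshift_immediate_stop",
                detail = paste0("codon ", codon_idx + 1L, " -> ", codon))
  } else {
    effect_call("not_lof",
                detail = paste0("first affected codon ", codon,
                                " is not a stop"))
  }
}

#' Classify a splice-site variant
#'
#' LoF iff the variant lies in the intron within 2 bp of an exon
#' boundary (donor +1/+2 or acceptor -1/-2, inclusive 1-based exon
#' ends) and the adjacent exon carries a non-empty coding subinterval.
#' Variants 3+ bp into the intron, exonic positions, or junctions of
#' UTR-only exons are not LoF.
#'
#' @param record A variant record (uses `pos`).
#' @param transcript A [transcript_model()] with >= 2 exons.
#' @return An effect call; `reason` is `"splice_2bp_coding"` when LoF.
#' @export
classify_splice <- function(record, transcript) {
  stopifnot(inherits(transcript, "transcript_model"))
  exons <- transcript$exons
  if (length(exons) < 2L) {
    stop("splice classification needs a multi-exon transcript")
  }
  pos <- record$pos
  span <- c(exons[[1L]][1L] - 2L, exons[[length(exons)]][2L] + 2L)
  if (pos < span[1L] || pos > span[2L]) {
    stop("variant position ", pos, " outside the transcript span")
  }
  in_exon <- any(vapply(exons, function(e) {
    pos >= e[1L] && pos <= e[2L]
  }, logical(1)))
  if (in_exon) {
    return(effect_call("not_lof", detail = "exonic position"))
  }
  for (i in seq_along(exons)) {
    e <- exons[[i]]
    coding <- !is.null(transcript$cds[[i]])
    near <- (pos >= e[1L] - 2L && pos <= e[1L] - 1L) ||
      (pos >= e[2L] + 1L && pos <= e[2L] + 2L)
    if (near) {
      if (coding) {
        side <- if (pos < e[1L]) "acceptor" else "donor"
        dist <- if (pos < e[1L]) e[1L] - pos else pos - e[2L]
        return(effect_call("splice_2bp_coding",
                           detail = paste0(side, " ", dist,
                                           " bp from junction")))
      }
      return(effect_call("not_lof", detail = "adjacent exon is UTR-only"))
    }
  }
  effect_call("not_lof", detail = "intronic, > 2 bp from any junction")
}

#' Attach LoF calls to a variant table
#'
#' Applies the three classification rules row-wise and adds `is_lof`
#' and `lof_reason` columns. Stop-affecting SNVs are classified from
#' the annotated effect class. Frameshift and splice variants are
#' classified from a supplied [transcript_model()] where one is
#' available for the variant's transcript; otherwise the table's own
#' evidence flags (`immediate_stop`, `splice_coding_2bp`) are used, so
#' that annotator-verified calls can drive the cascade when sequence
#' models are not distributed with the variant table.
#'
#' @param variants Variant table.
#' @param transcripts Optional named list of [transcript_model()]
#'   objects keyed by `transcript_id`. For frameshift classification a
#'   model must carry `cds_sequence`; the CDS offset is then looked up
#'   from an optional `cds_offset` column in the table.
#' @return `variants` with `is_lof` (logical) and `lof_reason`
#'   (character) columns.
#' @export
attach_lof_calls <- function(variants, transcripts = NULL) {
  n <- nrow(variants)
  is_lof <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    rec <- variants[i, ]
    call <- switch(
      rec$effect_class,
      stopgain = ,
      stoploss = classify_stop_variant(rec),
      frameshift = {
        tx <- transcripts[[rec$transcript_id]]
        if (!is.null(tx) && !is.na(tx$cds_sequence) &&
            "cds_offset" %in% names(variants) &&
            !is.na(rec$cds_offset)) {
          classify_frameshift(tx$cds_sequence, rec$cds_offset,
                              rec$ref, rec$alt)
        } else if ("immediate_stop" %in% names(variants) &&
                   isTRUE(rec$immediate_stop)) {
          effect_call("frameshift_immediate_stop",
                      detail = "annotated immediate stop")
        } else {
          effect_call("not_lof")
        }
      },
      splice = {
        tx <- transcripts[[rec$transcript_id]]
        if (!is.null(tx)) {
          classify_splice(rec, tx)
        } else if ("splice_coding_2bp" %in% names(variants) &&
                   isTRUE(rec$splice_coding_2bp)) {
          effect_call("splice_2bp_coding",
                      detail = "annotated near-junction coding splice")
        } else {
          effect_call("not_lof")
        }
      },
      effect_call("not_lof")
    )
    is_lof[i] <- call$is_lof
    reason[i] <- call$reason
  }
  variants$is_lof <- is_lof
  variants$lof_reason <- reason
  variants
}
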