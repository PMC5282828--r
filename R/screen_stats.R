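#' @title High-content RNAi screen statistics
#' @name screen_stats
#' @description
#' Per-well summarization with cell-level QC, Parkin-translocation
#' ratios, per-plate normalization to scrambled-sequence negative
#' controls, robust SSMD effect sizes with the two-clone hit rule,
#' Mann-Whitney tests with Benjamini-Hochberg FDR correction, and the
#' robust Z'-factor assay-quality statistic.
NULL

MAD_CONSISTENCY <- 1.4826  # normal-consistency constant for the MAD

raw_mad <- function(x) stats::mad(x, constant = 1)

SCREEN_PARAMETERS <- c("mito_count", "axial_length_ratio", "roundness",
                       "cmxros_intensity")

#' QC-filter cells and summarize a well
#'
#' Keeps only well-segmented, in-focus interphase cells away from the
#' image border, then takes the per-well median of each morphology
#' parameter. Wells where the perturbation strongly decreased cell
#' number (fewer than `min_cells` passing cells) are marked invalid.
#'
#' @param cells Data frame of per-cell features with QC flag columns
#'   `interphase`, `in_focus`, `well_segmented`, `border` (logical)
#'   and measurement columns among
#'   `r paste(SCREEN_PARAMETERS, collapse = ", ")`.
#' @param min_cells Validity floor on the post-QC cell count
#'   (default 50).
#' @return One-row data frame: well medians per parameter, `n_cells`,
#'   `valid`.
#' @export
qc_and_summarize <- function(cells, min_cells = 50) {
  stopifnot(is.data.frame(cells))
  pass <- rep(TRUE, nrow(cells))
  if ("interphase" %in% names(cells)) pass <- pass & cells$interphase
  if ("in_focus" %in% names(cells)) pass <- pass & cells$in_focus
  if ("well_segmented" %in% names(cells)) {
    pass <- pass & cells$well_segmented
  }
  if ("border" %in% names(cells)) pass <- pass & !cells$border
  kept <- cells[pass, , drop = FALSE]
  params <- intersect(SCREEN_PARAMETERS, names(cells))
  out <- data.frame(n_cells = nrow(kept),
                    valid = nrow(kept) >= min_cells)
  for (p in params) {
    out[[p]] <- if (nrow(kept) == 0L) NA_real_ else
      stats::median(kept[[p]], na.rm = TRUE)
  }
  out
}

#' Parkin translocation ratio for one well
#'
#' A cell is positive for translocation iff it contains strictly more
#' than two Parkin-GFP spots; the well statistic is the ratio of
#' positive to negative cells. With zero negative cells a 0.5
#' continuity offset is added to both counts and the result flagged.
#'
#' @param cells Data frame with a `spot_count` column (spots per
#'   cell).
#' @return List with `ratio`, `n_positive`, `n_negative`,
#'   `continuity_corrected`.
#' @export
translocation_ratio <- function(cells) {
  stopifnot("spot_count" %in% names(cells))
  spots <- cells$spot_count[!is.na(cells$spot_count)]
  pos <- sum(spots > 2)
  neg <- length(spots) - pos
  if (neg == 0L) {
    list(ratio = (pos + 0.5) / (neg + 0.5), n_positive = pos,
         n_negative = neg, continuity_corrected = TRUE)
  } else {
    list(ratio = pos / neg, n_positive = pos, n_negative = neg,
         continuity_corrected = FALSE)
  }
}

#' Normalize well values to per-plate negative controls
#'
#' Divides every valid well's value by the median of the valid
#' negative-control well values on its plate, so negative controls
#' centre on 1 by construction and plate-to-plate offsets cancel.
#'
#' @param wells Data frame with columns `plate`, `well`, `role`
#'   (`"sample"`, `"neg_control"`, `"pos_control"`), `value`, and
#'   optionally `valid` (defaults to all valid).
#' @return `wells` with a `normalized` column added.
#' @export
normalize_plate <- function(wells) {
  stopifnot(all(c("plate", "role", "value") %in% names(wells)))
  if (!"valid" %in% names(wells)) wells$valid <- TRUE
  wells$normalized <- NA_real_
  for (p in unique(wells$plate)) {
    on_plate <- wells$plate == p
    negs <- wells$value[on_plate & wells$role == "neg_control" &
                          wells$valid]
    if (length(negs) == 0L) {
      stop("plate ", p, " has no valid negative-control well")
    }
    centre <- stats::median(negs)
    idx <- on_plate & wells$valid
    wells$normalized[idx] <- wells$value[idx] / centre
  }
  wells
}

#' Robust strictly standardized median difference (SSMD*)
#'
#' `(median_t - median_c) / (1.4826 * sqrt(MAD_t^2 + MAD_c^2))` with
#' the raw (constant-free) median absolute deviation; the 1.4826
#' factor makes the denominator consistent for normal spread. The sign
#' preserves the direction of the effect. When both MADs are zero, the
#' value is 0 for equal medians and signed infinity otherwise.
#'
#' @param treatment,negctrl Replicate values (>= 2 each; the screens
#'   run 6 replicates per shRNA clone).
#' @return SSMD* value (possibly `Inf`/`-Inf`).
#' @export
robust_ssmd <- function(treatment, negctrl) {
  stopifnot(length(treatment) >= 2L, length(negctrl) >= 2L)
  dmed <- stats::median(treatment) - stats::median(negctrl)
  spread <- MAD_CONSISTENCY *
    sqrt(raw_mad(treatment)^2 + raw_mad(negctrl)^2)
  if (spread == 0) {
    if (dmed == 0) 0 else sign(dmed) * Inf
  } else {
    dmed / spread
  }
}

#' Robust Z'-factor
#'
#' Assay-quality statistic from positive/negative control separation:
#' `1 - 3 (1.4826 MAD_pos + 1.4826 MAD_neg) / |median_pos -
#' median_neg|`. Undefined (NA) when the control medians coincide.
#'
#' @param pos,neg Control values (>= 2 each).
#' @return Z' value, or `NA` when undefined.
#' @export
robust_zprime <- function(pos, neg) {
  stopifnot(length(pos) >= 2L, length(neg) >= 2L)
  sep <- abs(stats::median(pos) - stats::median(neg))
  if (sep == 0) return(NA_real_)
  1 - 3 * MAD_CONSISTENCY * (raw_mad(pos) + raw_mad(neg)) / sep
}

#' Mann-Whitney p-value for one clone against negative controls
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test; exact where the
#' sample sizes allow it.
#'
#' @param treatment,negctrl Replicate values.
#' @return Two-sided p-value.
#' @export
mann_whitney_p <- function(treatment, negctrl) {
  suppressWarnings(
    stats::wilcox.test(treatment, negctrl, exact = NULL)$p.value
  )
}

#' Gene-level hit calling with the two-clone rule
#'
#' A clone is significant iff |SSMD*| strictly exceeds `ssmd_cutoff`
#' and its FDR-adjusted (Benjamini-Hochberg, across all clones)
#' Mann-Whitney p-value is below `fdr_alpha`; under
#' `hit_rule = "ssmd_only"` the FDR condition is dropped. A gene is a
#' hit iff at least two independent clones are significant. Genes
#' whose significant clones all share an identical 7-mer seed
#' (positions 2-8 of the guide sequence, when sequences are supplied)
#' are flagged seed-confounded.
#'
#' @param clones Data frame with columns `gene`, `clone`, `ssmd`,
#'   `mw_p`, and optionally `guide_seq`.
#' @param fdr_alpha FDR level (default 0.05).
#' @param ssmd_cutoff Strict |SSMD*| threshold (default 4).
#' @param hit_rule `"both"` (SSMD and FDR, the default) or
#'   `"ssmd_only"`.
#' @return Data frame: `gene`, `n_clones`, `n_significant`, `hit`,
#'   `seed_confounded`.
#' @export
call_hits <- function(clones, fdr_alpha = 0.05, ssmd_cutoff = 4,
                      hit_rule = c("both", "ssmd_only")) {
  hit_rule <- match.arg(hit_rule)
  stopifnot(all(c("gene", "clone", "ssmd", "mw_p") %in% names(clones)))
  clones$fdr_p <- stats::p.adjust(clones$mw_p, method = "BH")
  sig <- abs(clones$ssmd) > ssmd_cutoff
  if (hit_rule == "both") sig <- sig & clones$fdr_p < fdr_alpha
  clones$significant <- sig

  genes <- unique(clones$gene)
  out <- do.call(rbind, lapply(genes, function(g) {
    cl <- clones[clones$gene == g, , drop = FALSE]
    nsig <- sum(cl$significant)
    confounded <- FALSE
    if ("guide_seq" %in% names(cl) && nsig >= 2L) {
      seeds <- substr(cl$guide_seq[cl$significant], 2L, 8L)
      confounded <- length(unique(seeds)) == 1L
    }
    data.frame(gene = g, n_clones = nrow(cl), n_significant = nsig,
               hit = nsig >= 2L, seed_confounded = confounded,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
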