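#' @title Gene-level rare-variant aggregation tests
#' @name burden
#' @description
#' One-sided burden and two-sided variance-component (SKAT-style)
#' score statistics per gene, with covariate adjustment and empirical
#' p-values from permutation of affection status. Inference rests
#' entirely on the permutation null; no analytic mixture-of-chi-square
#' approximations are used.
NULL

#' Sample-size-based rare/common MAF cutoff
#'
#' The boundary separating rare from common variants in the
#' aggregation tests, `1 / sqrt(2 n)`, reported at two significant
#' figures.
#'
#' @param n_samples Total post-QC sample count (cases + controls).
#' @param digits Significant figures for reporting (default 2).
#' @return The cutoff frequency.
#' @export
maf_cutoff_from_n <- function(n_samples, digits = 2) {
  if (!is.numeric(n_samples) || n_samples < 2) {
    stop("n_samples must be a count >= 2")
  }
  signif(1 / sqrt(2 * n_samples), digits)
}

#' Burden test design
#'
#' @param phenotype Numeric vector, case = 1 / control = 0.
#' @param covariates Optional numeric matrix (e.g. principal
#'   components, mean coverage, sex), one row per sample.
#' @param variant_class `"deleterious"` (LoF plus missense with CADD >
#'   20) or `"missense"` (all amino-acid-changing variants plus LoF).
#' @param maf_cutoff Rare/common boundary (see [maf_cutoff_from_n()]).
#' @param rare_only If `TRUE`, test rare variants only; if `FALSE`,
#'   combine rare and common components (see `mix`).
#' @param permutations Number of phenotype permutations (default
#'   10000).
#' @param weights `"beta"` for Beta(1,25)-density-based variant
#'   weights (squared density, the variance-component convention) or
#'   `"uniform"`.
#' @param mix Mixing weight for the combined rare+common statistic
#'   (default 0.5; applied to the rare component).
#' @return A list with class `burden_design`.
#' @export
burden_design <- function(phenotype, covariates = NULL,
                          variant_class = c("deleterious", "missense"),
                          maf_cutoff = NULL, rare_only = TRUE,
                          permutations = 10000,
                          weights = c("beta", "uniform"), mix = 0.5) {
  variant_class <- match.arg(variant_class)
  weights <- match.arg(weights)
  stopifnot(all(phenotype %in% c(0, 1)), permutations >= 1,
            mix >= 0, mix <= 1)
  if (is.null(maf_cutoff)) {
    maf_cutoff <- maf_cutoff_from_n(length(phenotype))
  }
  stopifnot(maf_cutoff > 0, maf_cutoff < 0.5)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(phenotype))
  }
  structure(list(phenotype = phenotype, covariates = covariates,
                 variant_class = variant_class,
                 maf_cutoff = maf_cutoff, rare_only = rare_only,
                 permutations = as.integer(permutations),
                 weights = weights, mix = mix),
            class = "burden_design")
}

# residual-maker for the null model phenotype ~ covariates (+ intercept)
null_qr <- function(design) {
  X <- cbind(rep(1, length(design$phenotype)), design$covariates)
  qr(X)
}

null_residuals <- function(design, y = design$phenotype) {
  qr.resid(null_qr(design), y)
}

sample_maf <- function(G) {
  freq <- colMeans(G, na.rm = TRUE) / 2
  pmin(freq, 1 - freq)
}

select_qualifying <- function(G, design) {
  maf <- sample_maf(G)
  if (design$rare_only) {
    G[, maf > 0 & maf <= design$maf_cutoff, drop = FALSE]
  } else {
    G[, maf > 0, drop = FALSE]
  }
}

variant_weights <- function(maf, weights) {
  if (weights == "uniform") rep(1, length(maf))
  else stats::dbeta(maf, 1, 25)^2
}

#' Select variants for a burden class
#'
#' `"deleterious"`: LoF variants plus missense variants with CADD >
#' 20. `"missense"`: all amino-acid-changing variants (missense and
#' LoF classes).
#'
#' @param variants Variant table with `is_lof` attached.
#' @param variant_class Class name.
#' @return Logical vector of qualifying rows.
#' @export
select_burden_variants <- function(variants,
                                   variant_class = c("deleterious",
                                                     "missense")) {
  variant_class <- match.arg(variant_class)
  lof <- if ("is_lof" %in% names(variants)) variants$is_lof else
    variants$effect_class %in% c("stopgain", "stoploss", "frameshift",
                                 "splice")
  if (variant_class == "deleterious") {
    lof | (variants$effect_class == "missense" &
             !is.na(variants$cadd) & variants$cadd > 20)
  } else {
    lof | variants$effect_class == "missense"
  }
}

#' One-sided burden score statistic for one gene
#'
#' Collapses qualifying rare-variant counts into a per-sample burden
#' score, adjusts score and phenotype for covariates, and returns the
#' standardized score statistic; positive values mean excess burden in
#' cases.
#'
#' @param G Genotype matrix for one gene, samples in rows, variants in
#'   columns (alternate-allele counts).
#' @param design A [burden_design()].
#' @return The statistic, or `NA` with attribute `untestable = TRUE`
#'   when no variant qualifies.
#' @export
burden_statistic <- function(G, design) {
  G <- as.matrix(G)
  G[is.na(G)] <- 0
  Gq <- select_qualifying(G, design)
  if (ncol(Gq) == 0L) {
    return(structure(NA_real_, untestable = TRUE))
  }
  s <- rowSums(Gq)
  qrX <- null_qr(design)
  r <- qr.resid(qrX, design$phenotype)
  sc <- qr.resid(qrX, s)
  denom <- sqrt(sum(sc^2) * mean(r^2))
  if (denom == 0) return(0)
  sum(sc * r) / denom
}

#' Variance-component (SKAT-style) statistic for one gene
#'
#' The quadratic-form score statistic `Q = r' G W G' r`, with `r` the
#' covariate-adjusted phenotype residuals and `W` diagonal MAF-based
#' weights. With `rare_only = FALSE` the statistic is a mixture
#' `mix * Q_rare + (1 - mix) * Q_common` over the rare/common split at
#' `maf_cutoff`, each component scaled by its number of variants so
#' neither side dominates by dimension alone. Calibration is by
#' permutation (see [empirical_pvalue()]).
#'
#' @inheritParams burden_statistic
#' @return The statistic `Q >= 0`, or `NA` with attribute
#'   `untestable = TRUE`.
#' @export
skat_statistic <- function(G, design) {
  G <- as.matrix(G)
  G[is.na(G)] <- 0
  r <- null_residuals(design)
  q_part <- function(Gp) {
    if (ncol(Gp) == 0L) return(NA_real_)
    w <- variant_weights(sample_maf(Gp), design$weights)
    sum(w * as.vector(crossprod(Gp, r))^2) / ncol(Gp)
  }
  if (ncol(G) == 0L) return(structure(NA_real_, untestable = TRUE))
  maf <- sample_maf(G)
  if (all(maf == 0)) return(0)  # variants supplied but no signal
  G <- G[, maf > 0, drop = FALSE]
  maf <- maf[maf > 0]
  rare <- maf <= design$maf_cutoff
  if (design$rare_only) {
    q <- q_part(G[, rare, drop = FALSE])
    if (is.na(q)) return(structure(NA_real_, untestable = TRUE))
    return(q)
  }
  qr_ <- q_part(G[, rare, drop = FALSE])
  qc_ <- q_part(G[, !rare, drop = FALSE])
  if (is.na(qr_) && is.na(qc_)) {
    return(structure(NA_real_, untestable = TRUE))
  }
  design$mix * ifelse(is.na(qr_), 0, qr_) +
    (1 - design$mix) * ifelse(is.na(qc_), 0, qc_)
}

#' Permutation p-value estimator
#'
#' `p = (1 + #\{permuted >= observed\}) / (1 + B)`. Ties count
#' against the observed value (conservative), so the estimate lies in
#' `[1/(B+1), 1]` and is invariant to any strictly monotone transform
#' applied to both the observed and permuted statistics.
#'
#' @param observed Observed statistic.
#' @param perm Vector of permuted statistics.
#' @return The empirical p-value.
#' @export
perm_pvalue <- function(observed, perm) {
  (1 + sum(perm >= observed, na.rm = TRUE)) / (1 + length(perm))
}

#' Empirical p-value by permutation of affection status
#'
#' `p = (1 + #\{permuted >= observed\}) / (1 + B)`: phenotype labels
#' are shuffled while covariates stay attached to their samples, the
#' statistic is recomputed under each shuffle, and ties count against
#' the observed value (conservative). Deterministic given `seed`.
#'
#' @param observed Observed statistic.
#' @param G Genotype matrix for the gene (samples x variants).
#' @param design A [burden_design()]; `design$permutations` sets `B`.
#' @param seed Integer seed for the permutation stream.
#' @param statistic `"burden"` or `"skat"`.
#' @return Empirical p-value in `[1/(B+1), 1]`.
#' @export
empirical_pvalue <- function(observed, G, design, seed,
                             statistic = c("burden", "skat")) {
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "burden") burden_statistic else
    skat_statistic
  B <- design$permutations
  perm <- numeric(B)
  set.seed(seed)
  for (b in seq_len(B)) {
    d <- design
    d$phenotype <- sample(design$phenotype)
    perm[b] <- stat_fun(G, d)
  }
  perm_pvalue(observed, perm)
}

#' Run the aggregation analysis over a gene list
#'
#' One row per gene x class x (rare-only / joint) combination, with
#' both the one-sided burden and the variance-component statistic and
#' their permutation p-values. All genes share a single permutation
#' stream (drawn once from `seed`), which keeps the run fast and the
#' per-gene nulls exchangeable.
#'
#' @param geno Genotype matrix, samples in rows, variants in columns
#'   (column names are variant keys).
#' @param variants Variant table aligned with `geno` columns (uses
#'   `gene`, `effect_class`, `cadd`, `is_lof`).
#' @param genes Character vector of genes to test.
#' @param design A [burden_design()] (its `variant_class`/`rare_only`
#'   are overridden per row).
#' @param seed Integer seed.
#' @param classes Variant classes to run (default both).
#' @param rare_settings Rare-only settings to run (default `TRUE` and
#'   `FALSE`).
#' @return Data frame with columns `gene`, `class`, `rare_only`,
#'   `statistic` (burden z), `skat_q`, `p_burden`, `p_skat`,
#'   `significant` (either empirical p < 0.05).
#' @export
run_burden <- function(geno, variants, genes, design, seed,
                       classes = c("deleterious", "missense"),
                       rare_settings = c(TRUE, FALSE)) {
  if (length(genes) == 0L) {
    return(data.frame(gene = character(0), class = character(0),
                      rare_only = logical(0), statistic = numeric(0),
                      skat_q = numeric(0), p_burden = numeric(0),
                      p_skat = numeric(0), significant = logical(0)))
  }
  B <- design$permutations
  qrX <- null_qr(design)
  set.seed(seed)
  perm_idx <- replicate(B, sample(length(design$phenotype)))
  Yperm <- apply(perm_idx, 2L, function(ix) design$phenotype[ix])
  Rperm <- qr.resid(qrX, Yperm)          # n x B permuted residuals
  r_obs <- qr.resid(qrX, design$phenotype)
  sigma2 <- mean(r_obs^2)

  rows <- list()
  for (cls in classes) {
    qual_cls <- select_burden_variants(variants, cls)
    for (ro in rare_settings) {
      for (g in genes) {
        cols <- which(variants$gene == g & qual_cls)
        Gg <- geno[, cols, drop = FALSE]
        Gg[is.na(Gg)] <- 0
        maf <- sample_maf(Gg)
        keep <- maf > 0 & (!ro | maf <= design$maf_cutoff)
        Gg <- Gg[, keep, drop = FALSE]
        if (ncol(Gg) == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, class = cls, rare_only = ro,
            statistic = NA_real_, skat_q = NA_real_,
            p_burden = NA_real_, p_skat = NA_real_,
            significant = NA)
          next
        }
        d <- design
        d$variant_class <- cls
        d$rare_only <- ro
        # burden: project the collapsed score once, reuse across perms
        s <- rowSums(Gg)
        sc <- qr.resid(qrX, s)
        sdenom <- sqrt(sum(sc^2) * sigma2)
        z_obs <- if (sdenom == 0) 0 else sum(sc * r_obs) / sdenom
        z_perm <- if (sdenom == 0) rep(0, B) else
          as.vector(crossprod(sc, Rperm)) / sdenom
        p_b <- perm_pvalue(z_obs, z_perm)
        # variance component via the same permutation stream
        q_obs <- skat_statistic(Gg, d)
        q_perm <- skat_q_perm(Gg, d, Rperm)
        p_q <- perm_pvalue(q_obs, q_perm)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, class = cls, rare_only = ro,
          statistic = z_obs, skat_q = as.numeric(q_obs),
          p_burden = p_b, p_skat = p_q,
          significant = p_b < 0.05 | p_q < 0.05)
      }
    }
  }
  do.call(rbind, rows)
}

# vectorized Q over a matrix of permuted residuals
skat_q_perm <- function(G, design, Rperm) {
  maf <- sample_maf(G)
  G <- G[, maf > 0, drop = FALSE]
  maf <- maf[maf > 0]
  rare <- maf <= design$maf_cutoff
  part <- function(sel) {
    if (!any(sel)) return(NULL)
    Gp <- G[, sel, drop = FALSE]
    w <- variant_weights(maf[sel], design$weights)
    U <- crossprod(Gp, Rperm)            # m x B
    colSums(w * U^2) / sum(sel)
  }
  if (design$rare_only) {
    q <- part(rare)
    if (is.null(q)) rep(NA_real_, ncol(Rperm)) else q
  } else {
    qr_ <- part(rare); qc_ <- part(!rare)
    design$mix * (if (is.null(qr_)) 0 else qr_) +
      (1 - design$mix) * (if (is.null(qc_)) 0 else qc_)
  }
}

#' Greedy r-squared window pruner for common variants
#'
#' Minimal stand-in for windowed LD pruning: slides a window of
#' `window` variants (step `step`) over the given LD matrix and
#' greedily drops one member of any pair whose r-squared exceeds
#' `threshold`, keeping the earlier variant.
#'
#' @param ld Square correlation matrix between variants (r, not r^2).
#' @param window Window size in variants (default 50).
#' @param step Step size (default 5).
#' @param threshold r-squared ceiling; the default 1/3 corresponds to
#'   a pairwise variance-inflation factor of 1.5.
#' @return Logical vector: `TRUE` for retained variants.
#' @export
prune_common_variants <- function(ld, window = 50, step = 5,
                                  threshold = 1 / 3) {
  m <- nrow(ld)
  keep <- rep(TRUE, m)
  start <- 1L
  while (start <= m) {
    end <- min(start + window - 1L, m)
    idx <- start:end
    for (a in idx) {
      if (!keep[a]) next
      for (b in idx) {
        if (b <= a || !keep[b]) next
        if (ld[a, b]^2 > threshold) keep[b] <- FALSE
      }
    }
    if (end == m) break
    start <- start + step
  }
  keep
}
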