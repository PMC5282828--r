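#' @title Organism modifier-screen scoring
#' @name organism_screens
#' @description
#' Scoring of the Drosophila alpha-synuclein retinal-degeneration
#' enhancer screen (pseudopupil penetrance with the two-line rule,
#' vacuole-area quantification with t-tests) and the C. elegans
#' viability and motility assays.
NULL

#' Penetrance of retinal degeneration for one RNAi line
#'
#' The fraction of examined retinae scored abnormal (reduced
#' rhabdomere numbers or altered light refraction). When scoring was
#' done blinded in triplicate, per-retina calls are resolved by
#' majority before the fraction is taken.
#'
#' @param n_abnormal Number of abnormal retinae (or a matrix of 0/1
#'   scorer calls, retinae in rows, scorers in columns, resolved by
#'   majority).
#' @param n_retinae Total retinae examined (ignored when a scorer
#'   matrix is given).
#' @param min_retinae Minimum examined for a full-confidence call
#'   (default 8); fewer flags the result under-sampled.
#' @return List with `penetrance` in \[0, 1\], `n_retinae`,
#'   `under_sampled`.
#' @export
penetrance <- function(n_abnormal, n_retinae = NULL, min_retinae = 8) {
  if (is.matrix(n_abnormal)) {
    calls <- rowMeans(n_abnormal) > 0.5
    n_retinae <- nrow(n_abnormal)
    n_abnormal <- sum(calls)
  }
  if (is.null(n_retinae) || n_retinae == 0) {
    stop("n_retinae must be >= 1")
  }
  stopifnot(n_abnormal >= 0, n_abnormal <= n_retinae)
  list(penetrance = n_abnormal / n_retinae, n_retinae = n_retinae,
       under_sampled = n_retinae < min_retinae)
}

#' Enhancer call from independent RNAi lines (two-line rule)
#'
#' A gene is called an enhancer iff at least two independent RNAi
#' lines targeting non-overlapping sequences each show penetrance of
#' 0.5 or greater (inclusive).
#'
#' @param line_penetrance Numeric vector of per-line penetrance values
#'   for one gene.
#' @param threshold Penetrance threshold (default 0.5, inclusive).
#' @param min_lines Required number of qualifying lines (default 2).
#' @return List with `enhancer` (logical) and `n_qualifying`.
#' @export
call_enhancer <- function(line_penetrance, threshold = 0.5,
                          min_lines = 2) {
  stopifnot(length(line_penetrance) >= 1L,
            all(line_penetrance >= 0 & line_penetrance <= 1))
  nq <- sum(line_penetrance >= threshold)
  list(enhancer = nq >= min_lines, n_qualifying = nq)
}

#' Vacuole-area fraction per animal, with t-test against control
#'
#' For each animal, sums the areas of vacuoles with diameter strictly
#' greater than `min_diameter` and divides by the total retinal area;
#' genotypes are compared to control by an unpaired two-tailed t-test.
#' Fewer than three animals per genotype is flagged under-powered but
#' the statistic is still computed; a zero-variance comparison is
#' flagged undefined.
#'
#' @param measurements Data frame with columns `animal`,
#'   `vacuole_area`, `vacuole_diameter`, `total_area` (one row per
#'   vacuole; animals without vacuoles appear with `NA` vacuole rows).
#' @param control As `measurements`, for the control genotype.
#' @param min_diameter Qualifying-diameter floor in micrometres
#'   (default 4, strict).
#' @return List with `fractions`, `control_fractions`, `t`, `p`,
#'   `under_powered`, `undefined_variance`.
#' @export
vacuole_fraction <- function(measurements, control, min_diameter = 4) {
  per_animal <- function(df) {
    vapply(split(df, df$animal), function(a) {
      qual <- !is.na(a$vacuole_area) &
        a$vacuole_diameter > min_diameter
      total <- a$total_area[1L]
      stopifnot(total > 0)
      sum(a$vacuole_area[qual]) / total
    }, numeric(1))
  }
  f_t <- per_animal(measurements)
  f_c <- per_animal(control)
  under <- length(f_t) < 3L || length(f_c) < 3L
  if (stats::var(f_t) == 0 && stats::var(f_c) == 0) {
    return(list(fractions = f_t, control_fractions = f_c,
                t = NA_real_, p = NA_real_, under_powered = under,
                undefined_variance = TRUE))
  }
  tt <- stats::t.test(f_t, f_c, var.equal = TRUE)
  list(fractions = f_t, control_fractions = f_c,
       t = unname(tt$statistic), p = tt$p.value,
       under_powered = under, undefined_variance = FALSE)
}

#' Worm viability effects with one-sided t-test
#'
#' Survival-fraction and offspring-count effects of an RNAi condition
#' against control, tested one-sided in the direction of reduction.
#'
#' @param treatment,control Numeric vectors of replicate measurements
#'   (>= 3 biological replicates each for the viability assays).
#' @return List with `effect` (mean difference, treatment - control),
#'   `p` (one-sided, alternative: treatment less than control).
#' @export
worm_viability <- function(treatment, control) {
  if (length(treatment) == 0L || length(control) == 0L) {
    stop("viability comparison needs replicates on both sides")
  }
  tt <- stats::t.test(treatment, control, alternative = "less",
                      var.equal = TRUE)
  list(effect = mean(treatment) - mean(control), p = tt$p.value,
       n = c(treatment = length(treatment),
             control = length(control)))
}

#' Relative body-bend motility
#'
#' Mean body-bend count per 30 s, normalized to the control mean, with
#' the standard error propagated by the delta method for a ratio of
#' independent means.
#'
#' @param treatment,control Numeric vectors of per-animal body-bend
#'   counts (the assay scores 15 animals per condition).
#' @return List with `relative` (treatment mean / control mean) and
#'   `sem` (propagated standard error), or `NA` values when the
#'   control mean is zero.
#' @export
body_bend_relative <- function(treatment, control) {
  stopifnot(length(treatment) >= 1L, length(control) >= 1L)
  mt <- mean(treatment)
  mc <- mean(control)
  if (mc == 0) {
    return(list(relative = NA_real_, sem = NA_real_, undefined = TRUE))
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rel <- mt / mc
  rel_sem <- if (mt == 0) {
    sem(treatment) / mc
  } else {
    abs(rel) * sqrt((sem(treatment) / mt)^2 + (sem(control) / mc)^2)
  }
  list(relative = rel, sem = rel_sem, undefined = FALSE)
}
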