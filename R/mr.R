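#' Harmonize exposure and outcome summary statistics into instruments
#'
#' Matches variants between the exposure (irQTL) records and the
#' outcome GWAS, aligning the outcome to the exposure's effect allele:
#' when the outcome's effect allele equals the exposure's other allele
#' the outcome beta flips sign; allele pairs that match in neither
#' orientation are dropped, as are strand-ambiguous variants (A/T,
#' C/G) with MAF > 0.4 (where orientation is unresolvable).
#'
#' @param exposure data.frame with `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` (and optionally `maf`, `p`).
#' @param outcome sumstats data.frame ([readSumstats()] layout).
#' @return instrument data.frame: `variant_id`, `effect_allele`,
#'   `other_allele`, `b_exp`, `se_exp`, `b_out`, `se_out` (+ `p_exp`,
#'   `maf` when present); errors when no variant is shared.
#' @export
harmonizeInstruments <- function(exposure, outcome) {
  i <- match(exposure$variant_id, outcome$variant_id)
  keep <- !is.na(i)
  if (!any(keep)) stop("no shared variants between exposure and outcome")
  ex <- exposure[keep, , drop = FALSE]
  ou <- outcome[i[keep], , drop = FALSE]
  e_ea <- toupper(ex$effect_allele); e_oa <- toupper(ex$other_allele)
  o_ea <- toupper(ou$effect_allele); o_oa <- toupper(ou$other_allele)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ambiguous <- e_ea == comp[e_oa]
  maf <- if (!is.null(ex$maf)) ex$maf else rep(NA_real_, nrow(ex))
  drop_amb <- ambiguous & !is.na(maf) & maf > 0.4
  same <- o_ea == e_ea & o_oa == e_oa
  swapped <- o_ea == e_oa & o_oa == e_ea
  keep2 <- (same | swapped) & !drop_amb
  ex <- ex[keep2, , drop = FALSE]
  ou <- ou[keep2, , drop = FALSE]
  if (nrow(ex) == 0) stop("no harmonizable instruments remain")
  b_out <- ifelse(swapped[keep2], -ou$beta, ou$beta)
  out <- data.frame(variant_id = ex$variant_id,
                    effect_allele = toupper(ex$effect_allele),
                    other_allele = toupper(ex$other_allele),
                    b_exp = ex$beta, se_exp = ex$se,
                    b_out = b_out, se_out = ou$se,
                    stringsAsFactors = FALSE)
  if (!is.null(ex$p)) out$p_exp <- ex$p
  if (!is.null(ex$maf)) out$maf <- ex$maf
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping of association records
#'
#' Repeatedly takes the remaining record with the smallest p-value and
#' removes all remaining records whose dosage r-squared with it is at
#' or above `r2_max`. Ties in p are broken by variant id, so the
#' result is deterministic. Records whose variant is absent from the
#' LD reference are dropped with a warning.
#'
#' @param records data.frame with `variant_id` and `p`.
#' @param g [GenotypeMatrix-class] LD reference (in-sample genotypes).
#' @param r2_max clumping threshold (default 0.001): retained
#'   instruments are pairwise `r2 < r2_max`.
#' @return `records` rows of the retained, mutually independent
#'   variants (ordered by p).
#' @export
ldClump <- function(records, g, r2_max = 0.001) {
  present <- records$variant_id %in% variantIDs(g)
  if (!all(present)) {
    warning(sprintf("ldClump: %d variant(s) absent from the LD reference dropped",
                    sum(!present)))
    records <- records[present, , drop = FALSE]
  }
  if (nrow(records) == 0) return(records)
  d <- dosages(g)[, records$variant_id, drop = FALSE]
  mu <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j]); if (any(nas)) d[nas, j] <- mu[j]
  }
  r2 <- suppressWarnings(stats::cor(d))^2
  r2[is.na(r2)] <- 0
  ord <- order(records$p, records$variant_id)
  alive <- rep(TRUE, nrow(records))
  keep <- integer(0)
  for (k in ord) {
    if (!alive[k]) next
    keep <- c(keep, k)
    alive[r2[k, ] >= r2_max] <- FALSE
  }
  records[keep, , drop = FALSE]
}

#' Inverse-variance weighted Mendelian randomization
#'
#' Fixed-effect IVW: `estimate = sum(b_exp b_out / se_out^2) /
#' sum(b_exp^2 / se_out^2)`, `se = sqrt(1 / sum(b_exp^2 / se_out^2))`,
#' two-sided normal p. With a single instrument this reduces to the
#' Wald ratio `b_out / b_exp`. A multiplicative random-effects variant
#' inflates the SE by the residual scale when it exceeds 1.
#'
#' @param inst instrument data.frame ([harmonizeInstruments()] layout)
#'   with >= 1 instrument and positive `se_out`.
#' @param random_effects use the multiplicative random-effects SE
#'   (default FALSE, the fixed-effect textbook estimator).
#' @return data.frame: `method`, `estimate`, `se`, `p`,
#'   `n_instruments`.
#' @export
mrIvw <- function(inst, random_effects = FALSE) {
  if (nrow(inst) < 1) stop("IVW needs at least one instrument")
  if (any(inst$se_out <= 0)) stop("outcome SEs must be > 0")
  w <- 1 / inst$se_out^2
  denom <- sum(inst$b_exp^2 * w)
  est <- sum(inst$b_exp * inst$b_out * w) / denom
  se <- sqrt(1 / denom)
  if (random_effects && nrow(inst) > 1) {
    resid <- (inst$b_out - est * inst$b_exp) * sqrt(w)
    scale <- sum(resid^2) / (nrow(inst) - 1)
    se <- se * sqrt(max(1, scale))
  }
  data.frame(method = if (random_effects) "IVW-RE" else "IVW",
             estimate = est, se = se,
             p = 2 * stats::pnorm(-abs(est / se)),
             n_instruments = nrow(inst), stringsAsFactors = FALSE)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure
#' effects with a free intercept (the directional-pleiotropy term),
#' weights `1 / se_out^2`, after orienting instruments so every
#' `b_exp >= 0`. Requires at least three independent instruments.
#' Coefficient SEs use a multiplicative residual scale floored at 1;
#' p-values are two-sided t with `n - 2` df.
#'
#' @param inst instrument data.frame with >= 3 instruments.
#' @return data.frame: `method`, `estimate` (slope), `se`, `p`,
#'   `n_instruments`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`.
#' @export
mrEgger <- function(inst) {
  if (nrow(inst) < 3)
    stop("MR-Egger requires at least three independent instruments")
  if (any(inst$se_out <= 0)) stop("outcome SEs must be > 0")
  flip <- inst$b_exp < 0
  bx <- abs(inst$b_exp)
  by <- ifelse(flip, -inst$b_out, inst$b_out)
  w <- 1 / inst$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  scale <- max(1, sm$sigma)
  co <- sm$coefficients
  se_i <- co[1, 2] / sm$sigma * scale
  se_s <- co[2, 2] / sm$sigma * scale
  df <- nrow(inst) - 2
  data.frame(method = "Egger",
             estimate = co[2, 1], se = se_s,
             p = 2 * stats::pt(-abs(co[2, 1] / se_s), df = df),
             n_instruments = nrow(inst),
             egger_intercept = co[1, 1],
             egger_intercept_se = se_i,
             egger_intercept_p = 2 * stats::pt(-abs(co[1, 1] / se_i),
                                               df = df),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR across MR results
#'
#' BH adjustment of the MR p-values across all exposure-trait pairs of
#' an analysis batch; `significant` flags FDR < `fdr`.
#'
#' @param results data.frame of MR results with a `p` column (one row
#'   per exposure-trait pair).
#' @param fdr significance level (default 0.05).
#' @return `results` with `fdr` and `significant` columns.
#' @export
mrFdr <- function(results, fdr = 0.05) {
  results$fdr <- stats::p.adjust(results$p, method = "BH")
  results$significant <- !is.na(results$fdr) & results$fdr < fdr
  results
}

#' Reverse-direction IVW check for reverse causality
#'
#' Uses genome-wide significant trait variants (after LD clumping) as
#' instruments for the trait and the isoform-ratio association scan as
#' the outcome; under a forward-only generative model the reverse IVW
#' estimate centers on zero. When no trait instrument reaches the
#' threshold the result is flagged instead of estimated.
#'
#' @param trait_ss trait sumstats (exposure side).
#' @param ratio_records isoform-ratio association records with
#'   `variant_id`, `beta`, `se` (outcome side, effect allele = the
#'   genotype matrix ALT).
#' @param g [GenotypeMatrix-class] LD reference for clumping.
#' @param alpha instrument significance threshold (default 5e-8).
#' @param r2_max clumping threshold (default 0.001).
#' @return one-row data.frame as [mrIvw()] with method
#'   `"reverse-IVW"`, or with `NA` estimate and a `note` of
#'   `"no instruments"`.
#' @export
reverseMrCheck <- function(trait_ss, ratio_records, g, alpha = 5e-8,
                           r2_max = 0.001) {
  cand <- trait_ss[!is.na(trait_ss$p) & trait_ss$p < alpha, ,
                   drop = FALSE]
  cand <- cand[cand$variant_id %in% ratio_records$variant_id, ,
               drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(method = "reverse-IVW", estimate = NA_real_,
                      se = NA_real_, p = NA_real_, n_instruments = 0L,
                      note = "no instruments", stringsAsFactors = FALSE))
  cand <- ldClump(cand, g, r2_max)
  j <- match(cand$variant_id, ratio_records$variant_id)
  inst <- data.frame(variant_id = cand$variant_id,
                     effect_allele = cand$effect_allele,
                     other_allele = cand$other_allele,
                     b_exp = cand$beta, se_exp = cand$se,
                     b_out = ratio_records$beta[j],
                     se_out = ratio_records$se[j],
                     stringsAsFactors = FALSE)
  inst <- inst[!is.na(inst$b_out) & inst$se_out > 0, , drop = FALSE]
  if (nrow(inst) == 0)
    return(data.frame(method = "reverse-IVW", estimate = NA_real_,
                      se = NA_real_, p = NA_real_, n_instruments = 0L,
                      note = "no instruments", stringsAsFactors = FALSE))
  res <- mrIvw(inst)
  res$method <- "reverse-IVW"
  res$note <- ""
  res
}
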