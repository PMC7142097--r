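#' Fold an alternate-allele read count onto the minor haplotype
#'
#' The copy-number estimator counts reads supporting the NUMT-derived
#' haplotype at an informative site. When the alternate allele is the major
#' allele (`AF > 50%`) the NUMT-derived reads are the reference-supporting
#' ones, so the count is folded: `Altmt = DPmtvar - Altmt'`. At or below
#' 50% the raw count is returned unchanged.
#'
#' @param dp_mtvar Total depth at the informative variant (`DPmtvar`).
#' @param alt_raw Raw alternate-supporting read count (`Altmt'`).
#' @return Folded read count (vectorised).
#' @export
fold_alt_count <- function(dp_mtvar, alt_raw) {
  if (any(alt_raw > dp_mtvar) || any(alt_raw < 0) || any(dp_mtvar <= 0)) {
    stop("require 0 <= alt_raw <= dp_mtvar with dp_mtvar > 0")
  }
  ifelse(alt_raw / dp_mtvar > 0.5, dp_mtvar - alt_raw, alt_raw)
}

#' Estimate the mtDNA-fragment copy number of a NUMT
#'
#' For each informative variant of the mixed haplotype, the number of
#' concatenated mtDNA-derived fragment copies is
#' `Nmt = Altmt / (DPadjnumt / 2)`, where `Altmt` is the (folded, see
#' [fold_alt_count()]) read count supporting the NUMT-derived allele and
#' `DPadjnumt` the mean nuclear depth flanking the insertion (both
#' chromosomes). The per-NUMT summary is the median of the per-variant
#' estimates, which resists junction-proximal outliers.
#'
#' @param variants Data frame with columns `dp_mtvar` and `alt_raw`, one
#'   row per informative variant (a `key` column is carried through if
#'   present).
#' @param dp_adj_numt Mean nuclear depth flanking the NUMT (> 0).
#' @param sample_id,numt_id Optional identifiers echoed in the result.
#' @return A list of class `copy_estimate` with the per-variant table
#'   (extra columns `alt_mt` and `nmt`) and `summary_nmt`.
#' @examples
#' estimate_nmt(data.frame(dp_mtvar = 1000, alt_raw = c(40, 44, 36)), 40)
#' @export
estimate_nmt <- function(variants, dp_adj_numt, sample_id = NA_character_,
                         numt_id = NA_character_) {
  if (is.null(variants) || !nrow(variants)) {
    stop("estimate_nmt needs at least one informative variant")
  }
  if (!is.finite(dp_adj_numt) || dp_adj_numt <= 0) {
    stop("dp_adj_numt must be positive")
  }
  variants$alt_mt <- fold_alt_count(variants$dp_mtvar, variants$alt_raw)
  variants$nmt <- variants$alt_mt / (dp_adj_numt / 2)
  structure(list(sample_id = sample_id, numt_id = numt_id,
                 per_variant = variants,
                 dp_adj_numt = dp_adj_numt,
                 summary_nmt = stats::median(variants$nmt)),
            class = "copy_estimate")
}

#' @export
print.copy_estimate <- function(x, ...) {
  cat(sprintf(
    "Copy estimate for %s / %s: median Nmt %.2f over %d informative variants (DPadj %.1fx)\n",
    x$sample_id, x$numt_id, x$summary_nmt, nrow(x$per_variant),
    x$dp_adj_numt))
  invisible(x)
}

#' Modelled mixed-haplotype fraction
#'
#' The expected allele fraction of a NUMT-derived allele read as apparent
#' mtDNA heteroplasmy:
#' `HTF = (DPnu/2 * Nmt) / (DPnu/2 * Nmt + DPmt)`, where `DPnu` is the
#' nuclear depth (the NUMT sits on one of two autosomes, hence the /2),
#' `Nmt` the fragment copy number and `DPmt` the true mtDNA depth.
#' Always in \[0, 1); increasing in `nmt` and `dp_nu`, decreasing in
#' `dp_mt`.
#'
#' @param dp_nu Nuclear depth of coverage (> 0).
#' @param dp_mt True mtDNA depth of coverage (> 0).
#' @param nmt Number of mtDNA-derived fragment copies (>= 0).
#' @return Expected allele fraction (vectorised).
#' @examples
#' htf(40, 360, 2)  # 0.1
#' @export
htf <- function(dp_nu, dp_mt, nmt) {
  stopifnot(all(dp_nu > 0), all(dp_mt > 0), all(nmt >= 0))
  num <- dp_nu / 2 * nmt
  num / (num + dp_mt)
}

#' Grid of modelled haplotype fractions with exact binomial bands
#'
#' Evaluates [htf()] over a grid of nuclear depths, mtDNA depths and copy
#' numbers, and attaches an exact binomial confidence band at each point:
#' with `n = round(dp_nu/2 * nmt + dp_mt)` total reads, the observed
#' fraction of NUMT-derived reads is `Binomial(n, htf)/n`, so the band is
#' the pair of exact binomial quantiles divided by `n`. Exact quantiles
#' (rather than a normal approximation) keep the band honest at one copy,
#' where alt counts are small.
#'
#' @param dp_nu_values Nuclear depths (default 35, 40, 45, 50).
#' @param dp_mt_values mtDNA depths (default 200 to 4500 in steps of 100).
#' @param nmt_values Copy numbers (default 1..20).
#' @param ci_level Band level (default 0.95).
#' @return Data frame with columns `dp_nu`, `dp_mt`, `nmt`, `htf`,
#'   `ci_low`, `ci_high`.
#' @export
htf_grid <- function(dp_nu_values = c(35, 40, 45, 50),
                     dp_mt_values = seq(200, 4500, by = 100),
                     nmt_values = 1:20, ci_level = 0.95) {
  g <- expand.grid(dp_nu = dp_nu_values, dp_mt = dp_mt_values,
                   nmt = nmt_values, KEEP.OUT.ATTRS = FALSE)
  g$htf <- htf(g$dp_nu, g$dp_mt, g$nmt)
  n <- round(g$dp_nu / 2 * g$nmt + g$dp_mt)
  alpha <- 1 - ci_level
  g$ci_low <- stats::qbinom(alpha / 2, n, g$htf) / n
  g$ci_high <- stats::qbinom(1 - alpha / 2, n, g$htf) / n
  g
}

#' Correlation between mtDNA depth and observed haplotype allele fraction
#'
#' Under the NUMT model the apparent heteroplasmy fraction falls as true
#' mtDNA content rises (the nuclear-derived reads are diluted), so the
#' correlation is expected to be negative. Pearson product-moment
#' correlation with a two-sided test.
#'
#' @param dp_mt mtDNA depths.
#' @param af Observed allele fractions (same length).
#' @return List with `r`, `p_value` and `n`.
#' @export
af_depth_correlation <- function(dp_mt, af) {
  if (length(dp_mt) != length(af) || length(af) < 3) {
    stop("need >= 3 paired observations")
  }
  if (stats::sd(dp_mt) == 0 || stats::sd(af) == 0) {
    stop("correlation undefined: zero variance in dp_mt or af")
  }
  ct <- stats::cor.test(dp_mt, af, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(af))
}
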