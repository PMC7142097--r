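#' Construct a trio of mtDNA callsets
#'
#' @param trio_id Trio identifier.
#' @param father,mother,child [mt_callset] objects with distinct sample
#'   ids.
#' @param extra_sibs Optional list of additional sibling [mt_callset]s;
#'   siblings do not change the trio's status but can be classified
#'   against the same father with [classify_trio()].
#' @return An object of class `mt_trio`.
#' @export
mt_trio <- function(trio_id, father, mother, child, extra_sibs = list()) {
  ids <- c(father$sample_id, mother$sample_id, child$sample_id,
           vapply(extra_sibs, function(s) s$sample_id, character(1)))
  if (anyDuplicated(ids)) {
    stop("sample ids within trio ", trio_id, " must be distinct")
  }
  structure(list(trio_id = as.character(trio_id), father = father,
                 mother = mother, child = child, extra_sibs = extra_sibs),
            class = "mt_trio")
}

#' Paternal variants informative for the mixed-haplotype screen
#'
#' Returns the father's variant keys at allele fraction strictly above
#' `af_threshold` whose key is absent from the mother's filtered callset.
#' A variant shared with the mother at any retained allele fraction is
#' non-informative (it could have been transmitted maternally), so
#' informativeness is decided per variant, not per trio.
#'
#' @param father,mother Filtered [mt_callset] objects.
#' @param af_threshold Screening threshold (default 0.05, strict `>`).
#' @return Character vector of `"pos:alt"` keys.
#' @export
informative_variants <- function(father, mother, af_threshold = 0.05) {
  fk <- variant_key(father)
  keep <- father$variants$af > af_threshold & !(fk %in% variant_key(mother))
  fk[keep]
}

#' Informative paternal variants shared with the child
#'
#' The subset of [informative_variants()] that the child also carries at
#' allele fraction strictly above `af_threshold` - the signature that, at
#' face value, suggests paternal transmission of mtDNA.
#'
#' @param trio An [mt_trio] of filtered callsets.
#' @param af_threshold Screening threshold (default 0.05).
#' @return Character vector of `"pos:alt"` keys.
#' @export
shared_paternal_variants <- function(trio, af_threshold = 0.05) {
  inf <- informative_variants(trio$father, trio$mother, af_threshold)
  inf[is_detected(trio$child, inf, af_threshold)]
}

#' Classify a trio in the mixed-haplotype screen
#'
#' Pipeline order: a trio with no informative paternal variant is
#' `non_informative`; with informative variants but none shared by the
#' child, `informative_only`. For trios with at least one shared paternal
#' variant, the father's homoplasmies (AF > 95%) not detected in the child
#' (child AF <= `af_threshold`) are counted: true paternal transmission of
#' mtDNA would carry *all* paternal homoplasmies into the child, so
#' `homoplasmy_mismatch_min` or more missing homoplasmies exclude the trio
#' (`excluded_homoplasmy_mismatch`); otherwise it is a
#' `mixed_haplotype_candidate`.
#'
#' @param trio An [mt_trio] of filtered callsets.
#' @param af_threshold Detection threshold (default 0.05).
#' @param homoplasmy_mismatch_min Missing-homoplasmy count that triggers
#'   exclusion (default 3).
#' @param check_depth_qc If `TRUE`, error when the trio fails
#'   [trio_depth_qc()] at `min_depth`; QC is normally applied upstream.
#' @param min_depth Depth threshold used when `check_depth_qc` is set.
#' @return A list of class `trio_classification` with `trio_id`, `status`,
#'   `informative_variants` (named by key, value = father AF),
#'   `shared_paternal_variants` (father and child AF) and
#'   `missing_homoplasmies`.
#' @export
classify_trio <- function(trio, af_threshold = 0.05,
                          homoplasmy_mismatch_min = 3L,
                          check_depth_qc = FALSE, min_depth = 500) {
  if (check_depth_qc &&
      !trio_depth_qc(trio$father, trio$mother, trio$child, min_depth)) {
    stop("trio ", trio$trio_id, " fails mtDNA depth QC (minimum ",
         min_depth, "x); exclude upstream")
  }
  inf <- informative_variants(trio$father, trio$mother, af_threshold)
  fk <- variant_key(trio$father)
  inf_af <- stats::setNames(trio$father$variants$af[match(inf, fk)], inf)

  shared <- inf[is_detected(trio$child, inf, af_threshold)]
  ck <- variant_key(trio$child)
  shared_tab <- data.frame(
    key = shared,
    father_af = trio$father$variants$af[match(shared, fk)],
    child_af = trio$child$variants$af[match(shared, ck)],
    stringsAsFactors = FALSE)

  homop <- fk[is_homoplasmic(trio$father$variants)]
  missing <- homop[!is_detected(trio$child, homop, af_threshold)]

  status <- if (!length(inf)) {
    "non_informative"
  } else if (!length(shared)) {
    "informative_only"
  } else if (length(missing) >= homoplasmy_mismatch_min) {
    "excluded_homoplasmy_mismatch"
  } else {
    "mixed_haplotype_candidate"
  }
  structure(list(trio_id = trio$trio_id, status = status,
                 informative_variants = inf_af,
                 shared_paternal_variants = shared_tab,
                 missing_homoplasmies = missing),
            class = "trio_classification")
}

TRIO_STATUSES <- c("non_informative", "informative_only",
                   "excluded_homoplasmy_mismatch",
                   "mixed_haplotype_candidate")

#' Screen a cohort of trios for mixed-haplotype candidates
#'
#' Classifies every trio with [classify_trio()] and tallies the statuses.
#' The candidate fraction is reported as a percentage of all screened
#' trios.
#'
#' @param trios List of [mt_trio] objects (all assumed to have passed QC).
#' @param ... Passed to [classify_trio()].
#' @return List of class `cohort_screen` with `classifications`, `tally`
#'   (named counts over all four statuses), `n_trios`, `candidates`
#'   (trio ids) and `candidate_fraction_pct`.
#' @export
screen_cohort <- function(trios, ...) {
  cls <- lapply(trios, classify_trio, ...)
  status <- vapply(cls, function(x) x$status, character(1))
  tally <- table(factor(status, levels = TRIO_STATUSES))
  cand <- vapply(cls[status == "mixed_haplotype_candidate"],
                 function(x) x$trio_id, character(1))
  n <- length(trios)
  structure(list(
    classifications = cls,
    tally = stats::setNames(as.integer(tally), names(tally)),
    n_trios = n,
    candidates = cand,
    candidate_fraction_pct = if (n) 100 * length(cand) / n else 0
  ), class = "cohort_screen")
}

#' @export
print.cohort_screen <- function(x, ...) {
  cat("Trio mixed-haplotype screen over", x$n_trios, "trios\n")
  for (s in names(x$tally)) cat(sprintf("  %-30s %d\n", s, x$tally[[s]]))
  cat(sprintf("  candidate fraction: %.2f%%\n", x$candidate_fraction_pct))
  invisible(x)
}

#' Count heteroplasmic variants in a filtered callset
#'
#' Heteroplasmies are filtered variants with allele fraction above the
#' pipeline floor (1%) but not homoplasmic (at most 95%).
#'
#' @param callset A filtered [mt_callset].
#' @param af_min Lower bound, strict (default 0.01).
#' @param af_max Upper bound, inclusive (default 0.95).
#' @return Integer count.
#' @export
count_heteroplasmies <- function(callset, af_min = 0.01, af_max = 0.95) {
  sum(callset$variants$af > af_min & callset$variants$af <= af_max)
}

#' Father-led screen for mega-NUMT carriers
#'
#' The independent discovery route: select fathers who (1) carry strictly
#' more than `het_min` heteroplasmic variants (1% < AF <= 95%) and
#' (2) carry at least one rare, large NUMT call - cohort frequency below
#' `numt_freq_max` and mtDNA breakpoint span above `mt_span_min` bp. This
#' route finds carriers whose offspring screen was negative (e.g. a
#' transmitted haplotype below the 5% screening threshold).
#'
#' @param fathers List of filtered [mt_callset] objects.
#' @param numts List of `numt_call` objects (see [group_numts()]).
#' @param het_min Heteroplasmy-count threshold, strict (default 12).
#' @param numt_freq_max Cohort-frequency ceiling, strict (default 0.001).
#' @param mt_span_min Minimum mtDNA breakpoint span in bp, strict
#'   (default 500).
#' @return Character vector of selected father sample ids.
#' @export
find_meganumt_fathers <- function(fathers, numts, het_min = 12L,
                                  numt_freq_max = 0.001, mt_span_min = 500) {
  rare_large <- Filter(function(nc) {
    nc$cohort_frequency < numt_freq_max &&
      length(nc$mt_breakpoints$pos) >= 2L && mt_span(nc) > mt_span_min
  }, numts)
  carriers <- unique(unlist(lapply(rare_large, function(nc) nc$carriers)))
  hits <- vapply(fathers, function(f) {
    count_heteroplasmies(f) > het_min && f$sample_id %in% carriers
  }, logical(1))
  vapply(fathers[hits], function(f) f$sample_id, character(1))
}

#' Tukey upper fence for per-father heteroplasmy counts
#'
#' Data-driven outlier threshold for the father-led screen:
#' `Q3 + 1.5 * IQR` of the per-father heteroplasmy counts, with quartiles
#' by linear interpolation (default sample quantiles).
#'
#' @param het_counts Integer vector of per-father heteroplasmy counts
#'   (>= 4 values).
#' @return The fence value.
#' @export
iqr_outlier_threshold <- function(het_counts) {
  if (length(het_counts) < 4L) {
    stop("need at least 4 heteroplasmy counts to set an IQR fence")
  }
  q <- stats::quantile(het_counts, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Read a trio pedigree table
#'
#' Tab-separated with header `trio_id, father_id, mother_id, child_id` and
#' an optional `sib_ids` column holding comma-separated additional sibling
#' ids (empty for none).
#'
#' @param path File path.
#' @return Data frame with a `sib_ids` list-column.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trio_id", "father_id", "mother_id", "child_id")
  if (!all(need %in% names(ped))) {
    stop("pedigree TSV must contain columns: ", paste(need, collapse = ", "))
  }
  ped$sib_ids <- if ("sib_ids" %in% names(ped)) {
    lapply(strsplit(as.character(ped$sib_ids), ","),
           function(x) x[nzchar(x)])
  } else {
    rep(list(character()), nrow(ped))
  }
  ped
}

#' Assemble trios from a pedigree and a pool of callsets
#'
#' @param pedigree Data frame from [read_pedigree()].
#' @param callsets Named list of [mt_callset] objects keyed by sample id.
#' @return List of [mt_trio] objects.
#' @export
build_trios <- function(pedigree, callsets) {
  lapply(seq_len(nrow(pedigree)), function(i) {
    row <- pedigree[i, ]
    get_cs <- function(id) {
      cs <- callsets[[id]]
      if (is.null(cs)) stop("no callset for sample ", id,
                            " (trio ", row$trio_id, ")")
      cs
    }
    mt_trio(row$trio_id, get_cs(row$father_id), get_cs(row$mother_id),
            get_cs(row$child_id),
            extra_sibs = lapply(row$sib_ids[[1]], get_cs))
  })
}

#' Write trio classifications to TSV
#'
#' One row per trio: status, the supporting variant keys
#' (semicolon-separated) and counts.
#'
#' @param screen A `cohort_screen` from [screen_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screen, path) {
  rows <- lapply(screen$classifications, function(cl) {
    data.frame(
      trio_id = cl$trio_id, status = cl$status,
      n_informative = length(cl$informative_variants),
      n_shared = nrow(cl$shared_paternal_variants),
      n_missing_homoplasmies = length(cl$missing_homoplasmies),
      informative_keys = paste(names(cl$informative_variants),
                               collapse = ";"),
      shared_keys = paste(cl$shared_paternal_variants$key, collapse = ";"),
      missing_homoplasmy_keys = paste(cl$missing_homoplasmies,
                                      collapse = ";"),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
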