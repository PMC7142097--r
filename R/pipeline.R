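#' Mean nuclear depth flanking a NUMT insertion
#'
#' `DPadjnumt`: mean per-base depth over 1 kb flanks on each side of the
#' insertion point, excluding `pad` bp around the junction itself (depth
#' there is distorted by clipped junction reads). Computed from aligned
#' read intervals (CIGAR reference length).
#'
#' @param reads An [aligned_reads] table for the sample.
#' @param contig Nuclear contig of the insertion.
#' @param insertion_pos Insertion point (1-based).
#' @param flank Flank width in bp (default 1000).
#' @param pad Junction exclusion half-width in bp (default 200).
#' @return Mean depth (x) over the two flank windows.
#' @export
estimate_dp_adj <- function(reads, contig, insertion_pos, flank = 1000L,
                            pad = 200L) {
  r <- reads[reads$contig == contig, , drop = FALSE]
  if (!nrow(r)) return(0)
  rlen <- cigar_ref_len(r$cigar)
  rs <- r$pos
  re <- r$pos + rlen - 1L
  windows <- rbind(c(insertion_pos - pad - flank, insertion_pos - pad - 1L),
                   c(insertion_pos + pad + 1L, insertion_pos + pad + flank))
  total <- 0
  for (w in seq_len(nrow(windows))) {
    ov <- pmax(0L, pmin(re, windows[w, 2]) - pmax(rs, windows[w, 1]) + 1L)
    total <- total + sum(ov)
  }
  total / (2 * flank)
}

cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    op <- substr(toks, nchar(toks), nchar(toks))
    len <- as.integer(sub(".$", "", toks))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Run the full mega-NUMT screening pipeline on a cohort
#'
#' Stage order: (1) sample/trio QC - mtDNA depth floor, recorded-sex
#' consistency from sex-chromosome depths when available; (2) mtDNA
#' variant filtering; (3) the child-led trio screen
#' ([screen_cohort()]); (4) the father-led heteroplasmy prescreen;
#' (5) NUMT and breakpoint detection from read evidence in every family
#' flagged by either route; (6) cohort-level NUMT grouping and the
#' father screen proper ([find_meganumt_fathers()]); (7) copy-number
#' estimation for carrier fathers; (8) the transmission summary over
#' father-offspring pairs of NUMT-carrier fathers. Both discovery routes
#' always run: the trio screen never consults NUMT calls, so removing
#' detection cannot change trio classifications.
#'
#' @param cohort A `sim_cohort` bundle, or any list providing `trios`,
#'   and optionally `samples`, `reads`, `pedigree` in the same layout.
#' @param min_depth Trio mtDNA depth floor (default 500).
#' @param af_threshold Detection threshold for the trio screen
#'   (default 0.05).
#' @param homoplasmy_mismatch_min Missing-homoplasmy exclusion count
#'   (default 3).
#' @param het_min Father-screen heteroplasmy threshold, strict
#'   (default 12).
#' @param numt_freq_max Father-screen NUMT cohort-frequency ceiling
#'   (default 0.001).
#' @param mt_span_min Father-screen mtDNA breakpoint span floor in bp
#'   (default 500).
#' @param cohort_size Number of individuals for NUMT frequencies
#'   (default: 3 x number of trios).
#' @param extreme_het_max Extreme-heterozygote QC flag threshold
#'   (samples above it are flagged, not excluded; default 50).
#' @param ... Further arguments passed to [detect_numts_sample()].
#' @return A list of class `run_report`; see the package vignette.
#' @export
run_full_screen <- function(cohort, min_depth = 500, af_threshold = 0.05,
                            homoplasmy_mismatch_min = 3L, het_min = 12L,
                            numt_freq_max = 0.001, mt_span_min = 500,
                            cohort_size = NULL, extreme_het_max = 50L,
                            ...) {
  trios <- cohort$trios
  n_total <- length(trios)
  if (is.null(cohort_size)) cohort_size <- 3L * n_total

  # --- stage 1: QC ---
  qc <- lapply(trios, function(t) {
    reasons <- character()
    if (!trio_depth_qc(t$father, t$mother, t$child, min_depth)) {
      reasons <- c(reasons, "mt_depth")
    }
    if (!is.null(cohort$samples)) {
      sm <- cohort$samples
      fs <- sm[sm$sample_id == t$father$sample_id, , drop = FALSE]
      ms <- sm[sm$sample_id == t$mother$sample_id, , drop = FALSE]
      if (nrow(fs) &&
          determine_sex(fs$depth_x, fs$depth_y) != "male") {
        reasons <- c(reasons, "father_sex")
      }
      if (nrow(ms) &&
          determine_sex(ms$depth_x, ms$depth_y) != "female") {
        reasons <- c(reasons, "mother_sex")
      }
    }
    list(trio_id = t$trio_id, pass = !length(reasons), reasons = reasons)
  })
  pass <- vapply(qc, function(x) x$pass, logical(1))
  kept <- trios[pass]

  # --- stage 2: variant filtering ---
  filtered <- lapply(kept, function(t) {
    mt_trio(t$trio_id, filter_callset(t$father), filter_callset(t$mother),
            filter_callset(t$child),
            extra_sibs = lapply(t$extra_sibs, filter_callset))
  })

  # --- stage 3: child-led trio screen ---
  screen <- screen_cohort(filtered, af_threshold = af_threshold,
                          homoplasmy_mismatch_min = homoplasmy_mismatch_min)
  status <- vapply(screen$classifications, function(x) x$status,
                   character(1))

  # --- stage 4: father-led heteroplasmy prescreen ---
  het_counts <- vapply(filtered, function(t) count_heteroplasmies(t$father),
                       integer(1))
  names(het_counts) <- vapply(filtered, function(t) t$father$sample_id,
                              character(1))
  iqr_fence <- if (length(het_counts) >= 4L)
    iqr_outlier_threshold(het_counts) else NA_real_
  prescreen_fathers <- names(het_counts)[het_counts > het_min]

  # --- stage 5: read-evidence NUMT detection in flagged families ---
  flagged_ids <- unique(c(
    vapply(filtered[status %in% c("mixed_haplotype_candidate",
                                  "excluded_homoplasmy_mismatch")],
           function(t) t$trio_id, character(1)),
    vapply(filtered[vapply(filtered, function(t)
      t$father$sample_id %in% prescreen_fathers, logical(1))],
      function(t) t$trio_id, character(1))))
  per_sample_calls <- list()
  if (!is.null(cohort$reads) && length(flagged_ids)) {
    refs <- cohort$refs
    for (t in filtered[vapply(filtered, function(t)
      t$trio_id %in% flagged_ids, logical(1))]) {
      for (member in list(t$father, t$mother, t$child)) {
        rd <- cohort$reads[[member$sample_id]]
        if (is.null(rd) || !nrow(rd)) next
        calls <- detect_numts_sample(rd, member$sample_id, refs$nuclear,
                                     refs$mt, ...)
        per_sample_calls <- c(per_sample_calls, calls)
      }
    }
  }

  # --- stage 6: cohort grouping + father screen ---
  numt_calls <- group_numts(per_sample_calls, cohort_size)
  fathers <- lapply(filtered, function(t) t$father)
  screen_hits <- find_meganumt_fathers(fathers, numt_calls,
                                       het_min = het_min,
                                       numt_freq_max = numt_freq_max,
                                       mt_span_min = mt_span_min)

  # --- stage 7: copy-number estimates for carrier fathers ---
  copy_estimates <- list()
  for (t in filtered) {
    fid <- t$father$sample_id
    if (!(fid %in% screen_hits)) next
    call <- Filter(function(nc) fid %in% nc$carriers, numt_calls)
    if (!length(call)) next
    call <- call[[1]]
    inf_keys <- informative_variants(t$father, t$mother,
                                     af_threshold = 0.01)
    v <- t$father$variants
    sel <- variant_key(v) %in% inf_keys & v$af <= 0.95
    if (!any(sel)) next
    dp_adj <- estimate_dp_adj(cohort$reads[[fid]], call$nuclear_contig,
                              round(mean(call$nuclear_interval)))
    if (dp_adj <= 0) next
    copy_estimates[[fid]] <- estimate_nmt(
      data.frame(key = variant_key(v)[sel], dp_mtvar = v$depth[sel],
                 alt_raw = v$alt_fwd[sel] + v$alt_rev[sel],
                 stringsAsFactors = FALSE),
      dp_adj, sample_id = fid, numt_id = call$numt_id)
  }

  # --- stage 8: transmission over carrier-father offspring pairs ---
  trans_pairs <- NULL
  for (t in filtered) {
    fid <- t$father$sample_id
    if (!(fid %in% screen_hits)) next
    call <- Filter(function(nc) fid %in% nc$carriers, numt_calls)
    if (!length(call)) next
    kids <- c(t$child$sample_id,
              vapply(t$extra_sibs, function(s) s$sample_id, character(1)))
    for (kid in kids) {
      trans_pairs <- rbind(trans_pairs, data.frame(
        father_id = fid, child_id = kid,
        transmitted = any(vapply(call, function(nc) kid %in% nc$carriers,
                                 logical(1))),
        stringsAsFactors = FALSE))
    }
  }
  transmission <- if (!is.null(trans_pairs) && nrow(trans_pairs)) {
    transmission_summary(trans_pairs$transmitted)
  } else NULL

  # candidate trios must either co-segregate with a NUMT call or be
  # flagged as unexplained
  cand_ids <- screen$candidates
  cand_numt <- vapply(cand_ids, function(tid) {
    t <- filtered[[which(vapply(filtered, function(x) x$trio_id == tid,
                                logical(1)))[1]]]
    any(vapply(numt_calls, function(nc)
      t$father$sample_id %in% nc$carriers, logical(1)))
  }, logical(1))

  structure(list(
    n_trios_input = n_total,
    n_trios_pass_qc = length(kept),
    qc = qc,
    screen = screen,
    candidate_fraction_pct = screen$candidate_fraction_pct,
    father_het_counts = het_counts,
    iqr_fence = iqr_fence,
    prescreen_fathers = prescreen_fathers,
    numt_calls = numt_calls,
    father_screen_hits = screen_hits,
    father_screen_fraction_pct =
      if (length(kept)) 100 * length(screen_hits) / length(kept) else 0,
    copy_estimates = copy_estimates,
    transmission_pairs = trans_pairs,
    transmission = transmission,
    candidate_numt_support = stats::setNames(cand_numt, cand_ids),
    thresholds = list(min_depth = min_depth, af_threshold = af_threshold,
                      homoplasmy_mismatch_min = homoplasmy_mismatch_min,
                      het_min = het_min, numt_freq_max = numt_freq_max,
                      mt_span_min = mt_span_min,
                      cohort_size = cohort_size)
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Mega-NUMT screen report\n")
  cat(sprintf("  trios: %d input, %d passing QC\n", x$n_trios_input,
              x$n_trios_pass_qc))
  for (s in names(x$screen$tally)) {
    cat(sprintf("  %-30s %d\n", s, x$screen$tally[[s]]))
  }
  cat(sprintf("  candidate fraction: %.2f%%\n", x$candidate_fraction_pct))
  cat(sprintf("  father screen: %d hit(s), %.2f%% of fathers\n",
              length(x$father_screen_hits), x$father_screen_fraction_pct))
  cat(sprintf("  NUMT calls: %d\n", length(x$numt_calls)))
  if (!is.null(x$transmission)) print(x$transmission)
  invisible(x)
}

#' Families sharing an identical NUMT
#'
#' Groups cohort-level NUMT calls whose carriers span more than one
#' family, reporting the shared mt-mt junctions - recurrent mega-NUMTs
#' co-segregate with identical mtDNA-derived junction sets across
#' unrelated families.
#'
#' @param calls List of `numt_call` objects from [group_numts()].
#' @param pedigree Data frame mapping samples to trios (columns
#'   `trio_id`, `father_id`, `mother_id`, `child_id`).
#' @return List of groups, each with `numt_id`, `trio_ids`, `carriers`
#'   and `mt_mt_junctions`.
#' @export
cross_family_numt_match <- function(calls, pedigree) {
  sample_trio <- c(
    stats::setNames(pedigree$trio_id, pedigree$father_id),
    stats::setNames(pedigree$trio_id, pedigree$mother_id),
    stats::setNames(pedigree$trio_id, pedigree$child_id))
  out <- list()
  for (nc in calls) {
    fams <- unique(unname(sample_trio[nc$carriers]))
    fams <- fams[!is.na(fams)]
    if (length(fams) < 2L) next
    jx <- nc$junctions
    mtmt <- if (!is.null(jx) && nrow(jx)) {
      unique(jx[jx$kind == "mt_mt",
                c("pos_a", "strand_a", "pos_b", "strand_b"), drop = FALSE])
    } else NULL
    out[[length(out) + 1L]] <- list(numt_id = nc$numt_id, trio_ids = fams,
                                    carriers = nc$carriers,
                                    mt_mt_junctions = mtmt)
  }
  out
}
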