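#' Construct a table of simplified aligned reads
#'
#' The package's SAM-level record: one row per aligned read end with its
#' own placement and (for paired reads) the mate's. Split/soft-clipped
#' reads carry the clip in `cigar` and the full sequence in `seq`.
#'
#' @param read_id Read (template) name; a pair shares one id.
#' @param contig Contig name (nuclear name or `"MT"`).
#' @param pos 1-based leftmost aligned position.
#' @param strand `"+"` or `"-"`.
#' @param mapq Mapping quality, 0..60.
#' @param cigar CIGAR string (e.g. `"150M"`, `"80M70S"`).
#' @param seq Read sequence (may be `NA` for pure pair evidence).
#' @param mate_contig,mate_pos,mate_strand Mate placement (`NA` for
#'   unpaired records).
#' @return A `data.frame` of class `aligned_reads`.
#' @export
aligned_reads <- function(read_id = character(), contig = character(),
                          pos = integer(), strand = character(),
                          mapq = integer(), cigar = character(),
                          seq = NA_character_, mate_contig = NA_character_,
                          mate_pos = NA_integer_,
                          mate_strand = NA_character_) {
  n <- length(read_id)
  r <- data.frame(
    read_id = as.character(read_id), contig = as.character(contig),
    pos = as.integer(pos), strand = as.character(strand),
    mapq = as.integer(mapq), cigar = as.character(cigar),
    seq = rep_len(as.character(seq), n),
    mate_contig = rep_len(as.character(mate_contig), n),
    mate_pos = rep_len(as.integer(mate_pos), n),
    mate_strand = rep_len(as.character(mate_strand), n),
    stringsAsFactors = FALSE)
  if (n) {
    stopifnot(all(r$pos >= 1L), all(r$mapq >= 0L & r$mapq <= 60L),
              all(r$strand %in% c("+", "-")))
  }
  class(r) <- c("aligned_reads", "data.frame")
  r
}

#' Extract nuclear-mtDNA discordant read pairs
#'
#' Keeps read pairs with exactly one end on a nuclear contig and the mate
#' on `"MT"`, both ends with mapping quality at least `mapq_min`.
#' Read ids present an unexpected number of times are skipped with a
#' warning.
#'
#' @param reads An [aligned_reads] table containing both ends of each
#'   pair as rows.
#' @param mapq_min Minimum mapping quality (default 20).
#' @return Data frame with one row per discordant pair: `read_id`,
#'   `nuclear_contig`, `nuclear_pos`, `nuclear_strand`, `mt_pos`,
#'   `mt_strand`.
#' @export
extract_discordant_pairs <- function(reads, mapq_min = 20L) {
  paired <- reads[!is.na(reads$mate_contig), , drop = FALSE]
  cnt <- table(paired$read_id)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad)) {
    warning("skipping ", length(bad),
            " read id(s) without exactly two paired ends")
    paired <- paired[!(paired$read_id %in% bad), , drop = FALSE]
  }
  empty <- data.frame(read_id = character(), nuclear_contig = character(),
                      nuclear_pos = integer(), nuclear_strand = character(),
                      mt_pos = integer(), mt_strand = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(paired)) return(empty)
  is_mt <- paired$contig == "MT"
  sp <- split(seq_len(nrow(paired)), paired$read_id)
  rows <- lapply(sp, function(ix) {
    if (sum(is_mt[ix]) != 1L) return(NULL)         # concordant or mt-mt pair
    if (any(paired$mapq[ix] < mapq_min)) return(NULL)
    nu <- ix[!is_mt[ix]]; mt <- ix[is_mt[ix]]
    data.frame(read_id = paired$read_id[nu],
               nuclear_contig = paired$contig[nu],
               nuclear_pos = paired$pos[nu],
               nuclear_strand = paired$strand[nu],
               mt_pos = paired$pos[mt], mt_strand = paired$strand[mt],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$nuclear_contig, out$nuclear_pos), , drop = FALSE]
}

#' Cluster discordant pairs into NUMT-candidate loci
#'
#' Pairs are partitioned by nuclear contig and orientation (the ordered
#' pair of nuclear-end and mt-end strands), their nuclear positions
#' sorted, and consecutive positions chained while the gap is at most
#' `gap` bp (single linkage). Chains supported by fewer than `min_pairs`
#' pairs are discarded. The cluster's mtDNA interval is the span of the
#' mate positions.
#'
#' @param pairs From [extract_discordant_pairs()].
#' @param gap Maximum chaining gap in bp (default 500).
#' @param min_pairs Minimum supporting pairs (default 5).
#' @return Data frame with one row per cluster: `nuclear_contig`,
#'   `start`, `end`, `nuclear_strand`, `mt_strand`, `mt_start`, `mt_end`,
#'   `n_pairs` and a `pair_ids` list-column.
#' @export
cluster_discordant <- function(pairs, gap = 500L, min_pairs = 5L) {
  empty <- data.frame(nuclear_contig = character(), start = integer(),
                      end = integer(), nuclear_strand = character(),
                      mt_strand = character(), mt_start = integer(),
                      mt_end = integer(), n_pairs = integer(),
                      stringsAsFactors = FALSE)
  empty$pair_ids <- list()
  if (!nrow(pairs)) return(empty)
  grp <- paste(pairs$nuclear_contig, pairs$nuclear_strand, pairs$mt_strand,
               sep = "\r")
  rows <- list()
  for (g in unique(grp)) {
    p <- pairs[grp == g, , drop = FALSE]
    p <- p[order(p$nuclear_pos), , drop = FALSE]
    cl <- cumsum(c(1L, diff(p$nuclear_pos) > gap))
    for (ci in unique(cl)) {
      m <- p[cl == ci, , drop = FALSE]
      if (nrow(m) < min_pairs) next
      row <- data.frame(nuclear_contig = m$nuclear_contig[1],
                        start = min(m$nuclear_pos), end = max(m$nuclear_pos),
                        nuclear_strand = m$nuclear_strand[1],
                        mt_strand = m$mt_strand[1],
                        mt_start = min(m$mt_pos), mt_end = max(m$mt_pos),
                        n_pairs = nrow(m), stringsAsFactors = FALSE)
      row$pair_ids <- list(m$read_id)
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$nuclear_contig, out$start), , drop = FALSE]
}

cigar_max_clip <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(0L)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    if (ops[1] == -1) return(0L)
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    clip <- grepl("[SH]$", toks)
    if (!any(clip)) return(0L)
    max(as.integer(sub("[MIDNSHP=X]$", "", toks[clip])))
  }, integer(1), USE.NAMES = FALSE)
}

#' Find split-read candidates near discordant clusters
#'
#' Returns soft-clipped reads (clip of at least `min_clip` bases) whose
#' nuclear position lies within `window` bp of a discordant cluster's
#' nuclear interval, plus all clipped reads aligned to `"MT"` (candidates
#' for junctions internal to an mtDNA-derived concatemer).
#'
#' @param reads An [aligned_reads] table.
#' @param clusters From [cluster_discordant()].
#' @param window Search window in bp (default 1000).
#' @param min_clip Minimum soft-clip length considered a split candidate
#'   (default 20, the minimum realignment piece).
#' @return The qualifying subset of `reads`.
#' @export
find_split_reads <- function(reads, clusters, window = 1000L,
                             min_clip = 20L) {
  if (!nrow(reads)) return(reads)
  clipped <- cigar_max_clip(reads$cigar) >= min_clip & !is.na(reads$seq)
  on_mt <- reads$contig == "MT"
  near <- rep(FALSE, nrow(reads))
  for (i in seq_len(nrow(clusters))) {
    near <- near | (reads$contig == clusters$nuclear_contig[i] &
                      reads$pos >= clusters$start[i] - window &
                      reads$pos <= clusters$end[i] + window)
  }
  reads[clipped & (on_mt | near), , drop = FALSE]
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# Canonical orientation of a junction: reading the opposite molecule
# strand swaps the sides and flips both strands, so pick the
# representation with the lexicographically smaller
# (contig, pos, strand) on side a; nuclear side always first for nu-mt.
canonical_junction <- function(ca, pa, sa, cb, pb, sb) {
  a_mt <- ca == "MT"; b_mt <- cb == "MT"
  swap <- ifelse(a_mt != b_mt,
                 a_mt,                       # nuclear side first
                 (ca > cb) | (ca == cb &
                                (pa > pb | (pa == pb & sa > sb))))
  out <- data.frame(contig_a = ca, pos_a = pa, strand_a = sa,
                    contig_b = cb, pos_b = pb, strand_b = sb,
                    stringsAsFactors = FALSE)
  if (any(swap)) {
    out[swap, ] <- data.frame(contig_a = cb[swap], pos_a = pb[swap],
                              strand_a = flip_strand(sb[swap]),
                              contig_b = ca[swap], pos_b = pa[swap],
                              strand_b = flip_strand(sa[swap]),
                              stringsAsFactors = FALSE)
  }
  out$kind <- ifelse(a_mt & b_mt, "mt_mt",
                     ifelse(a_mt | b_mt, "nu_mt", "nu_nu"))
  out
}

#' Call junctions from split-read realignments
#'
#' Groups split alignments whose breakpoint coordinates agree within
#' `tol` bp on both sides (single linkage, after canonicalising side
#' order and strand so that the two read orientations of one junction
#' coincide). Split support is the group size; the junction kind is
#' `nu_mt` when exactly one side is mitochondrial, `mt_mt` when both are.
#'
#' @param splits A list of results from [realign_split()] (`NULL`s are
#'   ignored).
#' @param tol Coordinate tolerance in bp (default 5).
#' @return Data frame with `kind`, `contig_a`, `pos_a`, `strand_a`,
#'   `contig_b`, `pos_b`, `strand_b`, `split_support`.
#' @export
call_junctions <- function(splits, tol = 5L) {
  splits <- splits[!vapply(splits, is.null, logical(1))]
  empty <- data.frame(kind = character(), contig_a = character(),
                      pos_a = integer(), strand_a = character(),
                      contig_b = character(), pos_b = integer(),
                      strand_b = character(), split_support = integer(),
                      stringsAsFactors = FALSE)
  if (!length(splits)) return(empty)
  tab <- canonical_junction(
    vapply(splits, function(s) s$side_a$contig, character(1)),
    vapply(splits, function(s) s$side_a$pos, integer(1)),
    vapply(splits, function(s) s$side_a$strand, character(1)),
    vapply(splits, function(s) s$side_b$contig, character(1)),
    vapply(splits, function(s) s$side_b$pos, integer(1)),
    vapply(splits, function(s) s$side_b$strand, character(1)))
  grp <- paste(tab$kind, tab$contig_a, tab$strand_a, tab$contig_b,
               tab$strand_b, sep = "\r")
  rows <- list()
  for (g in unique(grp)) {
    t2 <- tab[grp == g, , drop = FALSE]
    cl <- chain_2d(t2$pos_a, t2$pos_b, tol)
    for (ci in unique(cl)) {
      m <- t2[cl == ci, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        kind = m$kind[1], contig_a = m$contig_a[1],
        pos_a = as.integer(round(stats::median(m$pos_a))),
        strand_a = m$strand_a[1], contig_b = m$contig_b[1],
        pos_b = as.integer(round(stats::median(m$pos_b))),
        strand_b = m$strand_b[1], split_support = nrow(m),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$kind, out$contig_a, out$pos_a), , drop = FALSE]
}

# single-linkage components where |dx| <= tol and |dy| <= tol
chain_2d <- function(x, y, tol) {
  n <- length(x)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      link <- abs(x - x[i]) <= tol & abs(y - y[i]) <= tol
      tgt <- min(comp[link])
      if (any(comp[link] != tgt)) {
        comp[comp %in% comp[link]] <- tgt
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' Group per-sample NUMT detections into cohort-level calls
#'
#' Two per-sample detections merge (single linkage, across samples) when
#' they lie on the same nuclear contig with nuclear intervals within
#' `gap` bp of each other *and* mtDNA intervals within `gap` bp - the
#' both-axis rule keeps distinct insertions of different mtDNA regions at
#' nearby nuclear loci apart. Carriers are the union of sample ids and
#' the cohort frequency is carriers divided by `cohort_size`
#' (individuals). Mega-NUMT evidence is any mt-mt junction supported by
#' more than two split reads in a single carrier.
#'
#' @param per_sample_calls List of per-sample detections from
#'   [detect_numts_sample()].
#' @param cohort_size Number of individuals in the cohort.
#' @param gap Merge distance in bp (default 1000).
#' @return List of `numt_call` objects.
#' @export
group_numts <- function(per_sample_calls, cohort_size, gap = 1000L) {
  stopifnot(cohort_size >= 1)
  n <- length(per_sample_calls)
  if (!n) return(list())
  builds <- unique(vapply(per_sample_calls, function(x) {
    if (is.null(x$build)) "default" else x$build
  }, character(1)))
  if (length(builds) > 1L) {
    stop("per-sample calls come from different reference builds (",
         paste(builds, collapse = ", "), "); lift over upstream")
  }
  comp <- seq_len(n)
  idist <- function(s1, e1, s2, e2) max(0L, max(s1, s2) - min(e1, e2))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- per_sample_calls[[i]]; b <- per_sample_calls[[j]]
      if (a$nuclear_contig != b$nuclear_contig) next
      if (idist(a$nuclear_interval[1], a$nuclear_interval[2],
                b$nuclear_interval[1], b$nuclear_interval[2]) > gap) next
      if (idist(a$mt_interval[1], a$mt_interval[2],
                b$mt_interval[1], b$mt_interval[2]) > gap) next
      tgt <- min(comp[c(i, j)])
      comp[comp %in% comp[c(i, j)]] <- tgt
    }
  }
  groups <- split(seq_len(n), comp)
  calls <- lapply(seq_along(groups), function(k) {
    members <- per_sample_calls[groups[[k]]]
    junctions <- do.call(rbind, lapply(members, function(m) {
      if (is.null(m$junctions) || !nrow(m$junctions)) return(NULL)
      cbind(m$junctions, sample_id = m$sample_id, stringsAsFactors = FALSE)
    }))
    mt_bp <- numt_mt_breakpoints(members, junctions)
    carriers <- sort(unique(vapply(members, function(m) m$sample_id,
                                   character(1))))
    mega <- !is.null(junctions) &&
      any(junctions$kind == "mt_mt" & junctions$split_support > 2L)
    structure(list(
      numt_id = sprintf("numt_%s_%d", members[[1]]$nuclear_contig,
                        min(vapply(members, function(m)
                          m$nuclear_interval[1], numeric(1)))),
      nuclear_contig = members[[1]]$nuclear_contig,
      nuclear_interval = c(
        min(vapply(members, function(m) m$nuclear_interval[1], numeric(1))),
        max(vapply(members, function(m) m$nuclear_interval[2], numeric(1)))),
      mt_interval = c(
        min(vapply(members, function(m) m$mt_interval[1], numeric(1))),
        max(vapply(members, function(m) m$mt_interval[2], numeric(1)))),
      junctions = junctions,
      mt_breakpoints = mt_bp,
      n_discordant = sum(vapply(members, function(m) m$n_discordant,
                                numeric(1))),
      n_split = sum(vapply(members, function(m) m$n_split, numeric(1))),
      carriers = carriers,
      cohort_frequency = length(carriers) / cohort_size,
      mega_evidence = mega
    ), class = "numt_call")
  })
  calls[order(vapply(calls, function(x) x$nuclear_contig, character(1)),
              vapply(calls, function(x) x$nuclear_interval[1], numeric(1)))]
}

# mtDNA breakpoints of a NUMT: the mt sides of its nu-mt junctions
# (base-precise, Table-style); when split evidence leaves fewer than two,
# fall back to the discordant-cluster mtDNA interval bounds.
numt_mt_breakpoints <- function(members, junctions) {
  bp <- NULL
  if (!is.null(junctions) && nrow(junctions)) {
    num <- junctions[junctions$kind == "nu_mt", , drop = FALSE]
    if (nrow(num)) {
      bp <- unique(data.frame(pos = num$pos_b, strand = num$strand_b,
                              stringsAsFactors = FALSE))
    }
  }
  if (is.null(bp) || nrow(bp) < 2L) {
    iv <- data.frame(
      pos = unlist(lapply(members, function(m) m$mt_interval)),
      strand = NA_character_, stringsAsFactors = FALSE)
    bp <- unique(rbind(bp, iv))
  }
  bp[order(bp$pos), , drop = FALSE]
}

#' @export
print.numt_call <- function(x, ...) {
  cat(sprintf(
    "NUMT %s: %s:%d-%d | mt breakpoints %s | %d discordant, %d split | %d carrier(s), freq %.4f%%%s\n",
    x$numt_id, x$nuclear_contig, x$nuclear_interval[1],
    x$nuclear_interval[2],
    paste0(x$mt_breakpoints$pos,
           ifelse(is.na(x$mt_breakpoints$strand), "",
                  paste0("(", x$mt_breakpoints$strand, ")")),
           collapse = " / "),
    x$n_discordant, x$n_split, length(x$carriers),
    100 * x$cohort_frequency,
    if (x$mega_evidence) " | mega-NUMT evidence" else ""))
  invisible(x)
}

#' Linear mtDNA span of a NUMT call
#'
#' Distance between the two outermost mtDNA breakpoints on the printed
#' (linear) coordinate system; no circular wrap is applied, matching how
#' breakpoint pairs are reported.
#'
#' @param call A `numt_call`.
#' @return Span in bp.
#' @export
mt_span <- function(call) {
  pos <- call$mt_breakpoints$pos
  if (length(pos) < 2L) {
    stop("mtDNA span undefined: NUMT ", call$numt_id,
         " has fewer than two mtDNA breakpoints")
  }
  max(pos) - min(pos)
}

#' Detect NUMT candidates in one sample
#'
#' Runs the full read-evidence chain for a single sample: discordant-pair
#' extraction, clustering, split-read search, two-piece realignment and
#' junction calling, then merges clusters within `locus_gap` bp on the
#' same contig into per-insertion detections.
#'
#' @param reads An [aligned_reads] table for the sample.
#' @param sample_id Sample identifier.
#' @param nuclear_refs Named list of full nuclear contig sequences
#'   (character).
#' @param mt_ref mtDNA reference sequence.
#' @param mapq_min,gap,min_pairs,window,min_clip,tol Stage thresholds, see
#'   the stage functions.
#' @param locus_gap Clusters within this distance on the same contig are
#'   one insertion locus (default 1000).
#' @param realign_pad Nuclear window half-width around a locus used for
#'   split realignment (default 2000).
#' @return List of per-sample detections (possibly empty), each a list
#'   with `sample_id`, `nuclear_contig`, `nuclear_interval`,
#'   `mt_interval`, `junctions`, `n_discordant`, `n_split`.
#' @export
detect_numts_sample <- function(reads, sample_id, nuclear_refs, mt_ref,
                                mapq_min = 20L, gap = 500L, min_pairs = 5L,
                                window = 1000L, min_clip = 20L, tol = 5L,
                                locus_gap = 1000L, realign_pad = 2000L) {
  pairs <- extract_discordant_pairs(reads, mapq_min)
  clusters <- cluster_discordant(pairs, gap, min_pairs)
  if (!nrow(clusters)) return(list())
  splits_cand <- find_split_reads(reads, clusters, window, min_clip)

  # merge clusters into insertion loci (orientation-blind, same contig)
  loci <- list()
  for (ctg in unique(clusters$nuclear_contig)) {
    cc <- clusters[clusters$nuclear_contig == ctg, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    li <- cumsum(c(1L, pmax(cc$start[-1] - cummax(cc$end[-nrow(cc)]),
                            0L) > locus_gap))
    for (l in unique(li)) loci[[length(loci) + 1L]] <-
        cc[li == l, , drop = FALSE]
  }

  lapply(loci, function(cl) {
    ctg <- cl$nuclear_contig[1]
    lo <- max(1L, min(cl$start) - realign_pad)
    hi <- min(nchar(nuclear_refs[[ctg]]), max(cl$end) + realign_pad)
    targets <- make_split_targets(
      stats::setNames(list(list(seq = substr(nuclear_refs[[ctg]], lo, hi),
                                origin = lo - 1L)), ctg),
      mt_ref)
    near <- splits_cand$contig == "MT" |
      (splits_cand$contig == ctg &
         splits_cand$pos >= min(cl$start) - window &
         splits_cand$pos <= max(cl$end) + window)
    sr <- splits_cand[near, , drop = FALSE]
    splits <- lapply(sr$seq, realign_split, targets = targets,
                     min_piece = min_clip)
    junctions <- call_junctions(splits, tol)
    list(sample_id = sample_id,
         nuclear_contig = ctg,
         nuclear_interval = c(min(cl$start), max(cl$end)),
         mt_interval = c(min(cl$mt_start), max(cl$mt_end)),
         junctions = junctions,
         n_discordant = sum(cl$n_pairs),
         n_split = if (nrow(junctions)) sum(junctions$split_support) else 0L)
  })
}

#' Write cohort NUMT calls as a BED-like TSV
#'
#' @param calls List of `numt_call` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_numt_tsv <- function(calls, path) {
  rows <- lapply(calls, function(x) {
    data.frame(
      nuclear_contig = x$nuclear_contig,
      start = x$nuclear_interval[1], end = x$nuclear_interval[2],
      numt_id = x$numt_id, n_discordant = x$n_discordant,
      n_split = x$n_split,
      mt_breakpoints = paste0(
        x$mt_breakpoints$pos,
        ifelse(is.na(x$mt_breakpoints$strand), "",
               paste0("(", x$mt_breakpoints$strand, ")")), collapse = ";"),
      carriers = paste(x$carriers, collapse = ";"),
      frequency = x$cohort_frequency,
      mega_evidence = x$mega_evidence, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(nuclear_contig = character(), start = integer(),
                      end = integer(), numt_id = character(),
                      n_discordant = integer(), n_split = integer(),
                      mt_breakpoints = character(), carriers = character(),
                      frequency = numeric(), mega_evidence = logical())
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
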