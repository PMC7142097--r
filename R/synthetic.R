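#' Configuration for synthetic trio cohorts
#'
#' Defaults emulate the study conditions the package targets: 150 bp
#' paired reads, nuclear depth 30-99x, true mtDNA depth 200-4500x,
#' mega-NUMTs of 2-20 concatenated mtDNA-derived fragment copies
#' transmitted autosomally with probability 1/2, and father-mother mtDNA
#' haplotype divergence in two regimes (same haplogroup background: 1-5
#' differing sites; different: 20-40).
#'
#' @param n_trios Number of trios.
#' @param read_length Read length in bp.
#' @param dp_nu_range Nuclear depth range (x).
#' @param dp_mt_range True mtDNA depth range (x).
#' @param p_father_numt Fraction of fathers carrying a planted mega-NUMT.
#' @param n_numt_fathers Exact number of planted carrier fathers
#'   (overrides `p_father_numt` when non-`NULL`).
#' @param n_transmitting Exact number of carriers transmitting
#'   (`NULL`: each transmits independently with `p_transmit`).
#' @param nmt_copies_range Range of concatemer copy numbers K.
#' @param mt_fragment_min_span Minimum mtDNA span of each inserted
#'   fragment in bp (keeps planted NUMTs in the "large" class, breakpoint
#'   span well above 500 bp).
#' @param p_transmit Autosomal transmission probability.
#' @param haplogroup_divergence List with `same` and `different` ranges of
#'   father-mother differing site counts.
#' @param p_different_haplogroup Fraction of trios whose parents come
#'   from different haplogroup backgrounds.
#' @param n_numt_sites_range Range of divergent sites carried by the NUMT
#'   source haplotype within the inserted fragments; the lower bound
#'   keeps carrier heteroplasmy counts above the father-screen threshold.
#' @param htf_band Range of expected mixed-haplotype fractions realised
#'   in planted carriers; emulates the observed 5-25% band while leaving
#'   a safety margin to the 5% detection threshold.
#' @param carrier_dp_mt_min Minimum mtDNA depth drawn for members of
#'   planted trios (keeps them clear of the 500x QC floor).
#' @param background_het_rate Poisson mean of low-level background
#'   heteroplasmies per sample (allele fractions 1.5-4%).
#' @param nuclear_length,nuclear_contig Length and name of the synthetic
#'   nuclear contig carrying insertions.
#' @param disc_rate,split_rate Poisson intensity factors: discordant
#'   pairs per junction side ~ Pois(`disc_rate * dp_nu`), split reads per
#'   junction occurrence ~ Pois(`split_rate * dp_nu`).
#' @param max_split_per_junction Cap on emitted split reads per junction
#'   type (keeps read sets at realistic evidence levels).
#' @param noise_discordant Number of random scattered nuclear-mt
#'   discordant pairs per sample (default 0: clean background).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_trios = 50L, read_length = 150L,
                       dp_nu_range = c(30, 99),
                       dp_mt_range = c(200, 4500),
                       p_father_numt = 0.01,
                       n_numt_fathers = NULL,
                       n_transmitting = NULL,
                       nmt_copies_range = c(2L, 20L),
                       mt_fragment_min_span = 1000L,
                       p_transmit = 0.5,
                       haplogroup_divergence = list(same = c(1L, 5L),
                                                    different = c(20L, 40L)),
                       p_different_haplogroup = 0.5,
                       n_numt_sites_range = c(14L, 25L),
                       htf_band = c(0.08, 0.35),
                       carrier_dp_mt_min = 600,
                       background_het_rate = 2,
                       nuclear_length = 100000L,
                       nuclear_contig = "chrN",
                       disc_rate = 1 / 3, split_rate = 1 / 5,
                       max_split_per_junction = 30L,
                       noise_discordant = 0L,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_trios >= 0, read_length > 40,
            diff(dp_nu_range) >= 0, diff(dp_mt_range) >= 0,
            p_father_numt >= 0, p_father_numt <= 1,
            p_transmit >= 0, p_transmit <= 1,
            nmt_copies_range[1] >= 1,
            htf_band[1] > 0.05, htf_band[2] < 0.5)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate synthetic reference sequences
#'
#' A uniform-random nuclear contig and a 16,569 bp uniform-random
#' mitochondrial sequence (rCRS coordinate length). A real rCRS FASTA can
#' be substituted for the mtDNA downstream; all coordinates are
#' compatible.
#'
#' @param seed Optional integer seed (omit to draw from the current RNG
#'   stream).
#' @param nuclear_length Nuclear contig length in bp.
#' @param nuclear_contig Nuclear contig name.
#' @return List with `nuclear` (named list of contig sequences) and `mt`.
#' @export
make_references <- function(seed = NULL, nuclear_length = 100000L,
                            nuclear_contig = "chrN") {
  if (!is.null(seed)) set.seed(seed)
  nuc <- stats::setNames(list(random_dna(nuclear_length)), nuclear_contig)
  list(nuclear = nuc, mt = random_dna(MT_GENOME_LENGTH))
}

# positions eligible for planted variant sites: outside masked regions
# and outside `exclude`
site_pool <- function(exclude = integer(), region = NULL) {
  pool <- if (is.null(region)) seq_len(MT_GENOME_LENGTH) else region
  pool <- pool[!in_masked_region(pool)]
  setdiff(pool, exclude)
}

# draw n variant sites (pos, ref, alt) from the pool
draw_sites <- function(n, mt_ref, exclude = integer(), region = NULL) {
  if (n == 0L) {
    return(data.frame(pos = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  }
  pool <- site_pool(exclude, region)
  if (n > length(pool)) stop("site pool exhausted")
  pos <- sort(sample(pool, n))
  ref <- toupper(substring(mt_ref, pos, pos))
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Plant a mega-NUMT
#'
#' Draws an autosomal insertion of K concatenated copies of one or two
#' large mtDNA-derived fragments. The NUMT source haplotype is modelled
#' as the designated founder father's mtDNA haplotype plus
#' `n_numt_sites` additional divergent sites inside the inserted
#' fragments; what the screen observes is exactly the set of differences
#' between the NUMT-derived sequence and each carrier's own mtDNA.
#'
#' @param config A [sim_config].
#' @param refs From [make_references()].
#' @param numt_id Identifier.
#' @param insertion_pos 1-based nuclear position after which the
#'   concatemer is inserted.
#' @param founder_sites The founder father's haplotype site table.
#' @return A list of class `planted_numt` with `fragments`
#'   (`mt_start`, `mt_end`, `strand`), `copies`, `numt_sites`,
#'   `source_sites` (founder haplotype plus NUMT-private sites) and
#'   `mt_positions` (covered mtDNA positions).
#' @export
plant_numt <- function(config, refs, numt_id, insertion_pos,
                       founder_sites) {
  mlen <- MT_GENOME_LENGTH
  repeat {
    n_frag <- sample(1:2, 1)
    frags <- lapply(seq_len(n_frag), function(i) {
      span <- round(stats::runif(1, config$mt_fragment_min_span,
                                 min(8000, mlen / 2)))
      start <- sample(mlen - span, 1)
      data.frame(mt_start = start, mt_end = start + span,
                 strand = sample(c("+", "-"), 1),
                 stringsAsFactors = FALSE)
    })
    frags <- do.call(rbind, frags)
    if (any(frags$mt_start < 1 | frags$mt_end > mlen)) {
      stop("planted fragment outside mtDNA coordinates")
    }
    entry <- frag_boundary(frags[1, ], "entry")
    exit <- frag_boundary(frags[nrow(frags), ], "exit")
    # the two outer mtDNA breakpoints must be well beyond the 500 bp
    # large-NUMT rule, and fragments must not overlap each other
    ok_span <- abs(entry$pos - exit$pos) > 600
    ivs <- frags[order(frags$mt_start), ]
    ok_disjoint <- n_frag == 1 ||
      all(ivs$mt_start[-1] > ivs$mt_end[-nrow(ivs)] + 10)
    if (ok_span && ok_disjoint) break
  }
  copies <- sample(seq(config$nmt_copies_range[1],
                       config$nmt_copies_range[2]), 1)
  mt_positions <- sort(unique(unlist(
    Map(seq, frags$mt_start, frags$mt_end))))
  n_sites <- sample(seq(config$n_numt_sites_range[1],
                        config$n_numt_sites_range[2]), 1)
  numt_sites <- draw_sites(n_sites, refs$mt,
                           exclude = founder_sites$pos,
                           region = mt_positions)
  structure(list(
    numt_id = numt_id,
    nuclear_contig = names(refs$nuclear)[1],
    insertion_pos = as.integer(insertion_pos),
    fragments = frags, copies = copies,
    numt_sites = numt_sites,
    source_sites = rbind(founder_sites, numt_sites),
    mt_positions = mt_positions
  ), class = "planted_numt")
}

# junction-adjacent mtDNA coordinate of a fragment boundary, reading
# along the concatemer
frag_boundary <- function(frag, which = c("entry", "exit")) {
  which <- match.arg(which)
  if (frag$strand == "+") {
    if (which == "entry") list(pos = frag$mt_start, strand = "+")
    else list(pos = frag$mt_end, strand = "+")
  } else {
    if (which == "entry") list(pos = frag$mt_end, strand = "-")
    else list(pos = frag$mt_start, strand = "-")
  }
}

#' Distinct junction types of a planted concatemer
#'
#' @param numt A `planted_numt`.
#' @return Data frame of junction types: `kind` (`nu_mt`/`mt_mt`),
#'   side coordinates and `occurrences` in the K-fold concatemer.
#' @export
numt_junction_truth <- function(numt) {
  fr <- numt$fragments
  m <- nrow(fr)
  rows <- list()
  en1 <- frag_boundary(fr[1, ], "entry")
  exm <- frag_boundary(fr[m, ], "exit")
  rows[[1]] <- data.frame(
    kind = "nu_mt", contig_a = numt$nuclear_contig,
    pos_a = numt$insertion_pos, strand_a = "+",
    contig_b = "MT", pos_b = en1$pos, strand_b = en1$strand,
    occurrences = 1L, stringsAsFactors = FALSE)
  rows[[2]] <- data.frame(
    kind = "nu_mt", contig_a = "MT", pos_a = exm$pos, strand_a = exm$strand,
    contig_b = numt$nuclear_contig, pos_b = numt$insertion_pos + 1L,
    strand_b = "+", occurrences = 1L, stringsAsFactors = FALSE)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      ex <- frag_boundary(fr[i, ], "exit")
      en <- frag_boundary(fr[i + 1, ], "entry")
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "mt_mt", contig_a = "MT", pos_a = ex$pos, strand_a = ex$strand,
        contig_b = "MT", pos_b = en$pos, strand_b = en$strand,
        occurrences = numt$copies, stringsAsFactors = FALSE)
    }
  }
  if (numt$copies > 1) {
    ex <- frag_boundary(fr[m, ], "exit")
    en <- frag_boundary(fr[1, ], "entry")
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "mt_mt", contig_a = "MT", pos_a = ex$pos, strand_a = ex$strand,
      contig_b = "MT", pos_b = en$pos, strand_b = en$strand,
      occurrences = numt$copies - 1L, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# apply a haplotype site table to a reference sequence
apply_sites <- function(seq, sites) {
  if (!nrow(sites)) return(seq)
  s <- strsplit(seq, NULL)[[1]]
  s[sites$pos] <- sites$alt
  paste(s, collapse = "")
}

frag_seq <- function(frag, source_seq) {
  s <- substr(source_seq, frag$mt_start, frag$mt_end)
  if (frag$strand == "-") revcomp_chr(s) else s
}

#' Simulate aligned read evidence for a planted NUMT in one carrier
#'
#' Emits (i) discordant read pairs spanning each nuclear-mt junction side
#' (count ~ Poisson(`disc_rate * dp_nu`) per side, mates placed inside
#' the adjacent fragment); (ii) split reads crossing each nuclear-mt
#' junction and each distinct mt-mt junction of the concatemer (count ~
#' Poisson(`split_rate * dp_nu` x occurrences), capped), with sequences
#' literally constructed from the two reference sides; and (iii)
#' concordant background pairs at `dp_nu` coverage within 5 kb of the
#' insertion (used downstream for flanking-depth estimation).
#'
#' @param numt A `planted_numt`.
#' @param refs From [make_references()].
#' @param dp_nu Nuclear depth for this sample.
#' @param sample_id Sample identifier (prefixes read names).
#' @param config A [sim_config].
#' @param seed Optional seed.
#' @return An [aligned_reads] table.
#' @export
simulate_numt_reads <- function(numt, refs, dp_nu, sample_id,
                                config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(numt$fragments$mt_start < 1 |
            numt$fragments$mt_end > MT_GENOME_LENGTH)) {
    stop("planted fragment outside mtDNA coordinates")
  }
  L <- config$read_length
  chr <- numt$nuclear_contig
  nuc <- refs$nuclear[[chr]]
  source_seq <- apply_sites(refs$mt, numt$source_sites)
  fr <- numt$fragments
  m <- nrow(fr)
  ip <- numt$insertion_pos
  out <- list()
  rid <- 0L
  nid <- function(type) {
    rid <<- rid + 1L
    sprintf("%s_%s_%d", sample_id, type, rid)
  }

  # --- discordant pairs, left and right junction sides ---
  emit_disc <- function(side) {
    n <- stats::rpois(1, config$disc_rate * dp_nu)
    if (!n) return(NULL)
    frag <- if (side == "left") fr[1, ] else fr[m, ]
    flen <- frag$mt_end - frag$mt_start + 1L
    rows <- lapply(seq_len(n), function(i) {
      id <- nid(paste0("disc", substr(side, 1, 1)))
      if (side == "left") {
        npos <- ip - L - sample.int(300L, 1)
        nstrand <- "+"
      } else {
        npos <- ip + 1L + sample.int(300L, 1)
        nstrand <- "-"
      }
      off <- sample.int(max(1L, min(400L, flen - L)), 1) - 1L
      if (side == "left") {
        # mate lies near the concatemer start, inside fragment 1
        mpos <- if (frag$strand == "+") frag$mt_start + off
                else frag$mt_end - off - L + 1L
        mstrand <- if (frag$strand == "+") "-" else "+"
      } else {
        mpos <- if (frag$strand == "+") frag$mt_end - off - L + 1L
                else frag$mt_start + off
        mstrand <- if (frag$strand == "+") "+" else "-"
      }
      aligned_reads(
        read_id = c(id, id), contig = c(chr, "MT"),
        pos = c(npos, mpos), strand = c(nstrand, mstrand),
        mapq = 60L, cigar = paste0(L, "M"), seq = NA_character_,
        mate_contig = c("MT", chr), mate_pos = c(mpos, npos),
        mate_strand = c(mstrand, nstrand))
    })
    do.call(rbind, rows)
  }
  out$discL <- emit_disc("left")
  out$discR <- emit_disc("right")

  # --- split reads across every junction type ---
  jt <- numt_junction_truth(numt)
  left_flank <- substr(nuc, ip - L + 1L, ip)
  right_flank <- substr(nuc, ip + 1L, ip + L)
  fseqs <- lapply(seq_len(m), function(i) frag_seq(fr[i, ], source_seq))
  side_seq <- function(contig, pos, strand, role) {
    # role "a": sequence ENDING at the junction (read direction)
    # role "b": sequence STARTING at the junction
    if (contig != "MT") {
      if (role == "a") left_flank else right_flank
    } else {
      plus_bp <- if (role == "a") fr$mt_end else fr$mt_start
      minus_bp <- if (role == "a") fr$mt_start else fr$mt_end
      fi <- which((fr$strand == "+" & pos == plus_bp) |
                    (fr$strand == "-" & pos == minus_bp))
      fi <- fi[1]
      fs <- fseqs[[fi]]
      if (role == "a") substr(fs, nchar(fs) - L + 1L, nchar(fs))
      else substr(fs, 1L, L)
    }
  }
  anchor <- function(contig, pos, strand, u) {
    # SAM-style anchor of the read's first (matched) u bases on side a
    if (contig != "MT") {
      list(contig = contig, pos = ip - u + 1L, strand = "+",
           cigar = paste0(u, "M", L - u, "S"))
    } else if (strand == "+") {
      list(contig = "MT", pos = pos - u + 1L, strand = "+",
           cigar = paste0(u, "M", L - u, "S"))
    } else {
      list(contig = "MT", pos = pos, strand = "-",
           cigar = paste0(L - u, "S", u, "M"))
    }
  }
  for (j in seq_len(nrow(jt))) {
    n <- stats::rpois(1, config$split_rate * dp_nu * jt$occurrences[j])
    n <- min(n, config$max_split_per_junction)
    if (!n) next
    sa <- side_seq(jt$contig_a[j], jt$pos_a[j], jt$strand_a[j], "a")
    sb <- side_seq(jt$contig_b[j], jt$pos_b[j], jt$strand_b[j], "b")
    rows <- lapply(seq_len(n), function(i) {
      u <- sample(25:(L - 25), 1)
      rseq <- paste0(substr(sa, L - u + 1L, L), substr(sb, 1L, L - u))
      an <- anchor(jt$contig_a[j], jt$pos_a[j], jt$strand_a[j], u)
      aligned_reads(read_id = nid(paste0("split", j)), contig = an$contig,
                    pos = max(1L, an$pos), strand = an$strand, mapq = 60L,
                    cigar = an$cigar, seq = rseq)
    })
    out[[paste0("split", j)]] <- do.call(rbind, rows)
  }

  out$bg <- simulate_background_reads(chr, nuc, ip, dp_nu, sample_id, config)
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  class(res) <- c("aligned_reads", "data.frame")
  res
}

#' Simulate concordant background read pairs around a locus
#'
#' @param chr Contig name.
#' @param nuc Contig sequence.
#' @param center Locus centre position.
#' @param dp_nu Depth of coverage.
#' @param sample_id Read-name prefix.
#' @param config A [sim_config].
#' @param halfwidth Window half-width in bp (default 5000).
#' @return An [aligned_reads] table of proper pairs.
#' @export
simulate_background_reads <- function(chr, nuc, center, dp_nu, sample_id,
                                      config = sim_config(),
                                      halfwidth = 5000L) {
  L <- config$read_length
  lo <- max(1L, center - halfwidth)
  hi <- min(nchar(nuc) - 2L * L - 200L, center + halfwidth)
  n_pairs <- round(dp_nu * (hi - lo) / (2 * L))
  if (n_pairs < 1) return(NULL)
  p1 <- lo + sample.int(hi - lo, n_pairs, replace = TRUE) - 1L
  p2 <- p1 + L + 50L
  ids <- sprintf("%s_bg_%d", sample_id, seq_len(n_pairs))
  aligned_reads(
    read_id = rep(ids, each = 2L),
    contig = chr,
    pos = as.vector(rbind(p1, p2)),
    strand = rep(c("+", "-"), n_pairs),
    mapq = 60L, cigar = paste0(L, "M"), seq = NA_character_,
    mate_contig = chr,
    mate_pos = as.vector(rbind(p2, p1)),
    mate_strand = rep(c("-", "+"), n_pairs))
}

# scattered artefactual nuclear-mt pairs (never >= min_pairs clustered)
simulate_noise_reads <- function(chr, nuc_len, n, sample_id, config) {
  if (n < 1) return(NULL)
  L <- config$read_length
  pos <- sample.int(nuc_len - L, n)
  mpos <- sample.int(MT_GENOME_LENGTH - L, n)
  ids <- sprintf("%s_noise_%d", sample_id, seq_len(n))
  aligned_reads(
    read_id = rep(ids, each = 2L),
    contig = as.vector(rbind(rep(chr, n), rep("MT", n))),
    pos = as.vector(rbind(pos, mpos)),
    strand = sample(c("+", "-"), 2L * n, replace = TRUE),
    mapq = 60L, cigar = paste0(L, "M"), seq = NA_character_,
    mate_contig = as.vector(rbind(rep("MT", n), rep(chr, n))),
    mate_pos = as.vector(rbind(mpos, pos)),
    mate_strand = "+")
}

# expected (noise-free) allele fractions for one sample; own_sites is the
# sample's mtDNA haplotype, source_sites the NUMT content (NULL for
# non-carriers), cov_numt = dp_nu/2 * K
expected_site_table <- function(own_sites, dp_mt, source_sites = NULL,
                                mt_positions = NULL, cov_numt = 0) {
  all_sites <- unique(rbind(own_sites,
                            if (!is.null(source_sites)) source_sites))
  if (!nrow(all_sites)) {
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      in_numt = logical(), exp_depth = numeric(),
                      exp_af = numeric(), stringsAsFactors = FALSE))
  }
  own <- paste0(own_sites$pos, ":", own_sites$alt)
  src <- if (is.null(source_sites)) character() else
    paste0(source_sites$pos, ":", source_sites$alt)
  key <- paste0(all_sites$pos, ":", all_sites$alt)
  in_numt <- !is.null(mt_positions) & all_sites$pos %in% mt_positions
  dp <- dp_mt + ifelse(in_numt, cov_numt, 0)
  alt_cov <- dp_mt * (key %in% own) +
    ifelse(in_numt, cov_numt, 0) * (key %in% src)
  out <- all_sites
  out$in_numt <- in_numt
  out$exp_depth <- dp
  out$exp_af <- alt_cov / dp
  out[out$exp_af > 0, , drop = FALSE]
}

# binomial-sample a callset from an expected site table, adding
# background heteroplasmies
sample_callset <- function(sample_id, exp_tab, dp_mt, config, mt_ref) {
  n_bg <- stats::rpois(1, config$background_het_rate)
  if (n_bg > 0) {
    bg <- draw_sites(n_bg, mt_ref, exclude = exp_tab$pos)
    bg$in_numt <- FALSE
    bg$exp_depth <- dp_mt
    bg$exp_af <- stats::runif(n_bg, 0.015, 0.04)
  } else {
    bg <- NULL
  }
  tab <- rbind(exp_tab, bg)
  if (is.null(tab) || !nrow(tab)) {
    return(mt_callset(sample_id, mt_variants(), mean_mt_depth = dp_mt))
  }
  depth <- stats::rpois(nrow(tab), tab$exp_depth)
  depth[depth < 1L] <- 1L
  alt_n <- stats::rbinom(nrow(tab), depth, pmin(tab$exp_af, 1))
  keep <- alt_n > 0L
  tab <- tab[keep, , drop = FALSE]
  depth <- depth[keep]; alt_n <- alt_n[keep]
  alt_fwd <- stats::rbinom(length(alt_n), alt_n, 0.5)
  ref_n <- depth - alt_n
  ref_fwd <- stats::rbinom(length(ref_n), ref_n, 0.5)
  v <- mt_variants(pos = tab$pos, ref = tab$ref, alt = tab$alt,
                   depth = depth, alt_fwd = alt_fwd,
                   alt_rev = alt_n - alt_fwd, ref_fwd = ref_fwd,
                   ref_rev = ref_n - ref_fwd)
  mt_callset(sample_id, v, mean_mt_depth = dp_mt)
}

# expected-value trio classification: the generator's independent ground
# truth, computed from noise-free allele fractions with the screening
# thresholds (presence floor 1%, detection 5%, homoplasmy 95%,
# >= 3 missing homoplasmies)
expected_classification <- function(fa, mo, ch, transmitted) {
  keyf <- paste0(fa$pos, ":", fa$alt)
  keym <- paste0(mo$pos, ":", mo$alt)
  keyc <- paste0(ch$pos, ":", ch$alt)
  present_m <- keym[mo$exp_af > 0.01]
  inf <- keyf[fa$exp_af > 0.05 & !(keyf %in% present_m)]
  det_c <- keyc[ch$exp_af > 0.05]
  shared <- inf[inf %in% det_c]
  homop <- keyf[fa$exp_af > 0.95]
  missing <- homop[!(homop %in% det_c)]
  status <- if (!length(inf)) "non_informative"
  else if (!length(shared)) "informative_only"
  else if (length(missing) >= 3L) "excluded_homoplasmy_mismatch"
  else "mixed_haplotype_candidate"
  list(status = status, informative = inf, shared = shared,
       missing_homoplasmies = missing)
}

# draw a carrier's depths so the realised mixed-haplotype fraction falls
# inside config$htf_band while respecting depth ranges and the QC floor
draw_carrier_depths <- function(config, copies) {
  lo <- config$htf_band[1]; hi <- config$htf_band[2]
  dmin <- config$carrier_dp_mt_min
  # need cov_numt = dp_nu/2*K large enough that dp_mt >= dmin fits the band
  nu_min <- max(config$dp_nu_range[1], 2 * dmin * lo / (1 - lo) / copies)
  if (nu_min > config$dp_nu_range[2]) nu_min <- config$dp_nu_range[2]
  dp_nu <- round(stats::runif(1, nu_min, config$dp_nu_range[2]))
  cov <- dp_nu / 2 * copies
  mt_lo <- max(dmin, cov * (1 - hi) / hi)
  mt_hi <- min(config$dp_mt_range[2], cov * (1 - lo) / lo)
  if (mt_hi < mt_lo) mt_hi <- mt_lo
  dp_mt <- round(stats::runif(1, mt_lo, mt_hi))
  list(dp_nu = dp_nu, dp_mt = dp_mt, cov_numt = cov,
       htf = htf(dp_nu, dp_mt, copies))
}

#' Simulate one trio with optional planted mega-NUMT
#'
#' Maternal mtDNA transmission is exact: the child's true haplotype is
#' the mother's. Father and mother haplotypes differ at a
#' regime-dependent number of sites. When the father carries a planted
#' NUMT, every site where the NUMT source sequence differs from a
#' carrier's own mtDNA appears in that carrier's callset at expected
#' allele fraction `htf(dp_nu, dp_mt, K)`, with read counts drawn
#' binomially and strands split 50/50.
#'
#' @param config A [sim_config].
#' @param refs From [make_references()].
#' @param trio_id Identifier.
#' @param planted Optional `planted_numt` carried by the father; the
#'   trio's haplotype sites are drawn clear of the NUMT source sites.
#' @param transmitted Did the father transmit the NUMT to the child?
#' @param regime `"same"` or `"different"` parental haplogroup
#'   background.
#' @param seed Optional seed for standalone use.
#' @return List with `trio` (an [mt_trio] of raw sampled callsets),
#'   `depths`, `expected` per-member site tables, and `truth`
#'   (expected classification and planted metadata).
#' @export
simulate_trio <- function(config, refs, trio_id = "trio1", planted = NULL,
                          transmitted = FALSE, regime = c("same", "different"),
                          seed = NULL) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  carrier <- !is.null(planted)
  exclude <- if (carrier) planted$source_sites$pos else integer()

  n_shared <- sample(5:15, 1)
  shared <- draw_sites(n_shared, refs$mt, exclude = exclude)
  drange <- config$haplogroup_divergence[[regime]]
  d <- sample(seq(drange[1], drange[2]), 1)
  n_pf <- stats::rbinom(1, d, 0.5)
  if (carrier && transmitted) {
    # keep the planted label unambiguous: candidate-intent (same
    # background) trios leave at most one father-private homoplasmy
    # outside the NUMT; excluded-intent (different background) trios
    # carry at least five, placed outside the inserted fragments
    n_pf <- if (regime == "same") min(n_pf, 1L) else max(n_pf, 5L)
  }
  n_pm <- max(d - n_pf, 0L)
  pf_region <- if (carrier && transmitted && regime == "different") {
    setdiff(seq_len(MT_GENOME_LENGTH), planted$mt_positions)
  } else NULL
  priv_f <- draw_sites(n_pf, refs$mt, exclude = c(exclude, shared$pos),
                       region = pf_region)
  priv_m <- draw_sites(n_pm, refs$mt,
                       exclude = c(exclude, shared$pos, priv_f$pos))
  hap_f <- rbind(shared, priv_f)
  hap_m <- rbind(shared, priv_m)

  if (carrier) {
    K <- planted$copies
    df <- draw_carrier_depths(config, K)
    dc <- if (transmitted) draw_carrier_depths(config, K) else
      list(dp_nu = round(stats::runif(1, config$dp_nu_range[1],
                                      config$dp_nu_range[2])),
           dp_mt = round(stats::runif(1, config$carrier_dp_mt_min,
                                      config$dp_mt_range[2])),
           cov_numt = 0, htf = 0)
    dm_mt <- round(stats::runif(1, config$carrier_dp_mt_min,
                                config$dp_mt_range[2]))
  } else {
    draw_nu <- function() round(stats::runif(1, config$dp_nu_range[1],
                                             config$dp_nu_range[2]))
    draw_mt <- function() round(stats::runif(1, config$dp_mt_range[1],
                                             config$dp_mt_range[2]))
    df <- list(dp_nu = draw_nu(), dp_mt = draw_mt(), cov_numt = 0, htf = 0)
    dc <- list(dp_nu = draw_nu(), dp_mt = draw_mt(), cov_numt = 0, htf = 0)
    dm_mt <- draw_mt()
  }
  dm <- list(dp_nu = round(stats::runif(1, config$dp_nu_range[1],
                                        config$dp_nu_range[2])),
             dp_mt = dm_mt)

  src <- if (carrier) planted$source_sites else NULL
  mtp <- if (carrier) planted$mt_positions else NULL
  exp_f <- expected_site_table(hap_f, df$dp_mt, src, mtp, df$cov_numt)
  exp_m <- expected_site_table(hap_m, dm$dp_mt)
  exp_c <- expected_site_table(hap_m, dc$dp_mt,
                               if (carrier && transmitted) src else NULL,
                               if (carrier && transmitted) mtp else NULL,
                               dc$cov_numt)

  fid <- paste0(trio_id, "_F"); mid <- paste0(trio_id, "_M")
  cid <- paste0(trio_id, "_C")
  trio <- mt_trio(trio_id,
                  father = sample_callset(fid, exp_f, df$dp_mt, config,
                                          refs$mt),
                  mother = sample_callset(mid, exp_m, dm$dp_mt, config,
                                          refs$mt),
                  child = sample_callset(cid, exp_c, dc$dp_mt, config,
                                         refs$mt))

  truth <- c(expected_classification(exp_f, exp_m, exp_c, transmitted),
             list(trio_id = trio_id, regime = regime,
                  numt_id = if (carrier) planted$numt_id else NA_character_,
                  transmitted = carrier && transmitted,
                  copies = if (carrier) planted$copies else NA_integer_,
                  htf_father = df$htf, htf_child = dc$htf,
                  qc_pass = min(df$dp_mt, dm$dp_mt, dc$dp_mt) >= 500,
                  father_het_expected = sum(exp_f$exp_af > 0.01 &
                                              exp_f$exp_af <= 0.95)))
  list(trio = trio,
       depths = list(father = df, mother = dm, child = dc),
       expected = list(father = exp_f, mother = exp_m, child = exp_c),
       truth = truth)
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Generates `n_trios` independent trios, plants mega-NUMTs in a chosen
#' number of fathers (the first two carriers share one NUMT when there
#' are at least two, emulating recurrent insertions), transmits each
#' planted NUMT autosomally, and emits aligned-read evidence for every
#' member of a carrier family. All randomness flows from `config$seed`;
#' the same configuration reproduces the cohort bit for bit.
#'
#' Among transmitting carriers, parental backgrounds alternate
#' same/same/different/... so the cohort contains both
#' mixed-haplotype-candidate trios and trios excluded for missing
#' paternal homoplasmies, each with known labels.
#'
#' @param config A [sim_config].
#' @return A list of class `sim_cohort`: `config`, `refs`, `trios`
#'   (list of [mt_trio]), `samples` (per-sample metadata: depths, sex
#'   chromosome depths, nuclear het allele fractions), `reads` (named
#'   list of [aligned_reads] for carrier-family members), `pedigree`,
#'   `numts` (planted objects) and `truth` (per-trio expected labels).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  refs <- make_references(nuclear_length = config$nuclear_length,
                          nuclear_contig = config$nuclear_contig)
  n <- config$n_trios
  n_carrier <- if (!is.null(config$n_numt_fathers)) {
    min(config$n_numt_fathers, n)
  } else {
    stats::rbinom(1, n, config$p_father_numt)
  }
  carrier_idx <- if (n_carrier) sort(sample(n, n_carrier)) else integer()
  transmit <- if (!is.null(config$n_transmitting)) {
    k <- min(config$n_transmitting, n_carrier)
    ix <- rep(FALSE, n_carrier); ix[seq_len(k)] <- TRUE; ix
  } else {
    stats::runif(n_carrier) < config$p_transmit
  }
  # alternate parental-background regimes over transmitting carriers
  regimes <- character(n_carrier)
  regimes[transmit] <- rep(c("same", "same", "different"),
                           length.out = sum(transmit))
  regimes[!transmit] <- sample(c("same", "different"), sum(!transmit),
                               replace = TRUE)

  # planted NUMT loci, well separated on the nuclear contig
  n_distinct <- max(0L, n_carrier - if (n_carrier >= 2) 1L else 0L)
  slots <- if (n_distinct) {
    round(seq(15000, config$nuclear_length - 15000,
              length.out = max(n_distinct, 2))[seq_len(n_distinct)] +
            stats::runif(n_distinct, -2000, 2000))
  } else numeric()

  trios <- vector("list", n)
  truth <- vector("list", n)
  reads <- list()
  samples <- list()
  numts <- list()          # distinct planted NUMTs, named by numt_id
  carriers_of <- list()    # numt_id -> carrier sample ids
  carrier_ptr <- 0L
  for (i in seq_len(n)) {
    tid <- sprintf("trio%04d", i)
    planted <- NULL; trans <- FALSE
    if (i %in% carrier_idx) {
      carrier_ptr <- carrier_ptr + 1L
      trans <- transmit[carrier_ptr]
      regime <- regimes[carrier_ptr]
      if (carrier_ptr == 2L && length(numts) >= 1L) {
        planted <- numts[[1L]]       # recurrent NUMT shared with family 1
      } else {
        # found a new NUMT: its source haplotype is an independent mtDNA
        # lineage plus NUMT-private divergent sites inside the fragments
        slot_i <- length(numts) + 1L
        founder_sites <- draw_sites(sample(5:15, 1), refs$mt)
        planted <- plant_numt(config, refs,
                              numt_id = sprintf("numt%02d", slot_i),
                              insertion_pos = slots[slot_i],
                              founder_sites = founder_sites)
        numts[[planted$numt_id]] <- planted
      }
    } else {
      regime <- sample(c("same", "different"), 1,
                       prob = c(1 - config$p_different_haplogroup,
                                config$p_different_haplogroup))
    }
    st <- simulate_trio(config, refs, trio_id = tid, planted = planted,
                        transmitted = trans, regime = regime)
    trios[[i]] <- st$trio
    truth[[i]] <- st$truth
    dep <- st$depths
    for (role in c("father", "mother", "child")) {
      sid <- st$trio[[role]]$sample_id
      dn <- dep[[role]]$dp_nu
      sex <- if (role == "father") "male" else if (role == "mother")
        "female" else sample(c("male", "female"), 1)
      samples[[sid]] <- data.frame(
        sample_id = sid, trio_id = tid, role = role, dp_nu = dn,
        dp_mt = dep[[role]]$dp_mt,
        depth_x = if (sex == "female") dn else dn / 2,
        depth_y = if (sex == "female") dn / 100 else dn / 2,
        sex = sex, stringsAsFactors = FALSE)
    }
    if (!is.null(planted)) {
      fid <- st$trio$father$sample_id
      cid <- st$trio$child$sample_id
      mid <- st$trio$mother$sample_id
      reads[[fid]] <- simulate_numt_reads(planted, refs, dep$father$dp_nu,
                                          fid, config)
      reads[[cid]] <- if (trans) {
        simulate_numt_reads(planted, refs, dep$child$dp_nu, cid, config)
      } else {
        simulate_background_reads(config$nuclear_contig,
                                  refs$nuclear[[1]], planted$insertion_pos,
                                  dep$child$dp_nu, cid, config)
      }
      reads[[mid]] <- simulate_background_reads(
        config$nuclear_contig, refs$nuclear[[1]], planted$insertion_pos,
        dep$mother$dp_nu, mid, config)
      truth[[i]]$insertion_pos <- planted$insertion_pos
      carriers_of[[planted$numt_id]] <- unique(c(
        carriers_of[[planted$numt_id]], fid, if (trans) cid))
    }
    if (config$noise_discordant > 0) {
      for (role in c("father", "mother", "child")) {
        sid <- st$trio[[role]]$sample_id
        nz <- simulate_noise_reads(config$nuclear_contig,
                                   config$nuclear_length,
                                   config$noise_discordant, sid, config)
        reads[[sid]] <- if (is.null(reads[[sid]])) nz else
          rbind(reads[[sid]], nz)
      }
    }
  }
  for (nid in names(numts)) {
    attr(numts[[nid]], "carriers") <- carriers_of[[nid]]
  }
  pedigree <- data.frame(
    trio_id = vapply(trios, function(t) t$trio_id, character(1)),
    father_id = vapply(trios, function(t) t$father$sample_id, character(1)),
    mother_id = vapply(trios, function(t) t$mother$sample_id, character(1)),
    child_id = vapply(trios, function(t) t$child$sample_id, character(1)),
    stringsAsFactors = FALSE)
  structure(list(config = config, refs = refs, trios = trios,
                 samples = do.call(rbind, unname(samples)),
                 reads = reads, pedigree = pedigree, numts = numts,
                 truth = truth),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  st <- vapply(x$truth, function(t) t$status, character(1))
  cat("Synthetic cohort:", length(x$trios), "trios,",
      length(x$numts), "planted NUMT locus/loci,",
      sum(vapply(x$truth, function(t) isTRUE(t$transmitted), logical(1))),
      "transmitted\n")
  print(table(st))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Persists pedigree and callset TSVs, per-sample SAM files, reference
#' FASTA and a truth JSON (planted objects, expected labels, config
#' echo).
#'
#' @param cohort From [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$pedigree, file.path(dir, "pedigree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  callsets <- unlist(lapply(cohort$trios, function(t)
    c(list(t$father, t$mother, t$child), t$extra_sibs)), recursive = FALSE)
  write_mt_tsv(callsets, file.path(dir, "mt_calls.tsv"))
  write_fasta(cohort$refs, file.path(dir, "references.fasta"))
  lens <- c(vapply(cohort$refs$nuclear, nchar, integer(1)),
            MT = nchar(cohort$refs$mt))
  for (sid in names(cohort$reads)) {
    write_sam(cohort$reads[[sid]], file.path(dir, paste0(sid, ".sam")), lens)
  }
  truth <- list(
    config = cohort$config[setdiff(names(cohort$config),
                                   "haplogroup_divergence")],
    trios = lapply(cohort$truth, function(t)
      t[c("trio_id", "status", "regime", "numt_id", "transmitted",
          "copies", "htf_father", "htf_child", "qc_pass")]),
    numts = lapply(cohort$numts, function(nm) list(
      numt_id = nm$numt_id, nuclear_contig = nm$nuclear_contig,
      insertion_pos = nm$insertion_pos, copies = nm$copies,
      fragments = nm$fragments, carriers = attr(nm, "carriers"))))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
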