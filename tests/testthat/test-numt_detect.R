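disc_pair <- function(id, nuc_pos, mt_pos, contig = "chr13",
                      nuc_strand = "+", mt_strand = "-", mapq = 60L) {
  aligned_reads(read_id = c(id, id), contig = c(contig, "MT"),
                pos = c(nuc_pos, mt_pos), strand = c(nuc_strand, mt_strand),
                mapq = mapq, cigar = "150M", seq = NA_character_,
                mate_contig = c("MT", contig), mate_pos = c(mt_pos, nuc_pos),
                mate_strand = c(mt_strand, nuc_strand))
}

test_that("discordant extraction keeps nuclear-MT pairs above mapq 20", {
  r <- rbind(disc_pair("p1", 1000L, 5000L),
             disc_pair("p2", 1200L, 5100L, mapq = 19L),
             aligned_reads(read_id = c("p3", "p3"), contig = "chr13",
                           pos = c(1000L, 1300L), strand = c("+", "-"),
                           mapq = 60L, cigar = "150M",
                           mate_contig = "chr13",
                           mate_pos = c(1300L, 1000L),
                           mate_strand = c("-", "+")))
  out <- extract_discordant_pairs(r)
  expect_equal(out$read_id, "p1")
  expect_equal(out$nuclear_contig, "chr13")
  expect_equal(out$mt_pos, 5000L)
})

test_that("unpaired read ids are skipped with a warning", {
  r <- rbind(disc_pair("p1", 1000L, 5000L),
             aligned_reads("orphan", "chr13", 500L, "+", 60L, "150M",
                           mate_contig = "MT", mate_pos = 1L,
                           mate_strand = "+"))
  expect_warning(out <- extract_discordant_pairs(r), "two paired ends")
  expect_equal(out$read_id, "p1")
})

test_that("discordant clustering needs 5 pairs of one orientation", {
  mk <- function(n, base = 1000L, nuc_strand = "+") {
    do.call(rbind, lapply(seq_len(n), function(i)
      disc_pair(paste0(nuc_strand, base, "_", i), base + i * 50L,
                5000L + i * 10L, nuc_strand = nuc_strand)))
  }
  p5 <- extract_discordant_pairs(mk(5))
  cl <- cluster_discordant(p5)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_pairs, 5L)
  expect_equal(cl$mt_start, 5010L)
  expect_equal(cl$mt_end, 5050L)
  # four pairs: below threshold
  expect_equal(nrow(cluster_discordant(extract_discordant_pairs(mk(4)))), 0L)
  # 3 + 2 split over two orientations never clusters
  mixed <- extract_discordant_pairs(rbind(mk(3), mk(2, nuc_strand = "-")))
  expect_equal(nrow(cluster_discordant(mixed)), 0L)
  # a >500 bp gap splits the chain below threshold
  far <- extract_discordant_pairs(rbind(mk(3), mk(3, base = 10000L)))
  expect_equal(nrow(cluster_discordant(far)), 0L)
  far2 <- cluster_discordant(extract_discordant_pairs(
    rbind(mk(5), mk(5, base = 10000L))))
  expect_equal(nrow(far2), 2L)
})

test_that("orientation partitioning matches brute-force enumeration", {
  # every 2-orientation split of 9 pairs: a cluster forms only for the
  # orientation(s) holding >= 5 chainable pairs
  for (k in 0:9) {
    reads <- rbind(
      if (k > 0) do.call(rbind, lapply(seq_len(k), function(i)
        disc_pair(paste0("a", i), 1000L + i * 10L, 5000L))),
      if (k < 9) do.call(rbind, lapply(seq_len(9 - k), function(i)
        disc_pair(paste0("b", i), 1000L + i * 10L, 5000L,
                  nuc_strand = "-"))))
    cl <- cluster_discordant(extract_discordant_pairs(reads))
    expect_equal(nrow(cl), sum(c(k, 9 - k) >= 5L))
  }
})

test_that("split-read search respects the window around clusters", {
  cl <- data.frame(nuclear_contig = "chr13", start = 5000L, end = 5200L,
                   nuclear_strand = "+", mt_strand = "-",
                   mt_start = 100L, mt_end = 700L, n_pairs = 5L)
  mkread <- function(id, pos, cigar, contig = "chr13") {
    aligned_reads(id, contig, pos, "+", 60L, cigar, seq = strrep("A", 150))
  }
  r <- rbind(mkread("near", 4400L, "80M70S"),      # 600 bp from edge
             mkread("far", 6701L, "80M70S"),       # 1501 bp away
             mkread("unclipped", 5100L, "150M"),
             mkread("short_clip", 5100L, "140M10S"),
             mkread("on_mt", 3000L, "70M80S", contig = "MT"))
  out <- find_split_reads(r, cl)
  expect_setequal(out$read_id, c("near", "on_mt"))
})

test_that("split realignment recovers constructed junctions", {
  set.seed(21)
  refs <- make_references(nuclear_length = 4000)
  nuc <- refs$nuclear$chrN
  tg <- make_split_targets(list(chrN = list(seq = nuc, origin = 0L)),
                           refs$mt)
  # nu-mt: 75 nuclear bases then 75 mt bases
  read <- paste0(substr(nuc, 1926, 2000), substr(refs$mt, 7001, 7075))
  rs <- realign_split(read, tg)
  # micro-homology at the junction can shift the breakpoint by a few
  # bases without changing the alignment; allow the clustering tolerance
  expect_equal(rs$side_a$contig, "chrN")
  expect_equal(rs$side_a$strand, "+")
  expect_lte(abs(rs$side_a$pos - 2000L), 5L)
  expect_equal(rs$side_b$contig, "MT")
  expect_equal(rs$side_b$strand, "+")
  expect_lte(abs(rs$side_b$pos - 7001L), 5L)
  # the two sides shift together: total aligned bases stay the read length
  expect_equal((rs$side_a$pos - 2000L), (rs$side_b$pos - 7001L))
  # read entirely from one reference: no split
  expect_null(realign_split(substr(nuc, 501, 650), tg))
  # mt-mt with the second piece on the reverse strand
  rc <- meganumt:::revcomp_chr(substr(refs$mt, 12715, 12864))
  read2 <- paste0(substr(refs$mt, 14903, 14977), substr(rc, 1, 75))
  rs2 <- realign_split(read2, tg)
  expect_equal(rs2$side_a$contig, "MT")
  expect_equal(rs2$side_a$strand, "+")
  expect_lte(abs(rs2$side_a$pos - 14977L), 5L)
  expect_equal(rs2$side_b$contig, "MT")
  expect_equal(rs2$side_b$strand, "-")
  expect_lte(abs(rs2$side_b$pos - 12864L), 5L)
  # junction across the circular origin is recovered
  read3 <- paste0(substr(nuc, 926, 1000),
                  substr(paste0(refs$mt, refs$mt), 16540, 16614))
  rs3 <- realign_split(read3, tg)
  expect_lte(abs(rs3$side_b$pos - 16540L), 5L)
  expect_lte(abs(rs3$side_a$pos - 1000L), 5L)
})

test_that("split realignment honours piece length and identity floors", {
  set.seed(22)
  refs <- make_references(nuclear_length = 3000)
  tg <- make_split_targets(list(chrN = list(seq = refs$nuclear$chrN,
                                            origin = 0L)), refs$mt)
  # a 10 bp second piece cannot be reported (min_piece 20)
  read <- paste0(substr(refs$nuclear$chrN, 861, 1000),
                 substr(refs$mt, 5001, 5010))
  rs <- realign_split(read, tg)
  if (!is.null(rs)) expect_gte(rs$breakpoint, 20L)
  # heavy mismatching on one side suppresses the call
  noisy <- paste0(substr(refs$nuclear$chrN, 926, 1000),
                  meganumt:::random_dna(75))
  expect_null(realign_split(noisy, tg))
  expect_error(realign_split(strrep("A", 150),
                             make_split_targets(
                               list(x = list(seq = "ACGT", origin = 0L)),
                               NULL)),
               "shorter than the read")
})

test_that("junction calling groups splits within +/-5 bp on both sides", {
  mk <- function(pa, pb, ca = "chr3", cb = "MT") {
    list(side_a = list(contig = ca, pos = pa, strand = "+"),
         side_b = list(contig = cb, pos = pb, strand = "+"))
  }
  jx <- call_junctions(list(mk(56128996L, 11126L), mk(56128998L, 11128L),
                            mk(56128994L, 11124L)))
  expect_equal(nrow(jx), 1L)
  expect_equal(jx$kind, "nu_mt")
  expect_equal(jx$split_support, 3L)
  expect_equal(jx$pos_a, 56128996L)
  # 2 mt-mt reads at one junction: support 2, which is not mega evidence
  jx2 <- call_junctions(list(mk(14977L, 12864L, ca = "MT"),
                             mk(14977L, 12864L, ca = "MT")))
  expect_equal(jx2$kind, "mt_mt")
  expect_equal(jx2$split_support, 2L)
  # beyond tolerance on one side -> two junctions
  jx3 <- call_junctions(list(mk(100L, 200L), mk(100L, 230L)))
  expect_equal(nrow(jx3), 2L)
  expect_equal(nrow(call_junctions(list())), 0L)
})

test_that("opposite-orientation reads of one junction are canonicalised", {
  a <- list(side_a = list(contig = "chr3", pos = 500L, strand = "+"),
            side_b = list(contig = "MT", pos = 11126L, strand = "+"))
  flipped <- list(side_a = list(contig = "MT", pos = 11126L, strand = "-"),
                  side_b = list(contig = "chr3", pos = 500L, strand = "-"))
  jx <- call_junctions(list(a, flipped))
  expect_equal(nrow(jx), 1L)
  expect_equal(jx$split_support, 2L)
  expect_equal(jx$contig_a, "chr3")
})

test_that("cohort grouping merges on both nuclear and mt axes", {
  mkcall <- function(sid, nuc = c(1000L, 1400L), mt = c(5000L, 6000L)) {
    list(sample_id = sid, nuclear_contig = "chr5",
         nuclear_interval = nuc, mt_interval = mt,
         junctions = NULL, n_discordant = 8L, n_split = 3L)
  }
  # 800 bp apart on the nuclear axis, overlapping mt -> one call
  g1 <- group_numts(list(mkcall("s1"), mkcall("s2", nuc = c(2200L, 2400L))),
                    cohort_size = 33105)
  expect_length(g1, 1L)
  expect_setequal(g1[[1]]$carriers, c("s1", "s2"))
  expect_equal(g1[[1]]$cohort_frequency, 2 / 33105)
  # same nuclear distance but mt intervals 5 kb apart -> two calls
  g2 <- group_numts(list(mkcall("s1"), mkcall("s2", nuc = c(2200L, 2400L),
                                               mt = c(11000L, 12000L))),
                    cohort_size = 33105)
  expect_length(g2, 2L)
  # six carriers of an identical call: frequency 6/33105
  g3 <- group_numts(lapply(paste0("s", 1:6), mkcall), cohort_size = 33105)
  expect_length(g3, 1L)
  expect_equal(g3[[1]]$cohort_frequency, 6 / 33105)
})

test_that("grouping partitions its input and is order-invariant", {
  set.seed(9)
  calls <- lapply(1:12, function(i) {
    list(sample_id = paste0("s", i), nuclear_contig = "chr5",
         nuclear_interval = c(1000L, 1200L) + (i %% 3) * 40000L,
         mt_interval = c(2000L, 3000L),
         junctions = NULL, n_discordant = 6L, n_split = 1L)
  })
  g <- group_numts(calls, cohort_size = 100)
  expect_equal(sum(lengths(lapply(g, function(x) x$carriers))), 12L)
  gp <- group_numts(calls[sample(12)], cohort_size = 100)
  key <- function(gr) sort(vapply(gr, function(x)
    paste(sort(x$carriers), collapse = ","), character(1)))
  expect_equal(key(g), key(gp))
})

test_that("mixed reference builds refuse to group", {
  a <- list(sample_id = "s1", nuclear_contig = "chr5",
            nuclear_interval = c(1L, 2L), mt_interval = c(1L, 2L),
            junctions = NULL, n_discordant = 5L, n_split = 0L,
            build = "GRCh38")
  b <- a; b$sample_id <- "s2"; b$build <- "GRCh37"
  expect_error(group_numts(list(a, b), cohort_size = 10), "builds")
})

test_that("mega evidence requires an mt-mt junction with >2 split reads", {
  base <- list(sample_id = "s1", nuclear_contig = "chr5",
               nuclear_interval = c(1000L, 1200L),
               mt_interval = c(2000L, 3000L),
               n_discordant = 6L, n_split = 3L)
  jx <- data.frame(kind = "mt_mt", contig_a = "MT", pos_a = 100L,
                   strand_a = "+", contig_b = "MT", pos_b = 900L,
                   strand_b = "+", split_support = 3L,
                   stringsAsFactors = FALSE)
  with3 <- c(base, list(junctions = jx))
  g <- group_numts(list(with3), cohort_size = 10)
  expect_true(g[[1]]$mega_evidence)
  jx$split_support <- 2L
  with2 <- c(base, list(junctions = jx))
  expect_false(group_numts(list(with2), cohort_size = 10)[[1]]$mega_evidence)
})

test_that("mt span is the linear distance between outermost breakpoints", {
  expect_equal(mt_span(mk_numt_call(mt_pos = c(1641L, 13441L))), 11800L)
  expect_equal(mt_span(mk_numt_call(mt_pos = c(100L, 550L))), 450L)
  expect_equal(mt_span(mk_numt_call(mt_pos = c(7000L, 7000L))), 0L)
  expect_error(mt_span(mk_numt_call(mt_pos = 500L, mt_strand = "+")),
               "fewer than two")
})

test_that("SAM round trip preserves alignment records", {
  set.seed(30)
  r <- rbind(disc_pair("p1", 1000L, 5000L),
             aligned_reads("sp1", "MT", 4000L, "-", 55L, "60S90M",
                           seq = meganumt:::random_dna(150)))
  path <- tempfile(fileext = ".sam")
  write_sam(r, path, c(chr13 = 100000L, MT = 16569L))
  back <- read_sam(path)
  ord <- function(x) {
    x <- x[order(x$read_id, x$contig, x$pos), ]
    rownames(x) <- NULL
    x
  }
  cols <- c("read_id", "contig", "pos", "strand", "mapq", "cigar", "seq",
            "mate_contig", "mate_pos", "mate_strand")
  expect_equal(ord(back)[, cols], ord(r)[, cols])
})
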