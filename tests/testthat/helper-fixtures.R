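# Compact builders for unit-test objects.

# variant table from parallel vectors; alt counts derived from af
mkvars <- function(pos, af, depth = 1000L, ref = "A", alt = "G",
                   split = 0.5) {
  n <- length(pos)
  depth <- rep_len(depth, n)
  alt_n <- round(rep_len(af, n) * depth)
  alt_fwd <- round(alt_n * split)
  ref_n <- depth - alt_n
  mt_variants(pos = pos, ref = rep_len(ref, n), alt = rep_len(alt, n),
              depth = depth, alt_fwd = alt_fwd, alt_rev = alt_n - alt_fwd,
              ref_fwd = floor(ref_n / 2), ref_rev = ceiling(ref_n / 2))
}

# callset with variants given as "pos:af" pairs
mkcs <- function(id, pos = integer(), af = numeric(), depth = 1000L,
                 mean_depth = 1000) {
  mt_callset(id, mkvars(pos, af, depth), mean_mt_depth = mean_depth)
}

mktrio <- function(id = "t1", father, mother, child) {
  mt_trio(id, father, mother, child)
}

# minimal cohort-level NUMT call
mk_numt_call <- function(numt_id = "n1", carriers = "S1",
                         cohort_frequency = 1e-4,
                         mt_pos = c(1641L, 13441L),
                         mt_strand = c("+", "-"),
                         mega = FALSE, contig = "chr1",
                         interval = c(1000L, 2000L)) {
  structure(list(numt_id = numt_id, nuclear_contig = contig,
                 nuclear_interval = interval,
                 mt_interval = range(mt_pos),
                 junctions = NULL,
                 mt_breakpoints = data.frame(pos = mt_pos,
                                             strand = mt_strand,
                                             stringsAsFactors = FALSE),
                 n_discordant = 10L, n_split = 5L, carriers = carriers,
                 cohort_frequency = cohort_frequency,
                 mega_evidence = mega),
            class = "numt_call")
}
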