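test_that("reference generation is deterministic with correct geometry", {
  r1 <- make_references(seed = 42, nuclear_length = 5000)
  r2 <- make_references(seed = 42, nuclear_length = 5000)
  expect_identical(r1, r2)
  expect_equal(nchar(r1$mt), 16569L)
  expect_equal(nchar(r1$nuclear$chrN), 5000L)
  gc <- function(s) {
    tab <- table(strsplit(s, NULL)[[1]])
    sum(tab[c("G", "C")]) / sum(tab)
  }
  expect_gt(gc(r1$mt), 0.3); expect_lt(gc(r1$mt), 0.7)
  expect_gt(gc(r1$nuclear$chrN), 0.3); expect_lt(gc(r1$nuclear$chrN), 0.7)
})

test_that("cohort simulation is bit-reproducible from its seed", {
  cfg <- sim_config(n_trios = 6, n_numt_fathers = 1, n_transmitting = 1,
                    seed = 77)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- sim_config(n_trios = 6, n_numt_fathers = 1, n_transmitting = 1,
                     seed = 78)
  expect_false(identical(simulate_cohort(cfg)$refs,
                         simulate_cohort(cfg2)$refs))
})

test_that("an empty cohort still writes a valid bundle", {
  cfg <- sim_config(n_trios = 0, seed = 1)
  coh <- simulate_cohort(cfg)
  expect_length(coh$trios, 0L)
  d <- tempfile()
  write_cohort(coh, d)
  expect_true(all(file.exists(file.path(
    d, c("pedigree.tsv", "mt_calls.tsv", "references.fasta",
         "truth.json")))))
  expect_equal(nrow(read_pedigree(file.path(d, "pedigree.tsv"))), 0L)
})

test_that("children inherit the maternal mtDNA haplotype exactly", {
  cfg <- sim_config(n_trios = 8, n_numt_fathers = 0, seed = 13)
  coh <- simulate_cohort(cfg)
  refs <- coh$refs
  set.seed(99)
  for (i in seq_along(coh$trios)) {
    st <- simulate_trio(cfg, refs, trio_id = "t", regime = "same")
    key <- function(tab) paste0(tab$pos, ":", tab$alt)
    expect_setequal(key(st$expected$child), key(st$expected$mother))
    # every haplotype allele is sampled at exact homoplasmy
    ch <- st$trio$child
    hap <- key(st$expected$child)
    found <- variant_key(ch) %in% hap
    expect_true(all(ch$variants$af[found] == 1))
  }
})

test_that("planted NUMT alleles appear at the modelled haplotype fraction", {
  cfg <- sim_config(seed = 1)
  set.seed(55)
  refs <- make_references(nuclear_length = 20000)
  founder <- meganumt:::draw_sites(8, refs$mt)
  pn <- plant_numt(cfg, refs, "n1", 10000L, founder)
  st <- simulate_trio(cfg, refs, "t", planted = pn, transmitted = TRUE,
                      regime = "same")
  h <- st$truth$htf_father
  expect_gte(h, cfg$htf_band[1]); expect_lte(h, cfg$htf_band[2])
  keys <- paste0(pn$numt_sites$pos, ":", pn$numt_sites$alt)
  v <- st$trio$father$variants
  ix <- match(keys, variant_key(st$trio$father))
  expect_true(all(!is.na(ix)))
  # chi-square goodness of fit of alt counts against Binomial(depth, htf)
  alt <- v$alt_fwd[ix] + v$alt_rev[ix]
  dp <- v$depth[ix]
  x2 <- sum((alt - dp * h)^2 / (dp * h * (1 - h)))
  expect_gt(pchisq(x2, df = length(ix), lower.tail = FALSE), 0.01)
  # transmitted child shows the same alleles at its own expected fraction
  cx <- match(keys, variant_key(st$trio$child))
  expect_true(all(!is.na(cx)))
  hc <- st$truth$htf_child
  expect_lt(abs(mean(st$trio$child$variants$af[cx]) - hc), 5 * sqrt(
    hc * (1 - hc) / (length(cx) * min(st$trio$child$variants$depth[cx]))))
})

test_that("autosomal transmission frequency tracks p_transmit", {
  cfg <- sim_config(n_trios = 60, p_father_numt = 1, seed = 91,
                    background_het_rate = 0)
  coh <- simulate_cohort(cfg)
  trans <- vapply(coh$truth, function(t) isTRUE(t$transmitted), logical(1))
  ci <- clopper_pearson_ci(sum(trans), length(trans))
  expect_gte(0.5, ci[["low"]]); expect_lte(0.5, ci[["high"]])
})

test_that("non-carrier read sets contain no discordant nuclear-mt pairs", {
  cfg <- sim_config(n_trios = 3, n_numt_fathers = 1, n_transmitting = 0,
                    seed = 31)
  coh <- simulate_cohort(cfg)
  carrier_fid <- coh$pedigree$father_id[
    vapply(coh$truth, function(t) !is.na(t$numt_id), logical(1))]
  for (sid in names(coh$reads)) {
    pairs <- extract_discordant_pairs(coh$reads[[sid]])
    if (sid %in% carrier_fid) {
      expect_gt(nrow(pairs), 0)
    } else {
      expect_equal(nrow(pairs), 0L)
      expect_length(detect_numts_sample(coh$reads[[sid]], sid,
                                        coh$refs$nuclear, coh$refs$mt), 0L)
    }
  }
})

test_that("a single-copy single-fragment NUMT emits no mt-mt junctions", {
  refs <- make_references(seed = 3, nuclear_length = 20000)
  pn <- structure(list(
    numt_id = "n1", nuclear_contig = "chrN", insertion_pos = 10000L,
    fragments = data.frame(mt_start = 2000L, mt_end = 4000L, strand = "+",
                           stringsAsFactors = FALSE),
    copies = 1L,
    numt_sites = data.frame(pos = integer(), ref = character(),
                            alt = character()),
    source_sites = data.frame(pos = integer(), ref = character(),
                              alt = character()),
    mt_positions = 2000:4000), class = "planted_numt")
  jt <- numt_junction_truth(pn)
  expect_false(any(jt$kind == "mt_mt"))
  set.seed(6)
  rd <- simulate_numt_reads(pn, refs, 40, "s1", sim_config())
  expect_false(any(grepl("split3", rd$read_id)))
  # fragments outside the mtDNA coordinate space are invalid
  bad <- pn; bad$fragments$mt_end <- 20000L
  expect_error(simulate_numt_reads(bad, refs, 40, "s1", sim_config()),
               "outside mtDNA")
})

test_that("emitted junction reads realign to the planted breakpoints", {
  cfg <- sim_config(seed = 1)
  set.seed(207)
  refs <- make_references(nuclear_length = 30000)
  founder <- meganumt:::draw_sites(8, refs$mt)
  # insist on a two-fragment concatemer for an internal mt-mt junction
  repeat {
    pn <- plant_numt(cfg, refs, "n1", 15000L, founder)
    if (nrow(pn$fragments) == 2) break
  }
  rd <- simulate_numt_reads(pn, refs, 60, "s1", cfg)
  calls <- detect_numts_sample(rd, "s1", refs$nuclear, refs$mt)
  expect_length(calls, 1L)
  jx <- calls[[1]]$junctions
  truth <- numt_junction_truth(pn)
  # every truth junction with emitted reads is recovered within +/- 5 bp
  for (k in seq_len(nrow(truth))) {
    if (!any(grepl(paste0("split", k, "_"), rd$read_id))) next
    tp <- sort(c(truth$pos_a[k], truth$pos_b[k]))
    hit <- vapply(seq_len(nrow(jx)), function(j) {
      jp <- sort(c(jx$pos_a[j], jx$pos_b[j]))
      all(abs(jp - tp) <= 5L)
    }, logical(1))
    expect_true(any(hit))
  }
  # discordant support straddles the insertion point
  expect_gte(calls[[1]]$n_discordant, 5)
  expect_true(calls[[1]]$nuclear_interval[1] <= pn$insertion_pos + 300 &&
                calls[[1]]$nuclear_interval[2] >= pn$insertion_pos - 500)
})

test_that("planted NUMTs at 40x are recovered with high sensitivity", {
  cfg <- sim_config(seed = 1, max_split_per_junction = 5L)
  set.seed(808)
  refs <- make_references(nuclear_length = 30000)
  founder <- meganumt:::draw_sites(6, refs$mt)
  hits <- vapply(1:40, function(i) {
    pn <- plant_numt(cfg, refs, "n1", 15000L, founder)
    rd <- simulate_numt_reads(pn, refs, 40, "s1", cfg)
    length(detect_numts_sample(rd, "s1", refs$nuclear, refs$mt)) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
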