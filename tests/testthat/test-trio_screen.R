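test_that("informative variants require father AF > 5% and maternal absence", {
  f <- mkcs("f", pos = 100L, af = 0.30)
  m0 <- mkcs("m", mean_depth = 1000)
  expect_equal(informative_variants(f, m0), "100:G")
  # shared with mother at any retained AF -> non-informative
  m1 <- mkcs("m", pos = 100L, af = 0.02)
  expect_equal(informative_variants(f, m1), character())
  # father below the screening threshold
  f2 <- mkcs("f", pos = 100L, af = 0.04)
  expect_equal(informative_variants(f2, m0), character())
})

test_that("shared paternal variants require child AF > 5%", {
  f <- mkcs("f", pos = 100L, af = 0.20)
  m <- mkcs("m", mean_depth = 1000)
  expect_equal(
    shared_paternal_variants(mktrio("t", f, m, mkcs("c", 100L, 0.15))),
    "100:G")
  expect_equal(
    shared_paternal_variants(mktrio("t", f, m, mkcs("c", 100L, 0.04))),
    character())
  expect_equal(
    shared_paternal_variants(mktrio("t", f, m, mkcs("c"))),
    character())
})

test_that("trio classification follows the screen decision tree", {
  m <- mkcs("m", mean_depth = 1000)
  # father: 5 homoplasmies + 1 low-AF variant shared with child;
  # child detects 2 homoplasmies, 3 absent -> excluded
  f <- mkcs("f", pos = c(1:5 * 100L, 900L),
            af = c(rep(0.99, 5), 0.20))
  c1 <- mkcs("c", pos = c(100L, 200L, 900L), af = c(0.99, 0.99, 0.15))
  cl <- classify_trio(mktrio("t1", f, m, c1))
  expect_equal(cl$status, "excluded_homoplasmy_mismatch")
  expect_setequal(cl$missing_homoplasmies, c("300:G", "400:G", "500:G"))
  # homoplasmies detected in the child are shared too
  expect_setequal(cl$shared_paternal_variants$key,
                  c("100:G", "200:G", "900:G"))

  # classic mixed haplotype: 10 variants at 10-25% shared by the child
  pos <- seq(1000L, 1900L, by = 100L)
  f2 <- mkcs("f", pos = pos, af = seq(0.10, 0.25, length.out = 10))
  c2 <- mkcs("c", pos = pos, af = rep(0.15, 10))
  cl2 <- classify_trio(mktrio("t2", f2, m, c2))
  expect_equal(cl2$status, "mixed_haplotype_candidate")
  expect_length(cl2$informative_variants, 10L)

  # 2 missing homoplasmies < 3 stays a candidate
  f3 <- mkcs("f", pos = c(100L, 200L, 900L), af = c(0.99, 0.99, 0.20))
  c3 <- mkcs("c", pos = 900L, af = 0.15)
  expect_equal(classify_trio(mktrio("t3", f3, m, c3))$status,
               "mixed_haplotype_candidate")

  # no informative variants at all
  expect_equal(classify_trio(mktrio("t4", mkcs("f"), m, mkcs("c")))$status,
               "non_informative")
  # informative but nothing shared
  f5 <- mkcs("f", pos = 100L, af = 0.2)
  expect_equal(classify_trio(mktrio("t5", f5, m, mkcs("c")))$status,
               "informative_only")
})

test_that("classification is invariant to variant order", {
  m <- mkcs("m", mean_depth = 1000)
  pos <- c(100L, 200L, 300L, 900L)
  af <- c(0.99, 0.99, 0.99, 0.2)
  f <- mkcs("f", pos = pos, af = af)
  set.seed(3)
  perm <- sample(4)
  fp <- mkcs("f", pos = pos[perm], af = af[perm])
  ch <- mkcs("c", pos = 900L, af = 0.15)
  a <- classify_trio(mktrio("t", f, m, ch))
  b <- classify_trio(mktrio("t", fp, m, ch))
  expect_equal(a$status, b$status)
  expect_setequal(names(a$informative_variants),
                  names(b$informative_variants))
})

test_that("QC-failing trios error out of classification when checked", {
  f <- mkcs("f", pos = 100L, af = 0.2, mean_depth = 400)
  m <- mkcs("m", mean_depth = 1000)
  ch <- mkcs("c", mean_depth = 1000)
  expect_error(classify_trio(mktrio("t", f, m, ch), check_depth_qc = TRUE),
               "depth QC")
})

test_that("cohort screening tallies statuses and candidate fraction", {
  m <- mkcs("m", mean_depth = 1000)
  cand <- function(i) {
    mktrio(paste0("cand", i), mkcs("f", 900L, 0.2), m,
           mkcs("c", 900L, 0.15))
  }
  none <- mktrio("none", mkcs("f"), m, mkcs("c"))
  sc <- screen_cohort(c(lapply(1:3, cand), list(none)))
  expect_equal(sc$tally[["mixed_haplotype_candidate"]], 3L)
  expect_equal(sc$tally[["non_informative"]], 1L)
  expect_equal(sc$candidate_fraction_pct, 75)
  # empty cohort: empty tally, no error
  sc0 <- screen_cohort(list())
  expect_equal(sum(sc0$tally), 0L)
  expect_equal(sc0$candidate_fraction_pct, 0)
})

test_that("candidate fraction reproduces the 7-in-11035 arithmetic", {
  m <- mkcs("m", mean_depth = 1000)
  cand_trio <- mktrio("cand", mkcs("f", 900L, 0.2), m,
                      mkcs("c", 900L, 0.15))
  quiet_trio <- mktrio("quiet", mkcs("f"), m, mkcs("c"))
  trios <- c(
    lapply(1:7, function(i) { t <- cand_trio; t$trio_id <- paste0("c", i); t }),
    lapply(1:11028, function(i) quiet_trio))
  sc <- screen_cohort(trios)
  expect_equal(sc$n_trios, 11035L)
  expect_equal(sprintf("%.2f", sc$candidate_fraction_pct), "0.06")
})

test_that("the father screen needs >12 heteroplasmies and a rare large NUMT", {
  het13 <- mkcs("f1", pos = 1:13 * 50L, af = rep(0.1, 13))
  het12 <- mkcs("f2", pos = 1:12 * 50L, af = rep(0.1, 12))
  het20 <- mkcs("f3", pos = 1:20 * 50L, af = rep(0.1, 20))
  big_numt <- mk_numt_call(carriers = c("f1", "f2", "f3"),
                           cohort_frequency = 5e-4,
                           mt_pos = c(1000L, 1600L))
  small_numt <- mk_numt_call(numt_id = "n2", carriers = "f3",
                             cohort_frequency = 5e-4,
                             mt_pos = c(100L, 500L))
  common_numt <- mk_numt_call(numt_id = "n3", carriers = "f1",
                              cohort_frequency = 0.02,
                              mt_pos = c(1000L, 5000L))
  expect_equal(find_meganumt_fathers(list(het13, het12), list(big_numt)),
               "f1")
  expect_equal(find_meganumt_fathers(list(het20), list(small_numt)),
               character())
  expect_equal(find_meganumt_fathers(list(het13), list(common_numt)),
               character())
  # exactly at the het threshold is not enough (strictly more than 12)
  expect_equal(find_meganumt_fathers(list(het12), list(big_numt)),
               character())
})

test_that("heteroplasmy counting excludes homoplasmies and the 1% floor", {
  cs <- mkcs("s", pos = c(100L, 200L, 300L), af = c(0.5, 0.96, 0.011))
  expect_equal(count_heteroplasmies(cs), 2L)
})

test_that("the IQR fence matches a hand-rolled quantile oracle", {
  expect_equal(iqr_outlier_threshold(rep(3L, 10)), 3)
  x <- c(1L, 2L, 3L, 4L, 100L)
  expect_equal(iqr_outlier_threshold(x), oracle_iqr_fence(x))
  set.seed(17)
  for (i in 1:20) {
    y <- rpois(sample(4:50, 1), sample(1:20, 1))
    expect_equal(iqr_outlier_threshold(y), oracle_iqr_fence(y))
  }
  expect_error(iqr_outlier_threshold(1:3), "at least 4")
})

test_that("the IQR fence sits at or above the median of Poisson counts", {
  set.seed(0)
  x <- rpois(10000, 3)
  expect_gte(iqr_outlier_threshold(x), median(x))
})

test_that("pedigree round trip and trio assembly", {
  ped <- data.frame(trio_id = c("t1", "t2"),
                    father_id = c("f1", "f2"),
                    mother_id = c("m1", "m2"),
                    child_id = c("c1", "c2"),
                    sib_ids = c("s1", ""))
  path <- tempfile(fileext = ".tsv")
  write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_pedigree(path)
  expect_equal(back$sib_ids, list("s1", character()))
  pool <- lapply(c("f1", "m1", "c1", "s1", "f2", "m2", "c2"),
                 function(id) mkcs(id, mean_depth = 1000))
  names(pool) <- c("f1", "m1", "c1", "s1", "f2", "m2", "c2")
  trios <- build_trios(back, pool)
  expect_length(trios, 2L)
  expect_equal(trios[[1]]$father$sample_id, "f1")
  expect_length(trios[[1]]$extra_sibs, 1L)
  expect_error(build_trios(back, pool[-1]), "no callset")
})
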