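# Construct random 150-mers of three kinds (nu-mt junction, mt-mt
# junction, no junction) from a pair of small references, with a few
# random substitutions, for oracle-equivalence checks.
construct_split_read_set <- function(n, nuc_len = 1500L, mt_len = 2000L,
                                     read_len = 150L, max_mut = 3L,
                                     seed = 1L) {
  set.seed(seed)
  nuc <- meganumt:::random_dna(nuc_len)
  mt <- meganumt:::random_dna(mt_len)
  targets <- make_split_targets(list(chrA = list(seq = nuc, origin = 0L)),
                                mt, read_len = read_len)
  piece <- function(ref, start, len, rev = FALSE) {
    s <- substr(ref, start, start + len - 1L)
    if (rev) meganumt:::revcomp_chr(s) else s
  }
  mutate <- function(s, k) {
    if (k == 0) return(s)
    ch <- strsplit(s, NULL)[[1]]
    ix <- sample(length(ch), k)
    ch[ix] <- vapply(ch[ix], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }
  reads <- character(n)
  kinds <- sample(c("nu_mt", "mt_mt", "none"), n, replace = TRUE)
  for (i in seq_len(n)) {
    b <- sample(30:(read_len - 30), 1)
    k2 <- read_len - b
    r <- switch(
      kinds[i],
      nu_mt = paste0(
        piece(nuc, sample(nuc_len - b, 1), b),
        piece(mt, sample(mt_len - k2, 1), k2, rev = runif(1) < 0.5)),
      mt_mt = paste0(
        piece(mt, sample(mt_len - b, 1), b, rev = runif(1) < 0.5),
        piece(mt, sample(mt_len - k2, 1), k2, rev = runif(1) < 0.5)),
      none = piece(if (runif(1) < 0.5) nuc else mt,
                   sample(min(nuc_len, mt_len) - read_len, 1), read_len,
                   rev = runif(1) < 0.5))
    reads[i] <- mutate(r, sample(0:max_mut, 1))
  }
  list(reads = reads, kinds = kinds, targets = targets)
}

# compare implementation and oracle on one read
split_agrees <- function(read, targets) {
  a <- realign_split(read, targets)
  b <- oracle_realign_split(read, targets)
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) != is.null(b)) return(FALSE)
  isTRUE(a$score == b$score) &&
    identical(a$side_a, b$side_a) &&
    identical(a$side_b, b$side_b) &&
    a$breakpoint == b$breakpoint
}
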