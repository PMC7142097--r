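# Independent brute-force oracles used to cross-check the package's
# implementations.

# Clopper-Pearson interval by direct numeric inversion of the binomial
# tail sums (no beta quantiles).
oracle_clopper_pearson <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  low <- if (x == 0) 0 else {
    stats::uniroot(function(p) 1 - stats::pbinom(x - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  high <- if (x == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(low = low, high = high)
}

# Tukey fence by hand: sort and linearly interpolate the quartiles
# (type-7 sample quantiles), then Q3 + 1.5 * IQR.
oracle_iqr_fence <- function(x) {
  x <- sort(x)
  n <- length(x)
  interp <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
  }
  q1 <- interp(0.25)
  q3 <- interp(0.75)
  q3 + 1.5 * (q3 - q1)
}

# Exhaustive breakpoint-scan split realignment in plain R: every
# breakpoint, every piece placement on every target strand, dense match
# counting through matrix slices. Mirrors the contract of
# realign_split() through an independent code path.
oracle_realign_split <- function(read_seq, targets, min_piece = 20L,
                                 min_identity = 0.9) {
  read_seq <- toupper(read_seq)
  L <- nchar(read_seq)
  rc <- strsplit(read_seq, NULL)[[1]]
  targets <- Filter(function(t) t$width >= L, targets)
  nt <- length(targets)

  # best ungapped placement of every prefix (and, via reversal, every
  # suffix) by dense match matrices: row o = placement offset, column i
  # = piece length; cumulative matches via matrix cumsum
  best_pieces <- function(piece_chars, tc) {
    N <- length(tc)
    tcp <- c(tc, rep("#", L))             # sentinel pad never matches
    mm <- vapply(seq_len(L),
                 function(i) (tcp[seq_len(N) + i - 1L] == piece_chars[i]) * 1,
                 numeric(N))              # N x L match indicators
    # cumulative matches via multiplication with a triangular ones matrix:
    # cs[o, i] = matches of piece[1..i] placed at offset o
    cs <- mm %*% (upper.tri(diag(L), diag = TRUE) * 1)
    m <- integer(L); o <- integer(L)
    for (i in seq_len(L)) {               # piece length i fits N-i+1 offsets
      v <- cs[seq_len(N - i + 1L), i]
      m[i] <- max(v); o[i] <- which.max(v)
    }
    list(m = m, o = o)
  }
  pref_m <- matrix(0L, nt, L); pref_o <- matrix(1L, nt, L)
  suf_m <- matrix(0L, nt, L); suf_o <- matrix(1L, nt, L)
  for (ti in seq_len(nt)) {
    tc <- strsplit(targets[[ti]]$seq, NULL)[[1]]
    N <- length(tc)
    p <- best_pieces(rc, tc)
    pref_m[ti, ] <- p$m; pref_o[ti, ] <- p$o
    s <- best_pieces(rev(rc), rev(tc))
    for (k in seq_len(L)) {               # k = suffix length
      i <- L - k + 1L
      suf_m[ti, i] <- s$m[k]
      suf_o[ti, i] <- N - s$o[k] - k + 2L
    }
  }

  if (max(pref_m[, L]) / L >= min_identity) return(NULL)
  bs <- seq.int(min_piece, L - min_piece)
  best <- NULL
  for (b in bs) {
    ta <- which.max(pref_m[, b]); ma <- pref_m[ta, b]
    tb <- which.max(suf_m[, b + 1L]); mb <- suf_m[tb, b + 1L]
    if (ma / b < min_identity || mb / (L - b) < min_identity) next
    sc <- 2L * (ma + mb) - L
    if (is.null(best) || sc > best$score) {
      best <- list(score = sc, b = b, ta = ta, tb = tb,
                   oa = pref_o[ta, b], ob = suf_o[tb, b + 1L])
    }
  }
  if (is.null(best)) return(NULL)
  tA <- targets[[best$ta]]; tB <- targets[[best$tb]]
  ca <- oracle_coords(tA, best$oa, best$oa + best$b - 1L)
  cb <- oracle_coords(tB, best$ob, best$ob + (L - best$b) - 1L)
  list(score = best$score, breakpoint = best$b,
       side_a = list(contig = tA$contig, pos = ca$end, strand = tA$strand),
       side_b = list(contig = tB$contig, pos = cb$start, strand = tB$strand))
}

# independent re-derivation of the placement -> forward coordinate map
oracle_coords <- function(target, s, e) {
  if (target$strand == "+") {
    start <- target$origin + s; end <- target$origin + e
  } else {
    start <- target$origin + target$width - s + 1L
    end <- target$origin + target$width - e + 1L
  }
  if (!is.na(target$circular_len)) {
    start <- ((start - 1L) %% target$circular_len) + 1L
    end <- ((end - 1L) %% target$circular_len) + 1L
  }
  list(start = as.integer(start), end = as.integer(end))
}
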