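#' Reverse complement of a plain character sequence
#' @param s A DNA string (A/C/G/T).
#' @return Reverse-complemented string.
#' @keywords internal
revcomp_chr <- function(s) {
  vapply(strsplit(chartr("ACGTacgt", "TGCATGCA", s), NULL),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Build realignment targets for split-read breakpoint scanning
#'
#' Prepares the strand-expanded reference set that [realign_split()] scans:
#' each nuclear window contributes a forward and a reverse-complement
#' target, and the mtDNA reference contributes both strands of a
#' circular-extended copy (the first `read_len - 1` bases appended) so
#' that alignments crossing the 16569/1 origin are found.
#'
#' @param nuclear Named list of nuclear windows, each a list with `seq`
#'   (character) and `origin` (0-based coordinate offset of the window on
#'   its contig; 0 for a full contig). Names are contig names.
#' @param mt_seq The mtDNA reference sequence (character, length 16569 for
#'   rCRS coordinates).
#' @param read_len Maximum read length handled (default 150).
#' @return A list of target descriptors consumed by [realign_split()].
#' @export
make_split_targets <- function(nuclear, mt_seq, read_len = 150L) {
  targets <- list()
  for (nm in names(nuclear)) {
    w <- nuclear[[nm]]
    seq <- toupper(w$seq)
    targets[[length(targets) + 1L]] <- list(
      contig = nm, strand = "+", seq = seq, width = nchar(seq),
      origin = w$origin, circular_len = NA_integer_)
    targets[[length(targets) + 1L]] <- list(
      contig = nm, strand = "-", seq = revcomp_chr(seq), width = nchar(seq),
      origin = w$origin, circular_len = NA_integer_)
  }
  if (!is.null(mt_seq)) {
    mt_seq <- toupper(mt_seq)
    mlen <- nchar(mt_seq)
    ext <- paste0(mt_seq, substr(mt_seq, 1L, min(read_len - 1L, mlen)))
    targets[[length(targets) + 1L]] <- list(
      contig = "MT", strand = "+", seq = ext, width = nchar(ext),
      origin = 0L, circular_len = mlen)
    targets[[length(targets) + 1L]] <- list(
      contig = "MT", strand = "-", seq = revcomp_chr(ext),
      width = nchar(ext), origin = 0L, circular_len = mlen)
  }
  targets
}

# Map a placement [s, e] (1-based in target$seq, read orientation) to
# forward-reference coordinates of the read-direction start and end base.
target_coords <- function(target, s, e) {
  if (target$strand == "+") {
    start <- target$origin + s
    end <- target$origin + e
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

#' Two-piece split realignment of a candidate read
#'
#' Deterministic replacement for BLAT-style split-read realignment: the
#' read is partitioned at every admissible breakpoint into a prefix and a
#' suffix, and each piece is fitted ungapped at every placement on every
#' target strand (nuclear windows, both strands; circular mtDNA, both
#' strands). The reported split maximises total matching bases
#' (equivalently the match +1 / mismatch -1 score); ties resolve to the
#' leftmost breakpoint and the first target in [make_split_targets()]
#' order. Pieces are scored without gaps because at 150 bp scale junction
#' reads differ from the references by substitutions only; see the
#' methods vignette.
#'
#' A read whose full length already fits one target at `min_identity` or
#' better is not split. A split is reported only when both pieces are at
#' least `min_piece` bases and reach `min_identity`.
#'
#' @param read_seq The read sequence (<= length of every target).
#' @param targets From [make_split_targets()].
#' @param min_piece Minimum piece length in bases (default 20).
#' @param min_identity Minimum per-piece identity (default 0.9).
#' @return `NULL` when no admissible split exists, otherwise a list with
#'   `side_a`/`side_b` (each `contig`, `pos`, `strand`; `pos` is the
#'   junction-adjacent base), `piece_a`/`piece_b` full coordinate ranges,
#'   `breakpoint` (prefix length), `identity_a`, `identity_b`, `score`.
#' @export
realign_split <- function(read_seq, targets, min_piece = 20L,
                          min_identity = 0.9) {
  read_seq <- toupper(read_seq)
  L <- nchar(read_seq)
  if (L < 2L * min_piece) return(NULL)
  short <- vapply(targets, function(t) t$width < L, logical(1))
  if (all(short)) {
    stop("all realignment references are shorter than the read (",
         L, " bp)")
  }
  targets <- targets[!short]
  nt <- length(targets)

  pref_m <- matrix(0L, nt, L); pref_o <- matrix(0L, nt, L)
  suf_m <- matrix(0L, nt, L); suf_o <- matrix(0L, nt, L)
  for (ti in seq_len(nt)) {
    sc <- .piece_scan(read_seq, targets[[ti]]$seq)
    pref_m[ti, ] <- sc$pref[, 1]; pref_o[ti, ] <- sc$pref[, 2]
    suf_m[ti, ] <- sc$suf[, 1]; suf_o[ti, ] <- sc$suf[, 2]
  }

  # whole-read fit: no junction to call
  if (max(pref_m[, L]) / L >= min_identity) return(NULL)

  bs <- seq.int(min_piece, L - min_piece)
  ta <- apply(pref_m[, bs, drop = FALSE], 2, which.max)
  ma <- pref_m[cbind(ta, bs)]
  tb <- apply(suf_m[, bs + 1L, drop = FALSE], 2, which.max)
  mb <- suf_m[cbind(tb, bs + 1L)]
  ok <- (ma / bs >= min_identity) & (mb / (L - bs) >= min_identity)
  if (!any(ok)) return(NULL)
  score <- 2L * (ma + mb) - L
  score[!ok] <- -Inf
  bi <- which.max(score) # ties -> leftmost breakpoint
  b <- bs[bi]

  tA <- targets[[ta[bi]]]
  tB <- targets[[tb[bi]]]
  oA <- pref_o[ta[bi], b]
  oB <- suf_o[tb[bi], b + 1L]
  ca <- target_coords(tA, oA, oA + b - 1L)
  cb <- target_coords(tB, oB, oB + (L - b) - 1L)
  list(
    side_a = list(contig = tA$contig, pos = ca$end, strand = tA$strand),
    side_b = list(contig = tB$contig, pos = cb$start, strand = tB$strand),
    piece_a = list(contig = tA$contig, start = min(ca$start, ca$end),
                   end = max(ca$start, ca$end), strand = tA$strand),
    piece_b = list(contig = tB$contig, start = min(cb$start, cb$end),
                   end = max(cb$start, cb$end), strand = tB$strand),
    breakpoint = b,
    identity_a = ma[bi] / b,
    identity_b = mb[bi] / (L - b),
    score = score[bi]
  )
}
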