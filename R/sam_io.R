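#' Write aligned reads as a SAM file
#'
#' Emits a minimal valid SAM: `@HD`/`@SQ` header lines followed by one
#' record per row. Paired rows (non-`NA` mate fields) get paired flags
#' with mate position and `=`/contig RNEXT; reverse-strand reads are
#' stored reverse-complemented as the format requires.
#'
#' @param reads An [aligned_reads] table.
#' @param path Output file path.
#' @param contig_lengths Named integer vector of reference lengths for
#'   the `@SQ` header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, contig_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(contig_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm,
                       as.integer(contig_lengths[[nm]])), con)
  }
  if (!nrow(reads)) return(invisible(path))
  paired <- !is.na(reads$mate_contig)
  first <- !duplicated(reads$read_id)
  flag <- ifelse(paired, 1L, 0L) +
    ifelse(reads$strand == "-", 16L, 0L) +
    ifelse(paired & !is.na(reads$mate_strand) & reads$mate_strand == "-",
           32L, 0L) +
    ifelse(paired, ifelse(first, 64L, 128L), 0L)
  seq <- ifelse(is.na(reads$seq), "*",
                ifelse(reads$strand == "-", revcomp_chr(reads$seq),
                       reads$seq))
  rnext <- ifelse(paired,
                  ifelse(reads$mate_contig == reads$contig, "=",
                         reads$mate_contig), "*")
  pnext <- ifelse(paired, reads$mate_pos, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*",
                   reads$read_id, flag, reads$contig, reads$pos,
                   reads$mapq, reads$cigar, rnext, pnext, seq)
  writeLines(lines, con)
  invisible(path)
}

#' Read a SAM file into an aligned-reads table
#'
#' Parses via Rsamtools (SAM converted to BAM in a temporary directory,
#' then scanned), recovering the package's [aligned_reads] layout; mate
#' strand is taken from the flag bits and reverse-strand sequences are
#' restored to read orientation.
#'
#' @param path SAM file path.
#' @return An [aligned_reads] table.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand",
             "seq", "mrnm", "mpos"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  if (!n) return(aligned_reads())
  seq <- as.character(b$seq)
  seq[seq == ""] <- NA_character_
  rev <- bitwAnd(b$flag, 16L) > 0L
  seq[rev & !is.na(seq)] <- revcomp_chr(seq[rev & !is.na(seq)])
  paired <- bitwAnd(b$flag, 1L) > 0L
  aligned_reads(
    read_id = b$qname,
    contig = as.character(b$rname),
    pos = b$pos,
    strand = ifelse(rev, "-", "+"),
    mapq = b$mapq,
    cigar = b$cigar,
    seq = seq,
    mate_contig = ifelse(paired, as.character(b$mrnm), NA_character_),
    mate_pos = ifelse(paired, b$mpos, NA_integer_),
    mate_strand = ifelse(paired,
                         ifelse(bitwAnd(b$flag, 32L) > 0L, "-", "+"),
                         NA_character_))
}

#' Write reference sequences as FASTA
#'
#' @param refs List with `nuclear` (named list) and `mt`, as produced by
#'   [make_references()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refs, path) {
  seqs <- c(refs$nuclear, list(MT = refs$mt))
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read reference sequences from FASTA
#'
#' The sequence named `MT` (or `chrM`) becomes the mtDNA reference; all
#' others are nuclear contigs.
#'
#' @param path FASTA file path.
#' @return List with `nuclear` (named list of character sequences) and
#'   `mt`.
#' @export
read_fasta_refs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- stats::setNames(as.character(x), names(x))
  mt_name <- intersect(c("MT", "chrM", "chrMT"), names(seqs))[1]
  if (is.na(mt_name)) stop("no MT/chrM sequence in ", path)
  list(nuclear = as.list(seqs[setdiff(names(seqs), mt_name)]),
       mt = unname(seqs[[mt_name]]))
}

#' Read a single-sample mtDNA VCF into a callset
#'
#' Expects genotype (FORMAT) fields `DP` plus per-strand allele depths
#' `ADF`/`ADR` (reference first, then one entry per alternate allele,
#' the bcftools convention). Only single-nucleotide substitutions are
#' retained; multi-allelic records are split into one row per alternate
#' allele.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @param sample_id Optional sample id override (default: the VCF sample
#'   name).
#' @param mean_mt_depth Mean mtDNA depth; default is the mean of the DP
#'   field.
#' @return An [mt_callset].
#' @export
read_mt_vcf <- function(path, sample_id = NULL, mean_mt_depth = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_mt_vcf requires the VariantAnnotation package; ",
         "use read_mt_tsv otherwise")
  }
  vcf <- VariantAnnotation::readVcf(path)
  if (ncol(vcf) != 1L) stop("expected a single-sample VCF: ", path)
  if (is.null(sample_id)) sample_id <- colnames(vcf)[1]
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alts <- rr$ALT
  dp <- as.integer(VariantAnnotation::geno(vcf)$DP[, 1])
  adf <- VariantAnnotation::geno(vcf)$ADF[, 1]
  adr <- VariantAnnotation::geno(vcf)$ADR[, 1]
  rows <- list()
  for (i in seq_along(rr)) {
    a <- as.character(alts[[i]])
    for (j in seq_along(a)) {
      if (nchar(ref[i]) != 1L || nchar(a[j]) != 1L) next  # SNVs only
      rows[[length(rows) + 1L]] <- data.frame(
        pos = as.integer(BiocGenerics::start(rr))[i], ref = ref[i],
        alt = a[j],
        depth = dp[i],
        alt_fwd = adf[[i]][j + 1L], alt_rev = adr[[i]][j + 1L],
        ref_fwd = adf[[i]][1L], ref_rev = adr[[i]][1L],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  v <- if (is.null(tab)) mt_variants() else
    mt_variants(pos = tab$pos, ref = tab$ref, alt = tab$alt,
                depth = tab$depth, alt_fwd = tab$alt_fwd,
                alt_rev = tab$alt_rev, ref_fwd = tab$ref_fwd,
                ref_rev = tab$ref_rev)
  if (is.null(mean_mt_depth)) mean_mt_depth <- mean(dp)
  mt_callset(sample_id, v, mean_mt_depth = mean_mt_depth)
}
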