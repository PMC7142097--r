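#' @useDynLib meganumt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Length of the circular human mtDNA reference (rCRS coordinates)
#' @export
MT_GENOME_LENGTH <- 16569L

#' Low-complexity mtDNA regions masked during variant filtering
#'
#' Inclusive 1-based intervals on the mtDNA reference that are excluded from
#' variant calling because local alignment there is unreliable (homopolymer
#' and repeat tracts around the control region and known artefact hotspots).
#'
#' @format A data frame with columns `start` and `end`.
#' @export
MT_MASKED_REGIONS <- data.frame(
  start = c(66L, 300L, 513L, 3106L, 12418L, 16182L),
  end   = c(71L, 316L, 525L, 3107L, 12425L, 16194L)
)

#' Construct a table of mtDNA variant calls
#'
#' Builds and validates the canonical per-sample mtDNA variant table used
#' throughout the package. One row is one single-nucleotide call on the
#' 16,569 bp circular mitochondrial reference, identified by
#' `(pos, alt)`; multi-allelic sites are independent rows.
#'
#' @param pos 1-based position on the mtDNA reference (1..16569).
#' @param ref,alt Single reference / alternate bases (A, C, G or T).
#' @param depth Total read depth at the site (the per-variant depth
#'   `DPmtvar`).
#' @param alt_fwd,alt_rev Reads supporting the alternate allele on the
#'   forward / reverse strand.
#' @param ref_fwd,ref_rev Optional reads supporting the reference allele per
#'   strand; used by the strand filter when the alternate allele is the
#'   major allele. `NA` when unavailable.
#' @param af Allele fraction; computed as `(alt_fwd + alt_rev) / depth` when
#'   omitted, validated against it when supplied.
#' @return A `data.frame` of class `mt_variants` with columns `pos`, `ref`,
#'   `alt`, `depth`, `alt_fwd`, `alt_rev`, `ref_fwd`, `ref_rev`, `af`.
#' @examples
#' mt_variants(pos = 5000, ref = "A", alt = "G",
#'             depth = 1000, alt_fwd = 250, alt_rev = 250)
#' @export
mt_variants <- function(pos = integer(), ref = character(), alt = character(),
                        depth = integer(), alt_fwd = integer(),
                        alt_rev = integer(), ref_fwd = NA_integer_,
                        ref_rev = NA_integer_, af = NULL) {
  n <- length(pos)
  v <- data.frame(
    pos = as.integer(pos), ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)), depth = as.integer(depth),
    alt_fwd = as.integer(alt_fwd), alt_rev = as.integer(alt_rev),
    ref_fwd = rep_len(as.integer(ref_fwd), n),
    ref_rev = rep_len(as.integer(ref_rev), n),
    stringsAsFactors = FALSE
  )
  v$af <- if (is.null(af)) {
    ifelse(v$depth > 0, (v$alt_fwd + v$alt_rev) / v$depth, 0)
  } else {
    as.numeric(af)
  }
  validate_mt_variants(v)
  class(v) <- c("mt_variants", "data.frame")
  v
}

validate_mt_variants <- function(v) {
  bad <- which(v$pos < 1L | v$pos > MT_GENOME_LENGTH | is.na(v$pos))
  if (length(bad)) {
    stop("mtDNA position outside 1..", MT_GENOME_LENGTH, " for record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (pos = ", paste(utils::head(v$pos[bad], 5L), collapse = ", "), ")")
  }
  bases <- c("A", "C", "G", "T")
  if (nrow(v)) {
    if (!all(v$ref %in% bases) || !all(v$alt %in% bases)) {
      stop("ref/alt alleles must be single bases in {A,C,G,T}; ",
           "indels and symbolic alleles are rejected at parse time")
    }
    if (any(v$ref == v$alt)) {
      stop("ref and alt allele identical at position(s): ",
           paste(utils::head(v$pos[v$ref == v$alt], 5L), collapse = ", "))
    }
    if (any(v$alt_fwd + v$alt_rev > v$depth)) {
      stop("alt_fwd + alt_rev exceeds depth at position(s): ",
           paste(utils::head(v$pos[v$alt_fwd + v$alt_rev > v$depth], 5L),
                 collapse = ", "))
    }
    if (any(v$alt_fwd < 0L | v$alt_rev < 0L | v$depth < 0L)) {
      stop("negative read counts are invalid")
    }
    aft <- ifelse(v$depth > 0, (v$alt_fwd + v$alt_rev) / v$depth, 0)
    if (any(abs(v$af - aft) > 1e-9)) {
      stop("af inconsistent with (alt_fwd + alt_rev)/depth at position(s): ",
           paste(utils::head(v$pos[abs(v$af - aft) > 1e-9], 5L),
                 collapse = ", "))
    }
  }
  invisible(v)
}

#' Filter raw mtDNA variant calls
#'
#' Applies the five retention rules used throughout the analysis:
#' keep a call only if (1) its allele fraction is above 1%; (2) it is a
#' single-nucleotide substitution (enforced at construction); (3) depth is
#' at least 200x; (4) the minor allele is supported by at least 2 reads on
#' each strand; (5) the position lies outside the masked low-complexity
#' regions ([MT_MASKED_REGIONS]). Input order is preserved; records are
#' never modified, only dropped.
#'
#' The minor allele for rule (4) is the allele (ref or alt) with fewer
#' supporting reads. When the alternate allele is the major one
#' (`af > 0.5`) the rule is applied to the reference-supporting strand
#' counts `ref_fwd`/`ref_rev`; if those are absent the rule falls back to
#' the alt strand counts with a warning. A site with zero minor-allele
#' reads (e.g. a pure homoplasmy) has no minor allele to test and passes
#' rule (4).
#'
#' @param raw An [mt_variants] table.
#' @param af_min Allele-fraction floor (default 0.01, strict `>`).
#' @param depth_min Minimum depth (default 200, inclusive).
#' @param strand_min Minimum minor-allele reads per strand (default 2).
#' @return The retained subset, same class and column order.
#' @export
filter_variants <- function(raw, af_min = 0.01, depth_min = 200L,
                            strand_min = 2L) {
  validate_mt_variants(raw)
  if (!nrow(raw)) return(raw)
  keep_af <- raw$af > af_min
  keep_dp <- raw$depth >= depth_min
  keep_mask <- !in_masked_region(raw$pos)

  alt_n <- raw$alt_fwd + raw$alt_rev
  ref_n <- raw$depth - alt_n
  alt_minor <- alt_n <= ref_n
  have_ref_strands <- !is.na(raw$ref_fwd) & !is.na(raw$ref_rev)
  min_fwd <- ifelse(alt_minor, raw$alt_fwd,
                    ifelse(have_ref_strands, raw$ref_fwd, raw$alt_fwd))
  min_rev <- ifelse(alt_minor, raw$alt_rev,
                    ifelse(have_ref_strands, raw$ref_rev, raw$alt_rev))
  if (any(!alt_minor & !have_ref_strands)) {
    warning("major-allele variants without ref strand counts: strand rule ",
            "applied to alt counts for ",
            sum(!alt_minor & !have_ref_strands), " record(s)")
  }
  minor_n <- pmin(alt_n, ref_n)
  keep_strand <- minor_n == 0L | (min_fwd >= strand_min & min_rev >= strand_min)

  raw[keep_af & keep_dp & keep_mask & keep_strand, , drop = FALSE]
}

in_masked_region <- function(pos) {
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(MT_MASKED_REGIONS))) {
    out <- out | (pos >= MT_MASKED_REGIONS$start[i] &
                    pos <= MT_MASKED_REGIONS$end[i])
  }
  out
}

#' Is a variant homoplasmic?
#'
#' Homoplasmy is conservatively defined as an allele fraction strictly
#' above 95%.
#'
#' @param v An [mt_variants] table (or any data frame with an `af` column).
#' @return Logical vector, one value per record.
#' @export
is_homoplasmic <- function(v) {
  v$af > 0.95
}

#' Construct a per-sample mtDNA callset
#'
#' @param sample_id Sample identifier.
#' @param variants An [mt_variants] table; duplicate `(pos, alt)` keys are
#'   rejected.
#' @param mean_mt_depth Mean depth of coverage over the mtDNA genome
#'   (must be positive); used for trio-level depth QC.
#' @return An object of class `mt_callset`.
#' @export
mt_callset <- function(sample_id, variants = mt_variants(),
                       mean_mt_depth = NULL) {
  validate_mt_variants(variants)
  key <- variant_key(variants)
  if (anyDuplicated(key)) {
    stop("duplicate (position, alt) keys in callset for sample ", sample_id,
         ": ", paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (is.null(mean_mt_depth) || !is.finite(mean_mt_depth) ||
      mean_mt_depth <= 0) {
    stop("mean_mt_depth must be a positive number for sample ", sample_id)
  }
  structure(list(sample_id = as.character(sample_id),
                 variants = variants,
                 mean_mt_depth = as.numeric(mean_mt_depth)),
            class = "mt_callset")
}

#' @export
print.mt_callset <- function(x, ...) {
  cat("mtDNA callset for sample ", x$sample_id, ": ", nrow(x$variants),
      " variants, mean mtDNA depth ", round(x$mean_mt_depth, 1), "x\n",
      sep = "")
  invisible(x)
}

#' Variant keys of a callset or variant table
#'
#' Variant identity throughout the package is the pair
#' `(position, alt allele)`, printed as e.g. `"m.100A>G"`-style
#' `"100:G"` keys.
#'
#' @param x An [mt_variants] table or an [mt_callset].
#' @return Character vector of `"pos:alt"` keys.
#' @export
variant_key <- function(x) {
  if (inherits(x, "mt_callset")) x <- x$variants
  if (!nrow(x)) return(character())
  paste0(x$pos, ":", x$alt)
}

#' Filter every variant table inside a callset
#'
#' @param callset An [mt_callset].
#' @param ... Passed to [filter_variants()].
#' @return The callset with its variant table filtered.
#' @export
filter_callset <- function(callset, ...) {
  callset$variants <- filter_variants(callset$variants, ...)
  callset
}

#' Is a variant key detected in a callset above a threshold?
#'
#' A key counts as detected only if it is present in the (already
#' filtered) callset with allele fraction strictly above `threshold`.
#'
#' @param callset An [mt_callset] (assumed filtered).
#' @param key Character vector of `"pos:alt"` keys (see [variant_key()]).
#' @param threshold Allele-fraction threshold in (0,1); the screening
#'   default is 0.05.
#' @return Logical vector, one value per key.
#' @export
is_detected <- function(callset, key, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  ks <- variant_key(callset)
  idx <- match(key, ks)
  found <- !is.na(idx)
  found[found] <- callset$variants$af[idx[found]] > threshold
  found
}

#' Trio-level mtDNA depth QC
#'
#' A trio is analysable only when father, mother and child all have mean
#' mtDNA depth of at least `min_depth` (a sample strictly below the
#' threshold fails; exactly at threshold passes).
#'
#' @param father,mother,child [mt_callset] objects.
#' @param min_depth Minimum mean mtDNA depth (default 500).
#' @return `TRUE` if all three members pass.
#' @export
trio_depth_qc <- function(father, mother, child, min_depth = 500) {
  stopifnot(min_depth > 0)
  all(c(father$mean_mt_depth, mother$mean_mt_depth, child$mean_mt_depth) >=
        min_depth)
}

#' Read mtDNA variant calls from TSV
#'
#' The dialect is a tab-separated table with header columns
#' `sample_id, pos, ref, alt, depth, alt_fwd, alt_rev` and optionally
#' `ref_fwd, ref_rev, mean_mt_depth`. One file may hold several samples.
#'
#' @param path File path.
#' @return A named list of [mt_callset] objects, one per sample.
#' @export
read_mt_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pos", "ref", "alt", "depth", "alt_fwd", "alt_rev")
  if (!all(need %in% names(tab))) {
    stop("mtDNA call TSV must contain columns: ", paste(need, collapse = ", "))
  }
  if (!"ref_fwd" %in% names(tab)) tab$ref_fwd <- NA_integer_
  if (!"ref_rev" %in% names(tab)) tab$ref_rev <- NA_integer_
  if (!"mean_mt_depth" %in% names(tab)) tab$mean_mt_depth <- NA_real_
  out <- lapply(split(tab, tab$sample_id), function(s) {
    v <- mt_variants(pos = s$pos, ref = s$ref, alt = s$alt, depth = s$depth,
                     alt_fwd = s$alt_fwd, alt_rev = s$alt_rev,
                     ref_fwd = s$ref_fwd, ref_rev = s$ref_rev)
    md <- s$mean_mt_depth[1]
    if (is.na(md)) md <- mean(s$depth)
    mt_callset(s$sample_id[1], v, mean_mt_depth = md)
  })
  out[order(names(out))]
}

#' Write mtDNA callsets to TSV
#'
#' Inverse of [read_mt_tsv()]; writes one row per variant with the
#' sample's mean mtDNA depth echoed on every row.
#'
#' @param callsets A list of [mt_callset] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mt_tsv <- function(callsets, path) {
  rows <- lapply(callsets, function(cs) {
    v <- cs$variants
    if (!nrow(v)) return(NULL)
    cbind(data.frame(sample_id = cs$sample_id, stringsAsFactors = FALSE),
          v, mean_mt_depth = cs$mean_mt_depth)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(sample_id = character(), pos = integer(),
                      ref = character(), alt = character(), depth = integer(),
                      alt_fwd = integer(), alt_rev = integer(),
                      ref_fwd = integer(), ref_rev = integer(),
                      af = numeric(), mean_mt_depth = numeric())
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
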