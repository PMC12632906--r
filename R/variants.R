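#' Variant key tables
#'
#' Throughout mosaicbench a set of variants is represented as a plain
#' `data.frame` with columns `chrom` (character), `pos` (1-based reference
#' position, integer), `ref` and `alt` (uppercase allele strings).  Each row is
#' one biallelic record: multi-allelic input must be split (see
#' [normalize_variants()]).  `variant_id()` gives the canonical string identity
#' used for exact matching between call sets and truth sets.
#'
#' @param chrom,pos,ref,alt vectors describing one variant per element.
#' @return `variant_key()` returns a validated data.frame; `variant_id()` a
#'   character vector `"chrom:pos:ref:alt"`.
#' @examples
#' v <- variant_key("chr1", 100, "A", "G")
#' variant_id(v)
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    stringsAsFactors = FALSE
  )
  validate_variant_key(df)
  df
}

validate_variant_key <- function(df) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  check_alleles(df$ref)
  check_alleles(df$alt)
  if (any(df$ref == df$alt))
    stop("ref and alt alleles must differ")
  if (any(df$pos < 1L))
    stop("positions are 1-based and must be >= 1")
  invisible(df)
}

check_alleles <- function(x) {
  if (any(is.na(x) | nchar(x) == 0L))
    stop("empty or missing allele string")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop("allele contains non-DNA characters: ", paste(unique(x[bad]), collapse = ", "))
  invisible(x)
}

#' @rdname variant_key
#' @param key a variant key data.frame.
#' @export
variant_id <- function(key) {
  paste(key$chrom, key$pos, key$ref, key$alt, sep = ":")
}

#' @rdname variant_key
#' @export
is_snv <- function(key) {
  nchar(key$ref) == 1L & nchar(key$alt) == 1L
}

#' @rdname variant_key
#' @export
indel_length <- function(key) {
  abs(nchar(key$ref) - nchar(key$alt))
}

#' Normalize variant records to canonical biallelic form
#'
#' Splits multi-allelic records into one row per alternate allele, trims
#' redundant shared bases and left-aligns indels, reproducing the semantics of
#' `bcftools norm -a -m - -f`: the canonical representation of an indel is the
#' 5'-most, minimal-length form.  SNVs pass through unchanged.
#'
#' Left-alignment needs reference sequence context; supply it via `ref_seqs`, a
#' named character vector (or list) of contig sequences.  When the contig is
#' absent from `ref_seqs` the record is trimmed only (no left shift), which is
#' already canonical whenever the base preceding the event differs from the
#' repeated unit.
#'
#' @param chrom contig name (scalar).
#' @param pos 1-based position (scalar).
#' @param ref reference allele.
#' @param alt_list character vector of alternate alleles at this site.
#' @param ref_seqs optional named character vector of contig sequences used for
#'   left-alignment.
#' @return a variant key data.frame with one row per alternate allele.
#' @examples
#' normalize_variant("chr1", 100, "AT", c("A", "ATT"))
#' @export
normalize_variant <- function(chrom, pos, ref, alt_list, ref_seqs = NULL) {
  ref <- toupper(ref)
  alt_list <- toupper(alt_list)
  check_alleles(ref)
  check_alleles(alt_list)
  rows <- lapply(alt_list, function(alt) {
    norm1 <- normalize_one(chrom, as.integer(pos), ref, alt, ref_seqs)
    data.frame(chrom = chrom, pos = norm1$pos, ref = norm1$ref, alt = norm1$alt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  validate_variant_key(out)
  out
}

#' @rdname normalize_variant
#' @param keys a variant key data.frame (possibly with extra columns, which are
#'   preserved).
#' @export
normalize_variants <- function(keys, ref_seqs = NULL) {
  if (nrow(keys) == 0) return(keys)
  norm <- mapply(normalize_one, keys$chrom, keys$pos, keys$ref, keys$alt,
                 MoreArgs = list(ref_seqs = ref_seqs), SIMPLIFY = FALSE)
  keys$pos <- vapply(norm, `[[`, integer(1), "pos")
  keys$ref <- vapply(norm, `[[`, character(1), "ref")
  keys$alt <- vapply(norm, `[[`, character(1), "alt")
  validate_variant_key(keys)
  keys
}

# Trim shared suffix/prefix and left-align against the contig sequence.
# Mirrors the vt/bcftools normalization loop: repeatedly strip a shared
# terminal base (borrowing the preceding reference base when an allele would
# otherwise empty), then strip shared leading bases.
normalize_one <- function(chrom, pos, ref, alt, ref_seqs = NULL) {
  pos <- as.integer(pos)
  if (nchar(ref) == 1L && nchar(alt) == 1L)
    return(list(pos = pos, ref = ref, alt = alt))
  ctg <- if (!is.null(ref_seqs) && chrom %in% names(ref_seqs))
    toupper(ref_seqs[[chrom]]) else NULL
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (substr(ref, nr, nr) != substr(alt, na, na)) break
    if (nr == 1L || na == 1L) {
      # trimming would empty an allele; extend left with reference context
      if (is.null(ctg) || pos <= 1L) break
      prev <- substr(ctg, pos - 1L, pos - 1L)
      ref <- paste0(prev, substr(ref, 1L, nr - 1L))
      alt <- paste0(prev, substr(alt, 1L, na - 1L))
      pos <- pos - 1L
    } else {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
    }
  }
  # strip shared leading bases, keeping at least one base per allele
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
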