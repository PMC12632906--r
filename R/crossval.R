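#' Merge per-caller candidate call sets
#'
#' Builds the unified candidate set for truth-set construction: the union of
#' normalized PASS calls from each caller, keyed by exact variant identity,
#' with per-caller provenance flags and a caller count.  Indels longer than
#' `max_indel_len` (50 bp by default) are dropped at entry.  A call set
#' containing duplicate keys after normalization is rejected outright.
#'
#' @param callsets named list of call-set data.frames with columns `chrom`,
#'   `pos`, `ref`, `alt`, optionally `filter` (records whose filter is not in
#'   `pass_values` are dropped) and `caller_vaf`.
#' @param pass_values filter strings accepted as PASS-equivalent.
#' @param max_indel_len maximum indel length retained (bp).
#' @return data.frame of unique variants with one logical column per caller
#'   (`in_<caller>`) and `caller_count`.
#' @export
merge_candidates <- function(callsets, pass_values = c("PASS", "."),
                             max_indel_len = 49L) {
  stopifnot(is.list(callsets), length(callsets) >= 1)
  if (is.null(names(callsets)) || any(names(callsets) == ""))
    stop("callsets must be a named list (caller ids)")
  cleaned <- lapply(names(callsets), function(id) {
    cs <- callsets[[id]]
    validate_variant_key(cs)
    if ("filter" %in% names(cs)) cs <- cs[cs$filter %in% pass_values, , drop = FALSE]
    cs <- cs[indel_length(cs) <= max_indel_len, , drop = FALSE]
    if (anyDuplicated(variant_id(cs)))
      stop("call set '", id, "' contains duplicate variant keys; rejecting it")
    cs
  })
  names(cleaned) <- names(callsets)

  ids <- sort(unique(unlist(lapply(cleaned, variant_id))))
  if (length(ids) == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), caller_count = integer()))
  parts <- do.call(rbind, strsplit(ids, ":", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                    ref = parts[, 3], alt = parts[, 4],
                    stringsAsFactors = FALSE)
  for (id in names(cleaned))
    out[[paste0("in_", id)]] <- ids %in% variant_id(cleaned[[id]])
  out$caller_count <- rowSums(as.matrix(out[, paste0("in_", names(cleaned)),
                                            drop = FALSE]))
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve the major alternate allele at a multi-allelic locus
#'
#' Picks the alternate allele with the highest tumor read count; ties are
#' broken lexicographically (documented convention — the choice only matters
#' for exactly tied counts).
#'
#' @param alt_counts named numeric vector of alternate-allele read counts
#'   (reference allele excluded).
#' @return the major alternate allele, or `NA_character_` when no alternate
#'   read is present.
#' @export
resolve_multiallelic <- function(alt_counts) {
  alt_counts <- alt_counts[alt_counts > 0]
  if (length(alt_counts) == 0) return(NA_character_)
  cand <- names(alt_counts)[alt_counts == max(alt_counts)]
  sort(cand)[1]
}

#' Validate a candidate SNV with long-read pileup evidence
#'
#' A candidate SNV is validated when the alternate allele has at least
#' `min_support` reads in the long-read tumor pileup, zero reads in the
#' matched-normal pileup, and is the major alternate allele at its locus.
#' Otherwise the verdict carries the specific failure.  Missing pileup
#' evidence for either sample yields status `evidence_missing`: such sites
#' are masked downstream rather than rejected, so lack of long-read coverage
#' does not manufacture false negatives.
#'
#' @param key single-row variant key.
#' @param pb_tumor,pb_normal long-read pileup tables for tumor and matched
#'   normal (same quality tier).
#' @param tumor_sample,normal_sample sample labels within the pileups.
#' @param min_support minimum tumor alternate reads (default 2).
#' @return a one-row data.frame: the key, `status` and the evidence counts.
#' @export
validate_snv <- function(key, pb_tumor, pb_normal,
                         tumor_sample = "tumor", normal_sample = "normal",
                         min_support = 2L) {
  stopifnot(nrow(key) == 1)
  check_same_tier(pb_tumor, pb_normal)
  t_alt <- pileup_count(pb_tumor, key$chrom, key$pos, key$alt, tumor_sample)
  n_alt <- pileup_count(pb_normal, key$chrom, key$pos, key$alt, normal_sample)
  t_depth <- pileup_depth(pb_tumor, key$chrom, key$pos, tumor_sample)

  status <- if (is.na(t_alt) || is.na(n_alt)) {
    "evidence_missing"
  } else if (t_alt < min_support) {
    "no_tumor_support"
  } else if (n_alt > 0) {
    "normal_support"
  } else {
    site <- pb_tumor[pb_tumor$chrom == key$chrom & pb_tumor$pos == key$pos &
                       pb_tumor$sample == tumor_sample &
                       pb_tumor$allele != pb_tumor$ref, , drop = FALSE]
    counts <- stats::setNames(site$count, site$allele)
    major <- resolve_multiallelic(counts)
    if (!is.na(major) && major != key$alt) "superseded_multiallelic" else "validated"
  }
  data.frame(key, status = status, tumor_alt = t_alt, tumor_depth = t_depth,
             normal_alt = n_alt, stringsAsFactors = FALSE)
}

#' Exact binomial test against heterozygosity
#'
#' Two-sided exact binomial test of `k` successes in `N` trials against
#' success probability 0.5, used to separate true heterozygous (germline-like)
#' indels from subclonal events and platform artifacts: a clean heterozygote
#' should not reject.  The two-sided p-value sums the probabilities of all
#' outcomes no more likely than the observed one (the "minlike" convention, as
#' in `stats::binom.test`); deviation in either direction is suspect.
#'
#' @param depth number of trials N (total qualifying reads).
#' @param alt_count observed successes k (alternate reads), `0 <= k <= N`.
#' @return exact two-sided p-value.
#' @examples
#' binomial_het_pvalue(10, 5)    # 1: exactly the heterozygous expectation
#' binomial_het_pvalue(100, 10)  # tiny: clearly not heterozygous
#' @export
binomial_het_pvalue <- function(depth, alt_count) {
  if (length(depth) > 1 || length(alt_count) > 1)
    return(mapply(binomial_het_pvalue, depth, alt_count))
  if (is.na(depth) || depth < 1) stop("depth must be >= 1")
  if (alt_count < 0 || alt_count > depth) stop("alt_count must be in [0, depth]")
  probs <- stats::dbinom(0:depth, depth, 0.5)
  # relative tolerance guards against ties broken by floating-point noise,
  # matching the convention of stats::binom.test
  min(1, sum(probs[probs <= probs[alt_count + 1] * (1 + 1e-7)]))
}

#' Classify reads overlapping an indel breakpoint
#'
#' Reads are supplied as an abstraction: mapping quality plus the local allele
#' sequence the read exhibits at the breakpoint.  After discarding reads below
#' `min_mapq`, each read is compared with the reference allele and the
#' targeted indel allele; anything matching neither is tallied per distinct
#' sequence as an "other alternative".
#'
#' @param reads data.frame with columns `mapq` and `seq` (allele observed at
#'   the breakpoint).
#' @param target_key single-row variant key of the candidate indel.
#' @param min_mapq minimum mapping quality (default 1).
#' @return list with `depth`, `ref_support` (DR), `target_alt_support` (DTV),
#'   `other_alt` (named counts) and `af` (DTV/depth; `NA` at depth 0).
#' @export
classify_indel_reads <- function(reads, target_key, min_mapq = 1) {
  stopifnot(nrow(target_key) == 1)
  reads <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  depth <- nrow(reads)
  seqs <- toupper(reads$seq)
  dr <- sum(seqs == target_key$ref)
  dtv <- sum(seqs == target_key$alt)
  other <- seqs[seqs != target_key$ref & seqs != target_key$alt]
  other_alt <- if (length(other)) table(other) else integer(0)
  list(depth = depth, ref_support = dr, target_alt_support = dtv,
       other_alt = as.list(other_alt),
       af = if (depth > 0) dtv / depth else NA_real_)
}

#' Validate a candidate indel with long- and short-read evidence
#'
#' Applies the indel validation rule set in a fixed order, returning the first
#' failure: indels of 51 bp or longer are excluded (`length_fail`); the
#' long-read tumor sample must carry at least `min_pb_support` target-allele
#' reads (`no_tumor_support`); read support must be compatible with a clonal
#' heterozygous event by the exact binomial test, p > 0.05
#' (`allelic_imbalance_fail`); allele fraction must exceed 0.2 in both
#' long-read and short-read tumor data (`tumor_vaf_fail`); and the short-read
#' normal allele fraction must stay below 0.05 (`normal_vaf_fail`).  All
#' inequalities are strict; boundary values fail.  An undefined allele
#' fraction (depth 0) in any required sample yields `evidence_missing`.
#'
#' @param key single-row variant key of the indel.
#' @param pb_tumor,il_tumor,il_normal [classify_indel_reads()] results for the
#'   long-read tumor, short-read tumor and short-read normal data.
#' @param min_pb_support minimum long-read target support (default 2).
#' @param het_p,min_tumor_vaf,max_normal_vaf,max_len rule thresholds.
#' @return one-row data.frame with the key, `status`, and the evidence used.
#' @export
validate_indel <- function(key, pb_tumor, il_tumor, il_normal,
                           min_pb_support = 2L, het_p = 0.05,
                           min_tumor_vaf = 0.2, max_normal_vaf = 0.05,
                           max_len = 50L) {
  stopifnot(nrow(key) == 1)
  len <- indel_length(key)
  afs <- c(pb_tumor$af, il_tumor$af, il_normal$af)
  status <- if (len > max_len) {
    "length_fail"
  } else if (any(is.na(afs))) {
    "evidence_missing"
  } else if (pb_tumor$target_alt_support < min_pb_support) {
    "no_tumor_support"
  } else if (binomial_het_pvalue(pb_tumor$depth, pb_tumor$target_alt_support) <= het_p) {
    "allelic_imbalance_fail"
  } else if (!(pb_tumor$af > min_tumor_vaf && il_tumor$af > min_tumor_vaf)) {
    "tumor_vaf_fail"
  } else if (!(il_normal$af < max_normal_vaf)) {
    "normal_vaf_fail"
  } else {
    "validated"
  }
  data.frame(key, status = status, indel_len = len,
             pb_depth = pb_tumor$depth, pb_dtv = pb_tumor$target_alt_support,
             pb_af = pb_tumor$af, il_tumor_af = il_tumor$af,
             il_normal_af = il_normal$af, stringsAsFactors = FALSE)
}
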