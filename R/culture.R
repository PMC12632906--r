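#' Replicate sharing of admixture-specific variants
#'
#' Mutations acquired during cell-line passaging appear in the mixture
#' replicates but not in the parental-line reference set.  This operation
#' removes reference-set variants from each per-replicate merged call set and
#' tabulates, for every remaining (admixture-specific) variant, the number of
#' replicates `j` in which it was called — the n-way intersection classes of
#' an upset plot, C(n, j) for j = 1..n.
#'
#' @param replicate_callsets named list (one merged call set per replicate) of
#'   variant-key data.frames.
#' @param refset_positives variant-key data.frame of reference-set positives
#'   to remove before counting (may be empty).
#' @return list with `variants` (variant keys + `sharing` = j + per-replicate
#'   flags) and `class_sizes` (named integer vector, size of each class
#'   j = 1..n).
#' @export
replicate_sharing <- function(replicate_callsets, refset_positives = NULL) {
  n <- length(replicate_callsets)
  if (n < 2) stop("sharing analysis needs at least 2 replicates")
  if (is.null(names(replicate_callsets)))
    names(replicate_callsets) <- paste0("rep", seq_len(n))
  ref_ids <- if (!is.null(refset_positives) && nrow(refset_positives))
    variant_id(refset_positives) else character(0)
  kept <- lapply(replicate_callsets, function(cs) {
    validate_variant_key(cs)
    setdiff(unique(variant_id(cs)), ref_ids)
  })
  ids <- sort(unique(unlist(kept)))
  flags <- matrix(FALSE, length(ids), n,
                  dimnames = list(NULL, names(replicate_callsets)))
  for (r in seq_len(n)) flags[, r] <- ids %in% kept[[r]]
  sharing <- as.integer(rowSums(flags))
  parts <- if (length(ids)) do.call(rbind, strsplit(ids, ":", fixed = TRUE)) else
    matrix(character(0), 0, 4)
  variants <- data.frame(chrom = parts[, 1],
                         pos = as.integer(parts[, 2]),
                         ref = parts[, 3], alt = parts[, 4],
                         sharing = sharing, stringsAsFactors = FALSE)
  variants <- cbind(variants, as.data.frame(flags))
  class_sizes <- vapply(seq_len(n), function(j) sum(sharing == j), integer(1))
  names(class_sizes) <- paste0("j", seq_len(n))
  list(variants = variants, class_sizes = class_sizes)
}

#' Long-read support screen with a control exclusion
#'
#' A candidate admixture-only site is `supported` when the mutant allele has
#' at least `min_support` long reads in the admixture dataset *and* fewer than
#' `control_max` supporting reads in an unrelated control dataset sequenced
#' with the same protocol; control support at or above the threshold flags the
#' site `spurious` (a locus-specific systematic error), and insufficient
#' admixture support leaves it `unsupported`.
#'
#' @param sites variant-key data.frame of candidate sites.
#' @param admix_pileup,control_pileup pileup tables for the admixture
#'   long-read dataset and the unrelated control.
#' @param admix_sample,control_sample sample labels in the pileups.
#' @param min_support minimum admixture support (default 2).
#' @param control_max control support at or above this flags spurious
#'   (defaults to `min_support`, the symmetric rule).
#' @return the sites with a `screen` column in
#'   \{supported, spurious, unsupported, evidence_missing\}.
#' @export
longread_support_screen <- function(sites, admix_pileup, control_pileup,
                                    admix_sample = "admixture",
                                    control_sample = "control",
                                    min_support = 2L, control_max = min_support) {
  validate_variant_key(sites)
  a <- pileup_count(admix_pileup, sites$chrom, sites$pos, sites$alt, admix_sample)
  ctl <- pileup_count(control_pileup, sites$chrom, sites$pos, sites$alt,
                      control_sample)
  screen <- ifelse(is.na(a) | is.na(ctl), "evidence_missing",
            ifelse(ctl >= control_max, "spurious",
            ifelse(a >= min_support, "supported", "unsupported")))
  sites$admix_alt <- a
  sites$control_alt <- ctl
  sites$screen <- screen
  sites
}

#' Categorize the provenance of admixture-only candidate sites
#'
#' Distinguishes mutations acquired in the cultured normal line from genuine
#' admixture-only (culture-derived in the mixture) mutations.  Per site:
#' at least one supporting read for the mutant allele in the pure *normal*
#' line (either platform) with none in the pure tumor line →
#' `normal_line_only`; zero support in both pure lines *and* locus inside the
#' negative-control regions → `admixture_only`; anything else → `rejected`.
#'
#' @param sites variant-key data.frame.
#' @param pure_pileups named list of pileup tables, with names
#'   `pb_tumor`, `il_tumor`, `pb_normal`, `il_normal` (tier q = 1, Q = 20);
#'   each pileup's sample label is taken from `samples`.
#' @param samples named character vector mapping the four pileup roles to
#'   sample labels (defaults to the role names).
#' @param negative_regions `GRanges` of negative-control regions (1-based).
#' @return sites with a `provenance` column in
#'   \{admixture_only, normal_line_only, rejected\}.
#' @export
categorize_provenance <- function(sites, pure_pileups, negative_regions,
                                  samples = c(pb_tumor = "pb_tumor",
                                              il_tumor = "il_tumor",
                                              pb_normal = "pb_normal",
                                              il_normal = "il_normal")) {
  validate_variant_key(sites)
  cnt <- function(role) {
    k <- pileup_count(pure_pileups[[role]], sites$chrom, sites$pos, sites$alt,
                      samples[[role]])
    ifelse(is.na(k), 0, k)  # absent from a pure-line pileup = no evidence
  }
  tumor <- cnt("pb_tumor") + cnt("il_tumor")
  normal <- cnt("pb_normal") + cnt("il_normal")
  loci <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  in_neg <- IRanges::overlapsAny(loci, negative_regions)
  sites$provenance <- ifelse(normal >= 1 & tumor == 0, "normal_line_only",
                      ifelse(normal == 0 & tumor == 0 & in_neg, "admixture_only",
                             "rejected"))
  sites
}

#' Assemble the high-confidence culture-derived mutation set
#'
#' Convenience wrapper: the final culture set is the intersection of sites
#' passing the long-read support screen (`supported`) and categorized
#' `admixture_only`.
#'
#' @param screened output of [longread_support_screen()].
#' @param categorized output of [categorize_provenance()] on the same sites.
#' @return variant-key data.frame of culture-derived mutations, annotated
#'   `provenance = "culture"`.
#' @export
culture_mutation_set <- function(screened, categorized) {
  ok <- intersect(variant_id(screened)[screened$screen == "supported"],
                  variant_id(categorized)[categorized$provenance == "admixture_only"])
  out <- screened[variant_id(screened) %in% ok,
                  c("chrom", "pos", "ref", "alt"), drop = FALSE]
  out$provenance <- "culture"
  rownames(out) <- NULL
  out
}
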