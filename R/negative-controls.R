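#' Classify candidate homozygous-reference sites into the negative-control set
#'
#' Implements the iterative two-tier pileup procedure used to assemble
#' confident non-variant ("negative control") positions.  Candidate loci are
#' putative homozygous-reference positions shared by the tumor and normal
#' lines (from upstream germline genotyping; supplied, not re-derived).  Per
#' site:
#'
#' 1. No alternate read in either sample at the permissive long-read tier
#'    (q = 1, Q = 1) → `negative`.
#' 2. Otherwise, any alternate read at the stringent tier (q = 30, Q = 30) →
#'    `removed_highq_alt` (dropped from the negative set).
#' 3. Otherwise, if the permissive-tier alternate allele is corroborated by at
#'    least one short-read (Illumina, q = 1, Q = 1) read of the *same* allele
#'    → `excluded_both_platforms`; lacking short-read support →
#'    `negative_retained` (kept as a high-confidence negative, flagged
#'    distinctly so stricter definitions can drop it).
#'
#' Any site missing a required tier is labelled `evidence_missing` and left
#' masked.
#'
#' @param sites data.frame with one row per candidate locus and columns:
#'   `chrom`, `pos`, `pb_tumor_lowq_alt`, `pb_normal_lowq_alt` (alternate read
#'   counts at q=Q=1 in each long-read sample), `pb_tumor_highq_alt`,
#'   `pb_normal_highq_alt` (same at q=Q=30), `il_same_allele_alt` (short-read
#'   reads carrying the same alternate allele seen at the permissive tier).
#'   `NA` in a column marks missing evidence for that tier.
#' @return the input with a `label` column added.
#' @export
classify_nonvariant_sites <- function(sites) {
  need <- c("pb_tumor_lowq_alt", "pb_normal_lowq_alt",
            "pb_tumor_highq_alt", "pb_normal_highq_alt", "il_same_allele_alt")
  stopifnot(all(need %in% names(sites)))
  low <- sites$pb_tumor_lowq_alt + sites$pb_normal_lowq_alt
  high <- sites$pb_tumor_highq_alt + sites$pb_normal_highq_alt
  il <- sites$il_same_allele_alt
  label <- rep(NA_character_, nrow(sites))
  label[is.na(low)] <- "evidence_missing"
  step1 <- is.na(label) & low == 0
  label[step1] <- "negative"
  label[is.na(label) & is.na(high)] <- "evidence_missing"
  step2 <- is.na(label) & high > 0
  label[step2] <- "removed_highq_alt"
  label[is.na(label) & is.na(il)] <- "evidence_missing"
  step3 <- is.na(label) & il >= 1
  label[step3] <- "excluded_both_platforms"
  label[is.na(label)] <- "negative_retained"
  sites$label <- label
  sites
}

#' @rdname classify_nonvariant_sites
#' @param labels a vector of site labels.
#' @return `is_negative_label()`: logical — which labels count as negative
#'   controls (`negative` and `negative_retained`).
#' @export
is_negative_label <- function(labels) {
  labels %in% c("negative", "negative_retained")
}

#' GATK-style germline hard filters
#'
#' Flags a germline call as failing when any of the standard hard-filter
#' conditions holds: `QD < 2.0`, `FS > 60`, `DP < 10`, `ReadPosRankSum < -8.0`,
#' or `MQRankSum` outside (-2.5, 2.5).  A missing metric skips that rule
#' (annotation absence must not fail a site).
#'
#' @param QD,FS,DP,ReadPosRankSum,MQRankSum numeric vectors of site metrics
#'   (recycled to a common length; `NA` = metric absent).
#' @return data.frame with logical `pass` and a `failed` string listing the
#'   violated rules (empty when passing).
#' @examples
#' germline_hard_filter(QD = c(1.9, 30), FS = 1, DP = 50,
#'                      ReadPosRankSum = 0, MQRankSum = c(0, 2.6))
#' @export
germline_hard_filter <- function(QD = NA, FS = NA, DP = NA,
                                 ReadPosRankSum = NA, MQRankSum = NA) {
  n <- max(lengths(list(QD, FS, DP, ReadPosRankSum, MQRankSum)))
  QD <- rep_len(QD, n); FS <- rep_len(FS, n); DP <- rep_len(DP, n)
  ReadPosRankSum <- rep_len(ReadPosRankSum, n); MQRankSum <- rep_len(MQRankSum, n)
  rules <- cbind(
    QD = !is.na(QD) & QD < 2.0,
    FS = !is.na(FS) & FS > 60,
    DP = !is.na(DP) & DP < 10,
    ReadPosRankSum = !is.na(ReadPosRankSum) & ReadPosRankSum < -8.0,
    MQRankSum = !is.na(MQRankSum) & (MQRankSum < -2.5 | MQRankSum > 2.5)
  )
  failed <- apply(rules, 1, function(r) paste(colnames(rules)[r], collapse = ","))
  data.frame(pass = rowSums(rules) == 0, failed = failed,
             stringsAsFactors = FALSE)
}
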