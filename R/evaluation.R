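#' Assemble a truth set
#'
#' A truth set holds the positive reference variants (with provenance
#' `"crossval"` for validated parental-line mutations or `"culture"` for
#' culture-derived ones), the negative-control regions (confident non-variant
#' positions), and — implicitly — everything else as *masked*.  Assembly
#' enforces disjointness: a positive variant whose position falls inside a
#' negative region is a construction error and is reported, not silently
#' dropped.
#'
#' @param crossval_validated variant-key data.frame of validated parental-line
#'   variants (may carry `expected_vaf`).
#' @param culture_set variant-key data.frame of culture-derived mutations
#'   (may be empty or `NULL`).
#' @param negative_regions `GRanges` of negative-control regions (1-based).
#' @return an object of class `truth_set` with elements `positives`
#'   (variant keys + `provenance`) and `negatives` (`GRanges`).
#' @export
assemble_truth <- function(crossval_validated, culture_set = NULL,
                           negative_regions = GenomicRanges::GRanges()) {
  pos <- crossval_validated
  validate_variant_key(pos)
  if (!"provenance" %in% names(pos))
    pos$provenance <- rep("crossval", nrow(pos))
  if (!is.null(culture_set) && nrow(culture_set)) {
    validate_variant_key(culture_set)
    cs <- culture_set
    if (!"provenance" %in% names(cs)) cs$provenance <- "culture"
    common <- intersect(names(pos), names(cs))
    pos <- rbind(pos[, common, drop = FALSE], cs[, common, drop = FALSE])
  }
  if (anyDuplicated(variant_id(pos)))
    stop("duplicate positive variants across sources")
  if (nrow(pos) && length(negative_regions)) {
    loci <- GenomicRanges::GRanges(pos$chrom, IRanges::IRanges(pos$pos, pos$pos))
    clash <- IRanges::overlapsAny(loci, negative_regions)
    if (any(clash))
      stop("positive variant(s) inside negative-control regions: ",
           paste(utils::head(variant_id(pos)[clash], 10), collapse = ", "))
  }
  rownames(pos) <- NULL
  structure(list(positives = pos, negatives = negative_regions),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set> ", nrow(x$positives), " positives (",
      sum(x$positives$provenance == "culture"), " culture-derived), ",
      length(x$negatives), " negative region(s) covering ",
      sum(GenomicRanges::width(x$negatives)), " bp\n", sep = "")
  invisible(x)
}

#' Three-way classification of reported calls
#'
#' A reported call matching a truth positive by full normalized allele
#' identity is a true positive (`TP`); a call whose *position* lies inside the
#' negative-control regions is a false positive (`FP`); everything else is
#' `masked` — excluded from all tallies, because a site assignable to neither
#' set is ambiguous and must not penalize a caller.
#'
#' @param calls variant-key data.frame of reported calls (normalized).
#' @param truth a [assemble_truth()] truth set.
#' @return character vector in \{"TP", "FP", "masked"\}, one per call.
#' @export
classify_call <- function(calls, truth) {
  stopifnot(inherits(truth, "truth_set"))
  validate_variant_key(calls)
  if (nrow(calls) == 0) return(character(0))
  is_tp <- variant_id(calls) %in% variant_id(truth$positives)
  loci <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$pos, calls$pos))
  in_neg <- IRanges::overlapsAny(loci, truth$negatives)
  ifelse(is_tp, "TP", ifelse(in_neg, "FP", "masked"))
}

#' Choose the VAF used for binning
#'
#' Truth-set variants are binned by their allele fraction measured directly in
#' a permissive-tier (q = 1, Q = 1) pileup of the evaluated mixture dataset —
#' not by the caller's estimate; calls outside the truth set fall back to the
#' caller-reported VAF.  A truth variant with undefined or zero pileup VAF
#' (unsampled in this dataset) is assigned VAF 0 so it lands in the first bin
#' (documented convention; see `compute_metrics(denominator = )` for the
#' alternative of dropping unsampled truth).
#'
#' @param keys variant-key data.frame.
#' @param in_truth logical: is each variant a truth positive?
#' @param mixture_pileup pileup table of the evaluated dataset (tier q=1, Q=1);
#'   may be `NULL` when all variants are non-truth.
#' @param caller_vaf numeric caller-reported fractions (NA when unavailable).
#' @param sample sample label within `mixture_pileup`.
#' @return numeric VAFs for binning (NA only for non-truth calls lacking a
#'   caller VAF, which are excluded from binned metrics).
#' @export
eval_vaf <- function(keys, in_truth, mixture_pileup = NULL,
                     caller_vaf = rep(NA_real_, nrow(keys)),
                     sample = "mixture") {
  v <- rep(NA_real_, nrow(keys))
  if (any(in_truth)) {
    if (is.null(mixture_pileup))
      stop("mixture_pileup required to bin truth variants")
    pv <- pileup_vaf(mixture_pileup, keys$chrom[in_truth], keys$pos[in_truth],
                     keys$alt[in_truth], sample)
    pv[is.na(pv)] <- 0
    v[in_truth] <- pv
  }
  v[!in_truth] <- caller_vaf[!in_truth]
  v
}

#' Sensitivity, precision and F1 per VAF bin and genomic stratum
#'
#' Classifies a call set against the truth ([classify_call()]), bins every
#' call and every truth variant by VAF ([eval_vaf()]), stratifies positions by
#' genomic context when masks are given ([stratify_position()]), and tallies
#' TP / FP / FN with sensitivity = TP/(TP+FN), precision = TP/(TP+FP)
#' (undefined, `NaN`, when no calls survive masking) and F1 their harmonic
#' mean (0 when either is 0).  The sensitivity denominator is *all* truth
#' positives, including those never sampled in this dataset
#' (`denominator = "all"`); `denominator = "sampled"` restricts to truth
#' variants with at least one alternate read in the evaluated pileup.
#'
#' @param calls call data.frame: variant keys plus optional `caller_vaf`.
#' @param truth a truth set.
#' @param mixture_pileup permissive-tier pileup of the evaluated dataset used
#'   to bin truth variants; `NULL` bins truth by their `expected_vaf` column.
#' @param binning a [vaf_binning()].
#' @param strata optional list of two `GRanges` masks,
#'   `list(primary = , secondary = )`, for easy/difficult/extreme
#'   stratification; `NULL` evaluates a single `"all"` stratum.
#' @param sample sample label in `mixture_pileup`.
#' @param denominator `"all"` or `"sampled"` (see above).
#' @return data.frame: one row per (stratum, bin) plus an `overall` row per
#'   stratum, with columns TP, FP, FN, masked, sensitivity, precision, f1.
#' @export
compute_metrics <- function(calls, truth, mixture_pileup = NULL,
                            binning = vaf_binning(), strata = NULL,
                            sample = "mixture",
                            denominator = c("all", "sampled")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(truth, "truth_set"))
  cls <- classify_call(calls, truth)
  caller_vaf <- if ("caller_vaf" %in% names(calls)) calls$caller_vaf else
    rep(NA_real_, nrow(calls))

  truth_pos <- truth$positives
  truth_vaf <- if (!is.null(mixture_pileup)) {
    eval_vaf(truth_pos, rep(TRUE, nrow(truth_pos)), mixture_pileup,
             sample = sample)
  } else if ("expected_vaf" %in% names(truth_pos)) {
    truth_pos$expected_vaf
  } else stop("need mixture_pileup or an expected_vaf column to bin truth")
  if (denominator == "sampled") {
    keep <- truth_vaf > 0
    truth_pos <- truth_pos[keep, , drop = FALSE]
    truth_vaf <- truth_vaf[keep]
  }
  call_vaf <- rep(NA_real_, nrow(calls))
  is_tp <- cls == "TP"
  # TPs inherit the truth variant's binning VAF so both sides of the
  # confusion matrix live in the same bin
  call_vaf[is_tp] <- truth_vaf[match(variant_id(calls)[is_tp],
                                     variant_id(truth_pos))]
  call_vaf[!is_tp] <- caller_vaf[!is_tp]

  truth_bin <- assign_bin(pmin(truth_vaf, 1), binning)
  call_bin <- assign_bin(pmin(ifelse(is.na(call_vaf), 0, pmin(call_vaf, 1)), 1),
                         binning)

  truth_str <- stratum_of(truth_pos$chrom, truth_pos$pos, strata)
  call_str <- stratum_of(calls$chrom, calls$pos, strata)

  strata_levels <- if (is.null(strata)) "all" else c("easy", "difficult", "extreme")
  bins <- bin_labels(binning)
  out <- list()
  for (s in strata_levels) {
    for (b in c(bins, "overall")) {
      in_b_truth <- truth_str == s & (b == "overall" | truth_bin == b)
      in_b_call <- call_str == s & (b == "overall" | call_bin == b)
      tp_ids <- variant_id(calls)[is_tp & in_b_call]
      tp <- length(tp_ids)
      fp <- sum(cls == "FP" & in_b_call)
      msk <- sum(cls == "masked" & in_b_call &
                   !(is.na(caller_vaf) & b != "overall"))
      fn <- sum(!(variant_id(truth_pos)[in_b_truth] %in% tp_ids))
      sens <- if (tp + fn > 0) tp / (tp + fn) else NaN
      prec <- if (tp + fp > 0) tp / (tp + fp) else NaN
      f1 <- if (is.nan(sens) || is.nan(prec)) NaN
            else if (sens + prec == 0) 0 else 2 * sens * prec / (sens + prec)
      out[[length(out) + 1L]] <- data.frame(
        stratum = s, bin = b, TP = tp, FP = fp, FN = fn, masked = msk,
        sensitivity = sens, precision = prec, f1 = f1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

stratum_of <- function(chrom, pos, strata) {
  if (is.null(strata)) return(rep("all", length(chrom)))
  stratify_position(chrom, pos, strata$primary, strata$secondary)
}

#' Stratify positions by genomic context
#'
#' Partitions positions into `easy` (inside the primary mask, e.g. the 1000
#' Genomes strict mask of confidently short-read-callable regions),
#' `difficult` (inside the secondary, pan-genome-accessibility-style mask but
#' outside the primary) and `extreme` (outside both — repetitive or
#' structurally complex sequence).  A position inside the primary but outside
#' the secondary mask is classified `easy` with a consistency warning, since a
#' properly nested mask pair should not produce it.
#'
#' @param chrom,pos position vectors (1-based).
#' @param mask_primary,mask_secondary `GRanges` masks (1-based coordinates;
#'   read BED files with [read_bed()], which shifts 0-based starts).
#' @return character vector in \{"easy", "difficult", "extreme"\}.
#' @export
stratify_position <- function(chrom, pos, mask_primary, mask_secondary) {
  loci <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  in1 <- IRanges::overlapsAny(loci, mask_primary)
  in2 <- IRanges::overlapsAny(loci, mask_secondary)
  if (any(in1 & !in2))
    warning(sum(in1 & !in2),
            " position(s) inside the primary but outside the secondary mask;",
            " classified easy")
  ifelse(in1, "easy", ifelse(in2, "difficult", "extreme"))
}

#' Concordance between caller VAFs and designed mixture VAFs
#'
#' For variants with a designed expected VAF, checks whether the
#' caller-reported fraction falls inside an acceptance interval around the
#' expected value.  The default tolerance rule takes, per design VAF level,
#' half the distance to the adjacent levels (so intervals tile the design
#' space without overlapping); supply `tolerance_rule` to override — a
#' function mapping an expected VAF to `c(lo, hi)`.
#'
#' @param expected numeric expected mixture VAFs.
#' @param observed numeric caller VAFs (NA = variant not called).
#' @param levels the design's VAF levels (defaults to the distinct expected
#'   values).
#' @param tolerance_rule optional function(expected_vaf) -> c(lo, hi).
#' @return list with `concordant` (logical per pair; NA where observed is NA),
#'   `fraction` (overall concordance among called variants), `by_level`
#'   (data.frame per expected level) and `correlation` (Pearson r among
#'   called variants).
#' @export
vaf_concordance <- function(expected, observed, levels = sort(unique(expected)),
                            tolerance_rule = NULL) {
  if (length(expected) == 0 || length(expected) != length(observed))
    stop("expected and observed must be non-empty and the same length")
  if (is.null(tolerance_rule)) {
    lv <- sort(unique(levels))
    tolerance_rule <- function(e) {
      i <- which.min(abs(lv - e))
      lo <- if (i == 1) e - (lv[min(i + 1, length(lv))] - e) / 2 else (lv[i - 1] + e) / 2
      hi <- if (i == length(lv)) e + (e - lv[max(i - 1, 1)]) / 2 else (e + lv[i + 1]) / 2
      c(max(0, lo), min(1, hi))
    }
  }
  iv <- t(vapply(expected, tolerance_rule, numeric(2)))
  concordant <- ifelse(is.na(observed), NA,
                       observed >= iv[, 1] & observed < iv[, 2])
  called <- !is.na(observed)
  by_level <- do.call(rbind, lapply(sort(unique(expected)), function(e) {
    sel <- expected == e & called
    data.frame(expected_vaf = e, n_called = sum(sel),
               concordance = if (any(sel)) mean(concordant[sel]) else NaN)
  }))
  list(concordant = concordant,
       fraction = if (any(called)) mean(concordant[called]) else NaN,
       by_level = by_level,
       correlation = if (sum(called) >= 2 && stats::sd(observed[called]) > 0 &&
                         stats::sd(expected[called]) > 0)
         stats::cor(expected[called], observed[called]) else NA_real_)
}
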