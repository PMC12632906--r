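toy_truth <- function(n_pos = 10, neg_start = 5e5, neg_end = 9e5, seed = 61) {
  pos <- random_keys(n_pos, len = 4e5, seed = seed)
  pos$expected_vaf <- 0.01
  neg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(neg_start, neg_end))
  assemble_truth(pos, negative_regions = neg)
}

test_that("truth assembly unifies sources and enforces disjointness", {
  cv <- random_keys(10, len = 4e5, seed = 62)
  cu <- random_keys(2, len = 4e5, seed = 63)
  cu$pos <- cu$pos + 3L
  neg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5e5, 9e5))
  truth <- assemble_truth(cv, cu, neg)
  expect_equal(nrow(truth$positives), 12L)
  expect_equal(sum(truth$positives$provenance == "culture"), 2L)

  clash <- cv
  clash$pos[1] <- 6e5
  expect_error(assemble_truth(clash, negative_regions = neg),
               "inside negative-control regions")
  expect_error(assemble_truth(rbind(cv, cv[1, ])), "duplicate")
})

test_that("calls are classified TP / FP / masked and the split is conserved", {
  truth <- toy_truth()
  tp_call <- truth$positives[1:3, c("chrom", "pos", "ref", "alt")]
  fp_call <- data.frame(chrom = "chr1", pos = c(6e5, 7e5), ref = "A", alt = "G")
  masked_call <- data.frame(chrom = "chr1", pos = c(950001, 960001),
                            ref = "T", alt = "C")
  calls <- rbind(tp_call, fp_call, masked_call)
  cls <- classify_call(calls, truth)
  expect_equal(cls, c("TP", "TP", "TP", "FP", "FP", "masked", "masked"))
  expect_equal(sum(cls == "TP") + sum(cls == "FP") + sum(cls == "masked"),
               nrow(calls))

  # property: conservation holds for random call sets
  set.seed(64)
  for (i in 1:5) {
    rnd <- random_keys(50, len = 1e6, seed = 64 + i)
    cls <- classify_call(rnd, truth)
    expect_equal(length(cls), 50L)
    expect_true(all(cls %in% c("TP", "FP", "masked")))
  }
})

test_that("truth variants bin by pileup VAF, others by caller VAF", {
  truth <- toy_truth(n_pos = 3)
  keys <- rbind(truth$positives[, c("chrom", "pos", "ref", "alt")],
                data.frame(chrom = "chr1", pos = 6e5, ref = "A", alt = "G"))
  pil <- counts_pileup(truth$positives, alt_counts = c(3, 0, 6), depth = 300,
                       q = 1, Q = 1)
  v <- eval_vaf(keys, c(TRUE, TRUE, TRUE, FALSE), pil,
                caller_vaf = c(NA, NA, NA, 0.004))
  expect_equal(v, c(0.01, 0, 0.02, 0.004))
  b <- assign_bin(v)
  expect_equal(as.character(b), c("1-1.5%", "0-0.5%", "2-3%", "0-0.5%"))
})

test_that("metrics match a confusion-matrix oracle with full negative coverage", {
  # negatives tile everything except the positive loci: nothing is masked
  pos <- random_keys(20, len = 1e5, seed = 65)
  pos$expected_vaf <- rep(c(0.004, 0.012, 0.025, 0.08), 5)
  loci <- GenomicRanges::GRanges(pos$chrom, IRanges::IRanges(pos$pos, pos$pos))
  neg <- GenomicRanges::setdiff(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e5)), loci)
  truth <- assemble_truth(pos, negative_regions = neg)

  calls <- rbind(
    cbind(pos[1:12, c("chrom", "pos", "ref", "alt")],
          caller_vaf = pos$expected_vaf[1:12]),
    data.frame(chrom = "chr1", pos = 9e4 + 1:7, ref = "A", alt = "G",
               caller_vaf = 0.01))
  m <- compute_metrics(calls, truth, mixture_pileup = NULL)
  ov <- m[m$bin == "overall", ]
  expect_equal(ov$TP, 12); expect_equal(ov$FP, 7); expect_equal(ov$FN, 8)
  expect_equal(ov$masked, 0)
  expect_equal(ov$sensitivity, 12 / 20)
  expect_equal(ov$precision, 12 / 19)
  expect_equal(ov$f1, 2 * (12/20) * (12/19) / (12/20 + 12/19))
  # per-bin tallies are conserved
  bins <- m[m$bin != "overall", ]
  expect_equal(sum(bins$TP), 12); expect_equal(sum(bins$FP), 7)
  expect_equal(sum(bins$FN), 8)
})

test_that("a perfect caller scores 1 everywhere; an all-negative caller 0", {
  truth <- toy_truth(n_pos = 30, seed = 66)
  perfect <- cbind(truth$positives[, c("chrom", "pos", "ref", "alt")],
                   caller_vaf = truth$positives$expected_vaf)
  m <- compute_metrics(perfect, truth, mixture_pileup = NULL)
  filled <- m[!is.nan(m$sensitivity) & (m$TP + m$FN) > 0, ]
  expect_true(all(filled$sensitivity == 1))
  expect_true(all(filled$precision[!is.nan(filled$precision)] == 1))

  only_neg <- data.frame(chrom = "chr1", pos = 5e5 + 1:10, ref = "A",
                         alt = "G", caller_vaf = 0.01)
  m0 <- compute_metrics(only_neg, truth, mixture_pileup = NULL)
  ov <- m0[m0$bin == "overall", ]
  expect_equal(ov$precision, 0)
  expect_equal(ov$f1, 0)
})

test_that("positions stratify as easy / difficult / extreme by mask membership", {
  primary <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  secondary <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000))
  got <- stratify_position("chr1", c(500, 1500, 2500), primary, secondary)
  expect_equal(got, c("easy", "difficult", "extreme"))
  # non-nested masks warn but classify easy
  bad_secondary <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1200, 2000))
  expect_warning(got2 <- stratify_position("chr1", 500, primary, bad_secondary),
                 "primary")
  expect_equal(got2, "easy")
})

test_that("synthetic caller metrics recover the planted sensitivity within CI", {
  design <- colo829blt50_design()
  truth_tbl <- gen_genotypes(4000, design, contig_length = 5e7, seed = 67)
  loci <- GenomicRanges::GRanges(truth_tbl$chrom,
                                 IRanges::IRanges(truth_tbl$pos, truth_tbl$pos))
  neg <- GenomicRanges::setdiff(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5e7)), loci)
  truth <- assemble_truth(truth_tbl, negative_regions = neg)

  sens <- c("0-0.5%" = 0.2, "0.5-1%" = 0.5, "1-1.5%" = 0.7, "1.5-2%" = 0.8,
            "2-3%" = 0.9, ">=3%" = 0.95)
  calls <- simulate_callset(truth_tbl, sens_curve = sens, fp_rate_per_mb = 2,
                            negative_regions = neg, vaf_noise_sd = 0, seed = 68)
  m <- compute_metrics(calls, truth, mixture_pileup = NULL)
  # the two-component design populates bins 1-1.5% (het, 1%) and 2-3% (hom, 2%)
  for (b in c("1-1.5%", "2-3%")) {
    row <- m[m$bin == b, ]
    n_b <- row$TP + row$FN
    se <- sqrt(sens[[b]] * (1 - sens[[b]]) / n_b)
    expect_lt(abs(row$sensitivity - sens[[b]]), 1.96 * se * 1.5 + 0.01,
              label = paste("bin", b))
  }
  ov <- m[m$bin == "overall", ]
  expect_equal(ov$TP + ov$FP + ov$masked, nrow(calls))
})

test_that("VAF concordance uses the half-distance tolerance rule", {
  lv <- c(0.0025, 0.005, 0.01, 0.02)
  out <- vaf_concordance(expected = c(0.01, 0.01, 0.02, 0.0025),
                         observed = c(0.01, 0.05, 0.019, NA), levels = lv)
  expect_equal(out$concordant[1:3], c(TRUE, FALSE, TRUE))
  expect_true(is.na(out$concordant[4]))
  expect_equal(out$fraction, 2 / 3)
  expect_equal(out$by_level$n_called, c(0L, 2L, 1L))

  # binomial sampling noise: concordance decreases as depth drops
  set.seed(69)
  exp_v <- rep(0.01, 4000)
  conc_at_depth <- function(D)
    vaf_concordance(exp_v, rbinom(length(exp_v), D, exp_v) / D,
                    levels = lv)$fraction
  cc <- vapply(c(2000, 300, 60), conc_at_depth, numeric(1))
  expect_true(all(diff(cc) < 0))
})
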