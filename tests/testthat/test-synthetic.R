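test_that("generators are deterministic given a seed and leave the RNG alone", {
  design <- hapmap_mixture_design()
  g1 <- gen_genotypes(500, design, seed = 81)
  g2 <- gen_genotypes(500, design, seed = 81)
  expect_identical(g1, g2)
  expect_false(identical(g1, gen_genotypes(500, design, seed = 82)))

  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_genotypes(10, design, seed = 81))
  expect_identical(runif(1), before)  # caller RNG stream undisturbed

  p1 <- simulate_pileup(g1, depth = 100, seed = 83)
  p2 <- simulate_pileup(g1, depth = 100, seed = 83)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("genotype generator respects pattern weights and achievability", {
  design <- hapmap_mixture_design()
  only2 <- c("het:HG002" = 1)
  g <- gen_genotypes(300, design, pattern_weights = only2, seed = 84)
  expect_true(all(g$expected_vaf == 0.01))
  expect_false(anyDuplicated(variant_id(g)) > 0)

  w <- c("het:HG002" = 0.7, "hom:HG02622" = 0.3)
  g2 <- gen_genotypes(3000, design, pattern_weights = w, seed = 85)
  p_hat <- mean(g2$pattern == "het:HG002")
  expect_lt(abs(p_hat - 0.7), 3 * sqrt(0.7 * 0.3 / 3000))

  expect_error(gen_genotypes(10, design, pattern_weights = c(nope = 1)),
               "unknown pattern")
  bad <- list("bg" = c(HG005 = 0.5, HG002 = 0, HG00438 = 0, HG02257 = 0,
                       HG02486 = 0, HG02622 = 0))
  expect_error(gen_genotypes(10, design, pattern_weights = c(bg = 1),
                             patterns = bad), "background")
})

test_that("simulated pileups have binomial moments and clean negatives", {
  truth <- random_keys(10000, seed = 86)
  truth$expected_vaf <- 0.01
  p <- simulate_pileup(truth, depth = 500, sample = "s", seed = 87)
  k <- pileup_count(p, truth$chrom, truth$pos, truth$alt, "s")
  expect_lt(abs(mean(k) - 5), 3 * sqrt(500 * 0.01 * 0.99 / 10000))

  # error-free non-variant sites have zero alternate reads
  ns <- data.frame(chrom = "chr1", pos = 1:200 * 10L, ref = "G")
  p0 <- simulate_pileup(nonvariant_sites = ns, depth = 300, error_rate = 0,
                        sample = "s", seed = 88)
  expect_true(all(as.data.frame(p0)$allele == "G"))

  # f = 1 gives alt count = depth
  t1 <- truth[1:50, ]; t1$expected_vaf <- 1
  p1 <- simulate_pileup(t1, depth = 120, sample = "s", seed = 89)
  expect_true(all(pileup_count(p1, t1$chrom, t1$pos, t1$alt, "s") == 120))

  # error reads appear at roughly the configured rate
  pe <- simulate_pileup(nonvariant_sites = ns[rep(1:200, 10), ], depth = 500,
                        error_rate = 0.003, sample = "s", seed = 90)
  err <- as.data.frame(pe)
  err <- err[err$allele != err$ref, ]
  rate <- sum(err$count) / (2000 * 500)
  expect_lt(abs(rate - 0.003), 4 * sqrt(0.003 / (2000 * 500)))
})

test_that("simulated call sets honor the planted sensitivity extremes", {
  design <- colo829blt50_design()
  truth <- gen_genotypes(400, design, seed = 91)
  all_calls <- simulate_callset(truth, sens_curve = 1, seed = 92)
  expect_setequal(variant_id(all_calls), variant_id(truth))
  none <- simulate_callset(truth, sens_curve = 0, seed = 93)
  expect_equal(nrow(none), 0L)

  noisy <- simulate_callset(truth, sens_curve = 1, vaf_noise_sd = 0.2, seed = 94)
  expect_true(all(noisy$caller_vaf > 0 & noisy$caller_vaf <= 1))
  expect_gt(sd(noisy$caller_vaf / truth$expected_vaf[
    match(variant_id(noisy), variant_id(truth))]), 0)
})

test_that("mask generator produces nested masks at the target fractions", {
  for (seed in c(95, 96, 97)) {
    m <- gen_masks(1e6, easy_frac = 0.74, difficult_frac = 0.10, seed = seed)
    # nesting: primary fully contained in secondary
    outside <- GenomicRanges::setdiff(m$primary, m$secondary)
    expect_equal(length(outside), 0L)
    f_easy <- sum(GenomicRanges::width(m$primary)) / 1e6
    f_sec <- sum(GenomicRanges::width(m$secondary)) / 1e6
    expect_lt(abs(f_easy - 0.74), 0.01)
    expect_lt(abs(f_sec - 0.84), 0.01)
  }
  m1 <- gen_masks(1e6, easy_frac = 1, difficult_frac = 0, seed = 98)
  expect_equal(sum(GenomicRanges::width(m1$primary)), 1e6)
  expect_error(gen_masks(1e6, 0.8, 0.3), "sum to <= 1")

  # uniform positions stratify at the designed 74 / 10 / 16 proportions
  m <- gen_masks(2e6, seed = 99)
  pos <- seq(1, 2e6, by = 97)
  s <- stratify_position("chr1", pos, m$primary, m$secondary)
  frac <- table(factor(s, c("easy", "difficult", "extreme"))) / length(pos)
  expect_lt(abs(frac[["easy"]] - 0.74), 0.015)
  expect_lt(abs(frac[["difficult"]] - 0.10), 0.015)
  expect_lt(abs(frac[["extreme"]] - 0.16), 0.015)
})

test_that("end-to-end: synthetic truth, caller and evaluation close the loop", {
  design <- colo829blt50_design()
  truth_tbl <- gen_genotypes(2000, design, contig_length = 3e7, seed = 100)
  loci <- GenomicRanges::GRanges(truth_tbl$chrom,
                                 IRanges::IRanges(truth_tbl$pos, truth_tbl$pos))
  neg <- GenomicRanges::setdiff(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3e7)), loci)
  truth <- assemble_truth(truth_tbl, negative_regions = neg)
  masks <- gen_masks(3e7, seed = 101)

  calls <- simulate_callset(truth_tbl, sens_curve = 0.8, fp_rate_per_mb = 1,
                            negative_regions = neg, seed = 102)
  m <- compute_metrics(calls, truth, mixture_pileup = NULL, strata = masks)
  expect_true(all(c("easy", "difficult", "extreme") %in% m$stratum))
  tot <- m[m$bin == "overall", ]
  expect_equal(sum(tot$TP) + sum(tot$FP) + sum(tot$masked), nrow(calls))
  sens_all <- sum(tot$TP) / (sum(tot$TP) + sum(tot$FN))
  expect_lt(abs(sens_all - 0.8), 3 * sqrt(0.8 * 0.2 / 2000))
})
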