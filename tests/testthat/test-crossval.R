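make_callset <- function(keys, filter = "PASS") {
  cbind(keys, filter = filter, stringsAsFactors = FALSE)
}

test_that("candidate merge is the keyed union with provenance and caller counts", {
  a <- make_callset(random_keys(3, seed = 1))
  b <- make_callset(random_keys(3, seed = 2))
  m <- merge_candidates(list(c1 = a, c2 = b))
  expect_equal(nrow(m), length(union(variant_id(a), variant_id(b))))
  expect_equal(sum(m$caller_count), nrow(a) + nrow(b))

  same <- make_callset(random_keys(5, seed = 3))
  m4 <- merge_candidates(list(A = same, B = same, C = same, D = same))
  expect_equal(nrow(m4), 5L)
  expect_true(all(m4$caller_count == 4))

  # brute-force union oracle on a random 4-caller fixture
  sets <- lapply(1:4, function(i) make_callset(random_keys(20, seed = i)))
  names(sets) <- paste0("m", 1:4)
  merged <- merge_candidates(sets)
  oracle <- sort(unique(unlist(lapply(sets, variant_id))))
  expect_equal(sort(variant_id(merged)), oracle)
  for (id in names(sets))
    expect_equal(sort(variant_id(merged[merged[[paste0("in_", id)]], ])),
                 sort(unique(variant_id(sets[[id]]))))
})

test_that("merge drops non-PASS and long indels, rejects duplicate keys", {
  keys <- random_keys(4, seed = 9)
  cs <- make_callset(keys, filter = c("PASS", "LowQual", "PASS", "."))
  m <- merge_candidates(list(x = cs))
  expect_equal(nrow(m), 3L)

  long_indel <- data.frame(chrom = "chr1", pos = 10L,
                           ref = paste(rep("A", 61), collapse = ""),
                           alt = "A", filter = "PASS")
  expect_equal(nrow(merge_candidates(list(x = long_indel))), 0L)

  dup <- make_callset(rbind(keys, keys[1, ]))
  expect_error(merge_candidates(list(x = dup)), "duplicate")
})

test_that("major alternate allele is the tumor-count argmax, ties lexicographic", {
  expect_equal(resolve_multiallelic(c(A = 5, T = 2)), "A")
  expect_equal(resolve_multiallelic(c(T = 3, A = 3)), "A")
  expect_true(is.na(resolve_multiallelic(c(A = 0, T = 0))))
  set.seed(5)
  for (i in 1:30) {
    counts <- setNames(rpois(3, 4), sample(c("A", "C", "G", "T"), 3))
    if (all(counts == 0)) next
    got <- resolve_multiallelic(counts)
    expect_equal(counts[[got]], max(counts))  # argmax oracle
  }
})

test_that("SNV validation applies the >=2-tumor-read / 0-normal-read rule", {
  key <- variant_key("chr1", 100, "C", "A")
  normal0 <- one_site_pileup(c(C = 150), sample = "normal")
  tum <- function(a) one_site_pileup(c(C = 200 - a, A = a))

  expect_equal(validate_snv(key, tum(2), normal0)$status, "validated")
  expect_equal(validate_snv(key, tum(1), normal0)$status, "no_tumor_support")
  normal1 <- one_site_pileup(c(C = 149, A = 1), sample = "normal")
  expect_equal(validate_snv(key, tum(10), normal1)$status, "normal_support")

  multi <- one_site_pileup(c(C = 190, A = 3, T = 7))
  expect_equal(validate_snv(key, multi, normal0)$status, "superseded_multiallelic")
  keyT <- variant_key("chr1", 100, "C", "T")
  expect_equal(validate_snv(keyT, multi, normal0)$status, "validated")

  # missing pileup evidence masks rather than rejects
  empty <- pileup_table(as.data.frame(tum(2))[0, ], q = 1, Q = 20)
  expect_equal(validate_snv(key, empty, normal0)$status, "evidence_missing")
})

test_that("SNV validation is monotone in tumor and normal support", {
  key <- variant_key("chr1", 100, "C", "A")
  normal0 <- one_site_pileup(c(C = 150), sample = "normal")
  verdicts <- vapply(0:10, function(a)
    validate_snv(key, one_site_pileup(c(C = 200 - a, A = a)), normal0)$status,
    character(1))
  ok <- verdicts == "validated"
  expect_false(any(diff(ok) < 0))  # adding tumor reads never invalidates

  for (n_alt in 1:5) {
    normal <- one_site_pileup(c(C = 150 - n_alt, A = n_alt), sample = "normal")
    expect_false(validate_snv(key, one_site_pileup(c(C = 195, A = 5)),
                              normal)$status == "validated")
  }
})

test_that("exact het binomial p-value matches binom.test over all N <= 200", {
  for (N in c(1:12, 50, 137, 200)) {
    for (k in unique(c(0, 1, N %/% 3, N %/% 2, N))) {
      expect_equal(binomial_het_pvalue(N, k),
                   stats::binom.test(k, N, 0.5)$p.value, tolerance = 1e-12,
                   label = sprintf("N=%d k=%d", N, k))
    }
  }
  expect_equal(binomial_het_pvalue(1, 0), 1)
  expect_equal(binomial_het_pvalue(10, 5), 1)
  expect_lt(binomial_het_pvalue(100, 10), 0.05)
  expect_error(binomial_het_pvalue(0, 0), "depth")
  expect_error(binomial_het_pvalue(10, 11), "alt_count")
})

test_that("indel read classification matches a string-comparison oracle", {
  key <- variant_key("chr1", 50, "ATT", "A")
  reads <- data.frame(
    mapq = c(60, 60, 60, 60, 60, 60, 60, 60, 0, 60, 60),
    seq = c(rep("ATT", 8), "ATT", "A", "A"))
  cl <- classify_indel_reads(reads, key)
  expect_equal(cl$depth, 10)        # mapq-0 read excluded
  expect_equal(cl$ref_support, 8)
  expect_equal(cl$target_alt_support, 2)
  expect_equal(cl$af, 0.2)

  other <- data.frame(mapq = 60, seq = "AGGG")
  cl2 <- classify_indel_reads(other, key)
  expect_equal(cl2$target_alt_support, 0)
  expect_equal(cl2$other_alt, list(AGGG = 1L))

  empty <- classify_indel_reads(reads[0, ], key)
  expect_equal(empty$depth, 0)
  expect_true(is.na(empty$af))

  set.seed(8)
  for (i in 1:20) {
    seqs <- sample(c("ATT", "A", "AG", "ATTT"), 30, TRUE)
    mapq <- sample(c(0, 60), 30, TRUE, prob = c(.2, .8))
    cl <- classify_indel_reads(data.frame(mapq = mapq, seq = seqs), key)
    keep <- seqs[mapq >= 1]
    expect_equal(cl$ref_support, sum(keep == "ATT"))
    expect_equal(cl$target_alt_support, sum(keep == "A"))
    expect_equal(cl$depth, length(keep))
    expect_equal(sum(unlist(cl$other_alt)),
                 sum(!keep %in% c("ATT", "A")))
  }
})

test_that("indel validation applies thresholds in the documented order", {
  key <- variant_key("chr1", 50, "GTT", "G")
  mk <- function(depth, dtv) list(depth = depth, ref_support = depth - dtv,
                                  target_alt_support = dtv, other_alt = list(),
                                  af = if (depth > 0) dtv / depth else NA_real_)
  ok_pb <- mk(100, 45)   # het-compatible (p > 0.05), AF 0.45
  ok_il <- mk(100, 40)
  clean_normal <- mk(100, 0)
  expect_equal(validate_indel(key, ok_pb, ok_il, clean_normal)$status, "validated")

  long_key <- variant_key("chr1", 50, paste(c("G", rep("T", 60)), collapse = ""), "G")
  expect_equal(validate_indel(long_key, ok_pb, ok_il, clean_normal)$status,
               "length_fail")
  expect_equal(validate_indel(key, mk(100, 1), ok_il, clean_normal)$status,
               "no_tumor_support")
  # 25/100 has p ~ 5e-7: clear allelic imbalance despite AF > 0.2
  expect_equal(validate_indel(key, mk(100, 25), ok_il, clean_normal)$status,
               "allelic_imbalance_fail")
  # binomially balanced but weak Illumina tumor support
  expect_equal(validate_indel(key, ok_pb, mk(100, 15), clean_normal)$status,
               "tumor_vaf_fail")
  expect_equal(validate_indel(key, ok_pb, ok_il, mk(100, 10))$status,
               "normal_vaf_fail")
  # boundary values fail the strict inequalities
  expect_equal(validate_indel(key, ok_pb, mk(100, 20), clean_normal)$status,
               "tumor_vaf_fail")
  expect_equal(validate_indel(key, ok_pb, ok_il, mk(100, 5))$status,
               "normal_vaf_fail")
  expect_equal(validate_indel(key, ok_pb, mk(0, 0), clean_normal)$status,
               "evidence_missing")
})

test_that("validation sensitivity matches the closed-form binomial bound", {
  # planted tumor-only SNVs with Binomial(D, f) long-read support and clean
  # normals: P(validated) = P(X >= 2), X ~ Binom(D, f)
  set.seed(21)
  D <- 300; f <- 0.02; n <- 800
  truth <- random_keys(n, seed = 22)
  truth$expected_vaf <- f
  tum <- simulate_pileup(truth, depth = D, sample = "tumor", seed = 23)
  norm <- simulate_pileup(nonvariant_sites = truth[, c("chrom", "pos", "ref")],
                          depth = 180, sample = "normal", seed = 24)
  verdicts <- vapply(seq_len(n), function(i)
    validate_snv(truth[i, ], tum, norm)$status, character(1))
  sens <- mean(verdicts == "validated")
  expected <- pbinom(1, D, f, lower.tail = FALSE)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(sens - expected), 3.5 * se + 1e-9)
})
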