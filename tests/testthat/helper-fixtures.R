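# Shared in-code fixtures: tiny pileups and reference contexts built on the
# fly so no binary data ships with the package.

# A single-sample pileup with the given allele counts at one site.
one_site_pileup <- function(counts, chrom = "chr1", pos = 100L, ref = "C",
                            sample = "tumor", q = 1, Q = 20,
                            depth = sum(counts)) {
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, sample = sample,
                   depth = depth, allele = names(counts),
                   count = as.integer(counts), stringsAsFactors = FALSE)
  pileup_table(df, q = q, Q = Q)
}

# Pileup over many truth sites where alt counts are given exactly.
counts_pileup <- function(truth, alt_counts, depth, sample = "mixture",
                          q = 1, Q = 20) {
  df <- rbind(
    data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
               sample = sample, depth = depth, allele = truth$ref,
               count = depth - alt_counts, stringsAsFactors = FALSE),
    data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
               sample = sample, depth = depth, allele = truth$alt,
               count = alt_counts, stringsAsFactors = FALSE))
  df <- df[df$count > 0 | df$allele == df$ref, ]
  pileup_table(df, q = q, Q = Q)
}

# Deterministic toy contig sequence (repeat-rich so left-alignment matters).
toy_contig <- function(len = 400L, seed = 11L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(.35, .15, .15, .35)), collapse = "")
}

random_keys <- function(n, contig = "chr1", len = 1e6, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, TRUE)
  data.frame(chrom = contig, pos = sort(sample.int(len, n)), ref = ref,
             alt = vapply(ref, function(r) sample(setdiff(bases, r), 1), ""),
             stringsAsFactors = FALSE)
}
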