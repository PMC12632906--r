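#' Probability that a variant allele is sampled at depth
#'
#' For a variant at allele fraction `f` sequenced to depth `D`, the number of
#' alternate-allele reads is modelled as Binomial(D, f).  The variant is
#' "sampled" when at least `m` alternate reads are present (m = 1 by default:
#' the allele is represented in the data at all), so the sampling probability
#' is the upper binomial tail P(X >= m); for m = 1 this is
#' \eqn{1 - (1 - f)^D}.  `effective_depth_scale` deflates the nominal depth to
#' mimic reads lost to base/mapping-quality filtering (default 1: face-value
#' depth).
#'
#' @param f allele fraction(s) in [0, 1].
#' @param D sequencing depth(s), positive integers.
#' @param m minimum alternate reads to count as sampled (default 1).
#' @param effective_depth_scale multiplier applied to `D` (default 1).
#' @return sampling probability, vectorized over `f`/`D`.
#' @examples
#' analytic_sampling_prob(0.01, 180)  # ~0.836
#' @export
analytic_sampling_prob <- function(f, D, m = 1L, effective_depth_scale = 1) {
  if (any(f < 0 | f > 1)) stop("f must be in [0, 1]")
  if (any(D < 1)) stop("depth must be >= 1")
  if (m < 1) stop("m must be >= 1")
  D_eff <- pmax(1L, as.integer(round(D * effective_depth_scale)))
  stats::pbinom(m - 1L, D_eff, f, lower.tail = FALSE)
}

#' Sampling probability across replicate datasets
#'
#' Replicate sequencing datasets of the same mixture sample the allele
#' independently, each with its own depth.  With per-replicate sampling
#' probabilities \eqn{p_i =} [analytic_sampling_prob()]`(f, D_i, m)`, the
#' probability of being sampled in *all* replicates is \eqn{\prod p_i}, in *at
#' least one* is \eqn{1 - \prod (1 - p_i)}, and in at least `j` of them is the
#' Poisson-binomial upper tail.
#'
#' @param f allele fraction.
#' @param depths vector of replicate depths.
#' @param mode `"all"`, `"at_least_once"` or `"at_least_j"`.
#' @param j threshold for `"at_least_j"`.
#' @param m,effective_depth_scale passed to [analytic_sampling_prob()].
#' @return probability.
#' @examples
#' multi_replicate_sampling(0.01, c(473, 432, 250, 167), "all")
#' @export
multi_replicate_sampling <- function(f, depths,
                                     mode = c("all", "at_least_once", "at_least_j"),
                                     j = 1L, m = 1L, effective_depth_scale = 1) {
  mode <- match.arg(mode)
  if (length(depths) == 0) stop("depths must be non-empty")
  p <- analytic_sampling_prob(f, depths, m = m,
                              effective_depth_scale = effective_depth_scale)
  switch(mode,
    all = prod(p),
    at_least_once = 1 - prod(1 - p),
    at_least_j = {
      if (j < 0 || j > length(p)) stop("j must be in [0, number of replicates]")
      sum(poisson_binomial_pmf(p)[(j + 1L):(length(p) + 1L)])
    })
}

#' Poisson-binomial distribution of successes across unequal trials
#'
#' Exact probability mass of the number of successes among independent
#' Bernoulli trials with (possibly different) success probabilities `p`,
#' computed by iterative convolution.  This is the distribution of the number
#' of replicate datasets in which a variant is sampled.
#'
#' @param p vector of per-trial success probabilities.
#' @return numeric vector of length `length(p) + 1`: P(K = 0), ..., P(K = n).
#' @export
poisson_binomial_pmf <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf
}

#' Empirical sampling rates of truth variants across replicate pileups
#'
#' For each truth variant and each replicate dataset, the variant counts as
#' sampled when its alternate allele has at least `m` reads in that
#' replicate's pileup (missing pileup rows count as depth 0, i.e. unsampled).
#' Returns per-VAF-bin sampling rates per dataset and jointly (sampled in all
#' / at least one replicate), the sharing-class counts (sampled in exactly
#' j of n datasets, j = 0..n), and — when genomic-context masks are supplied —
#' the region composition of each sharing class.
#'
#' @param truth variant-key data.frame with an `expected_vaf` column.
#' @param replicate_pileups named list of pileup tables, one per replicate
#'   (all at the same quality tier).
#' @param samples sample label per replicate (recycled; defaults to the
#'   replicate names).
#' @param binning a [vaf_binning()] used to group truth variants by expected
#'   VAF.
#' @param m minimum alternate reads to count as sampled.
#' @param strata optional `list(primary = , secondary = )` masks for region
#'   composition of sharing classes.
#' @return list with `rates` (bin x dataset + `all` and `at_least_once`
#'   columns), `sharing` (counts per j = 0..n per bin) and optionally
#'   `sharing_regions`.
#' @export
empirical_sampling_rates <- function(truth, replicate_pileups,
                                     samples = names(replicate_pileups),
                                     binning = vaf_binning(), m = 1L,
                                     strata = NULL) {
  stopifnot("expected_vaf" %in% names(truth), length(replicate_pileups) >= 1)
  n <- length(replicate_pileups)
  if (is.null(names(replicate_pileups)))
    names(replicate_pileups) <- paste0("rep", seq_len(n))
  samples <- rep_len(samples, n)
  for (i in seq_len(n)[-1])
    check_same_tier(replicate_pileups[[1]], replicate_pileups[[i]])

  sampled <- vapply(seq_len(n), function(i) {
    k <- pileup_count(replicate_pileups[[i]], truth$chrom, truth$pos,
                      truth$alt, samples[i])
    !is.na(k) & k >= m
  }, logical(nrow(truth)))
  sampled <- matrix(sampled, nrow = nrow(truth),
                    dimnames = list(NULL, names(replicate_pileups)))
  j_count <- rowSums(sampled)

  bin <- assign_bin(pmin(truth$expected_vaf, 1), binning)
  bins <- levels(bin)
  rates <- do.call(rbind, lapply(bins, function(b) {
    sel <- bin == b
    if (!any(sel)) return(NULL)
    row <- as.data.frame(t(colMeans(sampled[sel, , drop = FALSE])))
    cbind(data.frame(bin = b, n = sum(sel)), row,
          data.frame(all = mean(j_count[sel] == n),
                     at_least_once = mean(j_count[sel] >= 1)))
  }))
  sharing <- table(bin = bin, j = factor(j_count, levels = 0:n))
  out <- list(rates = rates, sharing = sharing, sampled = sampled)
  if (!is.null(strata)) {
    region <- stratify_position(truth$chrom, truth$pos,
                                strata$primary, strata$secondary)
    out$sharing_regions <- table(j = factor(j_count, levels = 0:n),
                                 region = factor(region,
                                                 c("easy", "difficult", "extreme")))
  }
  out
}
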