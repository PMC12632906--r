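#' Seeded evaluation of simulation code
#'
#' All generators take a `seed` argument and evaluate under it while restoring
#' the caller's RNG state afterwards, so regeneration with the same seed is
#' identical and simulations never perturb user code.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Dosage patterns of a mixture design
#'
#' Enumerates the single-line ("private") dosage patterns of a design:
#' heterozygous and homozygous in each non-background component, labelled
#' `"het:<line>"` / `"hom:<line>"`.  These are the pattern labels accepted by
#' [gen_genotypes()]; arbitrary multi-line patterns can be supplied there
#' directly.
#'
#' @param design a [mixture_design()].
#' @return named list of dosage vectors.
#' @export
dosage_patterns <- function(design) {
  lines <- names(design$components)
  spike <- setdiff(lines, design$background)
  pats <- list()
  for (ln in spike) {
    for (d in c(het = 0.5, hom = 1)) {
      v <- stats::setNames(rep(0, length(lines)), lines)
      v[ln] <- d
      pats[[paste0(names(which(c(het = 0.5, hom = 1) == d)), ":", ln)]] <- v
    }
  }
  pats
}

#' Generate a synthetic genotype matrix and mixture truth table
#'
#' Draws `n_variants` SNVs at distinct uniform positions on a toy contig,
#' assigns each a dosage pattern sampled with the given weights, and annotates
#' expected mixture VAFs via [expected_vaf()].  Patterns must be achievable
#' under the design: every referenced line must be a component and background
#' dosage must be 0 (background carriers are germline, not somatic truth).
#'
#' @param n_variants number of variants.
#' @param design a [mixture_design()].
#' @param pattern_weights named numeric weights; names are pattern labels from
#'   [dosage_patterns()] or names of entries in `patterns`.  Default: private
#'   heterozygous variants in each spike-in line, weight proportional to 2,
#'   and private homozygous, weight 1 — mixtures of germline diploid lines
#'   carry roughly twice as many hets as homs.
#' @param patterns optional named list of custom dosage vectors extending
#'   [dosage_patterns()].
#' @param contig,contig_length toy contig name and length.
#' @param seed RNG seed.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, one dosage column per
#'   design component, `pattern` and `expected_vaf`.
#' @export
gen_genotypes <- function(n_variants, design, pattern_weights = NULL,
                          patterns = NULL, contig = "chr1",
                          contig_length = 1e7, seed = NULL) {
  base_pats <- c(dosage_patterns(design), patterns)
  if (is.null(pattern_weights)) {
    pattern_weights <- stats::setNames(
      ifelse(startsWith(names(dosage_patterns(design)), "het"), 2, 1),
      names(dosage_patterns(design)))
  }
  unknown <- setdiff(names(pattern_weights), names(base_pats))
  if (length(unknown))
    stop("weights on unknown pattern(s): ", paste(unknown, collapse = ", "))
  use <- base_pats[names(pattern_weights)]
  lines <- names(design$components)
  for (lab in names(use)) {
    v <- use[[lab]]
    if (!all(names(v) %in% lines))
      stop("pattern '", lab, "' references lines outside the design")
    if (!is.null(design$background) && isTRUE(v[design$background] > 0))
      stop("pattern '", lab, "' doses the background line; not a somatic pattern")
    check_dosages(v)
    if (sum(v) == 0) stop("pattern '", lab, "' is all-zero")
  }

  with_seed(seed, {
    pos <- sort(sample.int(contig_length, n_variants))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_variants, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    pat <- sample(names(use), n_variants, replace = TRUE,
                  prob = pattern_weights / sum(pattern_weights))
    dos <- do.call(rbind, use[pat])
    out <- data.frame(chrom = contig, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
    for (ln in lines) out[[ln]] <- dos[, ln]
    out$pattern <- pat
    out$expected_vaf <- expected_vaf(design, dos)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a per-site allele-count pileup
#'
#' At each truth site the alternate read count is Binomial(D, f) with f the
#' site's `expected_vaf` (override with `vaf_col`); remaining reads are
#' reference.  At supplied non-variant sites each non-reference base gets an
#' independent Binomial(D, error_rate/3) error count.  Depth is fixed at `D`
#' or drawn Poisson(D) per site.
#'
#' @param truth truth table with `chrom`, `pos`, `ref`, `alt` and the VAF
#'   column; may be `NULL`.
#' @param nonvariant_sites optional data.frame `chrom`, `pos`, `ref` of
#'   negative sites to cover.
#' @param depth nominal depth D.
#' @param error_rate per-base error rate e (split evenly over the 3 non-ref
#'   bases).
#' @param sample sample label recorded in the pileup.
#' @param q,Q,max_depth quality tier recorded on the pileup.
#' @param depth_mode `"fixed"` or `"poisson"`.
#' @param vaf_col name of the truth column holding the sampling fraction.
#' @param seed RNG seed.
#' @return a [pileup_table()].
#' @export
simulate_pileup <- function(truth = NULL, nonvariant_sites = NULL, depth,
                            error_rate = 0, sample = "mixture",
                            q = 1, Q = 20, max_depth = NA,
                            depth_mode = c("fixed", "poisson"),
                            vaf_col = "expected_vaf", seed = NULL) {
  depth_mode <- match.arg(depth_mode)
  with_seed(seed, {
    rows <- list()
    draw_depth <- function(n) {
      if (depth_mode == "fixed") rep(as.integer(depth), n) else
        stats::rpois(n, depth)
    }
    if (!is.null(truth) && nrow(truth)) {
      d <- draw_depth(nrow(truth))
      k <- stats::rbinom(nrow(truth), d, pmin(truth[[vaf_col]], 1))
      rows$truth_ref <- data.frame(chrom = truth$chrom, pos = truth$pos,
                                   ref = truth$ref, sample = sample, depth = d,
                                   allele = truth$ref, count = d - k,
                                   stringsAsFactors = FALSE)
      alt <- data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
                        sample = sample, depth = d, allele = truth$alt,
                        count = k, stringsAsFactors = FALSE)
      rows$truth_alt <- alt[alt$count > 0, , drop = FALSE]
    }
    if (!is.null(nonvariant_sites) && nrow(nonvariant_sites)) {
      ns <- nonvariant_sites
      d <- draw_depth(nrow(ns))
      bases <- c("A", "C", "G", "T")
      err <- matrix(0L, nrow(ns), 4, dimnames = list(NULL, bases))
      if (error_rate > 0) {
        for (b in bases) {
          can <- ns$ref != b
          err[can, b] <- stats::rbinom(sum(can), d[can], error_rate / 3)
        }
      }
      tot_err <- rowSums(err)
      over <- tot_err > d  # pathological only at large e; clip to depth
      if (any(over)) err[over, ] <- 0L
      rows$nv_ref <- data.frame(chrom = ns$chrom, pos = ns$pos, ref = ns$ref,
                                sample = sample, depth = d, allele = ns$ref,
                                count = d - rowSums(err),
                                stringsAsFactors = FALSE)
      for (b in bases) {
        hit <- err[, b] > 0
        if (any(hit))
          rows[[paste0("nv_", b)]] <- data.frame(
            chrom = ns$chrom[hit], pos = ns$pos[hit], ref = ns$ref[hit],
            sample = sample, depth = d[hit], allele = b, count = err[hit, b],
            stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    if (is.null(df))
      df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                       sample = character(), depth = integer(),
                       allele = character(), count = integer())
    df <- df[order(df$chrom, df$pos, df$allele), , drop = FALSE]
    rownames(df) <- NULL
    pileup_table(df, q = q, Q = Q, max_depth = max_depth)
  })
}

#' Simulate a caller's call set with planted performance
#'
#' Emits each truth variant with probability `sens_curve[bin]` (its expected
#' VAF's bin), plants false positives uniformly over the negative-control
#' regions at `fp_rate_per_mb`, and reports a noisy caller VAF
#' `f * (1 + Normal(0, vaf_noise_sd))` truncated to (0, 1].  False positives
#' get caller VAFs drawn uniformly from (0, `fp_vaf_max`] — sub-threshold
#' noise calls.
#'
#' @param truth truth table with `expected_vaf`.
#' @param sens_curve named numeric vector of per-bin sensitivities covering
#'   `bin_labels(binning)` (a scalar is recycled).
#' @param binning a [vaf_binning()].
#' @param fp_rate_per_mb expected false positives per megabase of negative
#'   region.
#' @param negative_regions `GRanges` where false positives may land.
#' @param vaf_noise_sd relative sd of the caller VAF.
#' @param fp_vaf_max upper bound of false-positive caller VAFs.
#' @param seed RNG seed.
#' @return call-set data.frame: keys, `filter = "PASS"`, `caller_vaf`.
#' @export
simulate_callset <- function(truth, sens_curve = 1, binning = vaf_binning(),
                             fp_rate_per_mb = 0,
                             negative_regions = GenomicRanges::GRanges(),
                             vaf_noise_sd = 0, fp_vaf_max = 0.03, seed = NULL) {
  labs <- bin_labels(binning)
  if (length(sens_curve) == 1 && is.null(names(sens_curve)))
    sens_curve <- stats::setNames(rep(sens_curve, length(labs)), labs)
  if (!all(labs %in% names(sens_curve)))
    stop("sens_curve must name every bin label")
  if (any(sens_curve < 0 | sens_curve > 1)) stop("sensitivities must be in [0,1]")

  with_seed(seed, {
    s <- sens_curve[as.character(assign_bin(pmin(truth$expected_vaf, 1), binning))]
    called <- stats::runif(nrow(truth)) < s
    tp <- truth[called, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    f <- truth$expected_vaf[called]
    vaf <- f * (1 + stats::rnorm(sum(called), 0, vaf_noise_sd))
    tp$caller_vaf <- pmin(pmax(vaf, 1e-6), 1)

    fp <- NULL
    neg_bp <- sum(GenomicRanges::width(negative_regions))
    if (fp_rate_per_mb > 0 && neg_bp > 0) {
      n_fp <- stats::rpois(1, fp_rate_per_mb * neg_bp / 1e6)
      if (n_fp > 0) {
        offs <- sort(sample.int(neg_bp, min(n_fp, neg_bp)))
        starts <- GenomicRanges::start(negative_regions)
        widths <- GenomicRanges::width(negative_regions)
        cum <- cumsum(widths)
        # map each flat offset along the concatenated regions to its interval
        idx <- vapply(offs, function(o) which(o <= cum)[1], integer(1))
        posn <- starts[idx] + (offs - c(0, cum)[idx]) - 1
        bases <- c("A", "C", "G", "T")
        rf <- sample(bases, length(posn), replace = TRUE)
        al <- vapply(rf, function(r) sample(setdiff(bases, r), 1), character(1))
        fp <- data.frame(
          chrom = as.character(GenomicRanges::seqnames(negative_regions))[idx],
          pos = posn, ref = rf, alt = al,
          caller_vaf = stats::runif(length(posn), 1e-4, fp_vaf_max),
          stringsAsFactors = FALSE)
      }
    }
    out <- rbind(tp, fp)
    if (is.null(out))
      out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                        alt = character(), caller_vaf = numeric())
    out$filter <- rep("PASS", nrow(out))
    out <- out[!duplicated(variant_id(out)), , drop = FALSE]
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a multi-replicate cohort with culture-acquired mutations
#'
#' Emulates the harvest model behind culture-derived mutation discovery: the
#' parental ("pure") lines define the base truth, while culture mutations are
#' present only in the mixture replicates, with a per-replicate VAF
#' trajectory.  Produces, per replicate, a short-read pileup and a call set
#' (a variant is called when it has at least `min_call_reads` alternate reads
#' in that replicate); plus a long-read admixture pileup over the culture
#' sites, a control pileup (no culture support except at
#' `spurious_control_rate`), and pure-line pileups with zero culture support.
#'
#' @param base_truth truth table of parental-line variants (`expected_vaf`).
#' @param culture variant-key data.frame of culture mutations.
#' @param trajectory numeric matrix (nrow = culture variants, ncol =
#'   n_replicates) of per-replicate culture VAFs, or a single vector recycled
#'   across variants.
#' @param depths per-replicate short-read depths (recycled to
#'   `n_replicates`).
#' @param n_replicates number of mixture replicates.
#' @param lr_depth,control_depth long-read depths of the admixture and
#'   control datasets.
#' @param pure_depth depth of the four pure-line pileups.
#' @param min_call_reads alternate reads required for a replicate call.
#' @param spurious_control_rate probability a culture site draws spurious
#'   control support (planted as `min_call_reads` reads).
#' @param seed RNG seed.
#' @return list: `callsets`, `pileups` (per replicate), `admix_pileup`,
#'   `control_pileup`, `pure_pileups` (roles pb/il x tumor/normal),
#'   `culture` (the planted table with final VAF).
#' @export
simulate_culture_cohort <- function(base_truth, culture, trajectory,
                                    depths, n_replicates = 5,
                                    lr_depth = 387, control_depth = 200,
                                    pure_depth = 300, min_call_reads = 2L,
                                    spurious_control_rate = 0, seed = NULL) {
  validate_variant_key(culture)
  depths <- rep_len(depths, n_replicates)
  if (is.null(dim(trajectory)))
    trajectory <- matrix(rep(trajectory, each = nrow(culture)),
                         nrow = nrow(culture))
  stopifnot(nrow(trajectory) == nrow(culture), ncol(trajectory) == n_replicates)

  with_seed(seed, {
    pileups <- list(); callsets <- list()
    for (r in seq_len(n_replicates)) {
      rep_truth <- rbind(
        base_truth[, c("chrom", "pos", "ref", "alt", "expected_vaf")],
        data.frame(culture[, c("chrom", "pos", "ref", "alt")],
                   expected_vaf = trajectory[, r]))
      p <- simulate_pileup(rep_truth, depth = depths[r], sample = "mixture")
      k <- pileup_count(p, rep_truth$chrom, rep_truth$pos, rep_truth$alt, "mixture")
      called <- !is.na(k) & k >= min_call_reads
      cs <- rep_truth[called, c("chrom", "pos", "ref", "alt"), drop = FALSE]
      cs$caller_vaf <- (k / depths[r])[called]
      cs$filter <- rep("PASS", nrow(cs))
      rownames(cs) <- NULL
      pileups[[paste0("rep", r)]] <- p
      callsets[[paste0("rep", r)]] <- cs
    }

    final_vaf <- trajectory[, n_replicates]
    culture_tr <- data.frame(culture[, c("chrom", "pos", "ref", "alt")],
                             expected_vaf = final_vaf)
    admix <- simulate_pileup(culture_tr, depth = lr_depth, sample = "admixture")

    spurious <- stats::runif(nrow(culture)) < spurious_control_rate
    ctl_sites <- data.frame(chrom = culture$chrom, pos = culture$pos,
                            ref = culture$ref)
    ctl <- simulate_pileup(nonvariant_sites = ctl_sites, depth = control_depth,
                           sample = "control")
    if (any(spurious)) {
      extra <- data.frame(chrom = culture$chrom[spurious],
                          pos = culture$pos[spurious],
                          ref = culture$ref[spurious], sample = "control",
                          depth = pileup_depth(ctl, culture$chrom[spurious],
                                               culture$pos[spurious], "control"),
                          allele = culture$alt[spurious],
                          count = min_call_reads, stringsAsFactors = FALSE)
      tier <- pileup_tier(ctl)
      ctl <- pileup_table(rbind(as.data.frame(ctl), extra),
                          q = tier$q, Q = tier$Q, max_depth = tier$max_depth)
    }

    pure_sites <- data.frame(chrom = culture$chrom, pos = culture$pos,
                             ref = culture$ref)
    pure <- lapply(c(pb_tumor = "pb_tumor", il_tumor = "il_tumor",
                     pb_normal = "pb_normal", il_normal = "il_normal"),
                   function(s) simulate_pileup(nonvariant_sites = pure_sites,
                                               depth = pure_depth, sample = s))
    list(callsets = callsets, pileups = pileups, admix_pileup = admix,
         control_pileup = ctl, pure_pileups = pure, culture = culture_tr)
  })
}

#' Generate nested genomic-context masks on a toy contig
#'
#' Tiles the contig into fixed-size blocks, shuffles them, and assigns the
#' first blocks to the primary ("easy") mask and the next to the
#' secondary-only ("difficult") layer, so primary ⊆ secondary by
#' construction.  Realized coverage fractions land within one block of the
#' targets (<= 1% for the default block size).
#'
#' @param contig_length contig length (bp).
#' @param easy_frac,difficult_frac target genome fractions of the easy and
#'   difficult strata (the remainder is extreme); must sum to <= 1.
#' @param block block size (bp).
#' @param contig contig name.
#' @param seed RNG seed.
#' @return `list(primary = GRanges, secondary = GRanges)` with primary
#'   contained in secondary.
#' @export
gen_masks <- function(contig_length, easy_frac = 0.74, difficult_frac = 0.10,
                      block = 1e4, contig = "chr1", seed = NULL) {
  if (easy_frac < 0 || difficult_frac < 0 || easy_frac + difficult_frac > 1)
    stop("mask fractions must be >= 0 and sum to <= 1")
  n_block <- ceiling(contig_length / block)
  with_seed(seed, {
    ord <- sample.int(n_block)
    n_easy <- round(easy_frac * n_block)
    n_diff <- round(difficult_frac * n_block)
    starts <- (ord - 1) * block + 1
    ends <- pmin(ord * block, contig_length)
    gr <- function(i) GenomicRanges::reduce(GenomicRanges::GRanges(
      contig, IRanges::IRanges(starts[i], ends[i])))
    primary <- if (n_easy > 0) gr(seq_len(n_easy)) else GenomicRanges::GRanges()
    secondary_idx <- seq_len(n_easy + n_diff)
    secondary <- if (length(secondary_idx)) gr(secondary_idx) else
      GenomicRanges::GRanges()
    list(primary = primary, secondary = secondary)
  })
}
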