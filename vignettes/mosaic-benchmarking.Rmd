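---
title: "Benchmarking ultra-low-VAF mosaic variant detection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking ultra-low-VAF mosaic variant detection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicbench)
```

## The problem

Mosaic (post-zygotic) mutations are present in only a subset of cells, so in
bulk sequencing they appear at variant allele fractions (VAFs) far below the
50% of a germline heterozygote — often under 2%. At these levels a call set
cannot be scored against an ordinary germline truth set: a handful of
supporting reads is compatible with both a real subclonal mutation and a
sequencing artifact, and many genuinely present variants are never sampled at
all. `mosaicbench` implements the benchmarking machinery this regime needs:

* truth sets built from **designed cell-line mixtures**, where every true
  variant has a known expected VAF;
* **orthogonal long-read validation** of short-read candidates, with explicit
  read-support, allele-competition and allelic-imbalance rules;
* an explicit **negative-control** set of confidently non-variant positions,
  so that false positives can be distinguished from ambiguous sites;
* discovery of **culture-derived mutations** — real mutations acquired during
  cell passaging that are absent from the parental-line truth data and would
  otherwise be mis-scored as false positives;
* **three-way evaluation** (true positive / false positive / masked) by VAF
  bin and genomic context; and
* a **binomial allele-sampling model** quantifying how often a low-VAF allele
  is observed at all at a given depth.

All stages run on synthetic data generated in-package, so every rule is
exercisable and testable without external downloads.

## Mixture designs and expected VAFs

A mixture design is a set of cell lines with proportions $p_i$ summing to 1.
Under a copy-number-neutral diploid model, a variant carried with dosage
$d_i \in \{0, 0.5, 1\}$ (absent / heterozygous / homozygous) in line $i$ has
expected mixture VAF

$$\mathrm{E}[\mathrm{VAF}] = \sum_i p_i\, d_i .$$

Two designs ship as constructors. `colo829blt50_design()` is a two-component
tumor/normal mixture (2% tumor, 98% matched normal): tumor-specific
heterozygous and homozygous variants land at 1% and 2% expected VAF.
`hapmap_mixture_design()` mixes six lines (0.5%, three at 2%, 10%, and an
83.5% background); enumerating all spike-in dosage combinations with the
background held at zero gives achievable expected VAFs from 0.25% (het in the
0.5% line) to 16.5% (hom in all five spike-ins):

```{r}
range(enumerate_expected_vafs(hapmap_mixture_design()))
```

`build_mixture_reference()` applies the truth-set filters for such designs:
SNVs only, sites inside the intersection of all per-line confident regions,
no `N` reference bases, and exclusion of any variant with non-zero dosage in
the background line (germline in the mixture, by construction). Where a
variant is carried by several spike-in lines the dosage contributions sum —
shared variants reach intermediate VAF levels. Dosage is deliberately
diploid and copy-number neutral; CNV-aware expectations are out of scope.

## Truth-set construction rules

Candidates from multiple callers are merged by exact normalized variant
identity (`merge_candidates()`): PASS records only, indels under 50 bp,
multi-allelic records split and indels left-aligned/trimmed
(`normalize_variants()`, matching `bcftools norm -a -m -` semantics).
Matching is exact — no distance-based indel rescue — because downstream set
operations must be unambiguous.

**SNVs** (`validate_snv()`) are validated when the alternate allele has at
least 2 long-read tumor reads, zero long-read normal reads, and is the major
alternate at its locus (`resolve_multiallelic()`; exact count ties break
lexicographically — the choice is arbitrary and documented rather than
silent). One supporting read is deliberately insufficient: at several-hundred-
fold long-read depth, single-read support is dominated by sequencing error.

**Indels** (`validate_indel()`) face stutter-type long-read artifacts near
homopolymers, so the rule set is stricter, applied in a fixed order so that
each rejected candidate reports one primary reason:

1. length ≥ 51 bp → `length_fail`;
2. fewer than 2 long-read tumor target reads → `no_tumor_support`;
3. exact binomial test of target reads vs depth against 0.5 with p ≤ 0.05 →
   `allelic_imbalance_fail` (a clonal event in a pure line should look
   heterozygous; strong imbalance in either direction indicates an artifact,
   hence the two-sided "minlike" convention in `binomial_het_pvalue()`);
4. long-read or short-read tumor VAF ≤ 0.2 → `tumor_vaf_fail`;
5. short-read normal VAF ≥ 0.05 → `normal_vaf_fail`.

All inequalities are strict exactly as stated (p > 0.05, VAF > 0.2,
VAF < 0.05); boundary values fail. Missing pileup evidence yields
`evidence_missing` and the site is masked downstream, never rejected: absence
of long-read coverage must not manufacture false negatives.

## Negative controls

`classify_nonvariant_sites()` implements an iterative two-tier screen over
candidate homozygous-reference positions (shared by both parental lines,
supplied by upstream germline genotyping):

1. no alternate read in either line at a permissive long-read tier
   (mapping quality ≥ 1, base quality ≥ 1) → `negative`;
2. otherwise, any alternate read at a stringent tier (both ≥ 30) →
   `removed_highq_alt`;
3. otherwise the permissive-tier allele is checked in short reads: the
   *same* allele seen in ≥ 1 Illumina read → `excluded_both_platforms`;
   no short-read corroboration → `negative_retained`.

The same-allele requirement in step 3 is a design decision (the procedure
text is ambiguous): cross-platform corroboration of a *specific* allele is
the signal of a real variant, whereas allele-agnostic co-occurrence of noise
is exactly what the negative set should tolerate. `negative_retained` sites
are flagged distinctly so stricter users can drop them. Germline call
curation uses the standard GATK-style hard filters
(`germline_hard_filter()`: QD < 2, FS > 60, DP < 10, ReadPosRankSum < −8,
|MQRankSum| > 2.5); a missing annotation skips its rule.

## Culture-derived mutations

Cell lines mutate during passaging, so mixture replicates contain real
mutations absent from the parental-line truth data. The discovery chain is:

1. `replicate_sharing()` — remove reference-set variants from each
   replicate's merged call set and count, per remaining variant, the number
   of replicates carrying it (upset-style classes; variants in all
   replicates are the strongest candidates);
2. `longread_support_screen()` — require ≥ 2 supporting long reads in the
   admixture dataset and exclude sites with ≥ 2 supporting reads in an
   unrelated control dataset sequenced with the same protocol (locus-specific
   systematic errors "confirm" in both). The control threshold defaults to
   the support threshold — the symmetric reading — but is separately
   configurable;
3. `categorize_provenance()` — sites with ≥ 1 supporting read in the pure
   normal line (either platform, tier q ≥ 1 / Q ≥ 20) are normal-line
   mutations; sites with zero support in both pure lines *and* inside the
   negative-control regions are admixture-only; the rest are rejected.

The final culture set (`culture_mutation_set()`) is the intersection of
screen-supported and admixture-only sites, and is added to the truth set with
provenance `"culture"`. The long-read screen tier defaults to the main
pileup settings (q = 1, Q = 20) since no separate tier is specified for it.

## Evaluation

`classify_call()` scores each reported call as **TP** (exact allele match to
a truth positive), **FP** (position inside the negative regions — negatives
are non-variant *sites*, so any allele there is wrong), or **masked**
(neither; excluded from all tallies). Masking is the point of the whole
construction: penalizing a caller for sites nobody can adjudicate measures
the truth set, not the caller.

Metrics are computed per VAF bin — default edges 0, 0.5, 1, 1.5, 2, 3% with
an explicit overflow bin for ≥ 3% (the bin list in the source procedure names
six bins but prints five ranges; we read the sixth as the overflow and make
edges configurable) — and per genomic stratum: `easy` inside a strict
primary mask, `difficult` inside the secondary (pan-genome accessibility)
mask only, `extreme` outside both (`stratify_position()`).

Truth variants are binned by their VAF *measured in the evaluated dataset's
permissive pileup* (q = Q = 1), not by the caller's estimate; calls outside
the truth set fall back to caller-reported VAF (`eval_vaf()`). Two
conventions here are deliberate and configurable:

* A depth-0 VAF is **undefined (`NA`)**, never silently 0, so unsampled truth
  variants are distinguishable from sampled-at-zero artifacts.
* The sensitivity denominator includes *all* truth positives — a variant the
  sequencer never sampled still counts against sensitivity, with its VAF
  taken as 0 (first bin). `compute_metrics(denominator = "sampled")` gives
  the sampled-only alternative; both are reported because the choice changes
  the lowest bin substantially.

`vaf_concordance()` compares caller VAFs with designed expected VAFs. No
tolerance rule is canonical, so the default acceptance interval per design
level is half the distance to the adjacent levels (intervals tile the design
range without overlap), and the rule is a plain function argument reported
alongside results.

## The allele-sampling model

A variant at fraction $f$ sequenced to depth $D$ yields
$X \sim \mathrm{Binomial}(D, f)$ alternate reads; it is *sampled* when
$X \ge m$ (default $m = 1$). `analytic_sampling_prob()` is the tail
$P(X \ge m)$, which for $m = 1$ is $1 - (1-f)^D$ — at $f = 1\%$ and 180×,
about 0.836; at 500×, about 0.993; at $f = 0.25\%$ even 500× reaches only
about 0.71. Across replicates with unequal depths the number of datasets
sampling the variant is Poisson-binomial (`poisson_binomial_pmf()`, exact by
convolution; `multi_replicate_sampling()` gives the all / at-least-once /
at-least-j probabilities). `empirical_sampling_rates()` measures the same
quantities on actual pileups and reports sharing classes and their region
composition.

Replicates are treated as independent given $f$, with one fixed depth per
dataset (a Poisson per-site option exists, since real coverage varies).
Real pileups at stringent quality tiers (q = Q = 30) lose reads to
filtering, so the face-depth model is an **upper bound** on empirically
observed sampling rates; `effective_depth_scale` (default 1.0, i.e. no
correction) lets users deflate depths if they have calibration data. We do
not fit this factor ourselves — no published correction is available — which
is why all-replicate sampling rates computed at face depth exceed rates
observed in quality-filtered data.

## The synthetic-data generator

`gen_genotypes()`, `simulate_pileup()`, `simulate_callset()`,
`simulate_culture_cohort()` and `gen_masks()` generate every input the
pipeline consumes on a toy contig (default one 10-Mb chromosome — desk
scale, with real chromosome names allowed for format realism). The
generator's statistical structure is exactly the modelled one: binomial
allele sampling at expected VAF, independent per-site base errors at rate
$e/3$ per non-reference base, per-bin planted caller sensitivity, uniform
false positives over negative regions, nondecreasing culture-clone VAF
trajectories across harvests, and nested random block masks hitting target
easy/difficult fractions (defaults 74%/10%, matching the published
genome-wide partition) within 1%.

What it deliberately does **not** emulate: alignment and mapping artifacts,
context-dependent error hotspots (an optional hotspot list can inject some),
strand bias, read-level features, or inter-site error correlation. Passing
tests therefore demonstrate that the *bookkeeping and statistics* of the
framework are correct under the stated model — not that any caller's
real-data performance is reproduced. Determinism is contractual: every
generator takes a seed, produces byte-identical output under it, and
restores the caller's RNG state.

Test problem sizes are chosen to make binomial confidence intervals tight
enough to detect real defects while keeping the suite fast: cohorts of
2,000–20,000 variants for parameter-recovery checks and 100,000 variants for
the simulation-versus-analytic sampling comparison, with agreement asserted
at 3 standard errors.

## Numerical and degenerate-input choices

* Bins are left-closed/right-open; a VAF exactly at an edge belongs to the
  upper bin. VAF 0 is in the first bin; values outside [0, 1] are errors.
* `binomial_het_pvalue()` sums outcome probabilities ≤ the observed one with
  a $1 + 10^{-7}$ relative guard against floating-point ties (the
  `binom.test` convention); it agrees with full enumeration to $10^{-12}$
  for all depths ≤ 200 (tested).
* Expected-VAF enumeration snaps sums to 12 decimals before deduplication,
  since equal dosage multisets can differ by float epsilon.
* Empty pileups, depth-0 sites and empty read sets yield `NA`/undefined
  values with explicit downstream handling, never silent zeros.
* `merge_candidates()` rejects a call set with duplicate normalized keys
  outright rather than deduplicating: duplicates signal an upstream
  normalization failure.

## Limitations

The framework evaluates against designed mixtures of (near-)diploid lines;
copy-number structure, haplotype phasing and multi-nucleotide block variants
are out of scope. Exact-identity matching will count a caller's differently-
normalized-but-equivalent indel as a miss unless inputs are run through
`normalize_variants()` with reference context. The sampling model absorbs
mapping-quality-driven coverage loss into an uncalibrated effective-depth
factor rather than modelling it.
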