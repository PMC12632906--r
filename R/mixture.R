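#' Cell-line mixture designs
#'
#' A mixture design is a set of cell-line components with mixing proportions
#' summing to 1, optionally designating one component as the germline
#' *background* (the line whose variants are considered germline in the
#' mixture and excluded from the somatic truth set).  Two designs from the
#' benchmarking literature ship as constructors:
#'
#' * [colo829blt50_design()] — 2% COLO829 tumor / 98% COLO829BL normal; tumor
#'   heterozygous and homozygous variants yield expected VAFs of 1% and 2%.
#' * [hapmap_mixture_design()] — six HapMap lines: HG00438 at 0.5%, HG002,
#'   HG02257 and HG02486 at 2% each, HG02622 at 10%, and HG005 as 83.5%
#'   background; spike-in genotype combinations span expected VAFs 0.25%–16.5%.
#'
#' @param components named numeric vector of proportions (names are line ids).
#' @param background optional line id treated as germline background.
#' @return an object of class `mixture_design`.
#' @examples
#' d <- mixture_design(c(tumor = 0.02, normal = 0.98), background = "normal")
#' expected_vaf(d, c(tumor = 0.5, normal = 0))
#' @export
mixture_design <- function(components, background = NULL) {
  if (is.null(names(components)) || any(names(components) == ""))
    stop("components must be a named vector of proportions")
  if (anyDuplicated(names(components)))
    stop("duplicate component ids")
  if (any(components <= 0))
    stop("proportions must be positive")
  if (abs(sum(components) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", format(sum(components)), ")")
  if (!is.null(background) && !background %in% names(components))
    stop("background line ", background, " is not a component")
  structure(list(components = components, background = background),
            class = "mixture_design")
}

#' @rdname mixture_design
#' @export
colo829blt50_design <- function() {
  mixture_design(c(COLO829 = 0.02, COLO829BL = 0.98), background = "COLO829BL")
}

#' @rdname mixture_design
#' @export
hapmap_mixture_design <- function() {
  mixture_design(
    c(HG00438 = 0.005, HG002 = 0.02, HG02257 = 0.02, HG02486 = 0.02,
      HG02622 = 0.10, HG005 = 0.835),
    background = "HG005"
  )
}

#' Expected VAF of a variant in a designed mixture
#'
#' Under a copy-number-neutral diploid model the expected allele fraction of a
#' variant in the mixture is the proportion-weighted sum of per-line allele
#' dosages: \eqn{\sum_i p_i d_i}, with dosage 0 (absent), 0.5 (heterozygous) or
#' 1 (homozygous).
#'
#' @param design a [mixture_design()].
#' @param dosages named numeric vector (or a matrix with one column per line)
#'   of dosages in \{0, 0.5, 1\}; must cover every design component.
#' @return expected allele fraction(s) in [0, 1].
#' @export
expected_vaf <- function(design, dosages) {
  stopifnot(inherits(design, "mixture_design"))
  p <- design$components
  if (is.matrix(dosages) || is.data.frame(dosages)) {
    dosages <- as.matrix(dosages)
    missing <- setdiff(names(p), colnames(dosages))
    if (length(missing))
      stop("dosage matrix lacks design component(s): ", paste(missing, collapse = ", "))
    check_dosages(dosages)
    return(as.numeric(dosages[, names(p), drop = FALSE] %*% p))
  }
  missing <- setdiff(names(p), names(dosages))
  if (length(missing))
    stop("dosage vector lacks design component(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(dosages), names(p))
  if (length(unknown))
    stop("unknown line id(s): ", paste(unknown, collapse = ", "))
  check_dosages(dosages)
  sum(p * dosages[names(p)])
}

check_dosages <- function(d) {
  if (!all(d %in% c(0, 0.5, 1)))
    stop("dosages must be 0, 0.5 or 1")
  invisible(d)
}

#' Enumerate the achievable expected VAFs of a design
#'
#' Enumerates all dosage vectors over \{0, 0.5, 1\} for the non-background
#' components (background dosage held at 0 when `exclude_background = TRUE`,
#' its default) with at least one non-zero entry, and returns the sorted set of
#' distinct expected VAFs.
#'
#' @param design a [mixture_design()].
#' @param exclude_background hold the background line at dosage 0.
#' @return sorted numeric vector of achievable expected VAFs; attributes
#'   `min`/`max` carry the extremes.
#' @examples
#' range(enumerate_expected_vafs(hapmap_mixture_design()))  # 0.0025 .. 0.165
#' @export
enumerate_expected_vafs <- function(design, exclude_background = TRUE) {
  stopifnot(inherits(design, "mixture_design"))
  lines <- names(design$components)
  free <- if (exclude_background && !is.null(design$background))
    setdiff(lines, design$background) else lines
  grids <- rep(list(c(0, 0.5, 1)), length(free))
  names(grids) <- free
  grid <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  fixed <- setdiff(lines, free)
  if (length(fixed)) {
    zeros <- matrix(0, nrow(grid), length(fixed), dimnames = list(NULL, fixed))
    grid <- cbind(grid, zeros)
  }
  # sums of the same dosage multiset can differ by float eps; snap before unique
  vafs <- sort(unique(round(expected_vaf(design, grid), 12)))
  structure(vafs, min = min(vafs), max = max(vafs))
}

#' Build a mixture truth set from component genotypes
#'
#' Applies the reference-set construction filters for a designed mixture:
#' keep SNVs only; keep sites inside the intersection of all per-line
#' confident regions (when supplied); drop reference alleles containing `N`;
#' drop any variant carried by the background line (germline in the mixture);
#' annotate the rest with their expected mixture VAF.  Dosages of a variant
#' carried by several spike-in lines are summed through [expected_vaf()].
#'
#' @param genotypes a data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   one numeric dosage column per design component (values 0/0.5/1).
#' @param design a [mixture_design()].
#' @param confident_regions optional `GRangesList`/list of per-line `GRanges`
#'   (1-based) of confident regions; only sites in their common intersection
#'   are kept.
#' @return the retained variant rows with an `expected_vaf` column and a
#'   `germline` attribute listing the excluded background variants.
#' @export
build_mixture_reference <- function(genotypes, design, confident_regions = NULL) {
  stopifnot(inherits(design, "mixture_design"))
  lines <- names(design$components)
  missing <- setdiff(lines, names(genotypes))
  if (length(missing))
    stop("genotype table lacks dosage column(s): ", paste(missing, collapse = ", "))
  g <- genotypes

  keep <- is_snv(g) & !grepl("N", g$ref, fixed = TRUE)
  g <- g[keep, , drop = FALSE]

  if (!is.null(confident_regions) && length(confident_regions)) {
    inter <- Reduce(GenomicRanges::intersect, as.list(confident_regions))
    if (length(inter) == 0) {
      warning("intersection of confident regions is empty; no variants retained")
      g <- g[0, , drop = FALSE]
    } else {
      loci <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$pos, g$pos))
      g <- g[IRanges::overlapsAny(loci, inter), , drop = FALSE]
    }
  }

  bg <- design$background
  germline <- if (!is.null(bg)) g[g[[bg]] > 0, , drop = FALSE] else g[0, ]
  if (!is.null(bg)) g <- g[g[[bg]] == 0, , drop = FALSE]
  g <- g[rowSums(as.matrix(g[, lines, drop = FALSE])) > 0, , drop = FALSE]

  g$expected_vaf <- if (nrow(g)) expected_vaf(design, g[, lines, drop = FALSE]) else numeric(0)
  attr(g, "germline") <- germline
  rownames(g) <- NULL
  g
}
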