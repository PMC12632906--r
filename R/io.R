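#' Read a caller call set from VCF
#'
#' Reads CHROM/POS/REF/ALT/FILTER (and the `AF` INFO key when present, as
#' `caller_vaf`) from a VCF 4.x file via \pkg{vcfR}.  Multi-allelic records
#' are split into one row per alternate allele; run the result through
#' [normalize_variants()] with reference context before matching if the
#' source may be unnormalized.
#'
#' @param path VCF file path (plain text or gzipped).
#' @return call-set data.frame: `chrom`, `pos`, `ref`, `alt`, `filter`,
#'   `caller_vaf`.
#' @export
read_callset_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  af <- suppressWarnings(vcfR::extract.info(v, "AF", as.numeric = TRUE))
  if (is.null(af)) af <- rep(NA_real_, nrow(fix))
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n <- lengths(alts)
  out <- data.frame(
    chrom = rep(fix$CHROM, n), pos = rep(as.integer(fix$POS), n),
    ref = rep(fix$REF, n), alt = unlist(alts),
    filter = rep(ifelse(is.na(fix$FILTER), ".", fix$FILTER), n),
    caller_vaf = rep(as.numeric(af), n), stringsAsFactors = FALSE)
  validate_variant_key(out)
  out
}

#' Write a variant table as a minimal VCF
#'
#' Emits a VCF 4.2 text file carrying CHROM/POS/REF/ALT plus INFO keys for any
#' of the columns `expected_vaf` (as `AF`), `caller_vaf` (as `AF` when
#' `expected_vaf` is absent), `provenance`, `depth` (`DP`), `ref_support`
#' (`DR`), `target_alt_support` (`DTV`) and `other_alt` (`OtherAlt`) present
#' in the table.
#'
#' @param variants variant-key data.frame.
#' @param path output path.
#' @param source string recorded in the `##source` header.
#' @export
write_variants_vcf <- function(variants, path, source = "mosaicbench") {
  validate_variant_key(variants)
  info_map <- c(expected_vaf = "AF", caller_vaf = "AF", depth = "DP",
                ref_support = "DR", target_alt_support = "DTV",
                other_alt = "OtherAlt", provenance = "PROV")
  cols <- intersect(names(info_map), names(variants))
  if (all(c("expected_vaf", "caller_vaf") %in% cols))
    cols <- setdiff(cols, "caller_vaf")
  info <- if (length(cols)) {
    apply(as.data.frame(variants[, cols, drop = FALSE]), 1, function(r)
      paste(paste0(info_map[cols], "=", unname(r)), collapse = ";"))
  } else rep(".", nrow(variants))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=", source),
           '##INFO=<ID=AF,Number=1,Type=Float,Description="Allele fraction">',
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##INFO=<ID=DR,Number=1,Type=Integer,Description="Reference-supporting reads">',
           '##INFO=<ID=DTV,Number=1,Type=Integer,Description="Target-allele-supporting reads">',
           '##INFO=<ID=OtherAlt,Number=1,Type=String,Description="Non-target alternate allele counts">',
           '##INFO=<ID=PROV,Number=1,Type=String,Description="Truth-set provenance">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", if ("filter" %in% names(variants)) variants$filter else "PASS",
                gsub(" ", "", info), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write BED interval files
#'
#' Thin wrappers over \pkg{rtracklayer}: BED's 0-based half-open intervals are
#' converted to the 1-based closed `GRanges` used throughout the package on
#' the way in, and back on the way out.
#'
#' @param path BED file path.
#' @return `read_bed()`: a `GRanges`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::granges(gr)
}

#' @rdname read_bed
#' @param gr a `GRanges`.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: input paths, parameters, seed and
#' package version, as JSON next to the outputs.  Re-running with identical
#' inputs yields an identical manifest.
#'
#' @param path output JSON path.
#' @param inputs,parameters named lists.
#' @param seed the run seed (or `NULL`).
#' @export
write_run_manifest <- function(path, inputs = list(), parameters = list(),
                               seed = NULL) {
  manifest <- list(
    tool = "mosaicbench",
    version = as.character(utils::packageVersion("mosaicbench")),
    seed = seed, inputs = inputs, parameters = parameters)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
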