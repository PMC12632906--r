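#' Pileup tables
#'
#' A pileup table records per-sample allele read counts at genomic sites under
#' a stated quality tier.  It is a long-format `data.frame` with columns
#' `chrom`, `pos` (1-based), `ref`, `sample`, `depth` (total qualifying reads at
#' the site) and one row per observed allele: `allele`, `count`.  Sites with no
#' non-reference reads still carry one row for the reference allele so that
#' depth is recorded.  The quality tier (minimum mapping quality `q`, minimum
#' base quality `Q`, optional `max_depth` cap) is attached as the `"tier"`
#' attribute; operations that combine pileups check that tiers match.
#'
#' @param df a data.frame with the columns above.
#' @param q,Q minimum mapping and base quality of the tier.
#' @param max_depth optional depth cap.
#' @return a `pileup_tbl` (data.frame subclass).
#' @export
pileup_table <- function(df, q, Q, max_depth = NA_integer_) {
  need <- c("chrom", "pos", "ref", "sample", "depth", "allele", "count")
  stopifnot(all(need %in% names(df)))
  if (any(df$count < 0) || any(df$depth < 0))
    stop("negative read counts")
  site_alt <- tapply(
    df$count * (df$allele != df$ref), paste(df$chrom, df$pos, df$sample),
    sum
  )
  site_depth <- tapply(df$depth, paste(df$chrom, df$pos, df$sample),
                       function(d) d[[1]])
  if (any(site_alt > site_depth))
    stop("allele counts exceed depth at some sites")
  structure(df,
            tier = list(q = q, Q = Q, max_depth = max_depth),
            class = c("pileup_tbl", "data.frame"))
}

#' @rdname pileup_table
#' @param x a pileup table.
#' @export
pileup_tier <- function(x) attr(x, "tier")

check_same_tier <- function(a, b) {
  ta <- pileup_tier(a); tb <- pileup_tier(b)
  if (!is.null(ta) && !is.null(tb) && !identical(ta[c("q", "Q")], tb[c("q", "Q")]))
    stop("pileups have different quality tiers (q/Q); refusing to compare")
  invisible(TRUE)
}

#' Query a pileup table
#'
#' `pileup_count()` returns the read count of a given allele at given sites (0
#' when the site is covered but the allele unobserved, `NA` when the site is
#' absent from the table); `pileup_depth()` the total depth (`NA` when absent);
#' `pileup_vaf()` the allele fraction count/depth, which is **undefined
#' (`NA`)** — never 0 — when depth is 0 or the site is missing.
#'
#' @param pileup a pileup table.
#' @param chrom,pos,allele,sample vectors (recycled) identifying the queries.
#' @return numeric vector, one element per query.
#' @examples
#' p <- pileup_table(data.frame(chrom = "chr1", pos = 100, ref = "A",
#'                              sample = "s1", depth = 100,
#'                              allele = c("A", "G"), count = c(99, 1)),
#'                   q = 1, Q = 20)
#' pileup_vaf(p, "chr1", 100, "G", "s1")  # 0.01
#' @export
pileup_count <- function(pileup, chrom, pos, allele, sample) {
  n <- max(length(chrom), length(pos), length(allele), length(sample))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  allele <- rep_len(allele, n); sample <- rep_len(sample, n)
  site_key <- paste(pileup$chrom, pileup$pos, pileup$sample)
  row_key <- paste(site_key, pileup$allele)
  hit <- match(paste(chrom, pos, sample, allele), row_key)
  covered <- paste(chrom, pos, sample) %in% site_key
  out <- ifelse(is.na(hit), ifelse(covered, 0, NA_real_), pileup$count[hit])
  as.numeric(out)
}

#' @rdname pileup_count
#' @export
pileup_depth <- function(pileup, chrom, pos, sample) {
  n <- max(length(chrom), length(pos), length(sample))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n); sample <- rep_len(sample, n)
  hit <- match(paste(chrom, pos, sample),
               paste(pileup$chrom, pileup$pos, pileup$sample))
  as.numeric(pileup$depth[hit])
}

#' @rdname pileup_count
#' @export
pileup_vaf <- function(pileup, chrom, pos, allele, sample) {
  k <- pileup_count(pileup, chrom, pos, allele, sample)
  d <- pileup_depth(pileup, chrom, pos, sample)
  ifelse(is.na(d) | d == 0, NA_real_, k / d)
}

#' Read and write the pileup TSV dialect
#'
#' The on-disk form is a TSV with columns `chrom, pos, ref, sample, depth,
#' allele, count` preceded by a header comment line
#' `"#tier q=<q> Q=<Q> max_depth=<cap>"` recording the quality tier.
#'
#' @param path file path.
#' @export
read_pileup_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#tier"))
    stop("pileup TSV must start with a '#tier' header line: ", path)
  kv <- strsplit(trimws(sub("^#tier", "", first)), "[ =]")[[1]]
  vals <- suppressWarnings(as.numeric(kv[seq(2, length(kv), 2)]))  # "NA" cap
  names(vals) <- kv[seq(1, length(kv), 2)]
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          colClasses = c(chrom = "character", ref = "character",
                                         sample = "character",
                                         allele = "character"))
  pileup_table(df, q = vals[["q"]], Q = vals[["Q"]],
               max_depth = if ("max_depth" %in% names(vals)) vals[["max_depth"]] else NA)
}

#' @rdname read_pileup_tsv
#' @param pileup a pileup table.
#' @export
write_pileup_tsv <- function(pileup, path) {
  tier <- pileup_tier(pileup)
  hdr <- sprintf("#tier q=%g Q=%g max_depth=%s", tier$q, tier$Q,
                 ifelse(is.na(tier$max_depth), "NA", format(tier$max_depth)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(pileup), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
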