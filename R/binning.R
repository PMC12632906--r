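#' VAF binning
#'
#' Evaluation stratifies variants into half-open VAF bins [e_i, e_{i+1}).  The
#' default edges follow the bins used for mosaic-challenge reporting —
#' 0–0.5%, 0.5–1%, 1–1.5%, 1.5–2% and 2–3% — chosen to spread sub-5%-VAF truth
#' variants evenly; everything at or above the last edge falls into an explicit
#' overflow bin (labelled `">=3%"` by default).  Edges are configurable, e.g.
#' `vaf_binning(c(0, 0.005, 0.01))` gives the coarser <=0.5% / (0.5,1]-style
#' bins used for mixture sampling summaries.
#'
#' @param edges strictly increasing fractions starting at 0; bins are
#'   `[edges[i], edges[i+1])` plus an overflow bin `[last edge, 1]`.
#' @param labels optional bin labels (length `length(edges) - 1`).
#' @param overflow_label label of the overflow bin.
#' @return an object of class `vaf_binning`.
#' @examples
#' b <- vaf_binning()
#' assign_bin(c(0.012, 0.005, 0.25), b)
#' @export
vaf_binning <- function(edges = c(0, 0.005, 0.01, 0.015, 0.02, 0.03),
                        labels = NULL, overflow_label = NULL) {
  edges <- as.numeric(edges)
  if (length(edges) < 2 || any(diff(edges) <= 0))
    stop("bin edges must be strictly increasing")
  if (edges[1] != 0 || edges[length(edges)] > 1)
    stop("bin edges must start at 0 and stay within [0, 1]")
  if (is.null(labels))
    labels <- paste0(format_pct(edges[-length(edges)]), "-",
                     format_pct(edges[-1]), "%")
  if (length(labels) != length(edges) - 1)
    stop("need one label per bin")
  if (is.null(overflow_label))
    overflow_label <- paste0(">=", format_pct(edges[length(edges)]), "%")
  structure(list(edges = edges, labels = labels,
                 overflow_label = overflow_label),
            class = "vaf_binning")
}

format_pct <- function(x) sub("\\.?0+$", "", formatC(100 * x, format = "f", digits = 3))

#' @rdname vaf_binning
#' @param binning a `vaf_binning` object.
#' @export
bin_labels <- function(binning, overflow = TRUE) {
  c(binning$labels, if (overflow) binning$overflow_label)
}

#' Assign VAFs to bins
#'
#' Intervals are left-closed/right-open; a value at or above the last edge gets
#' the overflow label.  Values outside [0, 1] are a domain error; `NA` input
#' yields `NA` output (callers decide how undefined VAFs are handled).
#'
#' @param v numeric vector of allele fractions in [0, 1].
#' @param binning a [vaf_binning()] object.
#' @return factor of bin labels with levels `bin_labels(binning)`.
#' @export
assign_bin <- function(v, binning = vaf_binning()) {
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("VAF outside [0, 1]")
  idx <- findInterval(v, binning$edges)  # in 1..length(edges); edge-inclusive left
  lab <- ifelse(idx >= length(binning$edges), binning$overflow_label,
                binning$labels[idx])
  factor(lab, levels = bin_labels(binning))
}
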