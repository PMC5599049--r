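# bin identifiers ("chrom:bin") covered by a set of genomic intervals;
# coordinates are 0-based half-open, bins are fixed-width, half-open,
# 0-based, deterministic given bin_size
bins_of_granges <- function(gr, bin_size) {
  if (length(gr) == 0L) return(character(0))
  start0 <- GenomicRanges::start(gr) - 1L   # GRanges is 1-based inclusive
  end0 <- GenomicRanges::end(gr)            # exclusive end in 0-based terms
  keep <- end0 > start0
  start0 <- start0[keep]; end0 <- end0[keep]
  chrom <- as.character(GenomicRanges::seqnames(gr))[keep]
  out <- unlist(lapply(seq_along(start0), function(i) {
    b <- seq.int(start0[i] %/% bin_size, (end0[i] - 1L) %/% bin_size)
    paste0(chrom[i], ":", b)
  }))
  unique(out)
}

read_bed_bins <- function(path, bin_size) {
  gr <- rtracklayer::import(path, format = "BED")
  bins_of_granges(gr, bin_size)
}

#' Derive a cistrome system from BED interval lists
#'
#' Bins genomic intervals into fixed-width windows and counts, per cistrome:
#' `p` = number of bins intersecting the TF's binding intervals, `r` = number
#' of bins intersecting its producing (TF-encoding) intervals, and, for each
#' pair of cistromes, `sigma` = number of producing bins they share.  Binning
#' uses 0-based half-open coordinates (BED convention); the default window is
#' 50 kb.  The counts are invariant to interval order and to splitting an
#' interval at a bin boundary.
#'
#' Producing bins are expected to be a subset of binding bins; a producing
#' bin absent from the binding set is added to `p` with a warning rather than
#' rejected, since peak calling and gene annotation can disagree at the
#' margin.
#'
#' @param binding_files Named character vector of BED3 paths (one per
#'   cistrome) with the TF binding intervals.
#' @param producing_files Named character vector (same names) with the
#'   producing intervals.
#' @param bin_size Window width in bp (default 50,000).
#' @return A [cistrome_system()] parameterised from the binned intervals.
#' @examples
#' beds <- toy_bed_fixture()
#' import_bed(beds$binding, beds$producing)
#' @export
import_bed <- function(binding_files, producing_files, bin_size = 50000L) {
  stopifnot(bin_size > 0)
  nms <- names(binding_files)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("'binding_files' must be named by cistrome", call. = FALSE)
  if (!identical(sort(nms), sort(names(producing_files))))
    stop("'producing_files' must have the same names as 'binding_files'",
         call. = FALSE)
  bind_bins <- lapply(setNames(nms, nms), function(nm)
    read_bed_bins(binding_files[[nm]], bin_size))
  prod_bins <- lapply(setNames(nms, nms), function(nm)
    read_bed_bins(producing_files[[nm]], bin_size))
  for (nm in nms) {
    extra <- setdiff(prod_bins[[nm]], bind_bins[[nm]])
    if (length(extra)) {
      warning(sprintf("%s: %d producing bin(s) not in the binding set; added to p",
                      nm, length(extra)), call. = FALSE)
      bind_bins[[nm]] <- c(bind_bins[[nm]], extra)
    }
  }
  specs <- lapply(nms, function(nm)
    cistrome(nm, p = length(bind_bins[[nm]]), r = length(prod_bins[[nm]])))
  k <- length(nms)
  sig <- matrix(0L, k, k, dimnames = list(nms, nms))
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    s <- length(intersect(prod_bins[[i]], prod_bins[[j]]))
    sig[i, j] <- sig[j, i] <- as.integer(s)
  }
  cistrome_system(specs, sigma = sig)
}
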