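# Internal interval algebra on 0-based half-open data.frames (chrom, start, end).
# All set operations delegate to IRanges/GenomicRanges; these wrappers only
# convert between the package's BED-like convention and 1-based closed ranges.

ivl <- function(chrom = character(), start = integer(), end = integer(), ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), ..., stringsAsFactors = FALSE)
  bad <- df$end < df$start
  if (any(bad)) stop("interval end < start at row ", which(bad)[1])
  df
}

empty_ivl <- function() ivl()

as_gr <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

gr_as_ivl <- function(gr) {
  if (length(gr) == 0) return(empty_ivl())
  ivl(as.character(GenomicRanges::seqnames(gr)),
      GenomicRanges::start(gr) - 1, GenomicRanges::end(gr))
}

# merge overlapping/adjacent intervals
ivl_reduce <- function(df) gr_as_ivl(GenomicRanges::reduce(as_gr(df)))

ivl_union <- function(a, b) gr_as_ivl(GenomicRanges::union(as_gr(a), as_gr(b)))

ivl_intersect <- function(a, b)
  gr_as_ivl(GenomicRanges::intersect(as_gr(a), as_gr(b)))

ivl_setdiff <- function(a, b)
  gr_as_ivl(GenomicRanges::setdiff(as_gr(a), as_gr(b)))

ivl_bp <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(0)
  sum(df$end - df$start)
}

# total bp of intersect(a, b) after merging each side
ivl_overlap_bp <- function(a, b) ivl_bp(ivl_intersect(a, b))

# per-row: does row i of `a` intersect any interval of `b` (>= 1 bp)?
ivl_hits <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (is.null(b) || nrow(b) == 0) return(rep(FALSE, nrow(a)))
  GenomicRanges::countOverlaps(as_gr(a), as_gr(b), minoverlap = 1L) > 0
}

# per-row bp of a's rows covered by the union of b
ivl_covered_bp <- function(a, b) {
  if (nrow(a) == 0) return(numeric(0))
  if (is.null(b) || nrow(b) == 0) return(rep(0, nrow(a)))
  ga <- as_gr(a)
  gb <- GenomicRanges::reduce(as_gr(b))
  hits <- GenomicRanges::findOverlaps(ga, gb)
  if (length(hits) == 0) return(rep(0, nrow(a)))
  ov <- IRanges::pintersect(ga[S4Vectors::queryHits(hits)],
                            gb[S4Vectors::subjectHits(hits)])
  out <- rep(0, nrow(a))
  w <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
  out[as.integer(names(w))] <- as.numeric(w)
  out
}

# complement of df within the given chromosome lengths (named vector)
ivl_complement <- function(df, chrom_sizes) {
  full <- ivl(names(chrom_sizes), 0, as.numeric(chrom_sizes))
  ivl_setdiff(full, df)
}

# depth-of-coverage track: list of interval sets -> (chrom, start, end, depth)
# each input set is self-merged first so depth counts sets, not raw intervals
ivl_depth <- function(sets) {
  sets <- lapply(sets, ivl_reduce)
  all <- do.call(rbind, c(sets, list(empty_ivl())))
  if (nrow(all) == 0) return(cbind(empty_ivl(), depth = integer()))
  cov <- GenomicRanges::coverage(as_gr(all))
  gr <- methods::as(cov, "GRanges")
  out <- gr_as_ivl(gr)
  out$depth <- as.integer(gr$score)
  out[out$end > out$start, , drop = FALSE]
}
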