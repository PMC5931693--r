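# Ancestral elements from outgroup alignment coverage.
#
# Reference bases aligned by many outgroup species almost certainly share
# ancestry with them; bases aligned by very few are often spurious alignments.
# The depth threshold trades type 1 errors (lineage-specific DNA called
# ancestral, measured against known lineage-specific repeats) against type 2
# errors (ancestral DNA missed, measured as chain-block bp without element
# support). All fractions are bp-weighted.

#' Merge outgroup chain-blocks into a coverage-depth track
#'
#' Each species' intervals are self-merged first (nets give a single layer of
#' coverage per species), so depth counts species, not raw intervals.
#'
#' @param outgroup_blocks Named list, one interval data.frame (chrom, start,
#'   end) per outgroup species, all on the same reference genome.
#' @return A \code{coverage_track}: data.frame (chrom, start, end, depth)
#'   sorted, non-overlapping, with adjacent equal-depth runs merged.
#' @export
merge_coverage <- function(outgroup_blocks) {
  stopifnot(is.list(outgroup_blocks))
  out <- ivl_depth(outgroup_blocks)
  out <- out[out$depth > 0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("coverage_track", "data.frame"),
            n_species = length(outgroup_blocks))
}

#' Type 1 / type 2 error trade-off across depth thresholds
#'
#' For every minimum depth threshold d, elements are the track regions with
#' depth >= d. The type 1 fraction is the share of known lineage-specific
#' repeat bp overlapped by those elements (false ancestry); the type 2
#' fraction is the share of ingroup chain-block bp they fail to cover
#' (missed ancestry).
#'
#' @param track A \code{coverage_track} from \code{\link{merge_coverage}}.
#' @param lineage_repeats Intervals of known lineage-specific repeats.
#' @param ingroup_blocks Intervals of reference-query chain-blocks (taken as
#'   truly ancestral); must be non-empty.
#' @param max_depth Largest threshold evaluated; defaults to the number of
#'   outgroup species behind the track.
#' @return data.frame (min_depth, ancestral_bp, type1_fraction,
#'   type2_fraction), one row per threshold 1..max_depth.
#' @export
error_profile <- function(track, lineage_repeats, ingroup_blocks,
                          max_depth = NULL) {
  if (is.null(max_depth)) max_depth <- attr(track, "n_species")
  if (is.null(max_depth) || max_depth < 1)
    stop("max_depth must be a positive integer")
  if (is.null(ingroup_blocks) || ivl_bp(ingroup_blocks) == 0)
    stop("ingroup_blocks is empty: type 2 error is undefined")
  rep_bp <- ivl_bp(lineage_repeats)
  blk_bp <- ivl_bp(ivl_reduce(ingroup_blocks))
  rows <- lapply(seq_len(max_depth), function(d) {
    el <- call_elements(track, d)
    data.frame(min_depth = d,
               ancestral_bp = ivl_bp(el),
               type1_fraction = if (rep_bp == 0) 0 else
                 ivl_overlap_bp(lineage_repeats, el) / rep_bp,
               type2_fraction = 1 - ivl_overlap_bp(ingroup_blocks, el) / blk_bp)
  })
  do.call(rbind, rows)
}

#' Select the outgroup coverage depth threshold
#'
#' Returns the highest threshold d at which the step reduction in the type 1
#' fraction from d-1 to d still exceeds the step increase in the type 2
#' fraction, i.e. the last depth where tightening the threshold removes more
#' false ancestry than true ancestry. Returns 1 if no step qualifies.
#'
#' @param profile data.frame from \code{\link{error_profile}} covering a
#'   contiguous range of thresholds (at least 2 rows).
#' @return Integer depth threshold.
#' @export
select_threshold <- function(profile) {
  if (nrow(profile) < 2) stop("profile needs at least 2 threshold rows")
  profile <- profile[order(profile$min_depth), , drop = FALSE]
  d <- profile$min_depth
  if (!all(diff(d) == 1)) stop("profile thresholds must be contiguous")
  t1_drop <- -diff(profile$type1_fraction)
  t2_rise <- diff(profile$type2_fraction)
  ok <- which(t1_drop > t2_rise)
  if (length(ok) == 0) return(d[1])
  d[max(ok) + 1L]
}

#' Call ancestral elements at a depth threshold
#'
#' @param track A \code{coverage_track}.
#' @param depth Minimum outgroup coverage depth (>= 1).
#' @return An \code{ancestral_elements} object: merged intervals (chrom,
#'   start, end) with the chosen depth stored as attribute
#'   \code{chosen_depth}.
#' @export
call_elements <- function(track, depth) {
  stopifnot(depth >= 1)
  el <- ivl_reduce(track[track$depth >= depth,
                         c("chrom", "start", "end"), drop = FALSE])
  structure(el, class = c("ancestral_elements", "data.frame"),
            chosen_depth = depth)
}
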