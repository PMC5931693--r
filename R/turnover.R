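# Chain-gap annotation and synthetic-genome placement.
#
# A chain-gap hosted (present) in genome A and absent from partner genome B is
# either DNA gained on the A lineage or DNA lost on the B lineage. Two
# complementary rules decide which:
#   * ancestral-element method: the gap is a B loss iff it overlaps an
#     ancestral element of A (the DNA predates the split), else an A gain;
#   * recent-transposon method: the gap is an A gain iff it overlaps a
#     lineage-specific insertion of A, else a B loss.
# Annotated gaps are then "placed" into the partner genome at the query-side
# coordinate between their flanking blocks, producing a synthetic genome whose
# length is the partner genome plus all placed gap lengths, and which carries
# both lineages' events in one coordinate system.

#' Annotate chain-gaps by the ancestral-element method
#'
#' @param gaps Gap table from \code{\link{extract_features}} (hosted in the
#'   \code{host} genome's coordinates).
#' @param elements Ancestral elements of the host genome.
#' @param host,partner Genome labels; the host genome is the one whose
#'   coordinates the gaps live in, the partner is the genome the sequence is
#'   absent from.
#' @return The gap table with \code{label} ("<host>_gain" or
#'   "<partner>_loss"), \code{method} and \code{length_bp} columns.
#' @export
annotate_gaps_ancestral <- function(gaps, elements, host, partner) {
  hit <- ivl_hits(ivl(gaps$chrom, gaps$ref_start, gaps$ref_end), elements)
  out <- gaps
  out$label <- ifelse(hit, paste0(partner, "_loss"), paste0(host, "_gain"))
  out$method <- rep_len("ancestral_element", nrow(out))
  out$length_bp <- gaps$ref_end - gaps$ref_start
  out
}

#' Annotate chain-gaps by the recent-transposon method
#'
#' @param gaps Gap table hosted in the \code{host} genome.
#' @param insertions Lineage-specific insertion intervals of the host genome
#'   (from \code{\link{recent_insertions}}).
#' @inheritParams annotate_gaps_ancestral
#' @return Annotated gap table as in \code{\link{annotate_gaps_ancestral}}.
#' @export
annotate_gaps_transposon <- function(gaps, insertions, host, partner) {
  hit <- ivl_hits(ivl(gaps$chrom, gaps$ref_start, gaps$ref_end), insertions)
  out <- gaps
  out$label <- ifelse(hit, paste0(host, "_gain"), paste0(partner, "_loss"))
  out$method <- rep_len("recent_transposon", nrow(out))
  out$length_bp <- gaps$ref_end - gaps$ref_start
  out
}

#' Cross-tabulate the two annotation methods
#'
#' Mb of gap bp in each (recent-transposon label x ancestral-element label)
#' cell, the layout used for per-genome method-agreement reporting.
#'
#' @param ann_tx,ann_anc Annotated gap tables for the same gap set from the
#'   two methods.
#' @return Matrix (Mb) with transposon-method labels as rows,
#'   ancestral-method labels as columns, plus row/column totals.
#' @export
cross_tabulate_methods <- function(ann_tx, ann_anc) {
  stopifnot(nrow(ann_tx) == nrow(ann_anc),
            all(ann_tx$gap_id == ann_anc$gap_id))
  labs <- sort(unique(c(ann_tx$label, ann_anc$label)))
  tab <- tapply(ann_tx$length_bp / 1e6,
                list(factor(ann_tx$label, labs), factor(ann_anc$label, labs)),
                sum, default = 0)
  tab <- cbind(tab, Total = rowSums(tab))
  rbind(tab, Total = colSums(tab))
}

#' Place annotated chain-gaps into the partner genome
#'
#' Each gap is inserted at its query-side anchor (the partner-genome
#' coordinate shared by its flanking blocks). Placement runs from the deepest
#' chain level up to the top and, within a level, in ascending anchor order;
#' every placement shifts all downstream synthetic coordinates by the gap's
#' host-side length. Host bases already placed by a deeper chain are not
#' placed twice (nested-net deduplication): the overlap is trimmed off and a
#' gap reduced to zero is skipped.
#'
#' @param annotations Annotated gap table (one method) hosted in the reference
#'   genome of \code{nets}.
#' @param query Genome descriptor of the partner (target) genome.
#' @param carry Optional named list of interval sets in partner coordinates
#'   (e.g. the partner genome's own gap annotations, masks) to lift into
#'   synthetic coordinates alongside the placement.
#' @return A \code{synthetic_genome}: chromosome lengths after placement, the
#'   placement table (query_chrom, anchor, length, synthetic_start,
#'   synthetic_end, label, orientation, gap_id), lifted \code{carry} sets, and
#'   the per-label interval sets of placed gaps in synthetic coordinates.
#' @export
place_gaps <- function(annotations, query, carry = list()) {
  stopifnot(inherits(query, "genome_descriptor"))
  a <- annotations
  if (nrow(a) > 0 && any(a$query_anchor < 0 |
                           a$query_anchor > query$chrom_sizes[a$query_chrom]))
    stop("gap anchor outside target chromosome")
  a <- a[order(-a$level, a$query_chrom, a$query_anchor), , drop = FALSE]
  a$length <- a$ref_end - a$ref_start

  # nested-net dedup: trim host bases already placed by a deeper level
  if (nrow(a) > 0 && length(unique(a$level)) > 1) {
    placed <- empty_ivl()
    lens <- numeric(nrow(a))
    for (i in seq_len(nrow(a))) {
      gi <- ivl(a$chrom[i], a$ref_start[i], a$ref_end[i])
      lens[i] <- ivl_bp(ivl_setdiff(gi, placed))
      placed <- ivl_union(placed, gi)
    }
    a$length <- lens
    a <- a[a$length > 0, , drop = FALSE]
  }

  # synthetic coordinate of each insertion: anchor plus the lengths of all
  # insertions at strictly smaller anchors, plus earlier-placed ties
  ins <- a[order(a$query_chrom, a$query_anchor,
                 seq_len(nrow(a))), , drop = FALSE]
  if (nrow(ins) > 0) {
    off <- stats::ave(ins$length, ins$query_chrom,
                      FUN = function(v) c(0, cumsum(v))[seq_along(v)])
    ins$synthetic_start <- ins$query_anchor + off
    ins$synthetic_end <- ins$synthetic_start + ins$length
  } else {
    ins$synthetic_start <- numeric(0)
    ins$synthetic_end <- numeric(0)
  }
  placed_bp <- tapply(ins$length, ins$query_chrom, sum)
  chrom_lengths <- query$chrom_sizes
  chrom_lengths[names(placed_bp)] <-
    chrom_lengths[names(placed_bp)] + as.numeric(placed_bp)

  placements <- data.frame(
    query_chrom = ins$query_chrom, anchor = ins$query_anchor,
    length = ins$length, synthetic_start = ins$synthetic_start,
    synthetic_end = ins$synthetic_end, label = ins$label,
    orientation = ins$orient, gap_id = ins$gap_id, stringsAsFactors = FALSE)

  categories <- split(
    ivl(placements$query_chrom, placements$synthetic_start,
        placements$synthetic_end),
    placements$label)
  sg <- structure(list(query = query, chrom_lengths = chrom_lengths,
                       placements = placements,
                       categories = lapply(categories, ivl_reduce),
                       carried = list()),
                  class = "synthetic_genome")
  sg$carried <- lapply(carry, lift_to_synthetic, map = sg)
  sg
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome on", x$query$name, "background:",
      format(sum(x$chrom_lengths), big.mark = ","), "bp =",
      format(sum(x$query$chrom_sizes), big.mark = ","), "(query) +",
      format(sum(x$placements$length), big.mark = ","), "placed bp in",
      nrow(x$placements), "gap(s)\n")
  invisible(x)
}

#' Lift partner-genome intervals into synthetic coordinates
#'
#' Carried bases map monotonically through the placement; an interval
#' spanning an insertion point is split around the inserted block.
#'
#' @param intervals data.frame (chrom, start, end) in partner (query)
#'   coordinates; extra columns are preserved on the fragments.
#' @param map A \code{synthetic_genome} from \code{\link{place_gaps}}.
#' @return data.frame of lifted (possibly split) intervals in synthetic
#'   coordinates.
#' @export
lift_to_synthetic <- function(intervals, map) {
  stopifnot(inherits(map, "synthetic_genome"))
  if (nrow(intervals) == 0) return(intervals)
  pl <- map$placements
  out <- lapply(split(intervals, intervals$chrom), function(iv) {
    chrom <- iv$chrom[1]
    p <- pl[pl$query_chrom == chrom, , drop = FALSE]
    p <- p[order(p$anchor, p$synthetic_start), , drop = FALSE]
    if (nrow(p) == 0) return(iv)
    # segments between successive anchors; segment k is shifted by the total
    # placed length at anchors <= its start
    ua <- unique(p$anchor)                       # already sorted
    La <- as.numeric(tapply(p$length, factor(p$anchor, ua), sum))
    seg_start <- c(0, ua)
    seg_end <- c(ua, unname(map$query$chrom_sizes[chrom]))
    shift <- c(0, cumsum(La))
    keep <- seg_end > seg_start
    seg <- ivl(chrom, seg_start[keep], seg_end[keep])
    shift <- shift[keep]
    hit <- GenomicRanges::findOverlaps(as_gr(iv), as_gr(seg))
    qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
    frag <- iv[qi, , drop = FALSE]
    s <- pmax(iv$start[qi], seg$start[si])
    e <- pmin(iv$end[qi], seg$end[si])
    frag$start <- s + shift[si]
    frag$end <- e + shift[si]
    frag
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Genome-size bookkeeping
#'
#' Solves the extant = ancestral + gain - loss identity for the ancestral
#' genome size: G_A = G_E - G_G + G_L.
#'
#' @param G_E Extant genome size (Mb).
#' @param G_G Lineage-specific gain (Mb).
#' @param G_L Lineage-specific loss (Mb).
#' @return Ancestral genome size G_A in Mb.
#' @export
genome_size_budget <- function(G_E, G_G, G_L) {
  stopifnot(G_E >= 0, G_G >= 0, G_L >= 0)
  G_E - G_G + G_L
}
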