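# Dating gain and loss events with ordered ingroup panels.
#
# A gain hosted in genome A is dated by the nearest A-related ingroup species
# whose alignment to A shows a gap over the event: the insertion happened
# after that species diverged (and, because no nearer species matched, before
# the previous divergence). A loss from lineage A is dated on the partner
# genome B, where the lost DNA survives, using the A-related ingroups aligned
# to B, processed farthest first: a loss shared with (absent from) the
# farthest relatives happened early. Epochs are numbered 1 (youngest, ending
# at 0 MY) to k+1 (oldest, starting at the reference/query split).

#' Build an ingroup panel
#'
#' @param species Character vector of species names, ordered nearest first
#'   (smallest divergence time first).
#' @param times_my Divergence times in MY, strictly increasing, same order.
#' @param gap_sets List of alignment-gap interval data.frames (chrom, start,
#'   end) versus the host genome, same order.
#' @param split_my Divergence time of the reference/query split (upper bound
#'   of the oldest epoch); must exceed \code{max(times_my)}.
#' @return An \code{ingroup_panel} object.
#' @export
ingroup_panel <- function(species, times_my, gap_sets, split_my) {
  stopifnot(length(species) == length(times_my),
            length(species) == length(gap_sets))
  if (length(times_my) && any(diff(times_my) <= 0))
    stop("divergence times must be strictly increasing (nearest first)")
  if (length(times_my) && split_my <= max(times_my))
    stop("split_my must exceed the farthest ingroup divergence time")
  structure(list(species = species, times_my = times_my,
                 gap_sets = gap_sets, split_my = split_my),
            class = "ingroup_panel")
}

#' @export
print.ingroup_panel <- function(x, ...) {
  cat("Ingroup panel:", length(x$species), "species, split at",
      x$split_my, "MY\n")
  if (length(x$species))
    cat(" ", paste0(x$species, " (", x$times_my, " MY)", collapse = ", "), "\n")
  invisible(x)
}

#' Date DNA gain events
#'
#' Species are processed nearest to farthest; an event overlapping (>= 1 bp)
#' the current species' gap set, and not yet claimed, is assigned the epoch
#' ending at that species' divergence. Events never matched fall in the
#' oldest epoch.
#'
#' @param events Interval data.frame of gain events in the host genome.
#' @param panel \code{\link{ingroup_panel}} of host-related species aligned to
#'   the host genome.
#' @return The events with \code{epoch} (1 = youngest), \code{epoch_start_my},
#'   \code{epoch_end_my} and \code{matched_species} columns.
#' @export
assign_epochs_gain <- function(events, panel) {
  stopifnot(inherits(panel, "ingroup_panel"))
  assign_epochs_sequential(events, panel, youngest_first = TRUE,
                           unmatched = length(panel$species) + 1L)
}

#' Date DNA loss events
#'
#' Events are the surviving copies of lost DNA, located in the partner
#' genome; the panel holds the losing lineage's relatives aligned to that
#' partner genome. Species are processed farthest to nearest (early losses
#' are shared across all relatives); unmatched events fall in the youngest
#' epoch.
#'
#' @param events Interval data.frame of loss events in the partner genome.
#' @param panel \code{\link{ingroup_panel}} (nearest-first as always; the
#'   processing order is reversed internally).
#' @return As \code{\link{assign_epochs_gain}}.
#' @export
assign_epochs_loss <- function(events, panel) {
  stopifnot(inherits(panel, "ingroup_panel"))
  assign_epochs_sequential(events, panel, youngest_first = FALSE,
                           unmatched = 1L)
}

assign_epochs_sequential <- function(events, panel, youngest_first,
                                     unmatched) {
  k <- length(panel$species)
  epoch <- rep(unmatched, nrow(events))
  matched <- rep(NA_character_, nrow(events))
  claimed <- rep(FALSE, nrow(events))
  order_idx <- if (youngest_first) seq_len(k) else rev(seq_len(k))
  for (i in order_idx) {
    hit <- !claimed & ivl_hits(events, panel$gap_sets[[i]])
    # species i (nearest-first index) bounds epochs i and i+1; a gain matched
    # at i is younger than t_i (epoch i), a loss matched at i is older (i+1)
    epoch[hit] <- if (youngest_first) i else i + 1L
    matched[hit] <- panel$species[i]
    claimed <- claimed | hit
  }
  bounds <- c(0, panel$times_my, panel$split_my)
  out <- events
  out$epoch <- as.integer(epoch)
  out$epoch_start_my <- bounds[epoch]
  out$epoch_end_my <- bounds[epoch + 1L]
  out$matched_species <- matched
  out
}

#' Per-epoch turnover totals and rates
#'
#' @param assignment Events with \code{epoch} column (from
#'   \code{\link{assign_epochs_gain}} or \code{\link{assign_epochs_loss}});
#'   event length is end - start.
#' @param panel The \code{\link{ingroup_panel}} used for assignment.
#' @return data.frame (epoch, start_my, end_my, duration_my, total_bp,
#'   rate_mb_per_my), one row per epoch, youngest first; totals sum to the
#'   event-set total.
#' @export
epoch_rates <- function(assignment, panel) {
  stopifnot(inherits(panel, "ingroup_panel"))
  bounds <- c(0, panel$times_my, panel$split_my)
  k <- length(bounds) - 1L
  dur <- diff(bounds)
  if (any(dur <= 0)) stop("zero-duration epoch")
  len <- assignment$end - assignment$start
  tot <- tapply(len, factor(assignment$epoch, seq_len(k)), sum, default = 0)
  data.frame(epoch = seq_len(k), start_my = bounds[-length(bounds)],
             end_my = bounds[-1], duration_my = dur,
             total_bp = as.numeric(tot),
             rate_mb_per_my = as.numeric(tot) / 1e6 / dur,
             row.names = NULL)
}
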