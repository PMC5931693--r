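# Gi* hotspot detection on binned synthetic genomes.
#
# The synthetic genome is tiled into fixed windows (200 kb by default; placed
# gaps larger than the window spread across boundaries, so no bin carries more
# than one window of any annotation). Bins with too little eligible sequence
# (outside assembly gaps and non-RBH masks) are discarded. Per-bin annotation
# tallies feed the Getis-Ord local statistic
#
#   Gi* = (sum_j w_ij x_j - Xbar sum_j w_ij) /
#         (S * sqrt((n sum_j w_ij^2 - (sum_j w_ij)^2) / (n - 1)))
#
# with binary weights w_ij = 1 for bins within a fixed number of neighbouring
# bins on the same chromosome (the focal bin included), Xbar = sum x_j / n and
# S = sqrt(sum x_j^2 / n - Xbar^2) taken over all retained bins genome-wide.
# Gi* values are converted to two-sided normal p-values, adjusted by
# Benjamini-Hochberg, and bins are called hot (Gi* > 0) or cold (Gi* < 0) at
# FDR < alpha.

#' Tile a genome into fixed-width bins
#'
#' @param chrom_lengths Named vector of chromosome lengths (e.g. the
#'   \code{chrom_lengths} of a \code{synthetic_genome}), or a
#'   \code{synthetic_genome} itself.
#' @param window Bin width in bp (default 200000); the last bin of each
#'   chromosome may be shorter.
#' @param min_eligible Minimum eligible bp for a bin to be retained
#'   (default 150000).
#' @param masks List of interval data.frames (assembly gaps, non-RBH regions,
#'   ...) in the same coordinates; masked bases are ineligible.
#' @return data.frame (bin_id, chrom, start, end, eligible_bp) of retained
#'   bins, in genome order.
#' @export
make_bins <- function(chrom_lengths, window = 200000, min_eligible = 150000,
                      masks = list()) {
  if (inherits(chrom_lengths, "synthetic_genome"))
    chrom_lengths <- chrom_lengths$chrom_lengths
  if (window <= 0) stop("window must be positive")
  tiles <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    s <- seq(0, len - 1, by = window)
    ivl(chrom, s, pmin(s + window, len))
  })
  bins <- do.call(rbind, tiles)
  mask <- if (length(masks)) ivl_reduce(do.call(rbind, lapply(masks, function(m)
    ivl(m$chrom, m$start, m$end)))) else empty_ivl()
  bins$eligible_bp <- (bins$end - bins$start) - ivl_covered_bp(bins, mask)
  bins <- bins[bins$eligible_bp >= min_eligible, , drop = FALSE]
  rownames(bins) <- NULL
  cbind(bin_id = seq_len(nrow(bins)), bins)
}

#' Tally annotation bp per bin
#'
#' Raw bp by interval intersection; the normalised value rescales each raw
#' tally to a full window of eligible sequence
#' (raw * window / eligible_bp).
#'
#' @param bins Bin table from \code{\link{make_bins}}.
#' @param annotations Named list of interval data.frames (one per annotation
#'   category) in the bins' coordinate system.
#' @param window Window size used for normalisation (default 200000).
#' @return The bin table with \code{raw_<category>} and \code{norm_<category>}
#'   columns appended.
#' @export
tally_annotations <- function(bins, annotations, window = 200000) {
  stopifnot(is.list(annotations), !is.null(names(annotations)))
  out <- bins
  for (cat in names(annotations)) {
    raw <- ivl_covered_bp(bins, annotations[[cat]])
    out[[paste0("raw_", cat)]] <- raw
    out[[paste0("norm_", cat)]] <- raw * window / bins$eligible_bp
  }
  out
}

#' Getis-Ord local statistic over ordered genomic bins
#'
#' @param values Numeric vector of per-bin values, in genome order.
#' @param chrom Chromosome label of each bin; neighbourhoods never cross
#'   chromosome boundaries (edge bins have truncated neighbourhoods).
#' @param neighbor_distance Number of neighbouring bins on each side given
#'   weight 1 (default 3 = 600 kb at 200-kb bins).
#' @param include_self Give the focal bin weight 1 as well (the Gi-star
#'   convention; default TRUE).
#' @param sided \code{"two"} (default) or \code{"one"}-sided normal p-values.
#' @return A \code{gi_result} data.frame (chrom, x, gi, p, q) with the global
#'   mean \code{xbar} and scale \code{S} as attributes. A constant input
#'   (S = 0) yields Gi* = 0 and p = 1 everywhere, with a warning.
#' @export
getis_ord <- function(values, chrom, neighbor_distance = 3,
                      include_self = TRUE, sided = c("two", "one")) {
  sided <- match.arg(sided)
  n <- length(values)
  stopifnot(length(chrom) == n, neighbor_distance >= 0)
  if (n < 2) stop("need at least 2 bins")
  xbar <- sum(values) / n
  S <- sqrt(sum(values^2) / n - xbar^2)

  # rolling window sums within chromosomes
  chrom <- as.character(chrom)
  win_sum <- function(x, d) {
    cs <- c(0, cumsum(x))
    i <- seq_along(x)
    lo <- pmax(i - d, 1L)
    hi <- pmin(i + d, length(x))
    cs[hi + 1L] - cs[lo]
  }
  d <- as.integer(neighbor_distance)
  wx <- numeric(n); wsum <- numeric(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    wx[idx] <- win_sum(values[idx], d)
    wsum[idx] <- win_sum(rep(1, length(idx)), d)
  }
  if (!include_self) {
    wx <- wx - values
    wsum <- wsum - 1
  }
  # binary weights: sum w^2 = sum w
  denom <- S * sqrt((n * wsum - wsum^2) / (n - 1))
  if (S == 0) {
    warning("constant values: S = 0, all Gi* set to 0")
    gi <- rep(0, n)
    p <- rep(1, n)
  } else {
    gi <- (wx - xbar * wsum) / denom
    gi[denom == 0] <- 0
    p <- if (sided == "two") 2 * stats::pnorm(-abs(gi)) else
      stats::pnorm(-gi)
  }
  out <- data.frame(chrom = chrom, x = values, gi = gi, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("gi_result", "data.frame"), xbar = xbar, S = S,
            neighbor_distance = d, include_self = include_self)
}

#' Call hotspots and coldspots from Gi* results
#'
#' A bin is hot iff Gi* > 0 and q < alpha, cold iff Gi* < 0 and q < alpha;
#' all other bins are uncalled.
#'
#' @param result A \code{gi_result} from \code{\link{getis_ord}}.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame (bin, chrom, gi, q, call) of called bins only, where
#'   \code{bin} indexes rows of \code{result}.
#' @export
call_hotspots <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "gi_result"))
  sig <- result$q < alpha & result$gi != 0
  idx <- which(sig)
  data.frame(bin = idx, chrom = result$chrom[idx], gi = result$gi[idx],
             q = result$q[idx],
             call = ifelse(result$gi[idx] > 0, "hot", "cold"),
             stringsAsFactors = FALSE)
}
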