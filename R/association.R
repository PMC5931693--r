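# Hotspot-feature enrichment and hotspot-hotspot overlap.

#' Summarise a genomic feature per bin
#'
#' @param bins Bin table from \code{\link{make_bins}}.
#' @param data For \code{kind = "coverage"}: interval data.frame (chrom,
#'   start, end); per-bin value is the bp intersection. For
#'   \code{kind = "mean_rate"}: intervals with a \code{rate} column; per-bin
#'   value is the overlap-length-weighted mean rate, NA for bins no rate
#'   interval touches. For \code{kind = "gc_fraction"}: aligned-block
#'   intervals with a \code{gc} column (G+C fraction of each block); per-bin
#'   value is the overlap-weighted G+C fraction of block bases in the bin,
#'   NA where no block bases fall.
#' @param kind Feature kind.
#' @param name Feature name recorded on the result.
#' @return data.frame (bin_id, value) with attributes \code{name} and
#'   \code{kind}.
#' @export
feature_per_bin <- function(bins, data,
                            kind = c("coverage", "mean_rate", "gc_fraction"),
                            name = deparse(substitute(data))) {
  kind <- match.arg(kind)
  gb <- as_gr(bins)
  gd <- as_gr(data)
  hit <- GenomicRanges::findOverlaps(gb, gd)
  qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
  ow <- pmin(bins$end[qi], data$end[si]) - pmax(bins$start[qi], data$start[si])
  val <- switch(kind,
    coverage = {
      v <- rep(0, nrow(bins))
      s <- tapply(ow, qi, sum)
      v[as.integer(names(s))] <- as.numeric(s)
      v
    },
    mean_rate = {
      stopifnot("rate" %in% names(data))
      v <- rep(NA_real_, nrow(bins))
      num <- tapply(ow * data$rate[si], qi, sum)
      den <- tapply(ow, qi, sum)
      v[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
      v
    },
    gc_fraction = {
      stopifnot("gc" %in% names(data))
      v <- rep(NA_real_, nrow(bins))
      num <- tapply(ow * data$gc[si], qi, sum)
      den <- tapply(ow, qi, sum)
      v[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
      v
    })
  structure(data.frame(bin_id = bins$bin_id, value = val),
            name = name, kind = kind)
}

#' Permutation test for feature enrichment in hotspots
#'
#' The observed statistic is the difference in feature means between hotspot
#' and non-hotspot bins. The null distribution permutes the hotspot /
#' non-hotspot partition over bins (label permutation without replacement,
#' preserving group sizes); the observed difference is standardised against
#' it. Positive Z means the feature is elevated in hotspots. Bins with NA
#' feature values are excluded from the universe before permuting (e.g. an
#' autosome-only rate track).
#'
#' @param values Per-bin feature values (numeric; NAs dropped with their
#'   bins).
#' @param is_hot Logical per-bin hotspot membership.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed for the permutation stream.
#' @return List of class \code{enrichment_result}: observed difference, null
#'   mean/sd, \code{z}, \code{n_perm}, \code{seed}, group sizes. Z is 0 when
#'   the null sd is 0.
#' @export
permutation_enrichment <- function(values, is_hot, n_perm = 10000,
                                   seed = NULL) {
  stopifnot(length(values) == length(is_hot))
  keep <- !is.na(values)
  values <- values[keep]; is_hot <- as.logical(is_hot)[keep]
  n1 <- sum(is_hot); n0 <- sum(!is_hot); n <- n1 + n0
  if (n1 == 0 || n0 == 0)
    stop("need at least one hotspot and one non-hotspot bin")
  obs <- mean(values[is_hot]) - mean(values[!is_hot])
  tot <- sum(values)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  null <- vapply(seq_len(n_perm), function(i) {
    s1 <- sum(values[sample.int(n, n1)])
    s1 / n1 - (tot - s1) / n0
  }, numeric(1))
  mu <- mean(null); sdev <- stats::sd(null)
  z <- if (sdev == 0) 0 else (obs - mu) / sdev
  structure(list(observed = obs, null_mean = mu, null_sd = sdev, z = z,
                 n_perm = n_perm, seed = seed, n_hot = n1, n_other = n0),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Permutation enrichment:", x$n_hot, "hotspot vs", x$n_other,
      "other bins,", x$n_perm, "permutations\n")
  cat("  observed diff:", signif(x$observed, 4), " Z:", signif(x$z, 4), "\n")
  invisible(x)
}

#' Fisher overlap test between two bin sets
#'
#' Partitions the bin universe into the 2 x 2 table (in both, A only, B only,
#' neither) and reports the two-sided Fisher exact p-value with the sample
#' cross-product odds ratio (0 and Inf allowed; no continuity correction).
#'
#' @param calls_a,calls_b Logical vectors over the universe, or vectors of
#'   bin ids contained in \code{universe}.
#' @param universe Universe size (integer) when calls are id vectors, or
#'   omitted when calls are logical vectors.
#' @return List of class \code{fisher_result}: \code{table}, \code{odds_ratio}
#'   (sample), \code{p}.
#' @export
overlap_test <- function(calls_a, calls_b, universe = NULL) {
  if (is.logical(calls_a) && is.logical(calls_b)) {
    stopifnot(length(calls_a) == length(calls_b))
    a <- calls_a; b <- calls_b
  } else {
    if (is.null(universe)) stop("universe required for id-vector calls")
    nU <- if (length(universe) == 1) universe else length(universe)
    ids <- if (length(universe) == 1) seq_len(universe) else universe
    a <- ids %in% calls_a; b <- ids %in% calls_b
  }
  if (length(a) == 0) stop("empty universe")
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(A = c("in", "out"), B = c("in", "out")))
  p <- stats::fisher.test(tab)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(table = tab, odds_ratio = or, p = p),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher overlap test: OR =", signif(x$odds_ratio, 4),
      " p =", signif(x$p, 4), "\n")
  print(x$table)
  invisible(x)
}

#' Fisher tests for a matrix of hotspot-set comparisons
#'
#' Runs \code{\link{overlap_test}} for every pair and BH-adjusts the p-values
#' over all comparisons.
#'
#' @param call_sets Named list of logical membership vectors over a common
#'   bin universe.
#' @return data.frame (set_a, set_b, odds_ratio, p, q), one row per ordered
#'   pair with set_a != set_b.
#' @export
overlap_matrix <- function(call_sets) {
  nm <- names(call_sets)
  stopifnot(!is.null(nm))
  pairs <- expand.grid(a = nm, b = nm, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i)
    overlap_test(call_sets[[pairs$a[i]]], call_sets[[pairs$b[i]]]))
  out <- data.frame(set_a = pairs$a, set_b = pairs$b,
                    odds_ratio = vapply(res, `[[`, 0, "odds_ratio"),
                    p = vapply(res, `[[`, 0, "p"))
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
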