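# Shared fixtures and independent oracles, all built in code.

desc1 <- function(len = 1000, name = "refA", chrom = "chr1", gaps = NULL)
  genome_descriptor(name, stats::setNames(len, chrom), gaps)

# three-level toy net: top chain with one gap, a child chain filling part of
# that gap, and a grandchild inside the child's gap
toy_net_text <- function() c(
  "net chr1 1000",
  " fill 100 800 chrQ + 50 820 id 1",
  "  gap 300 200 chrQ + 250 220",
  "   fill 320 120 chrQ + 300 120 id 2",
  "    gap 360 40 chrQ + 340 0",
  "     fill 370 20 chrQ + 345 20 id 3")

# per-base cover of a single-chromosome interval set (0-based half-open)
bitmap <- function(df, len) {
  v <- logical(len)
  for (i in seq_len(nrow(df))) {
    if (df$end[i] > df$start[i])
      v[(df$start[i] + 1):df$end[i]] <- TRUE
  }
  v
}

iv1 <- function(start, end, chrom = "chr1")
  data.frame(chrom = rep_len(chrom, length(start)), start = start, end = end,
             stringsAsFactors = FALSE)

# literal double-loop evaluation of the Getis-Ord statistic as printed
literal_gi <- function(x, chrom, d = 3, self = TRUE) {
  n <- length(x)
  xbar <- sum(x) / n
  S <- sqrt(sum(x^2) / n - xbar^2)
  idx <- stats::ave(seq_along(x), chrom, FUN = seq_along)
  vapply(seq_len(n), function(i) {
    w <- as.numeric(chrom == chrom[i] & abs(idx - idx[i]) <= d)
    if (!self) w[i] <- 0
    num <- sum(w * x) - xbar * sum(w)
    den <- S * sqrt((n * sum(w^2) - sum(w)^2) / (n - 1))
    if (den == 0) 0 else num / den
  }, numeric(1))
}

# Benjamini-Hochberg step-up written out directly
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# maximal runs of called bins -> regions; region-level precision/recall of
# calls against planted cluster bin-index ranges
region_score <- function(called_bins, planted_ranges) {
  if (length(called_bins) == 0)
    return(list(precision = 0, recall = 0))
  called_bins <- sort(called_bins)
  brk <- c(0, which(diff(called_bins) > 1), length(called_bins))
  regions <- lapply(seq_len(length(brk) - 1), function(k)
    range(called_bins[(brk[k] + 1):brk[k + 1]]))
  hit_region <- vapply(regions, function(r)
    any(planted_ranges[, 1] <= r[2] & planted_ranges[, 2] >= r[1]), TRUE)
  hit_plant <- vapply(seq_len(nrow(planted_ranges)), function(j)
    any(vapply(regions, function(r)
      planted_ranges[j, 1] <= r[2] && planted_ranges[j, 2] >= r[1], TRUE)),
    TRUE)
  list(precision = mean(hit_region), recall = mean(hit_plant))
}

# tiny simulation configuration for fast end-to-end tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(chrom_lengths = c(chr1 = 8e5, chr2 = 5e5), seed = seed, ...)
}

# all event rates zeroed: both genomes stay identical to the ancestor
zero_rate_config <- function(seed = 1) {
  fam0 <- sim_default_families("ref")
  fam0$gain_fraction <- 0
  famq <- sim_default_families("query")
  famq$gain_fraction <- 0
  sim_config(chrom_lengths = c(chr1 = 8e5), families_ref = fam0,
             families_query = famq, loss_rate = 0,
             anc_repeat_fraction = 0, seed = seed)
}
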