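# Forward simulation of two-lineage genome turnover.
#
# An ancestor genome splits into a reference and a query lineage. Each branch
# accrues transposon-family-structured insertions (gains) and deletions
# (losses) as Poisson processes over bp x MY; ingroup species mark staged
# divergence times along each branch, and outgroup species (idealised as the
# ancestor itself) provide alignment coverage for ancestral-element calling,
# optionally degraded by segment dropout and boundary jitter. Event
# footprints are kept disjoint on the ancestor (with a minimum separation) so
# that every event maps to exactly one chain-gap and can be scored exactly.
# All alignments are emitted from the known orthology as single-chain nets;
# no sequence is simulated.

#' Default transposon family table for a simulated lineage
#'
#' Families mimic the broad size classes of mammalian repeats (full-length
#' LINEs, truncated LINEs, SINEs, composite and LTR elements) with distinct
#' activity windows and a per-family divergence clock.
#'
#' @param lineage \code{"ref"} (slower, primate-like clock) or \code{"query"}
#'   (faster, rodent-like clock).
#' @return data.frame (family, consensus_bp, gain_fraction, t_start, t_end,
#'   clock_pct_my): \code{gain_fraction} is the expected share of the
#'   ancestor length gained through that family over its activity window
#'   (t_start younger bound, t_end older, MY).
#' @export
sim_default_families <- function(lineage = c("ref", "query")) {
  lineage <- match.arg(lineage)
  if (lineage == "ref")
    data.frame(
      family = c("L1P1", "L1P2", "AluY1", "AluS1", "SVA1", "LTR1"),
      consensus_bp = c(6000, 5000, 300, 300, 1500, 800),
      gain_fraction = c(0.09, 0.05, 0.045, 0.035, 0.02, 0.01),
      t_start = c(0, 40, 0, 30, 10, 50),
      t_end = c(45, 90, 35, 75, 60, 90),
      clock_pct_my = 0.30, stringsAsFactors = FALSE)
  else
    data.frame(
      family = c("L1Md1", "Lx2", "B1a", "B2a", "MT1", "IAP1"),
      consensus_bp = c(6000, 5000, 150, 190, 500, 1200),
      gain_fraction = c(0.10, 0.05, 0.04, 0.03, 0.02, 0.01),
      t_start = c(0, 35, 0, 25, 15, 45),
      t_end = c(40, 90, 30, 70, 65, 90),
      clock_pct_my = 0.45, stringsAsFactors = FALSE)
}

#' Configure a turnover simulation
#'
#' Defaults describe a 50-Mb two-chromosome ancestor evolving over a 90-MY
#' split with primate/rodent-like ingroup panels, eight outgroup species,
#' roughly a quarter of the ancestor gained and a quarter lost per lineage,
#' and noise-free alignments.
#'
#' @param chrom_lengths Named vector of ancestor chromosome lengths (bp).
#' @param split_my Reference/query divergence time (MY).
#' @param ingroup_times_ref,ingroup_times_query Named vectors of ingroup
#'   divergence times (MY), nearest first, all < \code{split_my}.
#' @param outgroup_times Named vector of outgroup divergence times (MY), all
#'   > \code{split_my}; the number of outgroups is its length.
#' @param families_ref,families_query Family tables as from
#'   \code{\link{sim_default_families}}.
#' @param loss_rate Deletions per bp per MY per branch.
#' @param loss_meanlog,loss_sdlog,loss_min,loss_max Lognormal deletion-length
#'   distribution (bp), truncated.
#' @param anc_families data.frame (family, consensus_bp, clock_pct_my) of
#'   repeat families already fixed in the ancestor.
#' @param anc_repeat_fraction bp fraction of the ancestor covered by
#'   ancestral repeat copies.
#' @param anc_age_range Age range (MY) of ancestral copies (older than the
#'   split).
#' @param div_noise_sd Gaussian noise (percentage points) on per-copy
#'   divergence around the family clock.
#' @param dropout Probability that an aligned segment is missing from a given
#'   outgroup's alignment.
#' @param jitter_bp Mean exponential boundary jitter (bp) by which outgroup
#'   alignment blocks spuriously extend into flanking gain gaps; 0 disables.
#' @param jitter_prob Probability that a given block boundary is jittered at
#'   all (per outgroup species and gap side).
#' @param min_separation Minimum shared bp kept between event footprints on
#'   the ancestor.
#' @param gain_hotspots NULL, or list(n, width, multiplier, lineage): plant
#'   \code{n} regions of \code{width} bp in which that lineage's insertion
#'   rate is \code{multiplier}-fold elevated.
#' @param seed Integer seed used by \code{\link{simulate_turnover}}.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 30e6, chr2 = 20e6),
                       split_my = 90,
                       ingroup_times_ref = c(ing_r1 = 6, ing_r2 = 29,
                                             ing_r3 = 67, ing_r4 = 74),
                       ingroup_times_query = c(ing_q1 = 21, ing_q2 = 70,
                                               ing_q3 = 82),
                       outgroup_times = stats::setNames(
                         seq(96, 160, length.out = 8),
                         sprintf("outg%02d", 1:8)),
                       families_ref = sim_default_families("ref"),
                       families_query = sim_default_families("query"),
                       loss_rate = 1.68e-5,
                       loss_meanlog = log(100), loss_sdlog = 1,
                       loss_min = 20, loss_max = 5000,
                       anc_families = data.frame(
                         family = c("MIR1", "L2A", "L1M1"),
                         consensus_bp = c(260, 2400, 5000),
                         clock_pct_my = c(0.15, 0.15, 0.20),
                         stringsAsFactors = FALSE),
                       anc_repeat_fraction = 0.10,
                       anc_age_range = c(95, 170),
                       div_noise_sd = 1.5,
                       dropout = 0, jitter_bp = 0, jitter_prob = 0.2,
                       min_separation = 20,
                       gain_hotspots = NULL,
                       seed = 1L) {
  cfg <- list(chrom_lengths = chrom_lengths, split_my = split_my,
              ingroup_times_ref = ingroup_times_ref,
              ingroup_times_query = ingroup_times_query,
              outgroup_times = outgroup_times,
              families_ref = families_ref, families_query = families_query,
              loss_rate = loss_rate, loss_meanlog = loss_meanlog,
              loss_sdlog = loss_sdlog, loss_min = loss_min,
              loss_max = loss_max, anc_families = anc_families,
              anc_repeat_fraction = anc_repeat_fraction,
              anc_age_range = anc_age_range, div_noise_sd = div_noise_sd,
              dropout = dropout, jitter_bp = jitter_bp,
              jitter_prob = jitter_prob,
              min_separation = min_separation,
              gain_hotspots = gain_hotspots, seed = seed)
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  for (tv in list(ingroup_times_ref, ingroup_times_query))
    if (length(tv) && (any(diff(tv) <= 0) || any(tv <= 0) ||
                         any(tv >= split_my)))
      stop("ingroup times must be increasing and inside (0, split_my)")
  if (any(outgroup_times <= split_my))
    stop("outgroup times must exceed split_my")
  if (loss_rate < 0 || dropout < 0 || dropout > 1)
    stop("invalid rate or dropout")
  structure(cfg, class = "sim_config")
}

# truncated lognormal deletion lengths
rdel_len <- function(n, cfg) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- round(stats::rlnorm(max(n, 100), cfg$loss_meanlog, cfg$loss_sdlog))
    out <- c(out, x[x >= cfg$loss_min & x <= cfg$loss_max])
  }
  out[seq_len(n)]
}

# draw family-structured gains for one lineage over total bp L
draw_gains <- function(fams, L, rate_scale = 1) {
  rows <- lapply(seq_len(nrow(fams)), function(i) {
    f <- fams[i, ]
    mean_len <- 0.75 * f$consensus_bp
    n <- stats::rpois(1, rate_scale * f$gain_fraction * L / mean_len)
    if (n == 0) return(NULL)
    data.frame(family = f$family,
               length = round(f$consensus_bp *
                                stats::runif(n, 0.5, 1)),
               time_my = stats::runif(n, f$t_start, f$t_end),
               clock = f$clock_pct_my, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) out <- data.frame(family = character(), length = numeric(),
                                      time_my = numeric(), clock = numeric())
  out
}

# place items with the given footprints disjointly (with separation `sep`)
# inside `segments` (ivl df); returns a data.frame with the anc position and
# owning chromosome per item (NA where an item was dropped because its
# segment overflowed)
place_in_segments <- function(foot, segments, sep) {
  m <- length(foot)
  out <- data.frame(pos = rep(NA_real_, m), chrom = rep(NA_character_, m),
                    stringsAsFactors = FALSE)
  if (m == 0 || nrow(segments) == 0) return(out)
  seglen <- segments$end - segments$start
  segid <- sample.int(nrow(segments), m, replace = TRUE,
                      prob = seglen / sum(seglen))
  for (s in seq_len(nrow(segments))) {
    idx <- which(segid == s)
    if (!length(idx)) next
    idx <- sample(idx)                     # random order inside the segment
    need <- cumsum(foot[idx] + sep) + sep
    fit <- idx[need <= seglen[s]]
    if (!length(fit)) next
    k <- length(fit)
    free <- seglen[s] - sep - sum(foot[fit] + sep)
    u <- sort(stats::runif(k, 0, free))
    starts <- segments$start[s] + sep + u +
      c(0, cumsum(foot[fit] + sep))[seq_len(k)]
    out$pos[fit] <- floor(starts)
    out$chrom[fit] <- segments$chrom[s]
  }
  out
}

#' Simulate a two-lineage turnover history
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed (defaults to \code{config$seed}); the same seed
#'   reproduces the simulation exactly.
#' @return A \code{turnover_sim} object holding the event table in ancestor
#'   coordinates, ground-truth event intervals in extant coordinates (gains
#'   in their own genome, losses in the partner genome where the DNA
#'   survives) with true epochs, per-genome repeat tables, extant chromosome
#'   lengths, genome names and, when hotspots were planted, the hotspot
#'   regions in extant host coordinates.
#' @export
simulate_turnover <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cfg <- config
  L <- sum(cfg$chrom_lengths)
  Tsplit <- cfg$split_my

  # --- draw events (lengths/times first, positions later) ---
  ev <- list()
  hot <- cfg$gain_hotspots
  hot_regions <- NULL
  hot_bp <- 0
  if (!is.null(hot) && hot$n > 0) {
    # plant disjoint elevated-rate regions on the ancestor
    segs <- ivl(names(cfg$chrom_lengths), 0, as.numeric(cfg$chrom_lengths))
    pl <- place_in_segments(rep(hot$width, hot$n), segs, cfg$min_separation)
    keep <- !is.na(pl$pos)
    hot_regions <- data.frame(chrom = pl$chrom[keep], start = pl$pos[keep],
                              end = pl$pos[keep] + hot$width,
                              stringsAsFactors = FALSE)
    hot_bp <- sum(keep) * hot$width
  }

  for (side in c("ref", "query")) {
    fams <- if (side == "ref") cfg$families_ref else cfg$families_query
    bg_L <- L - if (!is.null(hot) && identical(hot$lineage, side)) hot_bp else 0
    g <- draw_gains(fams, bg_L)
    g$lineage <- if (nrow(g)) side else character(0)
    g$type <- if (nrow(g)) "gain" else character(0)
    g$in_hotspot <- if (nrow(g)) FALSE else logical(0)
    ev[[paste0(side, "_gain")]] <- g
    if (!is.null(hot) && identical(hot$lineage, side) && hot_bp > 0) {
      gh <- draw_gains(fams, hot_bp, rate_scale = hot$multiplier)
      if (nrow(gh)) {
        gh$lineage <- side; gh$type <- "gain"; gh$in_hotspot <- TRUE
        ev[[paste0(side, "_gain_hot")]] <- gh
      }
    }
    nl <- stats::rpois(1, cfg$loss_rate * L * Tsplit)
    if (nl > 0)
      ev[[paste0(side, "_loss")]] <- data.frame(
        family = NA_character_, length = rdel_len(nl, cfg),
        time_my = stats::runif(nl, 0, Tsplit), clock = NA_real_,
        lineage = side, type = "loss", in_hotspot = FALSE,
        stringsAsFactors = FALSE)
  }
  # ancestral repeat copies, shared by descent (placed like events so they
  # stay clear of deletions and can be scored exactly)
  af <- cfg$anc_families
  anc_n <- stats::rpois(1, cfg$anc_repeat_fraction * L /
                          mean(0.75 * af$consensus_bp))
  if (anc_n > 0) {
    fi <- sample.int(nrow(af), anc_n, replace = TRUE)
    ev[["anc_repeat"]] <- data.frame(
      family = af$family[fi],
      length = round(af$consensus_bp[fi] * stats::runif(anc_n, 0.5, 1)),
      time_my = stats::runif(anc_n, cfg$anc_age_range[1], cfg$anc_age_range[2]),
      clock = af$clock_pct_my[fi], lineage = "ancestor", type = "repeat",
      in_hotspot = FALSE, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, ev)
  rownames(ev) <- NULL

  # --- place footprints disjointly on the ancestor ---
  foot <- ifelse(ev$type == "gain", 0, ev$length)
  segs_all <- ivl(names(cfg$chrom_lengths), 0, as.numeric(cfg$chrom_lengths))
  if (!is.null(hot_regions) && nrow(hot_regions)) {
    in_hot <- ev$in_hotspot
    pl <- data.frame(pos = rep(NA_real_, nrow(ev)),
                     chrom = rep(NA_character_, nrow(ev)))
    pl[in_hot, ] <- place_in_segments(foot[in_hot], hot_regions,
                                      cfg$min_separation)
    bg_segs <- ivl_setdiff(segs_all, hot_regions)
    pl[!in_hot, ] <- place_in_segments(foot[!in_hot], bg_segs,
                                       cfg$min_separation)
  } else {
    pl <- place_in_segments(foot, segs_all, cfg$min_separation)
  }
  ev$anc_start <- pl$pos
  ev$chrom <- pl$chrom
  ev <- ev[!is.na(pl$pos), , drop = FALSE]
  ev$anc_end <- ev$anc_start + ifelse(ev$type == "gain", 0, ev$length)
  ev <- ev[order(ev$chrom, ev$anc_start), , drop = FALSE]
  ev$id <- seq_len(nrow(ev))
  rownames(ev) <- NULL

  sim <- structure(list(config = cfg, events = ev,
                        ref_name = "refg", query_name = "qryg"),
                   class = "turnover_sim")
  sim$chrom_lengths <- list(
    ancestor = cfg$chrom_lengths,
    ref = extant_lengths(sim, "ref"),
    query = extant_lengths(sim, "query"))
  sim$truth <- sim_truth(sim)
  sim$repeats <- list(ref = sim_repeat_table(sim, "ref"),
                      query = sim_repeat_table(sim, "query"))
  if (!is.null(hot_regions)) {
    mp <- sim_mapper(sim, hot$lineage)
    sim$hotspot_regions <- data.frame(
      chrom = hot_regions$chrom,
      start = mp(hot_regions$chrom, hot_regions$start),
      end = mp(hot_regions$chrom, hot_regions$end))
  }
  sim
}

# event subset carried by a genome: the lineage's own events, optionally only
# those older than `min_age` (an ingroup that diverged min_age MY ago)
sim_event_ids <- function(sim, lineage, min_age = 0) {
  ev <- sim$events
  if (lineage == "ancestor") return(integer(0))
  ev$id[ev$lineage == lineage & ev$type %in% c("gain", "loss") &
          ev$time_my > min_age]
}

# ancestor -> extant coordinate mapper for the genome defined by event ids
sim_mapper <- function(sim, lineage, min_age = 0, ids = NULL) {
  if (is.null(ids)) ids <- sim_event_ids(sim, lineage, min_age)
  ev <- sim$events[sim$events$id %in% ids, , drop = FALSE]
  tabs <- lapply(split(ev, ev$chrom), function(e) {
    e <- e[order(e$anc_start), ]
    list(p = e$anc_start,
         cum = cumsum(ifelse(e$type == "gain", e$length, -e$length)))
  })
  function(chrom, x) {
    out <- numeric(length(x))
    for (ch in unique(chrom)) {
      i <- chrom == ch
      t <- tabs[[ch]]
      if (is.null(t)) { out[i] <- x[i]; next }
      k <- findInterval(x[i], t$p)
      out[i] <- x[i] + c(0, t$cum)[k + 1]
    }
    out
  }
}

extant_lengths <- function(sim, lineage, min_age = 0, ids = NULL) {
  if (is.null(ids)) ids <- sim_event_ids(sim, lineage, min_age)
  ev <- sim$events[sim$events$id %in% ids, , drop = FALSE]
  delta <- ifelse(ev$type == "gain", ev$length, -ev$length)
  adj <- tapply(delta, factor(ev$chrom, names(sim$config$chrom_lengths)),
                sum, default = 0)
  sim$config$chrom_lengths + as.numeric(adj)
}

# ground-truth events in extant coordinates with true epochs
sim_truth <- function(sim) {
  ev <- sim$events[sim$events$type %in% c("gain", "loss"), , drop = FALSE]
  mref <- sim_mapper(sim, "ref")
  mqry <- sim_mapper(sim, "query")
  host <- ifelse(ev$type == "gain", ev$lineage,
                 ifelse(ev$lineage == "ref", "query", "ref"))
  # a gain's extant interval ends at the mapped anchor (the host mapper puts
  # the inserted material just before it); a loss survives in the partner,
  # whose mapper has no event there, so its interval ends at ext(anc_end).
  # Both cases: [ext - length, ext).
  start <- numeric(nrow(ev)); end <- numeric(nrow(ev))
  for (h in c("ref", "query")) {
    i <- host == h
    m <- if (h == "ref") mref else mqry
    e_end <- m(ev$chrom[i], ifelse(ev$type[i] == "gain",
                                   ev$anc_start[i], ev$anc_end[i]))
    start[i] <- e_end - ev$length[i]
    end[i] <- e_end
  }
  tim_ref <- sim$config$ingroup_times_ref
  tim_qry <- sim$config$ingroup_times_query
  epoch <- ifelse(ev$lineage == "ref",
                  findInterval(ev$time_my, tim_ref) + 1L,
                  findInterval(ev$time_my, tim_qry) + 1L)
  data.frame(id = ev$id, lineage = ev$lineage, type = ev$type,
             family = ev$family, time_my = ev$time_my, epoch = epoch,
             host = host, chrom = ev$chrom, start = start, end = end,
             length = ev$length, in_hotspot = ev$in_hotspot,
             stringsAsFactors = FALSE)
}

# per-genome repeat table: the genome's own gain copies plus ancestral copies
sim_repeat_table <- function(sim, lineage) {
  cfg <- sim$config
  m <- sim_mapper(sim, lineage)
  ev <- sim$events
  own <- ev[ev$lineage == lineage & ev$type == "gain", , drop = FALSE]
  anc <- ev[ev$type == "repeat", , drop = FALSE]
  rows <- rbind(
    if (nrow(own)) {
      e <- m(own$chrom, own$anc_start)
      data.frame(chrom = own$chrom, start = e - own$length, end = e,
                 family = own$family,
                 class = "recent_sim", age = own$time_my,
                 clock = own$clock, stringsAsFactors = FALSE)
    },
    if (nrow(anc)) {
      s <- m(anc$chrom, anc$anc_start)
      data.frame(chrom = anc$chrom, start = s, end = s + anc$length,
                 family = anc$family, class = "ancestral_sim",
                 age = anc$time_my, clock = anc$clock,
                 stringsAsFactors = FALSE)
    })
  if (is.null(rows)) return(data.frame(chrom = character(), start = numeric(),
                                       end = numeric(), family = character(),
                                       class = character(),
                                       pct_div = numeric()))
  rows$pct_div <- pmax(0, pmin(60, rows$clock * rows$age +
                                 stats::rnorm(nrow(rows), 0,
                                              cfg$div_noise_sd)))
  rows <- rows[order(rows$chrom, rows$start),
               c("chrom", "start", "end", "family", "class", "pct_div")]
  rownames(rows) <- NULL
  rows
}

#' @export
print.turnover_sim <- function(x, ...) {
  ev <- x$events
  cat("Simulated turnover history:",
      format(sum(x$config$chrom_lengths), big.mark = ","), "bp ancestor,",
      "split", x$config$split_my, "MY\n")
  for (side in c("ref", "query")) {
    g <- ev$lineage == side & ev$type == "gain"
    l <- ev$lineage == side & ev$type == "loss"
    cat(sprintf("  %s: %d gains (%.2f Mb), %d losses (%.2f Mb)\n",
                if (side == "ref") x$ref_name else x$query_name,
                sum(g), sum(ev$length[g]) / 1e6,
                sum(l), sum(ev$length[l]) / 1e6))
  }
  invisible(x)
}
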