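# UCSC net alignment parsing and chain-block / chain-gap extraction.
#
# A net file arranges the highest-scoring alignment chains hierarchically:
# `net` header lines start a reference chromosome, indented `fill` records are
# chains (one more indent level per nesting step, chains filling the gaps of
# the chain above), and `gap` records are the non-aligning spaces between the
# aligned blocks of a fill. Both record types carry start/size on the
# reference and chromosome/strand/start/size on the query.
#
# Internally all coordinates are 0-based half-open on the forward strand;
# minus-strand query coordinates are converted on read (no sequence is stored,
# so nothing is reverse-complemented). The strand-space query start is kept
# alongside so that writing a parsed net reproduces the input.

#' Parse a UCSC-style net alignment
#'
#' @param x Path to a net file, or a character vector of net-format lines.
#' @param reference,query \code{\link{genome_descriptor}}s for the two genomes.
#'   Every chromosome referenced by the net must exist in them.
#' @return A \code{net_set}: list with the two descriptors, a \code{fills}
#'   data.frame (one row per fill record: chain_id, level with 1 = top,
#'   parent_id, ref_chrom/ref_start/ref_end, query_chrom, orient,
#'   query_start/query_end in forward coordinates) and a \code{gaps}
#'   data.frame of raw gap records attached to their chains.
#' @export
parse_net <- function(x, reference, query) {
  stopifnot(inherits(reference, "genome_descriptor"),
            inherits(query, "genome_descriptor"))
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    readLines(x) else unlist(strsplit(x, "\n", fixed = TRUE))
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(new_net_set(reference, query))

  indent <- nchar(lines) - nchar(sub("^ +", "", lines))
  toks <- strsplit(trimws(lines), " +")
  kind <- vapply(toks, `[`, "", 1L)
  bad <- !(kind %in% c("net", "fill", "gap"))
  if (any(bad))
    stop("malformed net record at line ", lineno[which(bad)[1]],
         ": unknown record type '", kind[which(bad)[1]], "'")

  nfield <- lengths(toks)
  need <- ifelse(kind == "net", 3L, 7L)
  short <- nfield < need
  if (any(short))
    stop("malformed net record at line ", lineno[which(short)[1]],
         ": too few fields")

  num <- function(i, j) {
    v <- suppressWarnings(as.numeric(vapply(toks[i], `[`, "", j)))
    if (anyNA(v))
      stop("malformed net record at line ", lineno[i][which(is.na(v))[1]],
           ": non-numeric coordinate")
    v
  }

  n <- length(lines)
  fills <- vector("list", n)
  gaps <- vector("list", n)
  cur_chrom <- NA_character_
  stack <- integer(0)          # chain_id of fill at each fill-depth
  auto_id <- 0L

  is_rec <- kind != "net"
  t_start <- rep(NA_real_, n); t_size <- rep(NA_real_, n)
  q_start <- rep(NA_real_, n); q_size <- rep(NA_real_, n)
  q_chrom <- rep(NA_character_, n); orient <- rep(NA_character_, n)
  if (any(is_rec)) {
    t_start[is_rec] <- num(which(is_rec), 2L)
    t_size[is_rec] <- num(which(is_rec), 3L)
    q_chrom[is_rec] <- vapply(toks[is_rec], `[`, "", 4L)
    orient[is_rec] <- vapply(toks[is_rec], `[`, "", 5L)
    q_start[is_rec] <- num(which(is_rec), 6L)
    q_size[is_rec] <- num(which(is_rec), 7L)
    ok <- orient[is_rec] %in% c("+", "-")
    if (!all(ok))
      stop("malformed net record at line ", lineno[which(is_rec)[!ok][1]],
           ": orientation must be + or -")
  }

  bad_chrom <- is_rec & !(q_chrom %in% names(query$chrom_sizes))
  if (any(bad_chrom))
    stop("unknown query chromosome '", q_chrom[which(bad_chrom)[1]],
         "' at line ", lineno[which(bad_chrom)[1]])

  # single pass for the hierarchy: record the owning chain and chromosome of
  # every fill/gap line; everything else is assembled vectorised afterwards
  rec_chrom <- rep(NA_character_, n)
  rec_level <- rep(NA_integer_, n)
  rec_chain <- rep(NA_integer_, n)
  rec_parent <- rep(NA_integer_, n)
  has_id <- vapply(toks, function(t) match("id", t[-(1:7)])[1], 0L)
  for (i in seq_len(n)) {
    k <- kind[i]
    if (k == "net") {
      cur_chrom <- toks[[i]][2]
      if (!cur_chrom %in% names(reference$chrom_sizes))
        stop("unknown reference chromosome '", cur_chrom, "' at line ", lineno[i])
      stack <- integer(0)
      next
    }
    if (is.na(cur_chrom))
      stop("malformed net record at line ", lineno[i], ": no net header seen")
    rec_chrom[i] <- cur_chrom
    if (k == "fill") {
      if (indent[i] %% 2L == 0L)
        stop("malformed net record at line ", lineno[i], ": bad fill indent")
      level <- (indent[i] + 1L) %/% 2L
      id <- if (!is.na(has_id[i])) as.integer(toks[[i]][7L + has_id[i] + 1L])
        else { auto_id <- auto_id + 1L; 1000000L + auto_id }
      length(stack) <- level - 1L
      rec_parent[i] <- if (level > 1L) stack[level - 1L] else NA_integer_
      stack[level] <- id
      rec_level[i] <- level
      rec_chain[i] <- id
    } else {                     # gap
      if (indent[i] %% 2L == 1L)
        stop("malformed net record at line ", lineno[i], ": bad gap indent")
      level <- indent[i] %/% 2L
      if (level < 1L || length(stack) < level || is.na(stack[level]))
        stop("malformed net record at line ", lineno[i], ": gap outside fill")
      rec_level[i] <- level
      rec_chain[i] <- stack[level]
    }
  }

  fi <- which(kind == "fill")
  gi <- which(kind == "gap")
  fills <- if (length(fi)) data.frame(
    chain_id = rec_chain[fi], level = rec_level[fi], parent_id = rec_parent[fi],
    ref_chrom = rec_chrom[fi], ref_start = t_start[fi],
    ref_end = t_start[fi] + t_size[fi], query_chrom = q_chrom[fi],
    orient = orient[fi], q_start_strand = q_start[fi], q_size = q_size[fi],
    stringsAsFactors = FALSE) else NULL
  gaps <- if (length(gi)) data.frame(
    chain_id = rec_chain[gi], level = rec_level[gi], ref_chrom = rec_chrom[gi],
    ref_start = t_start[gi], ref_end = t_start[gi] + t_size[gi],
    query_chrom = q_chrom[gi], orient = orient[gi],
    q_start_strand = q_start[gi], q_size = q_size[gi],
    stringsAsFactors = FALSE) else NULL
  nets <- new_net_set(reference, query, fills, gaps)
  validate_net_set(nets)
  nets
}

new_net_set <- function(reference, query, fills = NULL, gaps = NULL) {
  fill_cols <- c("chain_id", "level", "parent_id", "ref_chrom", "ref_start",
                 "ref_end", "query_chrom", "orient", "q_start_strand", "q_size")
  gap_cols <- c("chain_id", "level", "ref_chrom", "ref_start", "ref_end",
                "query_chrom", "orient", "q_start_strand", "q_size")
  if (is.null(fills))
    fills <- as.data.frame(stats::setNames(rep(list(numeric(0)), 10), fill_cols))
  if (is.null(gaps))
    gaps <- as.data.frame(stats::setNames(rep(list(numeric(0)), 9), gap_cols))
  qlen <- query$chrom_sizes
  fwd <- function(df) {
    if (nrow(df) == 0) {
      df$query_start <- numeric(0); df$query_end <- numeric(0); return(df)
    }
    minus <- df$orient == "-"
    qs <- df$q_start_strand; qe <- df$q_start_strand + df$q_size
    df$query_start <- ifelse(minus, qlen[df$query_chrom] - qe, qs)
    df$query_end <- ifelse(minus, qlen[df$query_chrom] - qs, qe)
    df
  }
  structure(list(reference = reference, query = query,
                 fills = fwd(fills), gaps = fwd(gaps)),
            class = "net_set")
}

validate_net_set <- function(nets) {
  f <- nets$fills
  if (nrow(f) == 0) return(invisible(nets))
  if (any(f$ref_end > nets$reference$chrom_sizes[f$ref_chrom]))
    stop("fill extends past reference chromosome end")
  if (any(f$query_end > nets$query$chrom_sizes[f$query_chrom]))
    stop("fill extends past query chromosome end")
  g <- nets$gaps
  if (nrow(g) > 0 && !all(g$chain_id %in% f$chain_id))
    stop("gap record references unknown chain")
  invisible(nets)
}

#' @export
print.net_set <- function(x, ...) {
  cat("net_set:", x$reference$name, "->", x$query$name, "|",
      nrow(x$fills), "fill(s),", nrow(x$gaps), "gap record(s),",
      "max level", if (nrow(x$fills)) max(x$fills$level) else 0, "\n")
  invisible(x)
}

#' Write a net_set back to UCSC net text
#'
#' Emits the same dialect \code{\link{parse_net}} reads; parsing the output
#' reproduces the net_set (round-trip identity).
#'
#' @param nets A \code{net_set}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_net <- function(nets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  f <- nets$fills; g <- nets$gaps
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  emit_fill <- function(id) {
    fr <- f[f$chain_id == id, , drop = FALSE]
    ind <- strrep(" ", 2L * fr$level - 1L)
    writeLines(paste0(ind, "fill ", fmt(fr$ref_start), " ",
                      fmt(fr$ref_end - fr$ref_start), " ", fr$query_chrom, " ",
                      fr$orient, " ", fmt(fr$q_start_strand), " ",
                      fmt(fr$q_size), " id ", id), con)
    kids_g <- g[g$chain_id == id, , drop = FALSE]
    kids_g <- kids_g[order(kids_g$ref_start), , drop = FALSE]
    kids_f <- f[!is.na(f$parent_id) & f$parent_id == id, , drop = FALSE]
    if (nrow(kids_f) == 0 && nrow(kids_g) > 0) {   # leaf chain: emit in bulk
      writeLines(paste0(strrep(" ", 2L * kids_g$level), "gap ",
                        fmt(kids_g$ref_start), " ",
                        fmt(kids_g$ref_end - kids_g$ref_start), " ",
                        kids_g$query_chrom, " ", kids_g$orient, " ",
                        fmt(kids_g$q_start_strand), " ", fmt(kids_g$q_size)),
                 con)
      return(invisible(NULL))
    }
    for (j in seq_len(nrow(kids_g))) {
      gr <- kids_g[j, ]
      writeLines(paste0(strrep(" ", 2L * gr$level), "gap ", fmt(gr$ref_start),
                        " ", fmt(gr$ref_end - gr$ref_start), " ",
                        gr$query_chrom, " ", gr$orient, " ",
                        fmt(gr$q_start_strand), " ", fmt(gr$q_size)), con)
      inside <- kids_f[kids_f$ref_start >= gr$ref_start &
                         kids_f$ref_end <= gr$ref_end, , drop = FALSE]
      for (cid in inside$chain_id[order(inside$ref_start)]) emit_fill(cid)
    }
  }
  for (chrom in unique(f$ref_chrom)) {
    writeLines(paste0("net ", chrom, " ",
                      fmt(nets$reference$chrom_sizes[chrom])), con)
    top <- f[f$ref_chrom == chrom & f$level == 1L, , drop = FALSE]
    for (cid in top$chain_id[order(top$ref_start)]) emit_fill(cid)
  }
  invisible(path)
}

#' Extract chain-blocks and chain-gaps from parsed nets
#'
#' Blocks are the aligned segments of each chain; gaps are the spaces between
#' consecutive blocks of the same chain. Any portion of a gap's reference
#' interval covered by a block of a deeper (lower-ranked) chain is subtracted
#' before the size filter, and the surviving fragments keep their parent gap's
#' chain and query anchor. Gaps shorter than \code{min_gap_bp} on the
#' reference side are dropped; the query-side length is recorded but never
#' filtered on.
#'
#' @param nets A \code{net_set} from \code{\link{parse_net}}.
#' @param min_gap_bp Minimum reference-side gap length retained (default 10).
#' @return List with \code{blocks} (chain_id, level, chrom, ref_start,
#'   ref_end, query_chrom, orient, query_start, query_end) and \code{gaps}
#'   (gap_id, chain_id, level, chrom, ref_start, ref_end, query_chrom, orient,
#'   query_anchor, query_side_length). All query coordinates are forward.
#' @export
extract_features <- function(nets, min_gap_bp = 10) {
  stopifnot(inherits(nets, "net_set"), min_gap_bp >= 0)
  f <- nets$fills; g <- nets$gaps
  qlen <- nets$query$chrom_sizes
  empty_blocks <- data.frame(chain_id = integer(), level = integer(),
                             chrom = character(), ref_start = numeric(),
                             ref_end = numeric(), query_chrom = character(),
                             orient = character(), query_start = numeric(),
                             query_end = numeric(), stringsAsFactors = FALSE)
  empty_gaps <- data.frame(gap_id = integer(), chain_id = integer(),
                           level = integer(), chrom = character(),
                           ref_start = numeric(), ref_end = numeric(),
                           query_chrom = character(), orient = character(),
                           query_anchor = numeric(),
                           query_side_length = numeric(),
                           stringsAsFactors = FALSE)
  if (nrow(f) == 0)
    return(list(blocks = empty_blocks, gaps = empty_gaps))

  per_fill <- lapply(seq_len(nrow(f)), function(i) {
    fr <- f[i, ]
    gg <- g[g$chain_id == fr$chain_id, , drop = FALSE]
    gg <- gg[order(gg$ref_start), , drop = FALSE]
    # block ref intervals: fill span minus its gaps
    bs <- c(fr$ref_start, gg$ref_end)
    be <- c(gg$ref_start, fr$ref_end)
    # strand-space query walk: blocks advance by their width, gaps by q_size
    bw <- be - bs
    gq <- gg$q_size
    qpos <- fr$q_start_strand +
      c(0, cumsum(bw[-length(bw)])) + c(0, cumsum(gq))
    keep <- bw > 0
    blocks <- data.frame(chain_id = fr$chain_id, level = fr$level,
                         chrom = fr$ref_chrom, ref_start = bs[keep],
                         ref_end = be[keep], query_chrom = fr$query_chrom,
                         orient = fr$orient, q_start_strand = qpos[keep],
                         q_size = bw[keep], stringsAsFactors = FALSE)
    ganchor <- fr$q_start_strand + cumsum(bw)[seq_len(nrow(gg))] +
      c(0, cumsum(gq))[seq_len(nrow(gg))]
    gaps <- if (nrow(gg)) data.frame(
      chain_id = fr$chain_id, level = fr$level, chrom = fr$ref_chrom,
      ref_start = gg$ref_start, ref_end = gg$ref_end,
      query_chrom = fr$query_chrom, orient = fr$orient,
      anchor_strand = ganchor, query_side_length = gq,
      stringsAsFactors = FALSE) else NULL
    list(blocks = blocks, gaps = gaps)
  })

  blocks <- do.call(rbind, lapply(per_fill, `[[`, "blocks"))
  minus <- blocks$orient == "-"
  qs <- blocks$q_start_strand; qe <- qs + blocks$q_size
  blocks$query_start <- ifelse(minus, qlen[blocks$query_chrom] - qe, qs)
  blocks$query_end <- ifelse(minus, qlen[blocks$query_chrom] - qs, qe)
  blocks <- blocks[, names(empty_blocks)]

  graw <- do.call(rbind, Filter(Negate(is.null),
                                lapply(per_fill, `[[`, "gaps")))
  if (is.null(graw) || nrow(graw) == 0)
    return(list(blocks = blocks, gaps = empty_gaps))
  minus <- graw$orient == "-"
  graw$query_anchor <- ifelse(
    minus, qlen[graw$query_chrom] - (graw$anchor_strand + graw$query_side_length),
    graw$anchor_strand)

  # subtract deeper chains' blocks from each gap record individually (gaps of
  # nested chains may overlap each other; they must not merge)
  block_cover <- ivl_reduce(ivl(blocks$chrom, blocks$ref_start, blocks$ref_end))
  comp <- ivl_complement(block_cover, nets$reference$chrom_sizes)
  gap_ivl <- ivl(graw$chrom, graw$ref_start, graw$ref_end)
  hit <- GenomicRanges::findOverlaps(as_gr(gap_ivl), as_gr(comp))
  if (length(hit) == 0) return(list(blocks = blocks, gaps = empty_gaps))
  src <- graw[S4Vectors::queryHits(hit), , drop = FALSE]
  cseg <- comp[S4Vectors::subjectHits(hit), , drop = FALSE]
  out <- data.frame(chain_id = src$chain_id, level = src$level,
                    chrom = src$chrom,
                    ref_start = pmax(src$ref_start, cseg$start),
                    ref_end = pmin(src$ref_end, cseg$end),
                    query_chrom = src$query_chrom, orient = src$orient,
                    query_anchor = src$query_anchor,
                    query_side_length = src$query_side_length,
                    stringsAsFactors = FALSE)
  out <- out[out$ref_end - out$ref_start >= min_gap_bp, , drop = FALSE]
  out <- out[order(out$chrom, out$ref_start), , drop = FALSE]
  out <- cbind(gap_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  list(blocks = blocks, gaps = out)
}

#' Keep only reciprocal-best-hit nets
#'
#' A reference chain survives only if its query-side footprint overlaps at
#' least one chain of the reciprocal (query-as-reference) alignment of the
#' same genome pair; everything else is usually segmental duplication and is
#' discarded. The discarded reference footprint is returned as a mask.
#'
#' @param ref_nets \code{net_set}, reference -> query.
#' @param reciprocal_nets \code{net_set}, query -> reference, same genome pair.
#' @return List with \code{nets} (filtered \code{net_set}) and \code{non_rbh}
#'   (data.frame of discarded reference intervals for masking).
#' @export
rbh_filter <- function(ref_nets, reciprocal_nets) {
  stopifnot(inherits(ref_nets, "net_set"), inherits(reciprocal_nets, "net_set"))
  if (ref_nets$query$name != reciprocal_nets$reference$name ||
      ref_nets$reference$name != reciprocal_nets$query$name)
    stop("reciprocal_nets must align the same genome pair in the other direction")
  f <- ref_nets$fills
  if (nrow(f) == 0) return(list(nets = ref_nets, non_rbh = empty_ivl()))
  recip <- reciprocal_nets$fills
  qfoot <- ivl(f$query_chrom, f$query_start, f$query_end)
  rfoot <- if (nrow(recip)) ivl(recip$ref_chrom, recip$ref_start, recip$ref_end)
    else empty_ivl()
  keep <- ivl_hits(qfoot, rfoot)
  dropped <- f[!keep, , drop = FALSE]
  kept <- f[keep, , drop = FALSE]
  gaps <- ref_nets$gaps[ref_nets$gaps$chain_id %in% kept$chain_id, , drop = FALSE]
  strand_cols <- c("chain_id", "level", "parent_id", "ref_chrom", "ref_start",
                   "ref_end", "query_chrom", "orient", "q_start_strand", "q_size")
  out <- new_net_set(ref_nets$reference, ref_nets$query,
                     kept[, strand_cols],
                     gaps[, setdiff(strand_cols, "parent_id")])
  non_rbh <- if (nrow(dropped))
    ivl_reduce(ivl(dropped$ref_chrom, dropped$ref_start, dropped$ref_end))
  else empty_ivl()
  list(nets = out, non_rbh = non_rbh)
}

#' Reference regions outside any net
#'
#' Complement of top-level net coverage within the reference chromosomes,
#' minus assembly gaps; used for masking and for per-genome accounting.
#'
#' @param nets A \code{net_set}.
#' @return data.frame of unnetted intervals (chrom, start, end).
#' @export
unnetted_regions <- function(nets) {
  stopifnot(inherits(nets, "net_set"))
  f <- nets$fills[nets$fills$level == 1L, , drop = FALSE]
  top <- if (nrow(f)) ivl(f$ref_chrom, f$ref_start, f$ref_end) else empty_ivl()
  out <- ivl_complement(top, nets$reference$chrom_sizes)
  ivl_setdiff(out, nets$reference$assembly_gaps)
}
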