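# Emitting simulated genomes as net alignments and on-disk datasets.

# Build net-format lines for the alignment of two genomes derived from the
# simulated ancestor. Each genome is defined by the set of event ids it
# carries (integer(0) = the ancestor itself, as for outgroups). Events
# carried by both genomes are invisible (shared DNA aligns); events carried
# by exactly one produce a chain-gap. Optional noise (outgroup alignments
# only): whole aligned segments drop out with probability `dropout`, and
# block boundaries jitter into flanking gain gaps with exponential mean
# `jitter_bp`.
sim_net_lines <- function(sim, ids_ref, ids_qry, dropout = 0, jitter_bp = 0,
                          jitter_prob = 0.2) {
  ev <- sim$events
  mapR <- sim_mapper(sim, NULL, ids = ids_ref)
  mapQ <- sim_mapper(sim, NULL, ids = ids_qry)
  lenR <- extant_lengths(sim, NULL, ids = ids_ref)
  lenQ <- extant_lengths(sim, NULL, ids = ids_qry)
  vis <- ev[xor(ev$id %in% ids_ref, ev$id %in% ids_qry), , drop = FALSE]
  chunks <- character(0)
  chain <- 0L
  for (ch in names(sim$config$chrom_lengths)) {
    e <- vis[vis$chrom == ch, , drop = FALSE]
    e <- e[order(e$anc_start), , drop = FALSE]
    in_ref <- e$id %in% ids_ref
    is_gain <- e$type == "gain"
    tS <- tZ <- qS <- qZ <- numeric(nrow(e))
    # gains carried by the net's reference genome
    i <- in_ref & is_gain
    tS[i] <- mapR(rep(ch, sum(i)), e$anc_start[i]) - e$length[i]
    tZ[i] <- e$length[i]
    qS[i] <- mapQ(rep(ch, sum(i)), e$anc_start[i]); qZ[i] <- 0
    # deletions carried by the reference (DNA survives only in the query)
    i <- in_ref & !is_gain
    tS[i] <- mapR(rep(ch, sum(i)), e$anc_end[i]); tZ[i] <- 0
    qS[i] <- mapQ(rep(ch, sum(i)), e$anc_start[i]); qZ[i] <- e$length[i]
    # gains carried by the query
    i <- !in_ref & is_gain
    tS[i] <- mapR(rep(ch, sum(i)), e$anc_start[i]); tZ[i] <- 0
    qS[i] <- mapQ(rep(ch, sum(i)), e$anc_start[i]) - e$length[i]
    qZ[i] <- e$length[i]
    # deletions carried by the query (DNA survives in the reference)
    i <- !in_ref & !is_gain
    tS[i] <- mapR(rep(ch, sum(i)), e$anc_start[i]); tZ[i] <- e$length[i]
    qS[i] <- mapQ(rep(ch, sum(i)), e$anc_end[i]); qZ[i] <- 0

    if (dropout > 0 && nrow(e) >= 0) {
      # aligned runs between visible events, in ancestor coordinates
      bs <- c(0, e$anc_end)
      be <- c(e$anc_start, unname(sim$config$chrom_lengths[ch]))
      keep <- be > bs
      bs <- bs[keep]; be <- be[keep]
      drop <- stats::runif(length(bs)) < dropout
      if (any(drop)) {
        dS <- mapR(rep(ch, sum(drop)), bs[drop])
        dq <- mapQ(rep(ch, sum(drop)), bs[drop])
        tS <- c(tS, dS); tZ <- c(tZ, be[drop] - bs[drop])
        qS <- c(qS, dq); qZ <- c(qZ, be[drop] - bs[drop])
      }
    }
    if (jitter_bp > 0) {
      # outgroup blocks spuriously extend into gain gaps (type-1 noise)
      jit <- which(tZ > 0 & qZ == 0)
      if (length(jit)) {
        on1 <- stats::runif(length(jit)) < jitter_prob
        on2 <- stats::runif(length(jit)) < jitter_prob
        d1 <- pmin(round(stats::rexp(length(jit), 1 / jitter_bp)) * on1,
                   floor(tZ[jit] / 2))
        d2 <- pmin(round(stats::rexp(length(jit), 1 / jitter_bp)) * on2,
                   floor((tZ[jit] - d1) / 2))
        tS[jit] <- tS[jit] + d1
        tZ[jit] <- tZ[jit] - d1 - d2
        keep <- tZ > 0 | qZ > 0
        tS <- tS[keep]; tZ <- tZ[keep]; qS <- qS[keep]; qZ <- qZ[keep]
      }
    }
    ord <- order(tS, qS)
    tS <- tS[ord]; tZ <- tZ[ord]; qS <- qS[ord]; qZ <- qZ[ord]
    chain <- chain + 1L
    fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
    chunks <- c(chunks,
                paste0("net ", ch, " ", fmt(lenR[[ch]])),
                paste0(" fill 0 ", fmt(lenR[[ch]]), " ", ch, " + 0 ",
                       fmt(lenQ[[ch]]), " id ", chain),
                if (length(tS))
                  paste0("  gap ", fmt(tS), " ", fmt(tZ), " ", ch, " + ",
                         fmt(qS), " ", fmt(qZ)))
  }
  chunks
}

#' Write a simulated dataset to disk
#'
#' Emits everything the analysis pipeline consumes: chromosome-size tables
#' for every genome, net alignments for the main pair (both directions),
#' host-vs-outgroup nets (with the configured dropout/jitter noise),
#' host-vs-ingroup nets for both lineages' panels, per-genome repeat tables,
#' known lineage-specific repeat BED files (the truly recent copies, playing
#' the role of the curated repeat lists used to estimate type 1 error), the
#' ground-truth event table, and a dataset manifest (JSON).
#'
#' @param sim A \code{turnover_sim}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_sim_data <- function(sim, dir) {
  cfg <- sim$config
  dir.create(file.path(dir, "nets"), recursive = TRUE, showWarnings = FALSE)
  rn <- sim$ref_name; qn <- sim$query_name
  ids_ref <- sim_event_ids(sim, "ref")
  ids_qry <- sim_event_ids(sim, "query")

  sizes <- list()
  sizes[[rn]] <- sim$chrom_lengths$ref
  sizes[[qn]] <- sim$chrom_lengths$query
  for (o in names(cfg$outgroup_times)) sizes[[o]] <- cfg$chrom_lengths
  ing <- rbind(
    data.frame(species = names(cfg$ingroup_times_ref),
               time_my = as.numeric(cfg$ingroup_times_ref), lineage = "ref",
               stringsAsFactors = FALSE),
    data.frame(species = names(cfg$ingroup_times_query),
               time_my = as.numeric(cfg$ingroup_times_query),
               lineage = "query", stringsAsFactors = FALSE))
  ing_ids <- lapply(seq_len(nrow(ing)), function(i)
    sim_event_ids(sim, ing$lineage[i], min_age = ing$time_my[i]))
  for (i in seq_len(nrow(ing)))
    sizes[[ing$species[i]]] <- extant_lengths(sim, NULL, ids = ing_ids[[i]])
  for (g in names(sizes))
    write_chrom_sizes(sizes[[g]], file.path(dir, paste0(g, ".sizes")))

  put_net <- function(lines, ref_g, qry_g)
    writeLines(lines, file.path(dir, "nets", paste0(ref_g, ".", qry_g, ".net")))
  put_net(sim_net_lines(sim, ids_ref, ids_qry), rn, qn)
  put_net(sim_net_lines(sim, ids_qry, ids_ref), qn, rn)
  for (o in names(cfg$outgroup_times)) {
    put_net(sim_net_lines(sim, ids_ref, integer(0), cfg$dropout,
                          cfg$jitter_bp, cfg$jitter_prob), rn, o)
    put_net(sim_net_lines(sim, ids_qry, integer(0), cfg$dropout,
                          cfg$jitter_bp, cfg$jitter_prob), qn, o)
  }
  for (i in seq_len(nrow(ing))) {
    put_net(sim_net_lines(sim, ids_ref, ing_ids[[i]]), rn, ing$species[i])
    put_net(sim_net_lines(sim, ids_qry, ing_ids[[i]]), qn, ing$species[i])
  }

  for (side in c("ref", "query")) {
    g <- if (side == "ref") rn else qn
    rep_tab <- sim$repeats[[side]]
    utils::write.table(rep_tab, file.path(dir, paste0(g, ".repeats.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(rep_tab[rep_tab$class == "recent_sim",
                      c("chrom", "start", "end", "family")],
              file.path(dir, paste0(g, ".lineage_repeats.bed")))
  }
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(ref_name = rn, query_name = qn,
                   outgroups = as.list(cfg$outgroup_times),
                   ingroups_ref = as.list(cfg$ingroup_times_ref),
                   ingroups_query = as.list(cfg$ingroup_times_query),
                   split_my = cfg$split_my, seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
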