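# End-to-end orchestration: from a dataset directory (as written by
# write_sim_data, or assembled by hand in the same layout) through feature
# extraction, ancestral elements, family classification, gap annotation,
# placement, binning, hotspot calling and event dating.

#' Run the full gain/loss pipeline on a dataset directory
#'
#' Expects the layout of \code{\link{write_sim_data}}: \code{dataset.json}
#' naming the genomes and panels, \code{<genome>.sizes} tables,
#' \code{nets/<reference>.<query>.net} alignments, \code{<genome>.repeats.tsv}
#' repeat tables and \code{<genome>.lineage_repeats.bed} known
#' lineage-specific repeat lists.
#'
#' @param dir Dataset directory.
#' @param params Named list overriding stage parameters: \code{min_gap_bp}
#'   (10), \code{window} (200000), \code{min_eligible} (150000),
#'   \code{neighbor_distance} (3), \code{alpha} (0.05), \code{ridge} (1e-6),
#'   \code{depth} (NULL = choose by \code{\link{select_threshold}}),
#'   \code{background} ("query" or "ref": which genome hosts the synthetic
#'   coordinate system).
#' @param outdir Optional directory for serialized stage outputs (BED/TSV
#'   summaries and a JSON manifest).
#' @return A list of class \code{turnover_run} with per-stage results:
#'   \code{features} (per host), \code{elements}, \code{depth},
#'   \code{error_profiles}, \code{classifier}, \code{families},
#'   \code{insertions}, \code{annotations} (per host x method),
#'   \code{cross_tabs}, \code{synthetic} (per method), \code{bins},
#'   \code{gi}, \code{hotspots}, \code{dating}, and \code{manifest}.
#' @export
run_turnover_pipeline <- function(dir, params = list(), outdir = NULL) {
  p <- utils::modifyList(list(min_gap_bp = 10, window = 200000,
                              min_eligible = 150000, neighbor_distance = 3,
                              alpha = 0.05, ridge = 1e-6, depth = NULL,
                              background = "query"), params)
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  rn <- meta$ref_name; qn <- meta$query_name
  desc <- function(g) genome_descriptor(
    g, read_chrom_sizes(file.path(dir, paste0(g, ".sizes"))))
  refd <- desc(rn); qryd <- desc(qn)
  net_of <- function(a, b, da, db)
    parse_net(file.path(dir, "nets", paste0(a, ".", b, ".net")), da, db)

  # --- nets, RBH filtering, feature extraction -------------------------------
  net_rq <- net_of(rn, qn, refd, qryd)
  net_qr <- net_of(qn, rn, qryd, refd)
  rbh_r <- rbh_filter(net_rq, net_qr)
  rbh_q <- rbh_filter(net_qr, net_rq)
  feats <- list(ref = extract_features(rbh_r$nets, p$min_gap_bp),
                query = extract_features(rbh_q$nets, p$min_gap_bp))
  hosts <- c(ref = rn, query = qn)
  descs <- list(ref = refd, query = qryd)

  # --- ancestral elements per host -------------------------------------------
  outg <- names(meta$outgroups)
  elements <- list(); depth <- list(); profiles <- list()
  for (h in c("ref", "query")) {
    blocks <- lapply(outg, function(o) {
      b <- extract_features(net_of(hosts[[h]], o, descs[[h]],
                                   desc(o)), p$min_gap_bp)$blocks
      ivl(b$chrom, b$ref_start, b$ref_end)
    })
    names(blocks) <- outg
    cov <- merge_coverage(blocks)
    lineage_reps <- read_bed(file.path(dir, paste0(hosts[[h]],
                                                   ".lineage_repeats.bed")))
    prof <- error_profile(cov, lineage_reps,
                          ivl(feats[[h]]$blocks$chrom,
                              feats[[h]]$blocks$ref_start,
                              feats[[h]]$blocks$ref_end))
    d <- if (is.null(p$depth)) select_threshold(prof) else p$depth
    profiles[[h]] <- prof
    depth[[h]] <- d
    elements[[h]] <- call_elements(cov, d)
  }

  # --- repeat family classification per host ---------------------------------
  classifier <- list(); families <- list(); insertions <- list()
  for (h in c("ref", "query")) {
    reps <- read_repeats(file.path(dir, paste0(hosts[[h]], ".repeats.tsv")))
    blocks <- ivl(feats[[h]]$blocks$chrom, feats[[h]]$blocks$ref_start,
                  feats[[h]]$blocks$ref_end)
    lab <- label_copies(reps, elements[[h]], blocks)
    fs <- family_stats(reps, elements[[h]], blocks)
    if (nrow(lab) == 0 || length(unique(lab$ancestry_label)) < 2) {
      # degenerate repeat landscape: no discriminant can be trained; fall
      # back to the prior copy labels at family level
      mod <- NULL
      fam <- stats::setNames(
        ifelse(fs$overlap_proportion > 0, "ancestral", "recent"), fs$family)
    } else {
      mod <- fit_family_classifier(lab, ridge = p$ridge)
      fam <- classify_families(mod, fs)
    }
    classifier[[h]] <- mod
    families[[h]] <- fam
    insertions[[h]] <- recent_insertions(reps, names(fam)[fam == "recent"],
                                         feats[[h]]$gaps)
  }

  # --- gap annotation, both methods, both hosts ------------------------------
  annotations <- list(); cross_tabs <- list()
  for (h in c("ref", "query")) {
    partner <- if (h == "ref") qn else rn
    ann_anc <- annotate_gaps_ancestral(feats[[h]]$gaps, elements[[h]],
                                       host = hosts[[h]], partner = partner)
    ann_tx <- annotate_gaps_transposon(feats[[h]]$gaps, insertions[[h]],
                                       host = hosts[[h]], partner = partner)
    annotations[[h]] <- list(ancestral_element = ann_anc,
                             recent_transposon = ann_tx)
    cross_tabs[[h]] <- cross_tabulate_methods(ann_tx, ann_anc)
  }

  # --- placement and hotspot calling on the chosen background ----------------
  bg <- p$background                 # genome hosting the synthetic system
  fg <- if (bg == "query") "ref" else "query"
  synthetic <- list(); bins <- list(); gi <- list(); hotspots <- list()
  bg_masks <- list(descs[[bg]]$assembly_gaps,
                   if (bg == "query") rbh_q$non_rbh else rbh_r$non_rbh)
  for (m in c("ancestral_element", "recent_transposon")) {
    ann_fg <- annotations[[fg]][[m]]
    ann_bg <- annotations[[bg]][[m]]
    carry <- split(ivl(ann_bg$chrom, ann_bg$ref_start, ann_bg$ref_end),
                   ann_bg$label)
    carry$mask <- do.call(rbind, lapply(bg_masks, function(x)
      x[, c("chrom", "start", "end"), drop = FALSE]))
    sg <- place_gaps(ann_fg, descs[[bg]], carry = carry)
    b <- make_bins(sg, p$window, p$min_eligible,
                   masks = sg$carried["mask"])
    cats <- c(sg$categories, sg$carried[setdiff(names(sg$carried), "mask")])
    # every run reports all four species-qualified categories, present or not
    for (lab in paste0(rep(c(rn, qn), each = 2), c("_gain", "_loss")))
      if (is.null(cats[[lab]])) cats[[lab]] <- empty_ivl()
    bt <- tally_annotations(b, cats, p$window)
    synthetic[[m]] <- sg
    bins[[m]] <- bt
    gi[[m]] <- lapply(names(cats), function(cat)
      getis_ord(bt[[paste0("norm_", cat)]], bt$chrom,
                p$neighbor_distance))
    names(gi[[m]]) <- names(cats)
    hotspots[[m]] <- lapply(gi[[m]], call_hotspots, alpha = p$alpha)
  }

  # --- dating (recent-transposon annotations, as in the source analysis) -----
  panel_for <- function(lineage, vs_host) {
    tv <- if (lineage == "ref") meta$ingroups_ref else meta$ingroups_query
    gaps <- lapply(names(tv), function(sp) {
      g <- extract_features(net_of(hosts[[vs_host]], sp, descs[[vs_host]],
                                   desc(sp)), p$min_gap_bp)$gaps
      ivl(g$chrom, g$ref_start, g$ref_end)
    })
    ingroup_panel(names(tv), as.numeric(unlist(tv)), gaps, meta$split_my)
  }
  dating <- list()
  for (lin in c("ref", "query")) {
    partner <- if (lin == "ref") "query" else "ref"
    gl <- paste0(hosts[[lin]], "_gain"); ll <- paste0(hosts[[lin]], "_loss")
    ann_host <- annotations[[lin]]$recent_transposon
    gains <- ann_host[ann_host$label == gl, , drop = FALSE]
    gains <- ivl(gains$chrom, gains$ref_start, gains$ref_end)
    ann_part <- annotations[[partner]]$recent_transposon
    losses <- ann_part[ann_part$label == ll, , drop = FALSE]
    losses <- ivl(losses$chrom, losses$ref_start, losses$ref_end)
    pg <- panel_for(lin, lin)
    pl <- panel_for(lin, partner)
    ag <- assign_epochs_gain(gains, pg)
    al <- assign_epochs_loss(losses, pl)
    dating[[lin]] <- list(gains = ag, losses = al,
                          gain_rates = epoch_rates(ag, pg),
                          loss_rates = epoch_rates(al, pl))
  }

  manifest <- list(
    dataset = normalizePath(dir), params = p,
    genomes = list(reference = rn, query = qn),
    depth = depth,
    gap_bp = lapply(feats, function(f) sum(f$gaps$ref_end - f$gaps$ref_start)),
    block_bp = lapply(feats, function(f)
      sum(f$blocks$ref_end - f$blocks$ref_start)),
    n_recent_families = lapply(families, function(f) sum(f == "recent")))

  run <- structure(list(features = feats, non_rbh = list(ref = rbh_r$non_rbh,
                                                         query = rbh_q$non_rbh),
                        error_profiles = profiles, depth = depth,
                        elements = elements, classifier = classifier,
                        families = families, insertions = insertions,
                        annotations = annotations, cross_tabs = cross_tabs,
                        synthetic = synthetic, bins = bins, gi = gi,
                        hotspots = hotspots, dating = dating,
                        manifest = manifest),
                   class = "turnover_run")
  if (!is.null(outdir)) write_run_outputs(run, outdir)
  run
}

#' @export
print.turnover_run <- function(x, ...) {
  cat("Turnover pipeline run:", x$manifest$genomes$reference, "vs",
      x$manifest$genomes$query, "\n")
  cat("  chain-gap bp:",
      paste(names(x$manifest$gap_bp),
            vapply(x$manifest$gap_bp, function(v)
              sprintf("%.2f Mb", v / 1e6), ""), collapse = ", "), "\n")
  cat("  ancestral-element depth:",
      paste(names(x$depth), unlist(x$depth), sep = "=", collapse = ", "), "\n")
  for (h in names(x$cross_tabs)) {
    cat("  method cross-tab (", h, "-hosted gaps, Mb):\n", sep = "")
    print(round(x$cross_tabs[[h]], 1))
  }
  invisible(x)
}

write_run_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (h in names(run$annotations))
    for (m in names(run$annotations[[h]])) {
      a <- run$annotations[[h]][[m]]
      write_bed(data.frame(chrom = a$chrom, start = a$ref_start,
                           end = a$ref_end, name = a$label),
                file.path(outdir, paste0("annotations_", h, "_", m, ".bed")))
    }
  for (m in names(run$bins))
    utils::write.table(run$bins[[m]],
                       file.path(outdir, paste0("bins_", m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}

#' Score gap annotations against simulated truth
#'
#' @param annotations Annotated gap table for one host genome (one method).
#' @param truth Truth table of a \code{turnover_sim} (\code{sim$truth}).
#' @param host \code{"ref"} or \code{"query"}: which genome hosts the gaps.
#' @param ref_name,query_name Genome labels used in the annotation labels.
#' @return List: \code{truth_bp} planted bp hosted in this genome,
#'   \code{correct_bp} annotated bp overlapping truth with the right label,
#'   and their ratio \code{recovery}.
#' @export
score_gap_annotations <- function(annotations, truth, host,
                                  ref_name = "refg", query_name = "qryg") {
  tr <- truth[truth$host == host, , drop = FALSE]
  # truth labels in this host: its own gains, the partner's losses
  tr$label <- ifelse(tr$type == "gain",
                     paste0(if (host == "ref") ref_name else query_name,
                            "_gain"),
                     paste0(if (host == "ref") query_name else ref_name,
                            "_loss"))
  correct <- 0
  for (lab in unique(tr$label)) {
    a <- annotations[annotations$label == lab, , drop = FALSE]
    t <- tr[tr$label == lab, , drop = FALSE]
    correct <- correct + ivl_overlap_bp(
      ivl(a$chrom, a$ref_start, a$ref_end), t[, c("chrom", "start", "end")])
  }
  tot <- sum(tr$end - tr$start)
  list(truth_bp = tot, correct_bp = correct,
       recovery = if (tot > 0) correct / tot else NA_real_)
}

#' Score epoch assignments against simulated truth
#'
#' Dated events are matched to truth events by interval overlap in the
#' hosting genome.
#'
#' @param assignment Output of \code{\link{assign_epochs_gain}} or
#'   \code{\link{assign_epochs_loss}}.
#' @param truth_events Truth rows for the same lineage/type, with their
#'   \code{host}-genome coordinates and true \code{epoch}.
#' @return Fraction of matched events whose assigned epoch equals the true
#'   epoch.
#' @export
score_epochs <- function(assignment, truth_events) {
  if (nrow(assignment) == 0) return(NA_real_)
  hit <- GenomicRanges::findOverlaps(
    as_gr(assignment[, c("chrom", "start", "end")]),
    as_gr(truth_events[, c("chrom", "start", "end")]))
  qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
  mean(assignment$epoch[qi] == truth_events$epoch[si])
}
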