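test_that("zero rates leave both genomes identical to the ancestor", {
  sim <- simulate_turnover(zero_rate_config())
  expect_equal(nrow(sim$events), 0)
  expect_equal(sim$chrom_lengths$ref, sim$config$chrom_lengths)
  expect_equal(sim$chrom_lengths$query, sim$config$chrom_lengths)
  d <- withr::local_tempdir()
  write_sim_data(sim, d)
  refd <- genome_descriptor("refg", sim$chrom_lengths$ref)
  qryd <- genome_descriptor("qryg", sim$chrom_lengths$query)
  nets <- parse_net(file.path(d, "nets", "refg.qryg.net"), refd, qryd)
  feats <- extract_features(nets)
  expect_equal(nrow(feats$gaps), 0)         # one full-length chain, no gaps
  expect_equal(sum(feats$blocks$ref_end - feats$blocks$ref_start),
               sum(sim$config$chrom_lengths))
})

test_that("the same seed reproduces the simulation exactly", {
  s1 <- simulate_turnover(small_sim_config(77))
  s2 <- simulate_turnover(small_sim_config(77))
  expect_identical(s1$events, s2$events)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$repeats, s2$repeats)
  s3 <- simulate_turnover(small_sim_config(78))
  expect_false(identical(s1$events, s3$events))
})

test_that("event counts follow the configured Poisson intensities", {
  # deletions: rate * L * T expected events, within 3 sqrt(lambda)
  cfg <- small_sim_config(5)
  lambda <- cfg$loss_rate * sum(cfg$chrom_lengths) * cfg$split_my
  counts <- vapply(1:5, function(s) {
    sim <- simulate_turnover(small_sim_config(s))
    sum(sim$events$type == "loss" & sim$events$lineage == "ref")
  }, numeric(1))
  expect_true(all(abs(counts - lambda) < 3 * sqrt(lambda) + 3))
})

test_that("a single planted insertion becomes a single reference chain-gap", {
  fam <- data.frame(family = "solo", consensus_bp = 400, gain_fraction = 3e-4,
                    t_start = 0, t_end = 45, clock_pct_my = 0.3)
  famq <- sim_default_families("query"); famq$gain_fraction <- 0
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), families_ref = fam,
                    families_query = famq, loss_rate = 0,
                    anc_repeat_fraction = 0, seed = 123)
  sim <- simulate_turnover(cfg)
  gains <- sim$events[sim$events$type == "gain", ]
  d <- withr::local_tempdir()
  write_sim_data(sim, d)
  refd <- genome_descriptor("refg", sim$chrom_lengths$ref)
  qryd <- genome_descriptor("qryg", sim$chrom_lengths$query)
  feats <- extract_features(parse_net(file.path(d, "nets", "refg.qryg.net"),
                                      refd, qryd))
  expect_equal(nrow(feats$gaps), nrow(gains))
  expect_equal(sort(feats$gaps$ref_end - feats$gaps$ref_start),
               sort(gains$length))
})

test_that("emitted nets round-trip to the truth bookkeeping", {
  sim <- simulate_turnover(small_sim_config(55))
  d <- withr::local_tempdir()
  write_sim_data(sim, d)
  refd <- genome_descriptor("refg", sim$chrom_lengths$ref)
  qryd <- genome_descriptor("qryg", sim$chrom_lengths$query)
  feats <- extract_features(parse_net(file.path(d, "nets", "refg.qryg.net"),
                                      refd, qryd), min_gap_bp = 0)
  tr <- sim$truth
  # reference-hosted gap bp = reference gains + query losses
  expect_equal(sum(feats$gaps$ref_end - feats$gaps$ref_start),
               sum(tr$length[tr$host == "ref"]))
  # block bp identical in both genomes' nets
  featq <- extract_features(parse_net(file.path(d, "nets", "qryg.refg.net"),
                                      qryd, refd), min_gap_bp = 0)
  expect_equal(sum(feats$blocks$ref_end - feats$blocks$ref_start),
               sum(featq$blocks$ref_end - featq$blocks$ref_start))
  # extant length identity per lineage (the accordion bookkeeping)
  for (lin in c("ref", "query")) {
    own <- sim$chrom_lengths[[lin]]
    expect_equal(sum(own),
                 sum(sim$config$chrom_lengths) +
                   sum(tr$length[tr$lineage == lin & tr$type == "gain"]) -
                   sum(tr$length[tr$lineage == lin & tr$type == "loss"]))
  }
})

test_that("per-copy divergence follows the family clock", {
  # zero noise: a copy inserted t MY ago at clock c diverges by exactly c*t
  cfg <- small_sim_config(60, div_noise_sd = 0)
  sim <- simulate_turnover(cfg)
  reps <- sim$repeats$ref
  gains <- sim$truth[sim$truth$lineage == "ref" & sim$truth$type == "gain", ]
  m <- match(paste(gains$chrom, gains$start),
             paste(reps$chrom, reps$start))
  expect_true(all(!is.na(m)))
  fam <- cfg$families_ref
  expect_equal(reps$pct_div[m],
               fam$clock_pct_my[match(gains$family, fam$family)] *
                 gains$time_my, tolerance = 1e-10)
  # family mean divergence is ordered by activity epoch
  fam_means <- tapply(reps$pct_div, reps$family, mean)
  expect_gt(fam_means[["L1P2"]], fam_means[["AluY1"]])  # old vs young window
  expect_gt(min(fam_means[c("MIR1", "L2A", "L1M1")]) /
              max(0.3, fam_means[["AluY1"]]), 1)        # ancestral oldest
})

test_that("outgroup dropout thins coverage; jitter adds type-1 overlap", {
  cfg <- small_sim_config(91, dropout = 0.3, jitter_bp = 30)
  sim <- simulate_turnover(cfg)
  d <- withr::local_tempdir()
  write_sim_data(sim, d)
  refd <- genome_descriptor("refg", sim$chrom_lengths$ref)
  outd <- genome_descriptor("outg01", sim$config$chrom_lengths)
  fo <- extract_features(parse_net(file.path(d, "nets", "refg.outg01.net"),
                                   refd, outd), min_gap_bp = 0)
  # the outgroup aligns strictly less than the full ancestral complement
  anc_bp <- sum(sim$chrom_lengths$ref) -
    sum(sim$truth$length[sim$truth$lineage == "ref" &
                           sim$truth$type == "gain"])
  out_bp <- sum(fo$blocks$ref_end - fo$blocks$ref_start)
  expect_lt(out_bp, anc_bp)
  # jitter: some outgroup block bp overlaps reference gains
  gains <- sim$truth[sim$truth$host == "ref" & sim$truth$type == "gain", ]
  blocks <- data.frame(chrom = fo$blocks$chrom, start = fo$blocks$ref_start,
                       end = fo$blocks$ref_end)
  ov <- gainloss:::ivl_overlap_bp(blocks, gains[, c("chrom", "start", "end")])
  expect_gt(ov, 0)
})

test_that("10x elevated insertion regions surface as Gi* hotspots", {
  cfg <- sim_config(seed = 314, gain_hotspots = list(
    n = 5, width = 1e6, multiplier = 10, lineage = "ref"))
  sim <- simulate_turnover(cfg)
  expect_equal(nrow(sim$hotspot_regions), 5)
  tr <- sim$truth
  # elevated regions actually carry an elevated share of gain events
  expect_gt(mean(tr$in_hotspot[tr$lineage == "ref" & tr$type == "gain"]),
            0.3)
  gains <- tr[tr$host == "ref" & tr$type == "gain",
              c("chrom", "start", "end")]
  bins <- make_bins(sim$chrom_lengths$ref)
  bt <- tally_annotations(bins, list(gain = gains))
  calls <- call_hotspots(getis_ord(bt$norm_gain, bt$chrom))
  reg <- sim$hotspot_regions
  planted <- t(vapply(seq_len(nrow(reg)), function(i)
    range(which(bins$chrom == reg$chrom[i] & bins$end > reg$start[i] &
                  bins$start < reg$end[i])), numeric(2)))
  sc <- region_score(calls$bin[calls$call == "hot"], planted)
  expect_gte(sc$recall, 0.8)
  expect_gte(sc$precision, 0.8)
})
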