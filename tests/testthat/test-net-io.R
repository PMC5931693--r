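refd <- desc1(1000, "refA")
qryd <- desc1(1000, "qryB", "chrQ")

test_that("trivial parses: empty stream and a single fill", {
  empty <- parse_net(character(0), refd, qryd)
  expect_s3_class(empty, "net_set")
  expect_equal(nrow(empty$fills), 0)

  one <- parse_net(c("net chr1 1000", " fill 0 100 chrQ + 0 100"),
                   refd, qryd)
  expect_equal(nrow(one$fills), 1)
  expect_equal(one$fills$ref_start, 0)
  expect_equal(one$fills$ref_end, 100)
  expect_equal(one$fills$level, 1L)
})

test_that("three-level toy net parses to the hand-traced tree", {
  nets <- parse_net(toy_net_text(), refd, qryd)
  f <- nets$fills[order(nets$fills$chain_id), ]
  expect_equal(f$chain_id, c(1L, 2L, 3L))
  expect_equal(f$level, c(1L, 2L, 3L))
  expect_equal(f$parent_id, c(NA, 1L, 2L))
  expect_equal(f$ref_start, c(100, 320, 370))
  expect_equal(f$ref_end, c(900, 440, 390))
  # child fill ref span contained in the parent's gap
  g <- nets$gaps
  expect_true(all(f$ref_start[2] >= g$ref_start[g$chain_id == 1] &
                    f$ref_end[2] <= g$ref_end[g$chain_id == 1]))
})

test_that("malformed or inconsistent input raises informative errors", {
  expect_error(parse_net(c("net chr1 1000", " fill 0 x chrQ + 0 100"),
                         refd, qryd), "line 2")
  expect_error(parse_net(c("net chrZ 1000"), refd, qryd), "chrZ")
  expect_error(parse_net(c("net chr1 1000", " fill 0 100 chrZ + 0 100"),
                         refd, qryd), "chrZ")
  expect_error(parse_net(c("net chr1 1000", " bogus 1 2"), refd, qryd),
               "bogus")
})

test_that("write_net / parse_net round-trips a nested net", {
  nets <- parse_net(toy_net_text(), refd, qryd)
  path <- withr::local_tempfile()
  write_net(nets, path)
  again <- parse_net(path, refd, qryd)
  expect_equal(again$fills[order(again$fills$chain_id), ],
               nets$fills[order(nets$fills$chain_id), ],
               ignore_attr = TRUE)
  expect_equal(again$gaps[order(again$gaps$chain_id, again$gaps$ref_start), ],
               nets$gaps[order(nets$gaps$chain_id, nets$gaps$ref_start), ],
               ignore_attr = TRUE)
})

test_that("extract_features conserves bp per chain and filters small gaps", {
  nets <- parse_net(toy_net_text(), refd, qryd)
  feats <- extract_features(nets, min_gap_bp = 10)
  # per chain: blocks plus (pre-subtraction) gap records tile the fill span
  for (id in nets$fills$chain_id) {
    fill <- nets$fills[nets$fills$chain_id == id, ]
    b <- feats$blocks[feats$blocks$chain_id == id, ]
    g <- nets$gaps[nets$gaps$chain_id == id, ]
    covered <- sum(b$ref_end - b$ref_start) + sum(g$ref_end - g$ref_start)
    expect_equal(covered, fill$ref_end - fill$ref_start)
    expect_equal(b$ref_end - b$ref_start, b$query_end - b$query_start)
  }
  # gap of 9 bp is excluded
  toy <- parse_net(c("net chr1 1000",
                     " fill 0 109 chrQ + 0 100",
                     "  gap 50 9 chrQ + 50 0"), refd, qryd)
  expect_equal(nrow(extract_features(toy, 10)$gaps), 0)
  expect_equal(nrow(extract_features(toy, 9)$gaps), 1)
  # a chain with no gap records yields blocks tiling its span and no gaps
  solid <- parse_net(c("net chr1 1000", " fill 10 200 chrQ + 0 200"),
                     refd, qryd)
  fs <- extract_features(solid)
  expect_equal(nrow(fs$gaps), 0)
  expect_equal(fs$blocks$ref_start, 10)
  expect_equal(fs$blocks$ref_end, 210)
})

test_that("gap regions covered by deeper chains are subtracted (bitmap oracle)", {
  # parent gap [300,350); child chain block covers [310,330)
  txt <- c("net chr1 1000",
           " fill 100 400 chrQ + 0 350 id 1",
           "  gap 300 50 chrQ + 200 0",
           "   fill 310 20 chrQ + 500 20 id 2")
  nets <- parse_net(txt, refd, qryd)
  feats <- extract_features(nets, min_gap_bp = 10)
  g1 <- feats$gaps[feats$gaps$chain_id == 1, ]
  # oracle: per-base subtraction of all blocks from the raw gap
  raw_gap <- iv1(300, 350)
  blocks <- feats$blocks[, c("chrom", "ref_start", "ref_end")]
  names(blocks) <- c("chrom", "start", "end")
  keep <- bitmap(raw_gap, 1000) & !bitmap(blocks, 1000)
  expect_equal(sum(g1$ref_end - g1$ref_start), sum(keep))
  expect_equal(nrow(g1), 2)          # two fragments, [300,310) and [330,350)
  expect_setequal(g1$ref_start, c(300, 330))
  # fragments inherit the parent gap's chain and anchor
  expect_true(all(g1$query_anchor == 200))
})

test_that("minus-strand query coordinates are converted to forward", {
  txt <- c("net chr1 1000",
           " fill 0 100 chrQ - 200 100",
           "  gap 40 20 chrQ - 230 0")
  nets <- parse_net(txt, refd, qryd)
  f <- nets$fills
  expect_equal(f$query_start, 1000 - 300)
  expect_equal(f$query_end, 1000 - 200)
  feats <- extract_features(nets, min_gap_bp = 10)
  expect_equal(feats$blocks$ref_end - feats$blocks$ref_start,
               feats$blocks$query_end - feats$blocks$query_start)
  # blocks walk the query strand backwards in forward coordinates
  b <- feats$blocks[order(feats$blocks$ref_start), ]
  expect_true(all(diff(b$query_start) < 0))
})

test_that("rbh_filter keeps reciprocal hits and masks the rest", {
  txt <- c("net chr1 1000",
           " fill 0 100 chrQ + 0 100 id 1",
           " fill 500 100 chrQ + 600 100 id 2")
  nets <- parse_net(txt, refd, qryd)
  # perfect reciprocity: mirror alignment
  mirror <- parse_net(c("net chrQ 1000",
                        " fill 0 100 chr1 + 0 100 id 1",
                        " fill 600 100 chr1 + 500 100 id 2"), qryd, refd)
  out <- rbh_filter(nets, mirror)
  expect_equal(nrow(out$nets$fills), 2)
  expect_equal(nrow(out$non_rbh), 0)
  # vacuous reciprocal: everything dropped, mask covers all netted bases
  none <- parse_net(character(0), qryd, refd)
  out2 <- rbh_filter(nets, none)
  expect_equal(nrow(out2$nets$fills), 0)
  expect_equal(sum(out2$non_rbh$end - out2$non_rbh$start), 200)
  # chain 2 maps to query [600,700) but the reciprocal only covers [0,100):
  # discarded, per a query-coordinate set intersection oracle
  partial <- parse_net(c("net chrQ 1000", " fill 0 100 chr1 + 0 100 id 9"),
                       qryd, refd)
  out3 <- rbh_filter(nets, partial)
  expect_equal(out3$nets$fills$chain_id, 1L)
  expect_equal(out3$non_rbh$start, 500)
  expect_equal(out3$non_rbh$end, 600)
  # mismatched genome pair
  expect_error(rbh_filter(nets, nets), "genome pair")
})

test_that("unnetted_regions is the masked complement of top-level cover", {
  gapd <- desc1(1000, "refA", gaps = iv1(0, 50))
  nets <- parse_net(c("net chr1 1000", " fill 100 800 chrQ + 0 800"),
                    gapd, qryd)
  out <- unnetted_regions(nets)
  expect_equal(out$start, c(50, 900))
  expect_equal(out$end, c(100, 1000))
  # full coverage -> empty
  full <- parse_net(c("net chr1 1000", " fill 0 1000 chrQ + 0 1000"),
                    refd, qryd)
  expect_equal(nrow(unnetted_regions(full)), 0)
  # no nets -> whole chromosome minus assembly gaps
  none <- parse_net(character(0), gapd, qryd)
  out2 <- unnetted_regions(none)
  expect_equal(sum(out2$end - out2$start), 950)
})

test_that("sibling fill spans at a level never overlap in parsed toy nets", {
  nets <- parse_net(c("net chr1 1000",
                      " fill 0 300 chrQ + 0 300 id 1",
                      " fill 400 300 chrQ + 400 300 id 2"), refd, qryd)
  f <- nets$fills[nets$fills$level == 1, ]
  f <- f[order(f$ref_start), ]
  expect_true(all(f$ref_start[-1] >= f$ref_end[-nrow(f)]))
})
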