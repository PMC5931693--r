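mk_repeats <- function(start, end, family = "famA", pct = 10,
                       class = "LINE") {
  data.frame(copy_id = seq_along(start), chrom = "chr1", start = start,
             end = end, family = family, repeat_class = class,
             pct_div = pct, stringsAsFactors = FALSE)
}

test_that("copies are labelled by >=1 bp overlap with elements or blocks", {
  reps <- mk_repeats(c(10, 200, 390), c(50, 240, 420))
  elements <- iv1(0, 60)
  blocks <- iv1(400, 500)
  lab <- label_copies(reps, elements, blocks)
  expect_equal(lab$ancestry_label, c("ancestral", "recent", "ancestral"))
  # family overlap feature is the family-level bp proportion, broadcast
  fs <- family_stats(reps, elements, blocks)
  expect_equal(unique(lab$family_overlap), fs$overlap_proportion)
  expect_equal(fs$overlap_proportion, (40 + 0 + 20) / (40 + 40 + 30))
})

test_that("label counts equal a brute-force intersection oracle", {
  withr::local_seed(42)
  reps <- mk_repeats(start <- sort(sample(0:900, 20)) * 1, start + 30,
                     family = sample(letters[1:4], 20, replace = TRUE))
  elements <- iv1(c(100, 500), c(220, 640))
  blocks <- iv1(800, 900)
  lab <- label_copies(reps, elements, blocks)
  support <- bitmap(rbind(elements, blocks), 1000)
  oracle <- vapply(seq_len(20), function(i)
    any(support[(reps$start[i] + 1):reps$end[i]]), TRUE)
  expect_equal(lab$ancestry_label == "ancestral", oracle)
})

test_that("well-separated classes train to 100% accuracy", {
  withr::local_seed(7)
  n <- 150
  cp <- data.frame(
    pct_div = c(rnorm(n, 5, 2), rnorm(n, 30, 3)),
    family_overlap = c(rnorm(n, 0.05, 0.03), rnorm(n, 0.9, 0.04)),
    ancestry_label = rep(c("recent", "ancestral"), each = n))
  m <- fit_family_classifier(cp)
  pred <- predict(m, cp[, 1:2])
  expect_equal(mean(pred == cp$ancestry_label), 1)
  # agreement with an independent reference implementation
  ml <- MASS::lda(cp[, 1:2], grouping = cp$ancestry_label)
  expect_equal(pred, as.character(predict(ml, cp[, 1:2])$class))
})

test_that("projection equals the closed form for a diagonal-covariance toy", {
  cp <- data.frame(
    pct_div = c(0, 4, 2, 2, 10, 14, 12, 12),
    family_overlap = c(0, 0, -1, 1, 5, 5, 4, 6),
    ancestry_label = rep(c("recent", "ancestral"), each = 4))
  m <- fit_family_classifier(cp)
  # pooled covariance is diag(8/3, 2/3); mu difference is (10, 5)
  expect_equal(unname(m$cov), diag(c(8 / 3, 2 / 3)))
  expect_equal(unname(m$weights), c(10 / (8 / 3), 5 / (2 / 3)))
})

test_that("degenerate geometry is rejected", {
  same <- data.frame(pct_div = c(1, 3, 1, 3), family_overlap = c(0, 1, 0, 1),
                     ancestry_label = c("recent", "recent", "ancestral",
                                        "ancestral"))
  expect_error(fit_family_classifier(same), "identical class means")
  # collinear two-point classes: singular pooled covariance, ridge recovers
  sing <- data.frame(pct_div = c(0, 2, 10, 12),
                     family_overlap = c(0, 0.1, 0.3, 0.4),
                     ancestry_label = c("recent", "recent", "ancestral",
                                        "ancestral"))
  expect_error(fit_family_classifier(sing), "ridge")
  m <- fit_family_classifier(sing, ridge = 1e-6)
  expect_equal(m$ridge, 1e-6)
  expect_equal(predict(m, sing[, 1:2]), sing$ancestry_label)
})

test_that("planted family classes are recovered from family means", {
  withr::local_seed(11)
  nfam <- 50
  truth <- rep(c("recent", "ancestral"), length.out = nfam)
  fam_div <- ifelse(truth == "recent", 6, 32) + rnorm(nfam, 0, 1.5)
  fam_ov <- ifelse(truth == "recent", 0.05, 0.92) + rnorm(nfam, 0, 0.03)
  copies <- do.call(rbind, lapply(seq_len(nfam), function(i)
    data.frame(pct_div = rnorm(12, fam_div[i], 1),
               family_overlap = fam_ov[i],
               ancestry_label = truth[i], family = paste0("f", i))))
  m <- fit_family_classifier(copies)
  stats <- data.frame(family = paste0("f", seq_len(nfam)),
                      mean_pct_divergence = fam_div,
                      overlap_proportion = fam_ov)
  cls <- classify_families(m, stats)
  expect_gte(sum(cls == truth), 49)
  # invariance to copy ordering and family renaming
  perm <- sample(nrow(copies))
  m2 <- fit_family_classifier(copies[perm, ])
  expect_equal(m2$weights, m$weights)
  stats2 <- stats
  stats2$family <- paste0("renamed_", stats2$family)
  cls2 <- classify_families(m, stats2)
  expect_equal(unname(cls2), unname(cls))
})

test_that("lineage-specific insertions require a recent family AND a gap hit", {
  reps <- mk_repeats(c(100, 300, 500), c(160, 360, 560),
                     family = c("young", "young", "old"))
  gaps <- data.frame(chrom = "chr1", ref_start = c(150, 540),
                     ref_end = c(200, 600))
  ins <- recent_insertions(reps, "young", gaps)
  expect_equal(ins$start, 100)      # overlaps a gap, recent family
  # copy in a block with no gap overlap excluded; old family excluded
  expect_false(300 %in% ins$start)
  expect_false(500 %in% ins$start)
  # brute-force oracle over a random toy
  withr::local_seed(3)
  reps2 <- mk_repeats(s <- sort(sample(0:950, 25)), s + 20,
                      family = sample(c("young", "old"), 25, replace = TRUE))
  gaps2 <- iv1(c(100, 400, 700), c(150, 460, 820))
  ins2 <- recent_insertions(reps2, "young",
                            data.frame(chrom = gaps2$chrom,
                                       ref_start = gaps2$start,
                                       ref_end = gaps2$end))
  gap_cover <- bitmap(gaps2, 1000)
  oracle <- vapply(seq_len(25), function(i)
    reps2$family[i] == "young" &&
      any(gap_cover[(reps2$start[i] + 1):reps2$end[i]]), TRUE)
  expect_equal(sort(ins2$start), sort(reps2$start[oracle]))
})

test_that("repeat tables round-trip through the TSV reader", {
  tab <- data.frame(chrom = "chr1", start = c(0, 50), end = c(30, 80),
                    family = c("a", "b"), class = c("LINE", "SINE"),
                    pct_div = c(1.5, 22))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_repeats(path)
  expect_equal(back$start, tab$start)
  expect_equal(back$family, tab$family)
  expect_equal(back$pct_div, tab$pct_div)
})

test_that("the RepeatMasker .out layout is read with coordinate conversion", {
  lines <- c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin  end   (left)  repeat  class/family",
    "",
    "  463  11.2  0.0  0.0  chr1      101    200   (800) + AluY1   SINE/Alu  1 100 (0) 1",
    "  239   2.5  0.1  0.0  chr1      501    700   (300) C L1P1    LINE/L1   1 200 (0) 2")
  path <- withr::local_tempfile()
  writeLines(lines, path)
  out <- read_repeats(path, format = "rmout")
  expect_equal(out$start, c(100, 500))     # 1-based inclusive -> half-open
  expect_equal(out$end, c(200, 700))
  expect_equal(out$family, c("AluY1", "L1P1"))
  expect_equal(out$pct_div, c(11.2, 2.5))
})
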