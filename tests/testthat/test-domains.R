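doms <- function(starts, ends, chrom = "chr1", label = "domain") {
  domain_set(data.frame(chrom = chrom, start = starts, end = ends,
                        label = label, stringsAsFactors = FALSE))
}

test_that("domain sets validate labels and non-overlap", {
  expect_error(doms(0, 100, label = "tad"), "label")
  expect_error(doms(c(0, 50), c(100, 150)), "overlap")
  expect_error(doms(10, 10), "start < end")
})

test_that("measure of concordance is 1 on self and symmetric", {
  set.seed(59)
  for (i in 1:5) {
    cuts <- sort(sample(1:99, sample(2:8, 1))) * 1e4
    a <- doms(c(0, cuts), c(cuts, 1e6))
    expect_equal(moc(a, a), 1, tolerance = 1e-12)
  }
  a <- doms(c(0, 100, 200), c(100, 200, 300))
  b <- doms(c(0, 150, 250), c(150, 250, 300))
  expect_equal(moc(a, b), moc(b, a), tolerance = 1e-12)
  # single-domain special case
  expect_equal(moc(doms(0, 500), doms(0, 500)), 1)
  expect_error(moc(doms(0, 100, label = "gap"), doms(0, 100)), "empty")
})

test_that("measure of concordance matches direct hand evaluation on a 3-domain fixture", {
  a <- doms(c(0, 100, 200), c(100, 200, 300))
  b <- doms(c(0, 150, 250), c(150, 250, 300))
  # overlaps: A1/B1=100, A2/B1=50, A2/B2=50, A3/B2=50, A3/B3=50
  s <- 100^2 / (100 * 150) + 50^2 / (100 * 150) + 50^2 / (100 * 100) +
    50^2 / (100 * 100) + 50^2 / (100 * 50)
  expect_equal(moc(a, b), (s - 1) / (sqrt(9) - 1), tolerance = 1e-12)
  # boundary/gap intervals are excluded from the metric
  a2 <- domain_set(rbind(a, data.frame(chrom = "chr1", start = 300,
                                       end = 400, label = "gap")))
  expect_equal(moc(a2, b), moc(a, b), tolerance = 1e-12)
})

test_that("TAD Jaccard handles identical, disjoint and sub-reciprocal sets", {
  a <- doms(c(0, 200), c(100, 300))
  expect_equal(tad_jaccard(a, a, "any"), 1)
  expect_equal(tad_jaccard(a, a, "reciprocal25"), 1)
  b <- doms(c(400, 600), c(500, 700))
  expect_equal(tad_jaccard(a, b, "any"), 0)
  expect_equal(tad_jaccard(a, b, "reciprocal25"), 0)
  # 20% reciprocal overlap: counted by any-mode, rejected by the 25% rule
  x <- doms(0, 100)
  y <- doms(80, 180)
  expect_equal(tad_jaccard(x, y, "any"), 20 / 180, tolerance = 1e-12)
  expect_equal(tad_jaccard(x, y, "reciprocal25"), 0)
  # 30% reciprocal overlap passes the rule
  y2 <- doms(70, 170)
  expect_gt(tad_jaccard(x, y2, "reciprocal25"), 0)
  expect_equal(tad_jaccard(x, y, "any"), tad_jaccard(y, x, "any"))
})

test_that("gap fraction reports per-class percentages by basepair intersection", {
  d <- domain_set(data.frame(
    chrom = "chr1", start = c(0, 100, 300), end = c(100, 300, 400),
    label = c("gap", "domain", "gap")))
  regions <- data.frame(chrom = "chr1", start = c(0, 200), end = c(200, 400),
                        class = c("unique", "repeat"))
  gf <- gap_fraction(d, regions)
  expect_equal(gf$percent_gap[gf$class == "unique"], 100 * 100 / 200)
  expect_equal(gf$percent_gap[gf$class == "repeat"], 100 * 100 / 200)
  all_gap <- domain_set(data.frame(chrom = "chr1", start = 0, end = 400,
                                   label = "gap"))
  expect_equal(gap_fraction(all_gap, regions)$percent_gap, c(100, 100))
  no_gap <- doms(0, 400)
  expect_equal(gap_fraction(no_gap, regions)$percent_gap, c(0, 0))
})

test_that("MAPQ class profile follows the any-overlap rule at the standard cutoffs", {
  ann <- data.frame(chrom = "chr1", start = c(0, 5000), end = c(1000, 6000),
                    class = c("SINE", "SD"))
  segs <- rbind(seg_row("r1", 0L, "chr1", 500, 1500, mapq = 60L),
                seg_row("r1", 1L, "chr1", 2000, 2100, mapq = 60L),
                seg_row("r2", 0L, "chr1", 5200, 5300, mapq = 5L),
                seg_row("r2", 1L, "chr1", 999, 5001, mapq = 30L))
  prof <- mapq_class_profile(segs, ann)
  expect_setequal(prof$class, c("SINE", "SD"))
  sine <- prof[prof$class == "SINE", ]
  # segments 1 (mapq 60) and 4 (mapq 30) overlap SINE by >= 1 bp
  expect_equal(sine$n_segments, 2L)
  expect_equal(sine$pct_mapq_ge_1, 100)
  expect_equal(sine$pct_mapq_ge_60, 50)
  sd <- prof[prof$class == "SD", ]
  # segment 4 spans into SD by exactly 1 bp and counts in both classes
  expect_equal(sd$n_segments, 2L)
  expect_equal(sd$pct_mapq_ge_10, 50)
  # non-increasing across the cutoff ladder
  ladder <- as.numeric(prof[1, paste0("pct_mapq_ge_", c(1, 10, 20, 30, 60))])
  expect_true(all(diff(ladder) <= 0))
  # all high-quality segments give 100% everywhere
  segs60 <- segs
  segs60$mapq <- 60L
  prof60 <- mapq_class_profile(segs60, ann)
  expect_true(all(prof60[, startsWith(names(prof60), "pct_")] == 100))
  # empty class omitted
  ann2 <- rbind(ann, data.frame(chrom = "chr2", start = 0, end = 100,
                                class = "LINE"))
  expect_false("LINE" %in% mapq_class_profile(segs, ann2)$class)
})

test_that("class profile matches brute-force interval intersection on random fixtures", {
  set.seed(61)
  ann <- data.frame(chrom = "chr1",
                    start = seq(0, 9000, by = 1000),
                    end = seq(0, 9000, by = 1000) + sample(200:900, 10),
                    class = rep(c("A", "B"), 5))
  segs <- seg_row("r", 0:49, "chr1",
                  start = sample(0:9500, 50),
                  end = NA)
  segs$ref_end <- segs$ref_start + sample(50:400, 50, replace = TRUE)
  segs$mapq <- sample(c(0L, 5L, 15L, 25L, 45L, 60L), 50, replace = TRUE)
  prof <- mapq_class_profile(segs, ann)
  for (cl in unique(ann$class)) {
    rows <- ann[ann$class == cl, ]
    hit <- sapply(seq_len(nrow(segs)), function(i)
      any(segs$ref_start[i] < rows$end & rows$start < segs$ref_end[i]))
    q <- segs$mapq[hit]
    got <- prof[prof$class == cl, ]
    expect_equal(got$n_segments, sum(hit))
    for (co in c(1, 10, 20, 30, 60))
      expect_equal(got[[paste0("pct_mapq_ge_", co)]], 100 * mean(q >= co))
  }
})
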