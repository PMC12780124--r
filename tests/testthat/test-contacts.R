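make_read_segments <- function(n, read_id = "r1", chrom = "chr1") {
  seg_row(read_id, seq_len(n) - 1L, chrom, start = seq_len(n) * 1e4)
}

test_that("pairwise expansion emits exactly n(n-1)/2 pairs", {
  for (n in c(0:5, 17)) {
    segs <- make_read_segments(max(n, 1))[seq_len(n), , drop = FALSE]
    if (n == 0) segs <- make_read_segments(1)[0, ]
    expect_equal(nrow(expand_pairwise(segs)), choose(n, 2))
  }
})

test_that("pair set equals exhaustive index enumeration", {
  for (n in 2:8) {
    segs <- make_read_segments(n)
    p <- expand_pairwise(segs)
    got <- sort(paste(pmin(p$seg1, p$seg2), pmax(p$seg1, p$seg2)))
    want <- apply(utils::combn(n, 2) - 1L, 2, paste, collapse = " ")
    expect_setequal(got, want)
  }
  expect_error(expand_pairwise(rbind(make_read_segments(2, "a"),
                                     make_read_segments(2, "b"))),
               "single read")
})

test_that("mate order follows the upper-triangle convention", {
  segs <- rbind(seg_row("r", 0L, "chr2", 5e4),
                seg_row("r", 1L, "chr1", 9e4),
                seg_row("r", 2L, "chr1", 1e4, strand = "-"))
  p <- expand_pairwise(segs)
  expect_true(all(p$chrom1 <= p$chrom2))
  cis <- p$chrom1 == p$chrom2
  expect_true(all(p$pos1[cis] <= p$pos2[cis]))
  expect_setequal(p$pair_class, c("cis", "trans"))
  # representative position is 5'-most, strand-aware
  expect_true((1e4 + 100 - 1) %in% c(p$pos1, p$pos2))
})

test_that("unmapped segments flow through expansion and are filtered later", {
  segs <- rbind(seg_row("r", 0L, "chr1", 1e4),
                seg_row("r", 1L, NA_character_, NA, NA, NA, NA),
                seg_row("r", 2L, "chr1", 9e4))
  p <- expand_pairwise(segs)
  expect_equal(nrow(p), 3L)
  expect_equal(sum(is.na(p$pair_class)), 2L)
  fl <- filter_pairs(p, 0L)
  expect_equal(unname(fl$tally["unmapped_mate"]), 2L)
  expect_equal(nrow(fl$pairs), 1L)
})

test_that("pair filtering applies both-mapped and min-MAPQ rules with exact tallies", {
  segs <- rbind(seg_row("r", 0L, "chr1", 1e4, mapq = 0L),
                seg_row("r", 1L, "chr1", 5e4, mapq = 60L))
  p <- expand_pairwise(segs)
  expect_equal(nrow(filter_pairs(p, 1L)$pairs), 0L)  # min mapq 0 < 1
  expect_equal(nrow(filter_pairs(p, 0L)$pairs), 1L)
  set.seed(23)
  segs <- do.call(rbind, lapply(1:40, function(i) {
    n <- sample(2:6, 1)
    s <- make_read_segments(n, paste0("r", i))
    s$mapq <- sample(c(0L, 1L, 10L, 20L, 30L, 60L), n, replace = TRUE)
    drop <- runif(n) < 0.15
    s$chrom[drop] <- NA; s$mapq[drop] <- NA
    s$ref_start[drop] <- NA; s$ref_end[drop] <- NA; s$strand[drop] <- NA
    s
  }))
  p <- pairs_from_segments(segs)
  prev <- NULL
  for (q in c(0L, 1L, 10L, 20L, 30L, 60L)) {
    fl <- filter_pairs(p, q)
    expect_equal(unname(fl$tally["input"]),
                 unname(fl$tally["retained"] + fl$tally["unmapped_mate"] +
                          fl$tally["low_mapq"]))
    keys <- paste(fl$pairs$read_id, fl$pairs$seg1, fl$pairs$seg2)
    if (!is.null(prev)) expect_true(all(keys %in% prev))  # nested sets
    prev <- keys
  }
})

test_that("duplicate marking finds fingerprint groups at the expected rate", {
  set.seed(31)
  base <- do.call(rbind, lapply(1:98, function(i) {
    s <- make_read_segments(sample(2:5, 1), sprintf("u%03d", i))
    s$ref_start <- s$ref_start + sample(1e6, nrow(s))
    s$ref_end <- s$ref_start + 100
    s
  }))
  copy_of <- function(src, new_id) {
    s <- base[base$read_id == src, ]
    s$read_id <- new_id
    s
  }
  segs <- rbind(base, copy_of("u001", "zdup1"), copy_of("u050", "zdup2"))
  dd <- mark_duplicates(segs)
  expect_equal(dd$rate, 0.02)
  expect_setequal(dd$reads$read_id[dd$reads$duplicate], c("zdup1", "zdup2"))
  # representative is first by read_id sort, stable under reordering
  shuffled <- segs[sample(nrow(segs)), ]
  dd2 <- mark_duplicates(shuffled)
  expect_equal(dd2$reads, dd$reads)
  again <- mark_duplicates(segs[segs$read_id %in%
                                  dd$reads$read_id[!dd$reads$duplicate], ])
  expect_equal(again$rate, 0)  # idempotent
})

test_that("distance histogram tallies cis pairs only and sums to 100%", {
  segs <- rbind(seg_row("r", 0L, "chr1", 1000),
                seg_row("r", 1L, "chr1", 51000))
  h <- distance_histogram(expand_pairwise(segs))
  expect_equal(sum(h$count), 1L)
  expect_equal(h$count[h$bin_start <= 50000 & h$bin_end > 50000], 1L)
  only_trans <- expand_pairwise(rbind(seg_row("r", 0L, "chr1", 1e4),
                                      seg_row("r", 1L, "chr2", 1e4)))
  expect_equal(sum(distance_histogram(only_trans)$count), 0L)
  set.seed(37)
  d <- 10^runif(1000, 2.1, 6.9)
  pairs <- data.frame(read_id = "x", seg1 = 0L, seg2 = 1L,
                      chrom1 = "chr1", pos1 = 0, strand1 = "+", mapq1 = 60L,
                      chrom2 = "chr1", pos2 = d, strand2 = "+", mapq2 = 60L,
                      pair_class = "cis", distance = d)
  breaks <- 10^seq(2, 7, by = 0.5)
  h <- distance_histogram(pairs, breaks)
  brute <- sapply(seq_len(length(breaks) - 1), function(i)
    sum(d >= breaks[i] & d < breaks[i + 1]))
  expect_equal(h$count, brute)
  expect_equal(sum(h$percent), 100)
})

test_that("segment statistics use lower-median and mode conventions", {
  segs <- rbind(make_read_segments(2, "a"), make_read_segments(17, "b"),
                make_read_segments(17, "c"))
  st <- segment_stats(segs)
  expect_equal(unname(st$segments_per_read["median"]), 17)
  expect_equal(unname(st$segments_per_read["mode"]), 17)
  one <- make_read_segments(3, "solo")
  st1 <- segment_stats(one)
  expect_equal(unname(st1$segments_per_read[c("mean", "median", "mode")]),
               c(3, 3, 3))
  # lower median on even counts; independent streaming recomputation
  set.seed(41)
  segs <- do.call(rbind, lapply(1:20, function(i)
    make_read_segments(sample(1:10, 1), paste0("r", i))))
  st <- segment_stats(segs)
  counts <- sort(as.integer(table(segs$read_id)))
  expect_equal(unname(st$segments_per_read["median"]),
               counts[floor((length(counts) + 1) / 2)])
  expect_equal(unname(st$segments_per_read["mean"]), mean(counts))
  expect_equal(unname(st$segments_per_read["sd"]), sd(counts))
  expect_error(segment_stats(segs[0, ]), "no segments")
})
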