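phase_read <- function(haps, chrom = "chr1", pos = NULL) {
  n <- length(haps)
  if (is.null(pos)) pos <- seq_len(n) * 1e6
  seg_row("r", seq_len(n) - 1L, chrom, start = pos, end = pos + 500,
          hap = haps)
}

test_that("within-read concordance handles agreement, conflict and eligibility", {
  rc <- read_concordance(phase_read(c(1L, 1L, 1L)))
  expect_true(rc$concordant)
  expect_equal(rc$pair_fraction, 1)
  rc <- read_concordance(phase_read(c(1L, 2L)))
  expect_false(rc$concordant)
  expect_equal(rc$pair_fraction, 0)
  # fewer than two same-chromosome phased segments -> ineligible
  segs <- rbind(phase_read(c(1L, NA))[1:2, ],
                seg_row("r", 2L, "chr2", 1e6, hap = 2L))
  rc <- read_concordance(segs)
  expect_false(rc$eligible)
  expect_true(is.na(rc$pair_fraction))
})

test_that("aggregate concordance equals hand enumeration on a constructed fixture", {
  reads <- list(c(1L, 1L, 1L),          # 3 pairs, 3 agree
                c(1L, 2L),              # 1 pair, 0 agree
                c(1L, 1L, 2L),          # 3 pairs, 1 agrees
                c(2L, 2L),              # 1 pair, 1 agrees
                c(1L, NA, NA))          # ineligible
  segs <- do.call(rbind, lapply(seq_along(reads), function(i) {
    s <- phase_read(reads[[i]])
    s$read_id <- paste0("r", i)
    s
  }))
  sm <- phasing_summary(segs)
  expect_equal(sm$n_eligible_reads, 4L)
  expect_equal(sm$read_concordance, 2 / 4)        # reads 1 and 4 concordant
  expect_equal(sm$pair_concordance, (3 + 0 + 1 + 1) / (3 + 1 + 3 + 1))
})

test_that("imputation follows the 30-Mbp full-concordance rule", {
  # single concordant neighbour within the window
  segs <- phase_read(c(1L, NA), pos = c(1e7, 2e7))
  out <- impute_phase(segs)
  expect_equal(out$segments$haplotype[2], 1L)
  expect_equal(nrow(out$log), 1L)
  # in-window conflict blocks imputation
  segs <- phase_read(c(1L, NA, 2L), pos = c(1e7, 2e7, 2.5e7))
  out <- impute_phase(segs)
  expect_true(is.na(out$segments$haplotype[2]))
  # beyond the window: no evidence
  segs <- phase_read(c(1L, NA), pos = c(1e7, 4.5e7))
  expect_true(is.na(impute_phase(segs)$segments$haplotype[2]))
  # boundary: 29,999,999 in, 30,000,001 out
  segs <- phase_read(c(1L, NA, NA), pos = c(0, 29999999, 30000001))
  out <- impute_phase(segs)
  expect_equal(out$segments$haplotype[2], 1L)
  expect_true(is.na(out$segments$haplotype[3]))
  # evidence must share the chromosome
  segs <- rbind(seg_row("r", 0L, "chr1", 1e6, hap = 1L),
                seg_row("r", 1L, "chr2", 1e6))
  expect_true(is.na(impute_phase(segs)$segments$haplotype[2]))
})

test_that("imputation is single-pass, order-independent and never rewrites originals", {
  # no chaining: the imputed tag at 2e7 is not evidence for 5.5e7
  segs <- phase_read(c(1L, NA, NA), pos = c(1e7, 2e7, 5.5e7))
  out <- impute_phase(segs)
  expect_equal(out$segments$haplotype[2], 1L)
  expect_true(is.na(out$segments$haplotype[3]))
  # originals untouched even amid conflict
  segs <- phase_read(c(1L, 2L, NA), pos = c(1e7, 1.1e7, 1.2e7))
  out <- impute_phase(segs)
  expect_equal(out$segments$haplotype[1:2], c(1L, 2L))
  # order independence
  segs <- phase_read(c(1L, NA, 1L, NA), pos = c(1e6, 2e6, 3e6, 4e6))
  shuffled <- segs[c(3, 1, 4, 2), ]
  a <- impute_phase(segs)$segments
  b <- impute_phase(shuffled)$segments
  b <- b[order(b$segment_index), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("window monotonicity holds in both directions", {
  # imputable at w stays imputable at w' > w when no conflict enters
  segs <- phase_read(c(1L, NA), pos = c(1e6, 5e6))
  for (w in c(5e6, 1e7, 3e7))
    expect_equal(impute_phase(segs, window = w)$segments$haplotype[2], 1L)
  # a larger window can only lose a segment by admitting a conflict
  segs <- phase_read(c(1L, NA, 2L), pos = c(1e6, 5e6, 4e7))
  expect_equal(impute_phase(segs, window = 1e7)$segments$haplotype[2], 1L)
  expect_true(is.na(impute_phase(segs, window = 4e7)$segments$haplotype[2]))
})

test_that("imputation on single-haplotype simulated reads is error-free", {
  ss <- small_sim()
  truth_tags <- truth_alignments(ss$sim$truth, keep_haplotype = TRUE)
  set.seed(5)
  partial <- truth_tags
  hide <- runif(nrow(partial)) > 0.3            # keep ~30% of tags
  partial$haplotype[hide] <- NA_integer_
  out <- impute_phase_all(partial)
  imp <- out$segments
  expect_gt(nrow(out$log), 0)
  expect_equal(sum(imp$haplotype != truth_tags$haplotype, na.rm = TRUE), 0)
  sm <- phasing_summary(partial, imp)
  expect_gt(sm$frac_phased_after, sm$frac_phased_before)
  expect_equal(sm$read_concordance, 1)
  expect_equal(sm$pair_concordance, 1)
})

test_that("phasing summary handles the degenerate extremes", {
  segs <- phase_read(c(NA, NA))
  sm <- phasing_summary(segs)
  expect_equal(sm$frac_phased_before, 0)
  expect_equal(sm$frac_phased_after, 0)
  segs <- phase_read(c(1L, 1L))
  out <- impute_phase(segs)
  expect_equal(nrow(out$log), 0L)  # nothing to impute
  expect_equal(phasing_summary(segs, out$segments)$frac_phased_after, 1)
})
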