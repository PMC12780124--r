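#' Simulation configuration
#'
#' Parameters of the synthetic diploid genome and ground-truth
#' proximity-ligation concatemer generator. Defaults describe a DpnII
#' library at desk scale: segments per read follow a shifted negative
#' binomial with median 17; the PCR duplicate rate is 1.8%; the diploid
#' SNV rate is 1e-3 per bp; cis partner distances decay as a power law
#' with exponent `alpha = 1` and a 5% trans-contact rate.
#'
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param snv_rate Per-bp substitution rate between the two haplotypes.
#' @param enzyme Enzyme (see [enzyme()]); its motif must be palindromic
#'   (all presets are) for the exact-invertibility junction model.
#' @param n_reads Number of concatemer reads to emit.
#' @param nseg_size,nseg_mu Size and mean of the negative binomial whose
#'   1-shifted draw gives segments per read.
#' @param alpha Cis distance-decay exponent (> 0); partner fragments are
#'   drawn with probability proportional to `d^-alpha` over fragment
#'   midpoint distance d to the anchor.
#' @param p_trans Probability that a partner fragment is trans.
#' @param dup_rate PCR duplicate rate used by [inject_duplicates()].
#' @param error_rate Per-base substitution error rate on emitted reads
#'   (default 0; errors break exact digestion invertibility).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 1.5e6, chr2 = 1e6),
                       snv_rate = 1e-3,
                       enzyme = "DpnII",
                       n_reads = 1000L,
                       nseg_size = 8, nseg_mu = 16.5,
                       alpha = 1.0,
                       p_trans = 0.05,
                       dup_rate = 0.018,
                       error_rate = 0) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            !is.null(names(chrom_lengths)),
            snv_rate >= 0, snv_rate <= 1,
            p_trans >= 0, p_trans <= 1,
            dup_rate >= 0, dup_rate < 1,
            error_rate >= 0, error_rate <= 1,
            alpha > 0, n_reads >= 1)
  structure(list(seed = as.integer(seed),
                 chrom_lengths = chrom_lengths, snv_rate = snv_rate,
                 enzyme = enzyme(enzyme), n_reads = as.integer(n_reads),
                 nseg_size = nseg_size, nseg_mu = nseg_mu, alpha = alpha,
                 p_trans = p_trans, dup_rate = dup_rate,
                 error_rate = error_rate),
            class = "sim_config")
}

.random_chrom <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.revcomp <- function(s) {
  # fast base-R reverse complement for A/C/G/T strings
  vapply(strsplit(chartr("ACGT", "TGCA", s), NULL),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Simulate a diploid genome
#'
#' Draws random chromosome sequences (haplotype 1) and derives haplotype 2
#' by substitutions at the configured SNV rate. Fully reproducible from the
#' config seed; substitutions never recreate the reference base.
#'
#' @param config A [sim_config()].
#' @return List with `hap1`, `hap2` (named character vectors of chromosome
#'   sequences; identical coordinates) and `variants` (`data.frame`:
#'   `chrom`, `pos` 0-based, `ref`, `alt`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$chrom_lengths < 1)) stop("zero-length chromosome")
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  hap1 <- vapply(config$chrom_lengths, .random_chrom, character(1))
  hap2 <- hap1
  variants <- list()
  for (ch in names(hap1)) {
    L <- nchar(hap1[[ch]])
    pos <- which(stats::runif(L) < config$snv_rate)  # 1-based
    if (length(pos)) {
      ref <- substring(hap1[[ch]], pos, pos)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
      s <- strsplit(hap2[[ch]], "")[[1]]
      s[pos] <- alt
      hap2[[ch]] <- paste(s, collapse = "")
      variants[[ch]] <- data.frame(chrom = ch, pos = pos - 1L,
                                   ref = ref, alt = unname(alt),
                                   stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(variants)) do.call(rbind, variants)
              else data.frame(chrom = character(0), pos = integer(0),
                              ref = character(0), alt = character(0))
  rownames(variants) <- NULL
  list(hap1 = hap1, hap2 = hap2, variants = variants)
}

# Genomic interval of an emitted segment built from fragment [fs, fe) of a
# palindromic m-mer motif cut at offset co. Junctions reconstitute exactly
# one motif copy, so flanks shift by (m - co) / co at read edges and by
# (m - 2co) on the minus strand.
.truth_interval <- function(fs, fe, strand, m, co, first, last) {
  if (strand == "+") {
    c(if (first) fs + (m - co) else fs,
      if (last) fe - co else fe)
  } else {
    c(if (last) fs + (m - co) else fs + m - 2 * co,
      if (first) fe - co else fe + m - 2 * co)
  }
}

#' Simulate ground-truth proximity-ligation concatemer reads
#'
#' Each read draws a haplotype uniformly, a segment count from the shifted
#' negative binomial, a uniform anchor restriction fragment, and partner
#' fragments that are trans (uniform on another chromosome) with
#' probability `p_trans` or cis with probability proportional to
#' `d^-alpha` over midpoint distance to the anchor (excluding the anchor
#' and its immediate neighbours — the one-fragment minimum-distance
#' floor). Fragments are concatenated in random orientations with exactly
#' one copy of the recognition motif reconstituted at each junction
#' (sticky-end religation), so in silico digestion of an error-free read
#' recovers the truth segment boundaries exactly.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()] (regenerated from the config
#'   if omitted).
#' @return List with `reads` (named character vector of read sequences) and
#'   `truth` (`data.frame`: `read_id`, `segment_index`, `chrom`, `start`,
#'   `end` 0-based half-open genomic, `strand`, `haplotype`,
#'   `read_start`, `read_end` offsets within the read, `duplicate_of` =
#'   `NA`), plus `config`.
#' @export
simulate_concatemers <- function(config, genome = NULL) {
  stopifnot(inherits(config, "sim_config"))
  enz <- config$enzyme
  if (!.is_palindromic(enz))
    stop("the concatemer simulator requires a palindromic recognition motif")
  if (is.null(genome)) genome <- simulate_genome(config)
  m <- nchar(enz$motif); co <- enz$cut_offset
  motif <- enz$motif
  fmaps <- list(digest_reference(genome$hap1, enz),
                digest_reference(genome$hap2, enz))
  haps <- list(genome$hap1, genome$hap2)
  # eligible fragments: internal, longer than the motif, internal neighbours
  frag_info <- lapply(fmaps, function(fm) {
    f <- fm$fragments
    f$mid <- (f$start + f$end) / 2
    elig <- rep(TRUE, nrow(f))
    for (ch in unique(f$chrom)) {
      idx <- which(f$chrom == ch)
      el <- rep(TRUE, length(idx))
      el[c(1, length(idx))] <- FALSE           # chromosome-terminal
      el <- el & (f$end[idx] - f$start[idx]) > m
      nb_len <- f$end[idx] - f$start[idx]
      el[-1] <- el[-1] & nb_len[-length(idx)] >= m      # left neighbour
      el[-length(idx)] <- el[-length(idx)] & nb_len[-1] >= m
      elig[idx] <- el
    }
    f$eligible <- elig
    f
  })
  set.seed(config$seed + 1L)
  reads <- character(config$n_reads)
  ids <- sprintf("sim%05d", seq_len(config$n_reads))
  truth <- vector("list", config$n_reads)
  for (r in seq_len(config$n_reads)) {
    hap <- sample(1:2, 1)
    f <- frag_info[[hap]]
    seqs <- haps[[hap]]
    elig_idx <- which(f$eligible)
    n <- 1L + stats::rnbinom(1, size = config$nseg_size, mu = config$nseg_mu)
    n <- min(n, length(elig_idx))
    for (attempt in 1:50) {
      anchor <- sample(elig_idx, 1)
      picks <- anchor
      if (n > 1L) {
        cis_cand <- elig_idx[f$chrom[elig_idx] == f$chrom[anchor]]
        cis_cand <- cis_cand[abs(cis_cand - anchor) >= 2]  # distance floor
        cis_w <- abs(f$mid[cis_cand] - f$mid[anchor])^(-config$alpha)
        trans_cand <- elig_idx[f$chrom[elig_idx] != f$chrom[anchor]]
        is_trans <- stats::runif(n - 1L) < config$p_trans &
          length(trans_cand) > 0L
        partners <- integer(n - 1L)
        if (any(!is_trans))
          partners[!is_trans] <- cis_cand[sample.int(
            length(cis_cand), sum(!is_trans), replace = TRUE, prob = cis_w)]
        if (any(is_trans))
          partners[is_trans] <- trans_cand[sample.int(
            length(trans_cand), sum(is_trans), replace = TRUE)]
        picks <- c(anchor, partners)
      }
      strands <- sample(c("+", "-"), length(picks), replace = TRUE)
      fs <- f$start[picks]; fe <- f$end[picks]
      cores <- substring(seqs[f$chrom[picks]], fs + (m - co) + 1L, fe - co)
      neg <- strands == "-"
      if (any(neg)) cores[neg] <- .revcomp(cores[neg])
      read_seq <- paste(cores, collapse = motif)
      lens <- nchar(cores)
      junctions <- cumsum(lens[-length(lens)]) +
        (seq_len(length(lens) - 1L) - 1L) * m
      intended <- junctions + co
      intended <- intended[intended > 0 & intended < nchar(read_seq)]
      if (identical(find_cut_sites(read_seq, enz), as.integer(intended)))
        break
      # rare spurious motif across a junction: resample this read
    }
    bounds <- c(0L, as.integer(intended), nchar(read_seq))
    tr <- data.frame(
      read_id = ids[r],
      segment_index = seq_along(picks) - 1L,
      chrom = f$chrom[picks], start = NA_real_, end = NA_real_,
      strand = strands, haplotype = hap,
      read_start = bounds[-length(bounds)], read_end = bounds[-1],
      duplicate_of = NA_character_, stringsAsFactors = FALSE)
    for (k in seq_along(picks)) {
      iv <- .truth_interval(f$start[picks[k]], f$end[picks[k]], strands[k],
                            m, co, first = k == 1L, last = k == length(picks))
      tr$start[k] <- iv[1]; tr$end[k] <- iv[2]
    }
    if (config$error_rate > 0) {
      s <- strsplit(read_seq, "")[[1]]
      hitpos <- which(stats::runif(length(s)) < config$error_rate)
      if (length(hitpos)) {
        s[hitpos] <- vapply(s[hitpos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        read_seq <- paste(s, collapse = "")
      }
    }
    reads[r] <- read_seq
    truth[[r]] <- tr
  }
  names(reads) <- ids
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(reads = reads, truth = truth, config = config)
}

#' Inject PCR duplicates
#'
#' Each read is duplicated with probability `delta`; duplicates get fresh
#' read ids and `duplicate_of` provenance in the truth table, so duplicate
#' marking can be checked against ground truth.
#'
#' @param sim Output of [simulate_concatemers()] (or a list with `reads`
#'   and `truth`).
#' @param delta Duplication probability in `[0, 1)` (defaults to the
#'   config's `dup_rate` when present).
#' @param seed Seed for the duplication draws.
#' @return Same shape as `sim`, with duplicates appended.
#' @export
inject_duplicates <- function(sim, delta = NULL, seed = 1L) {
  if (is.null(delta))
    delta <- if (!is.null(sim$config)) sim$config$dup_rate else 0
  stopifnot(delta >= 0, delta < 1)
  if (delta == 0) return(sim)
  set.seed(as.integer(seed))
  dup <- which(stats::runif(length(sim$reads)) < delta)
  if (!length(dup)) return(sim)
  src_ids <- names(sim$reads)[dup]
  new_ids <- paste0(src_ids, "_dup")
  new_reads <- stats::setNames(sim$reads[dup], new_ids)
  new_truth <- sim$truth[sim$truth$read_id %in% src_ids, , drop = FALSE]
  new_truth$duplicate_of <- new_truth$read_id
  new_truth$read_id <- paste0(new_truth$read_id, "_dup")
  sim$reads <- c(sim$reads, new_reads)
  sim$truth <- rbind(sim$truth, new_truth)
  rownames(sim$truth) <- NULL
  sim
}

#' Segment table from simulator truth
#'
#' Converts truth records into the aligned-segment table an aligner would
#' produce, standing in for real alignment in tests: reference coordinates
#' and strands are the truth values and MAPQ is constant (default 60) or
#' supplied per segment for filter exercises.
#'
#' @param truth Truth `data.frame` from [simulate_concatemers()].
#' @param mapq MAPQ value(s), recycled over segments.
#' @param keep_haplotype Copy the truth haplotype into the table (default
#'   `FALSE`: haplotype column is `NA`, as before phasing).
#' @return Segment table (see [segment_table()]).
#' @export
truth_alignments <- function(truth, mapq = 60L, keep_haplotype = FALSE) {
  segment_table(data.frame(
    read_id = truth$read_id,
    segment_index = truth$segment_index,
    chrom = truth$chrom,
    ref_start = truth$start, ref_end = truth$end,
    strand = truth$strand,
    mapq = as.integer(rep_len(mapq, nrow(truth))),
    haplotype = if (keep_haplotype) truth$haplotype else NA_integer_,
    stringsAsFactors = FALSE))
}

#' Fit a cis distance-decay exponent
#'
#' Estimates the power-law exponent of the cis contact distance
#' distribution by log-log regression of log-binned distance frequencies
#' (counts divided by bin width) against bin-centre distance — the
#' standard decay-curve readout for 3C data. The fit range should sit well
#' inside the chromosome so edge effects do not bend the curve.
#'
#' On simulator output, only anchor-partner distances follow the generative
#' `d^-alpha` law; partner-partner pairs of the same read mix two draws and
#' flatten the apparent decay. `anchor_only = TRUE` restricts the fit to
#' pairs involving segment 0 (the anchor), the estimator that targets the
#' generative exponent.
#'
#' @param pairs Pair table (cis rows are used).
#' @param d_min,d_max Fit range in bp.
#' @param n_bins Number of log-spaced bins.
#' @param anchor_only Restrict to pairs whose lower segment index is 0.
#' @return List with `alpha` (positive decay exponent), `n_pairs`, `fit`
#'   (the `lm` object).
#' @export
fit_decay_exponent <- function(pairs, d_min = 2e3, d_max = 1e5,
                               n_bins = 20L, anchor_only = FALSE) {
  if (anchor_only)
    pairs <- pairs[pmin(pairs$seg1, pairs$seg2) == 0L, , drop = FALSE]
  d <- pairs$distance[!is.na(pairs$pair_class) & pairs$pair_class == "cis"]
  d <- d[d >= d_min & d < d_max]
  if (length(d) < 100L) stop("too few cis pairs in the fit range")
  breaks <- exp(seq(log(d_min), log(d_max), length.out = n_bins + 1L))
  counts <- tabulate(findInterval(d, breaks), nbins = n_bins)
  width <- diff(breaks)
  centre <- sqrt(breaks[-1] * breaks[-length(breaks)])
  ok <- counts > 0
  fit <- stats::lm(log(counts[ok] / width[ok]) ~ log(centre[ok]))
  list(alpha = -unname(stats::coef(fit)[2]), n_pairs = length(d), fit = fit)
}
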