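#' Within-read haplotype concordance
#'
#' Concatemer reads overwhelmingly derive from a single chromosomal copy,
#' so phased segments of one read that map to the same chromosome should
#' share one haplotype. This computes, per read, (a) a boolean concordance
#' (every chromosome's phased segments carry a single haplotype) and (b)
#' the fraction of same-chromosome phased segment pairs that agree. Reads
#' with fewer than two same-chromosome phased segments are ineligible and
#' are excluded from aggregate denominators.
#'
#' @param segments Segment table for one read (with `haplotype` column).
#' @return `data.frame` (one row): `read_id`, `n_segments`, `n_phased`,
#'   `eligible`, `concordant`, `pair_fraction` (`NA` when ineligible),
#'   `n_pairs_same_chrom`, `n_pairs_agree`.
#' @export
read_concordance <- function(segments) {
  segments <- segment_table(segments)
  if (length(unique(segments$read_id)) > 1L)
    stop("read_concordance() takes segments of a single read")
  ph <- segments[!is.na(segments$haplotype) & !is.na(segments$chrom), ]
  n_pairs <- 0L; n_agree <- 0L
  for (ch in unique(ph$chrom)) {
    h <- ph$haplotype[ph$chrom == ch]
    if (length(h) >= 2L) {
      tab <- table(h)
      n_pairs <- n_pairs + choose(length(h), 2)
      n_agree <- n_agree + sum(choose(tab, 2))
    }
  }
  eligible <- n_pairs > 0L
  data.frame(
    read_id = segments$read_id[1],
    n_segments = nrow(segments),
    n_phased = nrow(ph),
    eligible = eligible,
    concordant = if (eligible) n_agree == n_pairs else NA,
    pair_fraction = if (eligible) n_agree / n_pairs else NA_real_,
    n_pairs_same_chrom = as.integer(n_pairs),
    n_pairs_agree = as.integer(n_agree),
    stringsAsFactors = FALSE
  )
}

#' Impute haplotype phase within a concatemer read
#'
#' For each unphased mapped segment, collects the originally phased
#' segments of the same read on the same chromosome whose representative
#' positions lie within `window` bp of the segment's position. If that
#' evidence set has at least `min_evidence` members and all share one
#' haplotype, the segment inherits it; any conflict or lack of in-window
#' evidence leaves it unassigned. Only original tags serve as evidence
#' (single pass, no chaining), and original tags are never modified —
#' a deliberately conservative rule.
#'
#' @param segments Segment table for one read.
#' @param window Evidence window in bp around each unphased segment
#'   (default 3e7, i.e. 30 Mbp; inclusive).
#' @param min_evidence Minimum number of in-window phased segments required
#'   (default 1).
#' @return List with `segments` (tags updated) and `log` (`data.frame`:
#'   `read_id`, `segment_index`, `haplotype`, `n_evidence` — one row per
#'   imputed segment).
#' @export
impute_phase <- function(segments, window = 3e7, min_evidence = 1L) {
  if (window <= 0) stop("window must be > 0")
  segments <- segment_table(segments)
  if (nrow(segments) && length(unique(segments$read_id)) > 1L)
    stop("impute_phase() takes segments of a single read")
  pos <- segment_position(segments)
  phased0 <- !is.na(segments$haplotype)
  log <- list()
  for (k in which(!phased0 & !is.na(segments$chrom))) {
    ev <- which(phased0 & segments$chrom == segments$chrom[k] &
                abs(pos - pos[k]) <= window)
    if (length(ev) >= min_evidence && length(ev) > 0L) {
      h <- unique(segments$haplotype[ev])
      if (length(h) == 1L) {
        segments$haplotype[k] <- h
        log[[length(log) + 1L]] <- data.frame(
          read_id = segments$read_id[k],
          segment_index = segments$segment_index[k],
          haplotype = h, n_evidence = length(ev),
          stringsAsFactors = FALSE)
      }
    }
  }
  log <- if (length(log)) do.call(rbind, log)
         else data.frame(read_id = character(0), segment_index = integer(0),
                         haplotype = integer(0), n_evidence = integer(0),
                         stringsAsFactors = FALSE)
  list(segments = segments, log = log)
}

#' @rdname impute_phase
#' @param segments Segment table for many reads.
#' @export
impute_phase_all <- function(segments, window = 3e7, min_evidence = 1L) {
  segments <- segment_table(segments)
  if (nrow(segments) == 0L)
    return(list(segments = segments,
                log = data.frame(read_id = character(0),
                                 segment_index = integer(0),
                                 haplotype = integer(0),
                                 n_evidence = integer(0))))
  parts <- lapply(split(segments, segments$read_id), impute_phase,
                  window = window, min_evidence = min_evidence)
  out <- do.call(rbind, lapply(parts, `[[`, "segments"))
  log <- do.call(rbind, lapply(parts, `[[`, "log"))
  rownames(out) <- rownames(log) <- NULL
  list(segments = out, log = log)
}

#' Phasing summary before and after imputation
#'
#' Reports the fraction of mapped segments carrying a haplotype tag before
#' and after imputation, and the within-read concordance aggregate both
#' ways (fraction of eligible reads fully concordant; pooled fraction of
#' agreeing same-chromosome phased pairs), since the natural denominator
#' is ambiguous.
#'
#' @param before,after Segment tables (many reads) pre-/post-imputation;
#'   `after` may be omitted to summarise a single state.
#' @return List: `n_segments_mapped`, `frac_phased_before`,
#'   `frac_phased_after`, `n_imputed`, `read_concordance` (fraction of
#'   eligible reads concordant), `pair_concordance` (pooled pair fraction),
#'   `n_eligible_reads`.
#' @export
phasing_summary <- function(before, after = before) {
  before <- segment_table(before)
  after <- segment_table(after)
  mapped_b <- !is.na(before$chrom)
  mapped_a <- !is.na(after$chrom)
  conc <- do.call(rbind, lapply(split(before, before$read_id),
                                read_concordance))
  if (is.null(conc))
    conc <- data.frame(eligible = logical(0), concordant = logical(0),
                       n_pairs_same_chrom = integer(0),
                       n_pairs_agree = integer(0))
  elig <- conc[conc$eligible, , drop = FALSE]
  list(
    n_segments_mapped = sum(mapped_b),
    frac_phased_before = if (any(mapped_b))
      sum(!is.na(before$haplotype[mapped_b])) / sum(mapped_b) else 0,
    frac_phased_after = if (any(mapped_a))
      sum(!is.na(after$haplotype[mapped_a])) / sum(mapped_a) else 0,
    n_imputed = sum(!is.na(after$haplotype)) - sum(!is.na(before$haplotype)),
    read_concordance = if (nrow(elig)) mean(elig$concordant) else NA_real_,
    pair_concordance = if (sum(conc$n_pairs_same_chrom) > 0)
      sum(conc$n_pairs_agree) / sum(conc$n_pairs_same_chrom) else NA_real_,
    n_eligible_reads = nrow(elig)
  )
}
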