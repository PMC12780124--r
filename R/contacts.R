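#' Aligned segment tables
#'
#' Most functions in this package consume a *segment table*: one row per
#' aligned (or unmapped) deconcatenated segment, with columns
#' `read_id`, `segment_index` (0-based within read), `chrom` (`NA` when
#' unmapped), `ref_start`, `ref_end` (0-based half-open reference
#' coordinates), `strand` (`"+"`/`"-"`), `mapq` (0-60, `NA` when unmapped)
#' and optionally `haplotype` (1, 2 or `NA`) and `sequence`.
#' `segment_table()` validates and normalises such a table.
#'
#' @param df A data.frame with at least the columns above.
#' @return The validated data.frame (haplotype column added as `NA` if
#'   absent).
#' @export
segment_table <- function(df) {
  need <- c("read_id", "segment_index", "chrom", "ref_start", "ref_end",
            "strand", "mapq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("segment table lacks column(s): ", paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  mapped <- !is.na(df$chrom)
  if (any(mapped & (is.na(df$ref_start) | is.na(df$ref_end) |
                    df$ref_start >= df$ref_end)))
    stop("mapped segments must have ref_start < ref_end")
  if (any(mapped & !df$strand %in% c("+", "-")))
    stop("mapped segments must have strand '+' or '-'")
  df$mapq[!mapped] <- NA_integer_
  if (!"haplotype" %in% names(df)) df$haplotype <- NA_integer_
  df
}

#' Representative contact position of a segment
#'
#' The 5'-most mapped reference coordinate, strand-aware: `ref_start` on the
#' plus strand, `ref_end - 1` on the minus strand. `NA` for unmapped
#' segments.
#'
#' @param segments A segment table.
#' @return Numeric vector of 0-based positions.
#' @export
segment_position <- function(segments) {
  ifelse(is.na(segments$chrom), NA_real_,
         ifelse(segments$strand == "+", segments$ref_start,
                segments$ref_end - 1))
}

.pair_columns <- c("read_id", "seg1", "seg2", "chrom1", "pos1", "strand1",
                   "mapq1", "chrom2", "pos2", "strand2", "mapq2",
                   "pair_class", "distance")

.empty_pairs <- function() {
  out <- data.frame(read_id = character(0), seg1 = integer(0),
                    seg2 = integer(0), chrom1 = character(0),
                    pos1 = numeric(0), strand1 = character(0),
                    mapq1 = integer(0), chrom2 = character(0),
                    pos2 = numeric(0), strand2 = character(0),
                    mapq2 = integer(0), pair_class = character(0),
                    distance = numeric(0), stringsAsFactors = FALSE)
  out
}

#' Expand the segments of concatemer reads into all pairwise contacts
#'
#' Every read with n segments contributes exactly `choose(n, 2)` contact
#' pairs — all unordered segment pairs, including pairs with unmapped
#' members (these carry `NA` coordinates and are removed later by
#' [filter_pairs()], so rejection tallies stay observable). Mates of fully
#' mapped pairs are ordered by the upper-triangle convention
#' (`chrom1 <= chrom2` by name sort order, `pos1 <= pos2` within a
#' chromosome).
#'
#' @param segments Segment table for one read ([expand_pairwise()]) or many
#'   reads ([pairs_from_segments()]).
#' @return Pair table with columns `read_id`, `seg1`, `seg2`, `chrom1`,
#'   `pos1`, `strand1`, `mapq1`, `chrom2`, `pos2`, `strand2`, `mapq2`,
#'   `pair_class` (`"cis"`, `"trans"` or `NA` when a mate is unmapped) and
#'   `distance` (`|pos2 - pos1|` for cis, `NA` otherwise).
#' @examples
#' segs <- data.frame(read_id = "r", segment_index = 0:2, chrom = "chr1",
#'                    ref_start = c(0, 1e4, 5e4), ref_end = c(500, 10500, 50500),
#'                    strand = "+", mapq = 60L)
#' expand_pairwise(segs)  # 3 pairs
#' @export
expand_pairwise <- function(segments) {
  segments <- segment_table(segments)
  if (length(unique(segments$read_id)) > 1L)
    stop("expand_pairwise() takes segments of a single read; ",
         "use pairs_from_segments() for a full table")
  n <- nrow(segments)
  if (n < 2L) return(.empty_pairs())
  segments <- segments[order(segments$segment_index), ]
  idx <- utils::combn(n, 2L)
  i <- idx[1, ]; j <- idx[2, ]
  pos <- segment_position(segments)
  p <- data.frame(
    read_id = segments$read_id[1],
    seg1 = segments$segment_index[i], seg2 = segments$segment_index[j],
    chrom1 = segments$chrom[i], pos1 = pos[i],
    strand1 = segments$strand[i], mapq1 = segments$mapq[i],
    chrom2 = segments$chrom[j], pos2 = pos[j],
    strand2 = segments$strand[j], mapq2 = segments$mapq[j],
    stringsAsFactors = FALSE
  )
  .finalise_pairs(p)
}

.finalise_pairs <- function(p) {
  # upper-triangle mate ordering for fully mapped pairs
  mapped <- !is.na(p$chrom1) & !is.na(p$chrom2)
  swap <- mapped & (p$chrom1 > p$chrom2 |
                    (p$chrom1 == p$chrom2 & p$pos1 > p$pos2))
  if (any(swap)) {
    sw <- function(a, b) {
      tmp <- p[[a]][swap]
      p[[a]][swap] <<- p[[b]][swap]
      p[[b]][swap] <<- tmp
    }
    sw("chrom1", "chrom2"); sw("pos1", "pos2")
    sw("strand1", "strand2"); sw("mapq1", "mapq2"); sw("seg1", "seg2")
  }
  p$pair_class <- ifelse(!mapped, NA_character_,
                         ifelse(p$chrom1 == p$chrom2, "cis", "trans"))
  p$distance <- ifelse(!is.na(p$pair_class) & p$pair_class == "cis",
                       abs(p$pos2 - p$pos1), NA_real_)
  p[, .pair_columns]
}

#' @rdname expand_pairwise
#' @export
pairs_from_segments <- function(segments) {
  segments <- segment_table(segments)
  if (nrow(segments) == 0L) return(.empty_pairs())
  parts <- split(segments, segments$read_id)
  out <- do.call(rbind, lapply(parts, expand_pairwise))
  rownames(out) <- NULL
  out
}

#' Filter contact pairs on mapping status and MAPQ
#'
#' A pair is retained iff both mates are mapped and
#' `min(mapq1, mapq2) >= mapq_min`. Rejections are tallied per reason;
#' a pair with an unmapped mate counts as `unmapped_mate` regardless of
#' MAPQ.
#'
#' @param pairs Pair table (see [expand_pairwise()]).
#' @param mapq_min Minimum MAPQ for both mates (default 1, the conventional
#'   threshold for contact matrices).
#' @return List with `pairs` (retained rows) and `tally` (named integer:
#'   `input`, `retained`, `unmapped_mate`, `low_mapq`).
#' @export
filter_pairs <- function(pairs, mapq_min = 1L) {
  unmapped <- is.na(pairs$chrom1) | is.na(pairs$chrom2)
  lowq <- !unmapped & (pmin(pairs$mapq1, pairs$mapq2) < mapq_min)
  keep <- !unmapped & !lowq
  list(
    pairs = pairs[keep, , drop = FALSE],
    tally = c(input = nrow(pairs), retained = sum(keep),
              unmapped_mate = sum(unmapped), low_mapq = sum(lowq))
  )
}

#' Mark PCR duplicate reads by alignment fingerprint
#'
#' Reads whose segments have identical ordered alignment fingerprints
#' (chrom, ref_start, strand of every segment, in segment order) form a
#' duplicate group; the first read id by sort order is kept as the
#' representative, the rest are flagged. The result is independent of input
#' row order and idempotent.
#'
#' @param segments Segment table (many reads).
#' @return List with `reads` (`data.frame`: `read_id`, `duplicate`,
#'   `duplicate_of`) and `rate` (flagged / total reads).
#' @export
mark_duplicates <- function(segments) {
  segments <- segment_table(segments)
  if (nrow(segments) == 0L)
    return(list(reads = data.frame(read_id = character(0),
                                   duplicate = logical(0),
                                   duplicate_of = character(0),
                                   stringsAsFactors = FALSE),
                rate = 0))
  segments <- segments[order(segments$read_id, segments$segment_index), ]
  fp <- vapply(split(segments, segments$read_id), function(s)
    paste(s$chrom, s$ref_start, s$strand, sep = ":", collapse = "|"),
    character(1))
  ids <- sort(names(fp))
  fp <- fp[ids]
  rep_of <- tapply(ids, fp, function(g) g[1])
  duplicate_of <- unname(rep_of[fp])
  dup <- duplicate_of != ids
  list(
    reads = data.frame(read_id = ids, duplicate = dup,
                       duplicate_of = if (length(ids))
                         ifelse(dup, duplicate_of, NA_character_)
                       else character(0),
                       stringsAsFactors = FALSE),
    rate = if (length(ids)) mean(dup) else 0
  )
}

#' Distance histogram of intrachromosomal contacts
#'
#' Tallies cis pair distances into (by default log-spaced) bins and reports
#' each bin as a percentage of all intrachromosomal pairs; trans pairs are
#' excluded from numerator and denominator.
#'
#' @param pairs Pair table (normally post-filter).
#' @param breaks Increasing numeric bin edges in bp; pairs outside the range
#'   are dropped. Default: 30 log-spaced bins from 100 bp to 300 Mbp.
#' @return `data.frame` with `bin_start`, `bin_end`, `count`, `percent`
#'   (percentages sum to 100 over non-empty input). Zero cis pairs yields a
#'   zero-count table, not an error.
#' @export
distance_histogram <- function(pairs,
                               breaks = 10^seq(2, log10(3e8), length.out = 31)) {
  d <- pairs$distance[!is.na(pairs$pair_class) & pairs$pair_class == "cis"]
  breaks <- sort(unique(as.numeric(breaks)))
  d <- d[d >= breaks[1] & d < breaks[length(breaks)]]
  counts <- if (length(d))
    tabulate(findInterval(d, breaks), nbins = length(breaks) - 1L)
  else rep(0L, length(breaks) - 1L)
  total <- sum(counts)
  data.frame(
    bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
    count = counts,
    percent = if (total > 0) 100 * counts / total else rep(0, length(counts))
  )
}

.mode_value <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])  # smallest value wins ties
}

.median_lower <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

#' Summaries of segments-per-read and segment-length distributions
#'
#' Computes mean, lower median, mode and standard deviation of (a) the
#' number of segments per read and (b) segment lengths, the two summary
#' panels conventionally reported for concatemer 3C libraries.
#'
#' @param segments Segment table. Lengths use `end - start` (read-space
#'   segments) when present, else `ref_end - ref_start`.
#' @return List with `segments_per_read` and `segment_length`, each a named
#'   vector `mean`, `median`, `mode`, `sd`, plus `n_reads`, `n_segments`.
#' @export
segment_stats <- function(segments) {
  if (nrow(segments) == 0L) stop("no segments")
  per_read <- as.integer(table(segments$read_id))
  len <- if (all(c("start", "end") %in% names(segments)))
    segments$end - segments$start
  else segments$ref_end - segments$ref_start
  summ <- function(x) c(mean = mean(x), median = .median_lower(x),
                        mode = .mode_value(x), sd = stats::sd(x))
  list(segments_per_read = summ(per_read),
       segment_length = summ(len),
       n_reads = length(per_read), n_segments = nrow(segments))
}
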