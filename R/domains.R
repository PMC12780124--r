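#' Labeled genomic domain sets
#'
#' A *domain set* is a data.frame with columns `chrom`, `start`, `end`
#' (0-based half-open) and `label`, where labels come from
#' `{"domain", "boundary", "gap"}` — the three-way classification emitted
#' by TAD callers such as TopDom. Intervals of one chromosome must not
#' overlap.
#'
#' @param df Data.frame with the columns above (missing `label` defaults to
#'   `"domain"`).
#' @return Validated domain-set data.frame.
#' @export
domain_set <- function(df) {
  if (!"label" %in% names(df)) df$label <- "domain"
  need <- c("chrom", "start", "end", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("domain set lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(df$label %in% c("domain", "boundary", "gap")))
    stop("labels must be one of: domain, boundary, gap")
  if (any(df$end <= df$start)) stop("intervals must satisfy start < end")
  for (ch in unique(df$chrom)) {
    x <- df[df$chrom == ch, ]
    x <- x[order(x$start), ]
    if (nrow(x) > 1L && any(x$start[-1] < x$end[-nrow(x)]))
      stop("intervals overlap on chromosome '", ch, "'")
  }
  df
}

.domain_granges <- function(df, label = NULL) {
  if (!is.null(label)) df <- df[df$label %in% label, , drop = FALSE]
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Measure of concordance (MoC) between two TAD partitions
#'
#' Basepair-overlap concordance between the domain-labeled intervals of two
#' TAD sets:
#' \deqn{MoC = \frac{1}{\sqrt{N_A N_B} - 1}\left(\sum_{i,j}
#'   \frac{|A_i \cap B_j|^2}{|A_i|\,|B_j|} - 1\right)}
#' with the convention MoC = 1 when both sets have a single domain.
#' Symmetric in its arguments; MoC(A, A) = 1 for any partition.
#'
#' @param domains_a,domains_b Domain sets (see [domain_set()]); only
#'   intervals labeled `"domain"` enter. The metric presumes both sets
#'   partition the same territory (values below 0 can arise when coverage
#'   differs and signal exactly that).
#' @return Scalar, 1 for identical partitions; in `[0, 1]` for two
#'   partitions of a shared span.
#' @export
moc <- function(domains_a, domains_b) {
  a <- domain_set(domains_a); b <- domain_set(domains_b)
  ga <- .domain_granges(a, "domain")
  gb <- .domain_granges(b, "domain")
  na <- length(ga); nb <- length(gb)
  if (na == 0L || nb == 0L) stop("empty domain set")
  if (na == 1L && nb == 1L) return(1)
  ov <- GenomicRanges::findOverlaps(ga, gb)
  inter <- GenomicRanges::width(GenomicRanges::pintersect(
    ga[S4Vectors::queryHits(ov)], gb[S4Vectors::subjectHits(ov)]))
  wa <- GenomicRanges::width(ga)[S4Vectors::queryHits(ov)]
  wb <- GenomicRanges::width(gb)[S4Vectors::subjectHits(ov)]
  s <- sum(as.numeric(inter)^2 / (as.numeric(wa) * as.numeric(wb)))
  (s - 1) / (sqrt(as.numeric(na) * nb) - 1)
}

#' Basepair Jaccard index between two TAD sets
#'
#' `mode = "any"` is the bedtools-style Jaccard of domain-covered
#' territory: intersection bp / union bp. `mode = "reciprocal25"` first
#' matches domain pairs requiring each to overlap the other by at least 25%
#' of its own length, then reports the Jaccard computed over the territory
#' of matched domains only (unmatched domains contribute only to the
#' union).
#'
#' @param domains_a,domains_b Domain sets; only `"domain"` intervals enter.
#' @param mode `"any"` or `"reciprocal25"`.
#' @param min_reciprocal Reciprocal-overlap fraction for matching (default
#'   0.25).
#' @return Scalar in `[0, 1]`.
#' @export
tad_jaccard <- function(domains_a, domains_b,
                        mode = c("any", "reciprocal25"),
                        min_reciprocal = 0.25) {
  mode <- match.arg(mode)
  a <- domain_set(domains_a); b <- domain_set(domains_b)
  ga <- GenomicRanges::reduce(.domain_granges(a, "domain"))
  gb <- GenomicRanges::reduce(.domain_granges(b, "domain"))
  union_bp <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::union(ga, gb))))
  if (union_bp == 0) return(0)
  if (mode == "any") {
    inter_bp <- sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(ga, gb))))
    return(inter_bp / union_bp)
  }
  ga <- .domain_granges(a, "domain")
  gb <- .domain_granges(b, "domain")
  ov <- GenomicRanges::findOverlaps(ga, gb)
  inter <- as.numeric(GenomicRanges::width(GenomicRanges::pintersect(
    ga[S4Vectors::queryHits(ov)], gb[S4Vectors::subjectHits(ov)])))
  wa <- as.numeric(GenomicRanges::width(ga)[S4Vectors::queryHits(ov)])
  wb <- as.numeric(GenomicRanges::width(gb)[S4Vectors::subjectHits(ov)])
  matched <- inter >= min_reciprocal * wa & inter >= min_reciprocal * wb
  ma <- unique(S4Vectors::queryHits(ov)[matched])
  mb <- unique(S4Vectors::subjectHits(ov)[matched])
  inter_bp <- sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(ga[ma]), GenomicRanges::reduce(gb[mb])))))
  inter_bp / union_bp
}

#' Gap fraction per annotation class
#'
#' For each region class, the percentage of its basepairs covered by
#' gap-labeled intervals of a TAD set — a measure of how much of a genome
#' class the TAD caller could not assign.
#'
#' @param domains Domain set (the `"gap"` intervals are used).
#' @param regions Data.frame `chrom`, `start`, `end`, `class` (0-based
#'   half-open labeled intervals).
#' @return `data.frame` with `class`, `total_bp`, `gap_bp`, `percent_gap`.
#' @export
gap_fraction <- function(domains, regions) {
  domains <- domain_set(domains)
  gaps <- GenomicRanges::reduce(.domain_granges(domains, "gap"))
  out <- lapply(unique(regions$class), function(cl) {
    r <- regions[regions$class == cl, , drop = FALSE]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      r$chrom, IRanges::IRanges(start = r$start + 1, end = r$end)))
    total <- sum(as.numeric(GenomicRanges::width(gr)))
    gap_bp <- sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(gr, gaps))))
    data.frame(class = cl, total_bp = total, gap_bp = gap_bp,
               percent_gap = if (total > 0) 100 * gap_bp / total else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' MAPQ profile of aligned segments per annotation class
#'
#' A mapped segment counts toward a class if it overlaps any interval of
#' that class by at least one basepair (a segment may count in several
#' classes). Per class, reports the percentage of its segments with MAPQ at
#' or above each cutoff in {1, 10, 20, 30, 60} — the standard ladder for
#' mappability profiling across repeat classes — which is non-increasing in
#' the cutoff by construction. Classes overlapping no segment are omitted.
#'
#' @param segments Segment table (unmapped rows are ignored).
#' @param annotations Data.frame `chrom`, `start`, `end`, `class`.
#' @param cutoffs MAPQ cutoffs (default `c(1, 10, 20, 30, 60)`).
#' @return `data.frame` with `class`, `total_bp` (class territory),
#'   `n_segments`, and one `pct_mapq_ge_<c>` column per cutoff.
#' @export
mapq_class_profile <- function(segments, annotations,
                               cutoffs = c(1L, 10L, 20L, 30L, 60L)) {
  segments <- segment_table(segments)
  segments <- segments[!is.na(segments$chrom), , drop = FALSE]
  gs <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(start = segments$ref_start + 1, end = segments$ref_end))
  out <- lapply(unique(annotations$class), function(cl) {
    r <- annotations[annotations$class == cl, , drop = FALSE]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      r$chrom, IRanges::IRanges(start = r$start + 1, end = r$end)))
    # disjoint chromosome sets are a legitimate "no overlap" case
    hit <- unique(S4Vectors::queryHits(suppressWarnings(
      GenomicRanges::findOverlaps(gs, gr, minoverlap = 1L))))
    if (length(hit) == 0L) return(NULL)
    q <- segments$mapq[hit]
    row <- data.frame(class = cl,
                      total_bp = sum(as.numeric(GenomicRanges::width(gr))),
                      n_segments = length(hit), stringsAsFactors = FALSE)
    for (co in cutoffs)
      row[[paste0("pct_mapq_ge_", co)]] <- 100 * mean(q >= co, na.rm = FALSE)
    row
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) {
    cols <- c("class", "total_bp", "n_segments",
              paste0("pct_mapq_ge_", cutoffs))
    return(stats::setNames(
      as.data.frame(lapply(cols, function(x) character(0)[0])), cols))
  }
  do.call(rbind, out)
}
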