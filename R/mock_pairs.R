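#' Emit mock Illumina-like paired-end records from contact pairs
#'
#' Converts each contact pair into one paired-end template with two mate
#' records, so that multi-contact data can feed tools built for short-read
#' Hi-C (scaffolders, pair-based pipelines): a read with 17 segments (136
#' pairs) becomes 272 mate records. Mate 1 takes up to `mate_length` bases
#' from its source segment's 5' end in read orientation; mate 2 is emitted
#' reverse-complemented, giving the standard FR (forward/reverse) pair
#' orientation. Mate reference coordinates are those of the source segment.
#'
#' @param pairs Pair table derived from `segments` (see [expand_pairwise()]).
#' @param segments Segment table the pairs came from; if it has a `sequence`
#'   column, mate sequences are sliced from it, else sequences are `NA` and
#'   only coordinates are emitted.
#' @param mate_length Mate length in bp (default 150, the conventional
#'   short-read length); must be >= 1.
#' @return `data.frame` with one row per mate: `template_id`, `read_id`,
#'   `mate` (1/2), `segment_index`, `chrom`, `ref_start`, `ref_end`,
#'   `strand`, `mapq`, `sequence`. Exactly `2 * nrow(pairs)` rows.
#' @export
emit_mock_pairs <- function(pairs, segments, mate_length = 150L) {
  mate_length <- as.integer(mate_length)
  if (is.na(mate_length) || mate_length < 1L)
    stop("mate_length must be >= 1")
  segments <- segment_table(segments)
  if (nrow(pairs) == 0L) {
    return(data.frame(template_id = character(0), read_id = character(0),
                      mate = integer(0), segment_index = integer(0),
                      chrom = character(0), ref_start = numeric(0),
                      ref_end = numeric(0), strand = character(0),
                      mapq = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(segments$read_id, segments$segment_index)
  lookup <- function(read_id, seg) match(paste(read_id, seg), key)
  has_seq <- "sequence" %in% names(segments)
  mate_seq <- function(row_idx, revcomp) {
    if (!has_seq) return(rep(NA_character_, length(row_idx)))
    s <- substr(segments$sequence[row_idx], 1L, mate_length)
    if (revcomp)
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(s)))
    s
  }
  one_mate <- function(seg_col, mate_no) {
    ridx <- lookup(pairs$read_id, pairs[[seg_col]])
    if (anyNA(ridx))
      stop("pairs reference segments absent from the segment table")
    data.frame(
      template_id = paste0(pairs$read_id, ":", pairs$seg1, "-", pairs$seg2),
      read_id = pairs$read_id, mate = mate_no,
      segment_index = segments$segment_index[ridx],
      chrom = segments$chrom[ridx],
      ref_start = segments$ref_start[ridx],
      ref_end = segments$ref_end[ridx],
      strand = segments$strand[ridx],
      mapq = segments$mapq[ridx],
      sequence = mate_seq(ridx, mate_no == 2L),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(one_mate("seg1", 1L), one_mate("seg2", 2L))
  out <- out[order(out$template_id, out$mate), ]
  rownames(out) <- NULL
  out
}

#' Write mock paired-end records as SAM
#'
#' Emits a minimal valid SAM file with mandatory paired flags (paired +
#' first/second in pair; mate 2 carries the reverse-strand bit from its
#' FR emission). Coordinates are converted to 1-based on write; unmapped
#' mates get `*` placeholders.
#'
#' @param mock Mate table from [emit_mock_pairs()].
#' @param chrom_lengths Named vector of chromosome lengths for the header.
#' @param path Output path.
#' @export
write_mock_sam <- function(mock, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ch in names(chrom_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch,
                       as.integer(chrom_lengths[[ch]])), con)
  if (nrow(mock) == 0L) return(invisible(path))
  flag <- 0x1 + ifelse(mock$mate == 1L, 0x40, 0x80)
  rev_self <- (mock$mate == 2L) != (mock$strand == "-")  # FR emission
  flag <- flag + ifelse(!is.na(mock$chrom) & rev_self, 0x10, 0)
  unmapped <- is.na(mock$chrom)
  flag <- flag + ifelse(unmapped, 0x4, 0)
  seq <- ifelse(is.na(mock$sequence), "*", mock$sequence)
  lines <- paste(
    mock$template_id, flag,
    ifelse(unmapped, "*", mock$chrom),
    ifelse(unmapped, 0L, as.integer(mock$ref_start) + 1L),
    ifelse(unmapped, 0L, ifelse(is.na(mock$mapq), 0L, mock$mapq)),
    ifelse(unmapped, "*", paste0(nchar(seq), "M")),
    "*", 0L, 0L, seq,
    "*", sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write mock paired-end records as interleaved FASTQ
#'
#' @param mock Mate table from [emit_mock_pairs()] (requires sequences).
#' @param path Output path.
#' @export
write_mock_fastq <- function(mock, path) {
  if (nrow(mock) > 0L && anyNA(mock$sequence))
    stop("mock records lack sequences; emit from segments with sequences")
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(mock)) {
    mock <- mock[order(mock$template_id, mock$mate), ]
    lines <- rbind(paste0("@", mock$template_id, "/", mock$mate),
                   mock$sequence, "+",
                   vapply(nchar(mock$sequence),
                          function(n) strrep("I", n), character(1)))
    writeLines(as.vector(lines), con)
  }
  invisible(path)
}
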