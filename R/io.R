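#' Read and write sequence files
#'
#' Thin wrappers over Biostrings for FASTA/FASTQ (gzip-transparent on
#' read). Sequences travel as named character vectors elsewhere in the
#' package.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              format = "fasta")
  invisible(path)
}

#' @rdname read_fasta
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n) strrep("I", n),
                                     character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write contact pairs in the 4DN pairs text format
#'
#' Emits the standard `## pairs format v1.0` header with `#chromsize` and
#' `#columns` lines; positions are converted to 1-based on write (internal
#' coordinates are 0-based half-open). Only fully mapped pairs can be
#' serialized.
#'
#' @param pairs Pair table (see [expand_pairwise()]).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param path Output path.
#' @param metadata Optional named character vector written as extra
#'   `#key: value` header lines (e.g. the MAPQ threshold applied).
#' @export
write_pairs <- function(pairs, chrom_lengths, path, metadata = NULL) {
  if (any(is.na(pairs$chrom1) | is.na(pairs$chrom2)))
    stop("cannot serialize pairs with unmapped mates; filter first")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## pairs format v1.0", con)
  writeLines("#shape: upper triangle", con)
  for (ch in names(chrom_lengths))
    writeLines(sprintf("#chromsize: %s %d", ch,
                       as.integer(chrom_lengths[[ch]])), con)
  if (!is.null(metadata))
    for (k in names(metadata))
      writeLines(sprintf("#%s: %s", k, metadata[[k]]), con)
  writeLines(paste("#columns: readID chrom1 pos1 chrom2 pos2 strand1",
                   "strand2 mapq1 mapq2"), con)
  if (nrow(pairs))
    writeLines(paste(pairs$read_id, pairs$chrom1,
                     format(pairs$pos1 + 1, scientific = FALSE, trim = TRUE),
                     pairs$chrom2,
                     format(pairs$pos2 + 1, scientific = FALSE, trim = TRUE),
                     pairs$strand1, pairs$strand2,
                     pairs$mapq1, pairs$mapq2, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_pairs
#' @return `read_pairs()`: list with `pairs` (pair table, 0-based
#'   positions, `pair_class`/`distance` recomputed) and `chrom_lengths`.
#' @export
read_pairs <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  cs <- hdr[startsWith(hdr, "#chromsize:")]
  parts <- strsplit(sub("^#chromsize:\\s*", "", cs), "\\s+")
  chrom_lengths <- stats::setNames(
    vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
    vapply(parts, `[[`, character(1), 1))
  if (!length(body)) return(list(pairs = .empty_pairs(),
                                 chrom_lengths = chrom_lengths))
  f <- utils::read.table(text = body, sep = "\t",
                         col.names = c("read_id", "chrom1", "pos1", "chrom2",
                                       "pos2", "strand1", "strand2",
                                       "mapq1", "mapq2"),
                         colClasses = c("character", "character", "numeric",
                                        "character", "numeric", "character",
                                        "character", "integer", "integer"))
  f$pos1 <- f$pos1 - 1
  f$pos2 <- f$pos2 - 1
  f$seg1 <- NA_integer_; f$seg2 <- NA_integer_
  list(pairs = .finalise_pairs(f), chrom_lengths = chrom_lengths)
}

#' Segment table TSV round trip
#'
#' Tab-separated segment tables with a documented header; coordinates stay
#' 0-based half-open (stated in a leading comment line).
#'
#' @param segments Segment table.
#' @param path File path.
#' @export
write_segments_tsv <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# concatemer segment table; coordinates 0-based half-open", con)
  cols <- intersect(c("read_id", "segment_index", "chrom", "ref_start",
                      "ref_end", "strand", "mapq", "haplotype"),
                    names(segments))
  utils::write.table(segments[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_segments_tsv
#' @export
read_segments_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          na.strings = ".", stringsAsFactors = FALSE,
                          colClasses = c(read_id = "character",
                                         chrom = "character"))
  segment_table(df)
}

#' Read BED-style labeled intervals
#'
#' 3+ column BED (0-based half-open); an optional 4th column becomes
#' `label` (for TAD domain/boundary/gap files) or `class` when
#' `as = "annotation"`.
#'
#' @param path BED file path.
#' @param as `"domains"` (default) or `"annotation"`.
#' @return Data.frame suitable for [domain_set()] or
#'   [mapq_class_profile()]/[gap_fraction()].
#' @export
read_bed <- function(path, as = c("domains", "annotation")) {
  as <- match.arg(as)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$chrom <- as.character(df$chrom)
  extra <- if (ncol(df) >= 4) as.character(df[[4]]) else NULL
  if (as == "domains") {
    df$label <- if (is.null(extra)) "domain" else extra
    domain_set(df[, c("chrom", "start", "end", "label")])
  } else {
    df$class <- if (is.null(extra)) "region" else extra
    df[, c("chrom", "start", "end", "class")]
  }
}

#' Ingest aligned segments from SAM/BAM
#'
#' Reads per-segment alignments where each record is one deconcatenated
#' segment and the parent read is recoverable from the record name by the
#' `readid:segindex` delimiter convention; `HP` tags, when present, become
#' the haplotype column. SAM input is converted through `Rsamtools`.
#'
#' @param path SAM or BAM path.
#' @return Segment table.
#' @export
read_segments_sam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "cigar",
             "strand", "mapq"),
    tag = "HP")
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  qname <- b$qname
  has_idx <- grepl(":", qname)
  read_id <- ifelse(has_idx, sub(":[0-9]+$", "", qname), qname)
  seg_idx <- ifelse(has_idx, as.integer(sub("^.*:", "", qname)), 0L)
  unmapped <- bitwAnd(b$flag, 4L) != 0L
  # reference span from CIGAR (M/D/N/=/X consume reference)
  ref_width <- vapply(b$cigar, function(cg) {
    if (is.na(cg)) return(NA_integer_)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    sum(as.integer(sub("[A-Z=]", "", toks[grepl("[MDN=X]$", toks)])))
  }, integer(1), USE.NAMES = FALSE)
  hp <- b$tag$HP
  if (is.null(hp)) hp <- rep(NA_integer_, length(qname))
  segment_table(data.frame(
    read_id = read_id, segment_index = seg_idx,
    chrom = ifelse(unmapped, NA_character_, as.character(b$rname)),
    ref_start = ifelse(unmapped, NA_real_, b$pos - 1),
    ref_end = ifelse(unmapped, NA_real_, b$pos - 1 + ref_width),
    strand = ifelse(unmapped, NA_character_, as.character(b$strand)),
    mapq = ifelse(unmapped, NA_integer_, b$mapq),
    haplotype = as.integer(hp),
    stringsAsFactors = FALSE))
}

#' Write a contact matrix as COO triples with a JSON sidecar header
#'
#' Plain-text `bin1 bin2 count` triples (upper triangle, 1-based bin
#' indices) plus `<path>.json` holding chromosome lengths and bin size.
#'
#' @param m A `contact_matrix`.
#' @param path Output path for the triples.
#' @export
write_matrix_coo <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  tri <- methods::as(methods::as(m$counts, "generalMatrix"), "TsparseMatrix")
  keep <- tri@i <= tri@j
  df <- data.frame(bin1 = tri@i[keep] + 1L, bin2 = tri@j[keep] + 1L,
                   count = tri@x[keep])
  df <- df[order(df$bin1, df$bin2), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(bin_size = m$bin_size,
         chrom_lengths = as.list(m$chrom_lengths)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_matrix_coo
#' @return `read_matrix_coo()`: a `contact_matrix`.
#' @export
read_matrix_coo <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  chrom_lengths <- unlist(meta$chrom_lengths)
  m <- bin_contacts(.empty_pairs(), chrom_lengths, meta$bin_size)
  m$counts <- Matrix::sparseMatrix(i = df$bin1, j = df$bin2, x = df$count,
                                   dims = dim(m$counts), symmetric = TRUE)
  m
}
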