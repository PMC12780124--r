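#' Split one concatemer read at its restriction cut sites
#'
#' A read with k interior cut sites yields k + 1 segments that exactly tile
#' the read; a read with no sites is returned as a single segment.
#'
#' @param sequence Read sequence (character or `DNAString`).
#' @param enz Enzyme (see [enzyme()]).
#' @param read_id Read identifier carried into the output.
#' @param min_length Segments shorter than this are dropped after splitting
#'   (default 0: keep all; the tiling property then holds exactly).
#' @return `data.frame` with columns `read_id`, `segment_index` (0-based),
#'   `start`, `end` (0-based half-open offsets within the read), `sequence`.
#' @examples
#' digest_read("GATCGATC", "DpnII")  # two segments [0,4) [4,8)
#' @export
digest_read <- function(sequence, enz, read_id = "read", min_length = 0L) {
  seq <- toupper(as.character(sequence))
  if (nchar(seq) < 1L) stop("read sequence must be non-empty")
  cuts <- find_cut_sites(seq, enz)
  starts <- c(0L, cuts)
  ends <- c(cuts, nchar(seq))
  keep <- (ends - starts) >= max(0L, as.integer(min_length))
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(
    read_id = rep(read_id, length(starts)),
    segment_index = seq_along(starts) - 1L,
    start = starts, end = ends,
    sequence = substring(seq, starts + 1L, ends),
    stringsAsFactors = FALSE
  )
}

#' Digest many reads
#'
#' @param reads Named character vector or `DNAStringSet`/`QualityScaledDNAStringSet`
#'   of read sequences; names are read ids.
#' @inheritParams digest_read
#' @return Row-bound segment table (see [digest_read()]).
#' @export
digest_reads <- function(reads, enz, min_length = 0L) {
  if (methods::is(reads, "XStringSet")) {
    ids <- names(reads)
    reads <- as.character(reads)
    names(reads) <- ids
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  enz <- enzyme(enz)
  out <- lapply(names(reads), function(id)
    digest_read(reads[[id]], enz, read_id = id, min_length = min_length))
  do.call(rbind, out)
}

#' In silico digestion of a reference genome
#'
#' Cuts every chromosome at the enzyme's sites and returns the resulting
#' restriction-fragment map. Fragments of one chromosome exactly tile
#' `[0, chromosome length)`.
#'
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences (names must be unique).
#' @param enz Enzyme (see [enzyme()]).
#' @return A `fragment_map`: list with `fragments` (`data.frame` of
#'   `fragment_id`, `chrom`, `start`, `end`; 0-based half-open) and
#'   `chrom_lengths` (named integer vector).
#' @export
digest_reference <- function(genome, enz) {
  if (methods::is(genome, "XStringSet")) {
    nm <- names(genome)
    genome <- as.character(genome)
    names(genome) <- nm
  }
  if (is.null(names(genome)) || anyNA(names(genome)))
    stop("genome sequences must be named")
  if (anyDuplicated(names(genome)))
    stop("duplicate chromosome names in genome")
  enz <- enzyme(enz)
  frags <- lapply(names(genome), function(chrom) {
    s <- toupper(genome[[chrom]])
    if (nchar(s) < 1L) stop("chromosome '", chrom, "' is empty")
    cuts <- find_cut_sites(s, enz)
    starts <- c(0L, cuts)
    ends <- c(cuts, nchar(s))
    data.frame(chrom = chrom, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, frags)
  frags <- cbind(fragment_id = seq_len(nrow(frags)) - 1L, frags)
  structure(
    list(fragments = frags,
         chrom_lengths = stats::setNames(nchar(genome), names(genome))),
    class = "fragment_map"
  )
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("<fragment_map> %d fragments over %d chromosome(s), %s bp\n",
              nrow(x$fragments), length(x$chrom_lengths),
              format(sum(as.numeric(x$chrom_lengths)), big.mark = ",")))
  invisible(x)
}

#' Map genomic positions to restriction fragments
#'
#' Binary-search lookup of the unique fragment whose half-open interval
#' contains each position.
#'
#' @param chrom Chromosome name(s), recycled against `position`.
#' @param position 0-based position(s); must lie in `[0, chrom length)`.
#' @param fmap A `fragment_map` from [digest_reference()].
#' @return Integer vector of `fragment_id`s.
#' @export
assign_to_fragment <- function(chrom, position, fmap) {
  stopifnot(inherits(fmap, "fragment_map"))
  n <- max(length(chrom), length(position))
  chrom <- rep_len(as.character(chrom), n)
  position <- rep_len(as.numeric(position), n)
  out <- integer(n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(fmap$chrom_lengths))
      stop("unknown chromosome '", ch, "'")
    idx <- which(chrom == ch)
    pos <- position[idx]
    L <- fmap$chrom_lengths[[ch]]
    if (any(pos < 0 | pos >= L))
      stop("position outside [0, ", L, ") on chromosome '", ch, "'")
    f <- fmap$fragments[fmap$fragments$chrom == ch, ]
    out[idx] <- f$fragment_id[findInterval(pos, f$start)]
  }
  out
}

#' Export a fragment map as BED
#'
#' Writes 0-based half-open BED with fragment ids in the name column.
#'
#' @param fmap A `fragment_map`.
#' @param path Output file path.
#' @export
write_fragments_bed <- function(fmap, path) {
  stopifnot(inherits(fmap, "fragment_map"))
  f <- fmap$fragments
  utils::write.table(
    data.frame(f$chrom, f$start, f$end, paste0("fragment_", f$fragment_id)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
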